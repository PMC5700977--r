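test_that("quarter partitions are balanced, seeded and validated", {
  p <- quarter_partition(418, 4, seed = 1)
  expect_equal(sort(tabulate(p$group_of, 4)), c(104, 104, 105, 105))
  expect_equal(tabulate(quarter_partition(8, 4, seed = 2)$group_of, 4),
               rep(2L, 4))
  expect_identical(quarter_partition(31, 4, seed = 9)$group_of,
                   quarter_partition(31, 4, seed = 9)$group_of)
  expect_error(quarter_partition(3, 4), "more groups than subjects")

  ens <- brain_ensemble(rep(list(subject_graph("s", "a", "b")), 10))
  parts <- split_ensemble(ens, quarter_partition(10, 4, seed = 3))
  expect_equal(sort(vapply(parts, `[[`, 0L, "n")), c(2L, 2L, 3L, 3L))
})

test_that("common items intersect stored edges and touched vertices", {
  atl <- atlas_node_set(letters[1:5])
  tab <- function(...) edge_frequencies(brain_ensemble(list(...), atlas = atl))
  t1 <- tab(subject_graph("1", c("a", "b"), c("b", "c")))
  t2 <- tab(subject_graph("2", c("a", "c"), c("b", "d")))
  expect_equal(common_items(list(t1, t2), "edge"), "a|b")
  expect_setequal(common_items(list(t1, t2), "vertex"), c("a", "b", "c"))
  expect_setequal(common_items(list(t1, t1), "edge"), c("a|b", "b|c"))
  t3 <- tab(subject_graph("3", "d", "e"))
  expect_length(common_items(list(t1, t3), "edge"), 0)
  expect_error(common_items(list(t1), "edge"), "at least 2")
  t4 <- edge_frequencies(brain_ensemble(list(subject_graph("4", "a", "b"))))
  expect_error(common_items(list(t1, t4), "edge"), "different atlases")
})

test_that("identical orders and all-tied orders are never discordant", {
  items <- paste0("e", 1:20)
  o <- random_order(items, 20)
  d <- discordance(list(o, o, o, o), items, n_samples = 5000, seed = 1)
  expect_equal(d$probability, 0)
  tied <- structure(setNames(rep(1L, 20), items), kind = "edge", n = 20,
                    class = "appearance_order")
  d2 <- discordance(list(tied, tied), items, exhaustive = TRUE)
  expect_equal(d2$probability, 0)
})

test_that("exhaustive discordance matches the brute-force oracle", {
  # the 3-item textbook case: only {e2, e3} flips
  o1 <- structure(c(e1 = 1L, e2 = 2L, e3 = 3L), kind = "edge", n = 3,
                  class = "appearance_order")
  o2 <- structure(c(e1 = 1L, e2 = 3L, e3 = 2L), kind = "edge", n = 3,
                  class = "appearance_order")
  d <- discordance(list(o1, o2), paste0("e", 1:3), exhaustive = TRUE)
  expect_equal(d$probability, 1 / 3)

  set.seed(11)
  for (rep in 1:10) {
    items <- paste0("e", 1:8)
    orders <- replicate(3, random_order(items, 8), simplify = FALSE)
    d <- discordance(orders, items, exhaustive = TRUE)
    expect_equal(d$probability,
                 oracle_discordance_exhaustive(lapply(orders, unclass), items))
  }
})

test_that("Monte-Carlo discordance is seed-stable and near the exhaustive value", {
  set.seed(5)
  items <- paste0("e", 1:15)
  orders <- replicate(4, random_order(items, 15), simplify = FALSE)
  exact <- discordance(orders, items, exhaustive = TRUE)$probability
  d1 <- discordance(orders, items, n_samples = 2e5, seed = 3)
  d2 <- discordance(orders, items, n_samples = 2e5, seed = 3)
  expect_identical(d1$probability, d2$probability)
  expect_lt(abs(d1$probability - exact), 4 * d1$standard_error)
  # two seeds agree within 4 combined standard errors
  d3 <- discordance(orders, items, n_samples = 2e5, seed = 77)
  se <- sqrt(d1$standard_error^2 + d3$standard_error^2)
  expect_lt(abs(d1$probability - d3$probability), 4 * se)
  expect_equal(d1$standard_error,
               sqrt(d1$probability * (1 - d1$probability) / d1$n_samples))
})

test_that("cross-ensemble discordance vanishes for identical orders, ~1/2 for independent ones", {
  set.seed(21)
  items <- paste0("e", 1:30)
  oa <- replicate(4, random_order(items, 30), simplify = FALSE)
  same <- cross_ensemble_discordance(oa, oa, items, n_samples = 1e4, seed = 2)
  # each group of A has the identical counterpart in B, but mixed group
  # pairs may still be discordant; identical order lists give 0 only when
  # all groups share one order
  one <- replicate(4, oa[[1L]], simplify = FALSE)
  expect_equal(cross_ensemble_discordance(one, one, items,
                                          n_samples = 1e4, seed = 2)$probability, 0)
  # independent random orders on both sides: discordance is 1/2 up to the
  # finite-item realization noise of the drawn permutations (~1/(3 sqrt(m))
  # per group pair) plus Monte-Carlo error; 0.02 is a > 4-sigma margin here
  items2 <- paste0("e", 1:200)
  oa2 <- replicate(8, random_order(items2, 200), simplify = FALSE)
  ob2 <- replicate(8, random_order(items2, 200), simplify = FALSE)
  ind <- cross_ensemble_discordance(oa2, ob2, items2, n_samples = 2e5, seed = 4)
  expect_lt(abs(ind$probability - 0.5), 0.02)
  expect_s3_class(same, "discordance_estimate")
  expect_error(cross_ensemble_discordance(oa2, ob2, items2[1]), "at least 2")
})
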