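#' Balanced random partition of subjects into groups
#'
#' Partitions n subjects into g disjoint groups whose sizes differ by at
#' most 1 ("quarter sets" for the default g = 4). The assignment is a
#' uniformly random balanced partition, deterministic given the seed.
#'
#' @param n_subjects Number of subjects.
#' @param g Number of groups (default 4).
#' @param seed Integer RNG seed.
#' @return An object of class `quarter_partition`: a list with `group_of`
#'   (integer vector of group ids, one per subject), `g` and `seed`.
#' @examples
#' table(quarter_partition(418, seed = 1)$group_of)  # sizes 105 105 104 104
#' @export
quarter_partition <- function(n_subjects, g = 4L, seed = NULL) {
  n_subjects <- as.integer(n_subjects); g <- as.integer(g)
  if (g < 2L) stop("need at least 2 groups")
  if (g > n_subjects) stop("more groups than subjects")
  if (!is.null(seed)) set.seed(seed)
  sizes <- rep(n_subjects %/% g, g)
  extra <- n_subjects %% g
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  group_of <- integer(n_subjects)
  group_of[sample.int(n_subjects)] <- rep(seq_len(g), sizes)
  structure(list(group_of = group_of, g = g, seed = seed),
            class = "quarter_partition")
}

#' @export
print.quarter_partition <- function(x, ...) {
  cat("Partition of", length(x$group_of), "subjects into", x$g,
      "groups (sizes:", paste(tabulate(x$group_of, x$g), collapse = ", "),
      ")\n")
  invisible(x)
}

#' Split an ensemble by a partition
#'
#' Convenience wrapper: returns one sub-ensemble per group, preserving the
#' shared atlas.
#'
#' @param ensemble A [brain_ensemble].
#' @param partition A [quarter_partition] over the same subject count.
#' @return A list of `g` [brain_ensemble] objects.
#' @export
split_ensemble <- function(ensemble, partition) {
  stopifnot(inherits(ensemble, "brain_ensemble"),
            inherits(partition, "quarter_partition"),
            length(partition$group_of) == ensemble$n)
  lapply(seq_len(partition$g), function(gi)
    brain_ensemble(ensemble$graphs[partition$group_of == gi],
                   atlas = ensemble$atlas))
}

#' Items common to every frequency table
#'
#' The robustness comparison is restricted to items defined in every
#' group: edges present in at least one subject graph of every table, or
#' vertices with at least one stored incident edge in every table.
#'
#' @param tables List of [edge_frequencies] results over the same atlas.
#' @param kind `"edge"` or `"vertex"`.
#' @return Character vector of item names (`"u|v"` for edges, labels for
#'   vertices).
#' @export
common_items <- function(tables, kind = c("edge", "vertex")) {
  kind <- match.arg(kind)
  if (length(tables) < 2L) stop("need at least 2 frequency tables")
  atl <- tables[[1L]]$atlas$labels
  if (!all(vapply(tables, function(t) identical(t$atlas$labels, atl),
                  logical(1))))
    stop("frequency tables are over different atlases")
  items <- lapply(tables, function(t) {
    if (kind == "edge") paste(t$edges$u, t$edges$v, sep = "|")
    else unique(c(t$edges$u, t$edges$v))
  })
  Reduce(intersect, items)
}

new_discordance <- function(p, n_samples, kind, mode, n_items) {
  structure(list(probability = p, n_samples = n_samples,
                 standard_error = sqrt(p * (1 - p) / n_samples),
                 item_kind = kind, mode = mode, n_items = n_items),
            class = "discordance_estimate")
}

#' @export
print.discordance_estimate <- function(x, ...) {
  cat(sprintf(
    "Discordance probability (%s, %s): %.4f +/- %.4f SE\n",
    x$item_kind, x$mode, x$probability, x$standard_error))
  cat("  ", format(x$n_samples, big.mark = ",", scientific = FALSE),
      "sampled pairs over",
      x$n_items, "common items (random-order null: 0.5)\n")
  invisible(x)
}

# discordance of one batch of sampled comparisons: steps_x/steps_y are
# matrices [sample, item 1..2]; strict reversals only, ties concordant
discordant_pairs <- function(sxe, sxf, sye, syf) {
  (sxe < sxf & syf < sye) | (sxf < sxe & sye < syf)
}

sample_distinct <- function(m, n) {
  a <- sample.int(m, n, replace = TRUE)
  b <- a + sample.int(m - 1L, n, replace = TRUE)
  list(a = a, b = (b - 1L) %% m + 1L)
}

#' Monte-Carlo discordance of appearance orders across groups
#'
#' Estimates the probability that two randomly chosen common items appear
#' in strictly opposite order in the CCDs of two randomly chosen distinct
#' groups: over a uniform random ordered pair of distinct groups (X, Y)
#' and a uniform random pair of distinct items {e, f}, the probability of
#' the event "e strictly before f in X and f strictly before e in Y, or
#' vice versa". Ties (equal appearance steps) count as concordant. Under a
#' random-order null the probability is 1/2; the smaller it is, the more
#' robust the appearance order across subject subsets.
#'
#' @param orders List (one per group) of `appearance_order` objects, as
#'   produced by [appearance_orders] on each group's frequency table.
#' @param items Character vector of common item names (see
#'   [common_items]); every item must have a defined step in every order.
#' @param n_samples Number of Monte-Carlo samples (default 1e6). Ignored
#'   when `exhaustive = TRUE`.
#' @param seed Integer RNG seed.
#' @param exhaustive If `TRUE`, enumerate all group pairs and all item
#'   pairs instead of sampling (feasible only for small item sets).
#' @return A `discordance_estimate`: list with `probability`, `n_samples`,
#'   `standard_error = sqrt(p(1-p)/n_samples)`, `item_kind`, `mode`.
#' @export
discordance <- function(orders, items, n_samples = 1e6, seed = NULL,
                        exhaustive = FALSE) {
  if (length(orders) < 2L) stop("need appearance orders for >= 2 groups")
  if (length(items) < 2L) stop("need at least 2 common items")
  kind <- attr(orders[[1L]], "kind")
  steps <- vapply(orders, function(o) {
    s <- unclass(o)[items]
    if (anyNA(s)) stop("an item has no appearance step in some group")
    as.numeric(s)
  }, numeric(length(items)))            # items x groups
  g <- ncol(steps); m <- nrow(steps)
  if (exhaustive) {
    gp <- utils::combn(g, 2L); ip <- utils::combn(m, 2L)
    tot <- 0L; cnt <- 0L
    for (j in seq_len(ncol(gp))) {
      sx <- steps[, gp[1L, j]]; sy <- steps[, gp[2L, j]]
      d <- discordant_pairs(sx[ip[1L, ]], sx[ip[2L, ]],
                            sy[ip[1L, ]], sy[ip[2L, ]])
      tot <- tot + sum(d); cnt <- cnt + length(d)
    }
    return(new_discordance(tot / cnt, cnt, kind, "within-ensemble", m))
  }
  if (!is.null(seed)) set.seed(seed)
  gs <- sample_distinct(g, n_samples)
  is <- sample_distinct(m, n_samples)
  sx <- steps[cbind(c(is$a, is$b), rep(gs$a, 2L))]
  sy <- steps[cbind(c(is$a, is$b), rep(gs$b, 2L))]
  half <- seq_len(n_samples)
  d <- discordant_pairs(sx[half], sx[-half], sy[half], sy[-half])
  new_discordance(mean(d), n_samples, kind, "within-ensemble", m)
}

#' Cross-ensemble discordance
#'
#' Same estimator as [discordance], but group X is drawn from the quarter
#' tables of ensemble A and group Y from those of ensemble B — the generic
#' form of comparing two processing pipelines (e.g. deterministic vs
#' probabilistic tractography) on the same subjects. Items must be common
#' to every quarter table of both ensembles.
#'
#' @param ordersA,ordersB Lists of `appearance_order` objects for the
#'   groups of each ensemble.
#' @param items Common item names across all tables of both ensembles.
#' @inheritParams discordance
#' @return A `discordance_estimate` with mode `"cross-ensemble"`.
#' @export
cross_ensemble_discordance <- function(ordersA, ordersB, items,
                                       n_samples = 1e6, seed = NULL,
                                       exhaustive = FALSE) {
  if (!length(ordersA) || !length(ordersB))
    stop("need appearance orders for both ensembles")
  if (length(items) < 2L) stop("need at least 2 cross-common items")
  kind <- attr(ordersA[[1L]], "kind")
  get_steps <- function(orders) vapply(orders, function(o) {
    s <- unclass(o)[items]
    if (anyNA(s)) stop("an item has no appearance step in some group")
    as.numeric(s)
  }, numeric(length(items)))
  sa <- get_steps(ordersA); sb <- get_steps(ordersB)
  m <- length(items)
  if (exhaustive) {
    ip <- utils::combn(m, 2L)
    tot <- 0L; cnt <- 0L
    for (ga in seq_len(ncol(sa))) for (gb in seq_len(ncol(sb))) {
      sx <- sa[, ga]; sy <- sb[, gb]
      d <- discordant_pairs(sx[ip[1L, ]], sx[ip[2L, ]],
                            sy[ip[1L, ]], sy[ip[2L, ]])
      tot <- tot + sum(d); cnt <- cnt + length(d)
    }
    return(new_discordance(tot / cnt, cnt, kind, "cross-ensemble", m))
  }
  if (!is.null(seed)) set.seed(seed)
  ga <- sample.int(ncol(sa), n_samples, replace = TRUE)
  gb <- sample.int(ncol(sb), n_samples, replace = TRUE)
  is <- sample_distinct(m, n_samples)
  sx <- sa[cbind(c(is$a, is$b), rep(ga, 2L))]
  sy <- sb[cbind(c(is$a, is$b), rep(gb, 2L))]
  half <- seq_len(n_samples)
  d <- discordant_pairs(sx[half], sx[-half], sy[half], sy[-half])
  new_discordance(mean(d), n_samples, kind, "cross-ensemble", m)
}

#' One-call quarter-set robustness analysis
#'
#' Partitions an ensemble into g balanced groups, builds each group's
#' frequency table and appearance order, restricts to the common items and
#' estimates the discordance probability.
#'
#' @param ensemble A [brain_ensemble].
#' @param g Number of groups (default 4).
#' @param kind `"edge"` or `"vertex"`.
#' @param n_samples Monte-Carlo samples.
#' @param seed Integer seed controlling both the partition and the
#'   sampling.
#' @param ensemble_b Optional second ensemble over the same atlas; if
#'   supplied, the cross-ensemble estimator is used (X from `ensemble`,
#'   Y from `ensemble_b`).
#' @return A `discordance_estimate`.
#' @export
quarter_set_robustness <- function(ensemble, g = 4L,
                                   kind = c("edge", "vertex"),
                                   n_samples = 1e6, seed = 1L,
                                   ensemble_b = NULL) {
  kind <- match.arg(kind)
  part <- quarter_partition(ensemble$n, g, seed = seed)
  tabs <- lapply(split_ensemble(ensemble, part), edge_frequencies)
  ords <- lapply(tabs, function(t)
    appearance_orders(t)[[if (kind == "edge") "edges" else "vertices"]])
  if (is.null(ensemble_b)) {
    items <- common_items(tabs, kind)
    discordance(ords, items, n_samples = n_samples, seed = seed + 1L)
  } else {
    part_b <- quarter_partition(ensemble_b$n, g, seed = seed + 2L)
    tabs_b <- lapply(split_ensemble(ensemble_b, part_b), edge_frequencies)
    ords_b <- lapply(tabs_b, function(t)
      appearance_orders(t)[[if (kind == "edge") "edges" else "vertices"]])
    items <- common_items(c(tabs, tabs_b), kind)
    cross_ensemble_discordance(ords, ords_b, items,
                               n_samples = n_samples, seed = seed + 1L)
  }
}
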