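#' Planted developmental-order model for synthetic ensembles
#'
#' Builds a generative model of a braingraph ensemble in which each edge
#' has a latent developmental rank and a per-subject inclusion probability
#' that decreases with rank. The ranks are produced by running the
#' doubly-preferential attachment simulator itself (with C > 0) and
#' recording the order in which edges arrive, so sampled ensembles carry a
#' DPA-like growth structure that the consensus machinery should
#' re-identify. Inclusion probabilities interpolate linearly in rank from
#' `q_max` (rank 1) down to `q_min` (last rank), with `coupling` scaling
#' the spread: `coupling = 0` gives every edge the constant probability
#' `(q_max + q_min)/2` (an exchangeable null with no order signal), while
#' `coupling = 1` gives the full `q_max`..`q_min` gradient.
#'
#' @param N Number of atlas nodes.
#' @param n_edges Number of edges with a planted rank,
#'   `<= choose(N, 2)`.
#' @param coupling Rank-probability coupling strength in `[0, 1]`.
#' @param q_max,q_min Inclusion probabilities of the first and last rank,
#'   `0 < q_min <= q_max <= 1`.
#' @param seed RNG seed for the generating simulation.
#' @param growth Optional [dpa] model to generate the arrival order;
#'   defaults to a small model scaled to N. Its `steps` field is ignored:
#'   the simulation runs until `n_edges` edges have arrived.
#' @return An object of class `planted_model`: list with `atlas`,
#'   `ordered_edges` (2-column character matrix in rank order),
#'   `inclusion_prob` (numeric vector along the ranks) and `coupling`.
#' @examples
#' pm <- planted_model(N = 30, n_edges = 60, coupling = 1, seed = 3)
#' pm
#' @export
planted_model <- function(N, n_edges, coupling = 1, q_max = 0.95,
                          q_min = 0.05, seed = NULL, growth = NULL) {
  N <- as.integer(N); n_edges <- as.integer(n_edges)
  if (n_edges < 1L || n_edges > choose(N, 2))
    stop("n_edges must be in 1..choose(N, 2)")
  if (!(coupling >= 0 && coupling <= 1)) stop("coupling must be in [0, 1]")
  if (!(q_min > 0 && q_min <= q_max && q_max <= 1))
    stop("need 0 < q_min <= q_max <= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(growth))
    growth <- dpa(N = N, A = 8, B = 0.05, C = 0.2 / choose(N, 2),
                  D = min(N, max(6L, N %/% 5L)), steps = 1L)
  labels <- sprintf("v%04d", seq_len(N))
  atlas <- atlas_node_set(labels)
  pp <- pair_index_vectors(N)
  state <- initial_graph(growth$m0, growth$D, N)
  order_ids <- sample(which(state$present))   # initial edges: random ranks
  max_steps <- 10000L
  s <- 0L
  while (length(order_ids) < n_edges && s < max_steps) {
    before <- state$present
    state <- simulate_step(state, growth)
    new <- which(state$present & !before)
    if (length(new) > 1L) new <- sample(new)  # break same-step ties randomly
    order_ids <- c(order_ids, new)
    s <- s + 1L
  }
  if (length(order_ids) < n_edges)
    stop("growth model failed to reach ", n_edges, " edges in ",
         max_steps, " steps")
  order_ids <- order_ids[seq_len(n_edges)]
  ordered_edges <- cbind(u = labels[pp$pu[order_ids]],
                         v = labels[pp$pv[order_ids]])
  mid <- (q_max + q_min) / 2; half <- (q_max - q_min) / 2
  frac <- if (n_edges == 1L) 0 else (seq_len(n_edges) - 1) / (n_edges - 1)
  q <- mid + coupling * half * (1 - 2 * frac)
  structure(list(atlas = atlas, ordered_edges = ordered_edges,
                 inclusion_prob = q, coupling = coupling),
            class = "planted_model")
}

#' @export
print.planted_model <- function(x, ...) {
  cat("Planted developmental-order model:", nrow(x$ordered_edges),
      "ranked edges over", x$atlas$N, "nodes\n")
  cat(sprintf("  coupling = %.2f, inclusion probability %.3f (rank 1) .. %.3f (rank %d)\n",
              x$coupling, x$inclusion_prob[1L],
              x$inclusion_prob[length(x$inclusion_prob)],
              length(x$inclusion_prob)))
  invisible(x)
}

#' Sample a braingraph ensemble from a planted model
#'
#' Each subject graph includes each ranked edge independently with its
#' inclusion probability, so the expected frequency of edge e over n
#' subjects is n q_e and, under positive coupling, early-rank edges appear
#' early in the consensus connectome dynamics of the sampled ensemble.
#'
#' @param model A [planted_model].
#' @param n_subjects Number of subject graphs to draw.
#' @param seed RNG seed.
#' @return A [brain_ensemble] over the model's atlas.
#' @export
sample_ensemble <- function(model, n_subjects, seed = NULL) {
  stopifnot(inherits(model, "planted_model"))
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  q <- model$inclusion_prob
  graphs <- lapply(seq_len(n_subjects), function(s) {
    keep <- stats::runif(length(q)) < q
    subject_graph(sprintf("synth%04d", s),
                  model$ordered_edges[keep, 1L],
                  model$ordered_edges[keep, 2L])
  })
  brain_ensemble(graphs, atlas = model$atlas)
}
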