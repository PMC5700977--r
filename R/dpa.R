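#' Doubly-preferential attachment model
#'
#' Constructs the parameter object of the doubly-preferential attachment
#' (DPA) random-graph model of consensus connectome growth. The graph
#' lives on a fixed set of N nodes; starting from a small random graph on
#' D of them, each step adds every currently absent edge uv independently
#' with probability
#' \deqn{p_{uv} = \frac{B}{2(N-1)}(\deg u + \deg v) + C,}
#' where degrees are taken from the previous step ("doubly" preferential:
#' both endpoints contribute, unlike vertex-arrival preferential
#' attachment where one endpoint is always the new vertex). The B term
#' gives an expected B|E| new edges per step, hence exponential growth of
#' the edge count as roughly floor(A) e^{Bk}; the constant C lets edges
#' appear between zero-degree nodes ("isolated" edges), and the initial
#' edge count is reduced from floor(A) to
#' floor(A - choose(N,2) C/B + 0.5) to compensate for the extra C-edges
#' accumulated over the geometric growth.
#'
#' @param N Number of nodes (default 1015, the atlas size the model
#'   targets).
#' @param A Exponential amplitude: the regression intercept of the
#'   edge-count curve, floor(A) being the nominal initial edge count.
#' @param B Exponential growth rate per step, 0 < B < 1.
#' @param C Per-pair, per-step inclusion probability for isolated edges,
#'   0 <= C < 1.
#' @param D Number of nodes eligible for the initial random graph,
#'   2 <= D <= N. Not identified by the edge-count curve; the default 60
#'   keeps the 18-46-edge initial graph non-trivially connected.
#' @param steps Number of growth steps (default 418, matching step i <->
#'   (n+1-i)-consensus over n = 418 subjects).
#' @param seed Base RNG seed for simulations; run r uses `seed + r - 1`.
#' @return An object of class `dpa`: a list of the validated parameters
#'   plus `m0`, the adjusted initial edge count.
#' @examples
#' model <- dpa(N = 100, A = 10, B = 0.05, C = 1e-5, D = 20, steps = 60)
#' model
#' @export
dpa <- function(N = 1015L, A = 46.37, B = 0.014, C = 7.6e-7, D = 60L,
                steps = 418L, seed = 1L) {
  N <- as.integer(N); D <- as.integer(D); steps <- as.integer(steps)
  if (N < 2L) stop("N must be >= 2")
  if (!(B > 0 && B < 1)) stop("B must be in (0, 1)")
  if (!(C >= 0 && C < 1)) stop("C must be in [0, 1)")
  if (D < 2L || D > N) stop("D must be in 2..N")
  if (steps < 1L) stop("steps must be >= 1")
  m0 <- adjusted_initial_edges(A, B, C, N)
  if (m0 > D * (D - 1) / 2)
    stop("adjusted initial edge count ", m0,
         " exceeds choose(D, 2) = ", D * (D - 1) / 2, "; increase D")
  structure(list(N = N, A = A, B = B, C = C, D = D, steps = steps,
                 seed = as.integer(seed), m0 = m0),
            class = "dpa")
}

#' @export
print.dpa <- function(x, ...) {
  cat("Doubly-preferential attachment model\n")
  cat(sprintf("  N = %d nodes, A = %.4g, B = %.4g, C = %.3g, D = %d, %d steps\n",
              x$N, x$A, x$B, x$C, x$D, x$steps))
  cat(sprintf("  initial graph: %d edges on %d random nodes (floor(A) = %d, C-adjusted)\n",
              x$m0, x$D, floor(x$A)))
  invisible(x)
}

#' @export
coef.dpa <- function(object, ...) {
  c(A = object$A, B = object$B, C = object$C,
    D = as.numeric(object$D), N = as.numeric(object$N))
}

#' Adjusted initial edge count
#'
#' The C term adds an expected choose(N,2) C edges per step; summing their
#' contribution over the (1+B)-fold geometric growth shows the edge count
#' runs ahead of floor(A) e^{Bk} by choose(N,2) C/B. The initial edge
#' count is therefore reduced to floor(A - choose(N,2) C/B + 0.5) (0.5 for
#' rounding to the nearest integer), floored at 0. With C = 0 this is
#' simply floor(A).
#'
#' @inheritParams dpa
#' @return Integer initial edge count.
#' @examples
#' adjusted_initial_edges(46.37, 0.014, 0, 1015)       # 46
#' adjusted_initial_edges(46.37, 0.014, 7.6e-7, 1015)  # 18
#' @export
adjusted_initial_edges <- function(A, B, C, N) {
  if (B <= 0) stop("B must be positive")
  max(0L, as.integer(floor(A - choose(N, 2) * C / B + 0.5)))
}

#' Per-pair inclusion probability
#'
#' Evaluates p_uv = B/(2(N-1)) (deg u + deg v) + C, clipped to [0, 1]
#' (with realistic parameters the clip never triggers: the maximum is
#' B + C < 1). With C = 0 the probability vanishes for a pair of
#' zero-degree nodes, which is why the model cannot create isolated edges
#' without the C term.
#'
#' @param deg_u,deg_v Non-negative integer degrees (vectorized).
#' @param model A [dpa] object (or any list with `N`, `B`, `C`).
#' @return Numeric probability (vector).
#' @export
edge_probability <- function(deg_u, deg_v, model) {
  if (any(deg_u < 0) || any(deg_v < 0)) stop("degrees must be non-negative")
  if (any(deg_u > model$N - 1) || any(deg_v > model$N - 1))
    stop("degrees cannot exceed N - 1")
  pmin(1, pmax(0, model$B / (2 * (model$N - 1)) * (deg_u + deg_v) + model$C))
}

# ---- simulation state ------------------------------------------------------
# Pairs u < v over N nodes are held in fixed linear order; `present` marks
# current edges and `deg` holds per-node degrees, so one step is a single
# vectorized Bernoulli draw over the absent pairs.

.pair_cache <- new.env(parent = emptyenv())

pair_index_vectors <- function(N) {
  key <- as.character(N)
  pp <- .pair_cache[[key]]
  if (is.null(pp)) {
    pu <- rep.int(seq_len(N - 1L), (N - 1L):1L)
    pp <- list(pu = pu, pv = sequence((N - 1L):1L) + pu)
    .pair_cache[[key]] <- pp
  }
  pp
}

# linear index of pair (u, v) with u < v in the pair_index_vectors order
pair_id <- function(u, v, N) (u - 1) * N - u * (u - 1) / 2 + (v - u)

#' Initial random graph of the DPA simulation
#'
#' Chooses D nodes uniformly from the N, then m distinct edges uniformly
#' among their choose(D,2) pairs.
#'
#' @param m Number of initial edges, `0 <= m <= choose(D, 2)`.
#' @param D Number of eligible nodes.
#' @param N Total number of nodes.
#' @param seed Optional RNG seed.
#' @return A `dpa_state`: list with `N`, `present` (logical over all
#'   pairs), `deg`, `step` (0), and per-step logs `new_edges`,
#'   `new_isolated`.
#' @export
initial_graph <- function(m, D, N, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- as.integer(m)
  if (m < 0L || m > D * (D - 1) / 2)
    stop("m must be in 0..choose(D, 2) = ", D * (D - 1) / 2)
  nodes <- sample.int(N, D)
  dp <- pair_index_vectors(D)
  sel <- sample.int(length(dp$pu), m)
  eu <- nodes[dp$pu[sel]]; ev <- nodes[dp$pv[sel]]
  swap <- eu > ev
  if (any(swap)) { tmp <- eu[swap]; eu[swap] <- ev[swap]; ev[swap] <- tmp }
  present <- logical(N * (N - 1L) / 2L)
  present[pair_id(eu, ev, N)] <- TRUE
  structure(list(N = N, present = present,
                 deg = tabulate(c(eu, ev), N), step = 0L,
                 new_edges = integer(0), new_isolated = integer(0)),
            class = "dpa_state")
}

#' One synchronous DPA growth step
#'
#' Every currently absent pair uv is added independently with probability
#' [edge_probability] evaluated at the degrees of the previous step
#' (synchronous update). An added edge is logged as isolated when neither
#' endpoint had positive degree before the step and it shares no endpoint
#' with any other edge added in the same step — i.e. it is isolated in the
#' full post-step graph, mirroring the consensus-connectome definition.
#'
#' @param state A `dpa_state` from [initial_graph] or a previous step.
#' @param model A [dpa] object.
#' @return The updated `dpa_state` (edge set grown monotonically, `step`
#'   incremented, logs appended).
#' @export
simulate_step <- function(state, model) {
  N <- state$N
  pp <- pair_index_vectors(N)
  absent <- which(!state$present)
  coefB <- model$B / (2 * (N - 1))
  p <- coefB * (state$deg[pp$pu[absent]] + state$deg[pp$pv[absent]]) + model$C
  add <- absent[stats::runif(length(absent)) < p]
  n_iso <- 0L
  if (length(add)) {
    au <- pp$pu[add]; av <- pp$pv[add]
    zero <- state$deg[au] == 0L & state$deg[av] == 0L
    inc <- tabulate(c(au, av), N)
    if (any(zero))
      n_iso <- sum(zero & inc[au] == 1L & inc[av] == 1L)
    state$present[add] <- TRUE
    state$deg <- state$deg + inc
  }
  state$step <- state$step + 1L
  state$new_edges <- c(state$new_edges, length(add))
  state$new_isolated <- c(state$new_isolated, n_iso)
  state
}

#' Expected number of new edges (C = 0 analytic check)
#'
#' For the pure preferential part the expected number of new edges in the
#' next step, summed over all pairs without excluding present edges, is
#' \deqn{\sum_{u < v} \frac{B}{2(N-1)}(\deg u + \deg v) = B|E|.}
#' Returns B|E| after verifying the exhaustive pair-sum agrees with it to
#' machine precision — the identity behind the model's exponential growth.
#'
#' @param state A `dpa_state`.
#' @param model A [dpa] object; only `B` and `N` are used (the C term is
#'   excluded from the identity).
#' @return Numeric: B times the current edge count.
#' @export
expected_new_edges <- function(state, model) {
  N <- state$N
  n_edges <- sum(state$present)
  closed <- model$B * n_edges
  # exhaustive sum over all unordered pairs: each deg appears (N-1) times
  pp <- pair_index_vectors(N)
  exhaustive <- sum(model$B / (2 * (N - 1)) *
                      (state$deg[pp$pu] + state$deg[pp$pv]))
  if (abs(exhaustive - closed) > 1e-9 * max(1, closed))
    stop("internal inconsistency: exhaustive pair-sum ", exhaustive,
         " != B|E| = ", closed)
  closed
}

# single full trajectory; returns per-step new edge / isolated counts
run_dpa_once <- function(model, seed) {
  state <- initial_graph(model$m0, model$D, model$N, seed = seed)
  for (s in seq_len(model$steps)) state <- simulate_step(state, model)
  list(edge_count = model$m0 + cumsum(state$new_edges),
       new_edges = state$new_edges,
       new_isolated = state$new_isolated,
       cumulative_isolated = cumsum(state$new_isolated))
}

#' Simulate the DPA model
#'
#' Runs `nsim` independent simulations of the model's full step count and
#' averages the per-step edge counts and cumulative isolated-edge counts.
#' Run r uses seed `seed + r - 1`, so results are reproducible run by run.
#'
#' @param object A [dpa] model.
#' @param nsim Number of independent runs (default 10).
#' @param seed Base seed; defaults to the model's own.
#' @param ... Unused.
#' @return An object of class `dpa_sim`: a list with `model`, `runs`,
#'   `trajectory` (data frame of per-step means with the standard
#'   trajectory columns; `k` equals the step index) and `raw` (per-run
#'   matrices `edge_count` and `cumulative_isolated`, steps x runs).
#' @examples
#' model <- dpa(N = 100, A = 10, B = 0.05, C = 1e-5, D = 20, steps = 50)
#' sim <- simulate(model, nsim = 3, seed = 7)
#' sim
#' @export
simulate.dpa <- function(object, nsim = 10L, seed = NULL, ...) {
  if (nsim < 1L) stop("nsim must be >= 1")
  if (is.null(seed)) seed <- object$seed
  runs <- lapply(seq_len(nsim), function(r) run_dpa_once(object, seed + r - 1L))
  ec <- vapply(runs, `[[`, numeric(object$steps), "edge_count")
  ci <- vapply(runs, `[[`, numeric(object$steps), "cumulative_isolated")
  ne <- vapply(runs, `[[`, numeric(object$steps), "new_edges")
  ni <- vapply(runs, `[[`, numeric(object$steps), "new_isolated")
  ec <- matrix(ec, ncol = nsim); ci <- matrix(ci, ncol = nsim)
  traj <- data.frame(step = seq_len(object$steps), k = seq_len(object$steps),
                     edge_count = rowMeans(ec),
                     new_edges = rowMeans(matrix(ne, ncol = nsim)),
                     new_isolated = rowMeans(matrix(ni, ncol = nsim)),
                     cumulative_isolated = rowMeans(ci))
  structure(list(model = object, runs = nsim, seed = seed,
                 trajectory = traj,
                 raw = list(edge_count = ec, cumulative_isolated = ci)),
            class = "dpa_sim")
}

#' @export
print.dpa_sim <- function(x, ...) {
  tr <- x$trajectory
  last <- nrow(tr)
  cat("DPA simulation:", x$runs, "runs x", last, "steps (N =",
      x$model$N, ")\n")
  cat(sprintf("  mean final edge count: %.1f\n", tr$edge_count[last]))
  cat(sprintf("  mean cumulative isolated edges at final step: %.2f\n",
              tr$cumulative_isolated[last]))
  invisible(x)
}

#' @export
summary.dpa_sim <- function(object, ...) {
  tr <- object$trajectory
  last <- nrow(tr)
  out <- list(runs = object$runs, steps = last, N = object$model$N,
              final_edges = tr$edge_count[last],
              final_edges_range = range(object$raw$edge_count[last, ]),
              isolated_total = tr$cumulative_isolated[last],
              isolated_range = range(object$raw$cumulative_isolated[last, ]))
  class(out) <- "summary.dpa_sim"
  out
}

#' @export
print.summary.dpa_sim <- function(x, ...) {
  cat("DPA simulation summary (", x$runs, " runs, ", x$steps, " steps, N = ",
      x$N, ")\n", sep = "")
  cat(sprintf("  final edge count: mean %.1f (range %.0f..%.0f)\n",
              x$final_edges, x$final_edges_range[1], x$final_edges_range[2]))
  cat(sprintf("  cumulative isolated edges: mean %.2f (range %.0f..%.0f)\n",
              x$isolated_total, x$isolated_range[1], x$isolated_range[2]))
  invisible(x)
}

#' @export
as.data.frame.dpa_sim <- function(x, ...) x$trajectory

#' Plot simulated trajectories
#'
#' Edge count (log scale) and cumulative isolated-edge curves: per-run
#' curves in grey, the across-run mean in black.
#'
#' @param x A `dpa_sim`.
#' @param ... Passed to [graphics::plot].
#' @export
plot.dpa_sim <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  tr <- x$trajectory
  graphics::matplot(tr$step, x$raw$edge_count, type = "l", lty = 1,
                    col = "grey70", log = "y", xlab = "step",
                    ylab = "edges", ...)
  graphics::lines(tr$step, tr$edge_count, lwd = 2)
  graphics::matplot(tr$step, x$raw$cumulative_isolated, type = "l", lty = 1,
                    col = "grey70", xlab = "step",
                    ylab = "cumulative isolated edges", ...)
  graphics::lines(tr$step, tr$cumulative_isolated, lwd = 2)
  invisible(x)
}

#' Fit an exponential growth curve to per-step edge counts
#'
#' Least-squares fit of log(count) against the step index: the model
#' count = A e^{Bk} becomes log(count) = log A + B k, fitted with
#' [stats::lm]. This is the regression that identifies the amplitude A and
#' rate B of a consensus-connectome edge-count curve.
#'
#' @param edge_counts Positive per-step edge counts.
#' @param steps Step indices (default `seq_along(edge_counts)`).
#' @return An object of class `exp_fit`: list with `A`, `B`, `r_squared`
#'   and the underlying `lm` fit.
#' @examples
#' fit_exponential(50 * exp(0.02 * (1:100)))  # recovers A = 50, B = 0.02
#' @export
fit_exponential <- function(edge_counts, steps = seq_along(edge_counts)) {
  if (length(edge_counts) < 3L) stop("need at least 3 points")
  if (any(edge_counts <= 0)) stop("edge counts must be positive")
  fit <- stats::lm(log(edge_counts) ~ steps)
  sst <- sum((log(edge_counts) - mean(log(edge_counts)))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(A = unname(exp(stats::coef(fit)[1L])),
                 B = unname(stats::coef(fit)[2L]),
                 r_squared = r2,
                 lm = fit),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("Exponential fit: %.4g * exp(%.4g k)  (R^2 = %.4f)\n",
              x$A, x$B, x$r_squared))
  invisible(x)
}

#' @export
coef.exp_fit <- function(object, ...) c(A = object$A, B = object$B)

#' Calibrate C against a target isolated-edge total
#'
#' Since two isolated edges rarely appear at the same node in one step,
#' C influences the cumulative isolated-edge total almost linearly: start
#' from a provisional C, simulate, and divide C by the ratio of the
#' simulated total to the target. The step is iterated until the ratio is
#' within `tol` of 1 or `max_iter` is reached.
#'
#' @param model A [dpa] model with a provisional `C > 0`.
#' @param target Desired cumulative isolated-edge total at the final step
#'   (> 0).
#' @param nsim Runs per evaluation (default 10).
#' @param seed Base seed for the simulations.
#' @param tol Relative tolerance on the ratio (default 0.05).
#' @param max_iter Maximum calibration iterations (default 5).
#' @return An object of class `dpa_calibration`: list with `C` (the
#'   calibrated value), `model` (the input model with `C` replaced and the
#'   initial edge count re-adjusted), `history` (data frame of C, simulated
#'   total and ratio per iteration) and `converged`.
#' @export
calibrate_C <- function(model, target, nsim = 10L, seed = NULL,
                        tol = 0.05, max_iter = 5L) {
  stopifnot(inherits(model, "dpa"))
  if (model$C <= 0) stop("provisional C must be positive")
  if (target <= 0) stop("target must be positive")
  if (is.null(seed)) seed <- model$seed
  C <- model$C
  hist <- data.frame(iter = integer(0), C = numeric(0),
                     simulated = numeric(0), ratio = numeric(0))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    m <- dpa(N = model$N, A = model$A, B = model$B, C = C, D = model$D,
             steps = model$steps, seed = model$seed)
    sim <- simulate(m, nsim = nsim, seed = seed + (it - 1L) * nsim)
    total <- sim$trajectory$cumulative_isolated[model$steps]
    if (total <= 0)
      stop("simulation produced no isolated edges with C = ", C,
           "; cannot form the calibration ratio")
    ratio <- total / target
    hist <- rbind(hist, data.frame(iter = it, C = C, simulated = total,
                                   ratio = ratio))
    if (abs(ratio - 1) <= tol) { converged <- TRUE; break }
    C <- C / ratio
  }
  final <- dpa(N = model$N, A = model$A, B = model$B, C = C, D = model$D,
               steps = model$steps, seed = model$seed)
  structure(list(C = C, model = final, history = hist,
                 converged = converged, target = target),
            class = "dpa_calibration")
}

#' @export
print.dpa_calibration <- function(x, ...) {
  cat(sprintf("Calibrated C = %.3g (target %.4g isolated edges, %s in %d iteration%s)\n",
              x$C, x$target,
              if (x$converged) "converged" else "max iterations reached",
              nrow(x$history), if (nrow(x$history) > 1L) "s" else ""))
  invisible(x)
}
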