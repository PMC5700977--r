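#' Per-edge subject frequencies
#'
#' Counts, for every edge occurring anywhere in the ensemble, the number of
#' subject graphs containing it. The frequency table is the quantity that
#' drives all k-consensus logic: an edge is k-frequent iff its frequency is
#' at least k, and the k-consensus connectome is the graph of all
#' k-frequent edges.
#'
#' @param ensemble A [brain_ensemble].
#' @return An object of class `edge_freq_table`: a list with `atlas`, `n`
#'   (subject count) and `edges`, a data frame with columns `u`, `v`
#'   (unordered pair, `u < v`) and `freq` in `1..n`. Pairs absent from
#'   every subject are not stored (frequency 0).
#' @examples
#' ens <- brain_ensemble(list(
#'   subject_graph("s1", c("a", "b"), c("b", "c")),
#'   subject_graph("s2", "a", "b"),
#'   subject_graph("s3", c("a", "c"), c("b", "d"))))
#' edge_frequencies(ens)
#' @export
edge_frequencies <- function(ensemble) {
  stopifnot(inherits(ensemble, "brain_ensemble"))
  keys <- unlist(lapply(ensemble$graphs, function(g) edge_keys(g$edges)))
  tab <- table(keys)
  parts <- strsplit(names(tab), "\t", fixed = TRUE)
  edges <- data.frame(u = vapply(parts, `[`, character(1), 1L),
                      v = vapply(parts, `[`, character(1), 2L),
                      freq = as.integer(tab),
                      stringsAsFactors = FALSE, row.names = NULL)
  new_edge_freq_table(ensemble$atlas, ensemble$n, edges)
}

new_edge_freq_table <- function(atlas, n, edges) {
  structure(list(atlas = atlas, n = as.integer(n), edges = edges),
            class = "edge_freq_table")
}

#' @export
print.edge_freq_table <- function(x, ...) {
  cat("Edge frequency table: n =", x$n, "subjects,", nrow(x$edges),
      "distinct edges over", x$atlas$N, "atlas nodes\n")
  if (nrow(x$edges))
    cat("  frequency range:", min(x$edges$freq), "..", max(x$edges$freq),
        "(", sum(x$edges$freq == x$n), "edges present in every subject )\n")
  invisible(x)
}

check_k <- function(table, k) {
  if (length(k) != 1L || is.na(k) || k != as.integer(k) ||
      k < 1L || k > table$n)
    stop("k must be a single integer in 1..n = 1..", table$n)
  as.integer(k)
}

#' k-consensus connectome
#'
#' Returns the edge set of the k-consensus connectome: all edges present in
#' at least k of the n subject graphs. For k = 1 this is the union of all
#' subject edge sets; for k = n, their intersection. The sets are nested:
#' the j-consensus connectome is contained in the i-consensus connectome
#' whenever i <= j.
#'
#' @param table An [edge_frequencies] result.
#' @param k Integer threshold, `1 <= k <= n`.
#' @return A 2-column character matrix of unordered edges.
#' @export
k_consensus <- function(table, k) {
  stopifnot(inherits(table, "edge_freq_table"))
  k <- check_k(table, k)
  e <- table$edges
  as.matrix(e[e$freq >= k, c("u", "v")])
}

#' Newly appearing isolated edges at threshold k
#'
#' An edge is isolated in the k-consensus connectome if it newly appears
#' there (it was not in the (k+1)-consensus connectome, i.e. its frequency
#' is exactly k) and, in the graph formed by all edges of the k-consensus
#' connectome, neither of its endpoints touches any other edge. Two edges
#' that appear at the same step but share a vertex are therefore not
#' isolated. For k = n the predecessor is the empty graph.
#'
#' @inheritParams k_consensus
#' @return Integer count of new isolated edges at this k.
#' @export
new_isolated_count <- function(table, k) {
  stopifnot(inherits(table, "edge_freq_table"))
  k <- check_k(table, k)
  e <- table$edges
  ink <- e$freq >= k
  if (!any(ink)) return(0L)
  vlab <- table$atlas$labels
  # degree within the k-consensus graph
  deg <- tabulate(match(c(e$u[ink], e$v[ink]), vlab), table$atlas$N)
  new <- which(e$freq == k)
  sum(deg[match(e$u[new], vlab)] == 1L & deg[match(e$v[new], vlab)] == 1L)
}

#' CCD trajectory
#'
#' The Consensus Connectome Dynamics trajectory records, for each step
#' i = 1..n with k = n+1-i, the size of the k-consensus connectome, the
#' number of edges that newly appear at that step, how many of those new
#' edges are isolated, and the running total of isolated edges. Decreasing
#' k from n to 1 relaxes the inclusion condition, so the edge count is
#' non-decreasing and the consensus graphs grow into the structured,
#' tree-like pattern the trajectory quantifies (a small isolated-edge total
#' is the signature of that structure).
#'
#' @param table An [edge_frequencies] result.
#' @return An object of classes `ccd_trajectory` and `data.frame` with
#'   columns `step`, `k`, `edge_count`, `new_edges`, `new_isolated`,
#'   `cumulative_isolated`, and attribute `n` (subject count).
#' @export
ccd_trajectory <- function(table) {
  stopifnot(inherits(table, "edge_freq_table"))
  n <- table$n
  e <- table$edges
  vlab <- table$atlas$labels
  ui <- match(e$u, vlab); vi <- match(e$v, vlab)
  edge_count <- new_edges <- new_iso <- integer(n)
  deg <- integer(table$atlas$N)
  cum <- 0L; prev_count <- 0L
  for (i in seq_len(n)) {
    k <- n + 1L - i
    idx <- which(e$freq == k)            # edges entering at this step
    if (length(idx)) {
      deg <- deg + tabulate(c(ui[idx], vi[idx]), table$atlas$N)
      iso <- sum(deg[ui[idx]] == 1L & deg[vi[idx]] == 1L)
    } else iso <- 0L
    prev_count <- prev_count + length(idx)
    edge_count[i] <- prev_count
    new_edges[i] <- length(idx)
    new_iso[i] <- iso
    cum <- cum + iso
  }
  structure(data.frame(step = seq_len(n), k = n:1, edge_count = edge_count,
                       new_edges = new_edges, new_isolated = new_iso,
                       cumulative_isolated = cumsum(new_iso)),
            n = n, class = c("ccd_trajectory", "data.frame"))
}

#' @export
print.ccd_trajectory <- function(x, ...) {
  n <- attr(x, "n")
  cat("CCD trajectory over n =", n, "subjects (step i <-> (n+1-i)-consensus)\n")
  cat("  edges:", x$edge_count[1L], "at k =", n, "->",
      x$edge_count[n], "at k = 1\n")
  cat("  cumulative isolated edges:", x$cumulative_isolated[n], "\n")
  invisible(x)
}

#' Plot a CCD trajectory
#'
#' Draws the edge count (log scale) and the cumulative isolated-edge count
#' against the step index.
#'
#' @param x A `ccd_trajectory`.
#' @param ... Passed to [graphics::plot].
#' @export
plot.ccd_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(x$step, pmax(x$edge_count, 1), type = "l", log = "y",
                 xlab = "step i (k = n+1-i)", ylab = "edges in consensus", ...)
  graphics::plot(x$step, x$cumulative_isolated, type = "s",
                 xlab = "step i", ylab = "cumulative isolated edges", ...)
  invisible(x)
}

#' Appearance orders of edges and vertices
#'
#' As k decreases from n to 1 the consensus connectomes grow; the
#' appearance step of an edge with frequency f is n+1-f, the step at which
#' it first enters the sequence. A vertex appears at the earliest
#' appearance step of its incident edges. Items absent from every subject
#' never appear and are not listed. Ties (equal steps) are allowed.
#'
#' @param table An [edge_frequencies] result.
#' @return A list with components `edges` and `vertices`, each of class
#'   `appearance_order`: a named integer vector of steps in `1..n` (names
#'   are `"u|v"` edge labels or vertex labels) with attributes `kind` and
#'   `n`.
#' @export
appearance_orders <- function(table) {
  stopifnot(inherits(table, "edge_freq_table"))
  n <- table$n
  e <- table$edges
  estep <- n + 1L - e$freq
  names(estep) <- paste(e$u, e$v, sep = "|")
  vstep <- tapply(c(estep, estep), c(e$u, e$v), min)
  vstep <- stats::setNames(as.integer(vstep), names(vstep))
  list(edges = structure(estep, kind = "edge", n = n,
                         class = "appearance_order"),
       vertices = structure(vstep, kind = "vertex", n = n,
                            class = "appearance_order"))
}

#' @export
print.appearance_order <- function(x, ...) {
  cat("Appearance order of", length(x), attr(x, "kind"),
      "items (steps 1..", attr(x, "n"), ")\n", sep = " ")
  invisible(x)
}
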