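#' Atlas node set
#'
#' An atlas is the shared, labeled node set of a braingraph ensemble: one
#' node per anatomically identified gray-matter region (ROI). All subject
#' graphs of an ensemble are defined over the same atlas, so edges can be
#' compared across subjects by label.
#'
#' @param labels Character vector of unique node labels (ROI names).
#' @return An object of class `atlas`, a list with `labels` and `N`.
#' @examples
#' atlas_node_set(c("lh.precentral", "rh.precentral", "brainstem"))
#' @export
atlas_node_set <- function(labels) {
  labels <- as.character(labels)
  if (anyNA(labels) || any(!nzchar(labels)))
    stop("atlas labels must be non-missing, non-empty strings")
  if (anyDuplicated(labels))
    stop("atlas labels must be unique")
  if (length(labels) < 2L)
    stop("an atlas needs at least 2 nodes")
  structure(list(labels = labels, N = length(labels)), class = "atlas")
}

#' @export
print.atlas <- function(x, ...) {
  cat("Atlas with", x$N, "nodes:",
      paste(utils::head(x$labels, 4L), collapse = ", "),
      if (x$N > 4L) "..." else "", "\n")
  invisible(x)
}

# canonical unordered-pair representation: 2-column character matrix with
# u < v lexicographically per row, no self-loops, no duplicates
canonical_edges <- function(u, v) {
  u <- as.character(u); v <- as.character(v)
  keep <- u != v                       # drop self-loops
  u <- u[keep]; v <- v[keep]
  swap <- u > v
  if (any(swap)) { tmp <- u[swap]; u[swap] <- v[swap]; v[swap] <- tmp }
  m <- cbind(u = u, v = v)
  m[!duplicated(edge_keys(m)), , drop = FALSE]
}

# internal string key of an unordered edge; "\t" never occurs in labels read
# from GraphML/TSV (it is the TSV field separator)
edge_keys <- function(edges) {
  if (nrow(edges) == 0L) return(character(0))
  paste(edges[, 1L], edges[, 2L], sep = "\t")
}

#' Subject braingraph
#'
#' A single subject's connectome: an undirected simple graph given by its
#' edge set over atlas node labels. Self-loops are dropped and parallel
#' edges collapsed on construction.
#'
#' @param subject_id Subject identifier (string).
#' @param u,v Character vectors of equal length: the two endpoints of each
#'   edge.
#' @return An object of class `subject_graph` with fields `subject_id` and
#'   `edges` (2-column character matrix, each row an unordered pair).
#' @examples
#' subject_graph("s1", c("a", "b"), c("b", "c"))
#' @export
subject_graph <- function(subject_id, u = character(0), v = character(0)) {
  if (length(u) != length(v)) stop("u and v must have equal length")
  structure(list(subject_id = as.character(subject_id)[1L],
                 edges = canonical_edges(u, v)),
            class = "subject_graph")
}

#' @export
print.subject_graph <- function(x, ...) {
  cat("Subject braingraph", sQuote(x$subject_id), "with",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Braingraph ensemble
#'
#' Bundles n subject graphs over one shared atlas. If no atlas is supplied
#' it is built as the sorted union of all node labels occurring in the
#' graphs. Every edge endpoint must be an atlas label.
#'
#' @param graphs List of [subject_graph] objects.
#' @param atlas Optional [atlas_node_set]; defaults to the label union.
#' @return An object of class `brain_ensemble` with fields `atlas`,
#'   `graphs` and `n`.
#' @examples
#' g1 <- subject_graph("s1", "a", "b")
#' g2 <- subject_graph("s2", c("a", "c"), c("b", "d"))
#' brain_ensemble(list(g1, g2))
#' @export
brain_ensemble <- function(graphs, atlas = NULL) {
  if (!length(graphs)) stop("an ensemble needs at least one subject graph")
  if (!all(vapply(graphs, inherits, logical(1), "subject_graph")))
    stop("graphs must be a list of subject_graph objects")
  labs <- unique(unlist(lapply(graphs, function(g) as.vector(g$edges))))
  if (is.null(atlas)) {
    atlas <- atlas_node_set(sort(labs))
  } else {
    stopifnot(inherits(atlas, "atlas"))
    unknown <- setdiff(labs, atlas$labels)
    if (length(unknown))
      stop("node label(s) not in atlas: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
  }
  structure(list(atlas = atlas, graphs = graphs, n = length(graphs)),
            class = "brain_ensemble")
}

#' @export
print.brain_ensemble <- function(x, ...) {
  ec <- vapply(x$graphs, function(g) nrow(g$edges), integer(1))
  cat("Braingraph ensemble: n =", x$n, "subjects over", x$atlas$N,
      "atlas nodes\n")
  cat("  edges per subject: min", min(ec), "/ median", stats::median(ec),
      "/ max", max(ec), "\n")
  invisible(x)
}
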