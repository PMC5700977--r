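#' Read a subject braingraph from GraphML
#'
#' Reads one subject's connectome from a GraphML file (the distribution
#' format of downloadable braingraph ensembles). The graph must be
#' undirected unless `symmetrize = TRUE`, in which case edge directions are
#' discarded. Self-loops are dropped, parallel edges collapsed, and all
#' edge weights/attributes ignored: consensus construction uses edge
#' presence only.
#'
#' @param path Path to a GraphML file.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @param label_attr Vertex attribute to use as the node label. The default
#'   prefers a `name` attribute (which igraph fills from GraphML node ids
#'   or a "name" key) and falls back to `id`, then to vertex position.
#' @param symmetrize If `TRUE`, a directed GraphML declaration is accepted
#'   and symmetrized; if `FALSE` (default) it is rejected.
#' @return A [subject_graph].
#' @export
read_graphml <- function(path, subject_id = NULL,
                         label_attr = c("name", "id"),
                         symmetrize = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::is_directed(g)) {
    if (!symmetrize)
      stop("GraphML file declares a directed graph: ", path,
           " (use symmetrize = TRUE to accept it)")
    g <- igraph::as_undirected(g, mode = "collapse")
  }
  attrs <- igraph::vertex_attr_names(g)
  lab <- NULL
  for (a in label_attr) if (a %in% attrs) {
    lab <- as.character(igraph::vertex_attr(g, a)); break
  }
  if (is.null(lab)) lab <- as.character(seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g, names = FALSE)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  subject_graph(subject_id, lab[el[, 1L]], lab[el[, 2L]])
}

#' Read a subject braingraph from an edge-list TSV
#'
#' Plain-text alternative to GraphML: two tab-separated node-label columns,
#' one edge per line, `#` comments allowed, no header required.
#'
#' @inheritParams read_graphml
#' @return A [subject_graph].
#' @export
read_edgelist <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.table(path, sep = "\t", comment.char = "#",
                         colClasses = "character", header = FALSE,
                         quote = "", blank.lines.skip = TRUE)
  if (ncol(d) < 2L) stop("edge-list TSV needs two tab-separated columns: ", path)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  subject_graph(subject_id, d[[1L]], d[[2L]])
}

#' Read a braingraph ensemble from files
#'
#' Reads one graph per path (GraphML by default, `.tsv`/`.txt` as edge-list
#' TSV) and assembles them into an ensemble over a common atlas. Subject
#' order equals path order.
#'
#' @param paths Character vector of file paths, one subject each.
#' @param atlas Optional [atlas_node_set] fixing the node set; labels found
#'   in a file but absent from a supplied atlas are an error. If `NULL`,
#'   the atlas is the sorted union of labels across files.
#' @param ... Passed on to [read_graphml].
#' @return A [brain_ensemble] with `n = length(paths)`.
#' @export
read_ensemble <- function(paths, atlas = NULL, ...) {
  if (!length(paths)) stop("read_ensemble needs at least one path")
  graphs <- lapply(paths, function(p) {
    if (grepl("\\.(tsv|txt)$", p, ignore.case = TRUE)) read_edgelist(p)
    else read_graphml(p, ...)
  })
  brain_ensemble(graphs, atlas = atlas)
}

#' Write a subject braingraph to GraphML
#'
#' @param graph A [subject_graph].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "subject_graph"))
  labs <- sort(unique(as.vector(graph$edges)))
  g <- igraph::make_empty_graph(n = length(labs), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = labs)
  if (nrow(graph$edges))
    g <- igraph::add_edges(g, rbind(match(graph$edges[, 1L], labs),
                                    match(graph$edges[, 2L], labs)))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

trajectory_cols <- c("step", "k", "edge_count", "new_edges",
                     "new_isolated", "cumulative_isolated")

#' Write a trajectory table to TSV
#'
#' Serializes a CCD trajectory ([ccd_trajectory]) or a simulated trajectory
#' ([simulate.dpa]) as a TSV with columns `step`, `k`, `edge_count`,
#' `new_edges`, `new_isolated`, `cumulative_isolated`. For simulations the
#' averaged curves are written and `k` equals the step index.
#'
#' @param traj A `ccd_trajectory` or `dpa_sim` object, or a data frame with
#'   the trajectory columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  d <- as.data.frame(traj)
  missing_cols <- setdiff(trajectory_cols, names(d))
  if (length(missing_cols))
    stop("trajectory lacks column(s): ", paste(missing_cols, collapse = ", "))
  utils::write.table(d[trajectory_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a trajectory TSV written by [write_trajectory]
#'
#' @param path Path to a trajectory TSV.
#' @return A data frame with the trajectory columns.
#' @export
read_trajectory <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE)
  missing_cols <- setdiff(trajectory_cols, names(d))
  if (length(missing_cols))
    stop("not a trajectory TSV (missing ",
         paste(missing_cols, collapse = ", "), "): ", path)
  d
}
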