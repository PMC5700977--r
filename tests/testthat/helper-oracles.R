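# Independent oracles and fixture builders shared by the tests.
# Oracles deliberately use a different code path from the package
# (edge-by-edge rebuilds, igraph degrees) so agreement is informative.

ekeys <- function(edges) {
  if (!nrow(edges)) return(character(0))
  paste(edges[, 1L], edges[, 2L])
}

toy_table <- function() {
  edge_frequencies(brain_ensemble(list(
    subject_graph("s1", c("a", "b"), c("b", "c")),
    subject_graph("s2", "a", "b"),
    subject_graph("s3", c("a", "c"), c("b", "d")))))
}

# random frequency table over N labeled nodes and n subjects
random_table <- function(N, n, p_edge = 0.4) {
  labels <- letters[seq_len(N)]
  pairs <- t(utils::combn(labels, 2L))
  keep <- stats::runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) pairs <- t(utils::combn(labels, 2L))[1, , drop = FALSE]
  freq <- sample.int(n, nrow(pairs), replace = TRUE)
  # edge e is present in subjects 1..freq(e), realizing the frequencies exactly
  graphs <- lapply(seq_len(n), function(s) {
    inc <- s <= freq
    subject_graph(paste0("s", s), pairs[inc, 1L], pairs[inc, 2L])
  })
  edge_frequencies(brain_ensemble(graphs,
                                  atlas = atlas_node_set(labels)))
}

# brute-force re-derivation of new_isolated_count: rebuild the k-consensus
# graph as an igraph object and test both defining conditions per edge
oracle_new_isolated <- function(table, k) {
  ek <- k_consensus(table, k)
  if (!nrow(ek)) return(0L)
  prev <- if (k == table$n) matrix(character(0), 0, 2)
          else k_consensus(table, k + 1L)
  prev_keys <- if (nrow(prev)) paste(prev[, 1], prev[, 2]) else character(0)
  g <- igraph::graph_from_edgelist(ek, directed = FALSE)
  deg <- igraph::degree(g)
  cnt <- 0L
  for (i in seq_len(nrow(ek))) {
    key <- paste(ek[i, 1], ek[i, 2])
    if (key %in% prev_keys) next
    if (deg[[ek[i, 1]]] == 1L && deg[[ek[i, 2]]] == 1L) cnt <- cnt + 1L
  }
  cnt
}

# exhaustive discordance over all group pairs and item pairs, written as a
# plain double loop over ordered comparisons
oracle_discordance_exhaustive <- function(step_list, items) {
  g <- length(step_list)
  disc <- 0L; tot <- 0L
  for (x in seq_len(g - 1L)) for (y in (x + 1L):g) {
    sx <- step_list[[x]][items]; sy <- step_list[[y]][items]
    m <- length(items)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      tot <- tot + 1L
      if ((sx[i] < sx[j] && sy[j] < sy[i]) ||
          (sx[j] < sx[i] && sy[i] < sy[j])) disc <- disc + 1L
    }
  }
  disc / tot
}

random_order <- function(items, n) {
  structure(stats::setNames(sample.int(length(items)), items),
            kind = "edge", n = n, class = "appearance_order")
}

# minimal hand-written GraphML (independent of igraph's writer)
graphml_text <- function(edges, directed = FALSE) {
  nodes <- unique(as.vector(edges))
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">\n',
    '<graph id="G" edgedefault="', if (directed) "directed" else "undirected",
    '">\n',
    paste0('<node id="', nodes, '"/>', collapse = "\n"), "\n",
    if (nrow(edges))
      paste0('<edge source="', edges[, 1L], '" target="', edges[, 2L], '"/>',
             collapse = "\n") else "",
    "\n</graph>\n</graphml>\n")
}

write_graphml_fixture <- function(edges, dir = tempdir(), directed = FALSE,
                                  name = "g") {
  path <- file.path(dir, paste0(name, ".graphml"))
  writeLines(graphml_text(edges, directed), path)
  path
}
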