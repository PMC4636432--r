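# shared fixtures: all graphs are built in code

# sample ER graphs until a connected one appears (caller controls the seed)
random_connected_graph <- function(n, p, directed = FALSE, max_tries = 1000L) {
  for (k in seq_len(max_tries)) {
    g <- er_graph(n, p, directed = directed)
    if (is_connected_graph(g)) return(g)
  }
  stop("no connected graph found")
}

# two disjoint undirected triangles: the canonical disconnected fixture
two_component_graph <- function() {
  g <- igraph::make_empty_graph(6, directed = FALSE)
  igraph::add_edges(g, c(1, 2, 2, 3, 3, 1, 4, 5, 5, 6, 6, 4))
}

# directed graph from a 0-based edge matrix
dgraph <- function(n, edges) {
  g <- igraph::make_empty_graph(n, directed = TRUE)
  if (length(edges)) g <- igraph::add_edges(g, t(matrix(edges, ncol = 2, byrow = TRUE) + 1L))
  g
}

# well-mixed Bd mutant-count rates: the tri-diagonal chain of the complete
# graph without self-replacement, used as an independent route to the
# well-mixed closed form
bd_wellmixed_rates <- function(r, n) {
  j <- seq_len(n - 1)
  tp <- (j * r / (j * r + n - j)) * (n - j) / (n - 1)
  tm <- ((n - j) / (j * r + n - j)) * j / (n - 1)
  chain_rates(tp, tm)
}
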