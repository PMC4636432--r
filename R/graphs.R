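#' @importFrom igraph vcount ecount degree is_connected as_edgelist
#'   graph_from_edgelist make_full_graph make_ring make_star make_empty_graph
#'   sample_gnp is_directed isomorphic add_edges components
NULL

#' Erdos-Renyi random graph
#'
#' Samples one G(N, p) graph: every possible link (ordered pair for directed
#' graphs, unordered pair otherwise) is present independently with probability
#' `p`; self-loops are never created. This is the ensemble generator behind
#' [run_sweep()]; draws are reproducible under [set.seed()].
#'
#' @param n number of nodes (positive integer).
#' @param p link probability in `[0, 1]`; `p = 0` and `p = 1` are allowed and
#'   give the empty and complete graph respectively.
#' @param directed logical; sample each ordered pair independently if `TRUE`.
#' @return an [igraph][igraph::aaa-igraph-package] graph with `n` nodes.
#' @examples
#' set.seed(1)
#' g <- er_graph(6, 0.5)
#' igraph::ecount(g)
#' @export
er_graph <- function(n, p, directed = FALSE) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == round(n))
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  igraph::sample_gnp(n, p, directed = directed, loops = FALSE)
}

#' Named graphs used as references and fixtures
#'
#' `graph_complete()` is the well-mixed population, `graph_cycle()` the ring,
#' `graph_star()` a hub with `n - 1` leaves, and `graph_directed_line()` the
#' chain `0 -> 1 -> ... -> n-1`, the textbook one-rooted suppressor.
#'
#' @param n number of nodes.
#' @return an igraph graph.
#' @export
graph_complete <- function(n) igraph::make_full_graph(n, directed = FALSE)

#' @rdname graph_complete
#' @export
graph_cycle <- function(n) igraph::make_ring(n, directed = FALSE)

#' @rdname graph_complete
#' @export
graph_star <- function(n) igraph::make_star(n, mode = "undirected", center = 1)

#' @rdname graph_complete
#' @export
graph_directed_line <- function(n) {
  g <- igraph::make_empty_graph(n, directed = TRUE)
  if (n >= 2) g <- igraph::add_edges(g, rbind(seq_len(n - 1L), seq_len(n - 1L) + 1L))
  g
}

#' Connectivity of the evolutionary substrate
#'
#' A graph is connected when every node can reach every other node, ignoring
#' link direction for directed graphs (weak connectivity). Mutants on a
#' disconnected graph can never occupy every node, so the fixation probability
#' is 0 and such graphs are set aside by the classification.
#'
#' @param g an igraph graph.
#' @return logical.
#' @export
is_connected_graph <- function(g) {
  if (igraph::vcount(g) == 0L) return(FALSE)
  igraph::is_connected(g, mode = "weak")
}

#' Node temperatures and isothermality
#'
#' The temperature of a node is the total replacement weight flowing into it:
#' under Bd, the sum of `1/outdeg(i)` over in-neighbours `i` (how often the
#' node is displaced by a neighbour's offspring); under dB, the chance per step
#' that the node dies and is refilled, which is `1/N` for every node with at
#' least one in-neighbour. A graph is isothermal when all temperatures are
#' equal; for unweighted undirected graphs under Bd this coincides with
#' degree-regularity. Isothermal graphs under Bd have exactly the well-mixed
#' fixation probability; no analogous theorem holds for dB.
#'
#' @param g a connected igraph graph.
#' @param rule `"Bd"` or `"dB"`.
#' @param tol numerical tolerance for equality of temperatures.
#' @return `node_temperatures()`: numeric vector, one entry per node;
#'   `is_isothermal()`: logical.
#' @export
node_temperatures <- function(g, rule = c("Bd", "dB")) {
  rule <- match.arg(rule)
  n <- igraph::vcount(g)
  el <- ordered_edges(g)
  temp <- numeric(n)
  if (nrow(el) == 0L) return(temp)
  if (rule == "Bd") {
    outdeg <- tabulate(el[, 1L], nbins = n)
    w <- 1 / outdeg[el[, 1L]]
    for (k in seq_len(nrow(el))) temp[el[k, 2L]] <- temp[el[k, 2L]] + w[k]
  } else {
    indeg <- tabulate(el[, 2L], nbins = n)
    temp[indeg > 0L] <- 1 / n
  }
  temp
}

#' @rdname node_temperatures
#' @export
is_isothermal <- function(g, rule = c("Bd", "dB"), tol = 1e-12) {
  temp <- node_temperatures(g, rule)
  diff(range(temp)) <= tol
}

#' Root census of a directed graph
#'
#' A root is a node with in-degree zero and positive out-degree: nothing can
#' ever displace it. A one-rooted graph fixes a randomly placed mutant with
#' probability exactly `1/N` (the mutant must land on the root); on a
#' multi-rooted graph fixation is impossible.
#'
#' @param g a directed igraph graph.
#' @return list with `n_roots` and `classification` (one of `"none"`,
#'   `"one_rooted"`, `"multi_rooted"`).
#' @export
root_census <- function(g) {
  if (!igraph::is_directed(g)) {
    stop("root_census() is defined for directed graphs only")
  }
  indeg <- igraph::degree(g, mode = "in")
  outdeg <- igraph::degree(g, mode = "out")
  n_roots <- sum(indeg == 0L & outdeg > 0L)
  cls <- if (n_roots == 0L) "none" else if (n_roots == 1L) "one_rooted" else "multi_rooted"
  list(n_roots = n_roots, classification = cls)
}

#' Number of source components of a directed graph
#'
#' Counts strongly connected components with no incoming link from outside.
#' A single mutant can only fix if one source component's lineage can seed the
#' whole graph and the mutant starts inside it; with more than one source
#' component fixation is impossible from any single start.
#'
#' @param g a directed igraph graph.
#' @return integer count of source components.
#' @keywords internal
n_source_components <- function(g) {
  comp <- igraph::components(g, mode = "strong")
  m <- comp$membership
  el <- igraph::as_edgelist(g, names = FALSE)
  has_in <- logical(comp$no)
  if (nrow(el) > 0L) {
    cross <- m[el[, 1L]] != m[el[, 2L]]
    has_in[unique(m[el[cross, 2L]])] <- TRUE
  }
  sum(!has_in)
}

#' All connected undirected graphs on four nodes
#'
#' Enumerates the \eqn{2^6} labelled graphs on 4 nodes, keeps the connected
#' ones, and removes isomorphic duplicates. There are exactly six: the path,
#' the star, the triangle with a pendant node, the cycle, the
#' cycle-plus-chord ("diamond"), and the complete graph. Only the cycle and
#' the complete graph are degree-regular.
#'
#' @return named list of six igraph graphs.
#' @examples
#' length(connected_n4_graphs())
#' @export
connected_n4_graphs <- function() {
  pairs <- t(utils::combn(4L, 2L))
  reps <- list()
  for (mask in 0:63) {
    sel <- bitwAnd(mask, 2L^(0:5)) > 0L
    if (sum(sel) < 3L) next  # fewer than n-1 edges cannot be connected
    g <- igraph::make_empty_graph(4L, directed = FALSE)
    g <- igraph::add_edges(g, t(pairs[sel, , drop = FALSE]))
    if (!is_connected_graph(g)) next
    if (!any(vapply(reps, function(h) igraph::isomorphic(g, h), logical(1L)))) {
      reps[[length(reps) + 1L]] <- g
    }
  }
  # stable, degree-sequence-based names
  nm <- vapply(reps, function(g) {
    ds <- paste(sort(igraph::degree(g)), collapse = "")
    switch(ds,
      "1122" = "path", "1113" = "star", "1223" = "triangle_pendant",
      "2222" = "cycle", "2233" = "diamond", "3333" = "complete",
      paste0("deg", ds)
    )
  }, character(1L))
  names(reps) <- nm
  reps[order(vapply(reps, igraph::ecount, numeric(1L)), nm)]
}

# ordered edge list (0-based not used here; igraph is 1-based internally).
# For undirected graphs each link is returned in both directions.
ordered_edges <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  if (!igraph::is_directed(g) && nrow(el) > 0L) {
    el <- rbind(el, el[, 2:1, drop = FALSE])
  }
  storage.mode(el) <- "integer"
  el
}

#' Read and write plain-text edge lists
#'
#' The format is one header line `N <directed|undirected>` followed by one
#' `i j` pair per line with 0-based node indices; undirected links are stored
#' once. Isolated nodes are preserved through the header count.
#'
#' @param g an igraph graph.
#' @param path file path.
#' @return `read_edgelist()` returns an igraph graph; `write_edgelist()`
#'   returns `path` invisibly.
#' @export
write_edgelist <- function(g, path) {
  header <- paste(igraph::vcount(g),
                  if (igraph::is_directed(g)) "directed" else "undirected")
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  lines <- c(header, sprintf("%d %d", el[, 1L], el[, 2L]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path) {
  lines <- readLines(path)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(header) != 2L || !header[2L] %in% c("directed", "undirected")) {
    stop("malformed edge-list header in ", path)
  }
  n <- as.integer(header[1L])
  directed <- header[2L] == "directed"
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  g <- igraph::make_empty_graph(n, directed = directed)
  if (length(body) > 0L) {
    parts <- do.call(rbind, strsplit(trimws(body), "\\s+"))
    el <- matrix(as.integer(parts), ncol = 2L) + 1L
    if (any(el < 1L) || any(el > n)) stop("edge endpoint out of range in ", path)
    if (any(el[, 1L] == el[, 2L])) stop("self-loop in ", path)
    g <- igraph::add_edges(g, t(el))
  }
  g
}
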