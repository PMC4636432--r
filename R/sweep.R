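#' Configuration of an ensemble sweep
#'
#' Describes one Erdos-Renyi classification experiment: for every link
#' probability in `p_grid`, `graphs_per_p` graphs of size `n_nodes` are
#' sampled, each is classified under `rule`, and the category proportions
#' are tallied. Every graph gets its own sub-seed derived from `seed`, so
#' any single graph can be regenerated exactly.
#'
#' @param n_nodes graph size (full solves are practical up to about 14).
#' @param p_grid link probabilities; default 21 evenly spaced values on
#'   `[0, 1]`.
#' @param graphs_per_p graphs sampled per grid point (default 200).
#' @param rule `"Bd"` or `"dB"`.
#' @param directed sample directed graphs?
#' @param seed base RNG seed for the whole sweep.
#' @param classification a [classification_config()].
#' @return list of class `sweep_config`.
#' @export
sweep_config <- function(n_nodes, p_grid = seq(0, 1, length.out = 21),
                         graphs_per_p = 200L, rule = c("Bd", "dB"),
                         directed = FALSE, seed = 1L,
                         classification = classification_config()) {
  rule <- match.arg(rule)
  stopifnot(n_nodes >= 2, n_nodes <= 14,
            all(p_grid >= 0), all(p_grid <= 1), graphs_per_p >= 1,
            is.finite(seed), inherits(classification, "classification_config"))
  structure(list(n_nodes = as.integer(n_nodes), p_grid = p_grid,
                 graphs_per_p = as.integer(graphs_per_p), rule = rule,
                 directed = directed, seed = as.integer(seed),
                 classification = classification),
            class = "sweep_config")
}

# deterministic sub-seed for graph k of grid point pi, kept below 2^31
subseed <- function(seed, pi, k) {
  (as.numeric(seed) * 1000003 + pi * 7919 + k) %% 2147483629
}

#' Run an Erdos-Renyi classification sweep
#'
#' For each `p` in the grid, samples graphs, classifies each with
#' [classify_graph()], and aggregates counts and proportions per category.
#' Analytic overlays are attached for comparison with the empirical
#' fractions: the connectivity probability ([p_connected()]), the
#' isothermal probability at `N = 4` ([p_isothermal_n4()]), and for
#' directed ensembles the probability of an in-degree-zero node
#' ([p_has_root()]). Deterministic given the config (including its seed).
#'
#' @param cfg a [sweep_config()].
#' @param keep_graphs store each sampled graph's edge list in the per-graph
#'   records (default `TRUE`; switch off for very large sweeps).
#' @return object of class `sweep_result`: `counts` and `proportions`
#'   (data.frames, one row per `p`, one column per label plus the
#'   subdivided `unclassified_margin` / `unclassified_mixed`), `overlays`,
#'   `graphs` (per-graph records: `p`, `subseed`, `label`, `margin`,
#'   edge list string), and the `config`.
#' @export
run_sweep <- function(cfg, keep_graphs = TRUE) {
  stopifnot(inherits(cfg, "sweep_config"))
  labs <- GRAPH_CLASS_LABELS
  counts <- matrix(0L, nrow = length(cfg$p_grid), ncol = length(labs) + 2L,
                   dimnames = list(NULL, c(labs, "unclassified_margin",
                                           "unclassified_mixed")))
  recs <- vector("list", length(cfg$p_grid) * cfg$graphs_per_p)
  ri <- 0L
  for (pi in seq_along(cfg$p_grid)) {
    p <- cfg$p_grid[pi]
    for (k in seq_len(cfg$graphs_per_p)) {
      ss <- subseed(cfg$seed, pi, k)
      set.seed(ss)
      g <- er_graph(cfg$n_nodes, p, directed = cfg$directed)
      cl <- classify_graph(g, cfg$rule, cfg$classification)
      counts[pi, cl$label] <- counts[pi, cl$label] + 1L
      if (identical(cl$label, "unclassified")) {
        col <- paste0("unclassified_", cl$unclassified_kind)
        counts[pi, col] <- counts[pi, col] + 1L
      }
      ri <- ri + 1L
      recs[[ri]] <- data.frame(
        p = p, subseed = ss, label = cl$label,
        margin = if (is.na(cl$margin)) NA_real_ else cl$margin,
        edges = if (keep_graphs) edgelist_string(g) else NA_character_)
    }
  }
  props <- counts[, labs, drop = FALSE] / cfg$graphs_per_p
  overlays <- data.frame(
    p = cfg$p_grid,
    p_connected = p_connected(cfg$n_nodes, cfg$p_grid),
    p_disconnected = 1 - p_connected(cfg$n_nodes, cfg$p_grid))
  if (cfg$n_nodes == 4L && !cfg$directed) {
    overlays$p_isothermal <- p_isothermal_n4(cfg$p_grid)
  }
  if (cfg$directed) {
    overlays$p_has_root <- p_has_root(cfg$n_nodes, cfg$p_grid)
  }
  structure(list(counts = data.frame(p = cfg$p_grid, counts,
                                     check.names = FALSE),
                 proportions = data.frame(p = cfg$p_grid, props,
                                          check.names = FALSE),
                 overlays = overlays,
                 graphs = do.call(rbind, recs[seq_len(ri)]),
                 config = cfg),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("ER sweep: N = %d, %s, %s, %d p-values x %d graphs (seed %d)\n",
              cfg$n_nodes, cfg$rule,
              if (cfg$directed) "directed" else "undirected",
              length(cfg$p_grid), cfg$graphs_per_p, cfg$seed))
  tot <- colSums(x$counts[, -1, drop = FALSE])
  tot <- tot[tot > 0]
  cat("totals:", paste(names(tot), tot, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# one-line edge-list encoding "i-j;i-j;..." (0-based), for per-graph records
edgelist_string <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  if (nrow(el) == 0L) return("")
  paste(sprintf("%d-%d", el[, 1L], el[, 2L]), collapse = ";")
}

#' Exhaustive census of the connected four-node graphs
#'
#' Classifies all six connected undirected graphs on four nodes (up to
#' isomorphism) under the given rule and reports the exact fixation
#' probability of a randomly placed mutant at each probe fitness. Under Bd
#' the four degree-heterogeneous graphs are amplifiers and the two regular
#' graphs (cycle, complete) match the well-mixed population; under dB the
#' cycle is the lone graph that is neither amplifier nor suppressor.
#'
#' @param rule `"Bd"` or `"dB"`.
#' @param cfg a [classification_config()].
#' @return data.frame with one row per graph: `graph`, `label`, `margin`,
#'   and one `phi_r<value>` column per probe fitness (reference values in
#'   attribute `"reference"`).
#' @export
run_n4_census <- function(rule = c("Bd", "dB"), cfg = classification_config()) {
  rule <- match.arg(rule)
  graphs <- connected_n4_graphs()
  r_all <- sort(unique(c(cfg$r_disadvantageous, 1, cfg$r_advantageous)))
  rows <- lapply(names(graphs), function(nm) {
    g <- graphs[[nm]]
    cl <- classify_graph(g, rule, cfg)
    phi <- vapply(r_all, function(r) fixation_probability(g, r, rule)$uniform_avg,
                  numeric(1L))
    out <- data.frame(graph = nm, label = cl$label, margin = cl$margin)
    out[paste0("phi_r", r_all)] <- as.list(phi)
    out
  })
  res <- do.call(rbind, rows)
  attr(res, "reference") <- data.frame(
    r = r_all, phi_ref = vapply(r_all, reference_phi, numeric(1L),
                                n = 4L, rule = rule))
  res
}

#' Write and re-read sweep results
#'
#' `write_sweep()` writes `<stem>.csv` (long table: `p`, `label`, `count`,
#' `proportion`, plus analytic overlay columns repeated per row) and
#' `<stem>.json` (full config echo, seed, and per-graph records including
#' edge lists), such that re-running the identical config reproduces the
#' CSV byte for byte. `read_sweep()` restores the result from the JSON.
#'
#' @param res a `sweep_result`.
#' @param stem output path without extension.
#' @return `write_sweep()`: invisible character vector of the two paths;
#'   `read_sweep()`: a `sweep_result`.
#' @export
write_sweep <- function(res, stem) {
  stopifnot(inherits(res, "sweep_result"))
  labs <- GRAPH_CLASS_LABELS
  long <- do.call(rbind, lapply(seq_along(res$counts$p), function(i) {
    data.frame(p = res$counts$p[i], label = labs,
               count = as.integer(res$counts[i, labs]),
               proportion = as.numeric(res$proportions[i, labs]))
  }))
  long <- merge(long, res$overlays, by = "p", sort = TRUE)
  long <- long[order(long$p, match(long$label, labs)), , drop = FALSE]
  csv <- paste0(stem, ".csv")
  json <- paste0(stem, ".json")
  utils::write.csv(long, csv, row.names = FALSE)
  cfg <- res$config
  payload <- list(
    config = list(n_nodes = cfg$n_nodes, p_grid = cfg$p_grid,
                  graphs_per_p = cfg$graphs_per_p, rule = cfg$rule,
                  directed = cfg$directed, seed = cfg$seed,
                  classification = unclass(cfg$classification)),
    counts = res$counts, proportions = res$proportions,
    overlays = res$overlays, graphs = res$graphs)
  jsonlite::write_json(payload, json, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(c(csv = csv, json = json))
}

#' @rdname write_sweep
#' @param path path to a `<stem>.json` written by `write_sweep()`.
#' @export
read_sweep <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cc <- payload$config$classification
  cfg <- sweep_config(
    n_nodes = payload$config$n_nodes, p_grid = payload$config$p_grid,
    graphs_per_p = payload$config$graphs_per_p, rule = payload$config$rule,
    directed = payload$config$directed, seed = payload$config$seed,
    classification = classification_config(cc$r_disadvantageous,
                                           cc$r_advantageous,
                                           cc$equality_tolerance))
  structure(list(counts = payload$counts, proportions = payload$proportions,
                 overlays = payload$overlays, graphs = payload$graphs,
                 config = cfg),
            class = "sweep_result")
}
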