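#' Classification settings
#'
#' The classification probes the fixation probability at a small set of
#' fitness values: one disadvantageous (`r = 0.75` by default) and three
#' advantageous (`1.25, 1.5, 1.75`). `r = 1` is also evaluated as a sanity
#' check (`phi = 1/N` exactly) but takes no part in the decision.
#' Differences from the reference smaller than `equality_tolerance` in
#' absolute value count as ties, i.e. as neither strict inequality.
#'
#' @param r_disadvantageous fitness values below 1 used in the decision.
#' @param r_advantageous fitness values above 1 used in the decision.
#' @param equality_tolerance absolute tolerance for calling
#'   `phi_G == phi_M`.
#' @return a list of class `classification_config`.
#' @export
classification_config <- function(r_disadvantageous = 0.75,
                                  r_advantageous = c(1.25, 1.5, 1.75),
                                  equality_tolerance = 1e-9) {
  stopifnot(all(r_disadvantageous > 0), all(r_disadvantageous < 1),
            all(r_advantageous > 1), equality_tolerance > 0)
  structure(list(r_disadvantageous = r_disadvantageous,
                 r_advantageous = r_advantageous,
                 equality_tolerance = equality_tolerance),
            class = "classification_config")
}

#' Well-mixed reference fixation probability for a rule
#'
#' Dispatches to the closed form matching the update rule — the reference
#' population must use the same microscopic process as the graph, because
#' Bd and dB well-mixed fixation probabilities differ at small `N`.
#'
#' @param r mutant fitness.
#' @param n population size.
#' @param rule `"Bd"` or `"dB"`.
#' @return fixation probability of the well-mixed population of size `n`.
#' @export
reference_phi <- function(r, n, rule = c("Bd", "dB")) {
  rule <- match.arg(rule)
  if (rule == "Bd") phi_wellmixed_bd(r, n) else phi_wellmixed_db(r, n)
}

#' Classify a graph as amplifier or suppressor of selection
#'
#' Applies the study's decision procedure in order: (1) disconnected graphs
#' are set aside (fixation probability 0); (2) directed graphs are screened
#' for roots — one-rooted graphs fix with probability `1/N`, multi-rooted
#' (or multi-source) graphs never fix; (3) under Bd, isothermal graphs have
#' exactly the well-mixed fixation probability (isothermal theorem) and are
#' labelled `wellmixed_equivalent` without solving; (4) otherwise
#' \eqn{\phi^G(r)} is computed exactly at every configured fitness and
#' compared with the rule-matched well-mixed reference \eqn{\phi^M(r)}:
#'
#' * **amplifier** — \eqn{\phi^G < \phi^M} at every disadvantageous `r`
#'   and \eqn{\phi^G > \phi^M} at every advantageous `r`;
#' * **suppressor** — both patterns reversed;
#' * **wellmixed_equivalent** — \eqn{|\phi^G - \phi^M|} within tolerance
#'   at every configured `r`;
#' * **unclassified** — anything else (e.g. the cycle under dB, which lies
#'   below the reference on both sides of `r = 1`).
#'
#' @param g an igraph graph.
#' @param rule `"Bd"` or `"dB"`.
#' @param cfg a [classification_config()].
#' @return object of class `graph_class`: `label`, `phi_values` (data.frame
#'   with `r`, `phi_graph`, `phi_ref`, `delta`), `margin` (smallest
#'   `|delta|` over decision fitnesses, `NA` if a short-circuit fired),
#'   `unclassified_kind` (`"margin"` if some decision delta was within
#'   tolerance, `"mixed"` for a genuinely mixed sign pattern, `NA`
#'   otherwise), `technically_suppressor` (`TRUE` for one-rooted graphs),
#'   `n`, `rule`.
#' @examples
#' classify_graph(graph_star(5), "Bd")$label # amplifier
#' classify_graph(graph_star(5), "dB")$label # suppressor
#' @export
classify_graph <- function(g, rule = c("Bd", "dB"), cfg = classification_config()) {
  rule <- match.arg(rule)
  stopifnot(inherits(cfg, "classification_config"))
  n <- igraph::vcount(g)
  res <- function(label, phi_values = NULL, margin = NA_real_,
                  unclassified_kind = NA_character_) {
    structure(list(label = label, phi_values = phi_values, margin = margin,
                   unclassified_kind = unclassified_kind,
                   technically_suppressor = identical(label, "one_rooted"),
                   n = n, rule = rule),
              class = "graph_class")
  }
  if (!is_connected_graph(g)) return(res("disconnected"))
  if (igraph::is_directed(g)) {
    if (n_source_components(g) > 1L) return(res("multi_rooted"))
    if (root_census(g)$classification == "one_rooted") return(res("one_rooted"))
  }
  if (rule == "Bd" && is_isothermal(g, "Bd")) return(res("wellmixed_equivalent"))

  r_dec <- c(cfg$r_disadvantageous, cfg$r_advantageous)
  r_all <- sort(unique(c(r_dec, 1)))
  phi_g <- vapply(r_all, function(r) fixation_probability(g, r, rule)$uniform_avg,
                  numeric(1L))
  phi_m <- vapply(r_all, reference_phi, numeric(1L), n = n, rule = rule)
  tab <- data.frame(r = r_all, phi_graph = phi_g, phi_ref = phi_m,
                    delta = phi_g - phi_m)
  dec <- tab[tab$r %in% r_dec, ]
  tol <- cfg$equality_tolerance
  below <- dec$delta < -tol
  above <- dec$delta > tol
  adv <- dec$r > 1
  margin <- min(abs(dec$delta))
  label <- if (all(abs(dec$delta) <= tol)) {
    "wellmixed_equivalent"
  } else if (all(below[!adv]) && all(above[adv])) {
    "amplifier"
  } else if (all(above[!adv]) && all(below[adv])) {
    "suppressor"
  } else {
    "unclassified"
  }
  kind <- if (label != "unclassified") NA_character_
          else if (any(abs(dec$delta) <= tol)) "margin" else "mixed"
  res(label, phi_values = tab, margin = margin, unclassified_kind = kind)
}

#' @export
print.graph_class <- function(x, ...) {
  cat(sprintf("Graph classification (%s, N = %d): %s", x$rule, x$n, x$label))
  if (!is.na(x$margin)) cat(sprintf("  (min decision margin %.3e)", x$margin))
  cat("\n")
  if (!is.null(x$phi_values)) print(x$phi_values, row.names = FALSE)
  invisible(x)
}

GRAPH_CLASS_LABELS <- c("amplifier", "suppressor", "unclassified",
                        "wellmixed_equivalent", "disconnected",
                        "one_rooted", "multi_rooted")
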