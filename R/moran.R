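#' @useDynLib moranfix, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom Matrix sparseMatrix Diagonal solve rowSums
#' @importFrom methods as
NULL

MAX_N_FULL_SOLVE <- 20L  # 2^20 states; beyond this the state space is absurd

# bit of node i (1-based); states are bitmask integers in [0, 2^n)
node_bits <- function(n) as.integer(2L^(0:(n - 1L)))

# popcount lookup table for all states 0..2^n-1 (indexed state + 1)
popcount_table <- function(n) {
  pc <- integer(2L^n)
  for (b in node_bits(n)) pc[bitwAnd(seq_along(pc) - 1L, b) > 0L] <- pc[bitwAnd(seq_along(pc) - 1L, b) > 0L] + 1L
  pc
}

#' Replacement weights of a graph under an update rule
#'
#' Under Bd updating the reproducing node `i` places its offspring on each
#' out-neighbour with weight `1/outdeg(i)`; the weights are
#' fitness-independent. Under dB updating the dying node `i` is refilled by
#' its in-neighbours competing proportionally to fitness, so only the
#' neutral weight `1/(N * indeg(i))` per candidate edge is fixed up front;
#' the fitness weighting is applied state by state when transitions are
#' built.
#'
#' @param g an igraph graph.
#' @param rule `"Bd"` or `"dB"`.
#' @return data.frame with columns `from`, `to` (1-based node indices) and
#'   `weight`.
#' @export
replacement_weights <- function(g, rule = c("Bd", "dB")) {
  rule <- match.arg(rule)
  n <- igraph::vcount(g)
  el <- ordered_edges(g)
  if (rule == "Bd") {
    outdeg <- tabulate(el[, 1L], nbins = n)
    w <- 1 / outdeg[el[, 1L]]
  } else {
    indeg <- tabulate(el[, 2L], nbins = n)
    if (any(indeg == 0L)) {
      stop("dB updating needs every node to have an in-neighbour; ",
           "rooted graphs are handled by fixation_probability()")
    }
    w <- 1 / (n * indeg[el[, 2L]])
  }
  data.frame(from = el[, 1L], to = el[, 2L], weight = w)
}

#' One-step transition distribution of the Moran process
#'
#' Computes the exact distribution over successor mutant configurations from
#' one configuration, by direct enumeration of birth/death events. A
#' configuration is a bitmask integer in `[0, 2^N)` whose bit `i - 1` is set
#' when node `i` carries the mutant. Bd: node `i` reproduces with
#' probability `f_i / F` (fitness `r` for mutants, 1 for wild-types; nodes
#' with no out-neighbour are excluded from the lottery) and its offspring
#' replaces out-neighbour `j` with probability `1/outdeg(i)`. dB: node `i`
#' dies with probability `1/N` and in-neighbour `j` fills the slot with
#' probability `f_j / sum of in-neighbour fitnesses`.
#'
#' @param g an igraph graph.
#' @param config bitmask integer in `[0, 2^N)`.
#' @param r mutant fitness, `r > 0`.
#' @param rule `"Bd"` or `"dB"`.
#' @return named numeric vector of probabilities; names are successor
#'   configuration bitmasks. Sums to 1.
#' @export
step_distribution <- function(g, config, r, rule = c("Bd", "dB")) {
  rule <- match.arg(rule)
  stopifnot(r > 0)
  n <- igraph::vcount(g)
  stopifnot(config >= 0, config < 2^n)
  bit <- node_bits(n)
  is_mut <- bitwAnd(config, bit) > 0L
  f <- ifelse(is_mut, r, 1)
  el <- ordered_edges(g)
  out <- new.env()
  add <- function(s, p) {
    key <- as.character(s)
    out[[key]] <- (if (is.null(out[[key]])) 0 else out[[key]]) + p
  }
  if (rule == "Bd") {
    outdeg <- tabulate(el[, 1L], nbins = n)
    active <- outdeg > 0L
    Ftot <- sum(f[active])
    stay <- 0
    for (k in seq_len(nrow(el))) {
      i <- el[k, 1L]; j <- el[k, 2L]
      p <- f[i] / Ftot / outdeg[i]
      if (is_mut[i] == is_mut[j]) stay <- stay + p
      else add(if (is_mut[i]) config + bit[j] else config - bit[j], p)
    }
    add(config, stay)
  } else {
    indeg <- tabulate(el[, 2L], nbins = n)
    if (any(indeg == 0L)) stop("dB updating needs every node to have an in-neighbour")
    stay <- 0
    for (i in seq_len(n)) {
      nb <- el[el[, 2L] == i, 1L]
      W <- sum(f[nb])
      for (j in nb) {
        p <- (1 / n) * f[j] / W
        if (is_mut[j] == is_mut[i]) stay <- stay + p
        else add(if (is_mut[j]) config + bit[i] else config - bit[i], p)
      }
    }
    add(config, stay)
  }
  res <- unlist(as.list(out))
  res[order(as.numeric(names(res)))]
}

#' Canonical-form transition model of the Moran process on a graph
#'
#' Builds the absorbing Markov chain over all `2^N` mutant configurations
#' and returns it in canonical form: the `t = 2^N - 2` transient states
#' first (ordered by bitmask value), then the two absorbing states
#' (extinction, fixation). `Q` holds transient-to-transient probabilities as
#' a sparse matrix; `R` the transitions into the absorbing pair. The build
#' is vectorised over states, one pass per directed link.
#'
#' @inheritParams step_distribution
#' @param g a graph on which the process has no unreachable recurrent class:
#'   connected, and for dB every node must have an in-neighbour. Use
#'   [fixation_probability()] for arbitrary graphs; it applies the
#'   structural short-circuits first.
#' @return an object of class `transition_model` with elements `Q`
#'   (`t x t` sparse), `R` (`t x 2`, columns extinction/fixation),
#'   `state_index` (bitmask of each transient row), `n`, `r`, `rule`.
#' @examples
#' m <- transition_model(graph_complete(4), r = 2, rule = "Bd")
#' dim(m$Q) # 14 x 14
#' @export
transition_model <- function(g, r, rule = c("Bd", "dB")) {
  rule <- match.arg(rule)
  stopifnot(r > 0)
  n <- igraph::vcount(g)
  stopifnot(n >= 2, n <= MAX_N_FULL_SOLVE)
  S <- 2L^n
  states <- 0:(S - 1L)
  bit <- node_bits(n)
  pc <- popcount_table(n)
  el <- ordered_edges(g)
  if (nrow(el) == 0L) stop("graph has no links")

  tri_from <- integer(0); tri_to <- integer(0); tri_p <- numeric(0)
  push <- function(from, to, p) {
    tri_from <<- c(tri_from, from); tri_to <<- c(tri_to, to); tri_p <<- c(tri_p, p)
  }

  if (rule == "Bd") {
    outdeg <- tabulate(el[, 1L], nbins = n)
    active_mask <- sum(bit[outdeg > 0L])
    n_act <- sum(outdeg > 0L)
    m_act <- pc[bitwAnd(states, active_mask) + 1L]
    Ftot <- r * m_act + (n_act - m_act)
    for (k in seq_len(nrow(el))) {
      i <- el[k, 1L]; j <- el[k, 2L]
      bi <- bitwAnd(states, bit[i]) > 0L
      bj <- bitwAnd(states, bit[j]) > 0L
      up <- which(bi & !bj)
      dn <- which(!bi & bj)
      if (length(up)) push(states[up], states[up] + bit[j], r / (Ftot[up] * outdeg[i]))
      if (length(dn)) push(states[dn], states[dn] - bit[j], 1 / (Ftot[dn] * outdeg[i]))
    }
  } else {
    indeg <- tabulate(el[, 2L], nbins = n)
    if (any(indeg == 0L)) {
      stop("dB updating needs every node to have an in-neighbour; ",
           "rooted graphs are handled by fixation_probability()")
    }
    in_mask <- vapply(seq_len(n), function(i) sum(bit[el[el[, 2L] == i, 1L]]), numeric(1L))
    for (i in seq_len(n)) {
      m_i <- pc[bitwAnd(states, as.integer(in_mask[i])) + 1L]
      W <- r * m_i + (indeg[i] - m_i)
      bi <- bitwAnd(states, bit[i]) > 0L
      for (j in el[el[, 2L] == i, 1L]) {
        bj <- bitwAnd(states, bit[j]) > 0L
        up <- which(bj & !bi)
        dn <- which(!bj & bi)
        if (length(up)) push(states[up], states[up] + bit[i], r / (n * W[up]))
        if (length(dn)) push(states[dn], states[dn] - bit[i], 1 / (n * W[dn]))
      }
    }
  }

  # off-diagonal mass, then diagonal = 1 - row sum; duplicates accumulate
  M <- Matrix::sparseMatrix(i = tri_from + 1L, j = tri_to + 1L, x = tri_p,
                            dims = c(S, S))
  diag_mass <- 1 - Matrix::rowSums(M)
  trans <- 2:(S - 1L)  # states 1 .. 2^n - 2
  Q <- M[trans, trans, drop = FALSE] +
    Matrix::Diagonal(length(trans), diag_mass[trans])
  R <- as.matrix(M[trans, c(1L, S), drop = FALSE])
  colnames(R) <- c("extinction", "fixation")
  structure(list(Q = as(Q, "CsparseMatrix"), R = R,
                 state_index = states[trans], n = n, r = r, rule = rule),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("Moran transition model (%s): N = %d, r = %g, %d transient states\n",
              x$rule, x$n, x$r, nrow(x$Q)))
  invisible(x)
}

#' Fixation probabilities from a canonical-form model
#'
#' Solves the absorption equations `(I - Q) Phi = R` of the fundamental-
#' matrix identity `Phi = (I - Q)^{-1} R` with one sparse linear solve (the
#' inverse is never formed). Rows of `Phi` corresponding to single-mutant
#' configurations give the fixation probability from each initial node; the
#' headline quantity is their uniform average, the fixation probability of a
#' mutant placed on a node chosen uniformly at random.
#'
#' @param model a [transition_model()].
#' @param tol residual tolerance: the max-norm residual of the linear solve
#'   must be below it.
#' @return object of class `fixation_result`: `per_node` (length `N`),
#'   `uniform_avg`, `per_state_fixation`, `per_state_extinction`, `r`,
#'   `rule`, `n`, `method`.
#' @export
fixation_probabilities <- function(model, tol = 1e-9) {
  stopifnot(inherits(model, "transition_model"))
  t_ <- nrow(model$Q)
  A <- Matrix::Diagonal(t_) - model$Q
  X <- tryCatch(
    as.matrix(Matrix::solve(A, model$R)),
    error = function(e) {
      stop("(I - Q) is singular: the chain has an unhandled recurrent class ",
           "(use fixation_probability() so structural short-circuits apply). ",
           conditionMessage(e))
    })
  resid <- max(abs(as.matrix(A %*% X) - model$R))
  if (resid > tol) {
    stop(sprintf("linear solve residual %.3e exceeds tolerance %.1e", resid, tol))
  }
  bit <- node_bits(model$n)
  rows <- match(bit, model$state_index)
  per_node <- X[rows, "fixation"]
  structure(list(per_node = per_node,
                 uniform_avg = mean(per_node),
                 per_state_fixation = X[, "fixation"],
                 per_state_extinction = X[, "extinction"],
                 r = model$r, rule = model$rule, n = model$n,
                 method = "solve"),
            class = "fixation_result")
}

#' @export
print.fixation_result <- function(x, ...) {
  cat(sprintf("Fixation of a single mutant (%s, r = %g, N = %d): phi = %.8f [%s]\n",
              x$rule, x$r, x$n, x$uniform_avg, x$method))
  invisible(x)
}

#' Fixation probability of a randomly placed mutant on any graph
#'
#' The front door of the solver. Structural short-circuits are applied
#' before the full `2^N` solve: a disconnected graph gets probability 0
#' (the mutant can never occupy every component); a directed graph with
#' more than one source strongly-connected component gets 0 (no single
#' start can seed the whole graph); a one-rooted directed graph gets
#' exactly `1/N` (the mutant fixes if and only if it lands on the root).
#' Everything else is solved exactly via [transition_model()] and
#' [fixation_probabilities()].
#'
#' @inheritParams step_distribution
#' @return a `fixation_result`; its `method` field records whether a
#'   short-circuit fired (`"disconnected"`, `"multi_rooted"`,
#'   `"one_rooted"`) or the full solve ran (`"solve"`).
#' @examples
#' fixation_probability(graph_complete(4), r = 2, rule = "Bd") # 8/15
#' fixation_probability(graph_directed_line(4), r = 2, rule = "Bd") # 1/4
#' @export
fixation_probability <- function(g, r, rule = c("Bd", "dB")) {
  rule <- match.arg(rule)
  stopifnot(r > 0)
  n <- igraph::vcount(g)
  stopifnot(n >= 2)
  shortcut <- function(per_node, method) {
    structure(list(per_node = per_node, uniform_avg = mean(per_node),
                   per_state_fixation = NULL, per_state_extinction = NULL,
                   r = r, rule = rule, n = n, method = method),
              class = "fixation_result")
  }
  if (!is_connected_graph(g)) return(shortcut(rep(0, n), "disconnected"))
  if (igraph::is_directed(g)) {
    ns <- n_source_components(g)
    if (ns > 1L) return(shortcut(rep(0, n), "multi_rooted"))
    census <- root_census(g)
    if (census$classification == "one_rooted") {
      indeg <- igraph::degree(g, mode = "in")
      per_node <- as.numeric(indeg == 0L)
      return(shortcut(per_node, "one_rooted"))
    }
  }
  fixation_probabilities(transition_model(g, r, rule))
}

#' Monte-Carlo estimate of the fixation probability
#'
#' Simulates the Moran chain (compiled code) from a uniformly random
#' single-mutant start until extinction or fixation, `n_reps` times. This is
#' the stochastic alternative to the exact solve and serves as an
#' independent cross-check; the binomial standard error shows why the exact
#' route is preferred for classification, where differences from the
#' well-mixed reference are tiny.
#'
#' @inheritParams step_distribution
#' @param n_reps number of independent realisations.
#' @return list with `estimate`, `se` (binomial standard error), `n_fixed`,
#'   `n_reps`.
#' @export
simulate_fixation <- function(g, r, rule = c("Bd", "dB"), n_reps = 10000L) {
  rule <- match.arg(rule)
  stopifnot(r > 0, n_reps >= 1)
  if (!is_connected_graph(g)) stop("simulate_fixation() requires a connected graph")
  n <- igraph::vcount(g)
  el <- ordered_edges(g)
  adj_out <- lapply(seq_len(n), function(i) as.integer(el[el[, 1L] == i, 2L] - 1L))
  adj_in  <- lapply(seq_len(n), function(i) as.integer(el[el[, 2L] == i, 1L] - 1L))
  if (rule == "dB" && any(lengths(adj_in) == 0L)) {
    stop("dB updating needs every node to have an in-neighbour")
  }
  n_fixed <- sim_fixation_cpp(adj_out, adj_in, n, r,
                              if (rule == "Bd") 0L else 1L, as.integer(n_reps))
  est <- n_fixed / n_reps
  list(estimate = est, se = sqrt(est * (1 - est) / n_reps),
       n_fixed = n_fixed, n_reps = n_reps)
}
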