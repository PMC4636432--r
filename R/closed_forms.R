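#' Fixation probability of a birth-death chain from its transition rates
#'
#' For any Markov chain on `0..N` mutants with tri-diagonal transitions and
#' absorbing states at 0 and N, the probability of reaching N from 1 is
#' \deqn{\phi = \frac{1}{1 + \sum_{k=1}^{N-1} \prod_{j=1}^{k} T_j^- / T_j^+}.}
#'
#' @param rates a list with numeric vectors `t_plus` and `t_minus` of equal
#'   length `N - 1`: `t_plus[j]` (`t_minus[j]`) is the probability of moving
#'   from `j` mutants to `j + 1` (`j - 1`). See [chain_rates()].
#' @return fixation probability from a single mutant.
#' @export
phi_chain <- function(rates) {
  stopifnot(is.list(rates), length(rates$t_plus) == length(rates$t_minus))
  tp <- rates$t_plus
  tm <- rates$t_minus
  if (any(tp <= 0)) stop("all gain probabilities T_j+ must be positive")
  1 / (1 + sum(cumprod(tm / tp)))
}

#' Transition rates of a mutant-count chain
#'
#' Light container for the gain/loss probabilities `T_j^+`, `T_j^-` of a
#' birth-death chain on the number of mutants, validated for use with
#' [phi_chain()].
#'
#' @param t_plus,t_minus numeric vectors of length `N - 1`; entries in
#'   `(0, 1]` resp. `[0, 1]` with `t_plus + t_minus <= 1` elementwise.
#' @return a list of class `chain_rates`.
#' @export
chain_rates <- function(t_plus, t_minus) {
  stopifnot(length(t_plus) == length(t_minus),
            all(t_plus > 0), all(t_plus <= 1),
            all(t_minus >= 0), all(t_minus <= 1),
            all(t_plus + t_minus <= 1 + 1e-12))
  structure(list(t_plus = t_plus, t_minus = t_minus), class = "chain_rates")
}

#' Well-mixed fixation probabilities
#'
#' Closed forms for the fixation probability of a single mutant of fitness
#' `r` (wild-type fitness 1) in a complete graph of size `n`:
#' Birth-death \deqn{\phi^M_{Bd} = \frac{1 - 1/r}{1 - 1/r^N},}
#' death-Birth \deqn{\phi^M_{dB} = \frac{N-1}{N}\,\frac{1 - 1/r}{1 -
#' 1/r^{N-1}}.}
#' Both are continuous at `r = 1` with value `1/N`; that limit is returned
#' explicitly rather than through floating-point cancellation. These are the
#' references against which graphs are called amplifiers or suppressors —
#' the reference must match the update rule, because the two differ at small
#' `N`.
#'
#' @param r mutant fitness, `r > 0`.
#' @param n population size (`n >= 2` for Bd, `n >= 3` for dB).
#' @return fixation probability.
#' @examples
#' phi_wellmixed_bd(2, 4) # 8/15
#' phi_wellmixed_db(2, 4) # 3/7
#' @export
phi_wellmixed_bd <- function(r, n) {
  stopifnot(all(r > 0), n >= 2, n == round(n))
  ifelse(abs(r - 1) < 1e-12, 1 / n, (1 - 1 / r) / (1 - 1 / r^n))
}

#' @rdname phi_wellmixed_bd
#' @export
phi_wellmixed_db <- function(r, n) {
  stopifnot(all(r > 0), n >= 3, n == round(n))
  ifelse(abs(r - 1) < 1e-12, 1 / n,
         (n - 1) / n * (1 - 1 / r) / (1 - 1 / r^(n - 1)))
}

#' death-Birth transition rates on the cycle
#'
#' On a cycle the mutants always occupy a contiguous arc, so the full
#' \eqn{2^N} chain collapses exactly onto the number of mutants `j`. A step
#' changes `j` only when a node at one of the two arc boundaries dies:
#' for interior `j` the two wild-type boundary nodes each die with
#' probability `1/N` and are replaced by their mutant neighbour with
#' probability `r/(r+1)`, giving `T_j^+ = (2/N) r/(r+1)`, and symmetrically
#' `T_j^- = (2/N)/(r+1)`. At the boundaries of the chain a lone mutant that
#' dies is surely replaced by wild-type (`T_1^- = 1/N`) and the last
#' wild-type that dies is surely replaced by a mutant (`T_{N-1}^+ = 1/N`).
#'
#' @param r mutant fitness.
#' @param n cycle length, `n >= 3`.
#' @return a [chain_rates()] object.
#' @export
cycle_db_rates <- function(r, n) {
  stopifnot(r > 0, n >= 3, n == round(n))
  j <- seq_len(n - 1L)
  tp <- rep(2 / n * r / (r + 1), n - 1L)
  tm <- rep(2 / n * 1 / (r + 1), n - 1L)
  tp[n - 1L] <- 1 / n
  tm[1L] <- 1 / n
  chain_rates(tp, tm)
}

#' Cycle fixation probability under death-Birth updating
#'
#' Exact fixation probability of a single mutant on the cycle of length `n`
#' under dB updating, via the contiguous-arc chain reduction. For `n = 4`
#' this equals \eqn{2r^2 / (3r^2 + 2r + 3)} exactly.
#'
#' @inheritParams cycle_db_rates
#' @return fixation probability.
#' @export
phi_cycle_db <- function(r, n) {
  vapply(r, function(rr) phi_chain(cycle_db_rates(rr, n)), numeric(1L))
}

#' Cycle-versus-well-mixed deficit under death-Birth updating
#'
#' Returns \eqn{\phi^\circ_{dB}(r, N) - \phi^M_{dB}(r, N)}. The difference
#' is at most 0 for every `r > 0`, with equality only at `r = 1`: the cycle
#' under dB lowers the fixation probability of advantageous *and*
#' disadvantageous mutants, so it is neither an amplifier nor a suppressor
#' of selection. At `n = 4` the deficit is
#' \eqn{-r^2 (r-1)^2 / \left(4 (r^2+r+1)(3r^2+2r+3)\right)}.
#'
#' @inheritParams cycle_db_rates
#' @return signed difference (non-positive).
#' @examples
#' cycle_db_deficit(2, 4) # -1/133
#' @export
cycle_db_deficit <- function(r, n) {
  phi_cycle_db(r, n) - phi_wellmixed_db(r, n)
}
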