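#' Probability that a G(N, p) graph is connected
#'
#' Evaluates the classical recursion
#' \deqn{P_N = 1 - \sum_{K=1}^{N-1} \binom{N-1}{K-1} P_K (1-p)^{K(N-K)},
#'   \quad P_1 = 1,}
#' which conditions on the size `K` of the component containing node 1. For
#' `N = 4` it reduces to the polynomial
#' \eqn{-6p^6 + 24p^5 - 33p^4 + 16p^3}.
#'
#' @param n number of nodes, `n >= 1`.
#' @param p link probability in `[0, 1]`.
#' @return probability that the undirected G(n, p) graph is connected.
#' @examples
#' p_connected(4, 0.5) # 0.59375
#' @export
p_connected <- function(n, p) {
  stopifnot(n >= 1, n == round(n), all(p >= 0), all(p <= 1))
  vapply(p, function(pp) {
    P <- numeric(n)
    P[1L] <- 1
    if (n > 1L) {
      for (m in 2:n) {
        K <- seq_len(m - 1L)
        P[m] <- 1 - sum(choose(m - 1L, K - 1L) * P[K] * (1 - pp)^(K * (m - K)))
      }
    }
    P[n]
  }, numeric(1L))
}

#' Probability that a G(4, p) graph is isothermal
#'
#' For four nodes the only degree-regular connected topologies are the
#' complete graph (probability \eqn{p^6}) and the cycle (probability
#' \eqn{3p^4(1-p)^2}: 3 labelled 4-cycles, each needing its two chords
#' absent), so the isothermal probability is their sum.
#'
#' @param p link probability in `[0, 1]`.
#' @return probability.
#' @export
p_isothermal_n4 <- function(p) {
  stopifnot(all(p >= 0), all(p <= 1))
  p^6 + 3 * p^4 * (1 - p)^2
}

#' Probability that a directed G(N, p) graph has an in-degree-zero node
#'
#' Each node independently lacks all `N - 1` possible incoming links with
#' probability \eqn{(1-p)^{N-1}}; the chance that at least one node does is
#' \deqn{1 - \left(1 - (1-p)^{N-1}\right)^N.}
#' This upper-bounds the one-rooted plus multi-rooted plus (most)
#' disconnected fractions of the directed ensemble.
#'
#' @param n number of nodes, `n >= 2`.
#' @param p link probability in `[0, 1]`.
#' @return probability.
#' @examples
#' p_has_root(4, 0.5) # 0.413818359375
#' @export
p_has_root <- function(n, p) {
  stopifnot(n >= 2, n == round(n), all(p >= 0), all(p <= 1))
  1 - (1 - (1 - p)^(n - 1))^n
}
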