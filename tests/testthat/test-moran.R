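test_that("replacement weights follow the update rule", {
  w <- replacement_weights(graph_star(5), "Bd")
  hub_out <- w[w$from == 1, ]
  expect_equal(nrow(hub_out), 4)
  expect_equal(hub_out$weight, rep(1 / 4, 4))
  leaf_out <- w[w$from == 2, ]
  expect_equal(leaf_out$weight, 1)

  w <- replacement_weights(graph_cycle(4), "Bd")
  expect_equal(w$weight, rep(1 / 2, 8))

  w <- replacement_weights(graph_directed_line(2), "Bd")
  expect_equal(w, data.frame(from = 1L, to = 2L, weight = 1))

  # dB neutral weights: 1 / (N * indeg), summing to 1/N per dying node
  w <- replacement_weights(graph_star(4), "dB")
  expect_equal(sum(w$weight[w$to == 1]), 1 / 4)
  expect_error(replacement_weights(graph_directed_line(3), "dB"), "in-neighbour")
})

test_that("one-step distributions match hand calculations", {
  pair <- graph_complete(2)
  r <- 1.7
  d <- step_distribution(pair, config = 1L, r = r, rule = "Bd")
  expect_equal(d[["3"]], r / (r + 1))
  expect_equal(d[["0"]], 1 / (r + 1))
  expect_equal(sum(d), 1)

  # cycle N = 4, single mutant, dB: total gain (1/2) r/(r+1), loss 1/4
  d <- step_distribution(graph_cycle(4), config = 1L, r = r, rule = "dB")
  gain <- sum(d[as.numeric(names(d)) > 1])
  loss <- d[["0"]]
  expect_equal(gain, r / (2 * (r + 1)), tolerance = 1e-14)
  expect_equal(loss, 1 / 4, tolerance = 1e-14)

  # absorbing configurations self-loop with probability 1
  for (rule in c("Bd", "dB")) {
    d <- step_distribution(graph_cycle(4), config = 15L, r = 2, rule = rule)
    expect_equal(d, c("15" = 1))
    d <- step_distribution(graph_cycle(4), config = 0L, r = 2, rule = rule)
    expect_equal(d, c("0" = 1))
  }
  expect_error(step_distribution(pair, 1L, r = -1, rule = "Bd"))
})

test_that("canonical matrices agree with step_distribution row by row", {
  set.seed(21)
  cases <- list(
    list(g = random_connected_graph(5, 0.5), r = 0.75),
    list(g = random_connected_graph(6, 0.4), r = 1.5),
    list(g = random_connected_graph(5, 0.7, directed = TRUE), r = 2))
  for (cs in cases) {
    n <- igraph::vcount(cs$g)
    for (rule in c("Bd", "dB")) {
      if (rule == "dB" && any(igraph::degree(cs$g, mode = "in") == 0)) next
      m <- transition_model(cs$g, cs$r, rule)
      full <- Matrix::cbind2(m$Q, m$R)
      expect_lt(max(abs(Matrix::rowSums(full) - 1)), 1e-12)
      expect_true(all(full@x >= -1e-15 & full@x <= 1 + 1e-15))
      for (s in sample(m$state_index, 5)) {
        row <- which(m$state_index == s)
        d <- step_distribution(cs$g, s, cs$r, rule)
        dense <- numeric(2^n)
        dense[as.numeric(names(d)) + 1] <- d
        model_row <- numeric(2^n)
        model_row[m$state_index + 1] <- as.numeric(m$Q[row, ])
        model_row[c(1, 2^n)] <- m$R[row, ]
        expect_equal(model_row, dense, tolerance = 1e-13)
      }
    }
  }
})

test_that("the two-node chain has the textbook canonical form", {
  r <- 2.5
  m <- transition_model(graph_complete(2), r, "Bd")
  expect_equal(dim(m$Q), c(2L, 2L))
  expect_equal(unname(m$R[1, ]), c(1 / (r + 1), r / (r + 1)))
  expect_equal(unname(m$R[2, ]), c(1 / (r + 1), r / (r + 1)))
  expect_equal(Matrix::diag(m$Q), c(0, 0))
  f <- fixation_probabilities(m)
  expect_equal(f$uniform_avg, phi_wellmixed_bd(r, 2), tolerance = 1e-12)
})

test_that("transient state count is 2^N - 2", {
  m <- transition_model(graph_cycle(4), 1.5, "Bd")
  expect_equal(nrow(m$Q), 14L)
  expect_equal(nrow(transition_model(graph_complete(6), 1.5, "dB")$Q), 62L)
})

test_that("the full solve reproduces closed forms to solver precision", {
  expect_equal(fixation_probability(graph_complete(4), 2, "Bd")$uniform_avg,
               8 / 15, tolerance = 1e-10)
  for (n in c(4, 6, 8)) {
    for (r in c(0.75, 1.5)) {
      expect_equal(fixation_probability(graph_complete(n), r, "Bd")$uniform_avg,
                   phi_wellmixed_bd(r, n), tolerance = 1e-10)
      expect_equal(fixation_probability(graph_complete(n), r, "dB")$uniform_avg,
                   phi_wellmixed_db(r, n), tolerance = 1e-10)
    }
  }
  # isothermal theorem: the Bd cycle matches the well-mixed closed form
  for (n in c(4, 5, 7)) {
    expect_equal(fixation_probability(graph_cycle(n), 1.5, "Bd")$uniform_avg,
                 phi_wellmixed_bd(1.5, n), tolerance = 1e-10)
  }
  expect_equal(fixation_probability(graph_cycle(4), 1.3, "dB")$uniform_avg,
               2 * 1.3^2 / (3 * 1.3^2 + 2 * 1.3 + 3), tolerance = 1e-10)
})

test_that("neutral mutants fix with probability exactly 1/N on every connected graph", {
  set.seed(31)
  for (k in 1:6) {
    n <- sample(4:8, 1)
    g <- random_connected_graph(n, stats::runif(1, 0.3, 0.8))
    for (rule in c("Bd", "dB")) {
      expect_equal(fixation_probability(g, 1, rule)$uniform_avg, 1 / n,
                   tolerance = 1e-9)
    }
  }
})

test_that("extinction and fixation probabilities sum to one from every start", {
  set.seed(32)
  g <- random_connected_graph(6, 0.5)
  for (rule in c("Bd", "dB")) {
    f <- fixation_probabilities(transition_model(g, 1.4, rule))
    expect_lt(max(abs(f$per_state_fixation + f$per_state_extinction - 1)), 1e-9)
  }
})

test_that("fixation probability is nondecreasing in r on tested graphs", {
  set.seed(33)
  grid <- c(0.5, 0.75, 1, 1.25, 1.5, 1.75, 2)
  graphs <- list(graph_star(5), random_connected_graph(6, 0.5),
                 random_connected_graph(7, 0.4))
  for (g in graphs) {
    for (rule in c("Bd", "dB")) {
      phis <- vapply(grid, function(r) fixation_probability(g, r, rule)$uniform_avg,
                     numeric(1))
      expect_true(all(diff(phis) > -1e-12))
    }
  }
})

test_that("structural short-circuits fire before the solve", {
  f <- fixation_probability(two_component_graph(), 1.5, "Bd")
  expect_equal(f$uniform_avg, 0)
  expect_equal(f$method, "disconnected")

  f <- fixation_probability(graph_directed_line(4), 2, "dB")
  expect_equal(f$uniform_avg, 1 / 4)
  expect_equal(f$method, "one_rooted")
  expect_equal(f$per_node, c(1, 0, 0, 0))

  two_roots <- dgraph(3, c(0, 2, 1, 2))
  f <- fixation_probability(two_roots, 2, "Bd")
  expect_equal(f$uniform_avg, 0)
  expect_equal(f$method, "multi_rooted")

  # no in-degree-zero node, but two source components: still impossible
  g <- dgraph(7, c(0,1, 1,2, 2,0, 3,4, 4,5, 5,3, 2,6, 5,6))
  f <- fixation_probability(g, 2, "Bd")
  expect_equal(f$uniform_avg, 0)
  expect_equal(f$method, "multi_rooted")

  # strongly connected directed graph goes to the full solve
  f <- fixation_probability(dgraph(3, c(0,1, 1,2, 2,0)), 2, "Bd")
  expect_equal(f$method, "solve")
  expect_equal(f$uniform_avg, phi_wellmixed_bd(2, 3), tolerance = 1e-10)
})

test_that("excluding out-degree-zero nodes from the Bd lottery equals null self-transitions", {
  # directed: {0,1} strongly connected, 2 is a pure sink
  g <- dgraph(3, c(0,1, 1,0, 0,2, 1,2))
  r <- 1.8
  f <- fixation_probability(g, r, "Bd")
  expect_equal(f$method, "solve")

  # independent dense oracle where the sink joins the lottery and its
  # birth event is a null self-transition
  n <- 3; S <- 2^n; bit <- 2^(0:2)
  outnb <- list(c(2, 3), c(1, 3), integer(0))
  P <- matrix(0, S, S)
  for (s in 0:(S - 1)) {
    mut <- bitwAnd(s, bit) > 0
    fit <- ifelse(mut, r, 1)
    Ftot <- sum(fit)
    for (i in 1:n) {
      if (length(outnb[[i]]) == 0) {
        P[s + 1, s + 1] <- P[s + 1, s + 1] + fit[i] / Ftot
      } else {
        for (j in outnb[[i]]) {
          s2 <- if (mut[i]) bitwOr(s, bit[j]) else bitwAnd(s, bitwNot(bit[j]))
          P[s + 1, s2 + 1] <- P[s + 1, s2 + 1] +
            fit[i] / Ftot / length(outnb[[i]])
        }
      }
    }
  }
  trans <- 2:(S - 1)
  phi <- solve(diag(length(trans)) - P[trans, trans], P[trans, S])
  oracle_per_node <- phi[bit]  # transient state k sits in row k
  expect_equal(f$per_node, oracle_per_node, tolerance = 1e-10)
})

test_that("dB solver refuses graphs with an in-degree-zero node", {
  g <- dgraph(3, c(0, 1, 1, 2, 2, 1))
  expect_error(transition_model(g, 1.5, "dB"), "in-neighbour")
})
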