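test_that("sequence weights: direct arithmetic on reference systems", {
  g <- valley_graph()
  expect_equal(sequence_weight(g, c("1", "2", "3")), 0.1 * 0.1 / 0.8)
  expect_equal(sequence_weight(g, c("1", "3")), 0.01)  # single edge: empty product
  # chain graph: product form
  g4 <- path_graph(4)
  expect_equal(sequence_weight(g4, c("1", "2", "3", "4")),
               0.05^3 / (0.9 * 0.9))
  # walk weight counts repeated visits each time
  gc <- cycle_walk_graph(nu1 = 0.01, nu2 = 0.5, nu_out = 0.01)
  expect_equal(sequence_weight(gc, c("1", "2", "3", "2", "4")),
               0.01 * 0.5 * 0.5 * 0.01 / (0.9^2 * 0.9))
})

test_that("weights agree with a naive-arithmetic oracle on random DAGs", {
  for (seed in 1:10) {
    set.seed(seed)
    g <- random_dag(6, 0.6)
    for (p in enumerate_paths(g)) {
      expect_equal(sequence_weight(g, p), naive_weight(g, p),
                   tolerance = 1e-12)
    }
  }
})

test_that("weight errors: non-edges and non-costly intermediates", {
  g <- valley_graph()
  expect_error(sequence_weight(g, c("1", "3", "2")), "non-edges")
  g_eq <- transition_graph(
    data.frame(id = c("1", "2", "3"), alpha = 1, beta = c(0.4, 0.4, 0.6)),
    data.frame(from = c("1", "2"), to = c("2", "3"), nu = 0.05),
    root = "1", target = "3")
  expect_error(sequence_weight(g_eq, c("1", "2", "3")), "growth rate")
})

test_that("weight table: totals, growth ratios, probabilities", {
  g <- valley_graph()
  tb <- weight_table(g)
  expect_equal(tb$phi_N, 0.0125 + 0.01)
  expect_equal(unname(tb$Phi[g$root]), 1)
  expect_equal(path_probability(tb, c("1", "2", "3")), 5 / 9)
  expect_equal(path_probability(tb, c("1", "3")), 4 / 9)
  # summed normalised weights over a set of paths
  expect_equal(path_probability(tb, list(c("1", "2", "3"), c("1", "3"))), 1)

  # chain graph: Phi_x is the running product of nu / cost
  g4 <- path_graph(4)
  tb4 <- weight_table(g4)
  expect_equal(unname(tb4$Phi[c("1", "2", "3")]),
               c(1, 0.05 / 0.9, (0.05 / 0.9)^2))
  # single-edge graph: phi equals the edge rate
  g1 <- transition_graph(data.frame(id = c("a", "b"), alpha = 1,
                                    beta = c(0.4, 0.2)),
                         data.frame(from = "a", to = "b", nu = 0.07),
                         root = "a", target = "b")
  expect_equal(weight_table(g1)$phi_N, 0.07)
})

test_that("path probabilities normalise to one over the enumerated set", {
  for (seed in 1:10) {
    set.seed(seed)
    g <- random_dag(sample(4:7, 1), 0.6)
    tb <- weight_table(g)
    probs <- tb$paths$probability[tb$paths$to == g$target]
    expect_equal(sum(probs), 1, tolerance = 1e-12)
  }
})

test_that("time advantage: t = 0 equals the path probability; logistic limits", {
  g <- valley_graph()
  tb <- weight_table(g)
  p_ind <- c("1", "2", "3")
  expect_equal(time_advantage(tb, p_ind, 0), path_probability(tb, p_ind))
  # closed form for this two-path system: [1 + e^{lam t} (lam - lam(2))]^{-1}
  ts <- c(-3, -1, 0, 0.5, 2)
  expect_equal(time_advantage(tb, p_ind, ts),
               1 / (1 + exp(0.6 * ts) * 0.8), tolerance = 1e-12)
  expect_equal(time_advantage(tb, p_ind, Inf), 0)
  expect_equal(time_advantage(tb, p_ind, -Inf), 1)
  # unique-path graph: probability one at any margin
  tb4 <- weight_table(path_graph(4))
  expect_equal(time_advantage(tb4, c("1", "2", "3", "4"), 5), 1)

  for (seed in 1:5) {
    set.seed(seed)
    g <- random_dag(6, 0.6)
    tb <- weight_table(g)
    for (p in enumerate_paths(g)) {
      expect_equal(time_advantage(tb, p, 0), path_probability(tb, p),
                   tolerance = 1e-12)
    }
  }
})

test_that("walk competition: cycle walk vs short path closed form", {
  g <- cycle_walk_graph(nu1 = 0.01, nu2 = 0.5, nu_out = 0.01)
  p <- c("1", "2", "4")
  w <- c("1", "2", "3", "2", "4")
  tb <- weight_table(g, sequences = list(p, w))
  # P(walk beats path) = [1 + (lam - lam(2))(lam - lam(3)) / nu2^2]^{-1}
  expect_equal(path_probability(tb, w),
               1 / (1 + 0.9 * 0.9 / 0.5^2), tolerance = 1e-12)
})

test_that("log-space totals survive application-scale rates", {
  g <- build_monotherapy(nu = 1e-8, m = 1e-7, s = 5e-3, d = 1e-2, z = 10)
  tb <- weight_table(g)
  expect_equal(tb$phi_N, 1e-8 * 1e-7 / 5e-3 + 1e-7 * 1e-8 / 1e-2,
               tolerance = 1e-12)
  expect_true(is.finite(tb$log_phi_N))
})
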