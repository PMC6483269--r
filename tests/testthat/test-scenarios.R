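test_that("monotherapy: graph shape, weights, ordering and median forms", {
  m <- monotherapy_metrics(alpha = 1, beta = 0.6, nu = 1e-6, m = 1e-3,
                           s = 5e-3, d = 1e-2, z = 100)
  expect_identical(nrow(validate_graph(m$graph)), 0L)
  expect_identical(length(enumerate_paths(m$graph)), 2L)
  expect_equal(unname(m$weights),
               c(1e-6 * 1e-3 / 5e-3, 1e-6 * 1e-3 / 1e-2), tolerance = 1e-12)
  expect_equal(m$p_mutation_first, 1e-2 / (5e-3 + 1e-2))
  # the scenario's closed-form median is the generic pipeline's median
  expect_equal(as.numeric(m$median), m$median_closed_form, tolerance = 1e-12)
  # generic path probability reproduces d/(s+d)
  p_mutmig <- path_probability(m$table,
                               c("sanct_sens", "sanct_res", "drug_res"))
  expect_equal(p_mutmig, m$p_mutation_first, tolerance = 1e-12)
})

test_that("monotherapy is symmetric under swapping mutation/migration with s/d", {
  a <- monotherapy_metrics(nu = 2e-6, m = 5e-4, s = 3e-3, d = 8e-3, z = 50)
  b <- monotherapy_metrics(nu = 5e-4, m = 2e-6, s = 8e-3, d = 3e-3, z = 50)
  expect_equal(unname(a$weights),
               unname(rev(b$weights)), tolerance = 1e-12)
  expect_equal(a$p_mutation_first, 1 - b$p_mutation_first, tolerance = 1e-12)
})

test_that("drug switch condition: limits and symmetry", {
  # identical drugs, equal sanctuaries: never switch
  same <- drug_switch_condition(z_A = 100, d_A = 1e-2, z_B = 100, d_B = 1e-2,
                                s = 5e-3)
  expect_false(same$switch)
  expect_equal(same$margin, 0)
  # a more penetrant, equally effective drug: switch
  pen <- drug_switch_condition(z_A = 100, d_A = 1e-2, z_B = 10, d_B = 1e-2,
                               s = 5e-3)
  expect_true(pen$switch)
  expect_gt(pen$margin, 0)
  # d_B -> Inf limit of the threshold
  lim <- drug_switch_condition(z_A = 100, d_A = 1e-2, z_B = 99, d_B = 1e12,
                               s = 5e-3)
  expect_equal(lim$threshold_dB_inf, 1 / (1 + 0.5), tolerance = 1e-12)
  expect_equal(lim$rhs, lim$threshold_dB_inf, tolerance = 1e-6)
})

test_that("combination graph: 12 states, 18 paths split 6 direct + 12 stepwise", {
  g <- build_combination(nu = 1e-6, m = 0.05, s = 1e-3, d = 0.9,
                         n_S = 5e5, n_D = 5e5, n_DD = 9e6)
  expect_identical(nrow(g$vertices), 12L)
  expect_identical(nrow(validate_graph(g)), 0L)
  paths <- enumerate_paths(g)
  expect_identical(length(paths), 18L)
  stepwise <- Filter(function(p) any(startsWith(p, "D.")), paths)
  expect_identical(length(stepwise), 12L)
  # the canonical stepwise route is present
  expect_true("S.0 -> S.A -> D.A -> D.AB -> DD.AB" %in%
                vapply(paths, path_key, ""))
  # sanctuary -> double-drug migration rate
  expect_equal(edge_rate_of(g, "S.0", "DD.0"),
               0.05 * 9e6 / (5e5 + 9e6), tolerance = 1e-12)
  # migration out-rates from the sanctuary sum to m per cell
  mig_S <- g$edges[g$edges$from == "S.0" & !startsWith(g$edges$to, "S."), ]
  expect_equal(sum(mig_S$nu), 0.05, tolerance = 1e-12)
  # every migration edge: m * destination share of the other two regions
  expect_equal(edge_rate_of(g, "D.A", "DD.A"),
               0.05 * 9e6 / (5e5 + 9e6), tolerance = 1e-12)
  expect_error(build_combination(nu = 1e-6, m = 0.05, s = 1e-3, d = 0.9,
                                 n_S = 1e6, n_D = 0, n_DD = 9e6),
               "geometry")
})

test_that("combination metrics: acceleration condition and stepwise probability", {
  base <- list(nu = 1e-6, m = 0.05, d = 0.9, n_S = 5e5, n_D = 5e5, n_DD = 9e6)
  cm <- do.call(combination_metrics, c(base, list(s = 1e-3)))
  # (n_S + n_D)/n_Tot = 0.1 > s/m = 0.02: single-drug region accelerates
  expect_true(cm$accelerates)
  cm2 <- do.call(combination_metrics, c(base, list(s = 6e-3)))
  expect_false(cm2$accelerates)  # s/m = 0.12 exceeds (n_S + n_D)/n_Tot = 0.1
  # the condition flips at s = m (nS+nD)/nTot
  s_crit <- 0.05 * 0.1
  cm_lo <- do.call(combination_metrics, c(base, list(s = s_crit * 0.9)))
  cm_hi <- do.call(combination_metrics, c(base, list(s = s_crit * 1.1)))
  expect_true(cm_lo$accelerates)
  expect_false(cm_hi$accelerates)
  # stepwise probability rises with the single-drug region's size
  pool <- 1e6
  p_step <- vapply(c(0.2, 0.5, 0.8), function(frac) {
    do.call(combination_metrics,
            list(nu = 1e-6, m = 0.05, s = 1e-3, d = 0.9,
                 n_S = pool * (1 - frac), n_D = pool * frac,
                 n_DD = 9e6))$p_stepwise_exact
  }, 0)
  expect_true(all(diff(p_step) > 0))
  # limit form converges to the exact-graph sum as s/d -> 0
  rel_err <- vapply(c(1e-1, 1e-2, 1e-3), function(s) {
    cmx <- do.call(combination_metrics, c(base, list(s = s * 0.9)))
    abs(cmx$p_stepwise_approx - cmx$p_stepwise_exact) / cmx$p_stepwise_exact
  }, 0)
  expect_true(all(diff(rel_err) < 0))
  expect_lt(rel_err[3], 1e-2)
  # most probable stepwise path: mutate-A, migrate, mutate-B, migrate
  expect_identical(cm$most_probable_stepwise,
                   "S.0 -> S.A -> D.A -> D.AB -> DD.AB")
})

test_that("median time along the canonical stepwise path is minimal near n_D = n_S", {
  # single-path medians as a function of n_D/n_S, holding n_S + n_D fixed
  pool <- 1e6; n_DD <- 9e6
  ratios <- c(0.4, 0.7, 1, 1.4, 2.5)
  meds <- vapply(ratios, function(r) {
    n_S <- pool / (1 + r)
    g <- build_combination(nu = 1e-6, m = 0.05, s = 1e-3, d = 0.9,
                           n_S = n_S, n_D = pool - n_S, n_DD = n_DD)
    w <- sequence_weight(g, c("S.0", "S.A", "D.A", "D.AB", "DD.AB"))
    h <- hitting_time_model(phi_N = w, alpha = 0.7, beta = 0.3, z = g$z)
    as.numeric(median_hitting_time(h))
  }, 0)
  expect_identical(which.min(meds), 3L)
})

test_that("CML: rate race, survival adjustment, two-amplification model", {
  res <- cml_analysis()
  expect_equal(res$p_point_first, 1 / 11, tolerance = 1e-12)
  expect_equal(res$rho_ratio_needed, 10)
  # equal survival factors cancel
  expect_equal(cml_analysis(rho_pm = 0.3, rho_ga = 0.3)$p_point_first, 1 / 11,
               tolerance = 1e-12)
  # rho_pm > 10 rho_ga tips the race to point mutations
  expect_gt(cml_analysis(rho_pm = 0.31, rho_ga = 0.03)$p_point_first, 0.5)
  expect_lt(cml_analysis(rho_pm = 0.29, rho_ga = 0.03)$p_point_first, 0.5)
  # two-amplification route: (1 + 8e-6/s)^{-1}
  expect_equal(cml_analysis(s = 1e-4)$p_point_two_amp,
               1 / (1 + 8e-6 / 1e-4), tolerance = 1e-12)
  expect_gt(cml_analysis(s = 8.1e-6)$p_point_two_amp, 0.5)
  expect_lt(cml_analysis(s = 7.9e-6)$p_point_two_amp, 0.5)
})

test_that("MDR ordering and two-path hitting law", {
  expect_equal(mdr_order_probability(0.88, 0.71),
               (1 - 0.71) / ((1 - 0.88) + (1 - 0.71)), tolerance = 1e-12)
  expect_equal(mdr_order_probability(0.5, 0.5), 0.5)
  expect_equal(mdr_order_probability(cost_1 = 0.12, cost_2 = 0.29),
               mdr_order_probability(0.88, 0.71), tolerance = 1e-12)
  # the general two-path builder reproduces the specialised formula: a
  # symmetric two-mutation graph analysed through the generic pipeline
  alpha <- 1; beta <- 0.4; nu_R <- 1e-7; nu_I <- 3e-7; s <- 0.05
  g <- transition_graph(
    vertices = data.frame(id = c("wt", "R", "I", "RI"), alpha = alpha,
                          beta = beta + c(0, s, s, 2 * s)),
    edges = data.frame(from = c("wt", "wt", "R", "I"),
                       to = c("R", "I", "RI", "RI"),
                       nu = c(nu_R, nu_I, nu_I, nu_R)),
    root = "wt", target = "RI")
  tb <- weight_table(g)
  expect_equal(tb$phi_N, 2 * nu_R * nu_I / s, tolerance = 1e-12)
  res <- mdr_two_path_analysis(alpha, beta, nu_R, nu_I, s, t = c(10, 30))
  expect_equal(res$mu, hitting_time_model(tb)$mu, tolerance = 1e-12)
  expect_equal(res$cdf$p, 1 - hitting_survival(hitting_time_model(tb),
                                               c(10, 30)),
               tolerance = 1e-12)
  # relative probability between lineages: small-time limit and symmetry
  rel <- mdr_relative_probability(c(2e-7, 2e-7), c(1e-7, 1e-7),
                                  t = c(5, 80), alpha = alpha, beta = beta,
                                  s = s)
  expect_equal(rel$ratio_limit, c(4, 4))
  expect_true(rel$limit_valid[1])
  expect_false(rel$limit_valid[2])
  expect_equal(rel$ratio[1], 4, tolerance = 1e-2)
  same <- mdr_relative_probability(c(1e-7, 3e-7), c(1e-7, 3e-7),
                                   t = c(0, 50), alpha, beta, s)
  expect_equal(same$ratio, c(1, 1), tolerance = 1e-12)
})

test_that("scenario builders all pass validation cleanly", {
  g1 <- build_monotherapy(nu = 1e-8, m = 1e-5, s = 1e-3, d = 1e-2, z = 1000)
  g2 <- build_combination(nu = 1e-6, m = 0.05, s = 1e-2, d = 0.9,
                          n_S = 2e5, n_D = 8e5, n_DD = 9e6)
  expect_identical(nrow(validate_graph(g1)), 0L)
  expect_identical(nrow(validate_graph(g2)), 0L)
})
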