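#' Monotherapy with imperfect drug penetration
#'
#' Builds the four-state graph for resistance emerging from a drug-free
#' sanctuary under a single drug.  Vertices: sanctuary-sensitive cells
#' (root; rates `alpha`, `beta`), sanctuary-resistant (death `beta + s`,
#' the cost of resistance), drug-compartment-sensitive (death `beta + d`,
#' the drug's effect) and drug-compartment-resistant (target, death
#' `beta + s`).  Mutation edges carry rate `nu`, migration edges rate `m`,
#' giving exactly two routes to resistance: mutation-then-migration
#' (weight `nu m / s`) and migration-then-mutation (weight `nu m / d`).
#'
#' @param alpha,beta division and death rate of sanctuary wild-type cells
#'   (`alpha > beta`).
#' @param nu per-cell mutation rate; `m` per-cell migration rate.
#' @param s fitness cost of resistance, added to the death rate; `d` drug
#'   effect on sensitive cells, added to the death rate.  Both `> 0`.
#' @param z initial number of sanctuary cells.
#' @return a [transition_graph()] with vertex ids `sanct_sens`,
#'   `sanct_res`, `drug_sens`, `drug_res`.
#' @examples
#' g <- build_monotherapy(nu = 1e-6, m = 1e-3, s = 5e-3, d = 1e-2, z = 100)
#' weight_table(g)
#' @export
build_monotherapy <- function(alpha = 1, beta = 0.6, nu, m, s, d, z = 1L) {
  stopifnot(alpha > beta, s > 0, d > 0, nu > 0, m > 0)
  transition_graph(
    vertices = data.frame(
      id = c("sanct_sens", "sanct_res", "drug_sens", "drug_res"),
      alpha = alpha,
      beta = beta + c(0, s, d, s)),
    edges = data.frame(
      from = c("sanct_sens", "sanct_sens", "sanct_res", "drug_sens"),
      to   = c("sanct_res", "drug_sens", "drug_res", "drug_res"),
      nu   = c(nu, m, m, nu)),
    root = "sanct_sens", target = "drug_res", z = z)
}

#' Summary metrics of the monotherapy scenario
#'
#' Runs the generic weight/hitting-time pipeline on the built graph and
#' reports the scenario's closed forms, which are the same formulas
#' specialised: path weights `(nu m / s, nu m / d)`, probability
#' `d / (s + d)` that resistance arises mutation-first, and the median
#' resistance time
#' `(1/lam) log(lam^2/alpha) - (1/lam) log(nu m / s + nu m / d) +
#'  (1/lam) log(alpha / (z lam))` (large-`z` form).
#'
#' @inheritParams build_monotherapy
#' @return list with `graph`, `table` ([weight_table()]), `weights` (named:
#'   `mutation_migration`, `migration_mutation`), `p_mutation_first`,
#'   `median` (generic pipeline) and `median_closed_form`.
#' @export
monotherapy_metrics <- function(alpha = 1, beta = 0.6, nu, m, s, d, z = 1L) {
  g <- build_monotherapy(alpha, beta, nu, m, s, d, z)
  tb <- weight_table(g)
  lam <- alpha - beta
  med_cf <- (log(lam^2 / alpha) - log(nu * m / s + nu * m / d) +
               log(alpha / (z * lam))) / lam
  list(graph = g, table = tb,
       weights = c(
         mutation_migration = sequence_weight(g, c("sanct_sens", "sanct_res", "drug_res")),
         migration_mutation = sequence_weight(g, c("sanct_sens", "drug_sens", "drug_res"))),
       p_mutation_first = d / (s + d),
       median = median_hitting_time(hitting_time_model(tb)),
       median_closed_form = med_cf)
}

#' When is switching to a better-penetrating drug worthwhile?
#'
#' Compares median resistance times under two drugs, A (in use) and B
#' (candidate), that share the resistance cost `s` and sanctuary growth
#' rate but differ in efficacy (`d_A`, `d_B`) and penetration (sanctuary
#' sizes `z_A`, `z_B`).  Switching to B delays resistance iff
#' `z_A / z_B > (1 + s/d_B) / (1 + s/d_A)`.
#' As `d_B -> Inf` the threshold tends to `(1 + s/d_A)^{-1}`: the best
#' possible gain from efficacy alone.
#'
#' @param z_A,z_B initial sanctuary populations under each drug.
#' @param d_A,d_B drug-induced death-rate increments.
#' @param s shared resistance cost.
#' @param alpha,beta,nu,m shared cellular rates (enter only the margin).
#' @return list with `switch` (logical), `lhs`, `rhs` (the two sides of the
#'   condition), `margin` (median under B minus median under A, in time
#'   units) and `threshold_dB_inf`.
#' @export
drug_switch_condition <- function(z_A, d_A, z_B, d_B, s,
                                  alpha = 1, beta = 0.6, nu = 1e-6, m = 1e-3) {
  stopifnot(z_A >= 1, z_B >= 1, d_A > 0, d_B > 0, s > 0, alpha > beta)
  lam <- alpha - beta
  med <- function(z, d) {
    (log(lam^2 / alpha) - log(nu * m / s + nu * m / d) +
       log(alpha / (z * lam))) / lam
  }
  lhs <- z_A / z_B
  rhs <- (1 + s / d_B) / (1 + s / d_A)
  list(switch = lhs > rhs, lhs = lhs, rhs = rhs,
       margin = med(z_B, d_B) - med(z_A, d_A),
       threshold_dB_inf = 1 / (1 + s / d_A))
}

# ---- combination therapy -------------------------------------------------

comb_genotypes <- c("0", "A", "B", "AB")
comb_regions <- c("S", "D", "DD")

# death-rate increment of a cell of given genotype in a given region:
# s per resistance mutation carried, d per drug present and not blocked
comb_cost <- function(region, genotype, s, d) {
  n_mut <- c("0" = 0, "A" = 1, "B" = 1, "AB" = 2)[[genotype]]
  drugs <- switch(region, S = character(), D = "A", DD = c("A", "B"))
  unblocked <- sum(!drugs %in% strsplit(genotype, "")[[1]])
  n_mut * s + unblocked * d
}

#' Combination therapy with nested drug penetration
#'
#' Builds the 12-state graph for two drugs, A and B, where drug B's
#' penetration region is nested inside drug A's: the system splits into a
#' sanctuary (capacity `n_S`, no drug), a single-drug region (`n_D`, drug
#' A only) and a double-drug region (`n_DD`, both drugs).  A cell's state
#' is its region plus its resistance genotype (`0`, `A`, `B`, `AB`); its
#' death rate is `beta` plus `s` per resistance mutation carried plus `d`
#' per unblocked drug present.  Mutations (rate `nu`) add one resistance;
#' migrations move a cell to one of the two other regions at rate `m`
#' times the destination's share of their combined capacity (e.g.
#' sanctuary to double-drug at `m n_DD / (n_D + n_DD)`); back-migrations
#' toward the sanctuary are neglected, as are reverse mutations.  The
#' root is the sensitive sanctuary state and the target is the fully
#' resistant double-drug state; exactly 18 root-to-target paths exist — 6
#' "direct" (bypassing the single-drug region) and 12 "stepwise" (through
#' it).
#'
#' Only this nested geometry is supported; requesting `n_D = 0` or
#' non-nested penetration is rejected.
#'
#' @inheritParams build_monotherapy
#' @param n_S,n_D,n_DD region capacities (all positive).
#' @param gamma initial sanctuary occupancy fraction; the run starts with
#'   `z = round(gamma * n_S)` cells (at least 1).
#' @param lam sanctuary growth rate; when `beta` is `NULL` the death rate
#'   is derived as `alpha - lam`.
#' @return a [transition_graph()] with vertex ids `<region>.<genotype>`.
#' @examples
#' g <- build_combination(nu = 1e-6, m = 0.05, s = 1e-3, d = 0.9,
#'                        n_S = 5e5, n_D = 5e5, n_DD = 9e6, gamma = 1e-3)
#' length(enumerate_paths(g))   # 18
#' @export
build_combination <- function(alpha = 0.7, beta = NULL, nu, m, s, d,
                              n_S, n_D, n_DD, gamma = 1e-3, lam = 0.4) {
  if (is.null(beta)) beta <- alpha - lam
  stopifnot(s > 0, d > 0, nu > 0, m > 0, gamma > 0, gamma < 1)
  if (beta < 0) stop("negative death rate: lower lam or raise alpha")
  if (n_S <= 0 || n_D <= 0 || n_DD <= 0) {
    stop("unsupported geometry: all three region capacities must be positive ",
         "(only the nested-penetration layout is modelled)")
  }
  states <- expand.grid(genotype = comb_genotypes, region = comb_regions,
                        stringsAsFactors = FALSE)
  states$id <- paste(states$region, states$genotype, sep = ".")
  states$beta <- beta + mapply(comb_cost, states$region, states$genotype,
                               MoreArgs = list(s = s, d = d))
  # mutation edges: gain resistance to one more drug, same region
  mut_step <- list(c("0", "A"), c("0", "B"), c("A", "AB"), c("B", "AB"))
  mut <- do.call(rbind, lapply(comb_regions, function(r) {
    do.call(rbind, lapply(mut_step, function(st) {
      data.frame(from = paste(r, st[1], sep = "."),
                 to = paste(r, st[2], sep = "."), nu = nu)
    }))
  }))
  # migration edges: S -> D, S -> DD, D -> DD (no back-migration), rate
  # m * destination capacity / (combined capacity of the two other regions)
  mig_spec <- data.frame(
    from_r = c("S", "S", "D"),
    to_r   = c("D", "DD", "DD"),
    rate   = c(m * n_D / (n_D + n_DD),
               m * n_DD / (n_D + n_DD),
               m * n_DD / (n_S + n_DD)))
  mig <- do.call(rbind, lapply(seq_len(nrow(mig_spec)), function(i) {
    data.frame(from = paste(mig_spec$from_r[i], comb_genotypes, sep = "."),
               to = paste(mig_spec$to_r[i], comb_genotypes, sep = "."),
               nu = mig_spec$rate[i])
  }))
  edges <- rbind(mut, mig)
  # the target is a sink: drop its outgoing migration edges, and the root a
  # source (it has no incoming edges by construction)
  edges <- edges[edges$from != "DD.AB", , drop = FALSE]
  z <- max(1L, round(gamma * n_S))
  states$alpha <- alpha
  transition_graph(states[, c("id", "alpha", "beta")], edges,
                   root = "S.0", target = "DD.AB", z = z)
}

#' Closed-form and exact-graph metrics for combination therapy
#'
#' Evaluates, for the nested-penetration combination scenario with total
#' capacity `n_Tot = n_S + n_D + n_DD`:
#'
#' * the median-resistance-time curve `t_half(n_D/n_S)` at fixed `n_DD`,
#'   obtained from [median_hitting_time()] on the built graph;
#' * the acceleration condition `(n_S + n_D)/n_Tot > s/m` under which
#'   enlarging the single-drug region *speeds up* resistance (valid in the
#'   regime `s << d`, `(n_S + n_D) << n_Tot`);
#' * the worst-case ratio `n_D/n_S ~ 1 - 2 s n_Tot / (m (n_S + n_D))`
#'   minimising the median time;
#' * the probability that resistance arises by stepwise evolution (through
#'   the single-drug region), both the limit form
#'   `[1 + s (n_DD + n_S) / (m n_D)]^{-1}` and the exact-graph sum of the
#'   12 stepwise path probabilities, so the quality of the `s << d`
#'   approximation is visible.
#'
#' @inheritParams build_combination
#' @param nD_over_nS ratios `n_D/n_S` at which to evaluate the median
#'   curve, holding `n_S + n_D` and `n_DD` fixed.
#' @return list with `curve` (data.frame `ratio`, `t_half`),
#'   `accelerates`, `condition_lhs`, `condition_rhs`, `worst_ratio`,
#'   `p_stepwise_approx`, `p_stepwise_exact`, `most_probable_stepwise`,
#'   `graph`, `table`.
#' @export
combination_metrics <- function(alpha = 0.7, beta = NULL, nu, m, s, d,
                                n_S, n_D, n_DD, gamma = 1e-3, lam = 0.4,
                                nD_over_nS = NULL) {
  g <- build_combination(alpha, beta, nu, m, s, d, n_S, n_D, n_DD, gamma, lam)
  tb <- weight_table(g)
  n_Tot <- n_S + n_D + n_DD
  paths <- enumerate_paths(g)
  stepwise <- Filter(function(p) any(startsWith(p, "D.")), paths)
  p_step_exact <- path_probability(tb, stepwise)
  sw_lab <- vapply(stepwise, format_path, "")
  sw_rows <- tb$paths[tb$paths$path %in% sw_lab, , drop = FALSE]
  most_prob <- sw_rows$path[which.max(sw_rows$log_weight)]
  curve <- NULL
  if (!is.null(nD_over_nS)) {
    pool <- n_S + n_D
    t_half <- vapply(nD_over_nS, function(r) {
      ns <- pool / (1 + r)
      gi <- build_combination(alpha, beta, nu, m, s, d,
                              n_S = ns, n_D = pool - ns, n_DD = n_DD,
                              gamma = gamma, lam = lam)
      as.numeric(median_hitting_time(hitting_time_model(gi)))
    }, 0)
    curve <- data.frame(ratio = nD_over_nS, t_half = t_half)
  }
  list(graph = g, table = tb, curve = curve,
       accelerates = (n_S + n_D) / n_Tot > s / m,
       condition_lhs = (n_S + n_D) / n_Tot, condition_rhs = s / m,
       worst_ratio = 1 - 2 * s * n_Tot / (m * (n_S + n_D)),
       p_stepwise_approx = 1 / (1 + s * (n_DD + n_S) / (m * n_D)),
       p_stepwise_exact = p_step_exact,
       most_probable_stepwise = most_prob)
}

# ---- chronic myeloid leukemia -------------------------------------------

#' Competing resistance mechanisms in chronic myeloid leukemia
#'
#' Imatinib resistance can arise through a point mutation in the drug
#' target (rate `nu_pm` per day) or through amplification of the driver
#' fusion gene (rate `nu_ga`).  Treating both as single-step routes, the
#' probability that a point mutation wins the race is the rate ratio
#' `nu_pm / (nu_pm + nu_ga)`.  Two refinements:
#'
#' * if the two resistant cell types differ in their survival probability
#'   (`rho_pm`, `rho_ga`), only lineages that persist should count; the
#'   successful-seeding adjustment multiplies each rate by its survival
#'   probability, and point mutations dominate once
#'   `rho_pm / rho_ga > nu_ga / nu_pm`;
#' * if resistance requires *two* amplifications, each adding `s` per day
#'   to the death rate, the amplification route becomes a two-step path of
#'   weight `nu_ga^2 / s` and the point-mutation probability rises to
#'   `nu_pm / (nu_pm + nu_ga^2 / s)`.
#'
#' @param nu_pm,nu_ga daily rates of resistance by point mutation and by
#'   gene amplification.
#' @param s death-rate increment per amplification (for the two-step
#'   model; `NULL` to skip).
#' @param rho_pm,rho_ga average survival probabilities of a lineage
#'   founded by each resistant type.
#' @return list with `p_point_first` (survival-adjusted single-step race),
#'   `rho_ratio_needed` (threshold on `rho_pm/rho_ga` for point mutations
#'   to dominate) and, when `s` is given, `p_point_two_amp`.
#' @examples
#' cml_analysis()$p_point_first            # 1/11
#' cml_analysis(s = 1e-4)$p_point_two_amp
#' @export
cml_analysis <- function(nu_pm = 8e-8, nu_ga = 8e-7, s = NULL,
                         rho_pm = 1, rho_ga = 1) {
  stopifnot(nu_pm > 0, nu_ga > 0, rho_pm >= 0, rho_pm <= 1,
            rho_ga >= 0, rho_ga <= 1)
  out <- list(
    p_point_first = rho_pm * nu_pm / (rho_pm * nu_pm + rho_ga * nu_ga),
    rho_ratio_needed = nu_ga / nu_pm)
  if (!is.null(s)) {
    stopifnot(s > 0)
    out$p_point_two_amp <- nu_pm / (nu_pm + nu_ga^2 / s)
  }
  out
}

# ---- antibacterial multidrug resistance ---------------------------------

#' Which resistance mutation comes first en route to multidrug resistance?
#'
#' Two drugs, two symmetric two-step paths: acquire resistance to drug 1
#' then drug 2, or vice versa.  With equal mutation rates on both paths,
#' the path-weight ratio reduces to the intermediate fitness costs: the
#' probability that drug-1 resistance is acquired first is
#' `c_2 / (c_1 + c_2)`, where `c_i` is the fitness cost of the strain
#' resistant only to drug `i`.  Costs may be given directly or as the
#' single-resistant strains' growth rates relative to wild type
#' (`c_i = lam (1 - ratio_i)`); the wild-type growth rate then cancels.
#'
#' @param ratio_1,ratio_2 relative growth rates (in (0,1)) of the strains
#'   resistant to drug 1 and drug 2; alternatively supply `cost_1`,
#'   `cost_2` directly.
#' @param cost_1,cost_2 absolute fitness costs (override the ratios).
#' @return probability that resistance to drug 1 arises first.
#' @examples
#' mdr_order_probability(0.88, 0.71)   # rifampicin (0.88) first: ~0.7
#' @export
mdr_order_probability <- function(ratio_1 = NULL, ratio_2 = NULL,
                                  cost_1 = NULL, cost_2 = NULL) {
  if (is.null(cost_1) || is.null(cost_2)) {
    stopifnot(ratio_1 > 0, ratio_1 < 1, ratio_2 > 0, ratio_2 < 1)
    cost_1 <- 1 - ratio_1
    cost_2 <- 1 - ratio_2
  }
  stopifnot(cost_1 > 0, cost_2 > 0)
  cost_2 / (cost_1 + cost_2)
}

#' Time to multidrug resistance along two symmetric mutational paths
#'
#' For a strain with wild-type division rate `alpha`, death rate `beta`
#' and per-drug mutation rates `nu_R`, `nu_I`, each mutation costing `s`,
#' the two paths to double resistance have total weight
#' `phi = 2 nu_R nu_I / s`, so with one founding cell
#' `P(T <= t) ~ 1 - ((lam/alpha) / (1 + exp(lam (t - mu))) + beta/alpha)`
#' with `mu = (1/lam) log(lam^2/alpha) + (1/lam) log(s / (2 nu_R nu_I))`.
#'
#' @param alpha,beta wild-type division and death rates.
#' @param nu_R,nu_I mutation rates to the two drugs.
#' @param s shared fitness cost per resistance mutation.
#' @param t times at which to evaluate the cumulative probability.
#' @return list with `mu`, `phi`, `cdf` (data.frame `t`, `p`), and the
#'   underlying [hitting_time_model()].
#' @export
mdr_two_path_analysis <- function(alpha, beta, nu_R, nu_I, s, t = numeric(0)) {
  stopifnot(nu_R > 0, nu_I > 0, s > 0)
  h <- hitting_time_model(phi_N = 2 * nu_R * nu_I / s,
                          alpha = alpha, beta = beta, z = 1)
  cdf <- if (length(t)) data.frame(t = t, p = 1 - hitting_survival(h, t))
  list(mu = h$mu, phi = h$phi_N, cdf = cdf, model = h)
}

#' Relative probability of multidrug resistance between two lineages
#'
#' Compares `P(T <= t)` for two lineages that differ only in their
#' mutation rates.  For small times (while
#' `nu_R nu_I exp(lam t)` stays negligible) the ratio tends to the
#' rate-product ratio `nu_R1 nu_I1 / (nu_R2 nu_I2)`; the full ratio is
#' always returned and the limit form is flagged invalid once the product
#' is no longer small.
#'
#' @param rates_1,rates_2 length-2 vectors `c(nu_R, nu_I)` for the two
#'   lineages.
#' @param t time (vectorised).
#' @inheritParams mdr_two_path_analysis
#' @param limit_tol the limit form is flagged invalid when
#'   `max(nu_R nu_I) * exp(lam t) * alpha / lam^2 / s` exceeds this.
#' @return data.frame with `t`, `ratio` (full form), `ratio_limit`
#'   (rate-product ratio) and `limit_valid`.
#' @export
mdr_relative_probability <- function(rates_1, rates_2, t, alpha, beta, s,
                                     limit_tol = 0.01) {
  stopifnot(length(rates_1) == 2, length(rates_2) == 2)
  h1 <- mdr_two_path_analysis(alpha, beta, rates_1[1], rates_1[2], s)$model
  h2 <- mdr_two_path_analysis(alpha, beta, rates_2[1], rates_2[2], s)$model
  lam <- alpha - beta
  p1 <- 1 - hitting_survival(h1, t)
  p2 <- 1 - hitting_survival(h2, t)
  scale <- pmax(prod(rates_1), prod(rates_2)) * 2 / s * exp(lam * t) *
    alpha / lam^2
  data.frame(t = t, ratio = p1 / p2,
             ratio_limit = prod(rates_1) / prod(rates_2),
             limit_valid = scale <= limit_tol)
}
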