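#' Exact stochastic simulation of the branching process on a graph
#'
#' Runs the continuous-time Markov branching process: every cell at vertex
#' `x` independently divides at rate `alpha(x)`, dies at rate `beta(x)` and
#' produces a daughter at vertex `y` at rate `nu(x, y)` (the parent
#' remains).  The population is bookkept by vertex lineage — the sequence
#' of distinct consecutive vertices in a cell's ancestry — so each run
#' records *which* root-to-target sequence produced the first target cell.
#'
#' Runs are reproducible: the master seed initialises R's generator, a
#' per-run seed table is drawn from it, and run `i` re-seeds the generator
#' with entry `i` — so run `i` of a larger batch equals run `i` of a
#' smaller one, and different master seeds give unrelated batches.
#'
#' @param g a [transition_graph()] (validated; structural errors stop).
#' @param n_runs number of independent realisations.
#' @param t_max time horizon (mandatory); runs still alive at `t_max` are
#'   reported as censored, never dropped.
#' @param seed master integer seed.
#' @param mode `"stop_at_first_target"` halts a run the moment a target
#'   cell appears; `"track_all_paths"` keeps going to `t_max`, recording
#'   the first arrival time of every distinct target lineage.
#' @param pop_cap population guard; a run reaching it is censored
#'   (status `"censored_pop"`).
#' @param record_times optional increasing times at which per-vertex counts
#'   `Z_x(t)` are snapshotted (needed by [estimate_scaled_sizes()]).
#' @return object of class `sim_result`: list with
#'   * `runs`: data.frame (`run`, `status`, `t_end`, `t_hit`, `seed_path`),
#'     where `status` is one of `target_hit`, `extinct`, `censored_time`,
#'     `censored_pop` and `seed_path` is the seeding lineage label (NA if
#'     the target was not reached),
#'   * `snapshots`: array `n_runs x length(record_times) x n_vertices`,
#'   * `arrivals`: per-run data.frames of first arrival times per target
#'     lineage (mode `"track_all_paths"`),
#'   * `graph`, `mode`, `seed`, `record_times`.
#' @examples
#' sim <- simulate_paths(valley_graph(), n_runs = 20, t_max = 40, seed = 1)
#' table(sim$runs$status)
#' @export
simulate_paths <- function(g, n_runs, t_max, seed,
                           mode = c("stop_at_first_target", "track_all_paths"),
                           pop_cap = 1e6, record_times = numeric(0)) {
  stopifnot(inherits(g, "transition_graph"), n_runs >= 1, t_max > 0,
            pop_cap > g$z)
  mode <- match.arg(mode)
  assert_valid_graph(g)
  record_times <- sort(record_times)
  if (length(record_times) && any(record_times > t_max)) {
    stop("record_times must lie within [0, t_max]")
  }
  ids <- g$vertices$id
  ef <- match(g$edges$from, ids) - 1L
  et <- match(g$edges$to, ids) - 1L
  root <- match(g$root, ids) - 1L
  target <- match(g$target, ids) - 1L
  stop_at <- mode == "stop_at_first_target"
  status_names <- c("target_hit", "extinct", "censored_time", "censored_pop")

  runs <- vector("list", n_runs)
  snaps <- if (length(record_times)) {
    array(NA_real_, dim = c(n_runs, length(record_times), length(ids)),
          dimnames = list(NULL, NULL, ids))
  } else NULL
  arrivals <- vector("list", n_runs)
  set.seed(as.integer(seed) %% 2147483647L)
  run_seeds <- sample.int(2147483646L, n_runs, replace = TRUE)
  for (i in seq_len(n_runs)) {
    set.seed(run_seeds[i])
    r <- ssa_run_cpp(g$vertices$alpha, g$vertices$beta, ef, et, g$edges$nu,
                     root, target, g$z, t_max, pop_cap, stop_at, record_times)
    seed_path <- if (!is.null(r$seed_lineage)) {
      format_path(ids[r$seed_lineage + 1L])
    } else NA_character_
    status <- status_names[r$status]
    if (!stop_at && !is.na(r$t_hit) &&
        status %in% c("censored_time", "censored_pop")) {
      status <- "target_hit"  # T is known; only later growth was truncated
    }
    runs[[i]] <- data.frame(run = i, status = status, t_end = r$t_end,
                            t_hit = r$t_hit, seed_path = seed_path)
    if (!is.null(snaps)) snaps[i, , ] <- r$snapshots
    if (!stop_at) {
      arrivals[[i]] <- data.frame(
        path = vapply(r$arrival_lineages,
                      function(l) format_path(ids[l + 1L]), ""),
        time = r$arrival_times)
    }
  }
  structure(list(runs = do.call(rbind, runs), snapshots = snaps,
                 arrivals = if (!stop_at) arrivals,
                 graph = g, mode = mode, seed = seed,
                 record_times = record_times, t_max = t_max),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulation:", nrow(x$runs), "runs, mode", x$mode,
      ", seed", x$seed, "\n")
  print(table(x$runs$status))
  hit <- x$runs$t_hit[!is.na(x$runs$t_hit)]
  if (length(hit)) {
    cat("hitting times: median", format(stats::median(hit), digits = 4),
        "over", length(hit), "hits\n")
  }
  invisible(x)
}

# Clopper-Pearson interval for x successes of n
binom_ci <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  lower <- ifelse(x == 0, 0, stats::qbeta(a, x, n - x + 1))
  upper <- ifelse(x == n, 1, stats::qbeta(1 - a, x + 1, n - x))
  cbind(lower = lower, upper = upper)
}

#' Empirical survival curve of the target hitting time
#'
#' Step-function estimate of `P(T > t)` from simulated runs, with
#' pointwise binomial (Clopper-Pearson) confidence bands.  Runs that never
#' hit the target contribute `T = Inf`; runs censored at `t_max` or at the
#' population cap restrict the curve's validity domain, reported in the
#' `t_valid` attribute.
#'
#' @param sim a [simulate_paths()] result with at least one uncensored run.
#' @param conditional condition on the target being reached, by discarding
#'   runs whose whole population went extinct first (the proxy for
#'   conditioning on root-population survival; the two events coincide in
#'   the small-rate limit)?
#' @param level confidence level of the pointwise bands.
#' @return data.frame (`t`, `survival`, `lower`, `upper`) at the observed
#'   hitting times, with attribute `t_valid`.
#' @export
estimate_hitting_survival <- function(sim, conditional = FALSE, level = 0.95) {
  stopifnot(inherits(sim, "sim_result"))
  runs <- sim$runs
  if (all(runs$status %in% c("censored_time", "censored_pop") & is.na(runs$t_hit))) {
    stop("all runs censored without reaching the target")
  }
  if (conditional) runs <- runs[runs$status != "extinct", , drop = FALSE]
  n <- nrow(runs)
  if (!n) stop("no runs left after conditioning")
  t_hit <- runs$t_hit
  censored <- runs$status %in% c("censored_time", "censored_pop") & is.na(t_hit)
  t_valid <- if (any(censored)) min(runs$t_end[censored]) else Inf
  ts <- sort(unique(t_hit[!is.na(t_hit)]))
  surv <- vapply(ts, function(tt) sum(is.na(t_hit) | t_hit > tt) / n, 0)
  ci <- binom_ci(round(surv * n), n, level)
  out <- data.frame(t = ts, survival = surv, lower = ci[, 1], upper = ci[, 2])
  attr(out, "t_valid") <- t_valid
  attr(out, "n") <- n
  out
}

#' Empirical distribution over seeding paths
#'
#' Frequency with which each root-to-target lineage produced the first
#' target cell, among runs where the target was reached, with binomial
#' confidence intervals.  Paths supplied in `paths` but never observed are
#' reported with frequency 0.
#'
#' @param sim a [simulate_paths()] result.
#' @param paths optional list of vertex-id sequences to tabulate against
#'   (e.g. the output of [enumerate_paths()]).
#' @param level confidence level.
#' @return data.frame (`path`, `hits`, `frequency`, `lower`, `upper`),
#'   with attribute `n_hit` (number of runs reaching the target).
#' @export
estimate_path_distribution <- function(sim, paths = NULL, level = 0.95) {
  stopifnot(inherits(sim, "sim_result"))
  sp <- sim$runs$seed_path[!is.na(sim$runs$seed_path)]
  if (!length(sp)) stop("no run reached the target")
  labels <- if (!is.null(paths)) {
    vapply(paths, format_path, "")
  } else sort(unique(sp))
  counts <- vapply(labels, function(l) sum(sp == l), 0L)
  extra <- setdiff(unique(sp), labels)
  if (length(extra)) {
    labels <- c(labels, extra)
    counts <- c(counts, vapply(extra, function(l) sum(sp == l), 0L))
  }
  n <- length(sp)
  ci <- binom_ci(counts, n, level)
  out <- data.frame(path = labels, hits = counts, frequency = counts / n,
                    lower = ci[, 1], upper = ci[, 2], row.names = NULL)
  attr(out, "n_hit") <- n
  out
}

#' Scaled population sizes and the realised growth variable W
#'
#' At a snapshot time `t_f`, the scaled counts `exp(-lam t_f) Z_x(t_f)`
#' approximate `W * Phi_x`: the run-specific growth variable `W` times the
#' deterministic ratio `Phi_x` from [weight_table()].  The root's scaled
#' size is the run's `W` estimate; dividing mean scaled sizes by the mean
#' `W` estimates `Phi_x`.
#'
#' @param sim a [simulate_paths()] result with `t_f` among its
#'   `record_times`.
#' @param t_f snapshot time.
#' @return list with `scaled` (runs x vertices matrix), `W` (per-run
#'   estimate), `Phi_hat` (named vector over non-target vertices).
#' @export
estimate_scaled_sizes <- function(sim, t_f) {
  stopifnot(inherits(sim, "sim_result"))
  if (is.null(sim$snapshots)) stop("simulation was run without record_times")
  j <- which(abs(sim$record_times - t_f) < 1e-9)
  if (!length(j)) {
    stop("t_f = ", t_f, " is not among the recorded snapshot times")
  }
  g <- sim$graph
  lam <- root_lam(g)
  scaled <- sim$snapshots[, j[1], , drop = FALSE]
  scaled <- matrix(scaled, nrow = dim(sim$snapshots)[1],
                   dimnames = list(NULL, g$vertices$id)) * exp(-lam * t_f)
  ok <- stats::complete.cases(scaled)
  scaled <- scaled[ok, , drop = FALSE]
  if (!nrow(scaled)) stop("no run has a complete snapshot at t_f")
  W <- scaled[, g$root]
  nontarget <- setdiff(g$vertices$id, g$target)
  Phi_hat <- colMeans(scaled[, nontarget, drop = FALSE]) / mean(W)
  list(scaled = scaled, W = W, Phi_hat = Phi_hat)
}
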