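#' Small-rate approximation of the target hitting time
#'
#' Packages the root parameters and total target weight needed by the
#' asymptotic hitting-time law.  The law states that as the target-seeding
#' rates tend to zero, `T - mu` converges in distribution, with the
#' centring constant
#' `mu = (1/lam) * log(lam^2 / (alpha * phi_N))`,
#' and limiting survival function
#' `((lam/alpha) / (1 + exp(lam t)) + beta/alpha)^z`.
#' The `beta/alpha` atom reflects root lineages that die out (for such
#' lineages the target is never reached at all).
#'
#' @param x a [transition_graph()] or a [weight_table()]; alternatively
#'   supply `phi_N`, `alpha`, `beta`, `z` directly with `x = NULL`.
#' @param phi_N,alpha,beta,z scalar overrides when building from raw
#'   parameters (e.g. a closed-form scenario weight).
#' @return object of class `hitting_time_model`: list with `alpha`, `beta`,
#'   `lam`, `z`, `phi_N`, `log_phi_N`, `mu`, `p_ever` (the probability
#'   `1 - (beta/alpha)^z` that the target is ever reached).
#' @examples
#' h <- hitting_time_model(path_graph(4))
#' h$mu
#' hitting_survival(h, h$mu)
#' @export
hitting_time_model <- function(x = NULL, phi_N = NULL, alpha = NULL,
                               beta = NULL, z = NULL) {
  if (inherits(x, "transition_graph")) x <- weight_table(x)
  if (inherits(x, "weight_table")) {
    alpha <- x$alpha; beta <- x$beta; z <- x$z
    log_phi_N <- x$log_phi_N
  } else if (is.null(x)) {
    stopifnot(is.numeric(phi_N), phi_N > 0, is.numeric(alpha),
              is.numeric(beta), is.numeric(z), z >= 1)
    log_phi_N <- log(phi_N)
  } else {
    stop("x must be a transition_graph, a weight_table, or NULL")
  }
  lam <- alpha - beta
  if (lam <= 0) stop("root growth rate must be positive (alpha > beta)")
  mu <- (log(lam^2 / alpha) - log_phi_N) / lam
  structure(list(alpha = alpha, beta = beta, lam = lam, z = as.integer(z),
                 phi_N = exp(log_phi_N), log_phi_N = log_phi_N, mu = mu,
                 p_ever = 1 - (beta / alpha)^z),
            class = "hitting_time_model")
}

#' @export
print.hitting_time_model <- function(x, ...) {
  cat("Hitting-time approximation (small seeding rates)\n")
  cat(sprintf("  alpha = %g, beta = %g, lam = %g, z = %d\n",
              x$alpha, x$beta, x$lam, x$z))
  cat(sprintf("  phi_N = %g, mu = %g, P(T < Inf) ~ %g\n",
              x$phi_N, x$mu, x$p_ever))
  invisible(x)
}

#' Approximate survival function of the target hitting time
#'
#' Evaluates
#' `P(T > t) ~ ((lam/alpha) / (1 + exp(lam t) phi_N alpha / lam^2) + beta/alpha)^z`,
#' which equals the limiting law evaluated at `t - mu` (the identity
#' `exp(lam mu) = lam^2 / (alpha phi_N)` shifts one onto the other).  The
#' value decreases from 1 (`t -> -Inf`) to the never-hit probability
#' `(beta/alpha)^z` (`t -> +Inf`).
#'
#' @param h a [hitting_time_model()].
#' @param t time (vectorised; infinities allowed).
#' @param limit_law if TRUE, evaluate the centred limit law (i.e. drop the
#'   `phi_N alpha / lam^2` factor so the argument is `t - mu`).
#' @return numeric vector of survival probabilities.
#' @export
hitting_survival <- function(h, t, limit_law = FALSE) {
  stopifnot(inherits(h, "hitting_time_model"))
  lx <- h$lam * t + if (limit_law) 0 else h$log_phi_N + log(h$alpha / h$lam^2)
  # (lam/alpha)/(1+e^lx) computed stably for large |lx|
  base <- (h$lam / h$alpha) / (1 + exp(lx)) + h$beta / h$alpha
  base[lx == -Inf] <- 1
  base[lx == Inf] <- h$beta / h$alpha
  base^h$z
}

#' Hitting-time law conditioned on the target being reached
#'
#' Conditions the approximate law on the root population surviving (the
#' proxy for the target ever being reached).  Writing `s1(t)` for the
#' single-cell (`z = 1`) unconditional survival value, independence of the
#' `z` founding lineages gives the conditional survival
#' `(s1(t)^z - (beta/alpha)^z) / (1 - (beta/alpha)^z)`.
#' For `z = 1` this reduces to the logistic `1 / (1 + exp(lam (t - mu)))`,
#' so `mu` is then the conditional median.  The density (minus the
#' derivative of the survival) is returned alongside.
#'
#' @param h a [hitting_time_model()] with `beta < alpha`.
#' @param t time (vectorised).
#' @return data.frame with columns `t`, `survival`, `density`.
#' @export
conditional_hitting <- function(h, t) {
  stopifnot(inherits(h, "hitting_time_model"))
  if (h$beta >= h$alpha) {
    stop("conditioning requires a surviving root population (beta < alpha)")
  }
  q <- (h$beta / h$alpha)^h$z
  lx <- h$lam * t + h$log_phi_N + log(h$alpha / h$lam^2)  # lam * (t - mu)
  ex <- exp(lx)
  s1 <- (h$lam / h$alpha) / (1 + ex) + h$beta / h$alpha
  surv <- (s1^h$z - q) / (1 - q)
  surv[lx == -Inf] <- 1
  surv[lx == Inf] <- 0
  # d s1/dt = -(lam/alpha) * lam * ex / (1+ex)^2
  dens <- h$z * s1^(h$z - 1) * (h$lam / h$alpha) * h$lam * ex / (1 + ex)^2 / (1 - q)
  dens[!is.finite(lx)] <- 0
  data.frame(t = t, survival = surv, density = dens)
}

#' Approximate median time until the target is populated
#'
#' Conditional on the root population surviving: for `z = 1` the median is
#' exactly the centring constant `mu`; for `z > 1` the initial-size shift
#' `h(z) ~ (1/lam) log(z lam / alpha)` (an asymptotic, large-`z` form)
#' gives `t_half ~ mu - h(z) = (1/lam) log(lam / (z phi_N))`.  The regime
#' used is attached as the `"regime"` attribute; for small `z > 1` the
#' large-`z` form is a documented approximation.
#'
#' @param h a [hitting_time_model()].
#' @return numeric median with attribute `regime` (`"z1"` or `"large_z"`).
#' @examples
#' median_hitting_time(hitting_time_model(path_graph(4)))
#' @export
median_hitting_time <- function(h) {
  stopifnot(inherits(h, "hitting_time_model"))
  if (h$z == 1L) {
    structure(h$mu, regime = "z1")
  } else {
    structure((log(h$lam) - log(h$z) - h$log_phi_N) / h$lam,
              regime = "large_z")
  }
}

#' Sample the limiting scaled population size W
#'
#' The scaled root-driven population `exp(-lam t) Z_x(t)` converges almost
#' surely to `W * Phi_x`, where `W` is a binomial--Erlang mixture: the sum
#' of `K` independent Exponential(`lam/alpha`) variables with
#' `K ~ Binomial(z, lam/alpha)`.  Its mean is exactly `z` and its atom at
#' zero, `P(W = 0) = (beta/alpha)^z`, is the probability the whole
#' population dies out.
#'
#' @param z initial root cell count (non-negative integer).
#' @param alpha,beta root division and death rates with `alpha > beta`.
#' @param n number of draws.
#' @return numeric vector of `n` non-negative draws.
#' @examples
#' set.seed(1)
#' mean(sample_W(5, 1, 0.4, 1e4))   # ~ 5
#' @export
sample_W <- function(z, alpha, beta, n) {
  lam <- alpha - beta
  if (lam <= 0) stop("requires alpha > beta")
  stopifnot(z >= 0, z == round(z), n >= 1)
  k <- stats::rbinom(n, size = z, prob = lam / alpha)
  w <- numeric(n)
  pos <- k > 0
  w[pos] <- stats::rgamma(sum(pos), shape = k[pos], rate = lam / alpha)
  w
}
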