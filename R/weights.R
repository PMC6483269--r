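# numerically stable log(sum(exp(x))) for weight totals spanning many
# orders of magnitude (application rates run 1e-8 .. 1e-1)
log_sum_exp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Weight of a root-to-target path or walk
#'
#' The weight of a sequence `p = (p1, ..., p_{l+1})` is the product of the
#' transition rates along its edges divided by the product of the fitness
#' costs `lam - lam(p_i)` of its internal vertices (`i = 2..l`; the empty
#' product is 1, so a single-edge path has weight equal to its edge rate).
#' Weights drive both the target hitting time (through the total weight)
#' and the probability that this particular sequence seeds the target.
#' Walks are weighted identically, counting repeated visits each time they
#' occur.
#'
#' Computation is carried out in log space; the linear value can underflow
#' to 0 harmlessly while the log remains finite.
#'
#' @param g a [transition_graph()].
#' @param p a vertex-id sequence (character vector), typically from
#'   [enumerate_paths()] or [enumerate_walks()].
#' @param log return the log weight?
#' @return positive numeric weight (or its log).
#' @examples
#' g <- valley_graph()
#' sequence_weight(g, c("1", "2", "3"))   # 0.1 * 0.1 / 0.8 = 0.0125
#' sequence_weight(g, c("1", "3"))        # 0.01
#' @export
sequence_weight <- function(g, p, log = FALSE) {
  p <- check_sequence(g, p, kind = "walk")
  lam1 <- root_lam(g)
  l <- length(p) - 1L
  nus <- vapply(seq_len(l), function(i) edge_rate(g, p[i], p[i + 1L]), 0)
  lw <- base::log(nus[1])
  if (l >= 2L) {
    internal <- p[2:l]
    costs <- lam1 - vertex_row(g, internal)$lam
    if (any(costs <= 0)) {
      stop("weight undefined: internal vertices ",
           paste(unique(internal[costs <= 0]), collapse = ", "),
           " have growth rate >= root growth rate")
    }
    lw <- lw + sum(base::log(nus[-1])) - sum(base::log(costs))
  }
  if (log) lw else exp(lw)
}

#' Table of path weights, totals and growth ratios
#'
#' For a set of root-to-vertex sequences (by default every simple path from
#' the root to every other vertex), computes each sequence's weight, the
#' per-vertex total weights `phi_x` (sum of weights of root-to-`x`
#' sequences), the target total `phi_N`, and the growth ratios
#' `Phi_x = phi_x / (lam - lam(x))` (with `Phi_root = 1`), which give the
#' asymptotic relative population sizes: `Z_x(t) ~ W * Phi_x * exp(lam t)`.
#'
#' @param g a [transition_graph()].
#' @param sequences optional list of vertex-id sequences all starting at the
#'   root; defaults to all simple root-to-`x` paths for every vertex `x`.
#'   Supplying truncated walk sets (from [enumerate_walks()]) yields the
#'   cyclic-graph approximation of the totals.
#' @param max_paths passed to [enumerate_paths()].
#' @return object of class `weight_table`: list with
#'   * `paths`: data.frame (`path`, `to`, `length`, `log_weight`, `weight`,
#'     and for target sequences `probability`),
#'   * `phi`, `log_phi`: named per-vertex totals,
#'   * `Phi`: named growth ratios for non-target vertices,
#'   * `phi_N`, `log_phi_N`: target total weight,
#'   * `lam`, `alpha`, `beta`, `z`: root parameters (for downstream laws).
#' @examples
#' weight_table(valley_graph())
#' @export
weight_table <- function(g, sequences = NULL, max_paths = 10000L) {
  stopifnot(inherits(g, "transition_graph"))
  assert_valid_graph(g)
  lam1 <- root_lam(g)
  if (is.null(sequences)) {
    others <- setdiff(g$vertices$id, g$root)
    sequences <- unlist(lapply(others, function(x) {
      enumerate_paths(g, g$root, x, max_paths = max_paths)
    }), recursive = FALSE)
  } else {
    sequences <- lapply(sequences, function(p) check_sequence(g, p, "walk"))
    if (any(vapply(sequences, `[`, "", 1L) != g$root)) {
      stop("all sequences must start at the root")
    }
  }
  ends <- vapply(sequences, function(p) p[length(p)], "")
  if (!any(ends == g$target)) {
    stop("no sequence reaches the target: target unreachable or sequence ",
         "set incomplete")
  }
  lw <- vapply(sequences, function(p) sequence_weight(g, p, log = TRUE), 0)
  paths <- data.frame(path = vapply(sequences, format_path, ""),
                      to = ends,
                      length = lengths(sequences) - 1L,
                      log_weight = lw,
                      weight = exp(lw))
  log_phi <- vapply(split(lw, ends), log_sum_exp, 0)
  phi <- exp(log_phi)
  nontarget <- setdiff(names(phi), g$target)
  costs <- lam1 - vertex_row(g, nontarget)$lam
  Phi <- stats::setNames(phi[nontarget] / costs, nontarget)
  Phi[g$root] <- 1
  log_phi_N <- unname(log_phi[g$target])
  paths$probability <- ifelse(paths$to == g$target,
                              exp(paths$log_weight - log_phi_N), NA_real_)
  rv <- vertex_row(g, g$root)
  structure(list(paths = paths, phi = phi, log_phi = log_phi, Phi = Phi,
                 phi_N = exp(log_phi_N), log_phi_N = log_phi_N,
                 lam = lam1, alpha = rv$alpha, beta = rv$beta, z = g$z,
                 root = g$root, target = g$target),
            class = "weight_table")
}

#' @export
print.weight_table <- function(x, ...) {
  cat("Weight table (root", x$root, "-> target", x$target, ")\n")
  cat("  phi_N =", format(x$phi_N, digits = 6),
      " log phi_N =", format(x$log_phi_N, digits = 6), "\n")
  tp <- x$paths[x$paths$to == x$target, , drop = FALSE]
  print(tp[, c("path", "length", "weight", "probability")], row.names = FALSE)
  invisible(x)
}

# rows of the table's target sequences matching path p; error if absent
match_target_path <- function(table, p) {
  key <- format_path(as.character(p))
  i <- which(table$paths$path == key & table$paths$to == table$target)
  if (!length(i)) stop("sequence ", key, " is not a target sequence of this table")
  i
}

#' Probability that the target is seeded via a given path
#'
#' In the small-transition-rate limit, conditional on the root population
#' surviving, the probability that the founding target cell arrives along
#' sequence `p` is its normalised weight `w(p) / phi_N`.  A list of
#' sequences gives the probability of seeding via any of them (their
#' normalised weights summed).
#'
#' @param table a [weight_table()] whose sequence set covers all
#'   root-to-target routes under consideration.
#' @param p a vertex-id sequence, or a list of them.
#' @return probability in (0, 1].
#' @examples
#' tb <- weight_table(valley_graph())
#' path_probability(tb, c("1", "2", "3"))   # 5/9
#' @export
path_probability <- function(table, p) {
  stopifnot(inherits(table, "weight_table"))
  if (is.list(p)) {
    i <- unique(unlist(lapply(p, match_target_path, table = table)))
  } else {
    i <- match_target_path(table, p)
  }
  exp(log_sum_exp(table$paths$log_weight[i]) - table$log_phi_N)
}

#' Probability of beating all competing paths by a time margin
#'
#' Probability, conditional on root survival and for small seeding rates,
#' that the target is reached along `p` more than `t` time units before it
#' is reached along any other sequence in the table:
#' `w(p) / (w(p) + exp(lam t) * sum of the other weights)`.
#' At `t = 0` this is [path_probability()]; it decreases logistically in
#' `t` at rate `lam`.
#'
#' @inheritParams path_probability
#' @param t time margin (any real; vectorised).
#' @return numeric vector of probabilities, one per `t`.
#' @examples
#' tb <- weight_table(valley_graph())
#' time_advantage(tb, c("1", "2", "3"), t = c(0, 1, 2))
#' @export
time_advantage <- function(table, p, t = 0) {
  stopifnot(inherits(table, "weight_table"))
  i <- match_target_path(table, p)
  tgt <- which(table$paths$to == table$target)
  lw_p <- log_sum_exp(table$paths$log_weight[i])
  lw_rest <- log_sum_exp(table$paths$log_weight[setdiff(tgt, i)])
  if (!is.finite(lw_rest)) return(rep(1, length(t)))  # unique path
  vapply(t, function(tt) {
    1 / (1 + exp(table$lam * tt + lw_rest - lw_p))
  }, 0)
}
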