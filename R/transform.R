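#' Expand a vertex into a finite mixture of fitness effects
#'
#' Models a stochastic fitness cost: a cell transitioning into vertex `y`
#' receives division/death rates `(alpha_i, beta_i)` with probability
#' `pi_i`.  This is equivalent to replacing `y` by one vertex per mixture
#' component, splitting every incoming edge rate `nu(x, y)` into
#' `nu(x, y) * pi_i`, and copying every outgoing edge of `y` to each new
#' vertex at its original rate.  The analytic and simulation machinery then
#' applies unchanged to the expanded graph.
#'
#' @param g a [transition_graph()].
#' @param mix a `fitness_mixture()`: components with division rate, death
#'   rate and probability, plus the vertex to expand.
#' @return a new [transition_graph()]; the input is not modified.  The new
#'   vertex ids are `"<y>.<component id>"`.
#' @examples
#' g <- path_graph(4)
#' mix <- fitness_mixture("2", alpha = c(1, 1), beta = c(1.0, 1.6),
#'                        pi = c(0.3, 0.7))
#' expand_fitness_distribution(g, mix)
#' @export
expand_fitness_distribution <- function(g, mix) {
  stopifnot(inherits(g, "transition_graph"), inherits(mix, "fitness_mixture"))
  y <- mix$vertex
  vertex_row(g, y)
  if (y %in% c(g$root, g$target)) {
    stop("cannot expand the root or target vertex, only intermediates")
  }
  lam1 <- root_lam(g)
  comp_lam <- mix$components$alpha - mix$components$beta
  if (any(comp_lam >= lam1)) {
    stop("every mixture component growth rate must be below the root growth rate")
  }
  new_ids <- paste(y, mix$components$id, sep = ".")
  if (any(new_ids %in% g$vertices$id)) {
    stop("expanded vertex ids collide with existing ids: ",
         paste(intersect(new_ids, g$vertices$id), collapse = ", "))
  }
  keep <- g$vertices[g$vertices$id != y, c("id", "alpha", "beta")]
  vertices <- rbind(keep,
                    data.frame(id = new_ids,
                               alpha = mix$components$alpha,
                               beta = mix$components$beta))
  e <- g$edges
  incoming <- e[e$to == y & e$from != y, , drop = FALSE]
  outgoing <- e[e$from == y & e$to != y, , drop = FALSE]
  rest <- e[e$from != y & e$to != y, , drop = FALSE]
  new_in <- do.call(rbind, lapply(seq_len(nrow(mix$components)), function(i) {
    data.frame(from = incoming$from, to = new_ids[i],
               nu = incoming$nu * mix$components$pi[i])
  }))
  new_out <- do.call(rbind, lapply(seq_len(nrow(mix$components)), function(i) {
    data.frame(from = new_ids[i], to = outgoing$to, nu = outgoing$nu)
  }))
  edges <- rbind(rest, new_in, new_out)
  transition_graph(vertices, edges, root = g$root, target = g$target, z = g$z)
}

#' Specify a finite distribution of fitness effects
#'
#' @param vertex the (intermediate) vertex whose post-transition fitness is
#'   random.
#' @param alpha,beta numeric vectors of per-component division and death
#'   rates.  Both are required — two states with equal growth rate but
#'   different turnover have different stochastic behaviour.
#' @param pi component probabilities; must sum to 1 within `tol`.
#' @param id optional component labels (default `1..k`).
#' @param tol tolerance on `sum(pi) - 1`.
#' @return object of class `fitness_mixture`.
#' @export
fitness_mixture <- function(vertex, alpha, beta, pi, id = seq_along(pi),
                            tol = 1e-12) {
  stopifnot(length(alpha) == length(pi), length(beta) == length(pi),
            all(pi > 0), all(alpha >= 0), all(beta >= 0))
  if (abs(sum(pi) - 1) > tol) {
    stop("mixture probabilities sum to ", format(sum(pi), digits = 15),
         ", not 1 (tol ", tol, ")")
  }
  structure(list(vertex = as.character(vertex),
                 components = data.frame(id = as.character(id),
                                         alpha = alpha, beta = beta, pi = pi)),
            class = "fitness_mixture")
}

#' Adjust target-seeding rates to count only successful founders
#'
#' The hitting time `T` waits for the *first* target cell, whose progeny
#' may nonetheless die out.  To wait instead for the first target cell
#' whose lineage survives forever, multiply every rate into the target by
#' the target survival probability `lam(N)/alpha(N)`; all results then
#' apply verbatim to the adjusted graph.
#'
#' @param g a [transition_graph()].
#' @return a new [transition_graph()] with adjusted target-incoming rates.
#' @examples
#' g <- path_graph(4)            # lam(target) = 0.4, alpha(target) = 1
#' successful_seeding_adjustment(g)$edges   # rate into target: 0.05 -> 0.02
#' @export
successful_seeding_adjustment <- function(g) {
  stopifnot(inherits(g, "transition_graph"))
  tv <- vertex_row(g, g$target)
  if (tv$alpha <= 0 || tv$lam <= 0) {
    stop("target survival probability lam(N)/alpha(N) is zero: every ",
         "founding lineage dies out and the successful-cell hitting time ",
         "is almost surely infinite")
  }
  e <- g$edges
  e$nu[e$to == g$target] <- e$nu[e$to == g$target] * tv$lam / tv$alpha
  transition_graph(g$vertices[, c("id", "alpha", "beta")], e,
                   root = g$root, target = g$target, z = g$z)
}

#' Growth-and-transition rate matrix and its eigenvalue condition
#'
#' For the non-target vertices, builds the matrix `A` with diagonal entries
#' the growth rates `lam(i)` and off-diagonal entries `a[i, j] = nu(j, i)`
#' for each edge `(j, i)`.  The small-rate hitting-time results extend to
#' cyclic graphs exactly when the largest real eigenvalue of `A` equals the
#' root growth rate and is simple.  For acyclic graphs `A` is triangular
#' under a topological order, so the condition reduces to the standing
#' fitness assumption and the flag is always true there.
#'
#' @param g a [transition_graph()].
#' @param tol numeric tolerance: the condition requires
#'   `|lam_star - lam| <= tol * max(1, |lam|)` and an eigenvalue gap
#'   exceeding `tol` for simplicity.
#' @return list with `A` (matrix, rows/cols in `setdiff(vertex order,
#'   target)`), `lam_star` (largest real eigenvalue), `condition`
#'   (TRUE/FALSE) and `gap` (distance from `lam_star` to the next
#'   eigenvalue real part).
#' @examples
#' rate_matrix_and_eigencheck(path_graph(4))$condition   # TRUE
#' @export
rate_matrix_and_eigencheck <- function(g, tol = 1e-9) {
  stopifnot(inherits(g, "transition_graph"))
  ids <- setdiff(g$vertices$id, g$target)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(A) <- vertex_row(g, ids)$lam
  e <- g$edges[g$edges$to != g$target & g$edges$from != g$target, , drop = FALSE]
  if (nrow(e)) A[cbind(match(e$to, ids), match(e$from, ids))] <- e$nu
  ev <- tryCatch(eigen(A, only.values = TRUE)$values,
                 error = function(err) stop("eigen-solver failure: ",
                                            conditionMessage(err)))
  re <- sort(Re(ev), decreasing = TRUE)
  lam_star <- re[1]
  gap <- if (n > 1) re[1] - re[2] else Inf
  lam1 <- root_lam(g)
  condition <- abs(lam_star - lam1) <= tol * max(1, abs(lam1)) && gap > tol
  list(A = A, lam_star = lam_star, condition = condition, gap = gap)
}
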