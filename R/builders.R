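#' Canonical example graphs
#'
#' Small graphs used throughout the documentation and tests.
#'
#' * `path_graph(n)` — the linear chain `1 -> 2 -> ... -> n`; the simplest
#'   multi-step system, e.g. sequential mutation accumulation.  Defaults put
#'   a fitness cost on every intermediate vertex (root grows at
#'   `alpha - beta_root`, intermediates decline at `alpha - beta_mid`).
#' * `valley_graph()` — three vertices with a direct root-to-target edge and
#'   an indirect two-step route through a deleterious intermediate (a
#'   fitness valley).  With the default rates the indirect route is the more
#'   probable seeding path even though its intermediate is costly.
#' * `cycle_walk_graph()` — four vertices with a reversible edge between the
#'   two intermediates, so root-to-target *walks* (sequences revisiting a
#'   vertex) compete with the simple path.
#'
#' @param n number of vertices in the chain (>= 2).
#' @param alpha common division rate.
#' @param beta_root root death rate.
#' @param beta_mid death rate of intermediate vertices.
#' @param beta_target death rate of the target vertex.
#' @param nu transition rate used on every edge.
#' @param z initial root cell count.
#' @param nu_direct rate of the direct root-to-target edge.
#' @param nu1 root-to-intermediate rate; `nu2` rate of the reversible pair of
#'   edges between the intermediates; `nu_out` rate into the target.
#' @return A [transition_graph()].
#' @examples
#' path_graph(4)
#' valley_graph()
#' @export
path_graph <- function(n = 4, alpha = 1, beta_root = 0.4, beta_mid = 1.3,
                       beta_target = 0.6, nu = 0.05, z = 1L) {
  stopifnot(n >= 2)
  ids <- as.character(seq_len(n))
  beta <- c(beta_root, rep(beta_mid, max(0L, n - 2L)), beta_target)
  transition_graph(
    vertices = data.frame(id = ids, alpha = alpha, beta = beta),
    edges = data.frame(from = ids[-n], to = ids[-1], nu = nu),
    root = ids[1], target = ids[n], z = z)
}

#' @rdname path_graph
#' @export
valley_graph <- function(alpha = 0.9, beta_root = 0.3, alpha_mid = 0.2,
                         beta_mid = 0.4, nu = 0.1, nu_direct = nu^2, z = 1L) {
  transition_graph(
    vertices = data.frame(id = c("1", "2", "3"),
                          alpha = c(alpha, alpha_mid, alpha),
                          beta  = c(beta_root, beta_mid, beta_root)),
    edges = data.frame(from = c("1", "2", "1"),
                       to   = c("2", "3", "3"),
                       nu   = c(nu, nu, nu_direct)),
    root = "1", target = "3", z = z)
}

#' @rdname path_graph
#' @export
cycle_walk_graph <- function(alpha = 1, beta_root = 0.4, beta_mid = 1.3,
                             beta_target = 0.6, nu1 = 0.01, nu2 = 0.5,
                             nu_out = 0.01, z = 1L) {
  transition_graph(
    vertices = data.frame(id = c("1", "2", "3", "4"),
                          alpha = alpha,
                          beta = c(beta_root, beta_mid, beta_mid, beta_target)),
    edges = data.frame(from = c("1", "2", "3", "2"),
                       to   = c("2", "3", "2", "4"),
                       nu   = c(nu1, nu2, nu2, nu_out)),
    root = "1", target = "4", z = z)
}
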