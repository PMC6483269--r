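# Independent brute-force oracles, deliberately kept free of the package's
# own enumeration and weight code paths.

# all simple paths from `from` to `to` by depth-first search over the raw
# edge data.frame
dfs_paths <- function(edges, from, to) {
  out <- list()
  recurse <- function(path) {
    last <- path[length(path)]
    if (last == to) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (y in sort(edges$to[edges$from == last])) {
      if (!y %in% path) recurse(c(path, y))
    }
  }
  recurse(from)
  out
}

# number of walks of length exactly l between all vertex pairs, by powers of
# the adjacency matrix (no-backtrack condition is vacuous without self-loops)
walk_count_oracle <- function(g, from, to, max_len) {
  ids <- g$vertices$id
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  A[cbind(match(g$edges$from, ids), match(g$edges$to, ids))] <- 1
  P <- diag(length(ids)); dimnames(P) <- dimnames(A)
  total <- 0
  for (l in seq_len(max_len)) {
    P <- P %*% A
    total <- total + P[from, to]
  }
  total
}

# direct arithmetic weight of a sequence, no log-space tricks
naive_weight <- function(g, p) {
  lam1 <- g$vertices$lam[g$vertices$id == g$root]
  w <- 1
  for (i in seq_len(length(p) - 1L)) {
    w <- w * g$edges$nu[g$edges$from == p[i] & g$edges$to == p[i + 1L]]
  }
  if (length(p) > 2L) {
    for (v in p[2:(length(p) - 1L)]) {
      w <- w / (lam1 - g$vertices$lam[g$vertices$id == v])
    }
  }
  w
}

path_key <- function(p) paste(p, collapse = " -> ")

parse_path_label <- function(s) strsplit(s, " -> ", fixed = TRUE)[[1]]

edge_rate_of <- function(g, from, to) {
  g$edges$nu[g$edges$from == from & g$edges$to == to]
}
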