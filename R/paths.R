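#' Enumerate simple paths between two vertices
#'
#' Returns every simple path (all vertices distinct) from `from` to `to`,
#' in deterministic lexicographic order over the vertex-id sequences, so
#' that path indices are stable across runs and platforms.
#'
#' @param g a [transition_graph()].
#' @param from,to vertex ids; default root and target.
#' @param max_paths guard against combinatorial blow-up: if more than this
#'   many simple paths exist an error is raised rather than silently
#'   truncating.
#' @return list of character vectors (each a vertex-id sequence).  Empty
#'   list when no path exists.
#' @examples
#' enumerate_paths(valley_graph())   # list((1,2,3), (1,3))
#' @export
enumerate_paths <- function(g, from = g$root, to = g$target,
                            max_paths = 10000L) {
  stopifnot(inherits(g, "transition_graph"))
  from <- as.character(from); to <- as.character(to)
  vertex_row(g, c(from, to))  # id check
  if (from == to) return(list())
  if (nrow(g$edges) == 0L) return(list())
  ig <- as_igraph(g)
  ps <- igraph::all_simple_paths(ig, from = from, to = to, mode = "out")
  if (length(ps) > max_paths) {
    stop("more than max_paths = ", max_paths, " simple paths from ",
         from, " to ", to)
  }
  ps <- lapply(ps, function(p) igraph::as_ids(p))
  sort_sequences(ps)
}

#' Enumerate bounded-length walks between two vertices
#'
#' A walk may revisit vertices (cycles allowed) but never repeats a vertex
#' in two consecutive positions — automatic here since the graph has no
#' self-loops.  All walks of edge-length at most `max_len` from `from` to
#' `to` are returned, which always includes the simple paths of length
#' `<= max_len`.  Output order is lexicographic over vertex sequences.
#'
#' @inheritParams enumerate_paths
#' @param max_len maximum number of edges in a walk.  If it is below the
#'   shortest-path length an empty list is returned with a warning.
#' @param max_walks blow-up guard, as `max_paths` in [enumerate_paths()].
#' @return list of character vectors.
#' @examples
#' g <- cycle_walk_graph()
#' enumerate_walks(g, max_len = 4)   # includes (1,2,4) and (1,2,3,2,4)
#' @export
enumerate_walks <- function(g, from = g$root, to = g$target, max_len,
                            max_walks = 100000L) {
  stopifnot(inherits(g, "transition_graph"), max_len >= 1)
  from <- as.character(from); to <- as.character(to)
  vertex_row(g, c(from, to))
  ig <- as_igraph(g)
  sp <- suppressWarnings(igraph::distances(ig, v = from, to = to, mode = "out")[1, 1])
  if (!is.finite(sp)) return(list())
  if (max_len < sp) {
    warning("max_len = ", max_len, " is below the shortest path length ", sp)
    return(list())
  }
  out_adj <- split(g$edges$to, factor(g$edges$from, levels = g$vertices$id))
  walks <- list()
  frontier <- list(from)
  for (l in seq_len(max_len)) {
    nxt <- list()
    for (w in frontier) {
      last <- w[length(w)]
      for (y in out_adj[[last]]) {
        w2 <- c(w, y)
        if (y == to) walks[[length(walks) + 1L]] <- w2
        if (l < max_len) nxt[[length(nxt) + 1L]] <- w2
        if (length(walks) > max_walks) {
          stop("more than max_walks = ", max_walks, " walks")
        }
      }
    }
    frontier <- nxt
  }
  sort_sequences(walks)
}

# lexicographic order over variable-length id sequences ("" pads short ones,
# so a proper prefix sorts before its extensions)
sort_sequences <- function(seqs) {
  if (length(seqs) <= 1L) return(seqs)
  len <- max(lengths(seqs))
  pad <- lapply(seq_len(len), function(i) {
    vapply(seqs, function(s) if (length(s) >= i) s[i] else "", "")
  })
  seqs[do.call(order, c(pad, list(method = "radix")))]
}

# "1 -> 2 -> 3" labels used in tabular output
format_path <- function(p) paste(p, collapse = " -> ")

parse_path <- function(s) strsplit(s, " -> ", fixed = TRUE)[[1]]

# checks a sequence is a walk of g (consecutive pairs are edges); paths
# additionally have distinct vertices
check_sequence <- function(g, p, kind = c("any", "path", "walk")) {
  kind <- match.arg(kind)
  p <- as.character(p)
  if (length(p) < 2L) stop("a path/walk needs at least two vertices")
  vertex_row(g, unique(p))
  key <- paste(g$edges$from, g$edges$to, sep = "\r")
  steps <- paste(p[-length(p)], p[-1L], sep = "\r")
  miss <- !(steps %in% key)
  if (any(miss)) {
    stop("sequence uses non-edges: ",
         paste(gsub("\r", " -> ", steps[miss]), collapse = ", "))
  }
  if (kind == "path" && anyDuplicated(p)) {
    stop("sequence revisits a vertex, so it is a walk, not a simple path")
  }
  p
}
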