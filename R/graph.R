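#' Construct a transition graph for a multitype branching process
#'
#' A transition graph couples a finite simple directed graph to cell-level
#' rates: cells at vertex `x` divide at rate `alpha(x)`, die at rate
#' `beta(x)`, and on division seed a cell at vertex `y` at rate `nu(x, y)`
#' whenever the edge `(x, y)` exists.  The population starts with `z` cells
#' at the root vertex; the quantity of interest is when, and along which
#' path, the target vertex is first populated.
#'
#' The growth rate (fitness) of vertex `x` is `lam(x) = alpha(x) - beta(x)`,
#' stored as a derived column.  The analytic machinery assumes the root has
#' the strictly largest fitness among non-target vertices and that the root
#' fitness is positive; [validate_graph()] reports departures from these
#' model assumptions as warnings and structural defects as errors.
#'
#' @param vertices data.frame with columns `id` (unique labels), `alpha`
#'   (division rate, >= 0) and `beta` (death rate, >= 0).
#' @param edges data.frame with columns `from`, `to` (vertex ids) and `nu`
#'   (transition rate, > 0).  Zero-rate edges must simply be omitted.
#' @param root,target vertex ids of the source (initial population) and the
#'   sink (cell state of interest).
#' @param z positive integer, the initial number of cells at the root.
#' @return An object of class `transition_graph`: a list with elements
#'   `vertices` (with derived `lam`), `edges`, `root`, `target`, `z` and
#'   `acyclic` (derived flag).
#' @seealso [validate_graph()], [enumerate_paths()], [weight_table()],
#'   [simulate_paths()]
#' @examples
#' g <- transition_graph(
#'   vertices = data.frame(id = c("1", "2", "3"),
#'                         alpha = c(0.9, 0.2, 0.9),
#'                         beta  = c(0.3, 0.4, 0.3)),
#'   edges = data.frame(from = c("1", "2", "1"),
#'                      to   = c("2", "3", "3"),
#'                      nu   = c(0.1, 0.1, 0.01)),
#'   root = "1", target = "3", z = 1)
#' g
#' @export
transition_graph <- function(vertices, edges, root, target, z = 1L) {
  stopifnot(is.data.frame(vertices), all(c("id", "alpha", "beta") %in% names(vertices)))
  vertices$id <- as.character(vertices$id)
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(from = character(), to = character(), nu = numeric())
  }
  edges <- as.data.frame(edges)
  stopifnot(all(c("from", "to", "nu") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  root <- as.character(root)
  target <- as.character(target)
  if (anyDuplicated(vertices$id)) {
    stop("duplicate vertex ids: ",
         paste(unique(vertices$id[duplicated(vertices$id)]), collapse = ", "))
  }
  dangling <- setdiff(c(edges$from, edges$to), vertices$id)
  if (length(dangling)) {
    stop("edges reference unknown vertex ids: ", paste(dangling, collapse = ", "))
  }
  if (!root %in% vertices$id) stop("root vertex '", root, "' not in vertex set")
  if (!target %in% vertices$id) stop("target vertex '", target, "' not in vertex set")
  if (root == target) stop("root and target must differ")
  if (!(is.numeric(z) && length(z) == 1L && z >= 1 && z == round(z))) {
    stop("z must be a positive integer")
  }
  vertices$lam <- vertices$alpha - vertices$beta
  vertices <- vertices[, c("id", "alpha", "beta", "lam")]
  rownames(vertices) <- NULL
  rownames(edges) <- NULL
  g <- structure(
    list(vertices = vertices, edges = edges, root = root, target = target,
         z = as.integer(z), acyclic = NA),
    class = "transition_graph")
  g$acyclic <- graph_is_acyclic(g)
  g
}

#' @export
print.transition_graph <- function(x, ...) {
  cat("Transition graph:", nrow(x$vertices), "vertices,",
      nrow(x$edges), "edges", if (isTRUE(x$acyclic)) "(acyclic)" else "(cyclic)", "\n")
  cat("  root:", x$root, " target:", x$target, " z:", x$z, "\n")
  cat("Vertices:\n")
  print(x$vertices, row.names = FALSE)
  if (nrow(x$edges)) {
    cat("Edges:\n")
    print(x$edges, row.names = FALSE)
  }
  invisible(x)
}

# igraph view of the transition graph (topology only; rates kept as attribute)
as_igraph <- function(g) {
  igraph::graph_from_data_frame(g$edges, directed = TRUE, vertices = g$vertices)
}

graph_is_acyclic <- function(g) {
  if (nrow(g$edges) == 0L) return(TRUE)
  igraph::is_dag(as_igraph(g))
}

vertex_row <- function(g, id) {
  i <- match(id, g$vertices$id)
  if (anyNA(i)) stop("unknown vertex id: ", paste(id[is.na(i)], collapse = ", "))
  g$vertices[i, , drop = FALSE]
}

edge_rate <- function(g, from, to) {
  i <- which(g$edges$from == from & g$edges$to == to)
  if (!length(i)) stop("no edge (", from, ", ", to, ") in graph")
  g$edges$nu[i]
}

root_lam <- function(g) vertex_row(g, g$root)$lam

#' Validate a transition graph
#'
#' Checks the structural requirements (target is a sink, root is a source,
#' target reachable, all rates admissible, no self-loops or parallel edges)
#' and the model assumptions under which the analytic approximations are
#' proven (root fitness positive and strictly larger than every
#' intermediate vertex's fitness).  Structural failures are classified as
#' `"error"`; assumption failures as `"warning"` — the stochastic simulator
#' is still exact outside the assumption regime, but the closed-form
#' approximations are not guaranteed there.
#'
#' The function is pure: it never modifies or repairs its input.
#'
#' @param g a [transition_graph()].
#' @return data.frame with columns `code`, `severity` (`"error"` or
#'   `"warning"`) and `message`; zero rows when the graph is clean.
#' @examples
#' g <- path_graph(4)
#' validate_graph(g)   # no violations
#' @export
validate_graph <- function(g) {
  stopifnot(inherits(g, "transition_graph"))
  v <- g$vertices
  e <- g$edges
  out <- list()
  add <- function(code, severity, message) {
    out[[length(out) + 1L]] <<- data.frame(code = code, severity = severity,
                                           message = message)
  }
  if (any(v$alpha < 0)) {
    add("negative_division_rate", "error",
        paste("alpha < 0 at:", paste(v$id[v$alpha < 0], collapse = ", ")))
  }
  if (any(v$beta < 0)) {
    add("negative_death_rate", "error",
        paste("beta < 0 at:", paste(v$id[v$beta < 0], collapse = ", ")))
  }
  if (nrow(e)) {
    if (any(e$nu <= 0)) {
      add("nonpositive_edge_rate", "error",
          "every edge rate nu must be > 0; omit zero-rate edges")
    }
    loops <- e$from == e$to
    if (any(loops)) {
      add("self_loop", "error",
          paste("self-loops at:", paste(unique(e$from[loops]), collapse = ", ")))
    }
    key <- paste(e$from, e$to, sep = "\r")
    if (anyDuplicated(key)) {
      add("parallel_edges", "error",
          paste("parallel edges:",
                paste(unique(key[duplicated(key)]), collapse = "; ")))
    }
    if (any(e$from == g$target)) {
      add("target_not_sink", "error", "target vertex has outgoing edges")
    }
    if (any(e$to == g$root)) {
      add("root_not_source", "error", "root vertex has incoming edges")
    }
  }
  reachable <- tryCatch({
    ig <- as_igraph(g)
    is.finite(igraph::distances(ig, v = g$root, to = g$target, mode = "out")[1, 1])
  }, error = function(e) FALSE)
  if (!reachable) {
    add("target_unreachable", "error", "target not reachable from root")
  }
  lam1 <- root_lam(g)
  if (lam1 <= 0) {
    add("root_fitness_nonpositive", "warning",
        sprintf("root growth rate lam = %g is not positive; analytic results assume lam > 0", lam1))
  }
  inter <- v[!(v$id %in% c(g$root, g$target)), , drop = FALSE]
  bad <- inter$lam >= lam1
  if (any(bad)) {
    add("intermediate_fitness_not_below_root", "warning",
        paste("intermediate vertices with lam >= root lam:",
              paste(inter$id[bad], collapse = ", "),
              "- analytic approximations are outside their proven regime"))
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(code = character(), severity = character(), message = character())
}

#' Stop on structural validation errors
#'
#' Convenience wrapper used by the analytic and simulation entry points:
#' raises an error listing all structural violations, and (optionally)
#' surfaces model-assumption warnings via [warning()].
#'
#' @param g a [transition_graph()].
#' @param warn emit R warnings for model-assumption violations?
#' @return `g`, invisibly.
#' @export
assert_valid_graph <- function(g, warn = FALSE) {
  rep <- validate_graph(g)
  errs <- rep[rep$severity == "error", , drop = FALSE]
  if (nrow(errs)) {
    stop("invalid transition graph:\n  ",
         paste(errs$message, collapse = "\n  "))
  }
  if (warn) {
    warns <- rep[rep$severity == "warning", , drop = FALSE]
    for (m in warns$message) warning(m, call. = FALSE)
  }
  invisible(g)
}
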