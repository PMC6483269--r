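SPEC_SCHEMA_VERSION <- 1L

#' Read and write transition-graph specification files
#'
#' The canonical on-disk format is JSON with keys `schema_version`,
#' `vertices` (array of `{id, alpha, beta}`), `edges` (array of
#' `{from, to, nu}`), `root`, `target` and `z`.  Loading validates the
#' structure field by field (unknown keys are rejected in strict mode) and
#' then applies [validate_graph()]: structural errors abort the load,
#' model-assumption warnings are surfaced as R warnings.
#'
#' @param path file path.
#' @param strict reject unknown top-level keys?
#' @return `read_graph_spec()` returns a [transition_graph()];
#'   `write_graph_spec()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_graph_spec(valley_graph(), f)
#' g <- read_graph_spec(f)
#' @export
read_graph_spec <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  required <- c("schema_version", "vertices", "edges", "root", "target", "z")
  miss <- setdiff(required, names(spec))
  if (length(miss)) {
    stop("graph spec ", path, " is missing keys: ", paste(miss, collapse = ", "))
  }
  unknown <- setdiff(names(spec), required)
  if (strict && length(unknown)) {
    stop("graph spec ", path, " has unknown keys: ",
         paste(unknown, collapse = ", "))
  }
  if (!identical(as.integer(spec$schema_version), SPEC_SCHEMA_VERSION)) {
    stop("unsupported schema_version ", spec$schema_version)
  }
  check_fields <- function(df, what, fields, numerics) {
    if (!is.data.frame(df)) stop("'", what, "' must be an array of objects")
    miss <- setdiff(fields, names(df))
    if (length(miss)) {
      stop("'", what, "' entries are missing fields: ",
           paste(miss, collapse = ", "))
    }
    for (f in numerics) {
      if (!is.numeric(df[[f]]) || anyNA(df[[f]])) {
        stop("'", what, "$", f, "' must be numeric and complete")
      }
    }
    df
  }
  vertices <- check_fields(spec$vertices, "vertices",
                           c("id", "alpha", "beta"), c("alpha", "beta"))
  if (any(vertices$alpha < 0) || any(vertices$beta < 0)) {
    stop("vertex rates must be non-negative")
  }
  edges <- if (length(spec$edges)) {
    e <- check_fields(spec$edges, "edges", c("from", "to", "nu"), "nu")
    if (any(e$nu < 0)) stop("edge rates must be non-negative")
    e
  } else NULL
  g <- transition_graph(vertices, edges, spec$root, spec$target, spec$z)
  assert_valid_graph(g, warn = TRUE)
  g
}

#' @param g a [transition_graph()].
#' @rdname read_graph_spec
#' @export
write_graph_spec <- function(g, path) {
  stopifnot(inherits(g, "transition_graph"))
  spec <- list(schema_version = SPEC_SCHEMA_VERSION,
               vertices = g$vertices[, c("id", "alpha", "beta")],
               edges = g$edges,
               root = g$root, target = g$target, z = g$z)
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate graph specification fixtures
#'
#' Writes a seeded, reproducible graph spec of a named kind to `dir`:
#' `path_graph` (linear chain, `params$n` vertices), `valley` (direct vs
#' two-step route), `cycle_walk` (reversible intermediate edge),
#' `monotherapy`, `combination` (the scenario builders' output) or
#' `random_dag` (`params$n` vertices, edge density `params$density`,
#' log-uniform rates in `params$nu_range`, intermediate fitnesses drawn
#' strictly below the root's).
#'
#' @param kind one of `"path_graph"`, `"valley"`, `"cycle_walk"`,
#'   `"monotherapy"`, `"combination"`, `"random_dag"`.
#' @param params named list overriding the kind's builder defaults.
#' @param seed integer seed (used by `random_dag`; harmless elsewhere).
#' @param dir output directory (created if needed).
#' @return the written file path, invisibly; the graph as the
#'   `"graph"` attribute.
#' @export
generate_fixtures <- function(kind, params = list(), seed = 1L,
                              dir = tempfile("fixtures")) {
  kinds <- c("path_graph", "valley", "cycle_walk", "monotherapy",
             "combination", "random_dag")
  if (!kind %in% kinds) {
    stop("invalid fixture kind '", kind, "'; choose from: ",
         paste(kinds, collapse = ", "))
  }
  set.seed(seed)
  g <- switch(kind,
    path_graph = do.call(path_graph, params),
    valley = do.call(valley_graph, params),
    cycle_walk = do.call(cycle_walk_graph, params),
    monotherapy = do.call(build_monotherapy, utils::modifyList(
      list(nu = 1e-6, m = 1e-3, s = 5e-3, d = 1e-2, z = 100L), params)),
    combination = do.call(build_combination, utils::modifyList(
      list(nu = 1e-6, m = 0.05, s = 1e-3, d = 0.9,
           n_S = 5e5, n_D = 5e5, n_DD = 9e6), params)),
    random_dag = do.call(random_dag, params))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, sprintf("%s_seed%d.json", kind, as.integer(seed)))
  write_graph_spec(g, path)
  structure(invisible(path), graph = g)
}

#' Random acyclic test graph
#'
#' Draws a DAG over the topological order `1..n`: every forward edge is
#' kept with probability `density`, a chain spine guarantees the target is
#' reachable, rates are log-uniform over `nu_range`, and intermediate
#' growth rates are drawn strictly below the root's so the model
#' assumptions always hold.  Uses the current RNG state; seed with
#' `set.seed()` (or via [generate_fixtures()]) for reproducibility.
#'
#' @param n number of vertices; `density` forward-edge probability.
#' @param density probability of including each forward edge.
#' @param nu_range range for the log-uniform transition rates.
#' @param alpha,beta_root root rates; `z` initial count.
#' @param z initial root cell count.
#' @return a [transition_graph()].
#' @export
random_dag <- function(n = 6, density = 0.5, nu_range = c(1e-3, 1e-1),
                       alpha = 1, beta_root = 0.4, z = 1L) {
  stopifnot(n >= 2, density >= 0, density <= 1)
  ids <- as.character(seq_len(n))
  lam1 <- alpha - beta_root
  lam_mid <- if (n > 2) stats::runif(n - 2, min = -0.5, max = lam1 - 0.05)
  beta <- c(beta_root, if (n > 2) alpha - lam_mid, stats::runif(1, 0.1, 1.5))
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < density
  spine <- pairs[, "col"] == pairs[, "row"] + 1L
  keep <- keep | spine
  nu <- exp(stats::runif(sum(keep), log(nu_range[1]), log(nu_range[2])))
  transition_graph(
    vertices = data.frame(id = ids, alpha = alpha, beta = beta),
    edges = data.frame(from = ids[pairs[keep, "row"]],
                       to = ids[pairs[keep, "col"]], nu = nu),
    root = ids[1], target = ids[n], z = z)
}
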