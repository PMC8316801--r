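## Full extraction pipeline: per connected component of the pre-extracted
## graph, auto-select terminals as the leaves of an all-terminal filtered
## tree, run the dynamics once per seeded source, and superpose the resulting
## trees with edgewise summed weights.

#' Auto-select eligible terminals
#'
#' Runs the dynamics on the graph with every node as a terminal (one chosen
#' uniformly at random as source, all others as sinks with demand 1/(n-1)),
#' filters the stationary tree, and returns its leaves. The leaves of this
#' all-terminal tree determine the coverage of the network: they sit in
#' distant parts of the subject.
#'
#' @param gpe A connected [pixel_graph] with at least 2 nodes.
#' @param seed Integer seed for the source draw.
#' @param beta,dt,tol,max_iter Dynamics parameters (see [run_dynamics]).
#' @return Object of class `terminal_set`: list with `ids` (leaf node ids),
#'   `seed`, `source` (the id used as source) and `tree` (the filtered
#'   all-terminal tree).
#' @export
select_terminals <- function(gpe, seed = 0, beta = 1.5, dt = 0.5,
                             tol = 1e-6, max_iter = 3000) {
  stopifnot(inherits(gpe, "pixel_graph"))
  n <- nrow(gpe$nodes)
  if (n < 2)
    stop_validation("terminal selection needs at least 2 nodes, got %d", n)
  src_idx <- with_seed(seed, sample.int(n, 1))
  f <- rep(-1 / (n - 1), n)
  f[src_idx] <- 1
  fit <- run_dynamics(transport_problem(gpe, f, beta = beta),
                      dt = dt, tol = tol, max_iter = max_iter)
  tree <- filter_graph(gpe, fit, expect_tree = beta >= 1)
  deg <- igraph::degree(as_igraph(tree))
  leaves <- tree$nodes$id[deg == 1]
  structure(list(ids = sort(leaves), seed = seed,
                 source = gpe$nodes$id[src_idx], tree = tree),
            class = "terminal_set")
}

#' @export
print.terminal_set <- function(x, ...) {
  cat(sprintf("terminal_set: %d eligible terminals (seed %d)\n",
              length(x$ids), x$seed))
  invisible(x)
}

#' One single-source dynamics run
#'
#' Forcing +1 at `source` and -1/(k-1) at each of the other k-1 terminals
#' (zero elsewhere); returns the filtered stationary tree with the optimal
#' conductivities as weights.
#'
#' @param gpe A connected [pixel_graph].
#' @param source Node id; must be one of the terminals.
#' @param terminals A `terminal_set` or a vector of node ids (>= 2).
#' @inheritParams select_terminals
#' @param eps_rel Optional filter threshold override (see [filter_graph]).
#' @return An [extracted_network] (a tree for beta >= 1).
#' @export
run_single_source <- function(gpe, source, terminals, beta = 1.5, dt = 0.5,
                              tol = 1e-6, max_iter = 3000, eps_rel = NULL) {
  stopifnot(inherits(gpe, "pixel_graph"))
  tids <- if (inherits(terminals, "terminal_set")) terminals$ids
          else as.integer(terminals)
  if (length(tids) < 2) stop_validation("need at least 2 terminals")
  if (!source %in% tids)
    stop_validation("source %s is not among the terminals", format(source))
  if (!all(tids %in% gpe$nodes$id))
    stop_validation("terminal ids not present in the graph")
  sinks <- setdiff(tids, source)
  f <- numeric(nrow(gpe$nodes))
  f[match(source, gpe$nodes$id)] <- 1
  f[match(sinks, gpe$nodes$id)] <- -1 / length(sinks)
  fit <- run_dynamics(transport_problem(gpe, f, beta = beta),
                      dt = dt, tol = tol, max_iter = max_iter)
  filter_graph(gpe, fit, eps_rel = eps_rel, expect_tree = beta >= 1)
}

#' Extract a network from an image field
#'
#' The full pipeline: build the pre-extracted pixel graph at threshold
#' `delta`; per connected component, auto-select terminals (unless supplied),
#' run the dynamics for up to `n_runs` distinct seeded sources drawn without
#' replacement from the terminal set, and superpose the filtered trees with
#' edgewise summed weights; finally merge the components disjointly.
#'
#' @param field A [pixel_field] (see [load_image]).
#' @param delta Intensity threshold in \[0, 1\].
#' @param beta Dynamics exponent in (0, 2); 1.5 by default.
#' @param n_runs Number of single-source runs per component (capped at the
#'   number of eligible terminals, with a warning).
#' @param seed Integer seed; drives terminal selection and source order.
#' @param terminals Optional user-supplied vector of node ids (row-major
#'   pixel indices) overriding auto-selection.
#' @param connectivity 8 or 4 neighbour adjacency for the pixel graph.
#' @param dt,tol,max_iter,eps_rel Dynamics and filter parameters.
#' @param verbose Emit per-component progress messages.
#' @return An object of classes `img2net` and `extracted_network`; attribute
#'   `gpe` holds the pre-extracted graph and attribute `config` the resolved
#'   parameters.
#' @examples
#' \donttest{
#' sc <- make_scene("ring", list(size = 48), seed = 1)
#' net <- image2net(rasterize(sc), delta = 0.5, n_runs = 3, seed = 1)
#' summary(net)
#' }
#' @export
image2net <- function(field, delta = 0.5, beta = 1.5, n_runs = 5, seed = 0,
                      terminals = NULL, connectivity = 8, dt = 0.5,
                      tol = 1e-6, max_iter = 3000, eps_rel = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(field, "pixel_field"))
  if (!is_count(n_runs) || n_runs < 1)
    stop_validation("n_runs must be a positive integer")
  gpe <- build_pixel_graph(field, delta, connectivity = connectivity)
  comps <- graph_components(gpe)
  nets <- list()
  term_sets <- list()
  for (ci in seq_along(comps)) {
    comp <- comps[[ci]]
    if (nrow(comp$nodes) < 2) next
    tset <- if (!is.null(terminals)) {
      ids <- intersect(as.integer(terminals), comp$nodes$id)
      if (length(ids) < 2) next
      structure(list(ids = sort(ids), seed = NA_integer_,
                     source = NA_integer_, tree = NULL),
                class = "terminal_set")
    } else {
      select_terminals(comp, seed = derive_seed(seed, "terminals", ci),
                       beta = beta, dt = dt, tol = tol, max_iter = max_iter)
    }
    n_eff <- min(n_runs, length(tset$ids))
    if (n_eff < n_runs)
      warning(sprintf(
        "component %d: n_runs truncated from %d to %d (only %d terminals)",
        ci, n_runs, n_eff, length(tset$ids)))
    src_order <- with_seed(derive_seed(seed, "sources", ci),
                           sample(tset$ids))
    runs <- lapply(src_order[seq_len(n_eff)], function(s) {
      if (verbose)
        message(sprintf("component %d: source %d", ci, s))
      run_single_source(comp, s, tset, beta = beta, dt = dt, tol = tol,
                        max_iter = max_iter, eps_rel = eps_rel)
    })
    nets[[length(nets) + 1]] <- superpose(runs)
    term_sets[[length(term_sets) + 1]] <- tset
  }
  if (length(nets) == 0) {
    if (nrow(gpe$nodes) == 0)
      NULL  # build_pixel_graph already warned on empty mask
    else
      warning("no component with >= 2 nodes; returning empty network")
    out <- extracted_network(
      data.frame(id = integer(), x = numeric(), y = numeric()),
      data.frame(from = integer(), to = integer(), weight = numeric(),
                 length_px = numeric(), length = numeric()))
  } else {
    out <- merge_disjoint(nets)
  }
  class(out) <- c("img2net", class(out))
  attr(out, "gpe") <- gpe
  attr(out, "terminals") <- term_sets
  attr(out, "config") <- list(delta = delta, beta = beta, n_runs = n_runs,
                              seed = seed, connectivity = connectivity,
                              dt = dt, tol = tol, max_iter = max_iter,
                              eps_rel = eps_rel)
  out
}

## Disjoint union of per-component networks (node ids are globally unique
## row-major pixel indices, so plain concatenation is safe).
merge_disjoint <- function(nets) {
  nodes <- do.call(rbind, lapply(nets, `[[`, "nodes"))
  edges <- do.call(rbind, lapply(nets, `[[`, "edges"))
  extracted_network(nodes, edges)
}

#' @export
print.img2net <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("img2net extraction (delta=%.3g, beta=%.3g, n_runs=%d, seed=%d)\n",
              cfg$delta, cfg$beta, cfg$n_runs, cfg$seed))
  NextMethod()
}
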