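## Image2net-MST baseline: replace the transport dynamics with classical
## routing optimization — minimum spanning tree for terminal selection, then
## repeated approximate Steiner trees on random terminal subsets, superposed
## exactly like the dynamics runs. Unlike the dynamics, this baseline does
## not assign new weights: edges keep the input graph's initial
## conductivities.

## Deterministic tie-break: perturb each length by a rank-scaled epsilon far
## below the smallest real length difference (sqrt(2) - 1), so equal-length
## edges are chosen in edge-id order.
tie_broken_lengths <- function(g) {
  m <- nrow(g$edges)
  g$edges$length * (1 + 1e-9 * seq_len(m) / max(m, 1))
}

#' Minimum spanning tree of a pixel graph
#'
#' MST under edge cost `l_e` with deterministic tie-breaking by edge id.
#' Edge weights of the output are the input initial conductivities (the
#' baseline never re-optimises weights). A disconnected input yields a
#' per-component spanning forest with a warning.
#'
#' @param gpe A [pixel_graph].
#' @return An [extracted_network].
#' @export
mst_tree <- function(gpe) {
  stopifnot(inherits(gpe, "pixel_graph"))
  if (nrow(gpe$edges) == 0)
    return(network_from_pixel_edges(gpe, integer(), numeric()))
  ig <- as_igraph_pixel_graph(gpe)
  igraph::E(ig)$eid <- seq_len(nrow(gpe$edges))
  if (igraph::components(ig)$no > 1)
    warning("disconnected input: returning a minimum spanning forest")
  mst <- igraph::mst(ig, weights = tie_broken_lengths(gpe))
  keep <- sort(igraph::E(mst)$eid)
  network_from_pixel_edges(gpe, keep, weights = gpe$edges$mu0[keep])
}

#' Approximate minimum Steiner tree
#'
#' Metric-closure 2-approximation: shortest-path distances between the
#' terminals define a complete graph, whose MST is expanded back into the
#' underlying shortest paths; the union is reduced to a tree (MST of the
#' union) and non-terminal leaves are pruned. The result is a tree
#' containing every terminal with total length at most twice the optimum.
#'
#' @param gpe A [pixel_graph].
#' @param terminals Vector of at least 2 node ids, all in one component.
#' @return An [extracted_network] with the input `mu0` as weights.
#' @export
steiner_run <- function(gpe, terminals) {
  stopifnot(inherits(gpe, "pixel_graph"))
  terminals <- sort(unique(as.integer(terminals)))
  if (length(terminals) < 2)
    stop_validation("need at least 2 terminals, got %d", length(terminals))
  tidx <- match(terminals, gpe$nodes$id)
  if (anyNA(tidx)) stop_validation("terminal ids not present in the graph")
  lens <- tie_broken_lengths(gpe)
  ig <- as_igraph_pixel_graph(gpe)
  memb <- igraph::components(ig)$membership
  if (length(unique(memb[tidx])) > 1)
    stop_validation("terminals in different components: {%s}",
                    paste(terminals, collapse = ", "))
  k <- length(tidx)

  ## metric closure MST over the terminals
  D <- igraph::distances(ig, v = tidx, to = tidx, weights = lens)
  cg <- igraph::make_full_graph(k)
  el <- igraph::as_edgelist(cg)
  igraph::E(cg)$weight <- D[el]
  cmst <- igraph::mst(cg)

  ## expand closure edges into shortest paths, take the union of their edges
  igraph::E(ig)$eid <- seq_len(nrow(gpe$edges))
  eids <- integer(0)
  for (r in seq_len(igraph::ecount(cmst))) {
    ends <- igraph::ends(cmst, r)
    sp <- igraph::shortest_paths(ig, from = tidx[ends[1]],
                                 to = tidx[ends[2]], weights = lens,
                                 output = "epath")$epath[[1]]
    eids <- union(eids, igraph::E(ig)$eid[as.integer(sp)])
  }
  ## the union may close cycles: reduce to its MST, then prune non-terminal
  ## leaves until only terminal-to-terminal structure remains
  sub <- igraph::subgraph_from_edges(ig, eids, delete.vertices = FALSE)
  smst <- igraph::mst(sub, weights = lens[igraph::E(sub)$eid])
  keep <- sort(igraph::E(smst)$eid)
  adj <- gpe$edges[keep, , drop = FALSE]
  repeat {
    deg <- table(factor(c(adj$from, adj$to),
                        levels = unique(c(adj$from, adj$to))))
    drop_nodes <- setdiff(as.integer(names(deg)[deg == 1]), terminals)
    if (length(drop_nodes) == 0) break
    dropping <- adj$from %in% drop_nodes | adj$to %in% drop_nodes
    if (!any(dropping)) break
    adj <- adj[!dropping, , drop = FALSE]
    keep <- keep[!dropping]
  }
  network_from_pixel_edges(gpe, keep, weights = gpe$edges$mu0[keep])
}

#' MST + Steiner baseline extraction
#'
#' Builds the pre-extracted graph (byte-identical to the one [image2net]
#' consumes for the same image and configuration); per component takes the
#' leaves of its MST as eligible terminals, draws `n_runs` seeded random
#' terminal subsets of size `n_terminals`, extracts an approximate Steiner
#' tree per draw, and superposes the trees with summed input weights.
#'
#' @inheritParams image2net
#' @param n_terminals Terminal subset size per run; default
#'   `min(5, #leaves)`.
#' @return An object of classes `img2net_mst` and `extracted_network`, with
#'   the same `gpe` and `config` attributes as [image2net].
#' @export
image2net_mst <- function(field, delta = 0.5, n_runs = 5,
                          n_terminals = NULL, seed = 0, connectivity = 8) {
  stopifnot(inherits(field, "pixel_field"))
  if (!is_count(n_runs) || n_runs < 1)
    stop_validation("n_runs must be a positive integer")
  if (!is.null(n_terminals) && (!is_count(n_terminals) || n_terminals < 2))
    stop_validation("n_terminals must be an integer >= 2")
  gpe <- build_pixel_graph(field, delta, connectivity = connectivity)
  comps <- graph_components(gpe)
  nets <- list()
  for (ci in seq_along(comps)) {
    comp <- comps[[ci]]
    if (nrow(comp$nodes) < 2) next
    mst <- mst_tree(comp)
    deg <- igraph::degree(as_igraph(mst))
    leaves <- sort(mst$nodes$id[deg == 1])
    if (length(leaves) < 2) leaves <- sort(comp$nodes$id)[1:2]
    k <- min(n_terminals %||% min(5, length(leaves)), length(leaves))
    k <- max(k, 2)
    runs <- lapply(seq_len(n_runs), function(r) {
      tr <- with_seed(derive_seed(seed, "steiner", ci * 1000L + r),
                      sort(sample(leaves, k)))
      steiner_run(comp, tr)
    })
    nets[[length(nets) + 1]] <- superpose(runs)
  }
  out <- if (length(nets) == 0) {
    warning("no component with >= 2 nodes; returning empty network")
    extracted_network(
      data.frame(id = integer(), x = numeric(), y = numeric()),
      data.frame(from = integer(), to = integer(), weight = numeric(),
                 length_px = numeric(), length = numeric()))
  } else merge_disjoint(nets)
  class(out) <- c("img2net_mst", class(out))
  attr(out, "gpe") <- gpe
  attr(out, "config") <- list(delta = delta, n_runs = n_runs,
                              n_terminals = n_terminals, seed = seed,
                              connectivity = connectivity)
  out
}
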