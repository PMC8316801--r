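## The extracted network G(V, E, W): weighted spatial graph in unit-square
## coordinates, produced by filtering a dynamics run or by superposing
## several runs.

#' Construct an extracted network
#'
#' @param nodes Data frame with columns `id`, `x`, `y` (optionally `row`,
#'   `col`). Must contain every edge endpoint; extra node rows are dropped
#'   unless listed in `isolated`.
#' @param edges Data frame with columns `from`, `to`, `weight` (> 0),
#'   `length_px` (graph metric, pixel units) and `length` (Euclidean,
#'   unit-square frame). An optional `runs` column records the contributing
#'   run indices.
#' @param isolated Node ids to keep although no edge touches them (declared
#'   isolated terminals).
#' @param units Length-unit marker for the `length` column.
#' @return Object of class `extracted_network`.
#' @export
extracted_network <- function(nodes, edges,
                              isolated = integer(),
                              units = "unit_square") {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    if (any(edges$weight <= 0)) stop_validation("edge weights must be > 0")
    if (any(edges$from == edges$to)) stop_validation("self-loop edge")
    swap <- edges$from > edges$to
    if (any(swap)) {
      tmp <- edges$from[swap]
      edges$from[swap] <- edges$to[swap]
      edges$to[swap] <- tmp
    }
    if (anyDuplicated(edges[c("from", "to")]))
      stop_validation("duplicate edges")
    if (any(!c(edges$from, edges$to) %in% nodes$id))
      stop_validation("edge endpoint missing from node table")
  }
  keep <- nodes$id %in% c(edges$from, edges$to, isolated)
  nodes <- nodes[keep, , drop = FALSE]
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  if (nrow(edges) > 0) {
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges, units = units),
            class = "extracted_network")
}

## Build a network from a subset of pixel-graph edges, with given weights.
network_from_pixel_edges <- function(graph, edge_idx, weights) {
  e <- graph$edges[edge_idx, , drop = FALSE]
  xy <- graph$nodes[, c("id", "x", "y")]
  x <- xy$x[match(e$from, xy$id)] - xy$x[match(e$to, xy$id)]
  y <- xy$y[match(e$from, xy$id)] - xy$y[match(e$to, xy$id)]
  cols <- intersect(c("id", "row", "col", "x", "y"), names(graph$nodes))
  extracted_network(
    graph$nodes[, cols, drop = FALSE],
    data.frame(from = e$from, to = e$to, weight = weights,
               length_px = e$length, length = sqrt(x^2 + y^2)))
}

#' Convert to an igraph object
#'
#' @param x An `extracted_network` or `pixel_graph`.
#' @param ... Unused.
#' @return An undirected igraph graph with vertex attributes `name` (node
#'   id), `x`, `y` and, for networks, edge attributes `weight` and `length`.
#' @export
as_igraph <- function(x, ...) UseMethod("as_igraph")

#' @export
as_igraph.extracted_network <- function(x, ...) {
  ig <- igraph::make_empty_graph(n = nrow(x$nodes), directed = FALSE)
  igraph::V(ig)$name <- as.character(x$nodes$id)
  igraph::V(ig)$x <- x$nodes$x
  igraph::V(ig)$y <- x$nodes$y
  if (nrow(x$edges) > 0) {
    ig <- igraph::add_edges(ig, rbind(match(x$edges$from, x$nodes$id),
                                      match(x$edges$to, x$nodes$id)))
    igraph::E(ig)$weight <- x$edges$weight
    igraph::E(ig)$length <- x$edges$length
  }
  ig
}

#' @export
as_igraph.pixel_graph <- function(x, ...) {
  ig <- as_igraph_pixel_graph(x, weights = x$edges$length)
  igraph::V(ig)$name <- as.character(x$nodes$id)
  ig
}

#' Number of independent cycles
#'
#' `|E| - |V| + #components` (the circuit rank); 0 exactly for forests.
#'
#' @param net An [extracted_network].
#' @return Non-negative integer.
#' @export
cycle_count <- function(net) {
  stopifnot(inherits(net, "extracted_network"))
  n <- nrow(net$nodes)
  if (n == 0) return(0L)
  comps <- igraph::components(as_igraph(net))$no
  as.integer(nrow(net$edges) - n + comps)
}

#' Total network length
#'
#' Sum over edges of the Euclidean distance between endpoint coordinates
#' (unit-square frame).
#'
#' @param net An [extracted_network].
#' @return Scalar length.
#' @export
network_length <- function(net) {
  stopifnot(inherits(net, "extracted_network"))
  if (nrow(net$edges) == 0) return(0)
  sum(net$edges$length)
}

#' Node and edge counts
#'
#' @param net An [extracted_network].
#' @return Named numeric vector `c(nodes = N, edges = E)`.
#' @export
network_counts <- function(net) {
  stopifnot(inherits(net, "extracted_network"))
  c(nodes = nrow(net$nodes), edges = nrow(net$edges))
}

#' Superpose filtered trees
#'
#' Union of the runs' node and edge sets with edgewise summed weights:
#' `w_jk = sum_r w_jk^r`, where a run contributes 0 on edges it does not
#' contain. This is how loops are recovered from several single-source tree
#' runs.
#'
#' @param runs Non-empty list of [extracted_network] objects over a shared
#'   node universe.
#' @return An [extracted_network]; the `runs` edge column lists the
#'   contributing run indices.
#' @export
superpose <- function(runs) {
  if (!is.list(runs) || length(runs) == 0 ||
      !all(vapply(runs, inherits, logical(1), "extracted_network")))
    stop_validation("superpose needs a non-empty list of extracted networks")
  nodes <- do.call(rbind, lapply(runs, function(r)
    r$nodes[, c("id", "x", "y"), drop = FALSE]))
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  ee <- do.call(rbind, lapply(seq_along(runs), function(r) {
    e <- runs[[r]]$edges
    if (nrow(e) == 0) return(NULL)
    data.frame(from = e$from, to = e$to, weight = e$weight,
               length_px = e$length_px, length = e$length, run = r)
  }))
  if (is.null(ee) || nrow(ee) == 0)
    return(extracted_network(nodes[0, , drop = FALSE],
                             data.frame(from = integer(), to = integer(),
                                        weight = numeric(),
                                        length_px = numeric(),
                                        length = numeric())))
  key <- paste(ee$from, ee$to)
  agg <- rowsum(ee$weight, key)
  runs_by_key <- vapply(split(ee$run, key), function(r)
    paste(sort(unique(r)), collapse = ","), character(1))
  out <- ee[!duplicated(key), c("from", "to", "length_px", "length"),
            drop = FALSE]
  okey <- paste(out$from, out$to)
  out$weight <- as.numeric(agg[okey, 1])
  out$runs <- unname(runs_by_key[okey])
  extracted_network(nodes, out)
}

#' @export
print.extracted_network <- function(x, ...) {
  cat(sprintf("extracted_network: %d nodes, %d edges, %d cycles, L = %.4g\n",
              nrow(x$nodes), nrow(x$edges), cycle_count(x),
              network_length(x)))
  invisible(x)
}

#' @export
summary.extracted_network <- function(object, ...) {
  ig <- as_igraph(object)
  deg <- if (nrow(object$nodes)) igraph::degree(ig) else integer()
  out <- list(
    nodes = nrow(object$nodes),
    edges = nrow(object$edges),
    components = if (nrow(object$nodes)) igraph::components(ig)$no else 0L,
    cycles = cycle_count(object),
    leaves = sum(deg == 1),
    total_length = network_length(object),
    weight_range = if (nrow(object$edges)) range(object$edges$weight)
                   else c(NA_real_, NA_real_))
  class(out) <- "summary.extracted_network"
  out
}

#' @export
print.summary.extracted_network <- function(x, ...) {
  cat(sprintf(
    paste0("extracted network summary\n",
           "  nodes: %d   edges: %d   components: %d\n",
           "  independent cycles: %d   leaves: %d\n",
           "  total length: %.4g   weight range: [%.4g, %.4g]\n"),
    x$nodes, x$edges, x$components, x$cycles, x$leaves,
    x$total_length, x$weight_range[1], x$weight_range[2]))
  invisible(x)
}

#' Plot an extracted network
#'
#' Draws the edges in unit-square coordinates, line width proportional to
#' weight, optionally over the source image.
#'
#' @param x An [extracted_network].
#' @param field Optional [pixel_field] drawn underneath.
#' @param lwd_max Line width of the heaviest edge.
#' @param ... Passed to [graphics::plot].
#' @export
plot.extracted_network <- function(x, field = NULL, lwd_max = 4, ...) {
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), asp = 1,
                 xlab = "x", ylab = "y", ...)
  if (!is.null(field))
    graphics::rasterImage(grDevices::as.raster(1 - field$intensity),
                          0, 0, 1, 1)
  if (nrow(x$edges) > 0) {
    i <- match(x$edges$from, x$nodes$id)
    j <- match(x$edges$to, x$nodes$id)
    w <- x$edges$weight / max(x$edges$weight)
    graphics::segments(x$nodes$x[i], x$nodes$y[i],
                       x$nodes$x[j], x$nodes$y[j],
                       lwd = 0.3 + (lwd_max - 0.3) * w, col = "steelblue4")
  }
  invisible(x)
}

#' Write an extracted network to TSV (and optionally GraphML)
#'
#' Edge list columns: source, target, weight, length (unit square),
#' length_px, and the contributing runs when present; node coordinates go to
#' a companion `.nodes.tsv`. Header lines (`# key=value`) carry the resolved
#' configuration so a run can be reproduced from its own output.
#'
#' @param net An [extracted_network].
#' @param path Output TSV path.
#' @param header Character vector of header lines (without the `# `).
#' @param nodes_path Companion node table path.
#' @param graphml Optional GraphML output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, header = character(),
                          nodes_path = sub("(\\.tsv)?$", ".nodes.tsv", path),
                          graphml = NULL) {
  cols <- intersect(c("from", "to", "weight", "length", "length_px", "runs"),
                    names(net$edges))
  e <- net$edges[, cols, drop = FALSE]
  names(e)[1:2] <- c("source", "target")
  write_tsv_with_header(e, path, header)
  write_tsv_with_header(net$nodes, nodes_path, header)
  if (!is.null(graphml))
    igraph::write_graph(as_igraph(net), graphml, format = "graphml")
  invisible(path)
}

#' Read a network written by [write_network]
#'
#' @param path Edge-list TSV path.
#' @param nodes_path Companion node table path.
#' @return An [extracted_network].
#' @export
read_network <- function(path, nodes_path = sub("(\\.tsv)?$", ".nodes.tsv",
                                                path)) {
  if (!file.exists(path)) stop_io("no such network file '%s'", path)
  e <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  n <- utils::read.table(nodes_path, header = TRUE, sep = "\t",
                         comment.char = "#")
  names(e)[names(e) == "source"] <- "from"
  names(e)[names(e) == "target"] <- "to"
  if (is.null(e$length_px)) e$length_px <- e$length
  extracted_network(n, e)
}
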