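## Pre-extraction: supra-threshold pixels become nodes (centre of mass),
## 8-neighbouring pixels become edges. This raw pixel-adjacency graph G^pe is
## the common input of the transport dynamics and the MST/Steiner baseline.

#' Low-level pixel graph constructor
#'
#' Validates and assembles a `pixel_graph` from node and edge tables. Used by
#' [build_pixel_graph]; also handy for building small fixtures directly.
#'
#' @param nodes Data frame with columns `id`, `x`, `y` (and optionally `row`,
#'   `col`, `intensity`). Ids must be unique and sorted ascending.
#' @param edges Data frame with columns `from`, `to` (node ids), `length`
#'   (positive) and `mu0` (positive initial conductivity).
#' @param height,width Pixel dimensions of the source image (NA for synthetic
#'   fixtures).
#' @param connectivity 4 or 8; metadata only.
#' @return Object of class `pixel_graph`: the two tables plus index columns
#'   `from_idx`/`to_idx` (positions in `nodes`), and the image geometry.
#' @export
pixel_graph <- function(nodes, edges, height = NA_integer_,
                        width = NA_integer_, connectivity = 8) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  if (nrow(nodes) > 0) {
    if (anyDuplicated(nodes$id)) stop_validation("duplicate node ids")
    if (is.unsorted(nodes$id)) nodes <- nodes[order(nodes$id), , drop = FALSE]
    rownames(nodes) <- NULL
  }
  if (nrow(edges) > 0) {
    if (any(edges$from == edges$to)) stop_validation("self-loop edge")
    swap <- edges$from > edges$to
    if (any(swap)) {
      tmp <- edges$from[swap]
      edges$from[swap] <- edges$to[swap]
      edges$to[swap] <- tmp
    }
    if (anyDuplicated(edges[c("from", "to")]))
      stop_validation("duplicate edges")
    if (any(!edges$from %in% nodes$id) || any(!edges$to %in% nodes$id))
      stop_validation("edge endpoint not among nodes")
    if (any(edges$length <= 0)) stop_validation("edge lengths must be > 0")
    if (any(edges$mu0 <= 0))
      stop_validation("initial conductivities must be > 0")
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
    edges$from_idx <- match(edges$from, nodes$id)
    edges$to_idx <- match(edges$to, nodes$id)
  } else {
    edges <- data.frame(from = integer(), to = integer(),
                        length = numeric(), mu0 = numeric(),
                        from_idx = integer(), to_idx = integer())
  }
  structure(list(nodes = nodes, edges = edges,
                 height = height, width = width,
                 connectivity = connectivity),
            class = "pixel_graph")
}

#' Build the pre-extracted pixel-adjacency graph
#'
#' Nodes are exactly the pixels with intensity > `delta` (ids are row-major
#' pixel indices); edges join every pair of such pixels sharing an edge or a
#' vertex (8-connectivity; lengths 1 for axis neighbours, sqrt(2) for
#' diagonal neighbours, in pixel units). Each edge's initial conductivity is
#' the mean intensity of its endpoint pixels, floored at `eps0` so the
#' dynamics' initial condition mu(0) > 0 holds.
#'
#' @param field A [pixel_field].
#' @param delta Threshold in \[0, 1\].
#' @param connectivity 8 (default) or 4 (axis neighbours only, for ablation).
#' @param eps0 Positive floor for initial conductivities.
#' @return A [pixel_graph]. An empty mask yields an empty graph with a
#'   warning.
#' @examples
#' f <- pixel_field(matrix(1, 2, 2))
#' g <- build_pixel_graph(f, 0.5)
#' nrow(g$nodes); nrow(g$edges)   # 4 nodes, 6 edges
#' @export
build_pixel_graph <- function(field, delta, connectivity = 8, eps0 = 1e-6) {
  stopifnot(inherits(field, "pixel_field"))
  if (!connectivity %in% c(4, 8))
    stop_config("connectivity must be 4 or 8")
  mask <- threshold_mask(field, delta)
  H <- field$height; W <- field$width
  if (!any(mask)) {
    warning("empty mask: no pixel exceeds delta; returning empty graph")
    return(pixel_graph(
      data.frame(id = integer(), row = integer(), col = integer(),
                 x = numeric(), y = numeric(), intensity = numeric()),
      data.frame(from = integer(), to = integer(), length = numeric(),
                 mu0 = numeric()),
      height = H, width = W, connectivity = connectivity))
  }
  rc <- which(mask, arr.ind = TRUE)
  ids <- (rc[, 1] - 1L) * W + rc[, 2]
  ord <- order(ids)
  rc <- rc[ord, , drop = FALSE]
  ids <- ids[ord]
  nodes <- data.frame(
    id = ids, row = rc[, 1], col = rc[, 2],
    x = (rc[, 2] - 0.5) / W, y = 1 - (rc[, 1] - 0.5) / H,
    intensity = field$intensity[cbind(rc[, 1], rc[, 2])])

  offsets <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8)
    offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  ef <- et <- integer(0); el <- emu <- numeric(0)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    rows <- seq_len(H - dr)
    cols <- if (dc >= 0) seq_len(W - dc) else seq.int(1 - dc, W)
    if (length(rows) == 0 || length(cols) == 0) next
    a <- mask[rows, cols, drop = FALSE]
    b <- mask[rows + dr, cols + dc, drop = FALSE]
    hit <- which(a & b, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    r1 <- rows[hit[, 1]]; c1 <- cols[hit[, 2]]
    r2 <- r1 + dr; c2 <- c1 + dc
    id1 <- (r1 - 1L) * W + c1
    id2 <- (r2 - 1L) * W + c2
    ef <- c(ef, pmin(id1, id2)); et <- c(et, pmax(id1, id2))
    el <- c(el, rep(sqrt(dr^2 + dc^2), length(id1)))
    emu <- c(emu, pmax((field$intensity[cbind(r1, c1)] +
                          field$intensity[cbind(r2, c2)]) / 2, eps0))
  }
  pixel_graph(nodes,
              data.frame(from = ef, to = et, length = el, mu0 = emu),
              height = H, width = W, connectivity = connectivity)
}

#' Signed incidence matrix
#'
#' Node-by-edge sparse matrix B with +1 at the lower-id endpoint and -1 at
#' the higher-id endpoint of each edge (the orientation only fixes flux
#' signs, never magnitudes).
#'
#' @param g A [pixel_graph].
#' @return A sparse `dgCMatrix` of size nodes x edges.
#' @export
incidence_matrix <- function(g) {
  stopifnot(inherits(g, "pixel_graph"))
  m <- nrow(g$edges)
  Matrix::sparseMatrix(
    i = c(g$edges$from_idx, g$edges$to_idx),
    j = rep(seq_len(m), 2),
    x = c(rep(1, m), rep(-1, m)),
    dims = c(nrow(g$nodes), m))
}

as_igraph_pixel_graph <- function(g, weights = NULL) {
  ig <- igraph::make_empty_graph(n = nrow(g$nodes), directed = FALSE)
  if (nrow(g$edges) > 0)
    ig <- igraph::add_edges(ig, rbind(g$edges$from_idx, g$edges$to_idx))
  if (!is.null(weights)) igraph::E(ig)$weight <- weights
  ig
}

subset_pixel_graph <- function(g, node_idx) {
  keep_ids <- g$nodes$id[node_idx]
  e <- g$edges[g$edges$from %in% keep_ids & g$edges$to %in% keep_ids,
               c("from", "to", "length", "mu0"), drop = FALSE]
  pixel_graph(g$nodes[node_idx, , drop = FALSE], e,
              height = g$height, width = g$width,
              connectivity = g$connectivity)
}

#' Split a pixel graph into connected components
#'
#' @param g A [pixel_graph].
#' @return List of `pixel_graph` objects, ordered by decreasing node count,
#'   ties broken by smallest node id; an empty graph yields an empty list.
#' @export
graph_components <- function(g) {
  stopifnot(inherits(g, "pixel_graph"))
  n <- nrow(g$nodes)
  if (n == 0) return(list())
  if (nrow(g$edges) == 0) {
    comps <- lapply(seq_len(n), function(i) subset_pixel_graph(g, i))
  } else {
    memb <- igraph::components(as_igraph_pixel_graph(g))$membership
    comps <- lapply(split(seq_len(n), memb),
                    function(idx) subset_pixel_graph(g, idx))
  }
  sizes <- vapply(comps, function(cg) nrow(cg$nodes), numeric(1))
  minid <- vapply(comps, function(cg) min(cg$nodes$id), numeric(1))
  comps[order(-sizes, minid)]
}

#' @export
print.pixel_graph <- function(x, ...) {
  cat(sprintf("pixel_graph: %d nodes, %d edges (%d-connectivity)\n",
              nrow(x$nodes), nrow(x$edges), x$connectivity))
  invisible(x)
}

#' Write a pixel graph as TSV tables
#'
#' Edge list (source, target, length, init_conductivity) plus a node table
#' with pixel and unit-square coordinates.
#'
#' @param g A [pixel_graph].
#' @param path Edge-list TSV path.
#' @param nodes_path Node-table TSV path; default derived from `path`.
#' @param header Optional character vector of `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_pixel_graph <- function(g, path,
                              nodes_path = sub("(\\.tsv)?$", ".nodes.tsv",
                                               path),
                              header = character()) {
  e <- g$edges[, c("from", "to", "length", "mu0")]
  names(e) <- c("source", "target", "length", "init_conductivity")
  write_tsv_with_header(e, path, header)
  write_tsv_with_header(g$nodes, nodes_path, header)
  invisible(path)
}

write_tsv_with_header <- function(df, path, header = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  ## fixed significant digits => byte-identical reruns
  df[] <- lapply(df, function(col)
    if (is.double(col)) sprintf("%.12g", col) else col)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
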