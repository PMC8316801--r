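## Grid-based similarity between an extracted network and the image it came
## from. The unit square is tiled by P = g^2 congruent cells; per cell the
## number (or weight) of network edges is compared with the number (or
## intensity mass) of supra-threshold pixels. Lower values mean higher
## similarity; 0 means per-cell equality.

#' Define a similarity grid
#'
#' `P = side^2` non-intersecting square cells tiling the unit square.
#'
#' @param side Grid side (cells per axis), a positive integer.
#' @return Object of class `similarity_grid` with elements `side` and `P`.
#' @export
similarity_grid <- function(side = 32) {
  if (!is_count(side) || side < 1)
    stop_validation("grid side must be a positive integer, got %s",
                    format(side))
  structure(list(side = as.integer(side), P = as.integer(side)^2),
            class = "similarity_grid")
}

## Cell index (1-based) of points in [0,1]^2; points on the upper boundary
## belong to the last cell so the cells cover the closed square.
cell_index <- function(x, y, side) {
  if (any(x < 0 | x > 1 | y < 0 | y > 1, na.rm = TRUE))
    stop_validation("coordinates outside the unit square: mismatched frames?")
  ix <- pmin(floor(x * side), side - 1)
  iy <- pmin(floor(y * side), side - 1)
  as.integer(iy * side + ix + 1)
}

## Per-cell sums of `val` for points (x, y); returns a length-P vector.
cell_accumulate <- function(x, y, val, grid) {
  out <- numeric(grid$P)
  if (length(x) == 0) return(out)
  idx <- cell_index(x, y, grid$side)
  s <- rowsum(val, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

## Edge cell contributions. "midpoint" assigns each edge (weight) to the cell
## containing its midpoint; "split" spreads it over `samples` points along
## the edge for a length-fraction assignment.
edge_cell_mass <- function(net, grid, val, edge_assign = "midpoint",
                           samples = 8) {
  if (nrow(net$nodes) > 0 &&
      any(net$nodes$x < 0 | net$nodes$x > 1 |
            net$nodes$y < 0 | net$nodes$y > 1))
    stop_validation(
      "network coordinates outside the unit square: mismatched frames?")
  e <- net$edges
  if (nrow(e) == 0) return(numeric(grid$P))
  i <- match(e$from, net$nodes$id)
  j <- match(e$to, net$nodes$id)
  x1 <- net$nodes$x[i]; y1 <- net$nodes$y[i]
  x2 <- net$nodes$x[j]; y2 <- net$nodes$y[j]
  if (edge_assign == "midpoint") {
    cell_accumulate((x1 + x2) / 2, (y1 + y2) / 2, val, grid)
  } else if (edge_assign == "split") {
    t <- (seq_len(samples) - 0.5) / samples
    xs <- as.vector(outer(x2 - x1, t) + x1)
    ys <- as.vector(outer(y2 - y1, t) + y1)
    cell_accumulate(xs, ys, rep(val / samples, times = samples), grid)
  } else {
    stop_config("unknown edge_assign '%s'", edge_assign)
  }
}

pixel_centres <- function(field) {
  H <- field$height; W <- field$width
  list(x = rep((seq_len(W) - 0.5) / W, each = H),
       y = rep(1 - (seq_len(H) - 0.5) / H, times = W),
       p = as.vector(field$intensity))
}

#' Binary grid similarity
#'
#' `w_b = (1/P) * sqrt( sum_cells (edge count - supra-delta pixel count)^2 )`.
#' An edge is counted in the cell containing its midpoint (configurable); a
#' pixel counts iff its intensity exceeds `delta` — the same threshold used
#' for extraction. 0 means exact per-cell agreement; lower is more similar.
#'
#' @param net An [extracted_network] with unit-square coordinates.
#' @param field The source [pixel_field].
#' @param delta Pixel threshold in \[0, 1\].
#' @param grid A [similarity_grid].
#' @param edge_assign `"midpoint"` (default) or `"split"` (length-fraction
#'   assignment over sample points).
#' @return Scalar similarity (lower is better).
#' @export
similarity_binary <- function(net, field, delta, grid = similarity_grid(),
                              edge_assign = "midpoint") {
  stopifnot(inherits(net, "extracted_network"),
            inherits(field, "pixel_field"),
            inherits(grid, "similarity_grid"))
  if (!is.numeric(delta) || delta < 0 || delta > 1)
    stop_validation("delta must lie in [0, 1]")
  ec <- edge_cell_mass(net, grid, rep(1, nrow(net$edges)), edge_assign)
  pc <- pixel_centres(field)
  on <- pc$p > delta
  pcnt <- cell_accumulate(pc$x[on], pc$y[on], rep(1, sum(on)), grid)
  sqrt(sum((ec - pcnt)^2)) / grid$P
}

#' Weighted grid similarity
#'
#' `w = (1/P) * sqrt( sum_cells (sum of edge weights - sum of pixel
#' intensities)^2 )`. No threshold is needed: low-intensity pixels are
#' penalised by their own small contribution.
#'
#' @inheritParams similarity_binary
#' @return Scalar similarity (lower is better).
#' @export
similarity_weighted <- function(net, field, grid = similarity_grid(),
                                edge_assign = "midpoint") {
  stopifnot(inherits(net, "extracted_network"),
            inherits(field, "pixel_field"),
            inherits(grid, "similarity_grid"))
  ew <- edge_cell_mass(net, grid, net$edges$weight, edge_assign)
  pc <- pixel_centres(field)
  pw <- cell_accumulate(pc$x, pc$y, pc$p, grid)
  sqrt(sum((ew - pw)^2)) / grid$P
}
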