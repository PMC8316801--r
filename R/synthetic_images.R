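## Parametric ground-truth scenes: planted graphs (trees, rings, lattices,
## curved filaments) rendered into pixel fields with anti-aliased strokes and
## optional noise, so every pipeline stage is testable without external
## image corpora.

#' Generate a ground-truth scene
#'
#' Builds a planted graph with coordinates in the unit square plus rendering
#' parameters. Kinds:
#' \describe{
#'   \item{`ring`}{a circle approximated by `n_seg` chords; 1 cycle, 0
#'     leaves. The centre is jittered slightly (seeded) so the rasterised
#'     annulus is not exactly grid-symmetric.}
#'   \item{`random_tree`}{a planar tree with exactly `n_leaves` tips, grown
#'     by recursive angular-sector branching from a central root with seeded
#'     jitter (sectors nest, so edges cannot cross).}
#'   \item{`loopy_grid`}{a `k` x `k` lattice; `(k-1)^2` independent cycles.}
#'   \item{`curved_path`}{a smooth filament: a heading random walk with
#'     bounded turn per step (river-like geometry).}
#' }
#'
#' @param kind One of `"random_tree"`, `"ring"`, `"loopy_grid"`,
#'   `"curved_path"`.
#' @param params Named list overriding kind-specific defaults (see Details)
#'   and the common rendering parameters `size` (canvas pixels, default 64),
#'   `width_px` (stroke width, default 2), `foreground` (0.95),
#'   `background` (0.05), `noise_sigma` (0), `salt_pepper` (0).
#' @param seed Integer seed; identical seeds give identical scenes.
#' @return Object of class `scene`: `nodes` (id, x, y), `edges` (from, to),
#'   rendering parameters and the seed.
#' @export
make_scene <- function(kind, params = list(), seed = 0) {
  defaults <- list(size = 64, width_px = 2, foreground = 0.95,
                   background = 0.05, noise_sigma = 0, salt_pepper = 0)
  p <- utils::modifyList(defaults, params)
  if (p$width_px < 1) stop_validation("stroke width must be >= 1 pixel")
  geom <- with_seed(derive_seed(seed, "scene"), switch(
    kind,
    ring = scene_ring(p),
    random_tree = scene_random_tree(p),
    loopy_grid = scene_loopy_grid(p),
    curved_path = scene_curved_path(p),
    stop_config("unknown scene kind '%s'", kind)))
  if (any(geom$nodes$x < 0 | geom$nodes$x > 1 |
            geom$nodes$y < 0 | geom$nodes$y > 1))
    stop_validation("planted coordinates left the unit square")
  structure(c(geom, list(kind = kind, size = p$size, width_px = p$width_px,
                         foreground = p$foreground, background = p$background,
                         noise_sigma = p$noise_sigma,
                         salt_pepper = p$salt_pepper, seed = seed)),
            class = "scene")
}

scene_ring <- function(p) {
  r <- p$radius %||% 0.3
  n <- p$n_seg %||% 60
  centre <- c(0.5, 0.5) + stats::runif(2, -0.015, 0.015)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  nodes <- data.frame(id = seq_len(n),
                      x = centre[1] + r * cos(th),
                      y = centre[2] + r * sin(th))
  edges <- data.frame(from = seq_len(n), to = c(seq_len(n)[-1], 1L))
  list(nodes = nodes, edges = edges)
}

## Recursive sector branching: a node owning an angular sector and a quota of
## leaves splits its sector among children until each carries one leaf.
## Sectors nest and radii increase monotonically, so edges never cross.
scene_random_tree <- function(p) {
  n_leaves <- p$n_leaves %||% 8
  if (n_leaves < 2) stop_validation("random_tree needs n_leaves >= 2")
  steps <- c(0.17, 0.12, 0.085, 0.06, 0.045, 0.035)
  nodes <- data.frame(id = 1L,
                      x = 0.5 + stats::runif(1, -0.02, 0.02),
                      y = 0.5 + stats::runif(1, -0.02, 0.02))
  edges <- data.frame(from = integer(), to = integer())
  new_node <- function(x, y) {
    id <- nrow(nodes) + 1L
    nodes[id, ] <<- list(id, min(max(x, 0.03), 0.97),
                         min(max(y, 0.03), 0.97))
    id
  }
  grow <- function(parent, a0, a1, quota, depth) {
    step <- steps[min(depth + 1, length(steps))] * stats::runif(1, 0.85, 1.1)
    if (quota == 1) {
      ang <- (a0 + a1) / 2 + stats::runif(1, -0.25, 0.25) * (a1 - a0)
      tip <- new_node(nodes$x[parent] + step * cos(ang),
                      nodes$y[parent] + step * sin(ang))
      edges[nrow(edges) + 1L, ] <<- list(parent, tip)
      return(invisible())
    }
    k <- if (depth == 0) min(quota, 4L) else 2L
    split <- rep(quota %/% k, k)
    extra <- quota %% k
    if (extra > 0) split[seq_len(extra)] <- split[seq_len(extra)] + 1L
    bounds <- a0 + (a1 - a0) * cumsum(c(0, split)) / quota
    for (ki in seq_len(k)) {
      b0 <- bounds[ki]; b1 <- bounds[ki + 1]
      ang <- (b0 + b1) / 2 + stats::runif(1, -0.15, 0.15) * (b1 - b0)
      child <- new_node(nodes$x[parent] + step * cos(ang),
                        nodes$y[parent] + step * sin(ang))
      edges[nrow(edges) + 1L, ] <<- list(parent, child)
      grow(child, b0, b1, split[ki], depth + 1L)
    }
  }
  a0 <- stats::runif(1, 0, 2 * pi)
  grow(1L, a0, a0 + 2 * pi, as.integer(n_leaves), 0L)
  list(nodes = nodes, edges = edges)
}

scene_loopy_grid <- function(p) {
  k <- p$k %||% 3
  if (k < 2) stop_validation("loopy_grid needs k >= 2")
  xs <- seq(0.25, 0.75, length.out = k)
  gridpts <- expand.grid(cx = xs, cy = xs)
  nodes <- data.frame(id = seq_len(nrow(gridpts)),
                      x = gridpts$cx, y = gridpts$cy)
  idx <- matrix(seq_len(k * k), k, k)   # [xi, yi]
  edges <- rbind(
    data.frame(from = as.vector(idx[-k, ]), to = as.vector(idx[-1, ])),
    data.frame(from = as.vector(idx[, -k]), to = as.vector(idx[, -1])))
  list(nodes = nodes, edges = edges)
}

scene_curved_path <- function(p) {
  n <- p$n_steps %||% 30
  max_turn <- p$max_turn %||% 0.35
  step <- p$step %||% (0.75 / n)
  x <- 0.12; y <- stats::runif(1, 0.3, 0.7)
  heading <- stats::runif(1, -0.3, 0.3)
  xs <- x; ys <- y
  for (i in seq_len(n)) {
    heading <- heading + stats::runif(1, -max_turn, max_turn)
    heading <- max(min(heading, 1.1), -1.1)   # keep marching rightward
    x <- x + step * cos(heading)
    y <- y + step * sin(heading)
    if (y < 0.08 || y > 0.92) heading <- -heading
    y <- min(max(y, 0.05), 0.95)
    xs <- c(xs, x); ys <- c(ys, y)
  }
  n1 <- length(xs)
  list(nodes = data.frame(id = seq_len(n1), x = xs, y = ys),
       edges = data.frame(from = seq_len(n1 - 1), to = seq.int(2, n1)))
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("scene '%s': %d nodes, %d edges, %dpx canvas, stroke %.3gpx\n",
              x$kind, nrow(x$nodes), nrow(x$edges), x$size, x$width_px))
  invisible(x)
}

#' Rasterize a scene into a pixel field
#'
#' Anti-aliased stroke rendering: per pixel, the coverage is
#' `clamp(width/2 + 0.5 - d, 0, 1)` with `d` the distance (in pixels) to the
#' nearest planted segment; intensity interpolates between the scene's
#' background and foreground levels. Noise (additive Gaussian, then
#' salt-and-pepper) is applied last and clipped to \[0, 1\], under a seed
#' derived from the scene's.
#'
#' @param scene A [make_scene] result.
#' @return A [pixel_field] of size `scene$size` squared.
#' @export
rasterize <- function(scene) {
  stopifnot(inherits(scene, "scene"))
  H <- W <- scene$size
  A <- matrix(0, H, W)
  halfw <- scene$width_px / 2
  ## planted coordinates -> continuous pixel frame (pixel (r,c) centre at
  ## (c - 0.5, r - 0.5))
  px <- scene$nodes$x * W
  py <- (1 - scene$nodes$y) * H
  for (k in seq_len(nrow(scene$edges))) {
    i <- scene$edges$from[k]; j <- scene$edges$to[k]
    x1 <- px[i]; y1 <- py[i]; x2 <- px[j]; y2 <- py[j]
    r0 <- max(1L, floor(min(y1, y2) - halfw - 1))
    r1 <- min(H, ceiling(max(y1, y2) + halfw + 1))
    c0 <- max(1L, floor(min(x1, x2) - halfw - 1))
    c1 <- min(W, ceiling(max(x1, x2) + halfw + 1))
    if (r0 > r1 || c0 > c1) next
    rows <- r0:r1; cols <- c0:c1
    cx <- matrix(cols - 0.5, length(rows), length(cols), byrow = TRUE)
    cy <- matrix(rows - 0.5, length(rows), length(cols))
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx^2 + dy^2
    t <- if (len2 == 0) 0 else pmin(pmax(((cx - x1) * dx +
                                            (cy - y1) * dy) / len2, 0), 1)
    d <- sqrt((cx - (x1 + t * dx))^2 + (cy - (y1 + t * dy))^2)
    a <- pmin(pmax(halfw + 0.5 - d, 0), 1)
    A[rows, cols] <- pmax(A[rows, cols], a)
  }
  I <- scene$background + (scene$foreground - scene$background) * A
  if (scene$noise_sigma > 0 || scene$salt_pepper > 0) {
    I <- with_seed(derive_seed(scene$seed, "noise"), {
      if (scene$noise_sigma > 0)
        I <- I + stats::rnorm(length(I), sd = scene$noise_sigma)
      if (scene$salt_pepper > 0) {
        hit <- stats::runif(length(I)) < scene$salt_pepper
        I[hit] <- stats::rbinom(sum(hit), 1, 0.5)
      }
      I
    })
  }
  pixel_field(matrix(pmin(pmax(I, 0), 1), H, W))
}

#' Compare an extraction against a planted scene
#'
#' Desk-scale topology report: leaf recall (fraction of planted degree-1
#' endpoints with an extracted degree-1 node within `tol_px` pixels),
#' independent-cycle counts of both graphs, and the mean displacement of the
#' matched leaves.
#'
#' @param net An [extracted_network] in the unit-square frame.
#' @param scene The [make_scene] ground truth.
#' @param tol_px Matching tolerance in pixels.
#' @return List with `leaf_recall`, `cycles_planted`, `cycles_extracted`,
#'   `cycle_match`, `mean_displacement_px`, `n_planted_leaves`,
#'   `n_extracted_leaves`.
#' @export
topology_match <- function(net, scene, tol_px = 3) {
  stopifnot(inherits(net, "extracted_network"), inherits(scene, "scene"))
  deg_p <- table(factor(c(scene$edges$from, scene$edges$to),
                        levels = scene$nodes$id))
  planted <- scene$nodes[deg_p == 1, , drop = FALSE]
  ig <- as_igraph(net)
  deg_e <- if (nrow(net$nodes)) igraph::degree(ig) else integer()
  exleaf <- net$nodes[deg_e == 1, , drop = FALSE]
  s <- scene$size
  if (nrow(planted) == 0) {
    recall <- NA_real_; disp <- NA_real_
  } else if (nrow(exleaf) == 0) {
    recall <- 0; disp <- NA_real_
  } else {
    d <- outer(planted$x, exleaf$x, "-")^2 + outer(planted$y, exleaf$y, "-")^2
    nearest <- sqrt(apply(d, 1, min)) * s
    recall <- mean(nearest <= tol_px)
    disp <- if (any(nearest <= tol_px)) mean(nearest[nearest <= tol_px])
            else NA_real_
  }
  cyc_p <- if (nrow(scene$edges) == 0) 0L else {
    ig_p <- igraph::make_empty_graph(n = nrow(scene$nodes),
                                     directed = FALSE)
    ig_p <- igraph::add_edges(ig_p, rbind(scene$edges$from, scene$edges$to))
    as.integer(nrow(scene$edges) - nrow(scene$nodes) +
                 igraph::components(ig_p)$no)
  }
  cyc_e <- cycle_count(net)
  list(leaf_recall = recall,
       cycles_planted = cyc_p,
       cycles_extracted = cyc_e,
       cycle_match = identical(cyc_p, cyc_e),
       mean_displacement_px = disp,
       n_planted_leaves = nrow(planted),
       n_extracted_leaves = nrow(exleaf))
}

#' Write a scene's ground truth as TSV
#'
#' Edge list plus node coordinates (unit square and pixel frame).
#'
#' @param scene A [make_scene] result.
#' @param path Output TSV path for edges; nodes go to a companion file.
#' @return `path`, invisibly.
#' @export
write_scene_truth <- function(scene, path) {
  nodes <- scene$nodes
  nodes$col_px <- nodes$x * scene$size
  nodes$row_px <- (1 - nodes$y) * scene$size
  write_tsv_with_header(scene$edges, path,
                        header = sprintf("scene kind=%s size=%d seed=%d",
                                         scene$kind, scene$size, scene$seed))
  write_tsv_with_header(nodes, sub("(\\.tsv)?$", ".nodes.tsv", path))
  invisible(path)
}
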