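empty_net <- function() {
  extracted_network(
    data.frame(id = integer(), x = numeric(), y = numeric()),
    data.frame(from = integer(), to = integer(), weight = numeric(),
               length_px = numeric(), length = numeric()))
}

one_edge_net <- function(x1, y1, x2, y2, w = 1) {
  extracted_network(
    data.frame(id = 1:2, x = c(x1, x2), y = c(y1, y2)),
    data.frame(from = 1, to = 2, weight = w,
               length_px = 1, length = sqrt((x2 - x1)^2 + (y2 - y1)^2)))
}

test_that("binary similarity matches hand-computed cases", {
  # empty network vs all-below-threshold field: 0
  expect_equal(similarity_binary(empty_net(),
                                 pixel_field(matrix(0.1, 3, 3)), 0.5,
                                 similarity_grid(1)), 0)
  # P = 1: one edge vs three supra-delta pixels -> sqrt((1-3)^2) = 2
  fld <- pixel_field(matrix(c(0.9, 0.9, 0.9, 0.1), 2, 2))
  expect_equal(similarity_binary(one_edge_net(0.2, 0.5, 0.4, 0.5),
                                 fld, 0.5, similarity_grid(1)), 2)
  # per-cell equality: 0 at any grid
  net <- one_edge_net(0.1, 0.9, 0.3, 0.9)          # midpoint in the cell of
  f1 <- matrix(0.05, 4, 4); f1[1, 1] <- 0.95       # pixel (1,1)
  for (side in c(1, 2, 4))
    expect_equal(similarity_binary(net, pixel_field(f1), 0.5,
                                   similarity_grid(side)), 0)
})

test_that("degenerate pixel self-edges give exact self-similarity", {
  set.seed(13)
  f <- pixel_field(matrix(runif(64), 8, 8))
  mask <- threshold_mask(f, 0.5)
  rc <- which(mask, arr.ind = TRUE)
  x <- (rc[, 2] - 0.5) / 8; y <- 1 - (rc[, 1] - 0.5) / 8
  n <- nrow(rc)
  # one zero-length-ish "edge" per supra-delta pixel, anchored at its centre
  nodes <- data.frame(id = seq_len(2 * n),
                      x = c(x, x + 1e-9), y = c(y, y))
  edges <- data.frame(from = seq_len(n), to = n + seq_len(n), weight = 1,
                      length_px = 0, length = 1e-9)
  net <- extracted_network(nodes, edges)
  expect_equal(similarity_binary(net, f, 0.5, similarity_grid(8)), 0)
})

test_that("weighted similarity is mass-matching and homogeneous", {
  # empty net vs (nearly) zero field
  expect_equal(similarity_weighted(empty_net(),
                                   pixel_field(matrix(0, 2, 2))), 0)
  # P = 1: one edge with weight 2 vs two pixels of intensity 1 -> 0
  fld <- pixel_field(matrix(c(1, 1, 0, 0), 2, 2))
  expect_equal(similarity_weighted(one_edge_net(0.2, 0.5, 0.4, 0.5, w = 2),
                                   fld, similarity_grid(1)), 0)
  # homogeneity: scaling weights and intensities by c scales the metric by c
  set.seed(17)
  f <- pixel_field(matrix(runif(36, 0, 0.5), 6, 6))
  net <- one_edge_net(0.3, 0.3, 0.7, 0.7, w = 1.3)
  base <- similarity_weighted(net, f, similarity_grid(3))
  scaled_net <- one_edge_net(0.3, 0.3, 0.7, 0.7, w = 2 * 1.3)
  f2 <- pixel_field(2 * f$intensity)
  expect_equal(similarity_weighted(scaled_net, f2, similarity_grid(3)),
               2 * base)
})

test_that("both metrics reject out-of-frame coordinates and bad grids", {
  bad <- extracted_network(
    data.frame(id = 1:2, x = c(0.2, 1.4), y = c(0.5, 0.5)),
    data.frame(from = 1, to = 2, weight = 1, length_px = 1, length = 1.2))
  f <- pixel_field(matrix(0.5, 2, 2))
  expect_error(similarity_binary(bad, f, 0.5, similarity_grid(2)),
               class = "img2net_validation")
  expect_error(similarity_grid(0), class = "img2net_validation")
})

test_that("length and counts summarise the network", {
  expect_equal(network_length(empty_net()), 0)
  expect_equal(unname(network_counts(empty_net())), c(0, 0))
  net <- one_edge_net(0, 0, 1, 0)
  expect_equal(unname(network_counts(net)), c(2, 1))
  # unit square cycle: length 4
  sq <- extracted_network(
    data.frame(id = 1:4, x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)),
    data.frame(from = c(1, 2, 3, 1), to = c(2, 3, 4, 4), weight = 1,
               length_px = 1, length = 1))
  expect_equal(network_length(sq), 4)
  expect_equal(cycle_count(sq), 1)
  # path of two unit edges (half-unit coordinates)
  p <- extracted_network(
    data.frame(id = 1:3, x = c(0, 0.5, 1), y = 0),
    data.frame(from = c(1, 2), to = c(2, 3), weight = 1,
               length_px = 1, length = c(1, 1)))
  expect_equal(network_length(p), 2)
  # 2x2 full pre-extracted block: (4, 6)
  g <- build_pixel_graph(pixel_field(matrix(1, 2, 2)), 0.5)
  net22 <- network_from_pixel_edges_for_test(g, seq_len(nrow(g$edges)))
  expect_equal(unname(network_counts(net22)), c(4, 6))
})

test_that("length-fraction edge assignment spreads mass across cells", {
  # a long edge crossing two cells: split mode sees both, midpoint only one
  net <- one_edge_net(0.05, 0.25, 0.95, 0.25)
  f <- pixel_field(matrix(0, 2, 2))
  gr <- similarity_grid(2)
  mid <- similarity_binary(net, f, 0.5, gr)
  split <- similarity_binary(net, f, 0.5, gr, edge_assign = "split")
  expect_equal(mid, sqrt(1) / 4)                   # all mass in one cell
  expect_equal(split, sqrt(0.5^2 + 0.5^2) / 4)     # half in each
})
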