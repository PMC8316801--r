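test_that("scene generators are deterministic and honour their contracts", {
  s1 <- make_scene("ring", list(size = 64), seed = 3)
  s2 <- make_scene("ring", list(size = 64), seed = 3)
  expect_identical(s1, s2)
  s3 <- make_scene("ring", list(size = 64), seed = 4)
  expect_false(identical(s1$nodes, s3$nodes))

  # planted ring: 1 cycle, 0 leaves
  deg <- table(c(s1$edges$from, s1$edges$to))
  expect_true(all(deg == 2))
  expect_equal(nrow(s1$edges), nrow(s1$nodes))

  # random tree: exactly the requested leaves, n-1 edges
  for (nl in c(2, 5, 8)) {
    tr <- make_scene("random_tree", list(n_leaves = nl), seed = nl)
    expect_equal(nrow(tr$edges), nrow(tr$nodes) - 1)
    degt <- table(factor(c(tr$edges$from, tr$edges$to),
                         levels = tr$nodes$id))
    expect_equal(sum(degt == 1), nl)
  }

  # loopy grid: (k-1)^2 independent cycles
  lg <- make_scene("loopy_grid", list(k = 3), seed = 1)
  expect_equal(nrow(lg$edges) - nrow(lg$nodes) + 1, 4)

  # curved path: a simple open chain inside the unit square
  cp <- make_scene("curved_path", list(), seed = 6)
  expect_equal(nrow(cp$edges), nrow(cp$nodes) - 1)
  expect_true(all(cp$nodes$x >= 0 & cp$nodes$x <= 1))

  expect_error(make_scene("moebius", seed = 1), class = "img2net_config")
})

test_that("rasterization separates subject from background", {
  sc <- make_scene("ring", list(size = 64), seed = 2)
  f <- rasterize(sc)
  expect_s3_class(f, "pixel_field")
  expect_equal(dim(f$intensity), c(64, 64))
  # subject >= 0.8, background <= 0.1 at zero noise
  expect_gte(max(f$intensity), 0.8)
  expect_lte(min(f$intensity), 0.1)
  # the supra-0.5 mask is one connected annulus (and it carries cycles)
  g <- build_pixel_graph(f, 0.5)
  expect_length(graph_components(g), 1)
  full <- network_from_pixel_edges_for_test(g, seq_len(nrow(g$edges)))
  expect_gte(cycle_count(full), 1)
})

test_that("an empty scene renders a uniform background", {
  sc <- make_scene("ring", list(size = 16), seed = 1)
  sc$edges <- sc$edges[0, , drop = FALSE]
  f <- rasterize(sc)
  expect_equal(unique(as.vector(f$intensity)), sc$background)
})

test_that("noise perturbs only pixels near the threshold level set", {
  s0 <- make_scene("random_tree", list(size = 48, n_leaves = 4), seed = 8)
  s1 <- s0; s1$noise_sigma <- 0.05
  m0 <- threshold_mask(rasterize(s0), 0.5)
  m1 <- threshold_mask(rasterize(s1), 0.5)
  changed <- which(m0 != m1, arr.ind = TRUE)
  if (nrow(changed) > 0) {
    # every flipped pixel had intensity within 4 sigma of delta
    i0 <- rasterize(s0)$intensity[changed]
    expect_true(all(abs(i0 - 0.5) < 0.2))
  }
  # zero-noise support recovers the planted strokes up to a 1-pixel band:
  # every supra-threshold pixel lies within (width/2 + 1) px of a segment
  f0 <- rasterize(s0)
  g <- build_pixel_graph(f0, 0.5)
  px <- s0$nodes$x * s0$size; py <- (1 - s0$nodes$y) * s0$size
  min_d <- vapply(seq_len(nrow(g$nodes)), function(i) {
    cx <- g$nodes$col[i] - 0.5; cy <- g$nodes$row[i] - 0.5
    min(vapply(seq_len(nrow(s0$edges)), function(k) {
      a <- s0$edges$from[k]; b <- s0$edges$to[k]
      dx <- px[b] - px[a]; dy <- py[b] - py[a]
      t <- max(0, min(1, ((cx - px[a]) * dx + (cy - py[a]) * dy) /
                        (dx^2 + dy^2)))
      sqrt((cx - px[a] - t * dx)^2 + (cy - py[a] - t * dy)^2)
    }, numeric(1)))
  }, numeric(1))
  expect_lte(max(min_d), s0$width_px / 2 + 1)
})

test_that("topology reports quantify leaf recall and cycle mismatch", {
  sc <- make_scene("random_tree", list(size = 48, n_leaves = 5), seed = 11)
  # perfect self-report: use the planted graph itself as the extraction
  net <- extracted_network(
    sc$nodes,
    data.frame(from = sc$edges$from, to = sc$edges$to, weight = 1,
               length_px = 1, length = 0.05))
  rep <- topology_match(net, sc)
  expect_equal(rep$leaf_recall, 1)
  expect_equal(rep$mean_displacement_px, 0)
  expect_true(rep$cycle_match)

  # planted ring vs a tree extraction: cycle counts 1 vs 0
  ring <- make_scene("ring", list(size = 48), seed = 2)
  net1 <- image2net(rasterize(ring), n_runs = 1, seed = 2)
  rep2 <- topology_match(net1, ring)
  expect_equal(rep2$cycles_planted, 1)
  expect_equal(rep2$cycles_extracted, 0)
  expect_false(rep2$cycle_match)
})

test_that("ground truth files are written alongside the rendering", {
  sc <- make_scene("loopy_grid", list(size = 32, k = 2), seed = 1)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_scene_truth(sc, tmp)
  edges <- read.table(tmp, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(edges), nrow(sc$edges))
  nodes <- read.table(sub("(\\.tsv)?$", ".nodes.tsv", tmp), header = TRUE,
                      sep = "\t", comment.char = "#")
  expect_true(all(c("x", "y", "col_px", "row_px") %in% names(nodes)))
})
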