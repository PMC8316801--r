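test_that("terminal auto-selection returns the leaves of the filtered tree", {
  # single edge: both endpoints
  g <- path_graph(2)
  ts <- select_terminals(g, seed = 1)
  expect_setequal(ts$ids, c(1, 2))

  # path of 5: the two endpoints
  ts5 <- select_terminals(path_graph(5), seed = 1)
  expect_setequal(ts5$ids, c(1, 5))

  # 4-connectivity star: the 4 spoke tips (ids 2,4,6,8 of the 3x3 plus)
  st <- star_graph()
  tst <- select_terminals(st, seed = 2)
  centre <- 5
  expect_false(centre %in% tst$ids)
  expect_setequal(tst$ids, setdiff(st$nodes$id, centre))

  expect_error(select_terminals(path_graph(2)[c("nodes", "edges")]),
               "pixel_graph")
  expect_error(select_terminals(subset_path <- pixel_graph(
    data.frame(id = 1, x = 0, y = 0),
    data.frame(from = integer(), to = integer(), length = numeric(),
               mu0 = numeric()))),
               class = "img2net_validation")
})

test_that("single-source runs return trees through the demanded terminals", {
  g <- path_graph(5)
  net <- run_single_source(g, 1, c(1, 5))
  expect_equal(nrow(net$edges), 4)                 # the whole path
  expect_true(all(net$edges$weight > 0))

  expect_error(run_single_source(g, 3, c(1, 5)),
               class = "img2net_validation")       # source not a terminal

  # ring with 2 terminals: one arc, never the full ring
  gr <- ring_graph(10)
  netr <- run_single_source(gr, 1, c(1, 4))
  expect_equal(cycle_count(netr), 0)
  expect_lt(nrow(netr$edges), 10)
  expect_true(all(c(1, 4) %in% netr$nodes$id))
})

test_that("superposition sums weights over the union of runs", {
  g <- path_graph(4)
  net <- run_single_source(g, 1, c(1, 4))
  # single run: identity
  s1 <- superpose(list(net))
  expect_equal(s1$edges[, c("from", "to", "weight")],
               net$edges[, c("from", "to", "weight")], ignore_attr = TRUE)
  # same tree five times: same topology, weights x5
  s5 <- superpose(rep(list(net), 5))
  expect_equal(nrow(s5$edges), nrow(net$edges))
  expect_equal(s5$edges$weight, 5 * net$edges$weight)
  expect_equal(s5$edges$runs, rep("1,2,3,4,5", nrow(net$edges)))

  # two runs covering complementary arcs of a ring close a cycle
  gr <- ring_graph(10)
  all_edges <- seq_len(10)
  arc_a <- network_from_pixel_edges_for_test(gr, 1:5)
  arc_b <- network_from_pixel_edges_for_test(gr, 5:10)
  both <- superpose(list(arc_a, arc_b))
  expect_equal(cycle_count(both), 1)
  # the shared edge got both contributions summed
  shared <- both$edges$runs == "1,2"
  expect_equal(sum(shared), 1)
  expect_equal(both$edges$weight[shared], 2)

  expect_error(superpose(list()), class = "img2net_validation")
})

test_that("image2net recovers a drawn tree and stays inside G^pe", {
  scene <- make_scene("random_tree", list(size = 48, n_leaves = 5), seed = 2)
  field <- rasterize(scene)
  net <- image2net(field, n_runs = 1, seed = 2)
  rep <- topology_match(net, scene, tol_px = 3)
  expect_gte(rep$leaf_recall, 0.8)
  expect_equal(rep$cycles_extracted, 0)

  # every output edge is an edge of the pre-extracted graph
  gpe <- attr(net, "gpe")
  expect_true(all(paste(net$edges$from, net$edges$to) %in%
                    paste(gpe$edges$from, gpe$edges$to)))
})

test_that("run coverage is nested along the seeded source sequence", {
  scene <- make_scene("ring", list(size = 40), seed = 5)
  field <- rasterize(scene)
  nets <- lapply(1:3, function(r) image2net(field, n_runs = r, seed = 5))
  for (r in 1:2) {
    e_r <- paste(nets[[r]]$edges$from, nets[[r]]$edges$to)
    e_r1 <- paste(nets[[r + 1]]$edges$from, nets[[r + 1]]$edges$to)
    expect_true(all(e_r %in% e_r1))
  }
})

test_that("n_runs is capped at the number of eligible terminals", {
  g <- matrix(0, 5, 5); g[3, ] <- 1                # a 5-pixel line: 2 leaves
  field <- pixel_field(g * 0.9 + 0.05)
  expect_warning(net <- image2net(field, n_runs = 5, seed = 1),
                 "truncated")
  expect_equal(cycle_count(net), 0)
})

test_that("identical image, config and seed give identical edge lists", {
  scene <- make_scene("random_tree", list(size = 40, n_leaves = 4), seed = 9)
  field <- rasterize(scene)
  n1 <- image2net(field, n_runs = 2, seed = 7)
  n2 <- image2net(field, n_runs = 2, seed = 7)
  expect_identical(n1$edges, n2$edges)
  expect_identical(n1$nodes, n2$nodes)
})

test_that("user-supplied terminals override auto-selection", {
  g5 <- matrix(0, 3, 7); g5[2, ] <- 1
  field <- pixel_field(g5 * 0.9 + 0.05)
  gpe <- build_pixel_graph(field, 0.5)
  ids <- range(gpe$nodes$id)
  net <- image2net(field, n_runs = 1, seed = 1, terminals = ids)
  expect_true(all(ids %in% net$nodes$id))

  # per-component handling: two separate strokes, both extracted
  m <- matrix(0, 9, 9); m[2, 1:4] <- 1; m[7:8, 6:9] <- 1
  net2 <- image2net(pixel_field(m * 0.9 + 0.05), n_runs = 1, seed = 1)
  ig <- as_igraph(net2)
  expect_equal(igraph::components(ig)$no, 2)
})

test_that("an empty mask yields an empty network with a warning", {
  field <- pixel_field(matrix(0.1, 4, 4))
  expect_warning(net <- image2net(field, delta = 0.5, seed = 1),
                 "empty mask")
  expect_equal(unname(network_counts(net)), c(0, 0))
  expect_equal(network_length(net), 0)
})
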