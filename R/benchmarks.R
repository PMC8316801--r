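## Seeded validation experiments: each function builds its own fixtures with
## the package's generators, runs the method, and returns the measured
## quantities. The test suite asserts on them and scripts/acceptance.R
## reports them.

#' Random connected graph fixture
#'
#' Erdos-Renyi graph resampled until connected, wrapped as a [pixel_graph]
#' with lengths drawn from \{1, sqrt(2)\} and positive random initial
#' conductivities. Node coordinates are uniform in the unit square (used for
#' reporting only).
#'
#' @param n Number of nodes (>= 2).
#' @param seed Integer seed.
#' @return A connected [pixel_graph].
#' @export
random_connected_graph <- function(n, seed = 0) {
  with_seed(seed, {
    p <- min(1, 2 * log(max(n, 2)) / max(n - 1, 1))
    repeat {
      ig <- igraph::sample_gnp(n, p)
      if (igraph::is_connected(ig) && igraph::ecount(ig) >= n - 1) break
      p <- min(1, p * 1.2)
    }
    el <- igraph::as_edgelist(ig)
    nodes <- data.frame(id = seq_len(n), x = stats::runif(n),
                        y = stats::runif(n))
    edges <- data.frame(
      from = pmin(el[, 1], el[, 2]), to = pmax(el[, 1], el[, 2]),
      length = sample(c(1, sqrt(2)), nrow(el), replace = TRUE),
      mu0 = stats::runif(nrow(el), 0.1, 2))
    pixel_graph(nodes, edges)
  })
}

#' Random connected pixel-blob fixture
#'
#' Grows a connected mask on an `h` x `w` canvas by repeatedly annexing a
#' random 4-neighbour of the current blob, assigns random intensities in
#' (0.5, 1\] (generic position: no two exactly equal, so the dynamics never
#' faces exactly degenerate parallel routes), and pre-extracts the
#' 8-connected pixel graph.
#'
#' @param n_px Number of supra-threshold pixels.
#' @param h,w Canvas size.
#' @param seed Integer seed.
#' @return A connected [pixel_graph].
#' @export
random_blob_graph <- function(n_px, h = 24, w = 24, seed = 0) {
  if (n_px > h * w) stop_validation("blob larger than canvas")
  with_seed(seed, {
    mask <- matrix(FALSE, h, w)
    r <- h %/% 2; c <- w %/% 2
    mask[r, c] <- TRUE
    frontier <- matrix(c(r, c), 1)
    while (sum(mask) < n_px) {
      k <- sample.int(nrow(frontier), 1)
      rc <- frontier[k, ]
      nb <- rbind(rc + c(0, 1), rc + c(0, -1), rc + c(1, 0), rc + c(-1, 0))
      nb <- nb[nb[, 1] >= 1 & nb[, 1] <= h & nb[, 2] >= 1 & nb[, 2] <= w, ,
               drop = FALSE]
      nb <- nb[!mask[nb], , drop = FALSE]
      if (nrow(nb) == 0) { frontier <- frontier[-k, , drop = FALSE]; next }
      pick <- nb[sample.int(nrow(nb), 1), ]
      mask[pick[1], pick[2]] <- TRUE
      frontier <- rbind(frontier, pick)
    }
    I <- matrix(0, h, w)
    I[mask] <- stats::runif(sum(mask), 0.55, 1)
    build_pixel_graph(pixel_field(I), delta = 0.5)
  })
}

balanced_random_forcing <- function(n, n_terminals, seed) {
  with_seed(seed, {
    t_idx <- sample.int(n, n_terminals)
    f <- numeric(n)
    v <- stats::runif(n_terminals - 1, 0.2, 1)
    f[t_idx[-1]] <- -v
    f[t_idx[1]] <- sum(v)
    f
  })
}

#' Kirchhoff solver vs dense pseudo-inverse oracle
#'
#' On `n_graphs` seeded random connected graphs (<= `n_max` nodes, random
#' positive conductivities, random balanced forcing), compares
#' [solve_kirchhoff] potentials with `MASS::ginv` applied to the dense
#' weighted Laplacian (gauge-aligned), and measures the worst flux
#' conservation residual `max |B F - f|`.
#'
#' @param n_graphs Number of fixtures.
#' @param seed Integer seed.
#' @param n_max Maximum node count.
#' @return List: `max_potential_err`, `max_flux_residual`, `n`.
#' @export
bench_kirchhoff <- function(n_graphs = 100, seed = 0, n_max = 20) {
  if (!requireNamespace("MASS", quietly = TRUE))
    stop("the dense oracle needs MASS")
  pe <- fr <- 0
  for (i in seq_len(n_graphs)) {
    g <- random_connected_graph(
      n = with_seed(derive_seed(seed, "kirch_n", i), sample(4:n_max, 1)),
      seed = derive_seed(seed, "kirch_g", i))
    n <- nrow(g$nodes)
    mu <- with_seed(derive_seed(seed, "kirch_mu", i),
                    stats::runif(nrow(g$edges), 0.05, 3))
    f <- balanced_random_forcing(
      n, with_seed(derive_seed(seed, "kirch_k", i), sample(2:4, 1)),
      derive_seed(seed, "kirch_f", i))
    u <- solve_kirchhoff(mu, g, f)
    ## dense oracle
    B <- as.matrix(incidence_matrix(g))
    L <- B %*% diag(mu / g$edges$length, nrow(g$edges)) %*% t(B)
    u0 <- as.numeric(MASS::ginv(L) %*% f)
    u0 <- u0 - u0[1]          # gauge: u = 0 at the lowest-id node
    pe <- max(pe, max(abs(u - u0)))
    fl <- compute_flux(mu, u, g)
    fr <- max(fr, max(abs(as.numeric(B %*% fl) - f)))
  }
  list(max_potential_err = pe, max_flux_residual = fr, n = n_graphs)
}

single_source_forcing <- function(g, seed) {
  n <- nrow(g$nodes)
  src <- with_seed(seed, sample.int(n, 1))
  f <- rep(-1 / (n - 1), n)
  f[src] <- 1
  f
}

#' Stationary fixed-point law
#'
#' Runs the dynamics on seeded single-source problems (half beta = 1, half
#' beta = 1.5) and measures the worst relative deviation of `mu_e` from
#' `|F_e|^beta` over surviving edges, plus the worst per-step Lyapunov
#' increase of the cost trajectories (relative to the initial cost).
#'
#' @param n_problems Number of fixtures.
#' @param seed Integer seed.
#' @param n_px Blob size (pixels) of each fixture.
#' @return List: `max_rel_dev`, `max_lyapunov_increase`, `frac_converged`,
#'   `n`.
#' @export
bench_fixed_point <- function(n_problems = 20, seed = 0, n_px = 60) {
  dev <- lyap <- 0
  conv <- 0L
  for (i in seq_len(n_problems)) {
    g <- random_blob_graph(n_px, seed = derive_seed(seed, "fp_g", i))
    beta <- if (i %% 2 == 0) 1.5 else 1.0
    f <- single_source_forcing(g, derive_seed(seed, "fp_s", i))
    fit <- run_dynamics(transport_problem(g, f, beta = beta))
    conv <- conv + fit$converged
    thr <- (min(abs(f[f != 0])) / 2)^beta
    surv <- fit$mu > thr
    dev <- max(dev, max(abs(fit$mu[surv] - abs(fit$flux[surv])^beta) /
                          fit$mu[surv]))
    lyap <- max(lyap, max(diff(fit$cost_trajectory)) /
                  abs(fit$cost_trajectory[1]))
  }
  list(max_rel_dev = dev, max_lyapunov_increase = lyap,
       frac_converged = conv / n_problems, n = n_problems)
}

#' Tree theorem at beta >= 1
#'
#' For seeded connected pixel-graph fixtures with single-source forcing and
#' beta = 1.5, checks that every filtered support is acyclic, spans all
#' terminals, and has exactly n - 1 edges when it spans all n nodes.
#'
#' @param n_fixtures Number of fixtures.
#' @param seed Integer seed.
#' @param n_px_range Range of blob sizes in pixels.
#' @return List: `frac_acyclic`, `frac_spanning_tree`,
#'   `frac_terminals_covered`, `max_lyapunov_increase`, `n`.
#' @export
bench_tree_property <- function(n_fixtures = 20, seed = 0,
                                n_px_range = c(100, 350)) {
  acyc <- span <- cover <- 0L
  lyap <- 0
  for (i in seq_len(n_fixtures)) {
    n_px <- with_seed(derive_seed(seed, "tree_n", i),
                      sample(n_px_range[1]:n_px_range[2], 1))
    g <- random_blob_graph(n_px, h = 26, w = 26,
                           seed = derive_seed(seed, "tree_g", i))
    f <- single_source_forcing(g, derive_seed(seed, "tree_s", i))
    fit <- run_dynamics(transport_problem(g, f, beta = 1.5))
    net <- filter_graph(g, fit)
    acyc <- acyc + (cycle_count(net) == 0)
    terminals <- g$nodes$id[f != 0]
    cover <- cover + all(terminals %in% net$nodes$id)
    n <- nrow(g$nodes)
    span <- span + (nrow(net$nodes) == n && nrow(net$edges) == n - 1)
    lyap <- max(lyap, max(diff(fit$cost_trajectory)) /
                  abs(fit$cost_trajectory[1]))
  }
  list(frac_acyclic = acyc / n_fixtures,
       frac_spanning_tree = span / n_fixtures,
       frac_terminals_covered = cover / n_fixtures,
       max_lyapunov_increase = lyap, n = n_fixtures)
}

#' Loop recovery on a ring scene
#'
#' Extracts a zero-noise ring scene with `n_runs = 5` and with `n_runs = 1`
#' and reports the independent-cycle counts (superposition of several
#' single-source trees should close the ring; a single run cannot).
#'
#' @param seed Integer seed.
#' @param size Canvas size in pixels.
#' @return List: `cycles_nruns5`, `cycles_nruns1`, `n` (pixel-graph nodes).
#' @export
bench_loop_recovery <- function(seed = 0, size = 64) {
  scene <- make_scene("ring", list(size = size), seed = seed)
  field <- rasterize(scene)
  net5 <- image2net(field, n_runs = 5, seed = seed)
  net1 <- image2net(field, n_runs = 1, seed = seed)
  list(cycles_nruns5 = cycle_count(net5),
       cycles_nruns1 = cycle_count(net1),
       n = nrow(attr(net5, "gpe")$nodes))
}

#' Topology recovery on planted trees
#'
#' Extracts seeded zero-noise random-tree scenes (single run per scene: for
#' a tree-like subject one source suffices) and reports mean leaf recall at
#' `tol_px` pixels and the total number of spurious cycles.
#'
#' @param n_scenes Number of scenes.
#' @param seed Integer seed.
#' @param size Canvas size in pixels.
#' @param n_leaves Planted leaf count per scene.
#' @param tol_px Leaf matching tolerance in pixels.
#' @return List: `mean_leaf_recall`, `min_leaf_recall`, `total_cycles`, `n`.
#' @export
bench_tree_recovery <- function(n_scenes = 10, seed = 0, size = 64,
                                n_leaves = 8, tol_px = 3) {
  recalls <- numeric(n_scenes)
  cycles <- 0L
  for (i in seq_len(n_scenes)) {
    scene <- make_scene("random_tree", list(size = size,
                                            n_leaves = n_leaves),
                        seed = derive_seed(seed, "scene", i))
    net <- image2net(rasterize(scene), n_runs = 1,
                     seed = derive_seed(seed, "extract", i))
    rep <- topology_match(net, scene, tol_px = tol_px)
    recalls[i] <- rep$leaf_recall
    cycles <- cycles + rep$cycles_extracted
  }
  list(mean_leaf_recall = mean(recalls), min_leaf_recall = min(recalls),
       total_cycles = cycles, n = n_scenes)
}

## Exact Steiner oracle for small graphs: the optimal Steiner tree is the
## cheapest MST over induced connected vertex subsets containing all
## terminals.
steiner_bruteforce_cost <- function(g, terminals) {
  ids <- g$nodes$id
  others <- setdiff(ids, terminals)
  best <- Inf
  for (mask in 0:(2^length(others) - 1)) {
    vs <- c(terminals, others[bitwAnd(mask, 2^(seq_along(others) - 1)) > 0])
    sel <- g$edges$from %in% vs & g$edges$to %in% vs
    if (sum(sel) < length(vs) - 1) next
    sub <- igraph::make_empty_graph(n = length(vs), directed = FALSE)
    sub <- igraph::add_edges(sub, rbind(match(g$edges$from[sel], vs),
                                        match(g$edges$to[sel], vs)))
    igraph::E(sub)$w <- g$edges$length[sel]
    if (igraph::components(sub)$no > 1) next
    mst <- igraph::mst(sub, weights = igraph::E(sub)$w)
    best <- min(best, sum(igraph::E(mst)$w))
  }
  best
}

#' Steiner approximation quality
#'
#' On seeded instances small enough for exhaustive search (<= `n_max`
#' nodes), compares [steiner_run] cost against the exact optimum obtained by
#' enumerating induced vertex subsets. Also reports whether [image2net] and
#' [image2net_mst] consumed identical pre-extracted graphs for a shared
#' scene.
#'
#' @param n_instances Number of instances.
#' @param seed Integer seed.
#' @param n_max Maximum node count per instance.
#' @return List: `max_ratio` (approx/optimal, <= 2 by the metric-closure
#'   bound), `gpe_identical` (1 or 0), `n`.
#' @export
bench_steiner <- function(n_instances = 10, seed = 0, n_max = 12) {
  ratio <- 1
  for (i in seq_len(n_instances)) {
    g <- random_blob_graph(
      with_seed(derive_seed(seed, "st_n", i), sample(8:n_max, 1)),
      h = 5, w = 5, seed = derive_seed(seed, "st_g", i))
    k <- with_seed(derive_seed(seed, "st_k", i), sample(2:4, 1))
    terminals <- with_seed(derive_seed(seed, "st_t", i),
                           sample(g$nodes$id, min(k, nrow(g$nodes))))
    net <- steiner_run(g, terminals)
    approx_cost <- sum(net$edges$length_px)
    opt <- steiner_bruteforce_cost(g, terminals)
    ratio <- max(ratio, approx_cost / opt)
  }
  scene <- make_scene("random_tree", list(size = 40, n_leaves = 4),
                      seed = seed)
  field <- rasterize(scene)
  g1 <- attr(image2net(field, n_runs = 1, seed = seed), "gpe")
  g2 <- attr(image2net_mst(field, n_runs = 1, seed = seed), "gpe")
  list(max_ratio = ratio,
       gpe_identical = as.integer(identical(g1, g2)),
       n = n_instances)
}

#' End-to-end CLI determinism
#'
#' Renders a scene to PNG, runs `img2net extract` twice with identical
#' configuration and seed, and reports whether the edge lists are
#' byte-identical.
#'
#' @param seed Integer seed.
#' @return List: `identical` (1 or 0), `n` (edge count of the output).
#' @export
bench_determinism <- function(seed = 0) {
  dir <- tempfile("det")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  img <- file.path(dir, "scene.png")
  scene <- make_scene("random_tree", list(size = 48, n_leaves = 5),
                      seed = seed)
  save_image(rasterize(scene), img)
  out1 <- file.path(dir, "a.tsv"); out2 <- file.path(dir, "b.tsv")
  code1 <- img2net_main(c("extract", img, "--seed", as.character(seed),
                          "--n-runs", "2", "--out", out1, "--quiet"))
  code2 <- img2net_main(c("extract", img, "--seed", as.character(seed),
                          "--n-runs", "2", "--out", out2, "--quiet"))
  same <- identical(readBin(out1, "raw", file.size(out1)),
                    readBin(out2, "raw", file.size(out2))) &&
    code1 == 0L && code2 == 0L
  list(identical = as.integer(same),
       n = nrow(read_network(out1)$edges))
}
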