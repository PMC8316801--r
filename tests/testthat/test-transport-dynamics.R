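test_that("Kirchhoff solve reproduces hand-solved circuits", {
  # single edge, unit conductance: unit potential drop
  g <- pixel_graph(data.frame(id = 1:2, x = c(0, 1), y = 0),
                   data.frame(from = 1, to = 2, length = 1, mu0 = 1))
  u <- solve_kirchhoff(1, g, c(1, -1))
  expect_equal(u[1] - u[2], 1)
  expect_equal(compute_flux(1, u, g), 1)

  # series path a-b-c: drops of 1 per edge (gauge-aligned to u_c = 0)
  g3 <- path_graph(3)
  u3 <- solve_kirchhoff(c(1, 1), g3, c(1, 0, -1))
  expect_equal(u3 - u3[3], c(2, 1, 0))
  expect_equal(compute_flux(c(1, 1), u3, g3), c(1, 1))

  # symmetric diamond: flux 1/2 on every edge
  gd <- pixel_graph(
    data.frame(id = 1:4, x = c(0, 1, 1, 2), y = c(0, 1, -1, 0)),
    data.frame(from = c(1, 1, 2, 3), to = c(2, 3, 4, 4), length = 1,
               mu0 = 1))
  ud <- solve_kirchhoff(rep(1, 4), gd, c(1, 0, 0, -1))
  expect_equal(abs(compute_flux(rep(1, 4), ud, gd)), rep(0.5, 4))
})

test_that("potentials match a dense pseudo-inverse oracle on random graphs", {
  res <- bench_kirchhoff(n_graphs = 30, seed = 7)
  expect_lte(res$max_potential_err, 1e-8)
  expect_lte(res$max_flux_residual, 1e-10)
})

test_that("Kirchhoff solve rejects bad forcings and names cut-off terminals", {
  g <- path_graph(3)
  expect_error(solve_kirchhoff(c(1, 1), g, c(1, 0, -0.5)),
               "not balanced", class = "img2net_validation")
  # mu support disconnects node 3 from the others
  err <- tryCatch(solve_kirchhoff(c(1, 0), g, c(1, 0, -1)),
                  error = function(e) e)
  expect_s3_class(err, "img2net_singular")
  expect_match(conditionMessage(err), "3")
})

test_that("flux, update and cost follow their closed forms", {
  g <- pixel_graph(data.frame(id = 1:2, x = c(0, 1), y = 0),
                   data.frame(from = 1, to = 2, length = 1, mu0 = 1))
  expect_equal(compute_flux(2, c(3, 0), g), 6)     # mu/l * drop
  expect_equal(compute_flux(0, c(3, 0), g), 0)
  gs <- pixel_graph(data.frame(id = 1:2, x = c(0, 1), y = c(0, 1)),
                    data.frame(from = 1, to = 2, length = sqrt(2), mu0 = 1))
  expect_equal(compute_flux(1, c(sqrt(2), 0), gs), 1)

  # fixed point of the update: with drop 1 and mu = 1, F = 1 = mu^(1/beta)
  for (beta in c(0.8, 1, 1.5))
    expect_equal(step_update(1, c(1, 0), g, beta, dt = 0.3), 1)
  # zero flux: geometric decay mu (1 - dt)
  expect_equal(step_update(0.8, c(0, 0), g, 1.5, dt = 0.25), 0.8 * 0.75)

  # cost: single edge mu=1, l=1, du=1, beta=1 -> 1/2 + 1/2
  expect_equal(transport_cost(1, c(1, 0), g, beta = 1), 1)
  expect_equal(transport_cost(0, c(1, 0), g, beta = 1), 0)
  # doubling lengths doubles the cost at fixed du/l
  gl <- pixel_graph(data.frame(id = 1:2, x = c(0, 1), y = 0),
                    data.frame(from = 1, to = 2, length = 2, mu0 = 1))
  expect_equal(transport_cost(1, c(2, 0), gl, beta = 1),
               2 * transport_cost(1, c(1, 0), g, beta = 1))
  expect_error(transport_cost(1, c(1, 0), g, beta = 2),
               class = "img2net_validation")
})

test_that("dynamics converge to the single-edge fixed point for any beta", {
  g <- pixel_graph(data.frame(id = 1:2, x = c(0, 1), y = 0),
                   data.frame(from = 1, to = 2, length = 1, mu0 = 0.3))
  for (beta in c(0.7, 1, 1.5, 1.9)) {
    fit <- run_dynamics(transport_problem(g, c(1, -1), beta = beta))
    expect_true(fit$converged)
    expect_equal(fit$mu, 1, tolerance = 1e-4)
  }
})

test_that("the dynamics select the shorter arm of an asymmetric diamond", {
  # paths 1-2-4 (length 2) and 1-3-4 (length 2 sqrt 2)
  gd <- pixel_graph(
    data.frame(id = 1:4, x = c(0, 1, 1, 2), y = c(0, 0.5, -0.5, 0)),
    data.frame(from = c(1, 1, 2, 3), to = c(2, 3, 4, 4),
               length = c(1, sqrt(2), 1, sqrt(2)),
               mu0 = c(0.8, 1.1, 0.9, 1.0)))
  fit <- run_dynamics(transport_problem(gd, c(1, 0, 0, -1), beta = 1.5))
  net <- filter_graph(gd, fit, expect_tree = TRUE)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(paste(net$edges$from, net$edges$to), c("1 2", "2 4"))
  # long-integration cross-check: surviving flux is the unit demand
  expect_equal(net$edges$weight, rep(1, 2), tolerance = 1e-3)
})

test_that("cost descends along trajectories and mu solves mu = |F|^beta", {
  res <- bench_fixed_point(n_problems = 6, seed = 3, n_px = 40)
  expect_lte(res$max_rel_dev, 1e-4)
  expect_lte(res$max_lyapunov_increase, 1e-8)
  expect_equal(res$frac_converged, 1)
})

test_that("filtering drops decayed edges, dangling nodes, and flags cycles", {
  g3 <- path_graph(3)
  f <- c(1, 0, -1)
  fit <- run_dynamics(transport_problem(g3, f, beta = 1.5))

  # all mu comparable: nothing dropped
  net <- filter_graph(g3, fit, eps_rel = 1e-6)
  expect_equal(nrow(net$edges), 2)

  # manual fit with a negligible second edge
  fit2 <- fit
  fit2$mu <- c(1, 1e-12)
  net2 <- filter_graph(g3, fit2, eps_rel = 1e-6)
  expect_equal(nrow(net2$edges), 1)
  expect_false(3 %in% net2$nodes$id)               # dangling node removed

  # cycle assertion: a fabricated cyclic mu under expect_tree errors
  gr <- ring_graph(6)
  fitr <- run_dynamics(transport_problem(gr, c(1, rep(-0.2, 5)), beta = 1.5))
  fitr$mu <- rep(1, 6)
  err <- tryCatch(filter_graph(gr, fitr, eps_rel = 1e-6, expect_tree = TRUE),
                  error = function(e) e)
  expect_s3_class(err, "img2net_singular")
  expect_match(conditionMessage(err), "cycle")
})

test_that("spanning-tree runs keep exactly n-1 edges on all n nodes", {
  g <- random_blob_graph(80, seed = 21)
  n <- nrow(g$nodes)
  f <- rep(-1 / (n - 1), n); f[5] <- 1
  fit <- run_dynamics(transport_problem(g, f, beta = 1.5))
  net <- filter_graph(g, fit, expect_tree = TRUE)
  expect_equal(nrow(net$nodes), n)
  expect_equal(nrow(net$edges), n - 1)
  expect_equal(cycle_count(net), 0)
})

test_that("transport problems validate forcing balance, beta and mu0", {
  g <- path_graph(2)
  expect_error(transport_problem(g, c(1, -0.9)),
               class = "img2net_validation")
  expect_error(transport_problem(g, c(1, -1), beta = 2),
               class = "img2net_validation")
  expect_error(transport_problem(g, c(1, -1), mu0 = 0),
               class = "img2net_validation")
  # Kirchhoff residual is available through residuals()
  fit <- run_dynamics(transport_problem(g, c(1, -1)))
  expect_lte(max(abs(residuals(fit))), 1e-10)
  expect_equal(coef(fit), fit$mu)
})
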