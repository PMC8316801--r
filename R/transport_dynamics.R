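## Adaptation (dynamic Monge-Kantorovich) dynamics on the pixel graph.
##
## Per edge e with conductivity mu_e, length l_e, and node potentials u:
##   flux        F_e   = mu_e / l_e * (u_from - u_to)
##   Kirchhoff   sum_e B_ie F_e = f_i                (solved for u)
##   adaptation  mu_e' = |F_e|^beta - mu_e           (explicit Euler)
## with mu(0) > 0. Stationary conductivities are the extracted edge weights.
## The trajectory descends the transport cost
##   L_beta = 1/2 sum mu (du/l)^2 l + beta/(2(2-beta)) sum mu^((2-beta)/beta) l
## (operational plus infrastructure cost); for beta >= 1 and single-source
## forcing the surviving support is a tree.

FREEZE_TOL <- 1e-12   # conductivities below this are frozen out of the solve

#' Define a transport problem
#'
#' Bundles the graph, balanced forcing, exponent beta and initial
#' conductivities for [run_dynamics].
#'
#' @param graph A [pixel_graph].
#' @param forcing Per-node mass rate (same order as `graph$nodes`); must sum
#'   to zero to within 1e-12 of its scale.
#' @param beta Exponent of the conductivity update, in (0, 2). The default
#'   1.5 consolidates the flow onto trees.
#' @param mu0 Optional positive initial conductivities; defaults to the
#'   graph's pixel-intensity-derived `mu0`.
#' @return Object of class `transport_problem`.
#' @export
transport_problem <- function(graph, forcing, beta = 1.5, mu0 = NULL) {
  stopifnot(inherits(graph, "pixel_graph"))
  n <- nrow(graph$nodes)
  if (length(forcing) != n)
    stop_validation("forcing must have one entry per node (%d), got %d",
                    n, length(forcing))
  scale <- max(abs(forcing), 1)
  if (abs(sum(forcing)) > 1e-12 * scale)
    stop_validation("forcing is not balanced: sum(f) = %.3e", sum(forcing))
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0 || beta >= 2)
    stop_validation("beta must lie in (0, 2), got %s", format(beta))
  mu0 <- mu0 %||% graph$edges$mu0
  if (length(mu0) != nrow(graph$edges) || any(mu0 <= 0))
    stop_validation("mu0 must be positive, one value per edge")
  structure(list(graph = graph, forcing = as.numeric(forcing),
                 beta = beta, mu0 = as.numeric(mu0)),
            class = "transport_problem")
}

## Grounded-Laplacian solve of Kirchhoff's law, per support component, with
## one step of iterative refinement. Gauge: u = 0 at the lowest-id node of
## each component.

#' Solve Kirchhoff's law for the node potentials
#'
#' Given conductivities `mu`, solves `B diag(mu/l) B^T u = f` on the support
#' of `mu` (edges with conductivity above the freeze tolerance), component by
#' component, grounding the lowest-id node of each component at u = 0.
#'
#' @param mu Per-edge conductivities (>= 0).
#' @param graph A [pixel_graph].
#' @param f Balanced per-node forcing.
#' @param tol_residual Required flux-conservation residual, relative to
#'   `max(abs(f))`.
#' @return Numeric vector of node potentials.
#' @export
solve_kirchhoff <- function(mu, graph, f, tol_residual = 1e-10) {
  stopifnot(inherits(graph, "pixel_graph"))
  n <- nrow(graph$nodes)
  if (length(f) != n) stop_validation("forcing length mismatch")
  fscale <- max(abs(f))
  if (abs(sum(f)) > 1e-12 * max(fscale, 1))
    stop_validation("forcing is not balanced: sum(f) = %.3e", sum(f))
  if (any(mu < 0)) stop_validation("conductivities must be >= 0")
  active <- which(mu > FREEZE_TOL)
  ei <- graph$edges$from_idx[active]
  ej <- graph$edges$to_idx[active]
  w <- mu[active] / graph$edges$length[active]

  ig <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(active)) ig <- igraph::add_edges(ig, rbind(ei, ej))
  memb <- igraph::components(ig)$membership

  ## every component must have internally balanced forcing
  csum <- tapply(f, memb, sum)
  bad <- names(csum)[abs(csum) > 1e-9 * max(fscale, 1)]
  if (length(bad)) {
    term <- graph$nodes$id[f != 0 & memb %in% as.integer(bad)]
    stop_singular(
      "terminals disconnected on the support of mu: nodes {%s} cannot exchange mass",
      paste(term, collapse = ", "))
  }

  u <- numeric(n)
  if (length(active) == 0 || fscale == 0) return(u)
  L <- Matrix::sparseMatrix(
    i = c(ei, ej, ei, ej), j = c(ei, ej, ej, ei),
    x = c(w, w, -w, -w), dims = c(n, n))
  for (cm in unique(memb)) {
    idx <- which(memb == cm)
    if (length(idx) < 2) next
    sub <- idx[-1]                      # idx sorted: idx[1] is lowest id
    Ls <- L[sub, sub, drop = FALSE]
    b <- f[sub]
    us <- tryCatch(as.numeric(Matrix::solve(Ls, b)),
                   error = function(e) stop_singular(
                     "Kirchhoff system singular on component with node %d: %s",
                     graph$nodes$id[idx[1]], conditionMessage(e)))
    for (k in 1:3) {                    # iterative refinement
      r <- b - as.numeric(Ls %*% us)
      if (max(abs(r)) <= tol_residual * fscale) break
      us <- us + as.numeric(Matrix::solve(Ls, r))
    }
    u[sub] <- us
  }
  u
}

#' Per-edge flux
#'
#' `F_e = mu_e / l_e * (u_from - u_to)` along the incidence orientation
#' (lower id -> higher id).
#'
#' @param mu Per-edge conductivities.
#' @param u Per-node potentials.
#' @param graph A [pixel_graph].
#' @return Numeric vector of signed fluxes.
#' @export
compute_flux <- function(mu, u, graph) {
  mu / graph$edges$length *
    (u[graph$edges$from_idx] - u[graph$edges$to_idx])
}

#' One explicit Euler step of the adaptation dynamics
#'
#' `mu <- mu + dt * (|F|^beta - mu)`, floored at zero. A stationary point
#' satisfies `mu_e = |F_e|^beta`; edges with zero flux decay geometrically.
#'
#' @param mu,u,graph Current state as in [compute_flux].
#' @param beta Exponent in (0, 2).
#' @param dt Positive step size.
#' @return Updated conductivities.
#' @export
step_update <- function(mu, u, graph, beta, dt) {
  if (dt <= 0) stop_validation("dt must be > 0")
  f <- abs(compute_flux(mu, u, graph))
  pmax(mu + dt * (f^beta - mu), 0)
}

#' Transport cost functional
#'
#' Operational cost plus infrastructure cost:
#' `L_beta = 1/2 sum_e mu_e (du_e/l_e)^2 l_e +
#'   beta/(2(2-beta)) sum_e mu_e^((2-beta)/beta) l_e`.
#'
#' @inheritParams compute_flux
#' @param beta Exponent in (0, 2); the functional is undefined at beta = 2.
#' @return Scalar cost.
#' @export
transport_cost <- function(mu, u, graph, beta) {
  if (!is.numeric(beta) || length(beta) != 1 || beta >= 2 || beta <= 0)
    stop_validation("transport cost requires beta in (0, 2), got %s",
                    format(beta))
  du <- u[graph$edges$from_idx] - u[graph$edges$to_idx]
  l <- graph$edges$length
  0.5 * sum(mu * (du / l)^2 * l) +
    beta / (2 * (2 - beta)) * sum(mu^((2 - beta) / beta) * l)
}

#' Run the adaptation dynamics to stationarity
#'
#' Iterates Kirchhoff solve -> flux -> conductivity update until the
#' dynamics' right-hand side is small: `max|dmu| / (dt * max(mu)) < tol`.
#' The step size adapts: a step that would increase the transport cost
#' beyond a tiny tolerance is retried with dt halved (the cost is a Lyapunov
#' function of the continuous dynamics), and dt relaxes back towards its
#' initial value after accepted steps.
#'
#' @param problem A [transport_problem].
#' @param dt Initial Euler step size.
#' @param tol Stationarity tolerance on the relative right-hand side.
#' @param max_iter Iteration cap; non-convergence yields a warning, not an
#'   error.
#' @return Object of class `transport_fit` with elements `mu`, `u`, `flux`,
#'   `cost_trajectory`, `converged`, `iterations`, `beta` and `problem`.
#'   Methods: `coef` (stationary conductivities), `fitted` (fluxes),
#'   `residuals` (Kirchhoff residual `B F - f`), `plot` (cost trajectory).
#' @export
run_dynamics <- function(problem, dt = 0.5, tol = 1e-6, max_iter = 3000) {
  stopifnot(inherits(problem, "transport_problem"))
  if (dt <= 0) stop_validation("dt must be > 0")
  g <- problem$graph
  f <- problem$forcing
  beta <- problem$beta
  mu <- problem$mu0
  dt0 <- dt

  u <- solve_kirchhoff(mu, g, f)
  cost <- transport_cost(mu, u, g, beta)
  traj <- cost
  lyap_tol <- 1e-10 * max(abs(cost), .Machine$double.xmin)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    fl <- abs(compute_flux(mu, u, g))^beta
    halvings <- 0L
    repeat {
      mu_new <- pmax(mu + dt * (fl - mu), 0)
      mu_new[mu_new < FREEZE_TOL] <- 0
      u_new <- solve_kirchhoff(mu_new, g, f)
      cost_new <- transport_cost(mu_new, u_new, g, beta)
      if (cost_new <= cost + lyap_tol || halvings >= 40L) break
      dt <- dt / 2
      halvings <- halvings + 1L
    }
    rhs_rel <- max(abs(mu_new - mu)) / (dt * max(mu_new, FREEZE_TOL))
    mu <- mu_new; u <- u_new; cost <- cost_new
    traj <- c(traj, cost)
    dt <- min(dt * 1.1, dt0)
    if (rhs_rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf(
      "dynamics did not reach tol=%.1e within %d iterations", tol, max_iter))
  structure(list(mu = mu, u = u, flux = compute_flux(mu, u, g),
                 cost_trajectory = traj, converged = converged,
                 iterations = iter, beta = beta, dt_final = dt,
                 problem = problem),
            class = "transport_fit")
}

#' @export
print.transport_fit <- function(x, ...) {
  cat(sprintf(
    "transport_fit: beta=%.3g, %d iterations (%s), cost %.6g -> %.6g\n",
    x$beta, x$iterations,
    if (x$converged) "converged" else "NOT converged",
    x$cost_trajectory[1], utils::tail(x$cost_trajectory, 1)))
  cat(sprintf("  %d/%d edges above 1e-6 * max(mu)\n",
              sum(x$mu > 1e-6 * max(x$mu)), length(x$mu)))
  invisible(x)
}

#' @export
coef.transport_fit <- function(object, ...) object$mu

#' @export
fitted.transport_fit <- function(object, ...) object$flux

#' @export
residuals.transport_fit <- function(object, ...) {
  g <- object$problem$graph
  as.numeric(incidence_matrix(g) %*% object$flux) - object$problem$forcing
}

#' @export
plot.transport_fit <- function(x, ...) {
  graphics::plot(seq_along(x$cost_trajectory) - 1, x$cost_trajectory,
                 type = "l", xlab = "iteration",
                 ylab = expression(L[beta]), log = "y", ...)
  invisible(x)
}

#' Filter the stationary network
#'
#' Keeps the edges whose stationary conductivity exceeds a threshold and
#' drops isolated nodes. With `eps_rel` given, the threshold is
#' `eps_rel * max(mu)`. By default (`eps_rel = NULL`) the threshold is
#' flux-aware: `(f_min/2)^beta`, where `f_min` is the smallest terminal
#' demand of the run's forcing — every edge of a single-source stationary
#' tree carries at least the smallest sink demand, so this separates
#' surviving from decaying edges independently of network size.
#'
#' @param graph The [pixel_graph] the fit was computed on.
#' @param fit A `transport_fit` from [run_dynamics].
#' @param eps_rel Optional relative threshold in \[0, 1).
#' @param expect_tree If `TRUE` (appropriate for beta >= 1 with
#'   single-source forcing), error with a diagnostic listing a cycle if the
#'   filtered support contains one.
#' @return An [extracted_network] whose edge weights are the stationary
#'   conductivities.
#' @export
filter_graph <- function(graph, fit, eps_rel = NULL, expect_tree = FALSE) {
  stopifnot(inherits(graph, "pixel_graph"), inherits(fit, "transport_fit"))
  mu <- fit$mu
  if (length(mu) != nrow(graph$edges))
    stop_validation("fit does not match graph: %d mu for %d edges",
                    length(mu), nrow(graph$edges))
  thr <- if (!is.null(eps_rel) && !is.na(eps_rel)) {
    if (eps_rel < 0 || eps_rel >= 1)
      stop_validation("eps_rel must lie in [0, 1)")
    eps_rel * max(mu)
  } else {
    f <- fit$problem$forcing
    if (any(f != 0)) (min(abs(f[f != 0])) / 2)^fit$beta
    else 1e-6 * max(mu)
  }
  keep <- which(mu > thr)
  net <- network_from_pixel_edges(graph, keep, weights = mu[keep])
  if (expect_tree) {
    cyc <- cycle_count(net)
    if (cyc > 0) {
      ig <- as_igraph(net)
      girth <- igraph::girth(ig, circle = TRUE)
      cyc_nodes <- net$nodes$id[as.integer(girth$circle)]
      stop_singular(
        "filtered support is not a tree (%d independent cycles); e.g. cycle through nodes {%s}",
        cyc, paste(cyc_nodes, collapse = ", "))
    }
  }
  net
}
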