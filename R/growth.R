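#' Deterministic orientation-noise field
#'
#' The orientation field theta is i.i.d.-uniform-like noise on [0,1],
#' generated by a deterministic hash of the global physical coordinates
#' and the seed. Keying on position (rather than a sequential RNG
#' stream) makes the field reproducible, independent of evaluation
#' order, and consistent across domain extensions: a collocation point
#' keeps its theta value when the domain grows.
#'
#' @param gx,gy vectors of global physical coordinates (recycled
#'   outer-product style via `outer` by callers).
#' @param seed integer seed.
#' @return numeric values in [0, 1).
#' @keywords internal
theta_noise <- function(gx, gy, seed) {
  v <- (gx * 73856.093 + gy * 19349.663 + (seed + 1) * 83492.791) %% 131071
  x <- sin(v * 0.12171 + 0.5) * 43758.5453
  x - floor(x)
}

.theta_field <- function(grid, seed) {
  outer(grid$gu + grid$origin[1], grid$gv + grid$origin[2],
        theta_noise, seed = seed)
}

#' Initialize the simulation state
#'
#' Sets up circular somas of radius `r0` (diffuse tanh interface), the
#' static orientation noise field, the initial tubulin profile
#' \eqn{c_{tub} = (1 + \tanh((r_0 - r)/2))/2} with `r` the distance to the
#' nearest soma center, the temperature field, and the frozen initial
#' phase field `phi0` with its normalized tubulin production source.
#'
#' @param params a [neuron_params()] object.
#' @param centers matrix (k x 2) of soma centers in physical coordinates.
#' @param grid a `collocation_grid`.
#' @return An object of class `neuron_state`.
#' @export
initialize_state <- function(params, centers, grid) {
  centers <- matrix(as.numeric(centers), ncol = 2)
  if (nrow(centers) < 1) stop("configuration error: need at least one center")
  r0 <- params$r0
  # non-overlap and domain-fit checks
  if (nrow(centers) > 1) {
    dd <- as.matrix(stats::dist(centers))
    diag(dd) <- Inf
    if (min(dd) < 2 * r0) {
      stop("configuration error: initial circles overlap ",
           "(min center distance ", round(min(dd), 2), " < 2*r0)")
    }
  }
  dom_x <- grid$ku$domain + grid$origin[1]
  dom_y <- grid$kv$domain + grid$origin[2]
  if (any(centers[, 1] - r0 < dom_x[1] | centers[, 1] + r0 > dom_x[2] |
          centers[, 2] - r0 < dom_y[1] | centers[, 2] + r0 > dom_y[2])) {
    stop("configuration error: initial circle does not fit inside the domain")
  }

  xy <- .grid_xy(grid)
  k <- nrow(centers)
  dists <- vapply(seq_len(k), function(i) {
    sqrt((xy$x - centers[i, 1])^2 + (xy$y - centers[i, 2])^2)
  }, numeric(length(xy$x)))
  dmin <- if (k == 1) dists[, 1] else apply(dists, 1, min)
  nearest <- if (k == 1) rep(1L, length(dmin)) else apply(dists, 1, which.min)

  phi <- matrix(0.5 * (1 + tanh((r0 - dmin) / 2)), grid$nu, grid$nv)
  c_tub <- matrix(0.5 * (1 + tanh((r0 - dmin) / 2)), grid$nu, grid$nv)
  theta <- .theta_field(grid, params$rng_seed)
  gtx <- grid_derivative(grid, theta, "x")
  gty <- grid_derivative(grid, theta, "y")
  temp <- matrix(params$T_init, grid$nu, grid$nv)
  neuron_labels <- matrix(ifelse(phi > params$phi_threshold, nearest, 0L),
                          grid$nu, grid$nv)

  st <- structure(list(
    phi = phi, phi0 = phi, theta = theta,
    grad_theta_mag = sqrt(gtx^2 + gty^2),
    c_tub = c_tub, temp = temp,
    E_field = matrix(0, grid$nu, grid$nv),
    src = NULL,  # filled below
    centers = centers, neuron_labels = neuron_labels,
    iteration = 0L, stage = 1L
  ), class = "neuron_state")
  st$src <- tubulin_source(st, grid, params)
  st
}

#' @export
print.neuron_state <- function(x, ...) {
  cat("Neuron growth state: iteration", x$iteration, "| stage", x$stage,
      "|", nrow(x$centers), "neuron(s) | field",
      nrow(x$phi), "x", ncol(x$phi), "\n")
  cat("  phi in [", round(min(x$phi), 3), ",", round(max(x$phi), 3),
      "] | c_tub in [", round(min(x$c_tub), 3), ",",
      round(max(x$c_tub), 3), "]\n")
  invisible(x)
}

# Normalized tubulin production source from the frozen initial interface:
# eps0 * |grad phi0|^2 / integral(|grad phi0|^2). Its discrete integral
# (sum * dx^2) equals eps0 exactly by construction.
tubulin_source <- function(state, grid, params) {
  g0x <- grid_derivative(grid, state$phi0, "x")
  g0y <- grid_derivative(grid, state$phi0, "y")
  g2 <- g0x^2 + g0y^2
  tot <- sum(g2) * grid$spacing^2
  if (tot < 1e-12) {
    stop("initialization error: initial phase field has no interface ",
         "(|grad phi0|^2 integrates to zero)")
  }
  params$eps0 * g2 / tot
}

#' Interface normal orientation
#'
#' Angle \eqn{\Psi} of the interface normal from the phase-field gradient,
#' with the convention \eqn{\Psi = 0} where the gradient is degenerate
#' (the anisotropy factors multiply the gradient there, so the convention
#' is inert).
#'
#' @param phi_grad_x,phi_grad_y gradient component fields.
#' @param tol degeneracy tolerance on `|grad phi|` (default 1e-10).
#' @return Field of angles in radians.
#' @export
interface_orientation <- function(phi_grad_x, phi_grad_y, tol = 1e-10) {
  psi <- atan2(phi_grad_y, phi_grad_x)
  psi[sqrt(phi_grad_x^2 + phi_grad_y^2) < tol] <- 0
  psi
}

#' Anisotropic gradient coefficient
#'
#' The j-fold anisotropy of the dendritic-solidification family:
#' \eqn{a(\Psi) = \bar a (1 + \delta \cos(j (\Psi - \theta_0)))} and its
#' analytic derivative with respect to \eqn{\Psi}.
#'
#' @param psi field of interface orientations (radians).
#' @param params a [neuron_params()] object.
#' @return list with fields `a` and `dadpsi`.
#' @export
anisotropy_coefficient <- function(psi, params) {
  if (abs(params$delta_aniso) >= 1) {
    stop("parameter error: |delta_aniso| must be < 1")
  }
  arg <- params$j_fold * (psi - params$theta_offset)
  list(a = params$a_bar * (1 + params$delta_aniso * cos(arg)),
       dadpsi = -params$a_bar * params$delta_aniso * params$j_fold * sin(arg))
}

#' Neurite extension rate
#'
#' \eqn{dL/dt = r_g c_{tub} - s_g}: tubulin assembly at the tip minus
#' disassembly.
#'
#' @param c_tub_at_tip tubulin concentration at the tip.
#' @param r assembly rate constant.
#' @param s disassembly rate constant.
#' @return extension rate (same shape as `c_tub_at_tip`).
#' @export
neurite_extension_rate <- function(c_tub_at_tip, r, s) {
  r * c_tub_at_tip - s
}

# smoothed Heaviside gate
heaviside_smooth <- function(x, eps) 0.5 * (1 + tanh(x / eps))

# driving force formula at given extension rate and undercooling
.driving_force <- function(dldt, dT, params) {
  e <- (params$alpha_E / pi) *
    atan(heaviside_smooth(dldt, params$heaviside_eps) * params$gamma * dT)
  e[dldt < 0] <- 0  # assembly below disassembly: growth inhibited exactly
  e
}

#' Growth-cone driving force in energy activation zones
#'
#' Evaluates \eqn{E = (\alpha/\pi) \arctan(H_\epsilon(dL/dt) \gamma
#' \Delta T)} inside the square activation zones centered at (or shifted
#' toward the cue of) each detected tip, and exactly 0 elsewhere. The
#' extension rate uses the tip-local tubulin concentration and the tip's
#' neurite rates; a tip whose assembly cannot balance disassembly
#' (`r * c_tub < s`) contributes `E = 0` over its whole zone. Overlapping
#' zones combine by pointwise maximum.
#'
#' @param state a `neuron_state`.
#' @param tips a tip table as returned by [detect_tips()] (columns `ix`,
#'   `iy`, optionally `zone_ci`, `zone_cj`, `r`, `s`); may have zero rows.
#' @param params a [neuron_params()] object.
#' @return The `E` field (matrix like `state$phi`).
#' @export
compute_driving_force <- function(state, tips, params) {
  nu <- nrow(state$phi); nv <- ncol(state$phi)
  E <- matrix(0, nu, nv)
  if (is.null(tips) || nrow(tips) == 0) return(E)
  z <- params$activation_zone_size
  dT <- params$T_eq - state$temp
  for (t in seq_len(nrow(tips))) {
    ci <- if (!is.null(tips$zone_ci)) tips$zone_ci[t] else tips$ix[t]
    cj <- if (!is.null(tips$zone_cj)) tips$zone_cj[t] else tips$iy[t]
    r <- if (!is.null(tips$r)) tips$r[t] else params$r_g
    s <- if (!is.null(tips$s)) tips$s[t] else params$s_g
    ctip <- state$c_tub[tips$ix[t], tips$iy[t]]
    dldt <- neurite_extension_rate(ctip, r, s)
    idx <- zone_indices(ci, cj, z, nu, nv)
    if (dldt < 0) next  # zone stays exactly 0
    Ez <- .driving_force(dldt, dT[idx$i, idx$j, drop = FALSE], params)
    E[idx$i, idx$j] <- pmax(E[idx$i, idx$j, drop = FALSE], Ez)
  }
  E
}

# Whole-interface driving force used during lamellipodia formation
# (stage 1), before any neurite tip exists: the same E formula with the
# global rates and the local tubulin concentration at every point.
compute_driving_force_global <- function(state, params) {
  dldt <- neurite_extension_rate(state$c_tub, params$r_g, params$s_g)
  .driving_force(dldt, params$T_eq - state$temp, params)
}

#' Phase-field right-hand side
#'
#' The collocated strong-form right-hand side of the phase evolution:
#' \deqn{M_\phi [ \nabla\cdot(a^2 \nabla\phi)
#'   - \partial_x(a\, a_\Psi\, \partial_y\phi)
#'   + \partial_y(a\, a_\Psi\, \partial_x\phi)
#'   + \phi(1-\phi)(\phi - 0.5 + E + 6 H |\nabla\theta|) ]}
#' with every derivative taken through the spline collocation operators.
#' With `params$reaction_on = FALSE` only the anisotropic diffusion terms
#' remain (a linear verification configuration).
#'
#' @param state a `neuron_state` (with current `E_field`).
#' @param grid a `collocation_grid`.
#' @param params a [neuron_params()] object.
#' @return Field of time derivatives at the collocation lattice.
#' @export
phase_field_rhs <- function(state, grid, params) {
  phi <- state$phi
  px <- grid_derivative(grid, phi, "x")
  py <- grid_derivative(grid, phi, "y")
  psi <- interface_orientation(px, py)
  an <- anisotropy_coefficient(psi, params)
  a2 <- an$a^2
  b <- an$a * an$dadpsi
  div_term <- grid_derivative(grid, a2 * px, "x") +
              grid_derivative(grid, a2 * py, "y")
  rot_term <- -grid_derivative(grid, b * py, "x") +
               grid_derivative(grid, b * px, "y")
  out <- div_term + rot_term
  if (params$reaction_on) {
    m <- phi - 0.5 + state$E_field + 6 * params$H_const * state$grad_theta_mag
    out <- out + phi * (1 - phi) * m
  }
  out <- params$M_phi * out
  if (!all(is.finite(out))) {
    stop("numerical blowup in phase_field_rhs at iteration ",
         state$iteration)
  }
  out
}

#' Tubulin balance right-hand side
#'
#' The time derivative of the conserved quantity \eqn{\phi c_{tub}}:
#' diffusion \eqn{\delta_t \nabla\cdot(\phi \nabla c)}, active transport
#' \eqn{-\alpha_t \cdot \nabla(\phi c)}, first-order decay
#' \eqn{-\beta_t \phi c}, and the normalized production source on the
#' frozen initial interface (whose discrete integral is exactly
#' \eqn{\epsilon_0}).
#'
#' @inheritParams phase_field_rhs
#' @return Field of \eqn{\partial(\phi c_{tub})/\partial t} values.
#' @export
tubulin_rhs <- function(state, grid, params) {
  tt <- tubulin_transport_terms(state, grid, params)
  tt$diffusion + tt$advection + tt$decay + state$src
}

# The individual tubulin terms (shared by tubulin_rhs and the integrator).
tubulin_transport_terms <- function(state, grid, params) {
  phi <- state$phi; ct <- state$c_tub
  w <- phi * ct
  cx <- grid_derivative(grid, ct, "x")
  cy <- grid_derivative(grid, ct, "y")
  diffusion <- params$delta_t *
    (grid_derivative(grid, phi * cx, "x") +
     grid_derivative(grid, phi * cy, "y"))
  al <- .alpha_field(state, grid, params)
  wx <- grid_derivative(grid, w, "x")
  wy <- grid_derivative(grid, w, "y")
  advection <- -(al$ax * wx + al$ay * wy)
  decay <- -params$beta_t * w
  list(diffusion = diffusion, advection = advection, decay = decay)
}

# active-transport velocity field: constant 2-vector, or radially outward
# from the nearest soma center with constant speed
.alpha_field <- function(state, grid, params) {
  nu <- nrow(state$phi); nv <- ncol(state$phi)
  if (params$alpha_t_mode == "constant") {
    return(list(ax = matrix(params$alpha_t[1], nu, nv),
                ay = matrix(params$alpha_t[2], nu, nv)))
  }
  xy <- .grid_xy(grid)
  k <- nrow(state$centers)
  dists <- vapply(seq_len(k), function(i) {
    sqrt((xy$x - state$centers[i, 1])^2 + (xy$y - state$centers[i, 2])^2)
  }, numeric(length(xy$x)))
  nearest <- if (k == 1) rep(1L, length(xy$x)) else apply(dists, 1, which.min)
  dx <- xy$x - state$centers[nearest, 1]
  dy <- xy$y - state$centers[nearest, 2]
  rr <- pmax(sqrt(dx^2 + dy^2), 1e-9)
  speed <- params$alpha_t[1]
  list(ax = matrix(speed * dx / rr, nu, nv),
       ay = matrix(speed * dy / rr, nu, nv))
}

#' Advance the undercooling temperature one step
#'
#' Implicit Euler step of the dendritic-solidification heat equation with
#' latent-heat release, \eqn{\partial T/\partial t = D_T \nabla^2 T +
#' K \partial\phi/\partial t}, with zero-flux boundaries. The undercooling
#' entering the driving force is \eqn{\Delta T = T_{eq} - T}.
#'
#' @param state a `neuron_state`.
#' @param grid a `collocation_grid`.
#' @param params a [neuron_params()] object.
#' @param dphidt field of phase time derivatives for the latent-heat term.
#' @param settings a [solver_settings()] object.
#' @return The state with `temp` advanced.
#' @export
evolve_undercooling <- function(state, grid, params, dphidt,
                                settings = solver_settings()) {
  dt <- params$dt
  dT <- if (is.null(params$T_diff)) 1 else params$T_diff
  rhs <- state$temp + dt * params$K_latent * dphidt
  amul <- function(W) {
    R <- W - dt * dT * grid_derivative(grid, W, "lap")
    .apply_bc_rows(R, W, grid, "neumann")
  }
  b <- .apply_bc_rows(rhs, NULL, grid, "neumann", zero = TRUE)
  prec <- .adi_preconditioner(grid, dt * dT, "neumann")
  state$temp <- .solve_krylov(amul, b, prec, x0 = state$temp,
                              tol = settings$linear_tol,
                              maxit = settings$linear_max_iters)
  state
}
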