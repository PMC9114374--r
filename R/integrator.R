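# Implicit Euler time stepping of the coupled phase-field / tubulin /
# undercooling system, with chord-Newton on the collocated strong form.

# regularization added to phi where the tubulin balance degenerates, and
# the phase cutoff below which tubulin is pinned to zero (the balance is
# written for phi * c_tub; outside the cell both the fluxes and the
# concentration vanish, and dividing spline-interpolation ringing by a
# near-zero phi there would destabilize the explicit transport terms)
.C_REG <- 1e-3
.C_CUT <- 0.005

#' One implicit Euler step of the coupled system
#'
#' Advances the phase field by implicit Euler, solving the collocated
#' nonlinear system \eqn{R(\phi^{n+1}) = \phi^{n+1} - \phi^n - \Delta t\,
#' rhs(\phi^{n+1}) = 0} with Newton-Raphson to residual infinity-norm
#' below `settings$newton_tol` (anisotropy coefficients lagged within each
#' linearization, reaction terms differentiated analytically); then
#' advances the tubulin balance (implicit in the local decay/time terms,
#' explicit in the transport terms, which are far below their stability
#' limit at the default coefficients); then the undercooling temperature.
#'
#' `state$E_field` is used as-is and should be current (see
#' [compute_driving_force()]).
#'
#' @param state a `neuron_state`.
#' @param grid a `collocation_grid`.
#' @param params a [neuron_params()] object.
#' @param settings a [solver_settings()] object.
#' @return The advanced `neuron_state`; element `last_newton` holds
#'   `list(iterations, residual)` of the accepted step.
#' @export
implicit_euler_step <- function(state, grid, params,
                                settings = solver_settings()) {
  phi_old <- state$phi
  state <- .step_phase(state, grid, params, settings)
  state <- .step_tubulin(state, grid, params, phi_old)
  dphidt <- (state$phi - phi_old) / params$dt
  state <- evolve_undercooling(state, grid, params, dphidt, settings)
  state$iteration <- state$iteration + 1L
  state
}

.step_phase <- function(state, grid, params, settings) {
  dt <- params$dt; M <- params$M_phi
  phi_old <- state$phi
  V <- phi_old
  noise_m <- if (params$reaction_on) {
    state$E_field + 6 * params$H_const * state$grad_theta_mag
  } else NULL
  iterate_lag <- identical(settings$anisotropy_lag, "iterate")

  # anisotropy coefficient fields a^2 and a * da/dPsi; with the default
  # "step" lagging they are frozen at the previous time level, which keeps
  # the residual a smooth function of phi and lets the analytic-reaction
  # Newton converge quadratically (iterate lagging re-evaluates them at
  # each Newton iterate).
  aniso_at <- function(P) {
    px <- grid_derivative(grid, P, "x")
    py <- grid_derivative(grid, P, "y")
    psi <- interface_orientation(px, py)
    an <- anisotropy_coefficient(psi, params)
    list(a2 = an$a^2, bb = an$a * an$dadpsi)
  }
  cf <- aniso_at(phi_old)

  spatial <- function(W, cf) {
    Wx <- grid$Gu %*% W
    Wy <- W %*% t(grid$Gv)
    grid$Gu %*% (cf$a2 * Wx) + (cf$a2 * Wy) %*% t(grid$Gv) -
      grid$Gu %*% (cf$bb * Wy) + (cf$bb * Wx) %*% t(grid$Gv)
  }
  residual <- function(V, cf) {
    R <- V - phi_old - dt * M * spatial(V, cf)
    if (params$reaction_on) {
      R <- R - dt * M * (V * (1 - V) * (V - 0.5 + noise_m))
    }
    if (!all(is.finite(R))) {
      stop("numerical blowup in the phase step at iteration ",
           state$iteration + 1L)
    }
    .apply_bc_rows(R, V, grid, "neumann")
  }

  prec <- .adi_preconditioner(grid, dt * M * params$a_bar^2, "neumann")
  R <- residual(V, cf)
  rn <- max(abs(R))
  iters <- 0L
  while (rn >= settings$newton_tol) {
    if (iters >= settings$newton_max_iters) {
      stop("Newton failed to converge at iteration ", state$iteration + 1L,
           ": residual inf-norm ", format(rn), " after ", iters,
           " iterations (tol ", settings$newton_tol, ")")
    }
    if (iterate_lag && iters > 0L) cf <- aniso_at(V)
    rp <- if (params$reaction_on) {
      (1 - 2 * V) * (V - 0.5 + noise_m) + V * (1 - V)
    } else 0
    jmul <- function(W) {
      JW <- W - dt * M * (spatial(W, cf) + rp * W)
      .apply_bc_rows(JW, W, grid, "neumann")
    }
    d <- .solve_krylov(jmul, -R, prec, tol = 1e-2,
                       atol = 0.2 * settings$newton_tol,
                       maxit = settings$linear_max_iters)
    V <- V + d
    R <- residual(V, cf)
    rn <- max(abs(R))
    iters <- iters + 1L
  }
  state$phi <- V
  state$last_newton <- list(iterations = iters, residual = rn)
  state
}

# Semi-implicit tubulin step. The conserved bookkeeping variable is
# w = max(phi, eps) * c_tub: the max-regularization keeps the division
# well defined in the extracellular region while leaving the discrete
# balance exact wherever phi >= eps. Decay and the time term are
# implicit; diffusion, advection and the production source are explicit.
# Concentrations are floored at 0 and pinned to 0 below the phase
# cutoff (spline-interpolation ringing divided by a near-zero phi would
# otherwise destabilize the explicit transport terms).
.step_tubulin <- function(state, grid, params, phi_old) {
  dt <- params$dt
  w_old <- pmax(phi_old, .C_REG) * state$c_tub
  tt <- tubulin_transport_terms(state, grid, params)  # uses new phi, old c
  w_new <- (w_old + dt * (tt$diffusion + tt$advection + state$src)) /
           (1 + dt * params$beta_t)
  c_new <- pmax(w_new / pmax(state$phi, .C_REG), 0)
  c_new[state$phi < .C_CUT] <- 0
  state$c_tub <- c_new
  state
}
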