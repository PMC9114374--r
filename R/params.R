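#' Model parameters for the neuron-growth phase-field system
#'
#' All coefficients of the phase-field equation, the tubulin balance, the
#' driving-force formula and the stage schedule, with documented defaults.
#' Lengths are in lattice units (knot spacing 1), time in simulation units
#' (time step `dt`), concentrations normalized to the initial intracellular
#' level.
#'
#' The structural constants stated by the model are fixed here: time step
#' `dt = 0.01`, initial soma radius `r0 = 20`, cubic splines, 6 x 6 energy
#' activation zones, and the four-stage iteration schedule
#' 500 / 10,500 / 28,500 / 35,000 at full scale. The remaining coefficients
#' have no direct physical counterpart and are calibrated empirically to
#' reproduce the qualitative staging (see the methods vignette); every one
#' of them can be overridden.
#'
#' @param ... named overrides of any default listed below.
#' @return An object of class `neuron_params` (a validated list).
#'
#' @section Parameters:
#' \describe{
#'   \item{M_phi}{phase-field mobility (default 25).}
#'   \item{a_bar, delta_aniso, j_fold, theta_offset}{anisotropic gradient
#'     coefficient \eqn{a(\Psi) = \bar a (1 + \delta \cos(j(\Psi -
#'     \theta_0)))}; defaults 0.55, 0.15, 6, 0 (equilibrium interface
#'     width ~2.8*a_bar/sqrt(2) lattice cells). Requires `|delta_aniso| < 1`.}
#'   \item{H_const}{orientation-penalty constant multiplying
#'     \eqn{6 |\nabla\theta|} in the reaction term (default 0.004; the
#'     noise term must stay below 0.5 everywhere or it would nucleate
#'     spurious cells in the extracellular medium).}
#'   \item{alpha_E, gamma}{driving-force scale and interfacial energy
#'     constant in \eqn{E = (\alpha/\pi)\arctan(H_\epsilon(dL/dt)\,\gamma\,
#'     \Delta T)}; defaults 0.9 and 10.}
#'   \item{heaviside_eps}{smoothing width of the regularized Heaviside
#'     \eqn{H_\epsilon(x) = (1 + \tanh(x/\epsilon))/2} (default 0.1).}
#'   \item{delta_t, alpha_t, alpha_t_mode, beta_t, eps0}{tubulin diffusion
#'     coefficient (2), active-transport speed (2), transport mode
#'     (`"radial"` outward from the soma, or `"constant"` 2-vector), decay
#'     (0.01) and production coefficient \eqn{\epsilon_0} (12).}
#'   \item{r_g, s_g, r_g_tip}{tubulin assembly / disassembly rate constants
#'     of the extension rate \eqn{dL/dt = r_g c_{tub} - s_g} (defaults 1,
#'     0.1) and the enhanced tip assembly rate of the selected axon (2).}
#'   \item{K_latent, T_diff, T_eq, T_init}{latent-heat coupling,
#'     thermal diffusivity, equilibrium and initial temperature of the
#'     undercooling equation \eqn{\partial T/\partial t = D_T \nabla^2 T
#'     + K \partial\phi/\partial t}, \eqn{\Delta T = T_{eq} - T}
#'     (defaults 1, 8, 1, 0). The undercooling field must relax fast
#'     relative to front motion (tip Peclet number below ~1) for
#'     sustained neurite extension.}
#'   \item{dt}{time step (0.01).}
#'   \item{r0}{initial soma radius in lattice units (20).}
#'   \item{activation_zone_size}{side of the square energy activation zone
#'     centered at each tip (6).}
#'   \item{zone_shift}{lattice shift of the activation zone toward an
#'     extracellular cue (2).}
#'   \item{cue_distance, cue_angle_mean, cue_angle_sd}{extracellular cue
#'     placement: distance from the tip (20) and the turning-angle normal
#'     distribution in degrees (41.673, 32.007 - the measured culture
#'     values).}
#'   \item{schedule}{cumulative iteration budgets of stages 1-4, default
#'     `c(500, 10500, 28500, 35000)`.}
#'   \item{phi_threshold}{interface threshold for masks (0.5).}
#'   \item{tip_exclusion}{soma exclusion radius for tip detection; `NA`
#'     means the default `1.1 * r0 + 4`.}
#'   \item{tip_match_radius, tip_min_separation, heading_window}{
#'     tip-to-neurite tracking radius (6), minimum lattice distance
#'     between detected tips (12; nearby boundary ripples merge into one
#'     growth cone), and number of recorded tip positions used for the
#'     heading (10).}
#'   \item{tip_prominence}{geodesic protrusion (in lattice units) above
#'     the local rim level required before a simulation registers a NEW
#'     neurite once growth cones exist (3); keeps shallow ripples of a
#'     broad front from spawning spurious neurites.}
#'   \item{retip_every}{iterations between topology refreshes (20).}
#'   \item{extension_margin}{tip-to-boundary distance (in points) that
#'     triggers domain extension (10), by 10 points on the approached side.}
#'   \item{extend_all_directions}{if `TRUE`, extend all four sides when any
#'     tip triggers (default `FALSE`: per-flagged-direction).}
#'   \item{reaction_on}{if `FALSE` the phase equation reduces to pure
#'     anisotropic diffusion (linear; used for verification problems).}
#'   \item{rng_seed}{seed for every stochastic element (1).}
#' }
#' @export
neuron_params <- function(...) {
  p <- list(
    M_phi = 25, a_bar = 0.55, delta_aniso = 0.15, j_fold = 6, theta_offset = 0,
    H_const = 0.004, alpha_E = 0.9, gamma = 10, heaviside_eps = 0.1,
    delta_t = 2, alpha_t = 2, alpha_t_mode = "radial", beta_t = 0.01,
    eps0 = 12, r_g = 1, s_g = 0.1, r_g_tip = 2,
    K_latent = 1, T_diff = 8, T_eq = 1, T_init = 0,
    dt = 0.01, r0 = 20, activation_zone_size = 6L, zone_shift = 2,
    cue_distance = 20, cue_angle_mean = 41.673, cue_angle_sd = 32.007,
    schedule = c(500L, 10500L, 28500L, 35000L),
    phi_threshold = 0.5, tip_exclusion = NA_real_,
    tip_match_radius = 6, tip_min_separation = 12, tip_prominence = 3,
    heading_window = 10L, retip_every = 20L,
    extension_margin = 10L, extend_all_directions = FALSE,
    reaction_on = TRUE, rng_seed = 1L
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  validate_neuron_params(p)
  structure(p, class = "neuron_params")
}

validate_neuron_params <- function(p) {
  stopifnot(p$dt > 0, p$r0 > 0, p$activation_zone_size >= 1)
  if (abs(p$delta_aniso) >= 1) {
    stop("parameter error: |delta_aniso| must be < 1 (gradient coefficient ",
         "a(Psi) would become nonpositive)")
  }
  num <- p[setdiff(names(p)[vapply(p, is.numeric, logical(1))],
                   "tip_exclusion")]  # NA means "use the default"
  if (!all(vapply(num, function(x) all(is.finite(x)), logical(1)))) {
    stop("parameter error: all numeric parameters must be finite")
  }
  if (!p$alpha_t_mode %in% c("radial", "constant")) {
    stop("alpha_t_mode must be 'radial' or 'constant'")
  }
  if (p$alpha_t_mode == "constant" && length(p$alpha_t) != 2) {
    stop("constant alpha_t must be a 2-vector")
  }
  stopifnot(length(p$schedule) == 4, !is.unsorted(p$schedule))
  invisible(p)
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("Neuron growth model parameters\n")
  cat("  phase field : M_phi =", x$M_phi, " a_bar =", x$a_bar,
      " delta =", x$delta_aniso, " j =", x$j_fold, " H =", x$H_const, "\n")
  cat("  driving E   : alpha =", x$alpha_E, " gamma =", x$gamma,
      " eps(Heaviside) =", x$heaviside_eps, "\n")
  cat("  tubulin     : delta_t =", x$delta_t, " alpha_t =",
      paste(x$alpha_t, collapse = ","), "(", x$alpha_t_mode, ") beta_t =",
      x$beta_t, " eps0 =", x$eps0, "\n")
  cat("  rates       : r_g =", x$r_g, " s_g =", x$s_g, " r_g_tip =",
      x$r_g_tip, "\n")
  cat("  stepping    : dt =", x$dt, " schedule =",
      paste(x$schedule, collapse = "/"), "\n")
  cat("  geometry    : r0 =", x$r0, " zone =", x$activation_zone_size, "x",
      x$activation_zone_size, " seed =", x$rng_seed, "\n")
  invisible(x)
}

tip_exclusion_radius <- function(params) {
  if (is.na(params$tip_exclusion)) 1.1 * params$r0 + 4 else params$tip_exclusion
}

#' Nonlinear solver settings
#'
#' @param newton_tol residual infinity-norm tolerance of the
#'   Newton-Raphson iteration (default `1e-4`).
#' @param newton_max_iters maximum Newton iterations per step (default 25).
#' @param linear_tol relative tolerance of the inner preconditioned
#'   linear solve (default `1e-9`).
#' @param linear_max_iters maximum inner iterations (default 200).
#' @param anisotropy_lag `"step"` (default) freezes the anisotropy
#'   coefficients at the previous time level for the whole step
#'   (first-order consistent, keeps the analytic-reaction Newton
#'   quadratic); `"iterate"` re-lags them at every Newton iterate.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(newton_tol = 1e-4, newton_max_iters = 25L,
                            linear_tol = 1e-9, linear_max_iters = 200L,
                            anisotropy_lag = c("step", "iterate")) {
  stopifnot(newton_tol > 0, linear_tol > 0)
  structure(list(newton_tol = newton_tol,
                 newton_max_iters = as.integer(newton_max_iters),
                 linear_tol = linear_tol,
                 linear_max_iters = as.integer(linear_max_iters),
                 anisotropy_lag = match.arg(anisotropy_lag)),
            class = "solver_settings")
}

# stage of an iteration under a cumulative schedule
stage_of_iteration <- function(iteration, schedule) {
  if (iteration <= schedule[1]) return(1L)
  if (iteration <= schedule[2]) return(2L)
  if (iteration <= schedule[3]) return(3L)
  4L
}

#' Write / read a flat key-value configuration file
#'
#' The configuration covers every model parameter plus the grid size and
#' soma centers; vector values are comma separated. The same format is
#' consumed by the command-line wrappers.
#'
#' @param config a list as returned by [reference_configs()] (elements
#'   `params`, `nu`, `nv`, `centers`, and optionally `name`).
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   a config list.
#' @export
write_config <- function(config, path) {
  p <- config$params
  kv <- c(
    list(nu = config$nu, nv = config$nv,
         centers_x = config$centers[, 1], centers_y = config$centers[, 2]),
    unclass(p)
  )
  lines <- vapply(names(kv), function(k) {
    paste0(k, " = ", paste(format(kv[[k]], digits = 15), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    vals <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    kv[[key]] <- if (all(!is.na(num))) num else vals
  }
  nu <- as.integer(kv$nu); nv <- as.integer(kv$nv)
  centers <- cbind(kv$centers_x, kv$centers_y)
  drop <- c("nu", "nv", "centers_x", "centers_y")
  pars <- kv[setdiff(names(kv), drop)]
  if (!is.null(pars$schedule)) pars$schedule <- as.integer(pars$schedule)
  if (!is.null(pars$alpha_t_mode)) pars$alpha_t_mode <- as.character(pars$alpha_t_mode)
  for (k in c("reaction_on", "extend_all_directions")) {
    if (!is.null(pars[[k]])) pars[[k]] <- as.logical(pars[[k]])
  }
  params <- do.call(neuron_params, pars)
  list(nu = nu, nv = nv, centers = centers, params = params)
}
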