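# Synthetic inputs for the test surface: star-shaped phase fields with
# known tips, planted-turn traces with known change points, and reduced
# reference configurations. Fixture truth is constructed geometrically,
# independent of the detectors under test.

#' Star-shaped phase field with known tips
#'
#' A soma disk with `k` radial arms (capsules) and smooth tanh edge
#' falloff. The analytic apex of each arm sits at distance
#' `soma_radius + arm_length` from the center along the arm axis (the
#' `phi = 0.5` level of the rounded arm end); the returned ground-truth
#' tips are the discrete apexes - the lattice point of each arm's
#' `phi > 0.5` region with maximal radius (ties toward the arm axis) -
#' computed from the analytic capsule geometry, independent of any
#' detector.
#'
#' @param k number of arms (`>= 2`, or 0 for a plain disk).
#' @param arm_length arm length beyond the soma radius.
#' @param arm_width full arm width at the `phi = 0.5` level.
#' @param soma_radius soma disk radius.
#' @param dim lattice dimensions `c(nu, nv)`.
#' @param center disk center (default: lattice center).
#' @param falloff tanh interface width (default 1).
#' @param angle0 orientation of the first arm in radians (default 0).
#' @return list with `phi` (matrix), `tips` (k x 2 matrix of discrete
#'   ground-truth tip lattice coordinates), `tips_exact` (analytic
#'   apexes), `center`, and the geometry parameters.
#' @export
make_star_phi <- function(k, arm_length = 28, arm_width = 5,
                          soma_radius = 10, dim = c(101, 101),
                          center = NULL, falloff = 1, angle0 = 0) {
  if (is.null(center)) center <- (dim + 1) / 2
  if (k > 0) {
    if (k < 2) stop("k must be 0 (plain disk) or >= 2")
    # arms must not overlap: angular spacing at the soma rim must exceed
    # the arm width
    if (2 * pi * soma_radius / k <= arm_width + 2) {
      stop("geometry overflow: arms overlap (angular spacing too small)")
    }
  }
  rmax <- if (k > 0) soma_radius + arm_length + arm_width else soma_radius + 2
  if (center[1] - rmax < 1 || center[1] + rmax > dim[1] ||
      center[2] - rmax < 1 || center[2] + rmax > dim[2]) {
    stop("geometry overflow: star does not fit in the grid")
  }
  ii <- rep(seq_len(dim[1]), times = dim[2])
  jj <- rep(seq_len(dim[2]), each = dim[1])
  dx <- ii - center[1]; dy <- jj - center[2]
  r <- sqrt(dx^2 + dy^2)
  half <- arm_width / 2
  # signed distance to the union of disk and capsules (negative inside)
  d <- r - soma_radius
  tips <- matrix(numeric(0), 0, 2)
  tips_exact <- matrix(numeric(0), 0, 2)
  if (k > 0 && arm_length > 0) {
    ang <- angle0 + 2 * pi * (seq_len(k) - 1) / k
    axis_len <- soma_radius + arm_length - half
    dsegs <- vector("list", k)
    for (s in seq_len(k)) {
      ux <- cos(ang[s]); uy <- sin(ang[s])
      tproj <- pmin(pmax(dx * ux + dy * uy, 0), axis_len)
      dsegs[[s]] <- sqrt((dx - tproj * ux)^2 + (dy - tproj * uy)^2) - half
      d <- pmin(d, dsegs[[s]])
    }
    tips_exact <- cbind(center[1] + (soma_radius + arm_length) * cos(ang),
                        center[2] + (soma_radius + arm_length) * sin(ang))
    # discrete ground truth: the lattice point of each arm (phi > 0.5,
    # i.e. inside the capsule) with maximal radius from the center, ties
    # broken toward the arm axis
    tips <- t(vapply(seq_len(k), function(s) {
      inside <- which(dsegs[[s]] < 0 & r > soma_radius + half)
      rr <- round(r[inside] * 2) / 2  # half-cell radius bins: symmetric
      axoff <- abs(dx[inside] * sin(ang[s]) - dy[inside] * cos(ang[s]))
      best <- inside[order(-rr, axoff)[1]]  # near-ties resolve on-axis
      c(ii[best], jj[best])
    }, numeric(2)))
  }
  phi <- matrix(0.5 * (1 - tanh(d / falloff)), dim[1], dim[2])
  list(phi = phi, tips = tips, tips_exact = tips_exact, center = center,
       k = k, arm_length = arm_length, arm_width = arm_width,
       soma_radius = soma_radius)
}

#' Planted-turn polyline trace
#'
#' A polyline made of straight runs of `steps_per_segment` steps of
#' length `step_length`, turning by the given angles at known interior
#' points, with optional Gaussian coordinate jitter. The returned truth
#' indices are the point indices of the planted turns.
#'
#' @param angles turn angles in degrees (signed, counterclockwise
#'   positive); `length(angles)` turns are planted.
#' @param steps_per_segment steps in each straight run (scalar or vector
#'   of length `length(angles) + 1`).
#' @param step_length step length in pixels (default 3, a typical manual
#'   tracing point spacing).
#' @param noise_sd Gaussian jitter sd added to each coordinate (pixels).
#' @param seed RNG seed (the caller's RNG stream is restored).
#' @param angle0 initial heading in degrees (default 0).
#' @return list with `trace` (a `trace`), `turn_indices` (truth point
#'   indices), `angles`, and the generation parameters.
#' @export
make_planted_trace <- function(angles = c(45, 45, 45),
                               steps_per_segment = 30, step_length = 3,
                               noise_sd = 0, seed = 1L, angle0 = 0) {
  nseg <- length(angles) + 1L
  steps <- rep_len(steps_per_segment, nseg)
  headings <- (angle0 + cumsum(c(0, angles))) * pi / 180
  dirs <- do.call(rbind, lapply(seq_len(nseg), function(s) {
    matrix(rep(c(cos(headings[s]), sin(headings[s])), steps[s]),
           ncol = 2, byrow = TRUE)
  }))
  pts <- rbind(c(0, 0), apply(dirs * step_length, 2, cumsum))
  if (noise_sd > 0) {
    pts <- pts + .with_seed(seed,
      matrix(stats::rnorm(length(pts), 0, noise_sd), nrow(pts), 2))
  }
  turn_indices <- cumsum(steps)[seq_along(angles)] + 1L
  list(trace = as_trace(pts), turn_indices = turn_indices,
       angles = angles, steps_per_segment = steps,
       step_length = step_length, noise_sd = noise_sd, seed = seed)
}

#' Reduced reference configurations
#'
#' Named simulation configurations: `smoke` (~100 x 100 lattice, 500
#' iterations), `staging` (~150 x 150, 2,000 iterations, all four stages
#' at reduced schedule) and `full_383` (the full-scale 383 x 383
#' single-neuron setup with the 500 / 10,500 / 28,500 / 35,000 stage
#' schedule; provided for completeness, not exercised by the test
#' suite). Stage budgets of the reduced configs scale the full schedule
#' proportionally.
#'
#' @param seed RNG seed stored in every config (default 1).
#' @return Named list of configs (`nu`, `nv`, `centers`, `params`).
#' @export
reference_configs <- function(seed = 1L) {
  list(
    smoke = list(
      nu = 100L, nv = 100L,
      centers = matrix(c(50.5, 50.5), 1, 2),
      params = neuron_params(r0 = 12,
                             schedule = c(120L, 300L, 420L, 500L),
                             rng_seed = seed)),
    staging = list(
      nu = 150L, nv = 150L,
      centers = matrix(c(75.5, 75.5), 1, 2),
      params = neuron_params(r0 = 20,
                             schedule = c(100L, 900L, 1500L, 2000L),
                             rng_seed = seed)),
    full_383 = list(
      nu = 383L, nv = 383L,
      centers = matrix(c(192, 192), 1, 2),
      params = neuron_params(r0 = 20,
                             schedule = c(500L, 10500L, 28500L, 35000L),
                             rng_seed = seed))
  )
}
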