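params_small <- function(...) neuron_params(r0 = 10, ...)

small_state <- function(n = 60, r0 = 10, ...) {
  p <- neuron_params(r0 = r0, ...)
  g <- build_collocation_grid(n, n)
  ctr <- cbind(g$gu[n %/% 2], g$gv[n %/% 2])
  list(state = initialize_state(p, ctr, g), grid = g, params = p, ctr = ctr)
}

test_that("initialization matches the tubulin profile formula", {
  s <- small_state(n = 70, r0 = 20)
  st <- s$state
  # at r = r0 the profile is exactly 1/2; at the center ~1 within 1e-8
  xy <- neurongrowth:::.grid_xy(s$grid)
  r <- sqrt((xy$x - s$ctr[1])^2 + (xy$y - s$ctr[2])^2)
  at_r0 <- which(abs(r - s$params$r0) < 1e-9)
  expect_true(length(at_r0) > 0)
  expect_equal(as.vector(st$c_tub)[at_r0],
               rep(0.5, length(at_r0)), tolerance = 1e-12)
  at_ctr <- which.min(r)
  expect_equal(as.vector(st$c_tub)[at_ctr], 1, tolerance = 1e-8)
  expect_equal(st$phi, st$phi0)
  expect_true(all(st$theta >= 0 & st$theta <= 1))
})

test_that("theta is reproducible from the seed and differs across seeds", {
  s1 <- small_state(rng_seed = 5L)
  s2 <- small_state(rng_seed = 5L)
  s3 <- small_state(rng_seed = 6L)
  expect_identical(s1$state$theta, s2$state$theta)
  expect_false(identical(s1$state$theta, s3$state$theta))
})

test_that("invalid initial geometry is rejected", {
  p <- neuron_params(r0 = 20)
  g <- build_collocation_grid(100, 100)
  expect_error(initialize_state(p, rbind(c(40, 40), c(60, 60)), g),
               "overlap")
  expect_error(initialize_state(p, cbind(10, 50), g), "fit")
})

test_that("interface orientation follows the gradient with a degenerate convention", {
  expect_equal(interface_orientation(1, 0), 0)
  expect_equal(interface_orientation(0, 1), pi / 2)
  expect_equal(interface_orientation(0, 0), 0)
  expect_equal(interface_orientation(-1e-11, 1e-12), 0)  # below tolerance
})

test_that("anisotropy coefficient has the j-fold form and analytic derivative", {
  p <- neuron_params()
  psi <- seq(-pi, pi, length.out = 41)
  iso <- anisotropy_coefficient(psi, neuron_params(delta_aniso = 0))
  expect_true(all(iso$a == p$a_bar))
  expect_true(all(iso$dadpsi == 0))
  ex <- anisotropy_coefficient(p$theta_offset, p)
  expect_equal(ex$a, p$a_bar * (1 + p$delta_aniso))
  expect_equal(ex$dadpsi, 0)
  # derivative vs central finite difference
  f <- function(x) anisotropy_coefficient(x, p)$a
  for (x in c(-2, -0.3, 0.4, 1.7)) {
    expect_equal(anisotropy_coefficient(x, p)$dadpsi, fd_central(f, x),
                 tolerance = 1e-6)
  }
  expect_error(anisotropy_coefficient(0, neuron_params(delta_aniso = 1)),
               "delta_aniso")
})

test_that("extension rate is the assembly-disassembly balance", {
  expect_equal(neurite_extension_rate(0.5, 0.2, 0.1), 0)
  expect_equal(neurite_extension_rate(3, 0, 0), 0)
  expect_equal(neurite_extension_rate(3, 2, 1), 5)
})

test_that("driving force is supported exactly on activation zones", {
  s <- small_state()
  st <- s$state
  st$temp <- matrix(0, nrow(st$phi), ncol(st$phi))  # full undercooling
  tips <- data.frame(neuron_id = 1L, neurite_id = 1L, ix = 30L, iy = 30L,
                     geodesic = 20, n_neighbors = 3L)
  class(tips) <- c("tip_set", "data.frame")
  st$c_tub[30, 30] <- 0.9
  E <- compute_driving_force(st, tips, s$params)
  inz <- matrix(FALSE, nrow(E), ncol(E)); inz[28:33, 28:33] <- TRUE
  expect_true(all(E[inz] > 0))
  expect_true(all(E[!inz] == 0))
  # empty tip set: identically zero
  E0 <- compute_driving_force(st, tips[0, ], s$params)
  expect_true(all(E0 == 0))
})

test_that("a tip with assembly below disassembly has an exactly zero zone", {
  s <- small_state()
  st <- s$state
  tips <- data.frame(neuron_id = 1L, neurite_id = 1L, ix = 30L, iy = 30L,
                     geodesic = 20, n_neighbors = 3L,
                     r = 0, s = s$params$s_g)
  st$c_tub[30, 30] <- 1  # r * c = 0 < s
  E <- compute_driving_force(st, tips, s$params)
  expect_true(all(E == 0))
})

test_that("driving force saturates at alpha/2 as its argument grows", {
  p <- neuron_params(gamma = 1e9, heaviside_eps = 1e-6)
  e <- neurongrowth:::.driving_force(1, 1, p)
  expect_equal(e, p$alpha_E / 2, tolerance = 1e-6)
})

test_that("uniform phase fields are stationary under the phase rhs", {
  s <- small_state()
  st <- s$state
  st$E_field <- matrix(0, nrow(st$phi), ncol(st$phi))
  for (v in c(0, 1)) {
    st$phi <- matrix(v, nrow(st$phi), ncol(st$phi))
    expect_lt(max(abs(phase_field_rhs(st, s$grid, s$params))), 1e-10)
  }
  # phi = 0.5 with uniform theta (no orientation gradient) and E = 0
  st$phi <- matrix(0.5, nrow(st$phi), ncol(st$phi))
  st$grad_theta_mag <- matrix(0, nrow(st$phi), ncol(st$phi))
  expect_lt(max(abs(phase_field_rhs(st, s$grid, s$params))), 1e-10)
})

test_that("the phase rhs matches the analytic expression for a smooth field", {
  # isotropic coefficient; Gaussian bump manufactured field
  errs <- vapply(c(40, 80), function(n) {
    L <- 40
    p <- neuron_params(delta_aniso = 0, H_const = 0, a_bar = 1.3, M_phi = 2)
    g <- build_collocation_grid(n, n, spacing = L / (n - 3))
    X <- outer(g$gu, rep(1, n)); Y <- outer(rep(1, n), g$gv)
    s2 <- 18
    phi <- exp(-((X - L/2)^2 + (Y - L/2)^2) / s2)
    lap <- phi * (4 * ((X - L/2)^2 + (Y - L/2)^2) / s2^2 - 4 / s2)
    st <- list(phi = phi,
               E_field = matrix(0, n, n),
               grad_theta_mag = matrix(0, n, n),
               iteration = 0L)
    class(st) <- "neuron_state"
    rhs <- phase_field_rhs(st, g, p)
    exact <- p$M_phi * (p$a_bar^2 * lap + phi * (1 - phi) * (phi - 0.5))
    max(abs(rhs - exact))
  }, numeric(1))
  expect_gt(log2(errs[1] / errs[2]), 1.8)  # ~second-order convergence
})

test_that("tubulin source integrates to eps0 and the rhs has the stated form", {
  s <- small_state()
  st <- s$state; g <- s$grid; p <- s$params
  expect_equal(sum(st$src) * g$spacing^2, p$eps0, tolerance = 1e-12)
  # arbitrary interface shapes keep the normalization exact
  star <- make_star_phi(4, arm_length = 15, soma_radius = 8,
                        dim = c(nrow(st$phi), ncol(st$phi)))
  st2 <- st; st2$phi0 <- star$phi
  src2 <- neurongrowth:::tubulin_source(st2, g, p)
  expect_equal(sum(src2) * g$spacing^2, p$eps0, tolerance = 1e-12)
  # phi = 1 and uniform c: diffusion and advection vanish pointwise
  st$phi <- matrix(1, nrow(st$phi), ncol(st$phi))
  st$c_tub <- matrix(0.7, nrow(st$phi), ncol(st$phi))
  rhs <- tubulin_rhs(st, g, p)
  inner <- rhs[4:(nrow(rhs) - 3), 4:(ncol(rhs) - 3)]
  exp_inner <- (-p$beta_t * 0.7 + st$src)[4:(nrow(rhs) - 3), 4:(ncol(rhs) - 3)]
  expect_equal(inner, exp_inner, tolerance = 1e-8)
  # eps0 = 0 and c = 0: identically zero balance
  p0 <- neuron_params(r0 = 10, eps0 = 0)
  st$c_tub <- matrix(0, nrow(st$phi), ncol(st$phi))
  st$src <- matrix(0, nrow(st$phi), ncol(st$phi))
  expect_true(all(abs(tubulin_rhs(st, g, p0)) < 1e-12))
  # a flat initial field has no interface to produce tubulin
  st$phi0 <- matrix(1, nrow(st$phi), ncol(st$phi))
  expect_error(neurongrowth:::tubulin_source(st, g, p), "interface")
})

test_that("undercooling evolution fixes uniform states and adds latent heat", {
  s <- small_state()
  st <- s$state; g <- s$grid; p <- s$params
  n <- nrow(st$phi)
  st$temp <- matrix(0.3, n, n)
  zero <- matrix(0, n, n)
  st1 <- evolve_undercooling(st, g, p, zero)
  expect_equal(st1$temp, st$temp, tolerance = 1e-10, ignore_attr = TRUE)
  st2 <- evolve_undercooling(st, g, p, matrix(2, n, n))
  expect_equal(st2$temp, st$temp + p$K_latent * 2 * p$dt,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("heat equation step matches a manufactured decaying mode", {
  # reaction off, K = 0: temperature obeys dT/dt = lap T; compare the
  # implicit step against the analytic solution over many steps
  n <- 40; L <- 40
  p <- neuron_params(K_latent = 0, T_diff = 1, r0 = 10)
  g <- build_collocation_grid(n, n, spacing = L / (n - 3))
  X <- outer(g$gu, rep(1, n)); Y <- outer(rep(1, n), g$gv)
  # Neumann-compatible mode: product of cosines
  Tm <- cos(pi * X / L) * cos(pi * Y / L)
  lam <- 2 * (pi / L)^2
  st <- list(phi = matrix(1, n, n), temp = Tm, iteration = 0L)
  class(st) <- "neuron_state"
  nsteps <- 50
  for (k in 1:nsteps) st <- evolve_undercooling(st, g, p, matrix(0, n, n))
  exact <- Tm * exp(-lam * nsteps * p$dt)
  # implicit Euler: O(dt) in time + O(h^2) in space
  expect_lt(max(abs(st$temp - exact)), 0.02 * max(abs(Tm)))
})
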