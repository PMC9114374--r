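test_that("trace construction validates its input", {
  expect_error(as_trace(matrix(c(0, 0), 1, 2)), "at least 2")
  expect_error(as_trace(rbind(c(0, 0), c(0, 0), c(1, 1))), "distinct")
  tr <- as_trace(rbind(c(0, 0), c(1, 0), c(2, 0)))
  expect_s3_class(tr, "trace")
})

test_that("trace CSV round-trips through the x,y format", {
  pt <- make_planted_trace(angles = 45, noise_sd = 0.2, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_trace(pt$trace, path)
  expect_equal(readLines(path, n = 1), '"x","y"')
  back <- read_trace(path)
  expect_equal(unclass(back), unclass(pt$trace), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a straight polyline yields no change points at any q", {
  tr <- as_trace(cbind(seq(0, 90, by = 3), 0))
  for (q in c(1, 3, 5)) {
    expect_length(change_point_test(tr, q = q)$indices, 0)
  }
  # straight with direction noise: usually none (error control elsewhere)
  pt <- make_planted_trace(angles = numeric(0), steps_per_segment = 40,
                           noise_sd = 0.2, seed = 9)
  expect_true(length(change_point_test(pt$trace, q = 3)$indices) <= 1)
})

test_that("a noise-free L-shaped polyline gives one 90-degree change point", {
  pt <- make_planted_trace(angles = 90, steps_per_segment = 10,
                           step_length = 2, noise_sd = 0)
  cps <- change_point_test(pt$trace, q = 2)
  expect_equal(cps$indices, pt$turn_indices)
  expect_equal(abs(cps$turning_angles), 90, tolerance = 1)
  expect_length(cps$segment_lengths, 2)
})

test_that("trace too short for the window is rejected", {
  tr <- as_trace(cbind(0:4, 0))
  expect_error(change_point_test(tr, q = 3), "insufficient-length")
})

test_that("planted turns are recovered with jitter", {
  hits <- 0
  for (s in 1:10) {
    pt <- make_planted_trace(angles = c(45, 45, 45),
                             steps_per_segment = 30, noise_sd = 0.3,
                             seed = s)
    cps <- change_point_test(pt$trace, q = 3, seed = s)
    ok <- length(cps$indices) == 3 &&
      all(abs(cps$indices - pt$turn_indices) <= 2)
    hits <- hits + ok
  }
  expect_gte(hits, 9)
})

test_that("the q-selection rule picks the lowest q with the most change points", {
  expect_equal(select_q_from_counts(c(`1` = 2, `2` = 5, `3` = 5, `4` = 4)), 2)
  expect_equal(select_q_from_counts(c(`1` = 0, `2` = 0, `3` = 0)), 1)
  expect_equal(select_q_from_counts(c(`1` = 3, `2` = 3, `3` = 3)), 1)
  # full pipeline: straight line picks q = 1 with 0 change points
  tr <- as_trace(cbind(seq(0, 120, by = 3), 0))
  sq <- select_q(tr, q_range = 1:10)
  expect_equal(sq$q, 1)
  expect_length(sq$cps$indices, 0)
  # q values the trace cannot support are skipped, all skipped errors
  short <- as_trace(cbind(seq(0, 18, by = 3), 0))
  expect_error(select_q(short, q_range = 9:10), "insufficient-length")
  # deterministic given trace and alpha
  pt <- make_planted_trace(angles = c(60, -60), noise_sd = 0.3, seed = 4)
  s1 <- select_q(pt$trace)
  s2 <- select_q(pt$trace)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$cps$indices, s2$cps$indices)
})

test_that("segment metrics compute arc lengths and signed turning angles", {
  # L fixture: arms 30 and 40 px along +x then +y
  tr <- as_trace(rbind(cbind(0:30, 0), cbind(30, 1:40)))
  sm <- segment_metrics(tr, cps = 31L, scale = 1)
  expect_equal(sm$lengths, c(30, 40))
  expect_equal(sm$angles, 90)  # east then north: +90 (ccw positive)
  # collinear split: zero angle
  tr2 <- as_trace(cbind(0:20, 0))
  expect_equal(segment_metrics(tr2, 11L)$angles, 0)
  # scale factor multiplies lengths only
  sm2 <- segment_metrics(tr, 31L, scale = 0.5)
  expect_equal(sm2$lengths, c(15, 20))
  expect_equal(sm2$angles, 90)
  expect_error(segment_metrics(tr, c(40L, 35L)), "increasing")
})

test_that("turning angles are rigid-motion invariant; lengths scale", {
  pt <- make_planted_trace(angles = c(30, -70, 110), noise_sd = 0.25,
                           seed = 6)
  cps <- change_point_test(pt$trace, q = 3)
  th <- 0.83; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- as_trace(sweep(unclass(pt$trace) %*% t(R), 2, c(-31, 47), "+"))
  cps2 <- change_point_test(moved, q = 3)
  expect_equal(cps2$indices, cps$indices)
  expect_equal(cps2$turning_angles, cps$turning_angles, tolerance = 1e-8)
  expect_equal(cps2$segment_lengths, cps$segment_lengths, tolerance = 1e-8)
})

test_that("angle summaries use linear-interpolation quartiles", {
  s <- summarize_angles(c(10, 20, 30, 40, 50))
  expect_equal(s$median, 30)
  expect_equal(s$q1, 20)
  expect_equal(s$q3, 40)
  expect_equal(s$mean, 30)
  cs <- summarize_angles(rep(7, 4))
  expect_equal(cs$sd, 0)
  expect_true(all(unlist(cs[c("min", "q1", "median", "q3", "max")]) == 7))
  one <- summarize_angles(42)
  expect_equal(one$sd, 0)
  expect_equal(one$mean, 42)
  expect_equal(one$min, one$max)
  expect_error(summarize_angles(numeric(0)), "empty")
  s2 <- summarize_angles(c(3, 1, 2))
  expect_true(s2$min <= s2$q1 && s2$q1 <= s2$median &&
              s2$median <= s2$q3 && s2$q3 <= s2$max)
})

test_that("Mann-Whitney comparison is exact for small untied samples", {
  res <- mann_whitney_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)
  expect_true(res$exact)
  # identical samples: zero shift estimate
  res0 <- mann_whitney_compare(c(1, 2, 3, 4), c(1, 2, 3, 4) + 1e-9)
  expect_lt(abs(res0$estimate), 1e-8)
  # swap symmetry
  set.seed(8)
  a <- stats::rnorm(6); b <- stats::rnorm(5, 1)
  r1 <- mann_whitney_compare(a, b)
  r2 <- mann_whitney_compare(b, a)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$estimate, -r2$estimate, tolerance = 1e-12)
})

test_that("exact p-values agree with brute-force enumeration for n+m <= 12", {
  set.seed(13)
  for (n in 2:6) for (m in 2:min(6, 12 - n)) {
    a <- stats::rnorm(n); b <- stats::rnorm(m, 0.8)
    res <- mann_whitney_compare(a, b)
    expect_equal(res$p, mw_enumerate_p(a, b), tolerance = 1e-12,
                 info = paste(n, m))
  }
})

test_that("tied samples fall back to the corrected normal approximation", {
  a <- c(1, 2, 2, 3); b <- c(2, 3, 3, 4)
  res <- mann_whitney_compare(a, b)
  expect_false(res$exact)
  expect_true(res$p > 0 && res$p <= 1)
})

test_that("traces extracted from a star field run along the arm", {
  star <- make_star_phi(4, arm_length = 24, arm_width = 5,
                        soma_radius = 9, dim = c(101, 101))
  tips <- detect_tips(star$phi, rbind(star$center), r0 = 9)
  tr <- extract_trace(star$phi, star$center, c(tips$ix[1], tips$iy[1]))
  expect_s3_class(tr, "trace")
  expect_gt(nrow(tr), 20)
  # endpoints anchored at the soma center and the tip
  expect_equal(as.numeric(tr[1, ]), as.numeric(round(star$center)))
  expect_equal(as.numeric(tr[nrow(tr), ]), c(tips$ix[1], tips$iy[1]))
})
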