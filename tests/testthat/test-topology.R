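test_that("connected components are labeled with neuron identity", {
  disk <- make_star_phi(0, soma_radius = 8, dim = c(60, 60))
  lab <- label_components(disk$phi, 0.5, centers = rbind(disk$center))
  expect_equal(sort(unique(as.vector(lab))), c(0L, 1L))
  # two disjoint somas get distinct ids keyed by their centers
  d1 <- make_star_phi(0, soma_radius = 6, dim = c(80, 80), center = c(20, 20))
  d2 <- make_star_phi(0, soma_radius = 6, dim = c(80, 80), center = c(60, 60))
  phi <- pmax(d1$phi, d2$phi)
  lab2 <- label_components(phi, 0.5, centers = rbind(c(20, 20), c(60, 60)))
  expect_equal(lab2[20, 20], 1L)
  expect_equal(lab2[60, 60], 2L)
  expect_equal(length(setdiff(unique(as.vector(lab2)), 0L)), 2)
  # a 4-armed cross is one connected component
  star <- make_star_phi(4, arm_length = 15, soma_radius = 8, dim = c(70, 70))
  lab4 <- label_components(star$phi, 0.5, centers = rbind(star$center))
  expect_equal(length(setdiff(unique(as.vector(lab4)), 0L)), 1)
  expect_error(label_components(matrix(0, 10, 10), 0.5), "empty-state")
})

test_that("a bare circular cell has no tips", {
  disk <- make_star_phi(0, soma_radius = 12, dim = c(70, 70))
  tips <- detect_tips(disk$phi, rbind(disk$center), r0 = 12)
  expect_equal(nrow(tips), 0)
})

test_that("star fixtures yield exact arm counts with tips at the truth points", {
  for (k in 2:8) {
    star <- make_star_phi(k, arm_length = 26, arm_width = 5,
                          soma_radius = 10, dim = c(101, 101))
    tips <- detect_tips(star$phi, rbind(star$center), r0 = 10)
    expect_equal(nrow(tips), k, info = paste("k =", k))
    # within one lattice point of truth in each direction
    d <- vapply(seq_len(k), function(i) {
      min(pmax(abs(tips$ix - star$tips[i, 1]),
               abs(tips$iy - star$tips[i, 2])))
    }, numeric(1))
    expect_true(all(d <= 1), info = paste("k =", k, "max d =", max(d)))
  }
})

test_that("a two-armed bar through the soma yields two tips", {
  bar <- make_star_phi(2, arm_length = 24, arm_width = 5,
                       soma_radius = 9, dim = c(101, 101))
  tips <- detect_tips(bar$phi, rbind(bar$center), r0 = 9)
  expect_equal(nrow(tips), 2)
})

test_that("activation zones have the exact cardinality and clip at edges", {
  empty <- data.frame(ix = integer(0), iy = integer(0))
  expect_equal(sum(activation_zones(empty, c(50, 50))), 0)
  one <- data.frame(ix = 25L, iy = 25L)
  expect_equal(sum(activation_zones(one, c(50, 50), 6)), 36)
  near <- data.frame(ix = 2L, iy = 25L)
  m <- activation_zones(near, c(50, 50), 6)
  expect_lt(sum(m), 36)
  expect_equal(sum(m), 5 * 6)  # rows 1..5 available of the 6
  # total cardinality is the sum of clipped zone areas
  tips2 <- data.frame(ix = c(25L, 2L), iy = c(25L, 25L))
  expect_equal(sum(activation_zones(tips2, c(50, 50), 6)), 36 + 30)
})

test_that("geodesic lengths follow lattice path arithmetic", {
  phi <- matrix(0, 60, 60)
  phi[10:40, 20] <- 1                      # horizontal arm, 30 steps
  expect_equal(geodesic_length(phi, c(10, 20), c(40, 20)), 30)
  expect_equal(geodesic_length(phi, c(10, 20), c(10, 20)), 0)
  phid <- matrix(0, 60, 60)
  diag_idx <- cbind(10:20, 10:20)          # diagonal arm, 10 steps
  phid[diag_idx] <- 1
  expect_equal(geodesic_length(phid, c(10, 10), c(20, 20)), 10 * sqrt(2),
               tolerance = 1e-12)
  phi2 <- matrix(0, 30, 30); phi2[5, 5] <- 1; phi2[20, 20] <- 1
  expect_error(geodesic_length(phi2, c(5, 5), c(20, 20)), "disconnected")
})

test_that("axon selection is an argmax with a deterministic tie rule", {
  p <- neuron_params()
  tips <- data.frame(neurite_id = 1:3, geodesic = c(5, 9, 3))
  sel <- select_axon(tips, p)
  expect_equal(sel$axon, 2)
  expect_equal(sel$rates$r[sel$rates$neurite_id == 2], p$r_g_tip)
  expect_true(all(sel$rates$r[sel$rates$neurite_id != 2] == 0))
  expect_true(all(sel$rates$s == p$s_g))
  tie <- data.frame(neurite_id = 1:2, geodesic = c(7, 7))
  expect_equal(select_axon(tie, p)$axon, 1)
  # invariance under relabeling up to the tie rule
  perm <- data.frame(neurite_id = c(3, 1, 2), geodesic = c(3, 5, 9))
  expect_equal(select_axon(perm, p)$axon, 2)
  expect_error(select_axon(tips[0, ], p), "empty")
})

test_that("non-axon zones have zero driving force after selection", {
  star <- make_star_phi(3, arm_length = 24, arm_width = 5,
                        soma_radius = 10, dim = c(101, 101))
  p <- neuron_params(r0 = 10)
  g <- build_collocation_grid(101, 101)
  tips <- detect_tips(star$phi, rbind(star$center), r0 = 10)
  tips$geodesic[2] <- tips$geodesic[2] + 5  # make neurite 2 the longest
  sel <- select_axon(tips, p)
  tips$r <- sel$rates$r[match(tips$neurite_id, sel$rates$neurite_id)]
  tips$s <- sel$rates$s[match(tips$neurite_id, sel$rates$neurite_id)]
  st <- list(phi = star$phi, c_tub = star$phi, temp = matrix(0, 101, 101))
  E <- compute_driving_force(st, tips, p)
  for (t in seq_len(nrow(tips))) {
    zone <- neurongrowth:::zone_indices(tips$ix[t], tips$iy[t], 6, 101, 101)
    if (tips$neurite_id[t] == sel$axon) {
      expect_gt(max(E[zone$i, zone$j]), 0)
    } else {
      expect_true(all(E[zone$i, zone$j] == 0))
    }
  }
})

test_that("cue placement geometry and sampling behave as specified", {
  p <- neuron_params()
  cp <- place_extracellular_cue(c(50, 50), c(1, 0), p, angle = 0)
  expect_equal(cp$cue, c(50 + p$cue_distance, 50))
  cp90 <- place_extracellular_cue(c(50, 50), c(1, 0), p, angle = 90)
  expect_equal(cp90$cue, c(50, 50 + p$cue_distance), tolerance = 1e-12)
  # |cue - tip| is always the configured distance
  set.seed(2)
  for (i in 1:20) {
    cp <- place_extracellular_cue(c(50, 50), stats::rnorm(2), p)
    expect_equal(sqrt(sum((cp$cue - c(50, 50))^2)), p$cue_distance,
                 tolerance = 1e-9)
  }
  # sampled |angle| mean matches the folded-normal expectation within 1%
  set.seed(11)
  angs <- replicate(1e5,
    place_extracellular_cue(c(0, 0), c(1, 0), p)$angle)
  expect_equal(mean(abs(angs)),
               folded_normal_mean(p$cue_angle_mean, p$cue_angle_sd),
               tolerance = 0.01)
  # seeded reproducibility of the cue sequence
  set.seed(7); s1 <- replicate(5, place_extracellular_cue(c(0, 0), c(1, 0), p)$angle)
  set.seed(7); s2 <- replicate(5, place_extracellular_cue(c(0, 0), c(1, 0), p)$angle)
  expect_identical(s1, s2)
  expect_error(place_extracellular_cue(c(0, 0), c(0, 0), p), "heading")
})

test_that("the intersection guard blocks same-neuron merges only", {
  # two parallel arms of one neuron advancing toward each other across a
  # 3-point gap: over repeated advance/relabel rounds neither crosses the
  # midline and the arm count is conserved
  grow_round <- function(phi, neuron_of_arm) {
    arms <- matrix(0L, 60, 60)
    arms[phi[, 1:28] > 0.5] <- 1L  # left block of columns  -> arm 1
    a2 <- phi > 0.5; a2[, 1:28] <- FALSE
    arms[a2] <- 2L
    # each arm tries to advance one column toward the other
    phi_new <- phi
    right_edge <- apply(phi[, 1:29] > 0.5, 1, function(r) {
      w <- which(r); if (length(w)) max(w) else NA
    })
    left_edge <- apply(phi > 0.5, 1, function(r) {
      w <- which(r); w <- w[w >= 29]; if (length(w)) min(w) else NA
    })
    for (i in 15:45) {
      if (!is.na(right_edge[i])) phi_new[i, right_edge[i] + 1] <- 1
      if (!is.na(left_edge[i])) phi_new[i, left_edge[i] - 1] <- 1
    }
    intersection_guard(phi, phi_new, arms, neuron_of_arm)
  }
  phi <- matrix(0, 60, 60)
  phi[15:45, 26] <- 1
  phi[15:45, 30] <- 1
  same <- phi
  for (k in 1:4) same <- grow_round(same, c(1L, 1L))
  # the two arms never merged: the midline band keeps them separate
  expect_equal(length(setdiff(unique(as.vector(
    label_components(same, 0.5))), 0L)), 2)
  # arms of different neurons: contact is permitted and they do merge
  diff_n <- phi
  for (k in 1:4) diff_n <- grow_round(diff_n, c(1L, 2L))
  expect_equal(length(setdiff(unique(as.vector(
    label_components(diff_n, 0.5))), 0L)), 1)
  # an isolated arm is untouched by the guard
  phi3 <- matrix(0, 40, 40); phi3[10:20, 20] <- 1
  arms3 <- matrix(0L, 40, 40); arms3[10:20, 20] <- 1L
  phi3_new <- phi3; phi3_new[21, 20] <- 1
  expect_equal(intersection_guard(phi3, phi3_new, arms3, 1L), phi3_new)
})
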