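# Discrete geometric reasoning on the phase field: component labeling,
# tip detection, activation zones, geodesic lengths, axon selection, cue
# placement and the same-neuron intersection guard. All operations work
# in lattice index coordinates (knot spacing 1, so indices ~ physical
# units away from the domain edges).

# 8-connected neighbor offsets (half set; the graph is undirected)
.OFFS <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
.OFFW <- c(1, 1, sqrt(2), sqrt(2))

# Weighted 8-connectivity graph over the TRUE cells of a mask.
# Returns list(graph, idx) where idx maps lattice positions to vertex ids.
.mask_graph <- function(mask) {
  nu <- nrow(mask); nv <- ncol(mask)
  pts <- which(mask)
  idx <- matrix(0L, nu, nv)
  idx[pts] <- seq_along(pts)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_along(.OFFS)) {
    di <- .OFFS[[k]][1]; dj <- .OFFS[[k]][2]
    i <- max(1L, 1L - di):min(nu, nu - di)
    j <- max(1L, 1L - dj):min(nv, nv - dj)
    a <- idx[i, j, drop = FALSE]
    b <- idx[i + di, j + dj, drop = FALSE]
    ok <- a > 0L & b > 0L
    if (any(ok)) {
      from <- c(from, a[ok]); to <- c(to, b[ok])
      w <- c(w, rep(.OFFW[k], sum(ok)))
    }
  }
  g <- igraph::make_empty_graph(n = length(pts), directed = FALSE)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to))
    igraph::E(g)$weight <- w
  }
  list(graph = g, idx = idx, pts = pts)
}

# 3x3 mean filter with edge-aware normalization
.mean3 <- function(m) {
  nu <- nrow(m); nv <- ncol(m)
  s <- matrix(0, nu, nv); cnt <- matrix(0, nu, nv)
  for (di in -1:1) for (dj in -1:1) {
    i <- max(1L, 1L - di):min(nu, nu - di)
    j <- max(1L, 1L - dj):min(nv, nv - dj)
    s[i, j] <- s[i, j] + m[i + di, j + dj]
    cnt[i, j] <- cnt[i, j] + 1
  }
  s / cnt
}

# count of TRUE 8-neighbors for every cell of a mask
.neighbor_count <- function(mask) {
  nu <- nrow(mask); nv <- ncol(mask)
  cnt <- matrix(0L, nu, nv)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    i <- max(1L, 1L - di):min(nu, nu - di)
    j <- max(1L, 1L - dj):min(nv, nv - dj)
    cnt[i, j] <- cnt[i, j] + mask[i + di, j + dj]
  }
  cnt
}

#' Label connected components of the cell region
#'
#' 8-connected components of `{phi > threshold}`. When soma `centers`
#' (lattice coordinates) are supplied, the component containing each
#' center keeps that neuron's id; remaining components get fresh ids.
#'
#' @param phi phase-field matrix.
#' @param threshold interface threshold in (0,1), default 0.5.
#' @param centers optional k x 2 matrix of soma centers (lattice coords).
#' @return Integer matrix of labels (0 outside all components).
#' @export
label_components <- function(phi, threshold = 0.5, centers = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  mask <- phi > threshold
  if (!any(mask)) stop("empty-state error: no points above threshold")
  mg <- .mask_graph(mask)
  comp <- igraph::components(mg$graph)$membership
  lab <- matrix(0L, nrow(phi), ncol(phi))
  lab[mg$pts] <- comp
  if (!is.null(centers)) {
    centers <- matrix(as.numeric(centers), ncol = 2)
    k <- nrow(centers)
    remap <- integer(max(comp))
    for (i in seq_len(k)) {
      ci <- round(centers[i, 1]); cj <- round(centers[i, 2])
      ci <- min(max(ci, 1), nrow(phi)); cj <- min(max(cj, 1), ncol(phi))
      cc <- lab[ci, cj]
      if (cc == 0L) {
        # center not above threshold: use nearest mask point
        pos <- arrayInd(mg$pts, dim(mask))
        d2 <- (pos[, 1] - centers[i, 1])^2 + (pos[, 2] - centers[i, 2])^2
        cc <- comp[which.min(d2)]
      }
      remap[cc] <- i
    }
    nxt <- k
    for (c0 in seq_along(remap)) {
      if (remap[c0] == 0L) { nxt <- nxt + 1L; remap[c0] <- nxt }
    }
    lab[mg$pts] <- remap[comp]
  }
  lab
}

# geodesic distance map from a soma center within one mask, -Inf outside
.distance_map <- function(mask, center) {
  mg <- .mask_graph(mask)
  pos <- arrayInd(mg$pts, dim(mask))
  d2 <- (pos[, 1] - center[1])^2 + (pos[, 2] - center[2])^2
  src <- which.min(d2)
  dd <- igraph::distances(mg$graph, v = src)[1, ]
  D <- matrix(-Inf, nrow(mask), ncol(mask))
  D[mg$pts] <- dd
  D[!is.finite(D) & mask] <- -Inf  # unreachable parts of other components
  D
}

#' Detect neurite tips
#'
#' Finds one tip per neurite arm as the plateau-aware local maxima of the
#' within-mask geodesic distance from the soma center (the discrete
#' endpoint of each protruding arm), clustered per growth cone and
#' refined to the arm apex (the near-maximal point of largest radius).
#' Points closer to the soma than the exclusion radius are never tips,
#' so a bare circular cell yields an empty tip set.
#'
#' @param phi phase-field matrix.
#' @param centers k x 2 matrix of soma centers (lattice coordinates).
#' @param r0 soma radius (used for the default exclusion radius).
#' @param threshold interface threshold (default 0.5).
#' @param exclusion geodesic exclusion radius; default `1.1 * r0 + 4`
#'   (the 8-connected metric overestimates Euclidean radii by up to ~8%,
#'   and the diffuse interface widens the mask, so a protrusion margin is
#'   required before a maximum counts as a tip).
#' @param smooth apply a 3x3 mean filter to `phi` before thresholding
#'   (an option for noisy fields; it erodes arm ends by about one cell,
#'   so it is off by default).
#' @param min_separation minimum lattice distance between reported tips
#'   (default 4): geodesic maxima closer than this are clustered into one
#'   growth cone, and of two distinct tips closer than this the one with
#'   the larger geodesic distance is kept (boundary ripples on a broad
#'   lamellipodia front merge into a single growth cone).
#' @return A `data.frame` of class `tip_set` with columns `neuron_id`,
#'   `neurite_id`, `ix`, `iy`, `geodesic`, `n_neighbors`. Zero rows if no
#'   arm protrudes beyond the exclusion radius.
#' @export
detect_tips <- function(phi, centers, r0, threshold = 0.5,
                        exclusion = NULL, smooth = FALSE,
                        min_separation = 4) {
  centers <- matrix(as.numeric(centers), ncol = 2)
  if (is.null(exclusion)) exclusion <- 1.1 * r0 + 4
  ph <- if (smooth) .mean3(phi) else phi
  mask <- ph > threshold
  out <- list()
  rim_level <- rep(NA_real_, nrow(centers))
  for (n in seq_len(nrow(centers))) {
    if (!any(mask)) break
    D <- .distance_map(mask, centers[n, ])
    bd <- mask & .neighbor_count(mask) < 8L & is.finite(D)
    if (any(bd)) rim_level[n] <- stats::median(D[bd])
    ismax <- mask & D > exclusion
    if (!any(ismax)) next
    for (k in seq_along(.OFFS)) {
      for (sgn in c(1L, -1L)) {
        di <- sgn * .OFFS[[k]][1]; dj <- sgn * .OFFS[[k]][2]
        nbr <- matrix(-Inf, nrow(mask), ncol(mask))
        i <- max(1L, 1L - di):min(nrow(mask), nrow(mask) - di)
        j <- max(1L, 1L - dj):min(ncol(mask), ncol(mask) - dj)
        nbr[i, j] <- D[i + di, j + dj]
        ismax <- ismax & (D >= nbr)
      }
    }
    if (!any(ismax)) next
    # single-linkage clustering of the maxima: maxima within the
    # separation radius belong to one growth cone (a rounded arm end can
    # carry several tied geodesic maxima)
    pos <- arrayInd(which(ismax), dim(mask))
    link <- max(min_separation, 2)
    dd <- as.matrix(stats::dist(pos))
    adj <- which(dd <= link & upper.tri(dd), arr.ind = TRUE)
    gcl <- igraph::make_empty_graph(n = nrow(pos), directed = FALSE)
    if (nrow(adj)) gcl <- igraph::add_edges(gcl, t(adj))
    cl <- igraph::components(gcl)$membership
    nb <- .neighbor_count(mask)
    mask_pos <- arrayInd(which(mask), dim(mask))
    for (c0 in sort(unique(cl))) {
      sel <- cl == c0
      cen <- colMeans(pos[sel, , drop = FALSE])
      # snap the centroid to the nearest masked lattice point, then
      # refine within the near-maximal geodesic band to the arm apex:
      # the point of largest radius from the soma (the 8-connected path
      # metric is anisotropic by up to ~8%, which would otherwise bias
      # the tip laterally on oblique arms)
      d2 <- (mask_pos[, 1] - cen[1])^2 + (mask_pos[, 2] - cen[2])^2
      best <- which.min(d2)
      ix <- mask_pos[best, 1]; iy <- mask_pos[best, 2]
      near <- which(abs(mask_pos[, 1] - ix) <= 3 &
                    abs(mask_pos[, 2] - iy) <= 3)
      Dn <- D[mask_pos[near, , drop = FALSE]]
      band <- near[Dn >= max(Dn) - 0.6]
      eu <- round(2 * sqrt((mask_pos[band, 1] - centers[n, 1])^2 +
                           (mask_pos[band, 2] - centers[n, 2])^2)) / 2
      dcen <- (mask_pos[band, 1] - cen[1])^2 + (mask_pos[band, 2] - cen[2])^2
      sc <- band[order(-eu, dcen)[1]]  # half-cell radius bins, then axis
      ix <- mask_pos[sc, 1]; iy <- mask_pos[sc, 2]
      out[[length(out) + 1L]] <- data.frame(
        neuron_id = n, neurite_id = NA_integer_, ix = ix, iy = iy,
        geodesic = max(D[ix, iy], max(D[pos[sel, , drop = FALSE]])),
        n_neighbors = nb[ix, iy])
    }
  }
  tips <- if (length(out)) do.call(rbind, out) else
    data.frame(neuron_id = integer(0), neurite_id = integer(0),
               ix = integer(0), iy = integer(0), geodesic = numeric(0),
               n_neighbors = integer(0))
  if (nrow(tips) && min_separation > 0) {
    keep <- logical(nrow(tips))
    for (k in order(-tips$geodesic, tips$ix, tips$iy)) {
      d <- sqrt((tips$ix[keep] - tips$ix[k])^2 +
                (tips$iy[keep] - tips$iy[k])^2)
      same <- tips$neuron_id[keep] == tips$neuron_id[k]
      if (!any(same & d < min_separation)) keep[k] <- TRUE
    }
    tips <- tips[keep, , drop = FALSE]
  }
  if (nrow(tips)) {
    # stable ordering: by neuron, then angle around the soma
    ang <- atan2(tips$iy - centers[tips$neuron_id, 2],
                 tips$ix - centers[tips$neuron_id, 1])
    tips <- tips[order(tips$neuron_id, ang), , drop = FALSE]
    rownames(tips) <- NULL
    tips$neurite_id <- seq_len(nrow(tips))
  }
  class(tips) <- c("tip_set", "data.frame")
  attr(tips, "rim_level") <- rim_level
  tips
}

#' Energy activation zone mask
#'
#' Union of `zone_size x zone_size` axis-aligned squares centered at each
#' tip (or its cue-shifted zone center), clipped to the lattice.
#'
#' @param tips a `tip_set` (columns `ix`, `iy`, optionally `zone_ci`,
#'   `zone_cj`).
#' @param dim lattice dimensions `c(nu, nv)`.
#' @param zone_size zone side length (default 6).
#' @return Logical matrix.
#' @export
activation_zones <- function(tips, dim, zone_size = 6) {
  stopifnot(zone_size >= 1)
  mask <- matrix(FALSE, dim[1], dim[2])
  if (is.null(tips) || nrow(tips) == 0) return(mask)
  for (t in seq_len(nrow(tips))) {
    ci <- if (!is.null(tips$zone_ci)) tips$zone_ci[t] else tips$ix[t]
    cj <- if (!is.null(tips$zone_cj)) tips$zone_cj[t] else tips$iy[t]
    idx <- zone_indices(ci, cj, zone_size, dim[1], dim[2])
    mask[idx$i, idx$j] <- TRUE
  }
  mask
}

#' Geodesic length from soma center to a tip
#'
#' Shortest-path length on the 8-connected lattice graph restricted to
#' `{phi > threshold}`, diagonal steps weighted sqrt(2).
#'
#' @param phi phase-field matrix.
#' @param soma_center,tip lattice coordinates `c(i, j)`.
#' @param threshold mask threshold (default 0: the strictly positive phase region).
#' @return Nonnegative path length.
#' @export
geodesic_length <- function(phi, soma_center, tip, threshold = 0) {
  mask <- phi > threshold
  mg <- .mask_graph(mask)
  a <- mg$idx[round(soma_center[1]), round(soma_center[2])]
  b <- mg$idx[round(tip[1]), round(tip[2])]
  if (a == 0L || b == 0L) {
    stop("disconnected-tip error: endpoint outside the phi > ",
         threshold, " region")
  }
  d <- igraph::distances(mg$graph, v = a, to = b)[1, 1]
  if (!is.finite(d)) {
    stop("disconnected-tip error: no path between soma center and tip")
  }
  d
}

#' Select the axon among detected neurites
#'
#' The neurite with maximal geodesic length differentiates into the axon:
#' its tip receives the enhanced assembly rate `r_g_tip` (chosen so that
#' `r_g_tip * c_tub > s_g` at a supplied tip, reflecting continued
#' extension), while every other neurite receives rates with
#' `r * c_tub < s` so its driving force vanishes. Ties break to the
#' lowest neurite id.
#'
#' @param tips a `tip_set` with `neurite_id` and `geodesic` columns.
#' @param params a [neuron_params()] object.
#' @return list with `axon` (selected neurite id) and `rates`, a
#'   `data.frame` of per-neurite `(neurite_id, r, s)`.
#' @export
select_axon <- function(tips, params = neuron_params()) {
  if (is.null(tips) || nrow(tips) == 0) {
    stop("selection error: empty tip set")
  }
  o <- order(-tips$geodesic, tips$neurite_id)
  axon <- tips$neurite_id[o[1]]
  rates <- data.frame(
    neurite_id = tips$neurite_id,
    r = ifelse(tips$neurite_id == axon, params$r_g_tip, 0),
    s = params$s_g)
  list(axon = axon, rates = rates)
}

#' Place an extracellular cue for a neurite tip
#'
#' Samples a turning angle from the normal distribution of measured
#' turning angles (`cue_angle_mean`, `cue_angle_sd`, degrees), assigns a
#' random sign with equal probability (the measurements are absolute
#' angles), and places the cue at `cue_distance` from the tip in the
#' direction of the tip heading rotated by the signed angle. The
#' activation zone is subsequently shifted toward the cue.
#'
#' @param tip lattice coordinates `c(i, j)` of the tip.
#' @param heading unit 2-vector of the tip's current heading; a newborn
#'   tip without one should be given its radially-outward direction.
#' @param params a [neuron_params()] object.
#' @param angle optional fixed signed angle in degrees (bypasses
#'   sampling; used for deterministic geometry checks).
#' @return list of class `cue_placement`: `cue` (x, y), `tip`, `angle`
#'   (signed degrees).
#' @export
place_extracellular_cue <- function(tip, heading, params, angle = NULL) {
  nh <- sqrt(sum(heading^2))
  if (!is.finite(nh) || nh < 1e-12) {
    stop("undefined heading: supply the radially-outward direction")
  }
  heading <- heading / nh
  if (is.null(angle)) {
    angle <- stats::rnorm(1, params$cue_angle_mean, params$cue_angle_sd) *
      sample(c(-1, 1), 1)
  }
  th <- angle * pi / 180
  rot <- c(cos(th) * heading[1] - sin(th) * heading[2],
           sin(th) * heading[1] + cos(th) * heading[2])
  structure(list(cue = tip + params$cue_distance * rot,
                 tip = tip, angle = angle),
            class = "cue_placement")
}

# Arm labeling: connected components of the above-threshold mask minus
# the soma disks; each arm maps to the neuron whose soma it touches.
arm_labels <- function(phi, centers, r0, threshold = 0.5) {
  centers <- matrix(as.numeric(centers), ncol = 2)
  mask <- phi > threshold
  nu <- nrow(phi); nv <- ncol(phi)
  ii <- rep(seq_len(nu), times = nv)
  jj <- rep(seq_len(nv), each = nu)
  soma <- matrix(FALSE, nu, nv)
  for (n in seq_len(nrow(centers))) {
    soma <- soma | matrix((ii - centers[n, 1])^2 + (jj - centers[n, 2])^2
                          <= r0^2, nu, nv)
  }
  arm_mask <- mask & !soma
  if (!any(arm_mask)) {
    return(list(arms = matrix(0L, nu, nv), neuron = integer(0)))
  }
  mg <- .mask_graph(arm_mask)
  comp <- igraph::components(mg$graph)$membership
  arms <- matrix(0L, nu, nv)
  arms[mg$pts] <- comp
  pos <- arrayInd(mg$pts, dim(mask))
  neuron <- integer(max(comp))
  for (c0 in seq_len(max(comp))) {
    sel <- comp == c0
    d2 <- outer(rep(1, sum(sel)), rep(0, nrow(centers)))
    for (n in seq_len(nrow(centers))) {
      d2[, n] <- (pos[sel, 1] - centers[n, 1])^2 +
                 (pos[sel, 2] - centers[n, 2])^2
    }
    neuron[c0] <- which.min(apply(d2, 2, min))
  }
  list(arms = arms, neuron = neuron)
}

# Points whose (window x window) neighborhood contains two distinct arms
# of the same neuron: advancing phi there would merge them.
.conflict_mask <- function(arms, neuron, window = 5) {
  nu <- nrow(arms); nv <- ncol(arms)
  conflict <- matrix(FALSE, nu, nv)
  if (length(neuron) < 2) return(conflict)
  h <- (window - 1) %/% 2
  for (n in unique(neuron)) {
    ids <- which(neuron == n)
    if (length(ids) < 2) next
    cnt <- matrix(0L, nu, nv)
    for (a in ids) {
      pres <- matrix(FALSE, nu, nv)
      am <- arms == a
      for (di in -h:h) for (dj in -h:h) {
        i <- max(1L, 1L - di):min(nu, nu - di)
        j <- max(1L, 1L - dj):min(nv, nv - dj)
        pres[i, j] <- pres[i, j] | am[i + di, j + dj]
      }
      cnt <- cnt + pres
    }
    conflict <- conflict | (cnt >= 2L)
  }
  conflict
}

#' Suppress same-neuron neurite merging
#'
#' Zeroes the phase-field increase at points where advancing the front
#' would merge two distinct neurite arms of the same neuron (both arms
#' present within a `window x window` neighborhood). Growth toward arms
#' of other neurons is untouched.
#'
#' @param phi_old,phi_new phase fields before and after a step.
#' @param arms integer matrix of arm labels (see the labeling of
#'   components of the cell mask minus the soma disks).
#' @param arm_neuron integer vector mapping arm id to neuron id.
#' @param window neighborhood size (default 5).
#' @return The constrained `phi_new`.
#' @export
intersection_guard <- function(phi_old, phi_new, arms, arm_neuron,
                               window = 5) {
  conflict <- .conflict_mask(arms, arm_neuron, window)
  sup <- conflict & (phi_new > phi_old)
  phi_new[sup] <- phi_old[sup]
  phi_new
}
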