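# Change-point-test segmentation of neurite tracings, segment-length and
# turning-angle metrics, summary tables, and the Mann-Whitney comparison
# between two angle samples.

# evaluate expr under a temporary RNG seed, restoring the caller's stream
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

# wrap angles to (-pi, pi]
.wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Construct a neurite trace
#'
#' An ordered (x, y) polyline, e.g. a manual tracing in pixel units or a
#' simulated neurite path in lattice units.
#'
#' @param coords two-column matrix or data.frame of (x, y) coordinates.
#' @return A matrix of class `trace`.
#' @export
as_trace <- function(coords) {
  m <- as.matrix(coords)[, 1:2, drop = FALSE]
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y")
  if (nrow(m) < 2) stop("a trace needs at least 2 points")
  if (any(rowSums(abs(diff(m))) == 0)) {
    stop("consecutive trace points must be distinct")
  }
  class(m) <- c("trace", class(m))
  m
}

#' Read / write a trace as CSV
#'
#' CSV with header `x,y`, one row per point - the format consumed by the
#' analysis command-line wrapper.
#'
#' @param path file path.
#' @param trace a `trace` (or 2-column coordinate matrix) for writing.
#' @return `read_trace` returns a `trace`; `write_trace` returns `path`.
#' @export
read_trace <- function(path) {
  as_trace(utils::read.csv(path))
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(data.frame(x = trace[, 1], y = trace[, 2]), path,
                   row.names = FALSE)
  invisible(path)
}

# deviation statistic between the q steps before and after each interior
# point. z: complex steps; returns list(t = candidate point indices,
# S = angular deviation in radians).
.cpt_stat <- function(z, q) {
  m <- length(z)
  cs <- c(0, cumsum(z))
  t <- (q + 1):(m - q + 1)
  back <- cs[t] - cs[t - q]
  fwd <- cs[t + q] - cs[t]
  list(t = t, S = abs(Arg(fwd * Conj(back))))
}

# robust direction-noise scale of a step sequence (complex steps):
# MAD of the wrapped step-direction increments, / sqrt(2)
.cpt_sigma <- function(z) {
  stats::mad(.wrap_angle(diff(Arg(z)))) / sqrt(2)
}

# null distribution of the STUDENTIZED maximum deviation statistic
# (max_t S / sigma_hat) over straight paths with isotropic direction
# noise; each replicate re-estimates its own noise scale, so the
# estimation uncertainty of sigma_hat cancels to first order and the
# per-trace error rate is calibrated
.cpt_null_max <- function(m, q, sigma, B) {
  eta <- matrix(stats::rnorm(m * B, 0, sigma), m, B)
  z <- exp(1i * eta)
  cs <- rbind(0, apply(z, 2, cumsum))
  t <- (q + 1):(m - q + 1)
  back <- cs[t, , drop = FALSE] - cs[t - q, , drop = FALSE]
  fwd <- cs[t + q, , drop = FALSE] - cs[t, , drop = FALSE]
  S <- abs(Arg(fwd * Conj(back)))
  d <- apply(eta, 2, function(e) stats::mad(.wrap_angle(diff(e)))) / sqrt(2)
  apply(S, 2, max) / pmax(d, 1e-12)
}

#' Change point test on a neurite trace
#'
#' Detects significant direction changes by comparing the mean direction
#' of the `q` step vectors before each interior point with the `q` step
#' vectors after it (the deviation statistic is the angle between the two
#' resultant directions). Significance is calibrated against a
#' Monte-Carlo null of straight paths with isotropic direction noise
#' matched to the trace (robust MAD estimate of the step-direction
#' increments); the critical value is the `1 - alpha` quantile of the
#' null maximum statistic, which controls the per-trace false-positive
#' rate at `alpha`. Declared change points are window-local maxima of the
#' statistic at least `q` indices apart.
#'
#' @param trace a `trace` (or coordinate matrix).
#' @param alpha significance level in (0, 1) (default 0.05).
#' @param q number of step vectors before/after a candidate turn.
#' @param n_null Monte-Carlo null replicates (default 1000).
#' @param seed RNG seed for the null (restored afterwards).
#' @param scale units per coordinate unit for segment lengths (default 1).
#' @return An object of class `change_point_set`: `indices` (point
#'   indices of the turns, strictly increasing, interior), `q`, `alpha`,
#'   `statistic` and `candidates`, `critical`, `sigma_hat`,
#'   `segment_lengths`, `turning_angles` (signed, degrees,
#'   counterclockwise positive) and `abs_angles`.
#' @export
change_point_test <- function(trace, alpha = 0.05, q, n_null = 1000,
                              seed = 1L, scale = 1) {
  trace <- as_trace(trace)
  stopifnot(alpha > 0, alpha < 1, q >= 1)
  n <- nrow(trace)
  m <- n - 1L
  if (m < 2 * q) {
    stop("insufficient-length error: trace with ", n,
         " points cannot support q = ", q)
  }
  dxy <- diff(trace)
  z <- complex(real = dxy[, 1], imaginary = dxy[, 2])
  st <- .cpt_stat(z, q)
  sigma_hat <- .cpt_sigma(z)
  crit <- if (sigma_hat <= 0) 1e-9 else {
    # critical value for S from the studentized null quantile
    mx <- .with_seed(seed, .cpt_null_max(m, q, sigma_hat, n_null))
    sigma_hat * stats::quantile(mx, 1 - alpha, names = FALSE, type = 7)
  }
  sig <- which(st$S > crit)
  keep <- integer(0)
  if (length(sig)) {
    # window-local maxima (ties to the earliest index), then greedy
    # separation of at least q indices
    is_locmax <- vapply(sig, function(k) {
      win <- which(abs(st$t - st$t[k]) <= q)
      mx <- max(st$S[win])
      st$S[k] >= mx - 1e-15 && st$t[k] == min(st$t[win][st$S[win] >= mx - 1e-15])
    }, logical(1))
    cand <- sig[is_locmax]
    cand <- cand[order(-st$S[cand], st$t[cand])]
    for (k in cand) {
      if (!length(keep) || all(abs(st$t[k] - st$t[keep]) >= q)) {
        keep <- c(keep, k)
      }
    }
    keep <- keep[order(st$t[keep])]
  }
  indices <- st$t[keep]
  sm <- segment_metrics(trace, indices, scale = scale)
  structure(list(indices = indices, q = q, alpha = alpha,
                 candidates = st$t, statistic = st$S,
                 critical = crit, sigma_hat = sigma_hat,
                 n_points = n,
                 segment_lengths = sm$lengths,
                 turning_angles = sm$angles,
                 abs_angles = abs(sm$angles)),
            class = "change_point_set")
}

#' @export
print.change_point_set <- function(x, ...) {
  cat("Change point test: q =", x$q, "alpha =", x$alpha, "|",
      length(x$indices), "change point(s) at",
      paste(x$indices, collapse = ", "), "\n")
  invisible(x)
}

#' Lowest-q-most-change-points rule
#'
#' Given change-point counts by q, returns the lowest q achieving the
#' maximal count.
#'
#' @param counts named numeric vector (names are q values) or plain
#'   vector indexed by q.
#' @return The selected q (integer).
#' @export
select_q_from_counts <- function(counts) {
  qs <- if (is.null(names(counts))) seq_along(counts) else
    as.integer(names(counts))
  min(qs[counts == max(counts)])
}

#' Run the CPT over a range of q and select q
#'
#' Runs the change point test for every `q` in `q_range` (q values the
#' trace is too short for are skipped) and selects the lowest q that
#' yields the most change points.
#'
#' @inheritParams change_point_test
#' @param q_range candidate q values (default 1:10).
#' @return list with `q` (selected), `counts` (named by q), and `cps`
#'   (the `change_point_set` for the selected q).
#' @export
select_q <- function(trace, alpha = 0.05, q_range = 1:10, n_null = 1000,
                     seed = 1L, scale = 1) {
  trace <- as_trace(trace)
  res <- list(); counts <- c()
  for (q in q_range) {
    r <- tryCatch(change_point_test(trace, alpha, q, n_null, seed, scale),
                  error = function(e) NULL)
    if (is.null(r)) next
    res[[as.character(q)]] <- r
    counts[as.character(q)] <- length(r$indices)
  }
  if (!length(res)) {
    stop("insufficient-length error: trace too short for every q in range")
  }
  qsel <- select_q_from_counts(counts)
  list(q = qsel, counts = counts, cps = res[[as.character(qsel)]])
}

#' Segment lengths and turning angles of a segmented trace
#'
#' Splits the trace at the change points; each segment's length is the
#' polyline arc length between consecutive breakpoints (times `scale`),
#' and each turning angle is the signed angle (degrees, counterclockwise
#' positive) between successive segment chords.
#'
#' @param trace a `trace` (or coordinate matrix).
#' @param cps a `change_point_set` or an integer vector of change-point
#'   indices (interior point indices).
#' @param scale units per coordinate unit (default 1).
#' @return list with `lengths` (one per segment) and `angles` (signed
#'   degrees, one per change point).
#' @export
segment_metrics <- function(trace, cps, scale = 1) {
  trace <- as_trace(trace)
  idx <- if (inherits(cps, "change_point_set")) cps$indices else
    as.integer(cps)
  n <- nrow(trace)
  if (length(idx) && (any(idx <= 1) || any(idx >= n) || is.unsorted(idx,
      strictly = TRUE))) {
    stop("change-point indices must be strictly increasing and interior")
  }
  b <- c(1L, idx, n)
  steps <- diff(trace)
  arc <- c(0, cumsum(sqrt(rowSums(steps^2))))
  lengths <- (arc[b[-1]] - arc[b[-length(b)]]) * scale
  chords <- trace[b[-1], , drop = FALSE] - trace[b[-length(b)], , drop = FALSE]
  angles <- numeric(0)
  if (nrow(chords) >= 2) {
    u <- chords[-nrow(chords), , drop = FALSE]
    v <- chords[-1, , drop = FALSE]
    angles <- atan2(u[, 1] * v[, 2] - u[, 2] * v[, 1],
                    u[, 1] * v[, 1] + u[, 2] * v[, 2]) * 180 / pi
  }
  list(lengths = as.numeric(lengths), angles = as.numeric(angles))
}

#' Summary statistics of a turning-angle sample
#'
#' Mean, standard deviation (n - 1 denominator; 0 for a single value by
#' convention), minimum, quartiles (linear interpolation between order
#' statistics), median and maximum - the layout of the comparison table.
#'
#' @param angles nonempty numeric sample (degrees).
#' @return A one-row `data.frame` of class `angle_summary` with columns
#'   `mean`, `sd`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
summarize_angles <- function(angles) {
  if (!length(angles)) stop("empty angle sample")
  qs <- stats::quantile(angles, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  out <- data.frame(
    mean = mean(angles),
    sd = if (length(angles) > 1) stats::sd(angles) else 0,
    min = min(angles), q1 = qs[1], median = qs[2], q3 = qs[3],
    max = max(angles))
  class(out) <- c("angle_summary", "data.frame")
  out
}

#' Mann-Whitney comparison of two angle (or length) samples
#'
#' Two-sided Mann-Whitney U test with the Hodges-Lehmann estimate of the
#' location shift and its distribution-based confidence interval. The
#' p-value is computed by exact enumeration when `min(n, m) <= 8`,
#' `n + m <= 20` and there are no ties, and by the normal approximation
#' with tie correction otherwise.
#'
#' @param a,b nonempty numeric samples.
#' @param conf_level target confidence level (default 0.95; the achieved
#'   level of the exact interval is reported).
#' @return list with `U`, `p`, `estimate` (Hodges-Lehmann median
#'   difference a - b), `conf_int`, `conf_level_achieved`, `exact`.
#' @export
mann_whitney_compare <- function(a, b, conf_level = 0.95) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  n <- length(a); m <- length(b)
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- min(n, m) <= 8 && (n + m) <= 20 && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    a, b, exact = use_exact, correct = !use_exact,
    conf.int = TRUE, conf.level = conf_level))
  list(U = unname(wt$statistic), p = wt$p.value,
       estimate = unname(wt$estimate),
       conf_int = as.numeric(wt$conf.int),
       conf_level_achieved = attr(wt$conf.int, "conf.level"),
       exact = use_exact)
}

#' Extract a neurite trace from a simulated phase field
#'
#' The soma-to-tip path within `{phi > threshold}` (8-connected shortest
#' path, which follows the arm to within half its width), as a `trace`
#' in lattice coordinates.
#'
#' @param phi phase-field matrix.
#' @param soma_center,tip lattice coordinates `c(i, j)`.
#' @param threshold mask threshold (default 0.5).
#' @return A `trace`.
#' @export
extract_trace <- function(phi, soma_center, tip, threshold = 0.5) {
  mask <- phi > threshold
  mg <- .mask_graph(mask)
  a <- mg$idx[round(soma_center[1]), round(soma_center[2])]
  b <- mg$idx[round(tip[1]), round(tip[2])]
  if (a == 0L || b == 0L) stop("endpoint outside the masked region")
  sp <- igraph::shortest_paths(mg$graph, from = a, to = b)$vpath[[1]]
  if (!length(sp)) stop("disconnected-tip error: no path")
  pos <- arrayInd(mg$pts[as.integer(sp)], dim(mask))
  as_trace(pos)
}
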