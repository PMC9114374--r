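# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Greville abscissae by direct knot averaging (brute force over indices)
greville_brute <- function(knots, p) {
  n <- length(knots) - p - 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in 1:p) acc <- acc + knots[i + k]
    out[i] <- acc / p
  }
  out
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# C(n+m, n) group assignments of the pooled ranks.
mw_enumerate_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a); m <- length(b)
  r <- rank(pooled)
  obsU <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  Us <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  mu <- n * m / 2
  mean(abs(Us - mu) >= abs(obsU - mu) - 1e-9)
}

# folded-normal mean E|X|, X ~ N(mu, sd)
folded_normal_mean <- function(mu, sd) {
  sd * sqrt(2 / pi) * exp(-mu^2 / (2 * sd^2)) +
    mu * (1 - 2 * stats::pnorm(-mu / sd))
}

# second-order central finite difference of f at x
fd_central <- function(f, x, h = 1e-5) (f(x + h) - f(x - h)) / (2 * h)
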