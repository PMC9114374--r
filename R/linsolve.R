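# Matrix-free linear algebra for the collocated implicit systems.
#
# All implicit solves share one structure: (identity - dt * spatial
# operator) on the Greville lattice, with boundary collocation rows
# replaced by boundary-condition rows. They are solved by BiCGSTAB with a
# tensor-product preconditioner P = Pu (x) Pv, Pu = I - beta * Guu (+ BC
# rows), whose inverse is two small dense matrix products. For the
# spectra at hand (second-derivative collocation eigenvalues are real and
# nonpositive) the preconditioned iteration converges for any beta.

# Replace boundary rows of a residual/operator application.
# For zero = TRUE, zeroes the boundary entries of a right-hand side.
# Corners carry the y-direction condition (single equation per point).
.apply_bc_rows <- function(R, W, grid, bc = c("neumann", "dirichlet"),
                           zero = FALSE) {
  bc <- match.arg(bc)
  nu <- grid$nu; nv <- grid$nv
  if (zero) {
    R[1, ] <- 0; R[nu, ] <- 0; R[, 1] <- 0; R[, nv] <- 0
    return(R)
  }
  if (bc == "neumann") {
    Wx <- grid$Gu %*% W
    Wy <- W %*% t(grid$Gv)
    R[1, ] <- Wx[1, ]; R[nu, ] <- Wx[nu, ]
    R[, 1] <- Wy[, 1]; R[, nv] <- Wy[, nv]
  } else {
    R[1, ] <- W[1, ]; R[nu, ] <- W[nu, ]
    R[, 1] <- W[, 1]; R[, nv] <- W[, nv]
  }
  R
}

# Cached tensor-product preconditioner: returns function(R) ~ P^-1 R.
.adi_preconditioner <- function(grid, beta, bc = "neumann") {
  key <- paste0("adi_", bc, "_", signif(beta, 12))
  hit <- grid$cache[[key]]
  if (!is.null(hit)) return(hit)
  mk <- function(n, G, G2) {
    P <- diag(n) - beta * G2
    if (bc == "neumann") {
      P[1, ] <- G[1, ]; P[n, ] <- G[n, ]
    } else {
      P[1, ] <- 0; P[1, 1] <- 1; P[n, ] <- 0; P[n, n] <- 1
    }
    solve(P)
  }
  Pui <- mk(grid$nu, grid$Gu, grid$Guu)
  Pvi <- mk(grid$nv, grid$Gv, grid$Gvv)
  f <- function(R) Pui %*% R %*% t(Pvi)
  grid$cache[[key]] <- f
  f
}

# Right-preconditioned BiCGSTAB on matrix-shaped unknowns.
# amul: function(W) -> A W (matrix in, matrix out); prec: function(R) ~ P^-1 R.
# Stops when ||r||_inf <= max(atol, tol * ||b||_inf).
.solve_krylov <- function(amul, b, prec, x0 = NULL, tol = 1e-9,
                          maxit = 200L, atol = 1e-13) {
  x <- if (is.null(x0)) b * 0 else x0
  r <- b - amul(x)
  target <- max(atol, tol * max(abs(b)))
  if (max(abs(r)) <= target) {
    attr(x, "iterations") <- 0L
    return(x)
  }
  rhat <- r
  rho <- 1; alpha <- 1; omega <- 1
  v <- r * 0; p <- r * 0
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    rho1 <- sum(rhat * r)
    if (abs(rho1) < 1e-300) { rhat <- r; rho1 <- sum(rhat * r) }
    beta <- (rho1 / rho) * (alpha / omega)
    p <- r + beta * (p - omega * v)
    ph <- prec(p)
    v <- amul(ph)
    denom <- sum(rhat * v)
    if (abs(denom) < 1e-300) break
    alpha <- rho1 / denom
    s <- r - alpha * v
    if (max(abs(s)) <= target) {
      x <- x + alpha * ph
      r <- s
      break
    }
    sh <- prec(s)
    t <- amul(sh)
    tt <- sum(t * t)
    if (tt < 1e-300) break
    omega <- sum(t * s) / tt
    x <- x + alpha * ph + omega * sh
    r <- s - omega * t
    if (max(abs(r)) <= target) break
    rho <- rho1
  }
  attr(x, "iterations") <- it
  attr(x, "residual") <- max(abs(r))
  x
}

# 6x6 (or z x z) activation-zone index ranges centered at (ci, cj),
# clipped to the lattice. Even sizes take floor((z-1)/2) points below and
# ceiling((z-1)/2)+1 above the center.
zone_indices <- function(ci, cj, z, nu, nv) {
  lo <- -floor((z - 1) / 2)
  hi <- lo + z - 1
  list(i = max(1L, ci + lo):min(nu, ci + hi),
       j = max(1L, cj + lo):min(nv, cj + hi))
}
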