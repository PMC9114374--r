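#' Open uniform knot vector
#'
#' Constructs the open (clamped) knot vector \eqn{U = \{u_1, \ldots,
#' u_{n+p+1}\}} for `n_basis` B-spline basis functions of degree `p` with
#' uniform interior spacing. The first and last knots are repeated `p + 1`
#' times so the spline interpolates the domain end points; the parametric
#' domain is `[0, (n_basis - p) * spacing]`.
#'
#' @param n_basis number of basis functions (`>= p + 1`).
#' @param degree spline degree `p` (default cubic, `p = 3`; must be `>= 2`
#'   for the second-derivative collocation operators to exist).
#' @param spacing interior knot spacing (default 1, so the parametric and
#'   physical lattices coincide and no geometric mapping is needed).
#' @return An object of class `knot_vector`: a list with elements `knots`,
#'   `degree`, `n_basis` and `spacing`.
#' @examples
#' kv <- make_open_knot_vector(5, 3)
#' kv$knots  # 0 0 0 0 1 2 2 2 2
#' @export
make_open_knot_vector <- function(n_basis, degree = 3, spacing = 1) {
  if (degree < 1) stop("degree must be >= 1")
  if (n_basis < degree + 1) {
    stop("invalid spline space: n_basis (", n_basis, ") < degree + 1 (",
         degree + 1, ")")
  }
  if (spacing <= 0) stop("spacing must be > 0")
  n_int <- n_basis - degree - 1  # interior knots
  L <- (n_basis - degree) * spacing
  knots <- c(rep(0, degree + 1),
             if (n_int > 0) spacing * seq_len(n_int),
             rep(L, degree + 1))
  structure(list(knots = knots, degree = degree, n_basis = n_basis,
                 spacing = spacing, domain = c(0, L)),
            class = "knot_vector")
}

#' @export
print.knot_vector <- function(x, ...) {
  cat("Open knot vector: degree", x$degree, "|", x$n_basis,
      "basis functions | domain [", x$domain[1], ",", x$domain[2],
      "] | spacing", x$spacing, "\n")
  invisible(x)
}

#' Greville abscissae of a knot vector
#'
#' One collocation point per basis function, the knot average
#' \eqn{\hat u_i = (u_{i+1} + \cdots + u_{i+p}) / p}. For an open knot
#' vector the first/last points coincide with the domain end points.
#'
#' @param kv a `knot_vector`.
#' @return Numeric vector of length `kv$n_basis`, nondecreasing.
#' @export
greville_abscissae <- function(kv) {
  stopifnot(inherits(kv, "knot_vector"))
  p <- kv$degree
  u <- kv$knots
  vapply(seq_len(kv$n_basis),
         function(i) sum(u[(i + 1):(i + p)]) / p, numeric(1))
}

# Cox-de Boor basis functions and derivatives at a single site.
# Returns the index of the knot span and the p+1 nonzero basis values
# (or derivative values) on that span. Port of the standard FindSpan /
# DersBasisFuns algorithms.
.find_span <- function(u, p, x) {
  n <- length(u) - p - 1          # number of basis functions
  if (x >= u[n + 1]) return(n)    # right end clamps to the last span
  if (x <= u[p + 1]) return(p + 1)
  lo <- p + 1; hi <- n + 1
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (x < u[mid]) hi <- mid else lo <- mid
  }
  lo
}

.ders_basis <- function(u, p, x, nder) {
  span <- .find_span(u, p, x)
  # triangular table of basis functions by degree (ndu), NURBS-book A2.3
  ndu <- matrix(0, p + 1, p + 1)
  left <- numeric(p + 1); right <- numeric(p + 1)
  ndu[1, 1] <- 1
  if (p > 0) {
    for (j in 1:p) {
      left[j + 1] <- x - u[span + 1 - j]
      right[j + 1] <- u[span + j] - x
      saved <- 0
      for (r in 0:(j - 1)) {
        ndu[j + 1, r + 1] <- right[r + 2] + left[j - r + 1]
        temp <- ndu[r + 1, j] / ndu[j + 1, r + 1]
        ndu[r + 1, j + 1] <- saved + right[r + 2] * temp
        saved <- left[j - r + 1] * temp
      }
      ndu[j + 1, j + 1] <- saved
    }
  }
  ders <- matrix(0, nder + 1, p + 1)
  ders[1, ] <- ndu[, p + 1]
  if (nder > 0 && p > 0) {
    a <- matrix(0, 2, p + 1)
    for (r in 0:p) {
      s1 <- 1L; s2 <- 2L
      a[1, 1] <- 1
      for (k in 1:nder) {
        d <- 0
        rk <- r - k; pk <- p - k
        if (r >= k) {
          a[s2, 1] <- a[s1, 1] / ndu[pk + 2, rk + 1]
          d <- a[s2, 1] * ndu[rk + 1, pk + 1]
        }
        j1 <- if (rk >= -1) 1L else -rk
        j2 <- if (r - 1 <= pk) k - 1L else p - r
        if (j1 <= j2) {
          for (j in j1:j2) {
            a[s2, j + 1] <- (a[s1, j + 1] - a[s1, j]) / ndu[pk + 2, rk + j + 1]
            d <- d + a[s2, j + 1] * ndu[rk + j + 1, pk + 1]
          }
        }
        if (r <= pk) {
          a[s2, k + 1] <- -a[s1, k] / ndu[pk + 2, r + 1]
          d <- d + a[s2, k + 1] * ndu[r + 1, pk + 1]
        }
        ders[k + 1, r + 1] <- d
        tmp <- s1; s1 <- s2; s2 <- tmp
      }
    }
    fac <- p
    for (k in 1:nder) {
      ders[k + 1, ] <- ders[k + 1, ] * fac
      fac <- fac * (p - k)
    }
  }
  list(span = span, ders = ders)
}

#' Evaluate B-spline basis functions at a site
#'
#' Cox-de Boor recursion with the explicit derivative recursion. Returns a
#' sparse coefficient row: the values (or derivative values) of all
#' `n_basis` basis functions at `u`, of which at most `p + 1` are nonzero.
#' Order-0 rows sum to 1 (partition of unity); derivative rows sum to 0.
#'
#' @param kv a `knot_vector`.
#' @param u evaluation site inside the knot span.
#' @param derivative_order 0, 1 or 2.
#' @return A numeric vector of length `kv$n_basis`.
#' @export
evaluate_basis <- function(kv, u, derivative_order = 0) {
  stopifnot(inherits(kv, "knot_vector"))
  if (u < kv$domain[1] - 1e-12 || u > kv$domain[2] + 1e-12) {
    stop("site u = ", u, " outside the knot domain [",
         kv$domain[1], ", ", kv$domain[2], "]")
  }
  if (!derivative_order %in% 0:2) stop("derivative_order must be 0, 1 or 2")
  res <- .ders_basis(kv$knots, kv$degree, u, derivative_order)
  row <- numeric(kv$n_basis)
  idx <- (res$span - kv$degree):res$span
  row[idx] <- res$ders[derivative_order + 1, ]
  row
}

# Dense collocation matrix of derivative order d: one row per site.
.basis_matrix <- function(kv, sites, d = 0) {
  t(vapply(sites, function(x) evaluate_basis(kv, x, d),
           numeric(kv$n_basis)))
}
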