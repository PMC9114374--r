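#' Tensor-product collocation grid
#'
#' Builds the two-dimensional cubic B-spline space on an open uniform knot
#' lattice, its Greville collocation points, and the value / derivative
#' collocation operators used to collocate the strong-form PDEs. The
#' parametric and physical domains coincide (knot spacing 1 by default), so
#' there is no geometric mapping.
#'
#' The grid carries two operator representations:
#' \itemize{
#'   \item sparse 2D operators `N`, `Du`, `Dv`, `Duu`, `Dvv`
#'     (coefficients at collocation points -> field / derivative values),
#'     each row with at most `(p+1)^2` nonzeros;
#'   \item dense 1D differentiation maps `Gu = D1u %*% solve(Nu)` (and
#'     `Gv`, `Guu`, `Gvv`) acting directly on lattice \emph{values}, used by
#'     the time integrator (a derivative of the interpolating spline is a
#'     single small dense matrix product per direction).
#' }
#'
#' Fields on the grid are `nu x nv` matrices, first index along u/x.
#'
#' @param nu,nv number of basis functions (= collocation points) per
#'   direction; both `>= degree + 1`.
#' @param degree spline degree (default 3).
#' @param spacing knot spacing (default 1).
#' @param origin physical coordinates of the parametric origin `(0,0)`;
#'   used by the multi-resolution domain extension to keep global
#'   coordinates stable.
#' @param index_origin global integer lattice index of the first
#'   collocation point per direction (used to key the deterministic
#'   orientation-noise field).
#' @return An object of class `collocation_grid`.
#' @export
build_collocation_grid <- function(nu, nv, degree = 3, spacing = 1,
                                   origin = c(0, 0), index_origin = c(0L, 0L)) {
  ku <- make_open_knot_vector(nu, degree, spacing)
  kvv <- make_open_knot_vector(nv, degree, spacing)
  gu <- greville_abscissae(ku)
  gv <- greville_abscissae(kvv)

  Nu  <- .basis_matrix(ku, gu, 0)
  D1u <- .basis_matrix(ku, gu, 1)
  D2u <- .basis_matrix(ku, gu, 2)
  Nv  <- .basis_matrix(kvv, gv, 0)
  D1v <- .basis_matrix(kvv, gv, 1)
  D2v <- .basis_matrix(kvv, gv, 2)

  Nui <- tryCatch(solve(Nu), error = function(e)
    stop("collocation assembly error: singular interpolation matrix in u"))
  Nvi <- tryCatch(solve(Nv), error = function(e)
    stop("collocation assembly error: singular interpolation matrix in v"))

  g <- list(
    ku = ku, kv = kvv, gu = gu, gv = gv, nu = nu, nv = nv,
    degree = degree, spacing = spacing,
    origin = origin, index_origin = as.integer(index_origin),
    Nu = Nu, D1u = D1u, D2u = D2u, Nv = Nv, D1v = D1v, D2v = D2v,
    Nui = Nui, Nvi = Nvi,
    # value-space differentiation maps
    Gu = D1u %*% Nui, Guu = D2u %*% Nui,
    Gv = D1v %*% Nvi, Gvv = D2v %*% Nvi,
    cache = new.env(parent = emptyenv())
  )
  class(g) <- "collocation_grid"
  g
}

#' @export
print.collocation_grid <- function(x, ...) {
  cat("Collocation grid:", x$nu, "x", x$nv, "Greville points | degree",
      x$degree, "| spacing", x$spacing, "| origin (",
      x$origin[1], ",", x$origin[2], ")\n")
  invisible(x)
}

# Sparse 2D operators, built lazily (solver uses the dense 1D maps).
# which: "N", "Du", "Dv", "Duu", "Dvv".
#' Sparse tensor-product collocation operator
#'
#' Returns the sparse operator mapping spline coefficients (column-major
#' vec of the `nu x nv` coefficient matrix, u fastest) to field or
#' derivative values at the Greville lattice.
#'
#' @param grid a `collocation_grid`.
#' @param which one of `"N"`, `"Du"`, `"Dv"`, `"Duu"`, `"Dvv"`.
#' @return A `dgCMatrix` of dimension `(nu*nv) x (nu*nv)`.
#' @export
collocation_operator <- function(grid, which = c("N", "Du", "Dv", "Duu", "Dvv")) {
  which <- match.arg(which)
  key <- paste0("op_", which)
  if (!is.null(grid$cache[[key]])) return(grid$cache[[key]])
  sp <- function(m) methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix")
  op <- switch(which,
    N   = Matrix::kronecker(sp(grid$Nv),  sp(grid$Nu)),
    Du  = Matrix::kronecker(sp(grid$Nv),  sp(grid$D1u)),
    Dv  = Matrix::kronecker(sp(grid$D1v), sp(grid$Nu)),
    Duu = Matrix::kronecker(sp(grid$Nv),  sp(grid$D2u)),
    Dvv = Matrix::kronecker(sp(grid$D2v), sp(grid$Nu)))
  op <- methods::as(op, "CsparseMatrix")
  grid$cache[[key]] <- op
  op
}

#' Interpolate lattice values by the spline space
#'
#' Solves the Greville interpolation problem `N %*% coef = values` by two
#' one-dimensional solves (the operator is a Kronecker product). The
#' round trip coefficients -> values -> coefficients is the identity to
#' solver precision.
#'
#' @param grid a `collocation_grid`.
#' @param values `nu x nv` matrix of field values at the Greville lattice.
#' @return `nu x nv` matrix of spline coefficients.
#' @export
values_to_coefficients <- function(grid, values) {
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$nu, grid$nv))) {
    stop("dimension error: values must be ", grid$nu, " x ", grid$nv)
  }
  grid$Nui %*% values %*% t(grid$Nvi)
}

#' Evaluate a coefficient field at the Greville lattice
#' @param grid a `collocation_grid`.
#' @param coef `nu x nv` coefficient matrix.
#' @return `nu x nv` matrix of values.
#' @export
coefficients_to_values <- function(grid, coef) {
  grid$Nu %*% coef %*% t(grid$Nv)
}

#' Collocated derivative of a lattice field
#'
#' Differentiates the spline interpolant of `values` and evaluates at the
#' Greville lattice.
#'
#' @param grid a `collocation_grid`.
#' @param values `nu x nv` matrix of field values.
#' @param which `"x"`, `"y"`, `"xx"`, `"yy"` or `"lap"` (Laplacian).
#' @return `nu x nv` matrix of derivative values.
#' @export
grid_derivative <- function(grid, values, which = c("x", "y", "xx", "yy", "lap")) {
  which <- match.arg(which)
  switch(which,
    x   = grid$Gu %*% values,
    y   = values %*% t(grid$Gv),
    xx  = grid$Guu %*% values,
    yy  = values %*% t(grid$Gvv),
    lap = grid$Guu %*% values + values %*% t(grid$Gvv))
}

# Evaluate the spline defined by lattice `values` on OLD grid at arbitrary
# physical points (x, y) (vectors); points outside the domain get `fill`.
# Used by the domain-extension transfer.
.evaluate_field_at <- function(grid, values, x, y, fill = 0) {
  coef <- values_to_coefficients(grid, values)
  xo <- x - grid$origin[1]
  yo <- y - grid$origin[2]
  out <- rep(fill, length(x))
  ok <- xo >= grid$ku$domain[1] - 1e-9 & xo <= grid$ku$domain[2] + 1e-9 &
        yo >= grid$kv$domain[1] - 1e-9 & yo <= grid$kv$domain[2] + 1e-9
  if (!any(ok)) return(out)
  xo <- pmin(pmax(xo[ok], grid$ku$domain[1]), grid$ku$domain[2])
  yo <- pmin(pmax(yo[ok], grid$kv$domain[1]), grid$kv$domain[2])
  Bu <- .basis_matrix(grid$ku, xo, 0)   # npts x nu
  Bv <- .basis_matrix(grid$kv, yo, 0)
  out[ok] <- rowSums((Bu %*% coef) * Bv)
  out
}

# Physical coordinates of all lattice points, as nu*nv vectors (u fastest).
.grid_xy <- function(grid) {
  list(x = rep(grid$gu + grid$origin[1], times = grid$nv),
       y = rep(grid$gv + grid$origin[2], each = grid$nu))
}

#' Solve a steady diffusion (Poisson) problem by collocation
#'
#' Collocates `lap(u) = f` at the interior Greville points with homogeneous
#' Dirichlet values at boundary points, and solves for the spline
#' coefficients directly. Used for convergence verification of the
#' collocation operators.
#'
#' @param grid a `collocation_grid`.
#' @param f `nu x nv` matrix of right-hand-side values at the lattice.
#' @return `nu x nv` matrix of solution values at the lattice.
#' @export
solve_steady_diffusion <- function(grid, f) {
  nu <- grid$nu; nv <- grid$nv
  L <- Matrix::kronecker(Matrix::Matrix(grid$Nv, sparse = TRUE),
                         Matrix::Matrix(grid$D2u, sparse = TRUE)) +
       Matrix::kronecker(Matrix::Matrix(grid$D2v, sparse = TRUE),
                         Matrix::Matrix(grid$Nu, sparse = TRUE))
  N2 <- collocation_operator(grid, "N")
  b <- as.vector(f)
  ii <- rep(seq_len(nu), times = nv)
  jj <- rep(seq_len(nv), each = nu)
  bdry <- ii == 1 | ii == nu | jj == 1 | jj == nv
  A <- L
  A[bdry, ] <- N2[bdry, ]
  b[bdry] <- 0
  coef <- Matrix::solve(A, b)
  matrix(as.vector(N2 %*% coef), nu, nv)
}
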