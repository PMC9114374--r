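# Multi-resolution domain extension: when a neurite tip approaches the
# boundary, the knot lattice is enlarged by 10 points on the approached
# side(s), all fields are transferred through their spline interpolants
# (values at surviving collocation points are preserved to interpolation
# accuracy), and new points get extracellular values.

EXTEND_WIDTH <- 10L

#' Extend the computational domain by fixed widths
#'
#' Low-level extension: enlarges the spline space by the given number of
#' knot spans per side, transfers all state fields by evaluating their
#' spline interpolants at the new Greville lattice (exact at surviving
#' points), fills newly uncovered points with extracellular values
#' (`phi = 0`, `c_tub = 0`, `temp = T_init`), and regenerates theta from
#' the position-keyed noise hash, so successive extensions commute.
#'
#' @param state a `neuron_state`.
#' @param grid a `collocation_grid`.
#' @param params a [neuron_params()] object.
#' @param widths integer `c(left, right, bottom, top)` in knot spans.
#' @return list with elements `state` and `grid`.
#' @export
extend_grid <- function(state, grid, params, widths) {
  widths <- as.integer(widths)
  stopifnot(length(widths) == 4, all(widths >= 0))
  if (all(widths == 0)) return(list(state = state, grid = grid))
  sp <- grid$spacing
  new_grid <- build_collocation_grid(
    grid$nu + widths[1] + widths[2],
    grid$nv + widths[3] + widths[4],
    degree = grid$degree, spacing = sp,
    origin = c(grid$origin[1] - widths[1] * sp,
               grid$origin[2] - widths[3] * sp),
    index_origin = c(grid$index_origin[1] - widths[1],
                     grid$index_origin[2] - widths[3]))
  xy <- .grid_xy(new_grid)
  tr <- function(values, fill) {
    matrix(.evaluate_field_at(grid, values, xy$x, xy$y, fill = fill),
           new_grid$nu, new_grid$nv)
  }
  st <- state
  st$phi <- tr(state$phi, 0)
  st$phi0 <- tr(state$phi0, 0)
  st$c_tub <- tr(state$c_tub, 0)
  st$temp <- tr(state$temp, params$T_init)
  st$theta <- .theta_field(new_grid, params$rng_seed)
  gtx <- grid_derivative(new_grid, st$theta, "x")
  gty <- grid_derivative(new_grid, st$theta, "y")
  st$grad_theta_mag <- sqrt(gtx^2 + gty^2)
  st$E_field <- matrix(0, new_grid$nu, new_grid$nv)
  st$src <- tubulin_source(st, new_grid, params)
  st$neuron_labels <- label_components(
    st$phi, params$phi_threshold,
    centers = .centers_lattice(st, new_grid))
  # transfer verification: surviving collocation points must keep their
  # field values, and the cell region its component count
  su <- match(round(grid$gu + grid$origin[1], 9),
              round(new_grid$gu + new_grid$origin[1], 9))
  sv <- match(round(grid$gv + grid$origin[2], 9),
              round(new_grid$gv + new_grid$origin[2], 9))
  ou <- which(!is.na(su)); ov <- which(!is.na(sv))
  terr <- max(abs(st$phi[su[ou], sv[ov]] - state$phi[ou, ov]),
              abs(st$c_tub[su[ou], sv[ov]] - state$c_tub[ou, ov]))
  ncomp <- function(phi) {
    if (!any(phi > params$phi_threshold)) return(0L)
    length(setdiff(unique(as.vector(
      label_components(phi, params$phi_threshold))), 0L))
  }
  list(state = st, grid = new_grid, transfer_error = terr,
       components_before = ncomp(state$phi),
       components_after = ncomp(st$phi))
}

# soma centers in lattice index coordinates of a grid
.centers_lattice <- function(state, grid) {
  cbind(
    vapply(state$centers[, 1] - grid$origin[1],
           function(x) which.min(abs(grid$gu - x)), numeric(1)),
    vapply(state$centers[, 2] - grid$origin[2],
           function(y) which.min(abs(grid$gv - y)), numeric(1)))
}

#' Extend the domain when a tip nears the boundary
#'
#' Checks every detected tip against the boundary margin and extends the
#' flagged side(s) by 10 grid points (or all four sides if
#' `params$extend_all_directions`). With no tip near the boundary the
#' state and grid are returned unchanged.
#'
#' @param state a `neuron_state`.
#' @param grid a `collocation_grid`.
#' @param tips a `tip_set` (lattice indices `ix`, `iy`).
#' @param params a [neuron_params()] object (fields `extension_margin`,
#'   `extend_all_directions`).
#' @return list with elements `state`, `grid` and `extended`, a logical
#'   4-vector (left, right, bottom, top).
#' @export
extend_domain <- function(state, grid, tips, params = neuron_params()) {
  flags <- c(left = FALSE, right = FALSE, bottom = FALSE, top = FALSE)
  m <- params$extension_margin
  if (!is.null(tips) && nrow(tips) > 0) {
    flags["left"] <- any(tips$ix <= m)
    flags["right"] <- any(tips$ix > grid$nu - m)
    flags["bottom"] <- any(tips$iy <= m)
    flags["top"] <- any(tips$iy > grid$nv - m)
  }
  if (any(flags) && params$extend_all_directions) flags[] <- TRUE
  if (!any(flags)) {
    return(list(state = state, grid = grid, extended = flags))
  }
  out <- extend_grid(state, grid, params, widths = EXTEND_WIDTH * flags)
  c(out, list(extended = flags))
}
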