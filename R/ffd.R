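# Free-form deformation on a uniform cubic B-spline control lattice.
#
# The displacement at x is the tensor-product interpolation of the 4x4x4
# neighbouring control displacements: with t = (x - origin)/delta and
# u = t - floor(t),
#   D(x) = sum_{l,m,n=0..3} B_l(u) B_m(v) B_n(w) Phi[floor(t)+l, ...]
# (1-based control indices; control j sits at origin + (j-1) delta).  A point
# is inside the lattice support when floor(t) >= 1 and floor(t)+3 <= n on
# every axis, i.e. the lattice needs a one-cell margin around the deformed
# region.

# l-th uniform cubic B-spline basis, l = 0..3, u in [0,1)
bspline_b <- function(l, u) {
  switch(l + 1L,
         (1 - u)^3 / 6,
         (3 * u^3 - 6 * u^2 + 4) / 6,
         (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
         u^3 / 6)
}

#' Free-form deformation control lattice
#'
#' @param origin world position (mm) of control point (1,1,1).
#' @param spacing uniform control spacing delta (mm).
#' @param dims integer lattice size per axis.
#' @param coef control displacements, array `dims x 3` (mm); zero if omitted.
#' @return an `ffd_grid` object.
#' @export
ffd_grid <- function(origin, spacing, dims, coef = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 4), spacing > 0)
  if (is.null(coef)) coef <- array(0, dim = c(dims, 3L))
  stopifnot(all(dim(coef) == c(dims, 3L)))
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dims = dims, coef = coef),
            class = "ffd_grid")
}

#' @export
print.ffd_grid <- function(x, ...) {
  cat(sprintf("ffd_grid: %s control points, spacing %g mm, max |disp| %.4g mm\n",
              paste(x$dims, collapse = " x "), x$spacing, max(abs(x$coef))))
  invisible(x)
}

# smallest lattice whose B-spline support covers the box [lo, hi]
ffd_lattice_covering <- function(lo, hi, spacing) {
  origin <- lo - spacing
  dims <- as.integer(ceiling((hi - origin) / spacing) + 4L)
  list(origin = origin, spacing = spacing, dims = pmax(dims, 4L))
}

# per-point cell indices and local coordinates; stops on unsupported points
# unless clamp = TRUE (clamped cells with polynomial extrapolation, used by
# inverse mapping where far-away points are legitimate)
ffd_locate <- function(grid, pts, what = "point", clamp = FALSE) {
  t <- sweep(sweep(pts, 2, grid$origin), 2, grid$spacing, "/")
  cell <- floor(t)
  if (clamp) {
    # constant extension outside the support: clamp both the cell and the
    # local coordinate, so the field stays bounded (polynomial extrapolation
    # diverges and would break fixed-point inversion)
    for (a in 1:3) cell[, a] <- pmin(pmax(cell[, a], 1), grid$dims[a] - 3L)
    return(list(cell = cell, u = pmin(pmax(t - cell, 0), 1)))
  } else {
    bad <- cell[, 1] < 1 | cell[, 1] + 3 > grid$dims[1] |
      cell[, 2] < 1 | cell[, 2] + 3 > grid$dims[2] |
      cell[, 3] < 1 | cell[, 3] + 3 > grid$dims[3]
    if (any(bad)) {
      w <- which(bad)[1]
      stop(sprintf("%s (%s) is outside the FFD lattice support",
                   what, paste(signif(pts[w, ], 5), collapse = ", ")))
    }
  }
  list(cell = cell, u = t - cell)
}

#' Evaluate the FFD displacement at points
#'
#' @param grid an [ffd_grid()].
#' @param pts n x 3 matrix of points (mm) inside the lattice support.
#' @param clamp allow points outside the support (clamped extrapolation).
#' @return n x 3 matrix of displacements (mm).
#' @export
ffd_displacement <- function(grid, pts, clamp = FALSE) {
  pts <- rbind(pts)
  loc <- ffd_locate(grid, pts, clamp = clamp)
  n <- nrow(pts)
  d <- grid$dims
  bx <- lapply(0:3, function(l) bspline_b(l, loc$u[, 1]))
  by <- lapply(0:3, function(l) bspline_b(l, loc$u[, 2]))
  bz <- lapply(0:3, function(l) bspline_b(l, loc$u[, 3]))
  out <- matrix(0, n, 3)
  nxy <- d[1] * d[2]
  base <- loc$cell[, 1] + d[1] * (loc$cell[, 2] - 1) + nxy * (loc$cell[, 3] - 1)
  cf <- matrix(grid$coef, ncol = 3)
  for (l in 0:3) for (m in 0:3) for (q in 0:3) {
    w <- bx[[l + 1]] * by[[m + 1]] * bz[[q + 1]]
    idx <- base + l + d[1] * m + nxy * q
    out <- out + w * cf[idx, , drop = FALSE]
  }
  out
}

#' Apply an FFD to points
#' @param grid an [ffd_grid()].
#' @param pts n x 3 matrix (mm).
#' @return displaced points `pts + D(pts)`.
#' @export
ffd_transform <- function(grid, pts) {
  pts <- rbind(pts)
  pts + ffd_displacement(grid, pts)
}

# sparse tensor-product design matrix A (n x prod(dims)); A %*% coef = disp
ffd_design_matrix <- function(grid, pts) {
  loc <- ffd_locate(grid, pts)
  n <- nrow(pts)
  d <- grid$dims
  nxy <- d[1] * d[2]
  base <- loc$cell[, 1] + d[1] * (loc$cell[, 2] - 1) + nxy * (loc$cell[, 3] - 1)
  bx <- lapply(0:3, function(l) bspline_b(l, loc$u[, 1]))
  by <- lapply(0:3, function(l) bspline_b(l, loc$u[, 2]))
  bz <- lapply(0:3, function(l) bspline_b(l, loc$u[, 3]))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (l in 0:3) for (m in 0:3) for (q in 0:3) {
    ii <- c(ii, seq_len(n))
    jj <- c(jj, base + l + d[1] * m + nxy * q)
    xx <- c(xx, bx[[l + 1]] * by[[m + 1]] * bz[[q + 1]])
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, prod(d)))
}

#' Fit an FFD to scattered displacements
#'
#' Least-squares fit of control displacements to scattered point
#' displacements with a small ridge penalty damping the unconstrained
#' control points (the scattered-data-interpolation view of non-rigid
#' registration).
#'
#' @param pts n x 3 points (mm) inside the lattice support.
#' @param disp n x 3 target displacements (mm).
#' @param lattice lattice skeleton: an [ffd_grid()] (its `coef` is ignored)
#'   or the result of an internal covering constructor.
#' @param lambda ridge damping on control displacements; the objective is
#'   the mean squared residual plus `lambda * |coef|^2`, so the damping is
#'   independent of the number of points and pulls unconstrained control
#'   points to zero.
#' @return an [ffd_grid()] with fitted coefficients; attribute
#'   `residual_rms` holds the fit residual (mm).
#' @export
fit_ffd_scattered <- function(pts, disp, lattice, lambda = 1e-6) {
  pts <- rbind(pts); disp <- rbind(disp)
  if (nrow(pts) == 0) stop("no points to fit")
  stopifnot(nrow(pts) == nrow(disp))
  if (!inherits(lattice, "ffd_grid"))
    lattice <- ffd_grid(lattice$origin, lattice$spacing, lattice$dims)
  A <- ffd_design_matrix(lattice, pts)
  # the mean displacement is represented exactly (partition of unity) and
  # carried outside the ridge, so translations are reproduced unbiased and
  # unconstrained control points relax to the mean rather than to zero
  dbar <- colMeans(disp)
  AtA <- Matrix::crossprod(A) + (lambda * nrow(pts)) * Matrix::Diagonal(ncol(A))
  Atb <- Matrix::crossprod(A, sweep(disp, 2, dbar))
  cf <- sweep(as.matrix(Matrix::solve(AtA, Atb)), 2, dbar, "+")
  grid <- ffd_grid(lattice$origin, lattice$spacing, lattice$dims,
                   array(cf, dim = c(lattice$dims, 3L)))
  res <- as.matrix(A %*% cf) - disp
  attr(grid, "residual_rms") <- sqrt(mean(rowSums(res^2)))
  grid
}

#' Refine an FFD to a finer control spacing
#'
#' Produces a finer lattice whose induced deformation reproduces the coarse
#' deformation over its support (sampled densely and re-fitted; constants,
#' e.g. translation fields, are reproduced exactly up to solver tolerance).
#'
#' @param coarse an [ffd_grid()].
#' @param new_spacing finer control spacing (mm), must be `< coarse$spacing`.
#' @return an [ffd_grid()] at the new spacing; attribute `max_deviation`
#'   reports the max abs deviation from the coarse field at check points.
#' @export
refine_ffd <- function(coarse, new_spacing) {
  if (new_spacing >= coarse$spacing)
    stop("new_spacing must be smaller than the current spacing")
  lo <- coarse$origin + coarse$spacing
  hi <- coarse$origin + (coarse$dims - 3) * coarse$spacing
  lat <- ffd_lattice_covering(lo, hi, new_spacing)
  # sample half the fine control spacing, capped to keep the fit tractable
  stepv <- pmax(new_spacing / 2, (hi - lo) / 64)
  sx <- seq(lo[1], hi[1], by = stepv[1]); sy <- seq(lo[2], hi[2], by = stepv[2])
  sz <- seq(lo[3], hi[3], by = stepv[3])
  pts <- as.matrix(expand.grid(sx, sy, sz))
  disp <- ffd_displacement(coarse, pts)
  fine <- fit_ffd_scattered(pts, disp, lat, lambda = 1e-10)
  chk <- pts[seq(1, nrow(pts), length.out = min(200, nrow(pts))), , drop = FALSE]
  dev <- max(abs(ffd_displacement(fine, chk) - ffd_displacement(coarse, chk)))
  attr(fine, "max_deviation") <- dev
  fine
}
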