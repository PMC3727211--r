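# Hierarchical non-rigid ICP over B-spline free-form deformations: the
# atlas-registration engine. Correspondences are closest points on the
# target surface; each schedule level re-solves the scattered-data
# interpolation problem for the total displacement on its own lattice, the
# coarser level's solution providing the starting correspondences.
#
# The deformation is represented in a canonical frame attached to the
# target mesh (centroid + principal axes, deterministic sign convention),
# so rigidly transforming both meshes transforms the recovered deformation
# covariantly.

canonical_frame <- function(mesh) {
  v <- mesh$vertices
  ctr <- colMeans(v)
  ev <- eigen(stats::cov(v), symmetric = TRUE)
  V <- ev$vectors
  for (c0 in 1:3) {
    w <- which.max(abs(V[, c0]))
    if (V[w, c0] < 0) V[, c0] <- -V[, c0]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  list(center = ctr, axes = V)
}

to_frame <- function(frame, pts) sweep(rbind(pts), 2, frame$center) %*% frame$axes
from_frame <- function(frame, pts) sweep(rbind(pts) %*% t(frame$axes), 2,
                                         frame$center, "+")

#' Non-rigid ICP surface registration over hierarchical FFDs
#'
#' Registers a source mesh onto a target mesh coarse-to-fine: at each FFD
#' control-spacing level, alternate (a) closest-point correspondence from
#' the deformed source vertices to the target surface, (b) a damped
#' least-squares fit of the control displacements to the correspondence
#' displacements, until the RMSE change falls below `tol` or `max_iter`.
#' Accuracy per level is the root-mean-square source-to-target surface
#' distance. Meshes should be similarity-aligned first (see
#' [fit_similarity_landmarks()]).
#'
#' @param source,target [surface_mesh()]es; the source is deformed onto the
#'   target.
#' @param schedule_mm decreasing FFD control spacings (mm).
#' @param max_iter iteration cap per level.
#' @param tol stop when the per-iteration RMSE improvement is below this (mm).
#' @param lambda ridge damping of the scattered fit (suppresses local
#'   oscillation of the deformation).
#' @param max_source_points deterministic subsample cap on source vertices.
#' @return an `icp_registration` with per-level grids and RMSEs;
#'   methods: [print()], [summary()], [predict()] (maps source-space
#'   points), [plot()] (RMSE against level).
#' @export
icp_nonrigid <- function(source, target, schedule_mm = c(20, 10, 5, 3, 1, 0.5),
                         max_iter = 50L, tol = 1e-3, lambda = 1e-6,
                         max_source_points = 2500L) {
  stopifnot(inherits(source, "surface_mesh"), inherits(target, "surface_mesh"))
  if (any(diff(schedule_mm) >= 0)) stop("schedule must be strictly decreasing")
  frame <- canonical_frame(target)
  tv <- to_frame(frame, target$vertices)
  tmesh <- surface_mesh(tv, target$faces)
  X <- to_frame(frame, subsample_vertices(source, max_source_points))

  cp0 <- closest_surface_points(X, tmesh)
  rmse0 <- sqrt(mean(cp0$dist^2))
  span <- max(apply(tv, 2, max) - apply(tv, 2, min))
  if (rmse0 > span)
    stop(sprintf(paste0("meshes do not overlap (initial RMSE %.1f mm > target",
                        " span %.1f mm); run a rigid/similarity",
                        " pre-registration first"), rmse0, span))

  bbox_lo <- pmin(apply(X, 2, min), apply(tv, 2, min))
  bbox_hi <- pmax(apply(X, 2, max), apply(tv, 2, max))
  P <- X
  grids <- vector("list", length(schedule_mm))
  rmse_levels <- numeric(length(schedule_mm))
  iters <- integer(length(schedule_mm))
  prev_grid <- NULL
  prev_rmse <- rmse0
  for (li in seq_along(schedule_mm)) {
    delta <- schedule_mm[li]
    lat <- ffd_lattice_covering(bbox_lo - 1, bbox_hi + 1, delta)
    best_rmse <- prev_rmse; best_grid <- prev_grid; best_P <- P
    last <- Inf
    it <- 0L
    repeat {
      it <- it + 1L
      cp <- closest_surface_points(P, tmesh)
      g <- fit_ffd_scattered(X, cp$points - X, lat, lambda = lambda)
      Pn <- X + ffd_displacement(g, X, clamp = TRUE)
      r <- sqrt(mean(closest_surface_points(Pn, tmesh)$dist^2))
      if (r < best_rmse) { best_rmse <- r; best_grid <- g; best_P <- Pn }
      if (it >= max_iter || abs(last - r) < tol) break
      last <- r
      P <- Pn
    }
    iters[li] <- it
    grids[[li]] <- if (is.null(best_grid)) fit_ffd_scattered(
      X, matrix(0, nrow(X), 3), lat, lambda = lambda) else best_grid
    rmse_levels[li] <- best_rmse
    P <- best_P
    prev_grid <- grids[[li]]
    prev_rmse <- best_rmse
  }
  structure(list(frame = frame, grids = grids, schedule = schedule_mm,
                 rmse = rmse_levels, initial_rmse = rmse0,
                 iterations = iters, n_source = nrow(X),
                 lambda = lambda, tol = tol),
            class = "icp_registration")
}

#' @export
print.icp_registration <- function(x, ...) {
  cat("Non-rigid ICP registration over hierarchical FFDs\n")
  cat(sprintf("  source points: %d, initial RMSE %.4f mm\n",
              x$n_source, x$initial_rmse))
  tab <- data.frame(spacing_mm = x$schedule, iterations = x$iterations,
                    rmse_mm = signif(x$rmse, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.icp_registration <- function(object, ...) {
  cat(sprintf("Final RMSE: %.4f mm (%.1f%% of initial)\n",
              object$rmse[length(object$rmse)],
              100 * object$rmse[length(object$rmse)] / object$initial_rmse))
  print(object)
  invisible(object)
}

#' @export
plot.icp_registration <- function(x, ...) {
  graphics::plot(seq_along(x$schedule), x$rmse, type = "b",
                 xaxt = "n", xlab = "FFD control spacing (mm)",
                 ylab = "RMSE (mm)", main = "Coarse-to-fine registration", ...)
  graphics::axis(1, at = seq_along(x$schedule), labels = x$schedule)
  invisible(x)
}

#' Map source-space points through a fitted registration
#'
#' @param object an `icp_registration`.
#' @param newdata n x 3 matrix of points (mm) in the source mesh space.
#' @param level schedule level to use (default: finest).
#' @param ... unused.
#' @return mapped points (mm) in target space.
#' @export
predict.icp_registration <- function(object, newdata,
                                     level = length(object$grids), ...) {
  pc <- to_frame(object$frame, newdata)
  from_frame(object$frame, ffd_transform(object$grids[[level]], pc))
}

# inverse map (target space -> source space) by fixed-point iteration
icp_inverse_points <- function(object, pts, level = length(object$grids),
                               tol = 0.05, max_iter = 60L) {
  g <- object$grids[[level]]
  y <- to_frame(object$frame, pts)
  z <- y
  for (it in seq_len(max_iter)) {
    znew <- y - ffd_displacement(g, z, clamp = TRUE)
    step <- max(abs(znew - z))
    z <- znew
    if (step < tol / 4) break
  }
  # invertibility is judged inside the lattice support only; outside it the
  # field continues as a bounded constant extension and the pulled-back
  # points are far from the registered structure anyway
  lo <- g$origin + g$spacing
  hi <- g$origin + (g$dims - 3) * g$spacing
  ins <- z[, 1] >= lo[1] & z[, 1] <= hi[1] & z[, 2] >= lo[2] & z[, 2] <= hi[2] &
    z[, 3] >= lo[3] & z[, 3] <= hi[3]
  if (any(ins)) {
    zi <- z[ins, , drop = FALSE]
    resid <- max(sqrt(rowSums((zi + ffd_displacement(g, zi, clamp = TRUE) -
                                 y[ins, , drop = FALSE])^2)))
    if (resid > tol)
      stop(sprintf("deformation not invertible at tolerance %.3g mm (worst residual %.3g mm)",
                   tol, resid))
  }
  from_frame(object$frame, z)
}
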