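#' Rectilinear (graded) grid
#'
#' Per-axis strictly increasing cell-edge coordinates in mm. Cell centres
#' are edge midpoints; grids may be uniform or graded (multiscale).
#'
#' @param xe,ye,ze numeric edge coordinate vectors (mm), strictly increasing.
#' @param roi optional `list(lo=, hi=)` recording the fine region.
#' @return a `rectilinear_grid` object.
#' @export
rectilinear_grid <- function(xe, ye, ze, roi = NULL) {
  for (e in list(xe, ye, ze))
    if (length(e) < 2 || any(diff(e) <= 0))
      stop("edge arrays must be strictly increasing with >= 1 cell")
  structure(list(edges = list(x = xe, y = ye, z = ze), roi = roi),
            class = "rectilinear_grid")
}

#' @export
print.rectilinear_grid <- function(x, ...) {
  n <- grid_dims(x)
  cat(sprintf("rectilinear_grid: %d x %d x %d cells (%s total), cell size %.3g..%.3g mm\n",
              n[1], n[2], n[3], format(prod(n), big.mark = ","),
              min(unlist(lapply(x$edges, diff))),
              max(unlist(lapply(x$edges, diff)))))
  invisible(x)
}

#' @export
#' @rdname rectilinear_grid
#' @param grid a `rectilinear_grid`.
grid_dims <- function(grid)
  vapply(grid$edges, function(e) length(e) - 1L, integer(1))

# per-axis cell sizes / centres
grid_cell_sizes <- function(grid) lapply(grid$edges, diff)
grid_centers <- function(grid)
  lapply(grid$edges, function(e) (e[-1] + e[-length(e)]) / 2)

# all cell centres, n x 3 (large!)
grid_center_points <- function(grid) {
  cc <- grid_centers(grid)
  n <- grid_dims(grid)
  cbind(rep(cc$x, times = n[2] * n[3]),
        rep(rep(cc$y, each = n[1]), times = n[3]),
        rep(cc$z, each = n[1] * n[2]))
}

#' Uniform grid over a box
#' @param lo,hi box corners (mm).
#' @param h cell size (mm).
#' @return a [rectilinear_grid()].
#' @export
uniform_grid <- function(lo, hi, h) {
  mk <- function(a, b) {
    n <- max(1L, ceiling((b - a) / h - 1e-9))
    a + h * (0:n)
  }
  rectilinear_grid(mk(lo[1], hi[1]), mk(lo[2], hi[2]), mk(lo[3], hi[3]))
}

#' Build a multiscale simulation grid
#'
#' Uniform fine cells across the region of interest, geometric grading
#' (adjacent-cell ratio bounded) out to coarse cells in the rest of the
#' domain — the graded-rectilinear-mesh realization of a fine grid embedded
#' in a coarse head grid.
#'
#' @param head_extent `list(lo=, hi=)` domain box (mm).
#' @param roi `list(lo=, hi=)` fine box (mm), inside the domain; a
#'   zero-volume roi yields a uniform coarse grid.
#' @param fine_mm fine cell size (default 0.2 mm).
#' @param coarse_mm coarse cell size (default 1 mm).
#' @param grading_ratio max adjacent-cell size ratio.
#' @return a [rectilinear_grid()] with the roi recorded.
#' @export
build_multiscale_grid <- function(head_extent, roi, fine_mm = 0.2,
                                  coarse_mm = 1.0, grading_ratio = 1.5) {
  lo <- head_extent$lo; hi <- head_extent$hi
  degenerate <- any(roi$hi <= roi$lo)
  if (!degenerate && (any(roi$lo < lo) || any(roi$hi > hi)))
    stop("roi extends outside the domain")
  ax <- function(a) {
    if (degenerate) {
      n <- max(1L, round((hi[a] - lo[a]) / coarse_mm))
      return(seq(lo[a], hi[a], length.out = n + 1))
    }
    nf <- max(1L, round((roi$hi[a] - roi$lo[a]) / fine_mm))
    fe <- roi$lo[a] + (roi$hi[a] - roi$lo[a]) / nf * (0:nf)
    grow <- function(dist) {
      if (dist <= 1e-9) return(numeric(0))
      sizes <- numeric(0); s <- fine_mm
      while (sum(sizes) < dist - 1e-12) {
        s <- min(s * grading_ratio, coarse_mm)
        sizes <- c(sizes, s)
      }
      sizes <- c(sizes, rep(coarse_mm, 2))
      # pick the truncation whose uniform rescale best respects the ratio cap
      best <- NULL; best_score <- Inf
      for (k in seq(max(1, length(sizes) - 4), length(sizes))) {
        s2 <- sizes[seq_len(k)] * (dist / sum(sizes[seq_len(k)]))
        r <- c(s2[1] / fine_mm, if (k > 1) s2[-1] / s2[-k])
        score <- max(r, 1 / r)
        if (score < best_score) { best_score <- score; best <- s2 }
      }
      best
    }
    lsz <- rev(grow(roi$lo[a] - lo[a]))
    rsz <- grow(hi[a] - roi$hi[a])
    c(roi$lo[a] - rev(cumsum(rev(lsz))), fe, roi$hi[a] + cumsum(rsz))
  }
  rectilinear_grid(ax(1), ax(2), ax(3), roi = if (degenerate) NULL else roi)
}

#' Courant-limited FDTD timestep for a grid
#'
#' `dt = safety / (c * sqrt(1/dx_min^2 + 1/dy_min^2 + 1/dz_min^2))` — the
#' explicit-leapfrog stability bound, proportional to the smallest cell.
#'
#' @param grid a [rectilinear_grid()].
#' @param safety Courant safety factor (default 0.99).
#' @return timestep in seconds.
#' @export
courant_dt <- function(grid, safety = 0.99) {
  h <- vapply(grid_cell_sizes(grid), min, numeric(1)) * 1e-3  # mm -> m
  safety / (299792458 * sqrt(sum(1 / h^2)))
}
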