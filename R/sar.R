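# Specific absorption rate: raw per-cell maps, IEEE-style cube-grown 1 g /
# 10 g mass averages, whole-head SAR, normalization to the no-implant
# reference, electrode-line profiles and coarse-vs-multiscale comparison
# statistics. E is stored as a peak phasor, so SAR = sigma |E|^2 / (2 rho).

#' Raw (per-cell) SAR map
#'
#' `SAR = sigma |E|^2 / (2 rho)` with `E` the peak phasor amplitude. Air and
#' implant cells are masked to zero: SAR is not computed in the space
#' occupied by the device.
#'
#' @param field a `field_volume` from [run_fdtd()].
#' @param materials the matching [assign_materials()] grid.
#' @return a `sar_map` with the raw SAR array (W/kg), peak and peak location.
#' @export
local_sar <- function(field, materials) {
  if (!identical(grid_dims(field$grid), grid_dims(materials$grid)))
    stop("field and material grids do not match")
  if (any(materials$rho[materials$tissue] <= 0))
    stop("non-positive density in tissue cells")
  mag2 <- Mod(field$Ex)^2 + Mod(field$Ey)^2 + Mod(field$Ez)^2
  sar <- array(0, dim(mag2))
  sel <- materials$tissue
  sar[sel] <- materials$sigma[sel] * mag2[sel] / (2 * materials$rho[sel])
  new_sar_map(sar, materials, kind = "raw")
}

new_sar_map <- function(sar, materials, kind, valid = NULL) {
  cc <- grid_centers(materials$grid)
  if (is.null(valid)) valid <- materials$tissue
  peak <- if (any(valid)) max(sar[valid]) else NA_real_
  loc <- if (any(valid)) {
    w <- which(valid & sar == peak)[1] - 1L
    n <- grid_dims(materials$grid)
    c(cc$x[w %% n[1] + 1L], cc$y[(w %/% n[1]) %% n[2] + 1L],
      cc$z[w %/% (n[1] * n[2]) + 1L])
  } else rep(NA_real_, 3)
  structure(list(sar = sar, kind = kind, grid = materials$grid,
                 valid = valid, peak = peak, peak_location = loc),
            class = "sar_map")
}

#' @export
print.sar_map <- function(x, ...) {
  cat(sprintf("sar_map (%s): peak %.4g W/kg at (%s) mm, %d valid cells\n",
              x$kind, x$peak, paste(signif(x$peak_location, 4), collapse = ", "),
              sum(x$valid)))
  invisible(x)
}

# cell masses (kg) and absorbed powers (W) on the material grid
cell_mass_power <- function(raw, materials) {
  h <- grid_cell_sizes(materials$grid)
  n <- grid_dims(materials$grid)
  volm3 <- array(outer(outer(h$x, h$y), h$z), n) * 1e-9  # mm^3 -> m^3
  mass <- ifelse(materials$tissue, materials$rho * volm3, 0)
  power <- raw$sar * mass
  list(mass = mass, power = power, vol = volm3)
}

#' Mass-averaged SAR (1 g / 10 g style)
#'
#' For every tissue cell, the smallest centred cube containing at least the
#' target tissue mass is grown (air and implant carry no mass and no power);
#' the averaged SAR is enclosed power over enclosed mass. Cells whose cube
#' cannot reach the target within the domain are flagged invalid.
#'
#' @param raw a raw `sar_map` from [local_sar()].
#' @param materials the matching material grid.
#' @param target_mass_g averaging mass in grams (1 or 10, typically).
#' @return a `sar_map` of kind `avg_<mass>g`.
#' @export
averaged_sar <- function(raw, materials, target_mass_g) {
  mp <- cell_mass_power(raw, materials)
  cc <- grid_centers(materials$grid)
  res <- .cube_avg_sar_cpp(grid_dims(materials$grid),
                           cc$x, cc$y, cc$z,
                           as.numeric(mp$mass), as.numeric(mp$power),
                           as.integer(materials$tissue),
                           target_mass_g / 1000)
  n <- grid_dims(materials$grid)
  valid <- array(res$valid, n)
  if (!any(valid)) stop("no cell can accumulate the target mass")
  avg <- array(ifelse(is.na(res$avg), 0, res$avg), n)
  new_sar_map(avg, materials, kind = sprintf("avg_%gg", target_mass_g),
              valid = valid)
}

#' Whole-head (whole-phantom) average SAR
#'
#' Total absorbed power over total tissue mass.
#' @param raw a raw `sar_map`.
#' @param materials the matching material grid.
#' @return SAR_w in W/kg.
#' @export
whole_head_sar <- function(raw, materials) {
  mp <- cell_mass_power(raw, materials)
  m <- sum(mp$mass)
  if (m <= 0) stop("no tissue mass")
  sum(mp$power) / m
}

#' Normalize field sets to a reference whole-head SAR
#'
#' One field scale factor `sqrt(target / reference_sar_w)` is applied to all
#' runs (implant and no-implant alike), so that the no-implant whole-head
#' SAR equals the target exactly.
#'
#' @param fields list of `field_volume`s to scale.
#' @param reference_sar_w whole-head SAR of the no-implant reference run.
#' @param target target SAR_w in W/kg (default 3.2).
#' @return list with `fields` (scaled) and `scale` (the field factor).
#' @export
normalize_to_reference <- function(fields, reference_sar_w, target = 3.2) {
  if (!is.finite(reference_sar_w) || reference_sar_w <= 0)
    stop("reference whole-head SAR must be positive")
  sc <- sqrt(target / reference_sar_w)
  list(fields = lapply(fields, scale_field, factor = sc), scale = sc)
}

# trilinear interpolation of a cell-centred array at world points
interp_cells <- function(arr, grid, pts) {
  cc <- grid_centers(grid)
  n <- grid_dims(grid)
  pts <- rbind(pts)
  out <- numeric(nrow(pts))
  loc <- function(cv, x) {
    i0 <- findInterval(x, cv)
    i0 <- pmin(pmax(i0, 1L), length(cv) - 1L)
    w <- (x - cv[i0]) / (cv[i0 + 1] - cv[i0])
    list(i = i0, w = pmin(pmax(w, 0), 1))
  }
  lx <- loc(cc$x, pts[, 1]); ly <- loc(cc$y, pts[, 2]); lz <- loc(cc$z, pts[, 3])
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) lx$w else 1 - lx$w) * (if (dy) ly$w else 1 - ly$w) *
      (if (dz) lz$w else 1 - lz$w)
    idx <- (lx$i + dx) + n[1] * (ly$i + dy - 1L) + n[1] * n[2] * (lz$i + dz - 1L)
    out <- out + w * arr[idx]
  }
  out
}

#' Sample |E| along a line
#'
#' Trilinear samples of the field magnitude between two points.
#'
#' @param field a `field_volume`.
#' @param start,end line endpoints (mm).
#' @param step_mm sample spacing (mm).
#' @return data frame with `s` (arc position, mm), `x`, `y`, `z`, `value`.
#' @export
line_profile <- function(field, start, end, step_mm = 0.1) {
  cc <- grid_centers(field$grid)
  lo <- c(cc$x[1], cc$y[1], cc$z[1])
  hi <- c(cc$x[length(cc$x)], cc$y[length(cc$y)], cc$z[length(cc$z)])
  if (any(start < lo - 1e-9) || any(start > hi + 1e-9) ||
      any(end < lo - 1e-9) || any(end > hi + 1e-9))
    stop("profile line extends outside the grid interior")
  len <- sqrt(sum((end - start)^2))
  s <- seq(0, len, by = step_mm)
  pts <- cbind(start[1] + s / len * (end[1] - start[1]),
               start[2] + s / len * (end[2] - start[2]),
               start[3] + s / len * (end[3] - start[3]))
  val <- interp_cells(field_magnitude(field), field$grid, pts)
  data.frame(s = s, x = pts[, 1], y = pts[, 2], z = pts[, 3], value = val)
}

#' Count profile extrema
#'
#' Strict interior local minima whose value is below `zero_tol` count as
#' zero-minima (field nulls at electrode contacts); maxima are strict local
#' maxima, with endpoints counted when strictly above their neighbour.
#'
#' @param values numeric profile samples (or a [line_profile()] frame).
#' @param zero_tol threshold under which a minimum counts as a zero-minimum.
#' @return list with `n_minima` (zero-minima), `n_maxima`, and indices.
#' @export
count_extrema <- function(values, zero_tol) {
  if (is.data.frame(values)) values <- values$value
  n <- length(values)
  if (n < 3) return(list(n_minima = 0L, n_maxima = 0L,
                         minima = integer(0), maxima = integer(0)))
  mid <- 2:(n - 1)
  is_min <- values[mid] < values[mid - 1] & values[mid] < values[mid + 1]
  minima <- mid[is_min & values[mid] <= zero_tol]
  is_max <- values[mid] > values[mid - 1] & values[mid] > values[mid + 1]
  maxima <- mid[is_max]
  if (values[1] > values[2]) maxima <- c(1L, maxima)
  if (values[n] > values[n - 1]) maxima <- c(maxima, n)
  list(n_minima = length(minima), n_maxima = length(maxima),
       minima = minima, maxima = maxima)
}

#' Compare two field solutions
#'
#' Peak locations are the tissue-cell argmax of |E| on each model's own
#' grid, compared in world mm; probe differences are |E| sampled at shared
#' world points.
#'
#' @param a,b `field_volume`s (e.g. multiscale and coarse models).
#' @param probes n x 3 matrix of probe points (mm), or NULL.
#' @param tissue_a,tissue_b logical arrays marking tissue cells on each
#'   grid (peak search region); defaults to everywhere.
#' @return list with `peak_shift_mm`, per-model peaks, and probe difference
#'   statistics (`mean`, `sd`, per-probe values).
#' @export
compare_models <- function(a, b, probes = NULL,
                           tissue_a = NULL, tissue_b = NULL) {
  peak_of <- function(f, tis) {
    m <- field_magnitude(f)
    if (!is.null(tis)) m[!tis] <- -Inf
    n <- grid_dims(f$grid)
    w <- which.max(m) - 1L
    cc <- grid_centers(f$grid)
    list(value = max(m),
         loc = c(cc$x[w %% n[1] + 1L], cc$y[(w %/% n[1]) %% n[2] + 1L],
                 cc$z[w %/% (n[1] * n[2]) + 1L]))
  }
  pa <- peak_of(a, tissue_a); pb <- peak_of(b, tissue_b)
  out <- list(peak_shift_mm = sqrt(sum((pa$loc - pb$loc)^2)),
              peak_a = pa$value, peak_b = pb$value,
              peak_loc_a = pa$loc, peak_loc_b = pb$loc)
  if (!is.null(probes)) {
    probes <- rbind(probes)
    va <- interp_cells(field_magnitude(a), a$grid, probes)
    vb <- interp_cells(field_magnitude(b), b$grid, probes)
    d <- va - vb
    out$probe_diff <- d
    out$probe_mean <- mean(abs(d))
    out$probe_sd <- stats::sd(abs(d))
  }
  out
}

#' @export
plot.sar_map <- function(x, slice_axis = 3, slice_mm = NULL, ...) {
  cc <- grid_centers(x$grid)
  ax <- cc[[slice_axis]]
  if (is.null(slice_mm)) slice_mm <- x$peak_location[slice_axis]
  k <- which.min(abs(ax - slice_mm))
  sl <- switch(slice_axis, x$sar[k, , ], x$sar[, k, ], x$sar[, , k])
  keep <- setdiff(1:3, slice_axis)
  graphics::image(cc[[keep[1]]], cc[[keep[2]]], sl, asp = 1,
                  xlab = c("x", "y", "z")[keep[1]],
                  ylab = c("x", "y", "z")[keep[2]],
                  main = sprintf("%s SAR, slice at %.1f mm", x$kind, ax[k]),
                  ...)
  invisible(x)
}
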