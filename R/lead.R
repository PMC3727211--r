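# Four-contact DBS lead: a continuous cubic-spline wire with an insulation
# tube swept along it and an array of cylindrical electrode contacts at the
# distal end, connected by the conducting core.

#' Lead specification
#'
#' Geometry of an implanted stimulation lead. Defaults follow a commercial
#' four-contact layout (1.5 mm contacts and gaps, 1.27 mm contact diameter,
#' 1 mm insulation radius); the printed dimensions of the modelled device are
#' not public, so all are overridable.
#'
#' @param control_points n x 3 matrix (mm), ordered proximal to distal
#'   (the last point is the tip); at least 4 points.
#' @param insulation_radius_mm radius of the swept insulation circle.
#' @param n_contacts number of cylindrical contacts.
#' @param contact_length_mm,contact_gap_mm contact length and inter-contact
#'   insulation gap along the arc.
#' @param contact_radius_mm contact radius.
#' @param core_radius_mm radius of the continuous conducting wire core.
#' @param tip_offset_mm arc distance from the distal tip to the first contact.
#' @return a `lead_spec` object.
#' @export
lead_spec <- function(control_points,
                      insulation_radius_mm = 1.0,
                      n_contacts = 4L,
                      contact_length_mm = 1.5,
                      contact_gap_mm = 1.5,
                      contact_radius_mm = 0.635,
                      core_radius_mm = 0.4,
                      tip_offset_mm = 0.5) {
  control_points <- as.matrix(control_points)
  stopifnot(ncol(control_points) == 3, nrow(control_points) >= 4)
  if (insulation_radius_mm <= 0 || contact_radius_mm <= 0 ||
      core_radius_mm <= 0)
    stop("radii must be positive")
  if (contact_gap_mm <= 0) stop("contacts overlap: gap must be positive")
  structure(list(control_points = control_points,
                 insulation_radius = insulation_radius_mm,
                 n_contacts = as.integer(n_contacts),
                 contact_length = contact_length_mm,
                 contact_gap = contact_gap_mm,
                 contact_radius = contact_radius_mm,
                 core_radius = core_radius_mm,
                 tip_offset = tip_offset_mm),
            class = "lead_spec")
}

#' Build the lead geometry from a specification
#'
#' Interpolates the control points with a natural cubic spline (per
#' coordinate, over chord-length parameter), computes an arc-length
#' parameterization by dense sampling, and places the contact intervals from
#' the distal tip. Arc length 0 is the distal tip.
#'
#' @param spec a [lead_spec()].
#' @param samples_per_mm density of the arc-length table.
#' @return a `lead_geometry` with the sampled centerline, cumulative arc
#'   length, and contact intervals (ordered distal to proximal).
#' @export
build_lead <- function(spec, samples_per_mm = 20) {
  cp <- spec$control_points
  chord <- c(0, cumsum(sqrt(rowSums(diff(cp)^2))))
  fx <- stats::splinefun(chord, cp[, 1], method = "natural")
  fy <- stats::splinefun(chord, cp[, 2], method = "natural")
  fz <- stats::splinefun(chord, cp[, 3], method = "natural")
  tt <- seq(0, max(chord), length.out = max(16, ceiling(max(chord) * samples_per_mm)))
  pts <- cbind(fx(tt), fy(tt), fz(tt))
  seg <- sqrt(rowSums(diff(pts)^2))
  s_from_prox <- c(0, cumsum(seg))
  total <- s_from_prox[length(s_from_prox)]
  # arc length measured from the distal tip (last sample)
  s <- total - s_from_prox
  ord <- rev(seq_len(nrow(pts)))
  centerline <- pts[ord, , drop = FALSE]
  arc <- s[ord]

  nc <- spec$n_contacts
  starts <- spec$tip_offset + (seq_len(nc) - 1) * (spec$contact_length + spec$contact_gap)
  ends <- starts + spec$contact_length
  if (max(ends) > total)
    stop(sprintf("contact array (%.2f mm) does not fit along the lead (%.2f mm)",
                 max(ends), total))
  structure(list(centerline = centerline, arc = arc, total_length = total,
                 contacts = cbind(start = starts, end = ends), spec = spec),
            class = "lead_geometry")
}

#' @export
print.lead_geometry <- function(x, ...) {
  cat(sprintf("lead_geometry: length %.2f mm, %d contacts (%.2g mm / %.2g mm gaps), insulation r=%.2g mm\n",
              x$total_length, nrow(x$contacts), x$spec$contact_length,
              x$spec$contact_gap, x$spec$insulation_radius))
  invisible(x)
}

#' Rasterize a lead onto a grid
#'
#' Classifies each cell centre within reach of the centerline: conductor if
#' inside the wire core or inside a contact interval within the contact
#' radius, else insulation if within the insulation radius, else none.
#'
#' @param lead a `lead_geometry` from [build_lead()].
#' @param grid a [rectilinear_grid()].
#' @return integer array on the grid: 0 none, 1 conductor, 2 insulation;
#'   class `implant_overlay`.
#' @export
rasterize_lead <- function(lead, grid) {
  n <- grid_dims(grid)
  cc <- grid_centers(grid)
  rmax <- max(lead$spec$insulation_radius, lead$spec$contact_radius,
              lead$spec$core_radius)
  cl <- lead$centerline
  lo <- apply(cl, 2, min) - rmax; hi <- apply(cl, 2, max) + rmax
  ix <- which(cc$x >= lo[1] & cc$x <= hi[1])
  iy <- which(cc$y >= lo[2] & cc$y <= hi[2])
  iz <- which(cc$z >= lo[3] & cc$z <= hi[3])
  out <- array(0L, n)
  if (!length(ix) || !length(iy) || !length(iz))
    stop("lead does not intersect the grid")
  pts <- as.matrix(expand.grid(x = cc$x[ix], y = cc$y[iy], z = cc$z[iz]))
  # nearest centerline sample (dense sampling; error << cell size)
  nn <- nearest_polyline(pts, cl)
  d <- nn$dist; s <- lead$arc[nn$index]
  contact_zone <- rep(FALSE, length(d))
  for (r in seq_len(nrow(lead$contacts)))
    contact_zone <- contact_zone |
      (s >= lead$contacts[r, 1] & s <= lead$contacts[r, 2])
  cls <- integer(length(d))
  cls[d <= lead$spec$insulation_radius] <- 2L
  cls[contact_zone & d <= lead$spec$contact_radius] <- 1L
  cls[d <= lead$spec$core_radius] <- 1L
  if (!any(cls > 0)) stop("lead does not intersect the grid")
  sub <- array(cls, c(length(ix), length(iy), length(iz)))
  out[ix, iy, iz] <- sub
  structure(out, class = "implant_overlay")
}

# chunked brute-force nearest sample on a polyline point cloud
nearest_polyline <- function(pts, cl, chunk = 20000L) {
  n <- nrow(pts)
  idx <- integer(n); dist <- numeric(n)
  for (a in seq(1, n, by = chunk)) {
    b <- min(a + chunk - 1L, n)
    block <- pts[a:b, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(cl^2), "+") - 2 * block %*% t(cl)
    w <- max.col(-d2, ties.method = "first")   # deterministic tie-break
    idx[a:b] <- w
    dist[a:b] <- sqrt(pmax(0, d2[cbind(seq_len(b - a + 1L), w)]))
  }
  list(index = idx, dist = dist)
}
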