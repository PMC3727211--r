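#' Simulation parameters for the FDTD solver
#'
#' @param frequency drive frequency in Hz (default 128 MHz, the proton
#'   Larmor frequency at 3 T).
#' @param courant_safety Courant safety factor on the stability limit.
#' @param pml_layers CPML thickness in cells (scalar or per-axis length 3;
#'   0 disables an axis, which then has PEC or periodic walls).
#' @param conv_db convergence threshold: per-period relative change of the
#'   in-tissue electric energy, in dB (negative).
#' @param max_periods hard cap on simulated periods.
#' @param ramp_periods raised-cosine source ramp length in periods.
#' @param source a source spec from [make_source()].
#' @param periodic_xy periodic side boundaries in x and y (plane-wave
#'   experiments; requires `pml_layers = c(0, 0, n)`).
#' @return a `simulation_params` object.
#' @export
simulation_params <- function(frequency = 128e6, courant_safety = 0.99,
                              pml_layers = 7L, conv_db = -40,
                              max_periods = 20L, ramp_periods = 2,
                              source = NULL, periodic_xy = FALSE) {
  pml_layers <- rep_len(as.integer(pml_layers), 3L)
  stopifnot(frequency > 0, courant_safety > 0, courant_safety <= 1,
            conv_db < 0, all(pml_layers >= 0))
  if (any(pml_layers > 0 & pml_layers < 4))
    stop("use at least 4 PML layers (or 0 to disable an axis)")
  structure(list(frequency = frequency, courant_safety = courant_safety,
                 pml_layers = pml_layers, conv_db = conv_db,
                 max_periods = as.integer(max_periods),
                 ramp_periods = ramp_periods, source = source,
                 periodic_xy = isTRUE(periodic_xy)),
            class = "simulation_params")
}

#' Idealized RF sources
#'
#' `cp_planewave`: two orthogonal uniform current sheets in phase
#' quadrature on a transverse plane, launching a circularly polarized plane
#' wave along +/-z (the idealization of a birdcage transmit field; requires
#' a uniform grid with periodic side boundaries). `dipole_ring`: a ring of
#' tangential current elements around the phantom with quadrature (azimuth)
#' phasing, the birdcage analog used for head simulations on arbitrary
#' grids.
#'
#' @param kind `"cp_planewave"` or `"dipole_ring"`.
#' @param frequency Hz.
#' @param amplitude drive amplitude (arbitrary units; fields are normalized
#'   downstream against the no-implant whole-head SAR).
#' @param polarization for `cp_planewave`: `"circular"` (default) or
#'   `"linear_x"`/`"linear_y"`.
#' @param z_mm sheet plane or ring plane z (mm).
#' @param center,radii_mm ring centre (x,y, mm) and per-axis radii (mm) for
#'   `dipole_ring`.
#' @param n_dipoles elements on the ring.
#' @param quadrature logical; `FALSE` drives all ring elements in phase
#'   (linear polarization).
#' @param rung_length_mm axial length of each ring element (the elements
#'   are z-directed line currents, like birdcage rungs).
#' @return a `source_spec`.
#' @export
make_source <- function(kind, frequency = 128e6, amplitude = 1,
                        polarization = "circular", z_mm = 0,
                        center = c(0, 0), radii_mm = c(18, 22),
                        n_dipoles = 16L, quadrature = TRUE,
                        rung_length_mm = 28) {
  if (!kind %in% c("cp_planewave", "dipole_ring"))
    stop(sprintf("unknown source kind '%s'", kind))
  structure(list(kind = kind, frequency = frequency, amplitude = amplitude,
                 polarization = polarization, z_mm = z_mm, center = center,
                 radii = radii_mm, n_dipoles = as.integer(n_dipoles),
                 quadrature = isTRUE(quadrature),
                 rung_length = rung_length_mm),
            class = "source_spec")
}

# resolve a source spec into kernel injection lists on a given grid.
# Injection coefficients are per-step E increments; they are scaled by
# dt/eps0 (and by cell volume for point elements) so the physical drive —
# a current density for sheets, a current-element moment for ring dipoles —
# is independent of the grid and timestep.
resolve_source <- function(src, grid, dt) {
  eps0 <- 8.8541878128e-12
  n <- grid_dims(grid)
  cc <- grid_centers(grid)
  comp <- integer(0); si <- integer(0); sj <- integer(0); sk <- integer(0)
  coef <- numeric(0); phase <- numeric(0)
  if (src$kind == "cp_planewave") {
    kz <- which.min(abs(grid$edges$z - src$z_mm)) - 1L  # z node index
    # fixed surface-current density: the injected volume current occupies
    # the dual-cell thickness at the sheet node, so scale by 1/dzd
    hz <- diff(grid$edges$z)
    dzd_m <- 1e-3 * (if (kz == 0) hz[1] / 2
                     else if (kz == length(hz)) hz[kz] / 2
                     else (hz[kz] + hz[kz + 1]) / 2)
    wantx <- src$polarization %in% c("circular", "linear_x")
    wanty <- src$polarization %in% c("circular", "linear_y")
    if (wantx) { # Ex nodes (i=0..nx-1, j=0..ny) on plane kz
      gi <- rep(0:(n[1] - 1L), times = n[2] + 1L)
      gj <- rep(0:n[2], each = n[1])
      comp <- c(comp, rep(0L, length(gi)))
      si <- c(si, gi); sj <- c(sj, gj); sk <- c(sk, rep(kz, length(gi)))
      coef <- c(coef, rep(src$amplitude, length(gi)))
      phase <- c(phase, rep(0, length(gi)))
    }
    if (wanty) { # Ey nodes (i=0..nx, j=0..ny-1), quadrature
      gi <- rep(0:n[1], times = n[2])
      gj <- rep(0:(n[2] - 1L), each = n[1] + 1L)
      comp <- c(comp, rep(1L, length(gi)))
      si <- c(si, gi); sj <- c(sj, gj); sk <- c(sk, rep(kz, length(gi)))
      coef <- c(coef, rep(src$amplitude, length(gi)))
      phase <- c(phase, rep(if (src$polarization == "circular") pi / 2 else 0,
                            length(gi)))
    }
    coef <- coef * dt / (eps0 * dzd_m)
  } else { # dipole_ring
    kz <- which.min(abs(cc$z - src$z_mm))
    th <- (seq_len(src$n_dipoles) - 1) * 2 * pi / src$n_dipoles
    px <- src$center[1] + src$radii[1] * cos(th)
    py <- src$center[2] + src$radii[2] * sin(th)
    tx <- -src$radii[1] * sin(th); ty <- src$radii[2] * cos(th)
    nrm <- sqrt(tx^2 + ty^2); tx <- tx / nrm; ty <- ty / nrm
    ph <- if (src$quadrature) th else rep(0, length(th))
    h <- grid_cell_sizes(grid)
    # dual spacings at nodes (0-based node index 0..n)
    dualsp <- function(d) c(d[1] / 2, (d[-length(d)] + d[-1]) / 2,
                            d[length(d)] / 2)
    dxd <- dualsp(h$x); dyd <- dualsp(h$y); dzd <- dualsp(h$z)
    # trilinear spread of a current element onto the 8 surrounding edges of
    # one E component; each edge is scaled by its own dual-cell volume so
    # the total injected current moment is exact on any grid
    spread <- function(component, pos, moment, phase0) {
      # edge coordinate systems: Ex edges at (centre_x, node_y, node_z) etc.
      axc <- list(cc$x, cc$y, cc$z)
      axn <- list(grid$edges$x, grid$edges$y, grid$edges$z)
      coords <- switch(component + 1L,
                       list(axc[[1]], axn[[2]], axn[[3]]),
                       list(axn[[1]], axc[[2]], axn[[3]]),
                       list(axn[[1]], axn[[2]], axc[[3]]))
      idx <- integer(3); wlo <- numeric(3)
      for (a in 1:3) {
        v <- coords[[a]]
        i0 <- findInterval(pos[a], v)
        i0 <- min(max(i0, 1L), length(v) - 1L)
        w <- (pos[a] - v[i0]) / (v[i0 + 1] - v[i0])
        idx[a] <- i0; wlo[a] <- 1 - min(max(w, 0), 1)
      }
      for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
        w <- (if (ox) 1 - wlo[1] else wlo[1]) *
          (if (oy) 1 - wlo[2] else wlo[2]) *
          (if (oz) 1 - wlo[3] else wlo[3])
        if (w < 1e-12) next
        e <- idx + c(ox, oy, oz)
        # convert to 0-based kernel indices; node-axis index i0 is already
        # the 0-based node number + 1
        ei <- e - 1L
        vdual <- switch(component + 1L,
                        h$x[e[1]] * dyd[e[2]] * dzd[e[3]],
                        dxd[e[1]] * h$y[e[2]] * dzd[e[3]],
                        dxd[e[1]] * dyd[e[2]] * h$z[e[3]]) * 1e-9
        comp <<- c(comp, component)
        si <<- c(si, ei[1]); sj <<- c(sj, ei[2]); sk <<- c(sk, ei[3])
        coef <<- c(coef, w * moment * dt / (eps0 * vdual))
        phase <<- c(phase, phase0)
      }
    }
    # each ring element is a z-directed line current ("rung") of length L
    # centred on the ring plane, discretized cell by cell so the total
    # injected current moment is exact regardless of local cell size
    L <- src$rung_length
    zlo <- src$z_mm - L / 2; zhi <- src$z_mm + L / 2
    ze <- grid$edges$z
    for (q in seq_along(th)) {
      for (k in seq_along(cc$z)) {
        len <- max(0, min(zhi, ze[k + 1]) - max(zlo, ze[k]))
        if (len <= 0) next
        spread(2L, c(px[q], py[q], cc$z[k]), src$amplitude * len / L, ph[q])
      }
    }
  }
  list(comp = comp, i = si, j = sj, k = sk, coef = coef, phase = phase)
}

#' Run the FDTD solver to steady state
#'
#' Leapfrog Yee updates with lossy-dielectric E updates on the (possibly
#' graded) rectilinear grid, CPML absorbing shells, perfect-conductor
#' treatment of flagged cells, a soft ramped CW source, and extraction of
#' steady-state phasors by a single-frequency DFT over the last simulated
#' period. The run stops when the per-period relative change of in-tissue
#' electric energy drops below `conv_db` (or at `max_periods`, with a
#' warning flag).
#'
#' The timestep is the Courant bound times the safety factor, then shortened
#' slightly so a drive period is an integer number of steps (exact
#' single-period DFT).
#'
#' @param materials a [assign_materials()] result.
#' @param params a [simulation_params()] with a source.
#' @return a `field_volume`: complex cell-centred `Ex`, `Ey`, `Ez` (V/m per
#'   unit drive), the grid, params, and a per-period `convergence` data
#'   frame.
#' @export
run_fdtd <- function(materials, params) {
  grid <- materials$grid
  n <- grid_dims(grid)
  if (is.null(params$source)) stop("params$source is required")
  if (params$periodic_xy && any(params$pml_layers[1:2] > 0))
    stop("periodic_xy requires pml_layers = c(0, 0, n)")
  h <- grid_cell_sizes(grid)
  dt_max <- courant_dt(grid, params$courant_safety)
  Tper <- 1 / params$frequency
  N <- 32L * as.integer(ceiling(Tper / dt_max / 32))
  dt <- Tper / N
  src <- resolve_source(params$source, grid, dt)
  min_periods <- as.integer(ceiling(params$ramp_periods) + 2L)
  res <- .fdtd_run_cpp(n, h$x * 1e-3, h$y * 1e-3, h$z * 1e-3,
                       as.numeric(materials$eps_r), as.numeric(materials$sigma),
                       as.integer(materials$pec), as.integer(materials$tissue),
                       dt, params$frequency, params$pml_layers,
                       params$periodic_xy,
                       src$comp, src$i, src$j, src$k, src$coef, src$phase,
                       "cw", N, params$max_periods, min_periods,
                       params$conv_db, params$ramp_periods,
                       0L, 0, 0, integer(0), integer(0), integer(0), integer(0))
  if (res$unstable)
    stop(sprintf("FDTD instability detected (dt = %.3g s, %d periods); check grading",
                 dt, res$periods))
  conv <- data.frame(period = seq_along(res$period_energy),
                     energy = res$period_energy, change_db = res$period_db)
  cen <- function(re, im, d1, d2, d3, avg) {
    E <- array(complex(real = re, imaginary = im), c(d1, d2, d3))
    avg(E)
  }
  Ex <- cen(res$Exre, res$Exim, n[1], n[2] + 1L, n[3] + 1L, function(E)
    0.25 * (E[, 1:n[2], 1:n[3], drop = FALSE] + E[, 2:(n[2] + 1), 1:n[3], drop = FALSE] +
            E[, 1:n[2], 2:(n[3] + 1), drop = FALSE] + E[, 2:(n[2] + 1), 2:(n[3] + 1), drop = FALSE]))
  Ey <- cen(res$Eyre, res$Eyim, n[1] + 1L, n[2], n[3] + 1L, function(E)
    0.25 * (E[1:n[1], , 1:n[3], drop = FALSE] + E[2:(n[1] + 1), , 1:n[3], drop = FALSE] +
            E[1:n[1], , 2:(n[3] + 1), drop = FALSE] + E[2:(n[1] + 1), , 2:(n[3] + 1), drop = FALSE]))
  Ez <- cen(res$Ezre, res$Ezim, n[1] + 1L, n[2] + 1L, n[3], function(E)
    0.25 * (E[1:n[1], 1:n[2], , drop = FALSE] + E[2:(n[1] + 1), 1:n[2], , drop = FALSE] +
            E[1:n[1], 2:(n[2] + 1), , drop = FALSE] + E[2:(n[1] + 1), 2:(n[2] + 1), , drop = FALSE]))
  # zero the phasors inside perfect conductors (tangential E is pinned on
  # their faces; the centre average must not leak boundary values in)
  pecsel <- materials$pec
  Ex[pecsel] <- 0; Ey[pecsel] <- 0; Ez[pecsel] <- 0
  structure(list(grid = grid, Ex = Ex, Ey = Ey, Ez = Ez,
                 params = params, dt = dt, steps_per_period = N,
                 converged = res$converged, periods = res$periods,
                 convergence = conv),
            class = "field_volume")
}

#' @export
print.field_volume <- function(x, ...) {
  n <- grid_dims(x$grid)
  cat(sprintf("field_volume: %d x %d x %d cells, %d periods (%s), max |E| = %.4g\n",
              n[1], n[2], n[3], x$periods,
              if (x$converged) "converged" else "NOT converged",
              max(field_magnitude(x))))
  invisible(x)
}

#' |E| magnitude of a field volume
#'
#' Peak-amplitude phasor magnitude `sqrt(|Ex|^2 + |Ey|^2 + |Ez|^2)` at cell
#' centres.
#' @param field a `field_volume`.
#' @return numeric array.
#' @export
field_magnitude <- function(field)
  sqrt(Mod(field$Ex)^2 + Mod(field$Ey)^2 + Mod(field$Ez)^2)

#' Scale the fields of a run by a factor
#' @param field a `field_volume`.
#' @param factor linear field scale.
#' @export
scale_field <- function(field, factor) {
  field$Ex <- field$Ex * factor
  field$Ey <- field$Ey * factor
  field$Ez <- field$Ez * factor
  field
}

# pulsed run with time-domain probes (PML reflection measurements)
fdtd_pulse_probe <- function(materials, pml_layers, probes, nsteps,
                             source, courant_safety = 0.99,
                             periodic_xy = TRUE, pulse_cycles = 3) {
  grid <- materials$grid
  n <- grid_dims(grid)
  h <- grid_cell_sizes(grid)
  dt <- courant_dt(grid, courant_safety)
  src <- resolve_source(source, grid, dt)
  width <- pulse_cycles * dt * 10
  res <- .fdtd_run_cpp(n, h$x * 1e-3, h$y * 1e-3, h$z * 1e-3,
                       as.numeric(materials$eps_r), as.numeric(materials$sigma),
                       as.integer(materials$pec), as.integer(materials$tissue),
                       dt, source$frequency, rep_len(as.integer(pml_layers), 3L),
                       periodic_xy,
                       src$comp, src$i, src$j, src$k, src$coef, src$phase,
                       "pulse", 0L, 0L, 0L, -40, 0,
                       as.integer(nsteps), 4 * width, width,
                       probes$comp, probes$i, probes$j, probes$k)
  list(probes = res$probes, dt = dt)
}
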