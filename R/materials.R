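# Dielectric assignment: label volumes -> per-cell (sigma, eps_r, rho) with
# implant overrides, on either the label grid or a graded simulation grid.
# Properties are linear, nondispersive, isotropic and heterogeneous in space.

#' Load a tissue dielectric table
#'
#' @param path YAML table; default is the bundled 128 MHz table.
#' @return a `tissue_table` list with `tissues`, `aliases`, `labels`.
#' @export
load_tissue_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "tissues.yaml", package = "mshead")
  tab <- yaml::read_yaml(path)
  names(tab$labels) <- as.character(names(tab$labels))
  structure(tab, class = "tissue_table")
}

#' Dielectric properties for a structure name
#'
#' Resolves aliases (e.g. the basal-ganglia nuclei map to grey matter and
#' the medullary laminae to white matter) and returns conductivity,
#' relative permittivity and density.
#'
#' @param label structure name (case-insensitive) or integer label.
#' @param table a [load_tissue_table()] result.
#' @return list with `sigma` (S/m), `eps_r`, `density` (kg/m^3).
#' @export
material_for <- function(label, table = load_tissue_table()) {
  key <- if (is.numeric(label)) {
    k <- table$labels[[as.character(as.integer(label))]]
    if (is.null(k)) stop(sprintf("unknown label %d; known: %s", label,
                                 paste(names(table$labels), collapse = ", ")))
    k
  } else tolower(label)
  if (!is.null(table$aliases[[key]])) key <- table$aliases[[key]]
  m <- table$tissues[[key]]
  if (is.null(m))
    stop(sprintf("unknown tissue '%s'; known: %s", label,
                 paste(names(table$tissues), collapse = ", ")))
  m
}

#' Per-cell material grid
#'
#' Samples label volumes at the grid cell centres (nearest voxel; later
#' volumes in a list override earlier ones inside their own extent), applies
#' the implant overlay on top, and tabulates (sigma, eps_r, rho) plus
#' implant/tissue flags. Conductor cells are flagged for perfect-conductor
#' treatment in the solver.
#'
#' @param vol a [label_volume()] or a list of them (override order).
#' @param implant optional `implant_overlay` on `grid` (from
#'   [rasterize_lead()]), or NULL.
#' @param table a [load_tissue_table()].
#' @param grid a [rectilinear_grid()]; if NULL, a uniform grid matching
#'   `vol`'s voxels is used.
#' @param pec_sigma conductivity threshold (S/m) above which a cell is
#'   treated as a perfect conductor.
#' @return a `material_grid`: arrays `sigma`, `eps_r`, `rho`, integer
#'   `implant` (0/1 conductor/2 insulation), logical `tissue`, the grid and
#'   the label array used.
#' @export
assign_materials <- function(vol, implant = NULL, table = load_tissue_table(),
                             grid = NULL, pec_sigma = 1e5) {
  vols <- if (inherits(vol, "label_volume")) list(vol) else vol
  if (is.null(grid)) {
    v1 <- vols[[1]]
    d <- dim(v1$data)
    grid <- rectilinear_grid(v1$origin[1] + v1$spacing[1] * (0:d[1]),
                             v1$origin[2] + v1$spacing[2] * (0:d[2]),
                             v1$origin[3] + v1$spacing[3] * (0:d[3]))
  }
  n <- grid_dims(grid)
  if (!is.null(implant) && !all(dim(implant) == n))
    stop("implant overlay grid does not match the material grid")
  pts <- grid_center_points(grid)
  lab <- rep(0L, nrow(pts))
  for (v in vols) {
    s <- sample_labels(v, pts, outside = NA_integer_)
    lab[!is.na(s)] <- s[!is.na(s)]
  }
  lab <- array(lab, n)

  ids <- sort(unique(as.vector(lab)))
  sigma <- array(0, n); epsr <- array(1, n); rho <- array(0, n)
  for (id in ids) {
    m <- material_for(id, table)
    sel <- lab == id
    sigma[sel] <- m$sigma; epsr[sel] <- m$eps_r; rho[sel] <- m$density
  }
  tissue <- lab > 0L
  imp <- array(0L, n)
  if (!is.null(implant)) {
    imp <- unclass(implant)
    mc <- material_for("conductor", table)
    mi <- material_for("insulation", table)
    sel <- imp == 1L
    sigma[sel] <- mc$sigma; epsr[sel] <- mc$eps_r; rho[sel] <- mc$density
    sel <- imp == 2L
    sigma[sel] <- mi$sigma; epsr[sel] <- mi$eps_r; rho[sel] <- mi$density
    tissue[imp > 0L] <- FALSE
  }
  structure(list(grid = grid, labels = lab, sigma = sigma, eps_r = epsr,
                 rho = rho, implant = imp, tissue = tissue,
                 pec = sigma >= pec_sigma),
            class = "material_grid")
}

#' @export
print.material_grid <- function(x, ...) {
  n <- grid_dims(x$grid)
  cat(sprintf("material_grid: %d x %d x %d cells; tissue %d, implant %d (PEC %d), air %d\n",
              n[1], n[2], n[3], sum(x$tissue), sum(x$implant > 0),
              sum(x$pec), sum(!x$tissue & x$implant == 0)))
  invisible(x)
}
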