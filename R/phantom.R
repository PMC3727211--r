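# Analytic head phantom with nested shells, basal-ganglia-like nuclei and
# sub-voxel medullary laminae. Ellipsoid-based on purpose: the ground truth
# is exact, which makes every downstream stage testable without any dataset.

# run expr with a fixed RNG seed, restoring caller RNG state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Named set of anatomical landmarks
#'
#' Three named fiducials analogous to the anterior commissure (AC), posterior
#' commissure (PC) and the superior interhemispheric point, in mm world
#' coordinates. Landmark-based similarity registration needs the triplet to
#' be non-collinear.
#'
#' @param pts 3 x 3 numeric matrix, one landmark per row.
#' @param names row names; defaults to AC/PC/IHA.
#' @return a `landmark_set` (a named 3 x 3 matrix).
#' @export
landmark_set <- function(pts, names = c("AC", "PC", "IHA")) {
  pts <- as.matrix(pts)
  stopifnot(nrow(pts) == 3, ncol(pts) == 3)
  v1 <- pts[2, ] - pts[1, ]; v2 <- pts[3, ] - pts[1, ]
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  if (sqrt(sum(cr^2)) < 1e-9)
    stop("landmarks are collinear (triangle area ~ 0)")
  rownames(pts) <- names
  structure(pts, class = c("landmark_set", "matrix"))
}

ellipsoid_q <- function(pts, center, semiaxes) {
  ((pts[, 1] - center[1]) / semiaxes[1])^2 +
    ((pts[, 2] - center[2]) / semiaxes[2])^2 +
    ((pts[, 3] - center[3]) / semiaxes[3])^2
}

prim <- function(name, label, center, semiaxes, lamina = FALSE)
  list(name = name, label = label, center = center, semiaxes = semiaxes,
       lamina = lamina)

#' Head phantom specification
#'
#' Defines the analytic geometry: nested shell ellipsoids (skin, skull, CSF,
#' white matter) and deep-nuclei blobs (caudate-, putamen-, GPe- and GPi-like)
#' separated by thin laminae. Primitives are ordered innermost-first; a point
#' takes the label of the first primitive containing it. Laminae are
#' sub-voxel-thin shells (default 0.4 mm): thicker than the fine (0.2 mm)
#' voxel but thinner than the coarse (1 mm) voxel, so rasterizing at coarse
#' spacing loses them and the pallidal segments merge, which is the
#' resolution effect the pipeline studies.
#'
#' @param outer_semiaxes_mm skin ellipsoid semiaxes (mm).
#' @param shell_thicknesses_mm named thicknesses for skin, skull, CSF (mm);
#'   white matter fills the remainder.
#' @param nuclei list of primitives (see [head_phantom_spec()] defaults);
#'   `NULL` keeps the default basal-ganglia set, `list()` drops all nuclei.
#' @param lamina_thickness_mm thickness of the medullary laminae analogs.
#' @param seed integer seed recorded with the spec.
#' @return a `head_phantom_spec` object.
#' @export
head_phantom_spec <- function(outer_semiaxes_mm = c(16, 20, 16),
                              shell_thicknesses_mm = c(skin = 1.5, skull = 2,
                                                       csf = 1.5),
                              nuclei = NULL,
                              lamina_thickness_mm = 0.4,
                              seed = 1L) {
  a <- outer_semiaxes_mm
  th <- shell_thicknesses_mm
  a_skull <- a - th[["skin"]]
  a_csf <- a_skull - th[["skull"]]
  a_wm <- a_csf - th[["csf"]]
  if (any(a_wm <= 0)) stop("shells thicker than the head")
  lt <- lamina_thickness_mm
  if (is.null(nuclei)) {
    gpi <- c(1.6, 2.2, 1.6)
    nuclei <- list(
      prim("GPi", 13L, c(0, -2, 0), gpi),
      prim("IML", 21L, c(0, -2, 0), gpi + lt, lamina = TRUE),
      prim("GPe", 12L, c(0, -2, 0), gpi + lt + 0.8),
      prim("EML", 20L, c(0, -2, 0), gpi + 2 * lt + 0.8, lamina = TRUE),
      prim("putamen", 11L, c(0, -2, 0), gpi + 2 * lt + 2.0),
      prim("caudate", 10L, c(4.5, 4.5, 3.5), c(2.0, 2.8, 2.0)))
  }
  prims <- c(nuclei, list(
    prim("WM", 4L, c(0, 0, 0), a_wm),
    prim("CSF", 3L, c(0, 0, 0), a_csf),
    prim("skull", 2L, c(0, 0, 0), a_skull),
    prim("skin", 1L, c(0, 0, 0), a)))
  labs <- vapply(prims, `[[`, integer(1), "label")
  if (anyDuplicated(labs)) stop("labels must be unique")
  spec <- structure(list(primitives = prims, outer_semiaxes = a,
                         wm_semiaxes = a_wm, seed = as.integer(seed),
                         lamina_thickness = lt),
                    class = "head_phantom_spec")
  validate_phantom_spec(spec)
  spec
}

# every nucleus must lie strictly inside the white-matter ellipsoid
validate_phantom_spec <- function(spec) {
  a_wm <- spec$wm_semiaxes
  theta <- seq(0, pi, length.out = 13)
  phi <- seq(0, 2 * pi, length.out = 25)[-25]
  sph <- cbind(rep(sin(theta), each = length(phi)) * cos(phi),
               rep(sin(theta), each = length(phi)) * sin(phi),
               rep(cos(theta), each = length(phi)))
  for (p in spec$primitives) {
    if (p$label >= 10) {
      surf <- sweep(sweep(sph, 2, p$semiaxes, "*"), 2, p$center, "+")
      if (any(ellipsoid_q(surf, c(0, 0, 0), a_wm) >= 1))
        stop(sprintf("nucleus '%s' is not strictly inside the white matter",
                     p$name))
    }
  }
  invisible(spec)
}

#' @export
print.head_phantom_spec <- function(x, ...) {
  cat("head_phantom_spec: outer semiaxes",
      paste(x$outer_semiaxes, collapse = " x "), "mm;",
      length(x$primitives), "primitives\n")
  invisible(x)
}

# first-match label at points, optionally skipping laminae
analytic_label <- function(spec, pts, skip_lamina = FALSE) {
  lab <- integer(nrow(pts))
  for (p in spec$primitives) {
    if (skip_lamina && isTRUE(p$lamina)) next
    todo <- lab == 0L
    if (!any(todo)) break
    q <- ellipsoid_q(pts[todo, , drop = FALSE], p$center, p$semiaxes)
    lab[todo][q <= 1] <- p$label
  }
  lab
}

#' Rasterize the head phantom
#'
#' Labels are assigned by the innermost primitive containing the voxel
#' centre. Laminae additionally require an absolute occupancy majority
#' (estimated by sub-voxel supersampling): a voxel is a lamina only if the
#' lamina fills more than half of it, otherwise it falls back to the
#' innermost non-lamina primitive. This reproduces how segmentation at a
#' given resolution loses sheets thinner than a voxel.
#'
#' @param spec a [head_phantom_spec()].
#' @param spacing_mm voxel size in mm.
#' @param region optional `list(lo =, hi =)` world bbox (mm) to rasterize;
#'   default covers the whole phantom.
#' @param subsamples per-axis sub-voxel samples for lamina occupancy.
#' @return `list(volume = label_volume, landmarks = landmark_set)`.
#' @export
make_head_phantom <- function(spec, spacing_mm, region = NULL,
                              subsamples = 4L) {
  stopifnot(inherits(spec, "head_phantom_spec"), spacing_mm > 0)
  validate_phantom_spec(spec)
  if (is.null(region)) {
    lo <- hi <- NULL
    for (p in spec$primitives) {
      lo <- if (is.null(lo)) p$center - p$semiaxes else pmin(lo, p$center - p$semiaxes)
      hi <- if (is.null(hi)) p$center + p$semiaxes else pmax(hi, p$center + p$semiaxes)
    }
    region <- list(lo = lo - spacing_mm, hi = hi + spacing_mm)
  }
  n <- pmax(1L, as.integer(ceiling((region$hi - region$lo) / spacing_mm)))
  origin <- region$lo
  cx <- origin[1] + (seq_len(n[1]) - 0.5) * spacing_mm
  cy <- origin[2] + (seq_len(n[2]) - 0.5) * spacing_mm
  cz <- origin[3] + (seq_len(n[3]) - 0.5) * spacing_mm
  pts <- cbind(rep(cx, times = n[2] * n[3]),
               rep(rep(cy, each = n[1]), times = n[3]),
               rep(cz, each = n[1] * n[2]))
  lab <- analytic_label(spec, pts, skip_lamina = TRUE)

  # lamina occupancy pass, restricted to voxels whose centre is in a lamina
  laminae <- Filter(function(p) isTRUE(p$lamina), spec$primitives)
  if (length(laminae)) {
    s <- subsamples
    off <- (seq_len(s) - 0.5) / s - 0.5   # sub-voxel offsets in voxel units
    sub <- as.matrix(expand.grid(off, off, off)) * spacing_mm
    for (lp in laminae) {
      inner <- inner_of_lamina(spec, lp)
      q_out <- ellipsoid_q(pts, lp$center, lp$semiaxes)
      q_in <- ellipsoid_q(pts, inner$center, inner$semiaxes)
      cand <- which(q_out <= 1 & q_in > 1)
      if (!length(cand)) next
      frac <- numeric(length(cand))
      for (r in seq_len(nrow(sub))) {
        sp <- sweep(pts[cand, , drop = FALSE], 2, sub[r, ], "+")
        inside <- ellipsoid_q(sp, lp$center, lp$semiaxes) <= 1 &
          ellipsoid_q(sp, inner$center, inner$semiaxes) > 1
        frac <- frac + inside
      }
      frac <- frac / nrow(sub)
      lab[cand[frac > 0.5]] <- lp$label
    }
  }
  vol <- label_volume(array(lab, dim = n), spacing_mm, origin)
  lms <- default_landmarks(spec)
  list(volume = vol, landmarks = lms)
}

# the primitive immediately preceding a lamina in the innermost-first order
inner_of_lamina <- function(spec, lamina) {
  idx <- which(vapply(spec$primitives, function(p) p$label, integer(1)) ==
                 lamina$label)
  if (idx <= 1) stop("lamina has no inner primitive")
  spec$primitives[[idx - 1]]
}

default_landmarks <- function(spec) {
  landmark_set(rbind(c(0, 3, 0), c(0, -5, 0), c(0, 0, 14)))
}

#' Generate the micro-resolution atlas from a fine head volume
#'
#' Takes a fine-resolution crop of the head phantom (the nuclei region) and
#' produces an "ex-vivo atlas" of it: the labels resampled (nearest
#' neighbour) through a known smooth deformation, composed of a similarity
#' misalignment and a random free-form deformation whose control
#' displacements are drawn uniformly from `[-warp_amplitude, warp_amplitude]`
#' on a lattice of spacing `warp_spacing`. The true transform is returned as
#' ground truth, along with the transformed landmark triplet, so registration
#' can be scored exactly.
#'
#' @param head_fine a fine-spacing [label_volume()] crop of the nuclei region.
#' @param warp_amplitude_mm max control-point displacement (mm); must be less
#'   than `warp_spacing_mm / 2` to keep the warp fold-free in practice.
#' @param warp_spacing_mm FFD control lattice spacing (mm).
#' @param seed integer seed for the random warp.
#' @param landmarks head-space [landmark_set()] to carry through the warp.
#' @param rotation_deg,scale,translation_mm similarity misalignment applied
#'   before the FFD (atlas -> head direction).
#' @return list with `volume` (the atlas), `ffd` (true [ffd_grid()]),
#'   `similarity` (true [similarity_transform()]) and `landmarks`
#'   (atlas-space triplet).
#' @export
make_micro_atlas <- function(head_fine, warp_amplitude_mm, warp_spacing_mm,
                             seed, landmarks = NULL,
                             rotation_deg = 5, scale = 1.03,
                             translation_mm = c(2, -1, 1)) {
  stopifnot(inherits(head_fine, "label_volume"))
  if (warp_amplitude_mm >= warp_spacing_mm / 2)
    stop("warp amplitude must be < half the warp spacing (folding risk)")
  d <- dim(head_fine$data)
  lo <- head_fine$origin
  hi <- head_fine$origin + d * head_fine$spacing
  lattice <- ffd_lattice_covering(lo - 5, hi + 5, warp_spacing_mm)
  nctl <- prod(lattice$dims) * 3L
  coef <- with_seed(seed, runif(nctl, -warp_amplitude_mm, warp_amplitude_mm))
  ffd_true <- ffd_grid(lattice$origin, warp_spacing_mm, lattice$dims,
                       array(coef, dim = c(lattice$dims, 3L)))
  th <- rotation_deg * pi / 180
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  sim_true <- similarity_transform(rot, scale, translation_mm)
  warp <- function(p) ffd_transform(ffd_true, apply_similarity(sim_true, p))

  ctr <- vox_center_grid(head_fine)
  lab <- sample_labels(head_fine, warp(ctr), outside = 0L)
  atlas <- label_volume(array(lab, dim = d), head_fine$spacing, head_fine$origin)

  if (is.null(landmarks)) landmarks <- default_landmarks(NULL)
  alm <- invert_warp_points(landmarks, sim_true, ffd_true)
  rownames(alm) <- rownames(landmarks)
  list(volume = atlas, ffd = ffd_true, similarity = sim_true,
       landmarks = landmark_set(alm, rownames(landmarks)))
}

# invert p -> ffd(sim(p)) at given head-space points by fixed-point iteration
invert_warp_points <- function(pts, sim, ffd, tol = 1e-8, max_iter = 100) {
  pts <- rbind(pts)
  z <- pts
  for (it in seq_len(max_iter)) {
    dz <- ffd_displacement(ffd, z)
    znew <- pts - dz
    if (max(abs(znew - z)) < tol) { z <- znew; break }
    z <- znew
  }
  apply_similarity(invert_similarity(sim), z)
}

#' Sample reproducible probe points on tissue layers
#'
#' Draws `n_per_layer` voxel-centre points from each requested label's voxel
#' set, mirroring probe layouts along the grey-matter and skin layers.
#'
#' @param head a [label_volume()].
#' @param n_per_layer points per layer.
#' @param labels named integer vector of layer labels
#'   (default skin and GPi-like grey matter).
#' @param seed RNG seed.
#' @return matrix of points (mm) with names like `S1..Sn`, `GM1..GMn`.
#' @export
make_probe_points <- function(head, n_per_layer, labels = c(S = 1L, GM = 13L),
                              seed = 1L) {
  out <- NULL
  d <- dim(head$data)
  for (nm in names(labels)) {
    idx <- which(head$data == labels[[nm]])
    if (!length(idx)) stop(sprintf("layer '%s' (label %d) is empty",
                                   nm, labels[[nm]]))
    if (n_per_layer > length(idx))
      stop(sprintf("layer '%s' has only %d voxels (< %d requested)",
                   nm, length(idx), n_per_layer))
    pick <- with_seed(seed + labels[[nm]],
                      sort(sample.int(length(idx), n_per_layer)))
    lin <- idx[pick] - 1L
    ii <- lin %% d[1]
    jj <- (lin %/% d[1]) %% d[2]
    kk <- lin %/% (d[1] * d[2])
    pts <- cbind(head$origin[1] + (ii + 0.5) * head$spacing[1],
                 head$origin[2] + (jj + 0.5) * head$spacing[2],
                 head$origin[3] + (kk + 0.5) * head$spacing[3])
    rownames(pts) <- paste0(nm, seq_len(n_per_layer))
    out <- rbind(out, pts)
  }
  out
}
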