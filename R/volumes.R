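#' Integer label volume on a regular grid
#'
#' The anatomical currency of the pipeline: a 3D array of integer structure
#' labels together with its voxel spacing and world origin, all in mm.
#' World coordinates follow the voxel-centre convention
#' `world = origin + (index - 1 + 0.5) * spacing` (1-based array indices),
#' so the origin is the outer corner of the first voxel.
#'
#' @param data integer 3D array of labels (0 = background/air).
#' @param spacing voxel size in mm; scalar or length-3.
#' @param origin world coordinates (mm) of the volume corner, length 3.
#' @return A `label_volume` object.
#' @export
label_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("label_volume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  tab <- table(x$data)
  cat("  labels:", paste(sprintf("%s(%d)", names(tab), as.integer(tab)),
                         collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$data)

# voxel-centre world coordinates along one axis
vox_centers <- function(vol, axis) {
  n <- dim(vol$data)[axis]
  vol$origin[axis] + (seq_len(n) - 0.5) * vol$spacing[axis]
}

# all voxel centres as an n x 3 matrix (may be large)
vox_center_grid <- function(vol) {
  d <- dim(vol$data)
  cx <- vox_centers(vol, 1); cy <- vox_centers(vol, 2); cz <- vox_centers(vol, 3)
  cbind(rep(cx, times = d[2] * d[3]),
        rep(rep(cy, each = d[1]), times = d[3]),
        rep(cz, each = d[1] * d[2]))
}

#' Sample labels at world points (nearest voxel)
#'
#' @param vol a [label_volume()].
#' @param pts n x 3 matrix of world coordinates in mm.
#' @param outside value returned for points outside the volume.
#' @return integer vector of labels.
#' @export
sample_labels <- function(vol, pts, outside = NA_integer_) {
  pts <- rbind(pts)
  d <- dim(vol$data)
  ii <- floor(sweep(sweep(pts, 2, vol$origin), 2, vol$spacing, "/")) + 1
  ok <- ii[, 1] >= 1 & ii[, 1] <= d[1] & ii[, 2] >= 1 & ii[, 2] <= d[2] &
    ii[, 3] >= 1 & ii[, 3] <= d[3]
  out <- rep(as.integer(outside), nrow(pts))
  if (any(ok)) {
    lin <- ii[ok, 1] + d[1] * (ii[ok, 2] - 1) + d[1] * d[2] * (ii[ok, 3] - 1)
    out[ok] <- vol$data[lin]
  }
  out
}

#' Extract a binary mask for one label
#' @param vol a [label_volume()].
#' @param label integer label.
#' @return logical array.
#' @export
label_mask <- function(vol, label) vol$data == label

#' Write a label volume as NIfTI
#'
#' Labels are stored as int16 with the voxel-centre affine in the sform.
#' @param vol a [label_volume()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @export
write_label_nifti <- function(vol, path) {
  img <- RNifti::asNifti(vol$data, datatype = "int16")
  aff <- diag(4)
  diag(aff)[1:3] <- vol$spacing
  # RNifti world coordinate of voxel (0,0,0) centre
  aff[1:3, 4] <- vol$origin + vol$spacing / 2
  RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label volume from NIfTI
#' @param path NIfTI file written by [write_label_nifti()] (or any axis-aligned
#'   label image).
#' @return a [label_volume()].
#' @export
read_label_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  spacing <- diag(aff)[1:3]
  origin <- aff[1:3, 4] - spacing / 2
  label_volume(array(as.integer(img), dim = dim(img)), spacing, origin)
}

#' Compute the volume of a labelled structure
#'
#' Voxel count times voxel volume.
#' @param mask logical array (or a [label_volume()] plus `label`).
#' @param spacing voxel spacing in mm (scalar or length 3).
#' @return volume in mm^3.
#' @export
structure_volume <- function(mask, spacing) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  sum(mask) * prod(spacing)
}
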