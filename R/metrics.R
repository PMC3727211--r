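# Label propagation through fitted transforms and segmentation scoring:
# centroid distance (Dc), percent match (PM = 100 TP / (TP + FN)) and
# positive predictive value (P+ = 100 TP / (TP + FP)).

#' Propagate atlas labels onto a target grid
#'
#' For each target voxel centre, pull back through the inverse of the
#' composite transform (similarity then structure-specific non-rigid
#' registration; the inverse of the deformation is computed by fixed-point
#' iteration) and take the atlas label by nearest neighbour. Structures are
#' processed in the given order, later entries overriding earlier ones
#' (pass smaller structures last so thin details survive). Voxels mapping
#' outside the atlas keep their current label.
#'
#' @param atlas the atlas [label_volume()].
#' @param similarity the atlas-to-target [similarity_transform()].
#' @param registrations list of `list(reg = icp_registration, labels = ints)`
#'   entries, one per registered structure, in override order.
#' @param target a [label_volume()] supplying the target grid and the
#'   base labels that propagation refines.
#' @param inverse_tol fixed-point inversion tolerance (mm).
#' @return a [label_volume()] on the target grid.
#' @export
propagate_labels <- function(atlas, similarity, registrations, target,
                             inverse_tol = 0.05) {
  out <- target$data
  ctr <- vox_center_grid(target)
  sim_inv <- invert_similarity(similarity)
  for (entry in registrations) {
    z <- icp_inverse_points(entry$reg, ctr, tol = inverse_tol)
    x <- apply_similarity(sim_inv, z)
    lab <- sample_labels(atlas, x, outside = NA_integer_)
    sel <- !is.na(lab) & lab %in% entry$labels
    out[sel] <- lab[sel]
  }
  label_volume(array(out, dim(target$data)), target$spacing, target$origin)
}

#' Centroid distance between two masks
#'
#' Euclidean distance (mm) between the voxel-centre centroids of the
#' predicted and ground-truth masks.
#'
#' @param pred,gt logical arrays of identical dimension.
#' @param spacing voxel spacing (mm), scalar or length 3.
#' @param origin world origin (mm), default 0 (cancels out).
#' @return Dc in mm.
#' @export
centroid_distance <- function(pred, gt, spacing, origin = c(0, 0, 0)) {
  if (!any(pred) || !any(gt)) stop("empty mask: centroid undefined")
  spacing <- rep_len(as.numeric(spacing), 3L)
  cen <- function(m) {
    idx <- which(m) - 1L
    d <- dim(m)
    ii <- cbind(idx %% d[1], (idx %/% d[1]) %% d[2], idx %/% (d[1] * d[2]))
    origin + (colMeans(ii) + 0.5) * spacing
  }
  sqrt(sum((cen(pred) - cen(gt))^2))
}

#' Overlap metrics: percent match and positive predictive value
#'
#' `PM = 100 TP / (TP + FN)` and `P+ = 100 TP / (TP + FP)`; 100 is perfect
#' localization. An empty prediction gives PM 0 and an error-flagged
#' (`NA`) P+.
#'
#' @param pred,gt logical arrays of identical dimension (gt non-empty).
#' @return list with `PM`, `Pplus`, and counts `TP`, `FP`, `FN`.
#' @export
overlap_metrics <- function(pred, gt) {
  if (!any(gt)) stop("empty ground truth")
  tp <- sum(pred & gt); fp <- sum(pred & !gt); fn <- sum(!pred & gt)
  list(PM = 100 * tp / (tp + fn),
       Pplus = if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp),
       TP = tp, FP = fp, FN = fn)
}

#' Score a propagated segmentation against ground truth
#'
#' Per-structure Dc, PM, P+ and volume.
#'
#' @param pred,gt [label_volume()]s on the same grid.
#' @param labels named integer vector of structure labels.
#' @return a `metrics_report` data frame.
#' @export
score_segmentation <- function(pred, gt, labels) {
  stopifnot(all(dim(pred$data) == dim(gt$data)))
  rows <- lapply(names(labels), function(nm) {
    lp <- pred$data == labels[[nm]]
    lg <- gt$data == labels[[nm]]
    if (!any(lg))
      return(data.frame(structure = nm, Dc_mm = NA, PM_pct = NA,
                        Pplus_pct = NA, volume_mm3 = NA, TP = 0L, FP = 0L,
                        FN = 0L))
    om <- overlap_metrics(lp, lg)
    dc <- if (any(lp)) centroid_distance(lp, lg, gt$spacing) else NA_real_
    data.frame(structure = nm, Dc_mm = dc, PM_pct = om$PM,
               Pplus_pct = om$Pplus,
               volume_mm3 = structure_volume(lp, pred$spacing),
               TP = om$TP, FP = om$FP, FN = om$FN)
  })
  structure(do.call(rbind, rows), class = c("metrics_report", "data.frame"))
}

#' Write a metrics report as CSV and JSON
#' @param report a `metrics_report`.
#' @param path_csv,path_json output paths (either may be NULL).
#' @export
write_metrics_report <- function(report, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv)) utils::write.csv(report, path_csv, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(report, path_json, dataframe = "rows", digits = NA)
  invisible(report)
}
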