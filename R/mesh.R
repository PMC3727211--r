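#' Triangular surface mesh
#'
#' @param vertices n x 3 matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return a `surface_mesh` object.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); faces <- as.matrix(faces)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  storage.mode(faces) <- "integer"
  if (nrow(faces) && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("faces index vertices out of range")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces, area %.2f mm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Total surface area of a mesh
#' @param mesh a [surface_mesh()].
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

# separable Gaussian smoothing of a 3D array (kernel sigma in voxels)
smooth3d <- function(arr, sigma = 1) {
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-r):r)^2 / (2 * sigma^2)); w <- w / sum(w)
  d <- dim(arr)
  for (ax in 1:3) {
    out <- array(0, d)
    for (o in -r:r) {
      src <- pmin(pmax(seq_len(d[ax]) + o, 1L), d[ax])  # replicate borders
      out <- out + w[o + r + 1] * switch(ax,
        arr[src, , , drop = FALSE], arr[, src, , drop = FALSE],
        arr[, , src, drop = FALSE])
    }
    arr <- out
  }
  arr
}

#' Extract the boundary surface of a labelled structure
#'
#' Converts the label to a binary indicator, smooths it slightly for
#' sub-voxel vertex placement, and extracts the 0.5 isosurface with a
#' marching-tetrahedra scheme (watertight by construction). Vertices are in
#' mm world coordinates.
#'
#' @param vol a [label_volume()].
#' @param label label to mesh; a vector meshes the union of labels (e.g. a
#'   compound structure such as the full globus pallidus).
#' @param smooth_sigma Gaussian sigma in voxels applied to the indicator.
#' @return a [surface_mesh()].
#' @export
extract_surface <- function(vol, label, smooth_sigma = 1) {
  mask <- array(vol$data %in% label, dim(vol$data))
  nvox <- sum(mask)
  if (nvox == 0) stop(sprintf("label %s is absent from the volume",
                              paste(label, collapse = "/")))
  if (nvox < 4) stop(sprintf("label %s has only %d voxels: degenerate input",
                             paste(label, collapse = "/"), nvox))
  ind <- smooth3d(array(as.numeric(mask), dim(mask)), smooth_sigma)
  res <- .march_tets_cpp(as.numeric(ind), dim(ind), 0.5, vol$spacing,
                         vol$origin)
  if (nrow(res$vertices) == 0)
    stop("label produced an empty isosurface")
  surface_mesh(res$vertices, res$faces)
}

#' RMSE between corresponding mesh points
#'
#' Root mean square distance between vertex i of `a` and vertex i of `b`;
#' both meshes must have the same vertex count with positional
#' correspondence.
#'
#' @param a,b [surface_mesh()]s (or plain point matrices).
#' @return RMSE in mm.
#' @export
mesh_rmse <- function(a, b) {
  va <- if (inherits(a, "surface_mesh")) a$vertices else as.matrix(a)
  vb <- if (inherits(b, "surface_mesh")) b$vertices else as.matrix(b)
  if (nrow(va) != nrow(vb))
    stop("meshes have different vertex counts; no correspondence")
  sqrt(mean(rowSums((va - vb)^2)))
}

#' Closest points on a mesh surface
#'
#' For each query point returns the nearest point on the triangulated
#' surface (not the nearest vertex) and the distance to it.
#'
#' @param pts n x 3 query points (mm).
#' @param mesh a [surface_mesh()].
#' @return list with `points` (n x 3) and `dist` (n).
#' @export
closest_surface_points <- function(pts, mesh) {
  .closest_on_mesh_cpp(rbind(pts), mesh$vertices, mesh$faces)
}

# deterministic vertex subsampling to at most n points
subsample_vertices <- function(mesh, n) {
  v <- mesh$vertices
  if (nrow(v) <= n) return(v)
  v[round(seq(1, nrow(v), length.out = n)), , drop = FALSE]
}

#' Write a mesh as ASCII PLY
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(mesh$vertices, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ASCII PLY mesh
#' @param path PLY file with xyz vertices and triangular faces.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1]))
  hdr <- which(lines == "end_header")[1]
  v <- matrix(as.numeric(unlist(strsplit(trimws(lines[(hdr + 1):(hdr + nv)]), "\\s+"))),
              ncol = 3, byrow = TRUE)
  f <- matrix(as.integer(unlist(strsplit(trimws(lines[(hdr + nv + 1):(hdr + nv + nf)]), "\\s+"))),
              ncol = 4, byrow = TRUE)[, 2:4, drop = FALSE] + 1L
  surface_mesh(v, f)
}

#' Write a mesh as Wavefront OBJ
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste("v", mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}

#' Read a Wavefront OBJ mesh (v/f records)
#' @param path OBJ file.
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  v <- matrix(as.numeric(unlist(strsplit(sub("^v ", "", vl), "\\s+"))),
              ncol = 3, byrow = TRUE)
  f <- matrix(as.integer(unlist(lapply(strsplit(sub("^f ", "", fl), "\\s+"),
                                       function(x) sub("/.*", "", x)))),
              ncol = 3, byrow = TRUE)
  surface_mesh(v, f)
}
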