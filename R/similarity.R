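#' Similarity transform (rotation, isotropic scale, translation)
#'
#' Maps points by `x -> scale * R x + t`, all in mm.
#'
#' @param rotation 3 x 3 orthonormal matrix with det +1.
#' @param scale positive scalar.
#' @param translation length-3 vector (mm).
#' @return a `similarity_transform` object.
#' @export
similarity_transform <- function(rotation = diag(3), scale = 1,
                                 translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), scale > 0)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      det(rotation) < 0)
    stop("rotation must be orthonormal with det +1")
  structure(list(rotation = rotation, scale = as.numeric(scale),
                 translation = as.numeric(translation)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("similarity_transform: rotation %.3f deg, scale %.6f, t = (%s) mm\n",
              ang, x$scale, paste(signif(x$translation, 5), collapse = ", ")))
  invisible(x)
}

#' Apply a similarity transform to points
#' @param tf a [similarity_transform()].
#' @param pts n x 3 matrix (mm).
#' @return transformed n x 3 matrix.
#' @export
apply_similarity <- function(tf, pts) {
  pts <- rbind(pts)
  sweep(tf$scale * pts %*% t(tf$rotation), 2, tf$translation, "+")
}

#' Invert a similarity transform
#' @param tf a [similarity_transform()].
#' @export
invert_similarity <- function(tf) {
  rt <- t(tf$rotation)
  similarity_transform(rt, 1 / tf$scale, -rt %*% tf$translation / tf$scale)
}

#' Least-squares landmark similarity fit
#'
#' Closed-form orthogonal-Procrustes-with-scale (Umeyama) alignment of two
#' corresponding landmark triplets: centroids are aligned, then the floating
#' set is rotated and scaled to minimize the sum of squared displacements to
#' the reference set.
#'
#' @param floating,reference corresponding [landmark_set()]s (floating is
#'   mapped onto reference).
#' @return a [similarity_transform()].
#' @export
fit_similarity_landmarks <- function(floating, reference) {
  x <- unclass(rbind(floating)); y <- unclass(rbind(reference))
  stopifnot(nrow(x) == nrow(y), ncol(x) == 3)
  for (m in list(x, y)) {
    v1 <- m[2, ] - m[1, ]; v2 <- m[3, ] - m[1, ]
    cr <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    if (nrow(m) == 3 && sqrt(sum(cr^2)) < 1e-9)
      stop("landmarks are collinear; similarity fit is degenerate")
  }
  mx <- colMeans(x); my <- colMeans(y)
  xc <- sweep(x, 2, mx); yc <- sweep(y, 2, my)
  S <- crossprod(yc, xc) / nrow(x)          # covariance of (reference, floating)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  varx <- sum(xc^2) / nrow(x)
  s <- sum(diag(D) * sv$d) / varx
  t <- my - s * R %*% mx
  similarity_transform(R, s, t)
}
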