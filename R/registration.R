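#' Fit a similarity transform from landmark pairs
#'
#' Least-squares fit of `q ~ s * R(theta) * p + t` mapping histology-space
#' landmarks `p` onto MSI-space landmarks `q`. By default rotation is
#' disabled (`theta = 0`), matching a registration restricted to
#' translation and scaling; the closed-form solution is then
#' `s = sum(p_c . q_c) / sum(|p_c|^2)` with centred coordinates and
#' `t = q_bar - s * p_bar`. With `rotation = TRUE` the full similarity is
#' fitted by SVD (Procrustes/Umeyama).
#'
#' Points are `(x, y)` pairs in 0-based pixel coordinates (`x = col`,
#' `y = row`).
#'
#' @param points_histo,points_msi Matrices or data.frames (n x 2) of
#'   corresponding landmarks; n >= 2, not all coincident.
#' @param rotation Allow a rotation component (default `FALSE`).
#' @return Object of class `similarity_transform` with fields `s`, `tx`,
#'   `ty`, `theta`, `residual_rms`.
#' @export
fit_similarity_transform <- function(points_histo, points_msi, rotation = FALSE) {
  p <- as.matrix(points_histo); q <- as.matrix(points_msi)
  stopifnot(ncol(p) == 2, ncol(q) == 2, nrow(p) == nrow(q))
  if (nrow(p) < 2) stop("at least 2 landmark pairs are required")
  pc <- sweep(p, 2, colMeans(p)); qc <- sweep(q, 2, colMeans(q))
  if (sum(pc^2) < .Machine$double.eps)
    stop("degenerate landmarks: all source points coincide")
  if (!rotation) {
    s <- sum(pc * qc) / sum(pc^2)
    theta <- 0
    R <- diag(2)
  } else {
    M <- crossprod(qc, pc) # 2x2
    sv <- svd(M)
    d <- sign(det(sv$u %*% t(sv$v)))
    S <- diag(c(1, d))
    R <- sv$u %*% S %*% t(sv$v)
    s <- sum(diag(S) * sv$d) / sum(pc^2)
    theta <- atan2(R[2, 1], R[1, 1])
  }
  if (s <= 0) stop("fitted scale is not positive; landmarks inconsistent")
  t_vec <- colMeans(q) - s * (R %*% colMeans(p))[, 1]
  fitted <- s * p %*% t(R) + matrix(t_vec, nrow(p), 2, byrow = TRUE)
  rms <- sqrt(mean(rowSums((fitted - q)^2)))
  structure(list(s = s, tx = t_vec[1], ty = t_vec[2], theta = theta,
                 residual_rms = rms, rotation = rotation),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> s=%.6g t=(%.6g, %.6g) theta=%.4g rad, residual RMS %.3g\n",
              x$s, x$tx, x$ty, x$theta, x$residual_rms))
  invisible(x)
}

#' Apply or invert a similarity transform
#'
#' @param transform A `similarity_transform`.
#' @param points n x 2 matrix of `(x, y)` points.
#' @return Transformed points (n x 2) for `apply_transform`; a
#'   `similarity_transform` for `invert_transform`.
#' @export
apply_transform <- function(transform, points) {
  p <- as.matrix(points)
  R <- matrix(c(cos(transform$theta), sin(transform$theta),
                -sin(transform$theta), cos(transform$theta)), 2, 2)
  out <- transform$s * p %*% t(R)
  out[, 1] <- out[, 1] + transform$tx
  out[, 2] <- out[, 2] + transform$ty
  out
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform) {
  s2 <- 1 / transform$s
  th2 <- -transform$theta
  R2 <- matrix(c(cos(th2), sin(th2), -sin(th2), cos(th2)), 2, 2)
  t2 <- -s2 * (R2 %*% c(transform$tx, transform$ty))[, 1]
  structure(list(s = s2, tx = t2[1], ty = t2[2], theta = th2,
                 residual_rms = transform$residual_rms,
                 rotation = transform$rotation),
            class = "similarity_transform")
}

#' Histology segmentation mask with a transform into MSI space
#'
#' @param label_image Integer label matrix in histology space (0 =
#'   background).
#' @param label_names Named integer vector mapping names to label ids.
#' @param transform A fitted `similarity_transform` (histology to MSI), or
#'   `NULL` before fitting.
#' @return Object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(label_image, label_names = NULL, transform = NULL) {
  stopifnot(is.matrix(label_image))
  storage.mode(label_image) <- "integer"
  if (any(label_image < 0)) stop("labels must be >= 0 (0 = background)")
  structure(list(label_image = label_image, label_names = label_names,
                 transform = transform),
            class = "segmentation_mask")
}

#' Project a histology mask onto the MSI grid
#'
#' Maps every MSI pixel centre through the inverse of the mask's fitted
#' transform and takes the nearest-neighbour histology label (labels are
#' categorical, so no interpolation). MSI pixels falling outside the
#' histology field of view become background (0).
#'
#' @param mask A [segmentation_mask()] with a fitted transform.
#' @param msi_grid_shape Target grid `c(rows, cols)`.
#' @return Integer label matrix of `msi_grid_shape`.
#' @export
project_mask <- function(mask, msi_grid_shape) {
  stopifnot(inherits(mask, "segmentation_mask"))
  if (is.null(mask$transform))
    stop("mask transform has not been fitted")
  inv <- invert_transform(mask$transform)
  nr <- msi_grid_shape[1]; nc <- msi_grid_shape[2]
  rows <- matrix(seq_len(nr) - 1L, nr, nc)
  cols <- matrix(seq_len(nc) - 1L, nr, nc, byrow = TRUE)
  h <- apply_transform(inv, cbind(as.vector(cols), as.vector(rows)))
  hc <- round(h[, 1]) + 1L; hr <- round(h[, 2]) + 1L
  out <- matrix(0L, nr, nc)
  ok <- hr >= 1 & hr <= nrow(mask$label_image) &
        hc >= 1 & hc <= ncol(mask$label_image)
  out[cbind(as.vector(rows) + 1L, as.vector(cols) + 1L)[ok, , drop = FALSE]] <-
    mask$label_image[cbind(hr[ok], hc[ok])]
  out
}

#' Per-segment mean and 99th-percentile spectra
#'
#' For each labelled tissue segment, computes per consolidated feature the
#' mean and the 99th percentile of the pixel intensities within the
#' segment. Percentiles use the linear-interpolation convention between
#' order statistics (R quantile type 7); the convention is recorded in the
#' result. Empty segments are flagged and excluded.
#'
#' @param dataset An [msi_dataset()].
#' @param labels Integer label matrix on the MSI grid (e.g. from
#'   [project_mask()]).
#' @param feature_mz Consolidated feature m/z values.
#' @param tol_ppm Peak-to-feature matching tolerance.
#' @param label_names Optional named integer vector naming the labels.
#' @return List with `mean` and `p99` (segments x features matrices),
#'   `n_pixels`, `feature_mz`, `empty_segments`, and
#'   `percentile_convention`.
#' @export
segment_spectra <- function(dataset, labels, feature_mz, tol_ppm = 20,
                            label_names = NULL) {
  stopifnot(all(dim(labels) == dataset$grid_shape))
  X <- pixel_feature_matrix(dataset, feature_mz, tol_ppm)
  px_lab <- labels[cbind(dataset$coords[, 1] + 1L, dataset$coords[, 2] + 1L)]
  ids <- sort(unique(px_lab[px_lab > 0]))
  seg_names <- if (!is.null(label_names)) {
    nm <- names(label_names)[match(ids, label_names)]
    ifelse(is.na(nm), as.character(ids), nm)
  } else as.character(ids)
  empty <- if (!is.null(label_names))
    setdiff(names(label_names), seg_names) else character(0)
  mean_m <- p99_m <- matrix(0, length(ids), length(feature_mz),
                            dimnames = list(seg_names, NULL))
  npx <- integer(length(ids))
  for (k in seq_along(ids)) {
    sel <- px_lab == ids[k]
    npx[k] <- sum(sel)
    Xi <- X[sel, , drop = FALSE]
    mean_m[k, ] <- colMeans(Xi)
    p99_m[k, ] <- apply(Xi, 2, stats::quantile, probs = 0.99, type = 7,
                        names = FALSE)
  }
  list(mean = mean_m, p99 = p99_m, n_pixels = stats::setNames(npx, seg_names),
       feature_mz = feature_mz, empty_segments = empty,
       percentile_convention = "type 7 (linear interpolation)")
}

#' Write / read a 16-bit label mask as TIFF
#'
#' @param label_image Integer label matrix (values 0..65535).
#' @param path Output TIFF path.
#' @return `path` invisibly; `read_mask_tiff` returns an integer matrix.
#' @export
write_mask_tiff <- function(label_image, path) {
  stopifnot(all(label_image >= 0), all(label_image <= 65535))
  tiff::writeTIFF(label_image / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  m <- round(img * 65535)
  storage.mode(m) <- "integer"
  m
}

#' Write / read landmark coordinates as CSV
#'
#' Two-column CSV per space (`x`, `y`), row-aligned between spaces.
#' @param points n x 2 matrix of `(x, y)` landmarks.
#' @param path CSV path.
#' @export
write_landmarks_csv <- function(points, path) {
  utils::write.csv(data.frame(x = points[, 1], y = points[, 2]), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_csv <- function(path) {
  d <- utils::read.csv(path)
  as.matrix(d[, c("x", "y")])
}
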