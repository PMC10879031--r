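#' MSI dataset of per-pixel centroid spectra on a 2-D grid
#'
#' The in-memory container for one section in one ionization mode. Pixel
#' coordinates are 0-based `(row, col)` on a `grid_shape = c(rows, cols)`
#' grid; imzML's 1-based `(x, y)` convention is converted at the I/O
#' boundary. Each spectrum is a list with strictly increasing `mz` and
#' non-negative `intensity` of equal length.
#'
#' @param spectra List of `list(mz =, intensity =)`.
#' @param coords Integer matrix (n x 2) of 0-based `(row, col)` pixel
#'   coordinates, one row per spectrum, unique and within the grid.
#' @param grid_shape `c(rows, cols)`.
#' @param pixel_size_um Pixel edge length in micrometres.
#' @param polarity `"positive"` or `"negative"`.
#' @param section_id Section identifier.
#' @param disease_class `"healthy"`, `"mild"`, `"advanced"` or `"unknown"`.
#' @return Object of class `msi_dataset`.
#' @export
msi_dataset <- function(spectra, coords, grid_shape, pixel_size_um = 45,
                        polarity = "positive", section_id = "section",
                        disease_class = "unknown") {
  polarity <- match.arg(polarity, c("positive", "negative"))
  disease_class <- match.arg(disease_class,
                             c("healthy", "mild", "advanced", "unknown"))
  coords <- as.matrix(coords)
  stopifnot(length(spectra) == nrow(coords), ncol(coords) == 2)
  if (any(coords < 0) || any(coords[, 1] >= grid_shape[1]) ||
      any(coords[, 2] >= grid_shape[2]))
    stop("pixel coordinates outside the grid")
  if (anyDuplicated(coords[, 1] * grid_shape[2] + coords[, 2]))
    stop("duplicate pixel coordinates")
  for (s in spectra) {
    if (length(s$mz) != length(s$intensity))
      stop("mz and intensity lengths differ")
    if (length(s$mz) > 1 && any(diff(s$mz) <= 0))
      stop("mz must be strictly increasing")
    if (any(s$intensity < 0)) stop("negative intensity")
  }
  structure(list(spectra = spectra, coords = coords,
                 grid_shape = as.integer(grid_shape),
                 pixel_size_um = pixel_size_um, polarity = polarity,
                 section_id = section_id, disease_class = disease_class),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  npk <- sum(vapply(x$spectra, function(s) length(s$mz), integer(1)))
  cat(sprintf(paste0("<msi_dataset> section '%s' (%s), %d x %d grid, ",
                     "%d pixels, %d peaks, %g um pixels, class %s\n"),
              x$section_id, x$polarity, x$grid_shape[1], x$grid_shape[2],
              length(x$spectra), npk, x$pixel_size_um, x$disease_class))
  invisible(x)
}

#' Mean spectrum intensity image for one m/z window
#'
#' Sums, per pixel, the intensities of all peaks within `tol_ppm` of `mz`
#' and returns the result as a `grid_shape` matrix (zero where no peak
#' matches).
#'
#' @param dataset An `msi_dataset`.
#' @param mz Centre m/z of the window (Da).
#' @param tol_ppm Half-width of the window in ppm.
#' @return Numeric matrix of `grid_shape`.
#' @export
ion_image <- function(dataset, mz, tol_ppm = 20) {
  img <- matrix(0, dataset$grid_shape[1], dataset$grid_shape[2])
  tol <- tol_ppm * 1e-6 * mz
  for (i in seq_along(dataset$spectra)) {
    s <- dataset$spectra[[i]]
    if (!length(s$mz)) next
    sel <- abs(s$mz - mz) <= tol
    if (any(sel))
      img[dataset$coords[i, 1] + 1L, dataset$coords[i, 2] + 1L] <-
        sum(s$intensity[sel])
  }
  img
}
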