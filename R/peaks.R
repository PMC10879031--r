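#' Pick peaks from a centroid spectrum
#'
#' Retains local maxima whose intensity reaches
#' `max(intensity_min, snr_min * noise)`, where the noise level is the
#' median absolute deviation of the intensities scaled by 1.4826 (the
#' consistency factor for a Gaussian, i.e. `stats::mad()` with its default
#' constant). A point is a local maximum if no point within half an
#' instrument-resolution element (`mz / resolution`) on either side is
#' more intense.
#'
#' @param mz,intensity Numeric vectors (strictly increasing `mz`), or pass
#'   a `list(mz =, intensity =)` as the first argument.
#' @param snr_min Minimum signal-to-noise ratio (default 3).
#' @param intensity_min Absolute intensity floor (default 0).
#' @param resolution Instrument resolving power used for the local-maximum
#'   window (default 20000, single-pass reflectron TOF).
#' @return `data.frame` with columns `mz`, `intensity`.
#' @export
pick_peaks <- function(mz, intensity = NULL, snr_min = 3, intensity_min = 0,
                       resolution = 20000) {
  if (is.list(mz) && is.null(intensity)) {
    intensity <- mz$intensity; mz <- mz$mz
  }
  stopifnot(length(mz) == length(intensity))
  if (!length(mz)) return(data.frame(mz = numeric(0), intensity = numeric(0)))
  noise <- stats::mad(intensity)   # MAD x 1.4826
  thr <- max(intensity_min, snr_min * noise)
  keep <- logical(length(mz))
  for (i in seq_along(mz)) {
    if (intensity[i] < thr) next
    half <- mz[i] / (2 * resolution)
    win <- which(mz >= mz[i] - half & mz <= mz[i] + half)
    mx <- max(intensity[win])
    # ties within a resolution element resolve to the lowest m/z
    keep[i] <- intensity[i] == mx && i == win[which(intensity[win] == mx)[1]]
  }
  data.frame(mz = mz[keep], intensity = intensity[keep])
}

#' Estimated carbon count from m/z
#'
#' Lipid-regime heuristic used when no formula is available: about 0.066
#' carbons per Da.
#' @param mz m/z in Da.
#' @return Estimated number of carbons.
#' @export
estimate_carbons <- function(mz) mz * 0.066

#' Remove isotopologue peaks from a centroid peak list
#'
#' Scans peaks in ascending m/z; any peak lying at 1, 2 or 3 times the C13
#' spacing (1.00335 Da) above a retained peak, within `iso_tol_da`, and not
#' exceeding the retained peak's carbon-count-scaled isotope ceiling, is
#' removed. The ceiling for the k-th isotopologue is
#' `intensity * r^k / k! * margin` with `r = 0.0109 x carbon count`
#' (carbons estimated from m/z via [estimate_carbons()]); `margin`
#' tolerates intensity noise. Monoisotopic peaks are always retained, and
#' the operation is idempotent.
#'
#' @param peaks `data.frame` with `mz`, `intensity`, sorted by `mz`.
#' @param iso_tol_da Matching tolerance around each isotope spacing (Da).
#' @param margin Multiplier on the isotope ceiling (default 1.5).
#' @return Filtered `data.frame` of monoisotopic peaks.
#' @export
deisotope <- function(peaks, iso_tol_da = 0.01, margin = 1.5) {
  if (!nrow(peaks)) return(peaks)
  stopifnot(!is.unsorted(peaks$mz))
  n <- nrow(peaks)
  retained <- rep(TRUE, n)
  spacing <- .mass_neutron_c13
  for (i in seq_len(n)) {
    if (!retained[i]) next
    r <- 0.0109 * estimate_carbons(peaks$mz[i])
    for (k in 1:3) {
      ceiling_k <- peaks$intensity[i] * r^k / factorial(k) * margin
      tgt <- peaks$mz[i] + k * spacing
      hits <- which(retained & abs(peaks$mz - tgt) <= iso_tol_da &
                    peaks$intensity <= ceiling_k)
      hits <- hits[hits != i]
      retained[hits] <- FALSE
    }
  }
  out <- peaks[retained, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sections-by-features table of consolidated m/z features
#'
#' @param feature_mz Consolidated feature m/z values (sorted).
#' @param matrix Sections (or segments) x features intensity matrix.
#' @param presence Logical sections x features presence matrix.
#' @param statistic Which per-section statistic the matrix holds.
#' @param section_ids Row identifiers.
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(feature_mz, matrix, presence,
                          statistic = "mean", section_ids = rownames(matrix)) {
  stopifnot(length(feature_mz) == ncol(matrix),
            all(dim(presence) == dim(matrix)),
            !is.unsorted(feature_mz), all(matrix >= 0))
  structure(list(feature_mz = feature_mz, matrix = matrix,
                 presence = presence, statistic = statistic,
                 section_ids = section_ids),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d sections x %d features (%s), m/z %.4f-%.4f\n",
              nrow(x$matrix), length(x$feature_mz), x$statistic,
              min(x$feature_mz), max(x$feature_mz)))
  invisible(x)
}

#' Consolidate per-section peak lists into a feature table
#'
#' Pools the peaks of all sections, sorts them by m/z, and forms features
#' by single-linkage clustering: a new feature starts wherever the gap to
#' the previous peak exceeds `mz_tol_ppm`. Each feature's m/z is the
#' intensity-weighted mean of its member peaks. A feature is present in a
#' section if the cluster contains at least one of that section's peaks;
#' its intensity there is the mean of those peaks (0 when absent — no
#' imputation).
#'
#' @param peak_lists Named list of per-section `data.frame(mz, intensity)`.
#' @param mz_tol_ppm Consolidation tolerance in ppm (default 20).
#' @return A [feature_table()].
#' @export
consolidate_features <- function(peak_lists, mz_tol_ppm = 20) {
  if (mz_tol_ppm <= 0) stop("mz_tol_ppm must be positive")
  stopifnot(length(peak_lists) >= 1)
  if (is.null(names(peak_lists)))
    names(peak_lists) <- paste0("S", seq_along(peak_lists))
  pooled <- do.call(rbind, lapply(names(peak_lists), function(nm) {
    p <- peak_lists[[nm]]
    if (!nrow(p)) return(NULL)
    data.frame(section = nm, mz = p$mz, intensity = p$intensity)
  }))
  ids <- names(peak_lists)
  if (is.null(pooled) || !nrow(pooled)) {
    m <- matrix(0, length(ids), 0, dimnames = list(ids, NULL))
    return(feature_table(numeric(0), m, m > 0, "peak", ids))
  }
  pooled <- pooled[order(pooled$mz), ]
  gap <- diff(pooled$mz)
  brk <- gap > mz_tol_ppm * 1e-6 * pooled$mz[-nrow(pooled)]
  cl <- cumsum(c(TRUE, brk))
  nf <- max(cl)
  fmz <- numeric(nf)
  mat <- matrix(0, length(ids), nf, dimnames = list(ids, NULL))
  pres <- matrix(FALSE, length(ids), nf, dimnames = list(ids, NULL))
  for (f in seq_len(nf)) {
    sel <- cl == f
    w <- pooled$intensity[sel]
    fmz[f] <- if (sum(w) > 0) stats::weighted.mean(pooled$mz[sel], w)
              else mean(pooled$mz[sel])
    agg <- tapply(pooled$intensity[sel], pooled$section[sel], mean)
    mat[names(agg), f] <- agg
    pres[names(agg), f] <- TRUE
  }
  ord <- order(fmz)
  feature_table(fmz[ord], mat[, ord, drop = FALSE], pres[, ord, drop = FALSE],
                "peak", ids)
}

#' Keep features present in at least `min_sections` sections
#'
#' The study-design prevalence filter (e.g. "at least 5 of 17 sections").
#'
#' @param table A [feature_table()].
#' @param min_sections Minimum number of sections a feature must be
#'   present in; must lie in `[1, n_sections]`.
#' @return Filtered [feature_table()].
#' @export
prevalence_filter <- function(table, min_sections) {
  stopifnot(inherits(table, "feature_table"))
  n <- nrow(table$matrix)
  if (min_sections < 1 || min_sections > n)
    stop("min_sections must be between 1 and the number of sections (", n, ")")
  keep <- colSums(table$presence) >= min_sections
  feature_table(table$feature_mz[keep],
                table$matrix[, keep, drop = FALSE],
                table$presence[, keep, drop = FALSE],
                table$statistic, table$section_ids)
}

#' Per-pixel intensities of consolidated features
#'
#' For every pixel of a dataset, sums the intensities of its peaks within
#' `tol_ppm` of each feature m/z (0 where no peak matches). Rows follow the
#' dataset's pixel order (`dataset$coords`).
#'
#' @param dataset An [msi_dataset()].
#' @param feature_mz Sorted numeric vector of feature m/z values.
#' @param tol_ppm Matching tolerance in ppm.
#' @return Numeric matrix, pixels x features.
#' @export
pixel_feature_matrix <- function(dataset, feature_mz, tol_ppm = 20) {
  stopifnot(inherits(dataset, "msi_dataset"), !is.unsorted(feature_mz))
  n <- length(dataset$spectra)
  X <- matrix(0, n, length(feature_mz))
  if (!length(feature_mz)) return(X)
  tol <- tol_ppm * 1e-6 * feature_mz
  for (i in seq_len(n)) {
    s <- dataset$spectra[[i]]
    if (!length(s$mz)) next
    # nearest feature for each peak, then tolerance check
    j <- findInterval(s$mz, feature_mz)
    jlo <- pmax(j, 1L); jhi <- pmin(j + 1L, length(feature_mz))
    dlo <- abs(s$mz - feature_mz[jlo]); dhi <- abs(s$mz - feature_mz[jhi])
    near <- ifelse(dlo <= dhi, jlo, jhi)
    ok <- abs(s$mz - feature_mz[near]) <= tol[near]
    if (any(ok)) {
      agg <- tapply(s$intensity[ok], near[ok], sum)
      X[i, as.integer(names(agg))] <- agg
    }
  }
  X
}

#' Section-level peak list from all pixels of a dataset
#'
#' Picks peaks per pixel, pools them, and collapses the pooled list into a
#' section-level centroid list by the same single-linkage gap clustering
#' used for cross-section consolidation; each cluster's intensity is the
#' summed pixel intensity divided by the number of pixels (mean spectrum
#' contribution).
#'
#' @inheritParams pick_peaks
#' @param dataset An [msi_dataset()].
#' @param mz_tol_ppm Within-section clustering tolerance (ppm).
#' @return `data.frame(mz, intensity)` sorted by m/z.
#' @export
section_peak_list <- function(dataset, snr_min = 3, intensity_min = 0,
                              resolution = 20000, mz_tol_ppm = 20) {
  picked <- lapply(dataset$spectra, pick_peaks, snr_min = snr_min,
                   intensity_min = intensity_min, resolution = resolution)
  pooled <- do.call(rbind, picked)
  if (is.null(pooled) || !nrow(pooled))
    return(data.frame(mz = numeric(0), intensity = numeric(0)))
  pooled <- pooled[order(pooled$mz), ]
  gap <- diff(pooled$mz)
  brk <- gap > mz_tol_ppm * 1e-6 * pooled$mz[-nrow(pooled)]
  cl <- cumsum(c(TRUE, brk))
  mzv <- as.numeric(tapply(pooled$mz * pooled$intensity, cl, sum) /
                    pmax(tapply(pooled$intensity, cl, sum), .Machine$double.eps))
  inten <- as.numeric(tapply(pooled$intensity, cl, sum)) / length(dataset$spectra)
  ord <- order(mzv)
  data.frame(mz = mzv[ord], intensity = inten[ord])
}
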