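#' Top-intensity-fraction mask of an ion image
#'
#' Selects exactly `ceiling(fraction * n)` pixels — the most intense ones —
#' among the `n` pixels of the `within` mask (by default the artery
#' segmentation, so the threshold is taken per section over artery
#' pixels). Ties at the threshold are broken deterministically by
#' row-major pixel order.
#'
#' @param ion_image Numeric intensity matrix.
#' @param fraction Fraction of pixels to select, in (0, 1); default 0.10.
#' @param within Logical mask of eligible pixels (same dimensions);
#'   default: all pixels.
#' @return Logical matrix marking the selected pixels.
#' @export
top_fraction_mask <- function(ion_image, fraction = 0.10, within = NULL) {
  stopifnot(is.matrix(ion_image), fraction > 0, fraction < 1)
  if (is.null(within)) within <- matrix(TRUE, nrow(ion_image), ncol(ion_image))
  stopifnot(all(dim(within) == dim(ion_image)))
  idx <- which(within, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty 'within' mask")
  n_sel <- ceiling(fraction * nrow(idx))
  rm_order <- (idx[, 1] - 1L) * ncol(ion_image) + idx[, 2]  # row-major rank
  inten <- ion_image[idx]
  sel <- order(-inten, rm_order)[seq_len(n_sel)]
  out <- matrix(FALSE, nrow(ion_image), ncol(ion_image))
  out[idx[sel, , drop = FALSE]] <- TRUE
  out
}

#' Percentage of a region covered by a top-intensity mask
#'
#' `100 * |region AND top| / |region|`. An empty region is undefined and
#' returns `NA` with a warning.
#'
#' @param region_mask,top_mask Logical matrices on the same grid.
#' @return Percentage in `[0, 100]`, or `NA` for an empty region.
#' @export
overlap_percentage <- function(region_mask, top_mask) {
  stopifnot(all(dim(region_mask) == dim(top_mask)))
  n <- sum(region_mask)
  if (n == 0) {
    warning("empty region; overlap undefined")
    return(NA_real_)
  }
  100 * sum(region_mask & top_mask) / n
}

#' Colocalization of ion images with histological regions
#'
#' The two-step colocalization statistic: (1) the `fraction` most intense
#' pixels of each feature's ion image inside `within` are identified;
#' (2) for each histological region the percentage of region pixels inside
#' that top mask is computed. An empirical null is built by placing an
#' equal-sized random pixel set inside `within` (`n_null` draws), giving a
#' baseline expectation (about `100 * fraction` for spatially unstructured
#' images) and an empirical p-value
#' `(1 + #{null >= observed}) / (1 + n_null)`. Features with an all-zero
#' image inside `within` are flagged and reported with `NA` overlap.
#'
#' @param images Named list of ion-image matrices (one per feature).
#' @param regions Named list of logical region masks (e.g. necrotic core,
#'   inflammatory cells), on the same grid.
#' @param within Logical mask restricting the analysis (default: all
#'   pixels).
#' @param fraction Top-intensity fraction (default 0.10).
#' @param n_null Null draws (default 1000).
#' @param seed Seed for the null draws.
#' @param annotations Optional [best_annotation()] table; joined on the
#'   numeric value of the image names.
#' @return `data.frame` with one row per (feature, region):
#'   `feature`, `region`, `percent_overlap`, `region_size`, `null_mean`,
#'   `p_value`, `flagged`.
#' @export
colocalization_table <- function(images, regions, within = NULL,
                                 fraction = 0.10, n_null = 1000, seed = 0,
                                 annotations = NULL) {
  stopifnot(length(images) >= 1, length(regions) >= 1)
  g <- dim(images[[1]])
  if (is.null(within)) within <- matrix(TRUE, g[1], g[2])
  set.seed(seed)
  idx_within <- which(within)
  n_w <- length(idx_within)
  n_sel <- ceiling(fraction * n_w)
  # shared null draws: random equal-size pixel sets inside `within`
  null_masks <- lapply(seq_len(n_null), function(b) {
    m <- matrix(FALSE, g[1], g[2])
    m[sample(idx_within, n_sel)] <- TRUE
    m
  })
  rows <- list()
  for (fi in seq_along(images)) {
    img <- images[[fi]]
    fname <- names(images)[fi] %||% as.character(fi)
    zero <- all(img[within] == 0)
    top <- if (!zero) top_fraction_mask(img, fraction, within) else NULL
    for (ri in seq_along(regions)) {
      reg <- regions[[ri]] & within
      rname <- names(regions)[ri] %||% as.character(ri)
      rsize <- sum(reg)
      if (zero || rsize == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          feature = fname, region = rname, percent_overlap = NA_real_,
          region_size = rsize, null_mean = NA_real_, p_value = NA_real_,
          flagged = TRUE)
        next
      }
      obs <- overlap_percentage(reg, top)
      null_ov <- vapply(null_masks, function(m) 100 * sum(reg & m) / rsize,
                        numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        feature = fname, region = rname, percent_overlap = obs,
        region_size = rsize, null_mean = mean(null_ov),
        p_value = (1 + sum(null_ov >= obs)) / (1 + n_null),
        flagged = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(annotations)) {
    # nearest-m/z join: feature names carry rounded m/z values
    fm <- suppressWarnings(as.numeric(out$feature))
    j <- vapply(fm, function(v) {
      if (is.na(v)) return(NA_integer_)
      d <- abs(annotations$feature_mz - v)
      if (min(d) <= 1e-3) which.min(d) else NA_integer_
    }, integer(1))
    out$annotation <- annotations$name[j]
  }
  rownames(out) <- NULL
  out
}
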