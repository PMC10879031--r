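#' Annotate feature m/z values by exact mass
#'
#' Matches consolidated feature m/z values against a lipid reference table
#' under every polarity-appropriate adduct, keeping all candidates whose
#' signed mass error is within `ppm_max` (the conventional 15 ppm bound for
#' TOF lipid annotation). All candidates are reported, ranked per feature
#' by absolute ppm error: sum-composition exact-mass annotation cannot
#' resolve isobars, so no winner is forced. Features with no candidate are
#' returned as one unannotated row.
#'
#' @param feature_mz Numeric vector of feature m/z values (Da).
#' @param polarity `"positive"` (adducts `[M+H]+`, `[M+Na]+`, `[M+K]+`) or
#'   `"negative"` (`[M-H]-`).
#' @param reference Reference table as from [read_reference_table()].
#' @param ppm_max Maximum absolute ppm error (default 15).
#' @return `data.frame` with columns `feature_mz`, `name`, `class`,
#'   `adduct`, `theoretical_mz`, `ppm`, `annotated`; one row per candidate
#'   (or per unannotated feature, with NA candidate fields).
#' @export
annotate_features <- function(feature_mz, polarity, reference, ppm_max = 15) {
  polarity <- match.arg(polarity, c("positive", "negative"))
  stopifnot(is.data.frame(reference), nrow(reference) > 0, ppm_max > 0)
  adducts <- polarity_adducts(polarity)
  # candidate grid: records x adducts
  theo <- outer(reference$mass, unname(adduct_shifts()[adducts]), `+`)
  out <- vector("list", length(feature_mz))
  for (i in seq_along(feature_mz)) {
    fmz <- feature_mz[i]
    ppm <- 1e6 * (fmz - theo) / theo
    hit <- which(abs(ppm) <= ppm_max, arr.ind = TRUE)
    if (nrow(hit) == 0) {
      out[[i]] <- data.frame(feature_mz = fmz, name = NA_character_,
        class = NA_character_, adduct = NA_character_,
        theoretical_mz = NA_real_, ppm = NA_real_, annotated = FALSE,
        stringsAsFactors = FALSE)
    } else {
      cand <- data.frame(
        feature_mz = fmz,
        name = reference$name[hit[, 1]],
        class = reference$class[hit[, 1]],
        adduct = adducts[hit[, 2]],
        theoretical_mz = theo[hit],
        ppm = ppm[hit],
        annotated = TRUE,
        stringsAsFactors = FALSE)
      out[[i]] <- cand[order(abs(cand$ppm)), , drop = FALSE]
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Confirm annotations against a high-mass-accuracy peak list
#'
#' Emulates a confirmation pass with a high-resolution instrument: an
#' annotation is flagged `confirmed` when some high-accuracy m/z matches
#' its theoretical m/z within `ppm_confirm` (a much tighter tolerance than
#' the annotation bound).
#'
#' @param annotations Output of [annotate_features()].
#' @param high_accuracy_mz Numeric vector of accurately measured m/z.
#' @param ppm_confirm Confirmation tolerance in ppm (default 3); must be
#'   tighter than the tolerance the annotations were made at.
#' @return `annotations` with a logical `confirmed` column.
#' @export
confirm_with_high_accuracy <- function(annotations, high_accuracy_mz,
                                       ppm_confirm = 3) {
  stopifnot(ppm_confirm > 0)
  conf <- rep(FALSE, nrow(annotations))
  if (length(high_accuracy_mz)) {
    for (i in seq_len(nrow(annotations))) {
      tm <- annotations$theoretical_mz[i]
      if (is.na(tm)) next
      conf[i] <- any(abs(1e6 * (high_accuracy_mz - tm) / tm) <= ppm_confirm)
    }
  }
  annotations$confirmed <- conf
  annotations
}

#' Best annotation label per feature
#'
#' Convenience: collapses an annotation table to one row per feature,
#' keeping the lowest-|ppm| candidate (NA for unannotated features).
#' @param annotations Output of [annotate_features()].
#' @return `data.frame` with one row per distinct `feature_mz`.
#' @export
best_annotation <- function(annotations) {
  sp <- split(annotations, annotations$feature_mz)
  out <- do.call(rbind, lapply(sp, function(d) {
    d[order(!d$annotated, abs(d$ppm)), , drop = FALSE][1, , drop = FALSE]
  }))
  out <- out[order(out$feature_mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}
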