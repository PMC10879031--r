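#' Pipeline configuration
#'
#' Collects the section manifest and per-stage parameters. Parameter
#' defaults are the study-convention values: SNR 3 peak picking, 20 ppm
#' feature consolidation, prevalence filter of 5 sections, 15 ppm
#' annotation, 10% top-intensity colocalization fraction, 7 CV folds,
#' VIP threshold 1.0. Any override is recorded in the provenance log.
#'
#' @param manifest `data.frame` with columns `section_id`, `polarity`,
#'   `class` (healthy/mild/advanced/unknown), `imzml` (file path), and
#'   optionally `mask` (label TIFF), `labelmap` (JSON id->name),
#'   `landmarks_histo`, `landmarks_msi` (CSV paths).
#' @param outdir Output directory for artifacts.
#' @param params Named list of overrides; see Details.
#' @return Object of class `pipeline_config`.
#' @details Available parameters and defaults: `snr_min = 3`,
#'   `intensity_min = 0`, `resolution = 20000`, `iso_tol_da = 0.01`,
#'   `mz_tol_ppm = 20`, `min_sections = 5`, `ppm_max = 15`,
#'   `fraction = 0.10`, `folds = 7`, `vip_threshold = 1.0`,
#'   `k_range = 2:6`, `n_perm = 100`, `n_null = 200`, `exclusion_q = 0.9`,
#'   `scaling = "uv"`, `seed = 1`, `reference_csv = NULL` (bundled table).
#' @export
pipeline_config <- function(manifest, outdir = tempfile("lipidmsi_run"),
                            params = list()) {
  defaults <- list(snr_min = 3, intensity_min = 0, resolution = 20000,
                   iso_tol_da = 0.01, mz_tol_ppm = 20, min_sections = 5,
                   ppm_max = 15, fraction = 0.10, folds = 7,
                   vip_threshold = 1.0, k_range = 2:6, n_perm = 100,
                   n_null = 200, exclusion_q = 0.9, scaling = "uv",
                   seed = 1, reference_csv = NULL)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p <- utils::modifyList(defaults, params)
  manifest <- as.data.frame(manifest)
  req <- c("section_id", "polarity", "class", "imzml")
  if (!all(req %in% names(manifest)))
    stop("manifest needs columns: ", paste(req, collapse = ", "))
  missing_files <- manifest$imzml[!file.exists(manifest$imzml)]
  if (length(missing_files))
    stop("manifest imzML file(s) not found: ",
         paste(missing_files, collapse = ", "))
  bad <- setdiff(manifest$class, c("healthy", "mild", "advanced", "unknown"))
  if (length(bad)) stop("unknown disease class: ", paste(bad, collapse = ", "))
  for (pol in unique(manifest$polarity)) {
    n_pol <- sum(manifest$polarity == pol)
    if (p$min_sections > n_pol)
      stop("min_sections (", p$min_sections, ") exceeds the number of ",
           pol, "-mode sections (", n_pol, ")")
  }
  structure(list(manifest = manifest, outdir = outdir, params = p,
                 overrides = names(params)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML holds `manifest` (list of records), optional `params`, and
#' optional `outdir`; relative file paths are resolved against the YAML's
#' directory.
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  man <- do.call(rbind, lapply(y$manifest, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  for (col in intersect(c("imzml", "mask", "labelmap", "landmarks_histo",
                          "landmarks_msi"), names(man))) {
    rel <- !is.na(man[[col]]) & nzchar(man[[col]]) &
           !grepl("^(/|[A-Za-z]:)", man[[col]])
    man[[col]][rel] <- file.path(base, man[[col]][rel])
  }
  params <- y$params %||% list()
  if (!is.null(params$k_range)) params$k_range <- as.integer(params$k_range)
  pipeline_config(man, outdir = y$outdir %||% file.path(base, "results"),
                  params = params)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, per ionization mode: ingest (imzML) -> per-pixel peak picking
#' -> deisotoping -> cross-section feature consolidation -> prevalence
#' filter -> exact-mass annotation -> landmark registration and mask
#' projection -> per-segment mean/p99 spectra -> NMF (whole tissue, then
#' artery-only, with K-means rank selection) -> colocalization of features
#' with necrotic-core/inflammatory regions; then, across modes: tissue
#' OPLS-DA (one-vs-rest) -> myocardium-feature exclusion -> artery PCA and
#' two-group OPLS-DA (healthy+mild vs advanced) with Q2, CV-ANOVA,
#' permutation test and VIP. Artifacts (CSV/JSON) and a machine-readable
#' provenance log are written under `config$outdir`.
#'
#' @param config A [pipeline_config()].
#' @return List of per-stage results, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$params
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  ref <- stage("reference", if (is.null(p$reference_csv))
    read_reference_table() else read_reference_table(p$reference_csv))
  res <- list(polarity = list())

  for (pol in unique(config$manifest$polarity)) {
    man <- config$manifest[config$manifest$polarity == pol, , drop = FALSE]
    datasets <- stage("ingest", lapply(man$imzml, read_imzml))
    for (i in seq_along(datasets)) {
      datasets[[i]]$section_id <- man$section_id[i]
      datasets[[i]]$disease_class <- man$class[i]
    }
    peaks <- stage("peaks", lapply(datasets, section_peak_list,
      snr_min = p$snr_min, intensity_min = p$intensity_min,
      resolution = p$resolution, mz_tol_ppm = p$mz_tol_ppm))
    peaks <- stage("deisotope", lapply(peaks, deisotope,
                                       iso_tol_da = p$iso_tol_da))
    names(peaks) <- man$section_id
    feats <- stage("consolidate", consolidate_features(peaks, p$mz_tol_ppm))
    feats <- stage("prevalence", prevalence_filter(feats, p$min_sections))
    ann <- stage("annotate", annotate_features(feats$feature_mz, pol, ref,
                                               p$ppm_max))
    # registration & segmentation
    labels <- vector("list", nrow(man))
    label_names_all <- NULL
    if (all(c("mask", "landmarks_histo", "landmarks_msi") %in% names(man))) {
      for (i in seq_len(nrow(man))) {
        if (is.na(man$mask[i]) || !nzchar(man$mask[i])) next
        lm_h <- read_landmarks_csv(man$landmarks_histo[i])
        lm_m <- read_landmarks_csv(man$landmarks_msi[i])
        tf <- stage("register", fit_similarity_transform(lm_h, lm_m))
        lbl_names <- NULL
        if ("labelmap" %in% names(man) && !is.na(man$labelmap[i])) {
          lm <- jsonlite::read_json(man$labelmap[i], simplifyVector = TRUE)
          lbl_names <- stats::setNames(as.integer(lm), names(lm))
        }
        msk <- segmentation_mask(read_mask_tiff(man$mask[i]), lbl_names, tf)
        labels[[i]] <- stage("project",
                             project_mask(msk, datasets[[i]]$grid_shape))
        label_names_all <- lbl_names %||% label_names_all
      }
    }
    # coarse tissue segments for the summary spectra: the artery segment is
    # the union of all intra-arterial labels (wall layers, plaque regions)
    artery_ids <- if (!is.null(label_names_all))
      label_names_all[names(label_names_all) %in%
                      c("artery", "media", "plaque", "intima", "adventitia",
                        "necrotic_core", "inflammatory")] else 1L
    coarse_names <- c(myocardium = 1L, PVAT = 2L, artery = 3L)
    coarse_label <- function(lbl) {
      cl <- matrix(0L, nrow(lbl), ncol(lbl))
      if (!is.null(label_names_all)) {
        if ("myocardium" %in% names(label_names_all))
          cl[lbl == label_names_all[["myocardium"]]] <- 1L
        if ("PVAT" %in% names(label_names_all))
          cl[lbl == label_names_all[["PVAT"]]] <- 2L
      }
      cl[lbl %in% artery_ids] <- 3L
      cl
    }
    seg <- vector("list", nrow(man))
    for (i in seq_len(nrow(man))) {
      lbl <- labels[[i]]
      if (is.null(lbl)) {  # no mask: the whole grid is one artery segment
        lbl <- matrix(unname(artery_ids[1]),
                      datasets[[i]]$grid_shape[1], datasets[[i]]$grid_shape[2])
      }
      seg[[i]] <- stage("segment", segment_spectra(datasets[[i]],
        coarse_label(lbl), feats$feature_mz, p$mz_tol_ppm,
        label_names = coarse_names))
    }
    names(seg) <- man$section_id
    # NMF on concatenated pixels: whole tissue, then artery only
    Xpix <- lapply(seq_along(datasets), function(i)
      pixel_feature_matrix(datasets[[i]], feats$feature_mz, p$mz_tol_ppm))
    tissue_sel <- lapply(seq_along(datasets), function(i) {
      lbl <- labels[[i]]
      if (is.null(lbl)) rep(TRUE, nrow(Xpix[[i]])) else {
        v <- lbl[cbind(datasets[[i]]$coords[, 1] + 1L,
                       datasets[[i]]$coords[, 2] + 1L)]
        v > 0
      }
    })
    artery_sel <- lapply(seq_along(datasets), function(i) {
      lbl <- labels[[i]]
      if (is.null(lbl)) rep(TRUE, nrow(Xpix[[i]])) else {
        v <- lbl[cbind(datasets[[i]]$coords[, 1] + 1L,
                       datasets[[i]]$coords[, 2] + 1L)]
        v %in% artery_ids
      }
    })
    nmf_run <- function(sel_list, tag) {
      X <- do.call(rbind, lapply(seq_along(Xpix), function(i)
        Xpix[[i]][sel_list[[i]], , drop = FALSE]))
      k <- stage(paste0("select_rank_", tag),
                 select_rank(X, p$k_range, seed = p$seed))
      fit <- stage(paste0("nmf_", tag),
                   run_nmf(X, k, seed = p$seed, max_iter = 300))
      list(k = as.integer(k), silhouette = attr(k, "silhouette"), fit = fit)
    }
    nmf_tissue <- nmf_run(tissue_sel, "tissue")
    nmf_artery <- nmf_run(artery_sel, "artery")
    # colocalization in sections with annotated plaque regions
    coloc <- NULL
    if (!is.null(label_names_all) &&
        any(c("necrotic_core", "inflammatory") %in% names(label_names_all))) {
      tabs <- list()
      for (i in seq_len(nrow(man))) {
        lbl <- labels[[i]]
        if (is.null(lbl)) next
        regs <- list()
        for (rn in intersect(c("necrotic_core", "inflammatory"),
                             names(label_names_all))) {
          m <- lbl == label_names_all[[rn]]
          if (any(m)) regs[[rn]] <- m
        }
        if (!length(regs)) next
        within <- matrix(FALSE, nrow(lbl), ncol(lbl))
        within[lbl %in% artery_ids] <- TRUE
        imgs <- lapply(seq_along(feats$feature_mz), function(j)
          ion_image(datasets[[i]], feats$feature_mz[j], p$mz_tol_ppm))
        names(imgs) <- sprintf("%.4f", feats$feature_mz)
        tab <- stage("colocalization", colocalization_table(imgs, regs,
          within, p$fraction, n_null = p$n_null, seed = p$seed,
          annotations = best_annotation(ann)))
        tab$section_id <- man$section_id[i]
        tabs[[length(tabs) + 1]] <- tab
      }
      if (length(tabs)) coloc <- do.call(rbind, tabs)
    }
    res$polarity[[pol]] <- list(manifest = man, features = feats,
      annotations = ann, segments = seg, nmf_tissue = nmf_tissue,
      nmf_artery = nmf_artery, colocalization = coloc)
    # per-polarity artifacts
    utils::write.csv(
      data.frame(mz = round(feats$feature_mz, 4), t(feats$matrix)),
      file.path(config$outdir, paste0("features_", pol, ".csv")),
      row.names = FALSE)
    utils::write.csv(ann, file.path(config$outdir,
      paste0("annotations_", pol, ".csv")), row.names = FALSE)
    utils::write.csv(
      data.frame(component = seq_len(nmf_artery$k), nmf_artery$fit$H),
      file.path(config$outdir, paste0("nmf_artery_H_", pol, ".csv")),
      row.names = FALSE)
    if (!is.null(coloc))
      utils::write.csv(coloc, file.path(config$outdir,
        paste0("colocalization_", pol, ".csv")), row.names = FALSE)
  }

  # multivariate models on p99 artery (and tissue) segment intensities
  res$multivariate <- stage("multivariate", {
    pols <- names(res$polarity)
    sec_ids <- unique(config$manifest$section_id)
    p99_block <- function(pol, segment) {
      pr <- res$polarity[[pol]]
      nf <- length(pr$features$feature_mz)
      M <- matrix(0, length(sec_ids), nf,
                  dimnames = list(sec_ids,
                    sprintf("%s_%.4f", pol, pr$features$feature_mz)))
      for (sid in pr$manifest$section_id) {
        sg <- pr$segments[[sid]]
        if (segment %in% rownames(sg$p99)) M[sid, ] <- sg$p99[segment, ]
      }
      M
    }
    seg_names <- unique(unlist(lapply(res$polarity, function(pr)
      unlist(lapply(pr$segments, function(s) rownames(s$p99))))))
    artery_seg <- if ("artery" %in% seg_names) "artery" else seg_names[1]
    X_art <- do.call(cbind, lapply(pols, p99_block, segment = artery_seg))
    classes <- config$manifest$class[match(sec_ids, config$manifest$section_id)]
    mv <- list()
    # tissue-level model and myocardium-feature exclusion
    excluded <- integer(0)
    tissue_segs <- intersect(c("myocardium", "PVAT", artery_seg), seg_names)
    if (length(tissue_segs) >= 2) {
      Xt <- do.call(rbind, lapply(tissue_segs, function(sgn)
        do.call(cbind, lapply(pols, p99_block, segment = sgn))))
      yt <- rep(tissue_segs, each = length(sec_ids))
      obs_t <- assemble_observations(Xt, yt, scaling = p$scaling)
      suppressWarnings(
        mv$tissue <- fit_oplsda_ovr(obs_t, n_ortho = 1, folds = p$folds,
                                    cv_seed = p$seed))
      if ("myocardium" %in% names(mv$tissue)) {
        keep_idx <- setdiff(seq_len(ncol(Xt)), obs_t$dropped)
        exc_local <- exclude_features_by_coefficient(mv$tissue$myocardium,
                                                     p$exclusion_q)
        excluded <- keep_idx[exc_local]
      }
    }
    mv$excluded_features <- excluded
    X_art2 <- if (length(excluded)) X_art[, -excluded, drop = FALSE] else X_art
    known <- classes %in% c("healthy", "mild", "advanced")
    if (sum(known) >= 4 && length(unique(classes[known])) >= 2) {
      obs3 <- suppressWarnings(assemble_observations(
        X_art2[known, , drop = FALSE], classes[known], scaling = p$scaling))
      mv$pca_artery <- fit_pca(obs3, n_comp = min(3, min(dim(obs3$X))))
      if (length(unique(classes[known])) == 3)
        mv$oplsda_3class <- tryCatch(
          suppressWarnings(fit_oplsda_ovr(obs3, n_ortho = 0,
            folds = p$folds, cv_seed = p$seed)), error = function(e) NULL)
      obs2 <- suppressWarnings(assemble_observations(
        X_art2[known, , drop = FALSE], classes[known], scaling = p$scaling,
        group_nonathero = TRUE))
      if (nlevels(obs2$y) == 2 && min(table(obs2$y)) >= 2) {
        m2 <- fit_oplsda(obs2, n_ortho = 0, folds = p$folds, cv_seed = p$seed,
                         positive_class = "atherosclerotic")
        mv$oplsda_2group <- m2
        mv$cv_anova <- cv_anova(m2)
        mv$permutation <- permutation_test(m2, n_perm = p$n_perm,
                                           seed = p$seed)
        mv$vip <- vip_scores(m2, p$vip_threshold)
      }
    }
    mv
  })
  if (!is.null(res$multivariate$oplsda_2group)) {
    m2 <- res$multivariate$oplsda_2group
    jsonlite::write_json(list(
      R2Y = m2$R2Y, Q2 = m2$Q2, n_ortho = m2$n_ortho,
      cv_anova_p = res$multivariate$cv_anova$p_value,
      permutation_p = res$multivariate$permutation$p_value),
      file.path(config$outdir, "model_summary.json"), auto_unbox = TRUE,
      digits = NA)
    utils::write.csv(data.frame(feature = names(m2$VIP), vip = m2$VIP,
                                coefficient = m2$coefficients),
      file.path(config$outdir, "vip_coefficients.csv"), row.names = FALSE)
  }
  prov <- list(package = "lipidmsi",
               version = as.character(utils::packageVersion("lipidmsi")),
               parameters = p[!vapply(p, is.null, logical(1))],
               overrides = config$overrides,
               n_sections = nrow(config$manifest),
               polarities = unique(config$manifest$polarity))
  jsonlite::write_json(prov, file.path(config$outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Simulate a phantom cohort and write it as files
#'
#' Generates a [make_cohort()] phantom cohort (with myocardium and PVAT
#' context regions) and writes, per section: imzML+ibd spectra, a 16-bit
#' histology-space label TIFF (through the inverse of `transform`), a JSON
#' label map, and landmark CSVs for both spaces; plus a cohort-level
#' species table CSV and a pipeline YAML config.
#'
#' @param outdir Output directory.
#' @param n_sections,class_assignment,effect_size,seed,polarity,noise_sd
#'   Passed to [make_cohort()].
#' @param transform Histology-to-MSI similarity `c(s, tx, ty)` used when
#'   emitting masks (default `c(0.5, -2, -1)`, i.e. histology at twice the
#'   MSI resolution, with a translation that keeps the whole MSI grid
#'   inside the histology field of view).
#' @param params Pipeline parameter overrides stored in the YAML.
#' @return Path to the written YAML config.
#' @export
simulate_cohort <- function(outdir, n_sections = 17,
                            class_assignment = rep(c("healthy", "mild", "advanced"),
                                                   c(6, 6, 5)),
                            effect_size = 1, seed = 0, polarity = "positive",
                            noise_sd = 0.05, transform = c(0.5, -2, -1),
                            params = list()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cohort <- make_cohort(n_sections, class_assignment, effect_size, seed,
                        polarity, include_tissue_context = TRUE,
                        noise_sd = noise_sd)
  manifest <- list()
  for (i in seq_along(cohort)) {
    ds <- cohort[[i]]$dataset
    tr <- cohort[[i]]$truth
    base <- sprintf("%s_%s", ds$section_id, polarity)
    write_imzml(ds, file.path(outdir, paste0(base, ".imzML")))
    em <- emit_histology_masks(tr, transform)
    write_mask_tiff(em$label_image, file.path(outdir, paste0(base, "_mask.tiff")))
    jsonlite::write_json(as.list(em$label_names),
      file.path(outdir, paste0(base, "_labels.json")), auto_unbox = TRUE)
    write_landmarks_csv(cbind(em$landmarks$hx, em$landmarks$hy),
      file.path(outdir, paste0(base, "_landmarks_histo.csv")))
    write_landmarks_csv(cbind(em$landmarks$mx, em$landmarks$my),
      file.path(outdir, paste0(base, "_landmarks_msi.csv")))
    manifest[[i]] <- list(section_id = ds$section_id, polarity = polarity,
      class = ds$disease_class, imzml = paste0(base, ".imzML"),
      mask = paste0(base, "_mask.tiff"), labelmap = paste0(base, "_labels.json"),
      landmarks_histo = paste0(base, "_landmarks_histo.csv"),
      landmarks_msi = paste0(base, "_landmarks_msi.csv"))
    utils::write.csv(tr$species_table,
      file.path(outdir, paste0(base, "_species.csv")), row.names = FALSE)
  }
  cfg_path <- file.path(outdir, "pipeline.yaml")
  yaml::write_yaml(list(manifest = manifest, params = params,
                        outdir = file.path(outdir, "results")), cfg_path)
  cfg_path
}
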