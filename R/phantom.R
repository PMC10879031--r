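#' Region specification for a synthetic MSI phantom
#'
#' A region is a labelled geometric shape carrying a lipid signature: a set
#' of (species, adduct, base intensity) triples planted at every pixel of
#' the region. `bleed` leaks a fraction of the signature into the one-pixel
#' neighbourhood of the region, emulating the spatial mixing seen at
#' tissue-boundary pixels.
#'
#' @param label Region name (e.g. `"media"`, `"plaque"`, `"necrotic_core"`,
#'   `"inflammatory"`, `"PVAT"`, `"myocardium"`).
#' @param geometry A list describing the shape, one of:
#'   `list(type = "annulus", center = c(row, col), r_inner =, r_outer =)`,
#'   `list(type = "ellipse", center = c(row, col), a =, b =)` (a = row
#'   semi-axis), `list(type = "rect", rows = c(r1, r2), cols = c(c1, c2))`,
#'   `list(type = "blobs", centers = list(c(row, col), ...), radius =)`.
#'   Coordinates are 1-based pixel centers.
#' @param signature `data.frame` with columns `name` (species in the
#'   reference table), `adduct`, `intensity` (base intensity, >= 0).
#' @param bleed Fraction of the signature leaking into adjacent pixels,
#'   in `[0, 1)`.
#' @param scale Spatial weight multiplier for the whole region (> 0);
#'   lets a region express a shared signature at reduced intensity (used
#'   for the small inflammatory foci, which carry weaker signal than the
#'   necrotic core).
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(label, geometry, signature, bleed = 0, scale = 1) {
  stopifnot(is.character(label), length(label) == 1, nzchar(label))
  stopifnot(is.list(geometry), !is.null(geometry$type))
  stopifnot(is.data.frame(signature),
            all(c("name", "adduct", "intensity") %in% names(signature)))
  if (any(signature$intensity < 0)) stop("signature intensities must be >= 0")
  if (bleed < 0 || bleed >= 1) stop("bleed must be in [0, 1)")
  if (scale <= 0) stop("scale must be positive")
  structure(list(label = label, geometry = geometry,
                 signature = signature, bleed = bleed, scale = scale),
            class = "region_spec")
}

sig_df <- function(names, adducts, intensities) {
  data.frame(name = names, adduct = adducts, intensity = intensities,
             stringsAsFactors = FALSE)
}

#' Species planted preferentially in advanced-disease plaque
#'
#' The designated discriminating set used by the cohort generator: species
#' whose intensity scales with the planted class effect size, mirroring the
#' lipid classes (CE, ether-linked PC, LPC, SM, sterols in positive mode;
#' CerPE, CerP, PI, LPI, HexCer in negative mode) that separate advanced
#' plaque from healthy/mild wall in arterial MSI.
#'
#' @param polarity `"positive"` or `"negative"`.
#' @return Character vector of species names.
#' @export
discriminating_species <- function(polarity = "positive") {
  switch(match.arg(polarity, c("positive", "negative")),
    positive = c("CE(18:2)", "CE(18:1)", "CE(16:0)", "PC(O-40:5)",
                 "PC(O-34:1)", "SM(36:1)", "cholesterol",
                 "7-ketocholesterol", "LPC(18:1)", "LPC(16:0)"),
    negative = c("CerPE(36:1)", "CerPE(38:1)", "CerP(34:1)", "CerP(36:1)",
                 "PI(36:2)", "LPI(18:0)", "HexCer(38:1)", "Cer(34:1)"))
}

#' Default phantom regions for an arterial cross-section
#'
#' Concentric-annulus artery morphology at toy scale: a TAG/DAG-rich tunica
#' media, a PC/SM-rich intima/plaque, and (advanced disease) an eccentric
#' cholesterol/CE-rich necrotic-core blob plus small inflammatory blobs
#' sharing the core signature. In negative mode the wall carries a
#' PI(38:4)-driven signature and the core a CerPE(36:1)-driven one. With
#' `include_tissue_context = TRUE` a myocardium strip and a PVAT annulus
#' are added (use `grid_shape = c(36, 48)`).
#'
#' @param polarity `"positive"` or `"negative"`.
#' @param grid_shape Grid (rows, cols).
#' @param disease_class `"healthy"`, `"mild"` or `"advanced"`; healthy and
#'   mild differ only in intimal thickness, advanced adds core and
#'   inflammatory regions whose intensities scale with `effect_size`.
#' @param effect_size Multiplier on the advanced-disease signature.
#' @param include_tissue_context Add myocardium and PVAT regions.
#' @param bleed Bleed fraction applied to all regions.
#' @param species_scale Optional named multipliers applied to individual
#'   species' base intensities (used for per-section variability).
#' @return List of [region_spec()] objects.
#' @export
default_regions <- function(polarity = "positive", grid_shape = c(36, 36),
                            disease_class = "advanced", effect_size = 1,
                            include_tissue_context = FALSE, bleed = 0.1,
                            species_scale = NULL) {
  polarity <- match.arg(polarity, c("positive", "negative"))
  disease_class <- match.arg(disease_class, c("healthy", "mild", "advanced"))
  ctr <- if (include_tissue_context) c(grid_shape[1] / 2 + 0.5, grid_shape[2] - 18.5)
         else (grid_shape + 1) / 2
  scl <- function(df) {
    if (!is.null(species_scale)) {
      m <- species_scale[df$name]
      m[is.na(m)] <- 1
      df$intensity <- df$intensity * unname(m)
    }
    df
  }
  # with a zero effect size the advanced lesion is absent altogether, so
  # an "advanced" section degenerates to the mild phenotype (intimal
  # thickening without atherosclerotic lipid)
  if (disease_class == "advanced" && effect_size == 0) disease_class2 <- "mild"
  else disease_class2 <- disease_class
  r_intima_in <- switch(disease_class2, healthy = 7.5, mild = 6, advanced = 4.5)
  if (polarity == "positive") {
    media_sig <- sig_df(c("TAG(52:2)", "TAG(54:3)", "DAG(34:1)"),
                        rep("[M+Na]+", 3), c(100, 80, 40))
    plaque_sig <- sig_df(c("PC(34:1)", "PC(36:2)", "SM(34:1)"),
                         rep("[M+H]+", 3), c(100, 70, 50))
    core_sig <- sig_df(discriminating_species("positive"),
                       c("[M+Na]+", "[M+Na]+", "[M+Na]+", "[M+H]+", "[M+H]+",
                         "[M+H]+", "[M+Na]+", "[M+Na]+", "[M+H]+", "[M+H]+"),
                       c(100, 60, 50, 50, 45, 40, 90, 40, 35, 35) * effect_size)
    myo_sig <- sig_df(c("PC(38:4)", "PC(36:4)", "PC(40:4)"),
                      rep("[M+H]+", 3), c(100, 70, 50))
    pvat_sig <- sig_df(c("TAG(50:1)", "TAG(52:3)", "DAG(36:2)"),
                       rep("[M+Na]+", 3), c(120, 90, 40))
  } else {
    media_sig <- sig_df(c("PI(38:4)", "PE(36:2)", "PA(36:2)", "FFA(20:4)"),
                        rep("[M-H]-", 4), c(100, 60, 40, 50))
    plaque_sig <- media_sig  # one wall signature in negative mode
    core_sig <- sig_df(discriminating_species("negative"),
                       rep("[M-H]-", 8),
                       c(100, 60, 70, 50, 50, 40, 45, 40) * effect_size)
    myo_sig <- sig_df(c("PI(38:4)", "PE(38:4)", "PS(36:1)"),
                      rep("[M-H]-", 3), c(120, 60, 50))
    pvat_sig <- sig_df(c("FFA(20:4)", "FFA(22:6)", "PE(36:2)"),
                       rep("[M-H]-", 3), c(90, 60, 30))
  }
  media_sig <- scl(media_sig); plaque_sig <- scl(plaque_sig)
  core_sig <- scl(core_sig); myo_sig <- scl(myo_sig); pvat_sig <- scl(pvat_sig)
  regions <- list()
  if (include_tissue_context) {
    regions <- c(regions, list(
      region_spec("myocardium",
        list(type = "rect", rows = c(2, grid_shape[1] - 1), cols = c(2, 9)),
        myo_sig, bleed),
      region_spec("PVAT",
        list(type = "annulus", center = ctr, r_inner = 11, r_outer = 14),
        pvat_sig, bleed)))
  }
  if (polarity == "positive") {
    regions <- c(regions, list(
      region_spec("media",
        list(type = "annulus", center = ctr, r_inner = 8, r_outer = 11),
        media_sig, bleed),
      region_spec("plaque",
        list(type = "annulus", center = ctr, r_inner = r_intima_in, r_outer = 8),
        plaque_sig, bleed)))
  } else {
    regions <- c(regions, list(
      region_spec("media",
        list(type = "annulus", center = ctr, r_inner = 8, r_outer = 11),
        media_sig, bleed),
      region_spec("plaque",
        list(type = "annulus", center = ctr, r_inner = r_intima_in, r_outer = 8),
        plaque_sig, bleed)))
  }
  # with a zero effect size, advanced disease plants no extra lipid at all:
  # the core/inflammatory regions are absent and classes differ only in
  # intimal geometry
  if (disease_class == "advanced" && effect_size > 0) {
    core_ctr <- ctr + c(3.8, -4.0)
    regions <- c(regions, list(
      region_spec("necrotic_core",
        list(type = "ellipse", center = core_ctr, a = 2.6, b = 2.0),
        core_sig, bleed),
      # inflammatory foci share the advanced signature at reduced weight:
      # small cell-scale structures carry less signal than the core
      region_spec("inflammatory",
        list(type = "blobs",
             centers = list(ctr + c(-5.2, 3.2), ctr + c(0.5, 6.2)),
             radius = 1.3),
        core_sig, bleed, scale = 0.7)))
  }
  regions
}

#' Configuration of a synthetic MSI phantom
#'
#' Collects grid, mass range, regions, noise level and seed. The defaults
#' emulate a 45-um-pixel TOF acquisition over m/z 300-1200 of an arterial
#' cross-section with three (positive mode) or two (negative mode) planted
#' spatial lipid signatures.
#'
#' @param grid_shape Pixels as `c(rows, cols)`.
#' @param pixel_size_um Pixel edge length in micrometres (default 45).
#' @param polarity `"positive"` or `"negative"`.
#' @param regions List of [region_spec()]; defaults to
#'   [default_regions()] for the polarity.
#' @param mz_range Mass range `c(min, max)` in Da (default 300-1200).
#' @param noise_sd Relative intensity noise (Gaussian sd as a fraction of
#'   each peak's intensity). 0 disables all noise, including chemical noise.
#' @param chem_noise_n Mean number of spurious low-intensity chemical-noise
#'   peaks per pixel (Poisson), active only when `noise_sd > 0`.
#' @param chem_noise_max Maximum intensity of chemical-noise peaks.
#' @param seed Integer seed; fully determines the phantom.
#' @param reference Lipid reference table giving formulas/masses for the
#'   planted species.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(36, 36), pixel_size_um = 45,
                           polarity = "positive", regions = NULL,
                           mz_range = c(300, 1200), noise_sd = 0.05,
                           chem_noise_n = 10, chem_noise_max = 5, seed = 0,
                           reference = build_reference_table()) {
  polarity <- match.arg(polarity, c("positive", "negative"))
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 4),
            length(mz_range) == 2, mz_range[1] < mz_range[2],
            noise_sd >= 0, chem_noise_n >= 0, chem_noise_max >= 0)
  if (is.null(regions)) regions <- default_regions(polarity, grid_shape)
  labels <- vapply(regions, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate region labels: ",
                                  paste(labels[duplicated(labels)], collapse = ", "))
  for (r in regions) check_geometry_in_grid(r$geometry, grid_shape, r$label)
  structure(list(grid_shape = as.integer(grid_shape),
                 pixel_size_um = pixel_size_um, polarity = polarity,
                 regions = regions, mz_range = mz_range, noise_sd = noise_sd,
                 chem_noise_n = chem_noise_n, chem_noise_max = chem_noise_max,
                 seed = as.integer(seed), reference = reference),
            class = "phantom_config")
}

check_geometry_in_grid <- function(g, grid_shape, label) {
  inside <- function(r, c) r >= 1 && r <= grid_shape[1] && c >= 1 && c <= grid_shape[2]
  ok <- switch(g$type,
    annulus = inside(g$center[1] - g$r_outer, g$center[2] - g$r_outer) &&
              inside(g$center[1] + g$r_outer, g$center[2] + g$r_outer),
    ellipse = inside(g$center[1] - g$a, g$center[2] - g$b) &&
              inside(g$center[1] + g$a, g$center[2] + g$b),
    rect    = inside(g$rows[1], g$cols[1]) && inside(g$rows[2], g$cols[2]),
    blobs   = all(vapply(g$centers, function(ct)
                inside(ct[1] - g$radius, ct[2] - g$radius) &&
                inside(ct[1] + g$radius, ct[2] + g$radius), logical(1))),
    stop("unknown geometry type: ", g$type))
  if (!ok) stop("region '", label, "' geometry extends outside the grid")
}

geometry_indicator <- function(g, grid_shape) {
  rows <- matrix(seq_len(grid_shape[1]), grid_shape[1], grid_shape[2])
  cols <- matrix(seq_len(grid_shape[2]), grid_shape[1], grid_shape[2], byrow = TRUE)
  switch(g$type,
    annulus = {
      d <- sqrt((rows - g$center[1])^2 + (cols - g$center[2])^2)
      d >= g$r_inner & d < g$r_outer
    },
    ellipse = ((rows - g$center[1]) / g$a)^2 + ((cols - g$center[2]) / g$b)^2 <= 1,
    rect = rows >= g$rows[1] & rows <= g$rows[2] &
           cols >= g$cols[1] & cols <= g$cols[2],
    blobs = {
      m <- matrix(FALSE, grid_shape[1], grid_shape[2])
      for (ct in g$centers)
        m <- m | sqrt((rows - ct[1])^2 + (cols - ct[2])^2) <= g$radius
      m
    })
}

dilate1 <- function(m) {
  # 8-neighbour binary dilation by one pixel
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- pmin(pmax(seq_len(nr) + dr, 1), nr)
    cs <- pmin(pmax(seq_len(nc) + dc, 1), nc)
    out <- out | m[rs, cs, drop = FALSE]
  }
  out
}

#' Generate a synthetic MSI phantom with ground truth
#'
#' Builds per-pixel centroid spectra as the sum over regions of the
#' region's signature times a spatial weight (1 inside the region, `bleed`
#' in its one-pixel neighbourhood), plus two-isotopologue envelopes (M+1 at
#' `0.0109 x carbon count` relative abundance, M+2 at half its square) and,
#' when `noise_sd > 0`, relative Gaussian intensity noise and uniform
#' low-intensity chemical-noise peaks. Intensities are clipped at zero.
#' The output is fully determined by `config$seed`.
#'
#' @param config A [phantom_config()].
#' @return List with `dataset` (an `msi_dataset`) and `truth` (class
#'   `phantom_truth`: `label_image` with region ids, `label_names`,
#'   `component_spectra` (features x k planted signatures),
#'   `species_table`, `true_transform`).
#' @export
make_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  gs <- config$grid_shape
  ref <- config$reference
  set.seed(config$seed)

  # label image: regions painted in order, later regions override
  label_image <- matrix(0L, gs[1], gs[2])
  indicators <- list()
  for (i in seq_along(config$regions)) {
    ind <- geometry_indicator(config$regions[[i]]$geometry, gs)
    indicators[[i]] <- ind
    label_image[ind] <- i
  }
  label_names <- stats::setNames(seq_along(config$regions),
    vapply(config$regions, `[[`, character(1), "label"))

  # species table: one row per planted (region, species, adduct)
  st <- list()
  for (i in seq_along(config$regions)) {
    sg <- config$regions[[i]]$signature
    sg <- sg[sg$intensity > 0, , drop = FALSE]
    if (!nrow(sg)) next
    j <- match(sg$name, ref$name)
    if (anyNA(j)) stop("species not in reference table: ",
                       paste(sg$name[is.na(j)], collapse = ", "))
    mz <- adduct_mz(ref$mass[j], sg$adduct)
    bad <- mz < config$mz_range[1] | mz > config$mz_range[2]
    if (any(bad)) stop("species outside mz_range: ",
                       paste(sg$name[bad], collapse = ", "))
    st[[length(st) + 1]] <- data.frame(
      region = config$regions[[i]]$label, region_id = i, name = sg$name,
      class = ref$class[j], formula = ref$formula[j], adduct = sg$adduct,
      mz = mz, base_intensity = sg$intensity,
      carbons = count_element(ref$formula[j], "C"), stringsAsFactors = FALSE)
  }
  species_table <- if (length(st)) do.call(rbind, st) else
    data.frame(region = character(), region_id = integer(), name = character(),
               class = character(), formula = character(), adduct = character(),
               mz = numeric(), base_intensity = numeric(), carbons = integer())

  # planted component spectra: one column per distinct signature
  feat_mz <- sort(unique(species_table$mz))
  sig_key <- vapply(seq_along(config$regions), function(i) {
    sg <- config$regions[[i]]$signature
    sg <- sg[sg$intensity > 0, , drop = FALSE]
    if (!nrow(sg)) return("")
    paste(sg$name, sg$adduct, signif(sg$intensity, 10), collapse = ";")
  }, character(1))
  uk <- unique(sig_key[nzchar(sig_key)])
  comp <- matrix(0, length(feat_mz), length(uk),
                 dimnames = list(NULL, rep("", length(uk))))
  for (u in seq_along(uk)) {
    i <- which(sig_key == uk[u])[1]
    rows <- species_table[species_table$region_id == i, ]
    comp[match(rows$mz, feat_mz), u] <- rows$base_intensity
    colnames(comp)[u] <- paste(names(label_names)[sig_key == uk[u]], collapse = "+")
  }

  # plant peaks: long table (pixel linear index, mz, intensity)
  iso <- .mass_neutron_c13
  px <- list(); k <- 0
  for (i in seq_along(config$regions)) {
    b <- config$regions[[i]]$bleed
    sc <- config$regions[[i]]$scale
    w_in <- which(label_image == i)
    w_bl <- if (b > 0) which(dilate1(indicators[[i]]) & label_image != i) else integer()
    idx <- c(w_in, w_bl)
    wts <- sc * c(rep(1, length(w_in)), rep(b, length(w_bl)))
    if (!length(idx)) next
    rows <- species_table[species_table$region_id == i, , drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      r1 <- 0.0109 * rows$carbons[r]
      for (k_iso in 0:2) {
        relint <- c(1, r1, r1^2 / 2)[k_iso + 1]
        k <- k + 1
        px[[k]] <- data.frame(pixel = idx,
                              mz = rows$mz[r] + k_iso * iso,
                              intensity = rows$base_intensity[r] * wts * relint)
      }
    }
  }
  peaks <- if (length(px)) do.call(rbind, px) else
    data.frame(pixel = integer(), mz = numeric(), intensity = numeric())

  if (config$noise_sd > 0 && nrow(peaks)) {
    peaks$intensity <- pmax(0, peaks$intensity +
      stats::rnorm(nrow(peaks), 0, config$noise_sd * peaks$intensity))
  }
  if (config$noise_sd > 0 && config$chem_noise_n > 0) {
    n_px <- prod(gs)
    counts <- stats::rpois(n_px, config$chem_noise_n)
    tot <- sum(counts)
    if (tot > 0) {
      peaks <- rbind(peaks, data.frame(
        pixel = rep(seq_len(n_px), counts),
        mz = stats::runif(tot, config$mz_range[1], config$mz_range[2]),
        intensity = stats::runif(tot, 0, config$chem_noise_max)))
    }
  }
  peaks <- peaks[peaks$intensity > 0, , drop = FALSE]

  # assemble per-pixel centroid spectra (row-major pixel order)
  n_px <- prod(gs)
  rc <- arrayInd(seq_len(n_px), gs)          # (row, col), 1-based
  coords <- cbind(row = rc[, 1] - 1L, col = rc[, 2] - 1L)
  spectra <- rep(list(list(mz = numeric(0), intensity = numeric(0))), n_px)
  if (nrow(peaks)) {
    peaks <- peaks[order(peaks$pixel, peaks$mz), ]
    sp <- split(seq_len(nrow(peaks)), peaks$pixel)
    for (nm in names(sp)) {
      ii <- sp[[nm]]
      mzv <- peaks$mz[ii]; inten <- peaks$intensity[ii]
      # merge coincident centroids (same species planted by two regions)
      grp <- cumsum(c(TRUE, diff(mzv) > 1e-9))
      if (max(grp) < length(mzv)) {
        inten <- as.numeric(tapply(inten, grp, sum))
        mzv <- as.numeric(tapply(mzv, grp, `[`, 1))
      }
      spectra[[as.integer(nm)]] <- list(mz = mzv, intensity = inten)
    }
  }

  dataset <- msi_dataset(spectra = spectra, coords = coords, grid_shape = gs,
                         pixel_size_um = config$pixel_size_um,
                         polarity = config$polarity, section_id = "phantom",
                         disease_class = "unknown")
  truth <- structure(list(label_image = label_image, label_names = label_names,
                          component_spectra = comp, feature_mz = feat_mz,
                          species_table = species_table,
                          true_transform = c(s = 1, tx = 0, ty = 0),
                          config = config),
                     class = "phantom_truth")
  list(dataset = dataset, truth = truth)
}

#' Emit histology-space masks and registration landmarks for a phantom
#'
#' Maps the ground-truth label image into a simulated histology space
#' through the inverse of the given similarity transform (the forward
#' transform maps histology pixel coordinates to MSI pixel coordinates:
#' `msi = s * histo + t`, in 0-based `(x = col, y = row)` coordinates), and
#' emits landmark pairs whose registration recovers `(s, tx, ty)`.
#'
#' @param truth `phantom_truth` from [make_phantom()].
#' @param transform Numeric `c(s, tx, ty)` with `s > 0`.
#' @param n_landmarks Number of landmark pairs (>= 2).
#' @return List with `label_image` (histology-space integer mask),
#'   `label_names`, `landmarks` (`data.frame` with `hx, hy, mx, my`), and
#'   `transform`.
#' @export
emit_histology_masks <- function(truth, transform = c(1, 0, 0), n_landmarks = 4) {
  stopifnot(inherits(truth, "phantom_truth"), length(transform) == 3)
  s <- transform[1]; tx <- transform[2]; ty <- transform[3]
  if (s <= 0) stop("scale must be positive")
  if (n_landmarks < 2) stop("at least 2 landmark pairs are required")
  gs <- dim(truth$label_image)
  # histology grid covering the image of the MSI grid under the inverse map
  hx_max <- (gs[2] - 1 - tx) / s; hy_max <- (gs[1] - 1 - ty) / s
  h_cols <- max(2L, ceiling(hx_max) + 1L)
  h_rows <- max(2L, ceiling(hy_max) + 1L)
  hist_img <- matrix(0L, h_rows, h_cols)
  hr <- matrix(seq_len(h_rows) - 1L, h_rows, h_cols)
  hc <- matrix(seq_len(h_cols) - 1L, h_rows, h_cols, byrow = TRUE)
  mr <- round(s * hr + ty) + 1L   # MSI row (1-based)
  mc <- round(s * hc + tx) + 1L
  ok <- mr >= 1 & mr <= gs[1] & mc >= 1 & mc <= gs[2]
  hist_img[ok] <- truth$label_image[cbind(mr[ok], mc[ok])]
  # landmarks spread over the in-field histology area (deterministic)
  fx <- seq(0.1, 0.9, length.out = ceiling(sqrt(n_landmarks)))
  gpts <- expand.grid(hx = fx * max(hx_max, 1), hy = fx * max(hy_max, 1))
  gpts <- gpts[seq_len(n_landmarks), , drop = FALSE]
  lm <- data.frame(hx = gpts$hx, hy = gpts$hy,
                   mx = s * gpts$hx + tx, my = s * gpts$hy + ty)
  list(label_image = hist_img, label_names = truth$label_names,
       landmarks = lm, transform = c(s = s, tx = tx, ty = ty))
}

#' Generate a multi-section phantom cohort with disease classes
#'
#' Emulates a study of coronary artery sections graded healthy / mild /
#' advanced: all sections share the wall signatures; healthy and mild
#' differ only in intimal thickness (not lipid signature); advanced
#' sections additionally carry the discriminating species set (necrotic
#' core and inflammatory blobs) at intensities scaled by `effect_size`
#' (0 makes the classes lipidomically indistinguishable). Per-section
#' log-normal species multipliers (`section_cv`) provide within-class
#' biological variability.
#'
#' @param n_sections Number of sections (>= 2).
#' @param class_assignment Character vector of length `n_sections` with
#'   values in healthy/mild/advanced; default the 6/6/5 design.
#' @param effect_size Multiplier on the advanced-disease signature (>= 0).
#' @param seed Integer seed.
#' @param polarity `"positive"` or `"negative"`.
#' @param grid_shape Grid per section.
#' @param noise_sd Relative intensity noise.
#' @param section_cv Log-normal sd of per-section species multipliers.
#' @param include_tissue_context Add myocardium and PVAT regions.
#' @param reference Lipid reference table.
#' @return List of per-section lists with elements `dataset` and `truth`.
#' @export
make_cohort <- function(n_sections = 17,
                        class_assignment = rep(c("healthy", "mild", "advanced"),
                                               c(6, 6, 5)),
                        effect_size = 1, seed = 0, polarity = "positive",
                        grid_shape = if (include_tissue_context) c(36, 48) else c(36, 36),
                        noise_sd = 0.05, section_cv = 0.15,
                        include_tissue_context = FALSE,
                        reference = build_reference_table()) {
  stopifnot(n_sections >= 2, effect_size >= 0,
            length(class_assignment) == n_sections)
  bad <- setdiff(class_assignment, c("healthy", "mild", "advanced"))
  if (length(bad)) stop("unknown class label: ", paste(bad, collapse = ", "))
  set.seed(seed)
  sec_seeds <- sample.int(.Machine$integer.max - 1L, n_sections)
  all_species <- unique(unlist(lapply(
    default_regions(polarity, grid_shape, "advanced",
                    include_tissue_context = include_tissue_context),
    function(r) r$signature$name)))
  out <- vector("list", n_sections)
  for (i in seq_len(n_sections)) {
    mult <- stats::setNames(exp(stats::rnorm(length(all_species), 0, section_cv)),
                            all_species)
    cfg <- phantom_config(
      grid_shape = grid_shape, polarity = polarity,
      regions = default_regions(polarity, grid_shape,
                                disease_class = class_assignment[i],
                                effect_size = effect_size,
                                include_tissue_context = include_tissue_context,
                                species_scale = mult),
      noise_sd = noise_sd, seed = sec_seeds[i], reference = reference)
    ph <- make_phantom(cfg)
    ph$dataset$section_id <- sprintf("S%02d", i)
    ph$dataset$disease_class <- class_assignment[i]
    out[[i]] <- ph
  }
  out
}
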