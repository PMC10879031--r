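test_that("pick_peaks keeps isolated apexes and resolves close points", {
  # single isolated peak above a flat noise floor
  set.seed(1)
  mz <- sort(runif(60, 300, 1200))
  inten <- abs(rnorm(60, 0, 1))
  mz <- sort(c(mz, 700))
  inten <- append(inten, 50, after = which(mz == 700) - 1)
  pk <- pick_peaks(mz, inten, snr_min = 3)
  expect_true(700 %in% pk$mz)
  expect_true(all(pk$intensity >= 3 * mad(inten)))
  # two peaks separated by more than one resolution element: both kept
  pk2 <- pick_peaks(c(700.0, 700.2), c(10, 8), snr_min = 0, intensity_min = 1)
  expect_equal(pk2$mz, c(700.0, 700.2))
  # two points inside one resolution element: only the apex survives
  pk3 <- pick_peaks(c(700.000, 700.010), c(10, 8), snr_min = 0,
                    intensity_min = 1)
  expect_equal(pk3$mz, 700.000)
  expect_equal(nrow(pick_peaks(numeric(0), numeric(0))), 0)
})

test_that("pure-noise spectra yield under 5% false positives at SNR 3", {
  # Monte-Carlo oracle for the MAD-based threshold, under the same
  # bounded (uniform) chemical-noise intensity model the phantom plants
  set.seed(42)
  fp <- vapply(1:200, function(b) {
    mz <- sort(runif(120, 300, 1200))
    inten <- runif(120, 0, 5)
    nrow(pick_peaks(mz, inten, snr_min = 3)) / 120
  }, numeric(1))
  expect_lt(mean(fp), 0.05)
})

test_that("deisotoping removes isotopologues below the carbon-count ceiling", {
  # the worked rule: 0.42 relative at +1.0034 from m/z 700 is an isotope
  pk <- data.frame(mz = c(700.000, 701.0034), intensity = c(1.0, 0.42))
  expect_equal(deisotope(pk)$mz, 700.000)
  # off-spacing survivor
  pk2 <- data.frame(mz = c(700.000, 700.500), intensity = c(1.0, 0.4))
  expect_equal(deisotope(pk2)$mz, c(700.000, 700.500))
  # a peak at isotope spacing but too intense to be an isotope is kept
  pk3 <- data.frame(mz = c(700.000, 701.0034), intensity = c(1.0, 0.95))
  expect_equal(nrow(deisotope(pk3)), 2)
  expect_equal(nrow(deisotope(pk3[0, ])), 0)
})

test_that("deisotoping clears all planted envelopes with no monoisotopic loss", {
  ph <- make_phantom(small_config(noise_sd = 0))
  st <- ph$truth$species_table
  pl <- section_peak_list(ph$dataset, snr_min = 0, intensity_min = 1e-9)
  de <- deisotope(pl)
  mono <- sort(unique(st$mz))
  iso <- sort(unique(c(st$mz + 1.0033548378, st$mz + 2 * 1.0033548378)))
  iso <- setdiff(round(iso, 4), round(mono, 4))
  kept <- round(de$mz, 4)
  expect_true(all(round(mono, 4) %in% kept))           # 0 monoisotopic losses
  expect_false(any(iso %in% kept))                     # all isotopologues gone
  # idempotence
  expect_equal(deisotope(de), de)
})

test_that("feature consolidation merges within tolerance and is order-invariant", {
  p1 <- data.frame(mz = c(500.000, 700.000), intensity = c(10, 5))
  p2 <- data.frame(mz = c(500.0025, 700.010), intensity = c(20, 5))  # 5 ppm / 14 ppm
  ft <- consolidate_features(list(a = p1, b = p2), mz_tol_ppm = 20)
  expect_length(ft$feature_mz, 2)
  expect_equal(colSums(ft$presence), c(2, 2), ignore_attr = TRUE)
  # feature m/z is the intensity-weighted mean
  expect_equal(ft$feature_mz[1],
               weighted.mean(c(500.000, 500.0025), c(10, 20)))
  # identical lists in 2 sections: everything present in 2/2
  ft2 <- consolidate_features(list(a = p1, b = p1), 20)
  expect_true(all(colSums(ft2$presence) == 2))
  # permutation invariance of the feature m/z set
  ft3 <- consolidate_features(list(b = p2, a = p1), 20)
  expect_equal(sort(ft$feature_mz), sort(ft3$feature_mz))
  expect_error(consolidate_features(list(a = p1), 0), "positive")
  # peaks 5 ppm apart at tol 20 ppm collapse to one feature
  ft4 <- consolidate_features(list(a = data.frame(mz = 800, intensity = 1),
                                   b = data.frame(mz = 800.004, intensity = 1)), 20)
  expect_length(ft4$feature_mz, 1)
})

test_that("consolidation on a phantom cohort recovers the planted feature count", {
  co <- make_cohort(5, class_assignment = rep("advanced", 5), seed = 3,
                    grid_shape = c(24, 24), noise_sd = 0)
  lists <- lapply(co, function(s)
    deisotope(section_peak_list(s$dataset, snr_min = 0, intensity_min = 1e-9)))
  names(lists) <- vapply(co, function(s) s$dataset$section_id, character(1))
  ft <- consolidate_features(lists, 20)
  planted <- sort(unique(unlist(lapply(co, function(s) s$truth$feature_mz))))
  expect_length(ft$feature_mz, length(planted))
  expect_equal(ft$feature_mz, planted, tolerance = 1e-6)
})

test_that("the prevalence filter applies the >= min_sections rule exactly", {
  pres <- matrix(FALSE, 17, 3)
  pres[1:5, 1] <- TRUE   # present in exactly 5/17 -> kept at min 5
  pres[1:4, 2] <- TRUE   # present in 4/17 -> dropped at min 5
  pres[1:17, 3] <- TRUE
  mat <- pres * 1.0
  ft <- feature_table(c(400, 500, 600), mat, pres, "peak",
                      sprintf("S%02d", 1:17))
  f5 <- prevalence_filter(ft, 5)
  expect_equal(f5$feature_mz, c(400, 600))
  expect_equal(prevalence_filter(ft, 1)$feature_mz, ft$feature_mz)
  expect_error(prevalence_filter(ft, 0), "between 1 and")
  expect_error(prevalence_filter(ft, 18), "between 1 and")
  # monotone non-increasing feature sets in min_sections
  sets <- lapply(1:17, function(k) prevalence_filter(ft, k)$feature_mz)
  for (k in 2:17) expect_true(all(sets[[k]] %in% sets[[k - 1]]))
})
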