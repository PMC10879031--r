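test_that("phantoms are bit-identical for the same seed", {
  a <- make_phantom(small_config(seed = 7))
  b <- make_phantom(small_config(seed = 7))
  expect_identical(a$dataset$spectra, b$dataset$spectra)
  expect_identical(a$truth$label_image, b$truth$label_image)
  c <- make_phantom(small_config(seed = 8))
  expect_false(identical(a$dataset$spectra, c$dataset$spectra))
})

test_that("single-region noiseless phantom plants exactly one isotope cluster", {
  ref <- build_reference_table()
  reg <- region_spec("blob",
                     list(type = "ellipse", center = c(8, 8), a = 3, b = 3),
                     sig_df <- data.frame(name = "PC(34:1)", adduct = "[M+H]+",
                                          intensity = 100), bleed = 0)
  cfg <- phantom_config(grid_shape = c(16, 16), regions = list(reg),
                        noise_sd = 0, seed = 1, reference = ref)
  ph <- make_phantom(cfg)
  inside <- as.vector(ph$truth$label_image) == 1
  mz0 <- adduct_mz(ref$mass[ref$name == "PC(34:1)"], "[M+H]+")
  for (i in which(inside)) {
    s <- ph$dataset$spectra[[i]]
    expect_equal(length(s$mz), 3)          # M, M+1, M+2
    expect_equal(s$mz[1], mz0, tolerance = 1e-9)
    expect_equal(diff(s$mz), rep(1.0033548378, 2), tolerance = 1e-9)
  }
  for (i in which(!inside))
    expect_length(ph$dataset$spectra[[i]]$mz, 0)
})

test_that("isotope envelopes follow the carbon-count approximation", {
  ph <- make_phantom(small_config(noise_sd = 0))
  st <- ph$truth$species_table
  # pick a pure in-region pixel per region and check M+1/M ratios
  for (rid in unique(st$region_id)) {
    px <- which(as.vector(ph$truth$label_image) == rid)[1]
    s <- ph$dataset$spectra[[px]]
    rows <- st[st$region_id == rid, ]
    for (j in seq_len(nrow(rows))) {
      i_m <- which(abs(s$mz - rows$mz[j]) < 1e-9)
      i_m1 <- which(abs(s$mz - (rows$mz[j] + 1.0033548378)) < 1e-9)
      expect_length(i_m, 1)
      ratio <- s$intensity[i_m1] / s$intensity[i_m]
      approx <- 0.0109 * rows$carbons[j]
      expect_lt(abs(ratio - approx) / approx, 0.2)
    }
  }
  # all intensities non-negative even with noise
  phn <- make_phantom(small_config(noise_sd = 0.3, seed = 3))
  expect_true(all(vapply(phn$dataset$spectra,
                         function(s) all(s$intensity >= 0), logical(1))))
})

test_that("core-signature species concentrate inside the core region", {
  ph <- make_phantom(small_config(seed = 2))
  st <- ph$truth$species_table
  core_id <- ph$truth$label_names[["necrotic_core"]]
  core_mz <- st$mz[st$region == "necrotic_core"][1]
  img <- ion_image(ph$dataset, core_mz)
  in_core <- ph$truth$label_image == core_id
  expect_gt(mean(img[in_core]), mean(img[!in_core]))  # direct pixel averaging
})

test_that("invalid phantom configurations are rejected", {
  sig <- data.frame(name = "PC(34:1)", adduct = "[M+H]+", intensity = 100)
  r1 <- region_spec("a", list(type = "ellipse", center = c(8, 8), a = 2, b = 2), sig)
  r2 <- region_spec("a", list(type = "ellipse", center = c(4, 4), a = 2, b = 2), sig)
  expect_error(phantom_config(grid_shape = c(16, 16), regions = list(r1, r2)),
               "duplicate region labels")
  r3 <- region_spec("b", list(type = "ellipse", center = c(1, 1), a = 3, b = 3), sig)
  expect_error(phantom_config(grid_shape = c(16, 16), regions = list(r3)),
               "outside the grid")
  expect_error(region_spec("c", list(type = "rect", rows = c(1, 2), cols = c(1, 2)),
                           data.frame(name = "x", adduct = "[M+H]+",
                                      intensity = -1)), ">= 0")
  expect_error(region_spec("c", list(type = "rect", rows = c(1, 2), cols = c(1, 2)),
                           sig, bleed = 1), "bleed")
  # species whose adduct m/z falls outside the mass range are rejected
  low <- data.frame(name = "FFA(16:0)", adduct = "[M-H]-", intensity = 10)
  r4 <- region_spec("d", list(type = "ellipse", center = c(8, 8), a = 2, b = 2), low)
  expect_error(make_phantom(phantom_config(grid_shape = c(16, 16),
                                           polarity = "negative",
                                           regions = list(r4),
                                           mz_range = c(300, 1200),
                                           noise_sd = 0)),
               "outside mz_range")
})

test_that("cohort respects the class design and effect-size contract", {
  co <- make_cohort(17, seed = 5, noise_sd = 0.02, grid_shape = c(24, 24))
  expect_length(co, 17)
  cls <- vapply(co, function(s) s$dataset$disease_class, character(1))
  expect_equal(unname(table(cls)[c("healthy", "mild", "advanced")]),
               c(6L, 6L, 5L), ignore_attr = TRUE)
  expect_equal(vapply(co, function(s) s$dataset$section_id, character(1)),
               sprintf("S%02d", 1:17))
  # healthy and mild share the same species set (geometry-only difference)
  sp_h <- sort(unique(co[[1]]$truth$species_table$name))
  sp_m <- sort(unique(co[[7]]$truth$species_table$name))
  expect_identical(sp_h, sp_m)
  # advanced sections carry the discriminating set
  sp_a <- unique(co[[13]]$truth$species_table$name)
  expect_true(all(discriminating_species("positive") %in% sp_a))
  expect_false(any(discriminating_species("positive") %in% sp_h))
  expect_error(make_cohort(4, class_assignment = c("healthy", "bad", "mild",
                                                   "advanced")),
               "unknown class label")
  # determinism
  co2 <- make_cohort(4, class_assignment = rep(c("healthy", "advanced"), 2),
                     seed = 9, grid_shape = c(24, 24))
  co3 <- make_cohort(4, class_assignment = rep(c("healthy", "advanced"), 2),
                     seed = 9, grid_shape = c(24, 24))
  expect_identical(co2[[2]]$dataset$spectra, co3[[2]]$dataset$spectra)
})

test_that("zero effect size leaves classes statistically indistinguishable", {
  # Monte-Carlo oracle: with effect_size = 0 advanced sections plant no
  # extra lipid, so the per-section p99 feature vectors (the statistic the
  # downstream models consume, insensitive to intimal geometry) of mild
  # and advanced sections come from the same distribution
  co <- make_cohort(50, class_assignment = rep(c("mild", "advanced"), 25),
                    effect_size = 0, seed = 21, grid_shape = c(24, 24),
                    noise_sd = 0.02)
  obs <- cohort_p99(co)
  pvals <- vapply(seq_along(obs$mzs), function(j)
    t.test(obs$X[obs$classes == "mild", j],
           obs$X[obs$classes == "advanced", j])$p.value, numeric(1))
  expect_gt(min(p.adjust(pvals, "bonferroni")), 0.01)
  # and the advanced truth contains no discriminating species at all
  expect_false(any(discriminating_species("positive") %in%
                   co[[2]]$truth$species_table$name))
})
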