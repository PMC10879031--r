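test_that("similarity fit recovers exact transforms and reports residuals", {
  set.seed(2)
  p <- cbind(runif(6, 0, 30), runif(6, 0, 30))
  # identity
  tf0 <- fit_similarity_transform(p, p)
  expect_equal(c(tf0$s, tf0$tx, tf0$ty, tf0$residual_rms), c(1, 0, 0, 0))
  # scale 2, shift (10, -5): closed-form exact recovery
  q <- 2 * p
  q[, 1] <- q[, 1] + 10; q[, 2] <- q[, 2] - 5
  tf <- fit_similarity_transform(p, q)
  expect_equal(c(tf$s, tf$tx, tf$ty), c(2, 10, -5), tolerance = 1e-12)
  expect_lt(tf$residual_rms, 1e-12)
  # fit-apply round trip stays within the reported residual
  qn <- q + matrix(rnorm(length(q), 0, 0.3), nrow(q))
  tfn <- fit_similarity_transform(p, qn)
  fitted <- apply_transform(tfn, p)
  expect_equal(sqrt(mean(rowSums((fitted - qn)^2))), tfn$residual_rms)
  # degenerate inputs
  expect_error(fit_similarity_transform(p[1, , drop = FALSE],
                                        q[1, , drop = FALSE]), "at least 2")
  same <- matrix(5, 4, 2)
  expect_error(fit_similarity_transform(same, q[1:4, ]), "degenerate")
})

test_that("rotation-enabled fit recovers a rotated similarity", {
  set.seed(3)
  p <- cbind(runif(8, 0, 20), runif(8, 0, 20))
  th <- 0.3; s <- 1.5
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  q <- s * p %*% t(R)
  q[, 1] <- q[, 1] + 4; q[, 2] <- q[, 2] + 7
  tf <- fit_similarity_transform(p, q, rotation = TRUE)
  expect_equal(tf$s, s, tolerance = 1e-10)
  expect_equal(tf$theta, th, tolerance = 1e-10)
  expect_equal(c(tf$tx, tf$ty), c(4, 7), tolerance = 1e-9)
  # invert o apply = identity
  back <- apply_transform(invert_transform(tf), apply_transform(tf, p))
  expect_equal(back, p, tolerance = 1e-9)
})

test_that("scale estimates stay within 0.05 under half-pixel landmark jitter", {
  # Monte-Carlo: 6 pairs, sigma = 0.5 px
  set.seed(11)
  ok <- vapply(1:500, function(b) {
    p <- cbind(runif(6, 0, 30), runif(6, 0, 30))
    q <- 2 * p + matrix(rnorm(12, 0, 0.5), 6, 2)
    q[, 1] <- q[, 1] + 10; q[, 2] <- q[, 2] - 5
    abs(fit_similarity_transform(p, q)$s - 2) < 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("mask projection is exact under identity and recovers phantom labels", {
  ph <- make_phantom(small_config(seed = 6, noise_sd = 0))
  # identity transform, equal grids: labels unchanged
  id <- fit_similarity_transform(cbind(c(0, 10, 0), c(0, 0, 10)),
                                 cbind(c(0, 10, 0), c(0, 0, 10)))
  m0 <- segmentation_mask(ph$truth$label_image, ph$truth$label_names, id)
  expect_identical(project_mask(m0, dim(ph$truth$label_image)),
                   ph$truth$label_image)
  # emitted histology masks at scale 0.5 project back onto >= 99% of pixels
  em <- emit_histology_masks(ph$truth, c(0.5, -2, -1))
  tf <- fit_similarity_transform(cbind(em$landmarks$hx, em$landmarks$hy),
                                 cbind(em$landmarks$mx, em$landmarks$my))
  expect_equal(c(tf$s, tf$tx, tf$ty), c(0.5, -2, -1), tolerance = 1e-9)
  msk <- segmentation_mask(em$label_image, em$label_names, tf)
  proj <- project_mask(msk, dim(ph$truth$label_image))
  expect_gte(mean(proj == ph$truth$label_image), 0.99)
  # transform moving the mask fully off-grid: all background
  far <- fit_similarity_transform(cbind(c(0, 10), c(0, 10)),
                                  cbind(c(1000, 1010), c(1000, 1010)))
  mf <- segmentation_mask(em$label_image, em$label_names, far)
  expect_true(all(project_mask(mf, dim(ph$truth$label_image)) == 0L))
  expect_error(project_mask(segmentation_mask(em$label_image), c(24, 24)),
               "not been fitted")
  expect_error(emit_histology_masks(ph$truth, c(-1, 0, 0)), "positive")
  expect_error(emit_histology_masks(ph$truth, c(1, 0, 0), n_landmarks = 1),
               "at least 2")
})

test_that("mask TIFF and landmark CSV round-trip losslessly", {
  ph <- make_phantom(small_config(seed = 6, noise_sd = 0))
  f <- withr::local_tempfile(fileext = ".tiff")
  write_mask_tiff(ph$truth$label_image, f)
  expect_identical(read_mask_tiff(f), ph$truth$label_image)
  pts <- cbind(c(0.5, 10.25, 3), c(2, 4, 8.5))
  g <- withr::local_tempfile(fileext = ".csv")
  write_landmarks_csv(pts, g)
  expect_equal(unname(read_landmarks_csv(g)), pts, ignore_attr = TRUE)
})

test_that("segment spectra use the linear-interpolation percentile convention", {
  # constant segment: mean = p99 = c
  sp <- lapply(1:100, function(i) list(mz = 500, intensity = 7))
  co <- arrayInd(1:100, c(10, 10)) - 1L
  d <- msi_dataset(sp, co, c(10, 10))
  lab <- matrix(1L, 10, 10)
  sg <- segment_spectra(d, lab, 500)
  expect_equal(unname(sg$mean[1, 1]), 7)
  expect_equal(unname(sg$p99[1, 1]), 7)
  # intensities 1..100: p99 = 99.01 under linear interpolation
  sp2 <- lapply(1:100, function(i) list(mz = 500, intensity = as.numeric(i)))
  d2 <- msi_dataset(sp2, co, c(10, 10))
  sg2 <- segment_spectra(d2, lab, 500)
  expect_equal(unname(sg2$p99[1, 1]), 99.01)
  expect_equal(unname(sg2$mean[1, 1]), mean(1:100))
  expect_match(sg2$percentile_convention, "linear")
  # p99 lies between the median and the max
  expect_gte(sg2$p99[1, 1], median(1:100))
  expect_lte(sg2$p99[1, 1], 100)
  # empty segments are flagged and excluded
  lab2 <- lab; lab2[] <- 1L
  sg3 <- segment_spectra(d2, lab2, 500,
                         label_names = c(artery = 1L, core = 2L))
  expect_equal(sg3$empty_segments, "core")
  expect_false("core" %in% rownames(sg3$mean))
})
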