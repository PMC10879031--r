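test_that("top-fraction masks select exact counts with a documented tie rule", {
  set.seed(14)
  img <- matrix(runif(100), 10, 10)
  within <- matrix(TRUE, 10, 10)
  top <- top_fraction_mask(img, 0.10, within)
  expect_equal(sum(top), 10)
  expect_true(all(img[top] >= max(img[!top])))
  # ceiling rule: fraction 0.5 of 7 pixels selects 4
  w7 <- matrix(FALSE, 10, 10); w7[1, 1:7] <- TRUE
  expect_equal(sum(top_fraction_mask(img, 0.5, w7)), 4)
  # constant image: the first ceil(0.1 n) pixels in row-major order
  cimg <- matrix(1, 4, 5)
  tc <- top_fraction_mask(cimg, 0.1, matrix(TRUE, 4, 5))
  expect_equal(sum(tc), 2)
  expect_true(tc[1, 1] && tc[1, 2])  # row-major tie-breaking
  expect_error(top_fraction_mask(img, 0.1, matrix(FALSE, 10, 10)), "empty")
  expect_error(top_fraction_mask(img, 0), "fraction")
  # invariance to monotone intensity transforms
  t2 <- top_fraction_mask(img^3 + 5, 0.10, within)
  expect_identical(top, t2)
})

test_that("overlap percentages follow the definition and conserve pixels", {
  reg <- matrix(FALSE, 10, 10); reg[1:4, 1:5] <- TRUE   # 20 px
  top <- matrix(FALSE, 10, 10); top[1:2, 1:5] <- TRUE   # covers 10 of them
  expect_equal(overlap_percentage(reg, top), 50)
  expect_equal(overlap_percentage(top, top), 100)       # region inside mask
  expect_warning(ov <- overlap_percentage(matrix(FALSE, 10, 10), top),
                 "empty region")
  expect_true(is.na(ov))
  # pixel conservation: over a partition of `within`,
  # sum(|region| x overlap / 100) = |top mask|
  set.seed(15)
  img <- matrix(runif(144), 12, 12)
  within <- matrix(TRUE, 12, 12)
  top <- top_fraction_mask(img, 0.1, within)
  parts <- list(a = matrix(FALSE, 12, 12), b = matrix(FALSE, 12, 12),
                c = matrix(FALSE, 12, 12))
  parts$a[1:4, ] <- TRUE; parts$b[5:8, ] <- TRUE; parts$c[9:12, ] <- TRUE
  tot <- sum(vapply(parts, function(r)
    sum(r) * overlap_percentage(r, top) / 100, numeric(1)))
  expect_equal(tot, sum(top))
})

test_that("random images overlap regions at the baseline fraction", {
  set.seed(16)
  reg <- matrix(FALSE, 20, 20); reg[5:10, 5:10] <- TRUE
  within <- matrix(TRUE, 20, 20)
  ov <- vapply(1:500, function(b) {
    img <- matrix(runif(400), 20, 20)
    overlap_percentage(reg, top_fraction_mask(img, 0.1, within))
  }, numeric(1))
  expect_equal(mean(ov), 10, tolerance = 0.1)  # 10% +/- 1 (absolute)
})

test_that("colocalization tables find planted core species and flag zeros", {
  ph <- make_phantom(small_config(seed = 21))
  truth <- ph$truth
  lab <- truth$label_image
  nm <- truth$label_names
  within <- matrix(lab > 0, nrow(lab))
  core <- matrix(lab == nm[["necrotic_core"]], nrow(lab))
  infl <- matrix(lab == nm[["inflammatory"]], nrow(lab))
  st <- truth$species_table
  core_mz <- st$mz[st$region == "necrotic_core"][1]
  media_mz <- st$mz[st$region == "media"][1]
  imgs <- list(core = ion_image(ph$dataset, core_mz),
               media = ion_image(ph$dataset, media_mz),
               zero = matrix(0, nrow(lab), ncol(lab)))
  tab <- colocalization_table(imgs, list(necrotic_core = core,
                                         inflammatory = infl),
                              within, fraction = 0.10, n_null = 200, seed = 1)
  rec <- tab[tab$feature == "core" & tab$region == "necrotic_core", ]
  expect_gt(rec$percent_overlap, 90)
  expect_lt(rec$p_value, 0.01)
  expect_equal(rec$null_mean, 10, tolerance = 3)
  # all-zero image flagged with undefined overlap
  z <- tab[tab$feature == "zero", ]
  expect_true(all(z$flagged) && all(is.na(z$percent_overlap)))
  # small inflammatory blobs colocalize less than the core for the shared
  # signature (structural-size caveat): at a tighter top fraction the
  # weaker cell-scale signal drops out of the top-intensity mask first
  tab5 <- colocalization_table(imgs["core"], list(necrotic_core = core,
                                                  inflammatory = infl),
                               within, fraction = 0.05, n_null = 50, seed = 1)
  c_ov <- tab5[tab5$region == "necrotic_core", "percent_overlap"]
  i_ov <- tab5[tab5$region == "inflammatory", "percent_overlap"]
  expect_lt(i_ov, c_ov)
})

test_that("spatially uniform species sit at the baseline with null-like p", {
  ph <- make_phantom(small_config(seed = 22))
  lab <- ph$truth$label_image
  within <- matrix(lab > 0, nrow(lab))
  reg <- matrix(lab == ph$truth$label_names[["media"]], nrow(lab))
  set.seed(9)
  flat <- matrix(runif(length(lab)), nrow(lab))  # unstructured intensity
  tab <- colocalization_table(list(flat = flat), list(media = reg), within,
                              n_null = 300, seed = 2)
  expect_equal(tab$percent_overlap, tab$null_mean, tolerance = 6)
  expect_gt(tab$p_value, 0.05)
})
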