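test_that("observation assembly centres, scales, and groups classes", {
  set.seed(5)
  X <- matrix(rnorm(10 * 6, mean = 3), 10, 6)
  cls <- rep(c("healthy", "advanced"), 5)
  uv <- assemble_observations(X, cls, "uv")
  expect_equal(unname(apply(uv$X, 2, sd)), rep(1, 6))
  expect_equal(unname(colMeans(uv$X)), rep(0, 6), tolerance = 1e-12)
  none <- assemble_observations(X, cls, "none")
  expect_equal(none$X, sweep(X, 2, colMeans(X)), ignore_attr = TRUE)
  par <- assemble_observations(X, cls, "pareto")
  expect_equal(unname(apply(par$X, 2, sd)),
               unname(sqrt(apply(X, 2, sd))), tolerance = 1e-12)
  # zero-variance feature dropped with a warning under uv
  X2 <- cbind(X, 5)
  expect_warning(z <- assemble_observations(X2, cls, "uv"), "zero-variance")
  expect_equal(ncol(z$X), 6)
  expect_error(assemble_observations(cbind(X, NA), cls), "missing")
  # 17-section design groups to 12 vs 5
  cls17 <- rep(c("healthy", "mild", "advanced"), c(6, 6, 5))
  g <- assemble_observations(matrix(rnorm(17 * 4), 17, 4), cls17,
                             group_nonathero = TRUE)
  expect_equal(unname(table(g$y)[c("non-atherosclerotic", "atherosclerotic")]),
               c(12L, 5L), ignore_attr = TRUE)
})

test_that("PCA explains rank-1 data fully and conserves variance", {
  set.seed(6)
  u <- rnorm(12); v <- rnorm(5)
  X1 <- outer(u, v)
  p1 <- fit_pca(X1, 2)
  expect_equal(p1$explained[1], 1, tolerance = 1e-12)
  X <- matrix(rnorm(15 * 6), 15, 6)
  p <- fit_pca(X, 4)
  expect_lte(sum(p$explained), 1 + 1e-12)
  # deterministic sign convention: largest-|loading| entry positive
  for (j in 1:4) expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  expect_error(fit_pca(X, 20), "n_comp")
})

test_that("advanced sections separate in PCA score space on the cohort", {
  co <- make_cohort(12, class_assignment = rep(c("healthy", "advanced"), 6),
                    effect_size = 2, seed = 13, grid_shape = c(24, 24))
  obs <- cohort_p99(co)
  suppressWarnings(om <- assemble_observations(obs$X, obs$classes, "uv"))
  p <- fit_pca(om, 2)
  sil <- mean(vapply(seq_along(obs$classes), function(i) {
    own <- obs$classes == obs$classes[i]
    D <- as.matrix(dist(p$scores))
    a <- sum(D[i, own]) / max(1, sum(own) - 1)
    b <- mean(D[i, !own])
    (b - a) / max(a, b)
  }, numeric(1)))
  expect_gt(sil, 0.3)
})

test_that("OPLS-DA with no orthogonal components equals PLS1", {
  set.seed(7)
  for (r in 1:10) {
    X <- matrix(rnorm(14 * 9), 14, 9)
    y <- factor(rep(c("a", "b"), 7))
    m <- fit_oplsda(X, y, n_ortho = 0, folds = 4)
    t_oracle <- pls1_scores(X, as.numeric(y == "b"))
    expect_lt(max(abs(abs(c(m$t_pred)) - abs(t_oracle))), 1e-8)
  }
})

test_that("a single decisive feature dominates R2Y, coefficients and VIP", {
  set.seed(8)
  X <- matrix(rnorm(20 * 6), 20, 6)
  y <- factor(rep(c("a", "b"), each = 10))
  X[, 4] <- as.numeric(y == "b") * 4 + rnorm(20, 0, 0.01)
  m <- fit_oplsda(X, y, n_ortho = 0)
  expect_gt(m$R2Y, 0.99)
  expect_equal(which.max(abs(m$coefficients)), 4, ignore_attr = TRUE)
  expect_equal(which.max(m$VIP), 4, ignore_attr = TRUE)
  expect_equal(mean(m$VIP^2), 1, tolerance = 1e-9)
  expect_lte(m$Q2, m$R2Y + 1e-9)
  # orthogonality of predictive and orthogonal scores
  m1 <- fit_oplsda(X, y, n_ortho = 1)
  expect_lt(abs(crossprod(m1$t_pred, m1$t_orth[, 1])), 1e-8)
  # prediction on training data classifies correctly
  pr <- predict(m, X)
  expect_equal(pr$class, as.character(y))
  expect_error(fit_oplsda(X[1:3, ], y[1:3]), "at least 4|class")
  expect_error(fit_oplsda(X, factor(rep("a", 20))), "2 classes")
})

test_that("all-equal informative features share one VIP value", {
  set.seed(9)
  y <- factor(rep(c("a", "b"), each = 8))
  base <- as.numeric(y == "b")
  X <- cbind(base, base, base, base) + matrix(0, 16, 4)
  m <- fit_oplsda(X, y, n_ortho = 0, folds = 4)
  expect_equal(max(m$VIP) - min(m$VIP), 0, tolerance = 1e-9)
})

test_that("sevenfold Q2 is deterministic, stratified, and honest under noise", {
  set.seed(10)
  X <- matrix(rnorm(21 * 8), 21, 8)
  y <- factor(rep(c("a", "b", "b"), 7))
  q1 <- q2_sevenfold(X, y, seed = 3)
  q2 <- q2_sevenfold(X, y, seed = 3)
  expect_identical(q1, q2)
  q3 <- q2_sevenfold(X, y, seed = 4)
  expect_false(identical(q1$fold_id, q3$fold_id))
  # every training fold keeps both classes
  for (f in 1:7) expect_equal(length(unique(y[q1$fold_id != f])), 2)
  # pure-noise response: Q2 <= 0 in at least 80% of simulations
  neg <- vapply(1:60, function(b) {
    Xb <- matrix(rnorm(20 * 10), 20, 10)
    yb <- factor(rep(c("a", "b"), each = 10))
    q2_sevenfold(Xb, yb, seed = b)$Q2 <= 0
  }, logical(1))
  expect_gte(mean(neg), 0.8)
  # folds that would strand a class raise a clear error
  ysmall <- factor(c("a", rep("b", 12)))
  expect_error(q2_sevenfold(matrix(rnorm(13 * 4), 13), ysmall, folds = 13),
               "without one class")
})

test_that("strong planted effects produce high Q2 at the study size", {
  co <- make_cohort(17, effect_size = 2, seed = 17, grid_shape = c(24, 24))
  obs <- cohort_p99(co)
  suppressWarnings(om <- assemble_observations(obs$X, obs$classes, "uv",
                                               group_nonathero = TRUE))
  m <- fit_oplsda(om, n_ortho = 0, positive_class = "atherosclerotic")
  expect_gt(m$Q2, 0.5)
  expect_gt(m$R2Y, m$Q2 - 1e-9)
})

test_that("CV-ANOVA hits its limits: p -> 0 for perfect prediction, 1 for none", {
  set.seed(12)
  y <- factor(rep(c("a", "b"), each = 10))
  X <- cbind(as.numeric(y == "b") * 2, matrix(rnorm(20 * 3, 0, 0.005), 20, 3))
  m <- fit_oplsda(X, y, n_ortho = 0)
  cv <- cv_anova(m)
  expect_lt(cv$p_value, 1e-6)
  # pure noise: PRESS >= SStot typically -> p = 1
  Xn <- matrix(rnorm(20 * 30), 20, 30)
  mn <- fit_oplsda(Xn, y, n_ortho = 0, cv_seed = 5)
  if (mn$press >= mn$sstot) expect_equal(cv_anova(mn)$p_value, 1)
  # p decreases monotonically along a planted effect-size grid
  pvals <- vapply(c(0.3, 0.8, 1.6, 3), function(es) {
    set.seed(99)
    Xe <- matrix(rnorm(20 * 8), 20, 8)
    Xe[, 1] <- Xe[, 1] + as.numeric(y == "b") * es
    cv_anova(fit_oplsda(Xe, y, n_ortho = 0, cv_seed = 1))$p_value
  }, numeric(1))
  expect_true(!is.unsorted(rev(pvals)))
})

test_that("permutation p honours its lower bound and flags real effects", {
  set.seed(13)
  y <- factor(rep(c("a", "b"), each = 8))
  X <- matrix(rnorm(16 * 5), 16, 5)
  X[, 2] <- X[, 2] + as.numeric(y == "b") * 3
  m <- fit_oplsda(X, y, n_ortho = 0)
  pt <- permutation_test(m, n_perm = 30, seed = 2)
  expect_gte(pt$p_value, 1 / 31)
  expect_lte(pt$p_value, 2 / 31)
  # deterministic given the seed
  pt2 <- permutation_test(m, n_perm = 30, seed = 2)
  expect_identical(pt$null_q2, pt2$null_q2)
  # no real effect: permutation p-values are not systematically small
  pnull <- vapply(1:5, function(r) {
    Xn <- matrix(rnorm(16 * 5), 16, 5)
    mn <- fit_oplsda(Xn, y, n_ortho = 0, cv_seed = r)
    permutation_test(mn, n_perm = 30, seed = r)$p_value
  }, numeric(1))
  expect_gt(mean(pnull), 0.2)
  expect_error(permutation_test(m, n_perm = 5), "20")
})

test_that("myocardium-style coefficient exclusion is monotone and targeted", {
  co <- make_cohort(8, class_assignment = rep(c("healthy", "advanced"), 4),
                    effect_size = 1, seed = 19, grid_shape = c(36, 48),
                    include_tissue_context = TRUE)
  # build tissue-level observations: myocardium vs artery-wall segments
  mzs <- sort(unique(unlist(lapply(co, function(s) s$truth$feature_mz))))
  seg_rows <- list(); seg_cls <- character(0)
  for (s in co) {
    P <- pixel_feature_matrix(s$dataset, mzs, 20)
    lab <- as.vector(s$truth$label_image)
    nm <- s$truth$label_names
    myo <- lab == nm[["myocardium"]]
    art <- lab %in% nm[setdiff(names(nm), c("myocardium", "PVAT"))]
    seg_rows[[length(seg_rows) + 1]] <-
      apply(P[myo, , drop = FALSE], 2, quantile, 0.99, names = FALSE)
    seg_cls <- c(seg_cls, "myocardium")
    seg_rows[[length(seg_rows) + 1]] <-
      apply(P[art, , drop = FALSE], 2, quantile, 0.99, names = FALSE)
    seg_cls <- c(seg_cls, "artery")
  }
  Xt <- do.call(rbind, seg_rows)
  suppressWarnings(om <- assemble_observations(Xt, seg_cls, "uv"))
  m <- fit_oplsda(om, n_ortho = 0, positive_class = "myocardium")
  # only the myocardium-exclusive species attain positive coefficients
  # toward myocardium, so a moderate quantile picks them out
  exc <- exclude_features_by_coefficient(m, 0.3)
  # kept feature indices map back through the dropped-feature bookkeeping
  keep <- setdiff(seq_along(mzs), om$dropped)
  exc_mz <- mzs[keep][exc]
  myo_species <- unique(co[[1]]$truth$species_table[
    co[[1]]$truth$species_table$region == "myocardium", "mz"])
  myo_only <- setdiff(myo_species,
    co[[1]]$truth$species_table$mz[
      co[[1]]$truth$species_table$region != "myocardium"])
  expect_true(all(exc_mz %in% myo_only))
  expect_gt(length(exc_mz), 0)
  # exclusion size is monotone non-increasing in q, empty near 1
  sizes <- vapply(c(0.1, 0.3, 0.5, 0.8, 0.999),
                  function(q) length(exclude_features_by_coefficient(m, q)),
                  numeric(1))
  expect_true(!is.unsorted(rev(sizes)))
  expect_equal(sizes[5], 0)
  expect_error(exclude_features_by_coefficient(m, 1), "in \\(0, 1\\)")
  # one-vs-rest wrapper fits one model per class with that class positive
  ovr <- suppressWarnings(fit_oplsda_ovr(om$X, om$y, n_ortho = 0))
  expect_named(ovr, c("artery", "myocardium"))
  expect_equal(ovr$myocardium$positive_class, "myocardium")
})
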