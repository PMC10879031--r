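# Shared fixtures and independent oracles, built in code at test time.

# small, fast artery phantom (default morphology on a 24 x 24 grid)
small_config <- function(polarity = "positive", noise_sd = 0.05, seed = 0, ...) {
  phantom_config(grid_shape = c(24, 24), polarity = polarity,
                 regions = default_regions(polarity, c(24, 24)),
                 noise_sd = noise_sd, seed = seed, ...)
}

# pixels x features matrix over the planted feature m/z, artery pixels only
phantom_artery_matrix <- function(ph, tol_ppm = 20) {
  X <- pixel_feature_matrix(ph$dataset, ph$truth$feature_mz, tol_ppm)
  X[as.vector(ph$truth$label_image) > 0, , drop = FALSE]
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# exhaustive-permutation assignment of recovered components to planted
# signatures (optimal for the small ranks used here; independent of any
# package code)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(p) c(v[i], p))))
}
matched_cosines <- function(H, planted) {
  k <- ncol(planted)
  stopifnot(nrow(H) == k)
  best <- NULL; best_mean <- -Inf
  for (p in all_perms(seq_len(k))) {
    cs <- vapply(seq_len(k), function(j) cosine(H[p[j], ], planted[, j]),
                 numeric(1))
    if (mean(cs) > best_mean) { best_mean <- mean(cs); best <- cs }
  }
  best
}

# independent NIPALS PLS1 (one component) used as the OPLS-DA equivalence
# oracle
pls1_scores <- function(X, y01) {
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y01 - mean(y01)
  w <- crossprod(Xc, yc)
  w <- w / sqrt(sum(w^2))
  c(Xc %*% w)
}

# per-section artery p99 observation matrix from a phantom cohort, using
# the planted ground-truth features
cohort_p99 <- function(cohort) {
  mzs <- sort(unique(unlist(lapply(cohort, function(s) s$truth$feature_mz))))
  X <- t(vapply(cohort, function(s) {
    P <- pixel_feature_matrix(s$dataset, mzs, 20)
    art <- as.vector(s$truth$label_image) > 0
    apply(P[art, , drop = FALSE], 2, stats::quantile, 0.99, type = 7,
          names = FALSE)
  }, numeric(length(mzs))))
  list(X = X, mzs = mzs,
       classes = vapply(cohort, function(s) s$dataset$disease_class,
                        character(1)))
}
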