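#' Assemble an observation matrix for multivariate modelling
#'
#' Centres and scales a segments-or-sections x features intensity matrix
#' (typically the 99th-percentile segment intensities, with positive- and
#' negative-mode features concatenated) and attaches class labels. Scaling
#' follows chemometrics conventions: `"uv"` (unit variance, the default),
#' `"pareto"` (divide by the square root of the standard deviation), or
#' `"none"` (centring only). Features with zero variance are dropped with
#' a warning under `"uv"` and `"pareto"`. With `group_nonathero = TRUE`,
#' healthy and mild labels are merged into `"non-atherosclerotic"` and
#' advanced becomes `"atherosclerotic"`.
#'
#' @param X Numeric matrix, observations x features (missing = 0 upstream).
#' @param classes Character vector of class labels, one per row of `X`.
#' @param scaling `"uv"`, `"pareto"` or `"none"`.
#' @param group_nonathero Merge healthy+mild vs advanced into two groups.
#' @param feature_meta Optional `data.frame` of per-feature metadata (m/z,
#'   polarity, annotation), subset alongside dropped features.
#' @return Object of class `observation_matrix`: processed `X`, `y`
#'   (factor), `scaling`, `center`, `scale`, `dropped`, `feature_meta`.
#' @export
assemble_observations <- function(X, classes, scaling = c("uv", "pareto", "none"),
                                  group_nonathero = FALSE, feature_meta = NULL) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(classes))
  if (anyNA(X)) stop("X must not contain missing values (absent feature = 0)")
  y <- as.character(classes)
  if (group_nonathero) {
    y[y %in% c("healthy", "mild")] <- "non-atherosclerotic"
    y[y == "advanced"] <- "atherosclerotic"
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sds <- apply(X, 2, stats::sd)
  dropped <- integer(0)
  scl <- rep(1, ncol(X))
  if (scaling %in% c("uv", "pareto")) {
    dropped <- which(sds == 0)
    if (length(dropped)) {
      warning(length(dropped), " zero-variance feature(s) dropped under ",
              scaling, " scaling")
      Xc <- Xc[, -dropped, drop = FALSE]
      sds <- sds[-dropped]
      ctr <- ctr[-dropped]
      if (!is.null(feature_meta))
        feature_meta <- feature_meta[-dropped, , drop = FALSE]
    }
    scl <- if (scaling == "uv") sds else sqrt(sds)
    Xc <- sweep(Xc, 2, scl, `/`)
  }
  structure(list(X = Xc, y = factor(y), scaling = scaling, center = ctr,
                 scale = scl, dropped = dropped, feature_meta = feature_meta),
            class = "observation_matrix")
}

#' Principal component analysis with a deterministic sign convention
#'
#' Singular value decomposition of the (already centred/scaled) matrix.
#' For each component, the loading of largest magnitude is made positive,
#' which fixes the sign indeterminacy of the SVD.
#'
#' @param x An `observation_matrix` or a numeric matrix (a plain matrix is
#'   centred here).
#' @param n_comp Number of components, at most `min(dim)`.
#' @return List with `scores` (n x n_comp), `loadings` (p x n_comp),
#'   `explained` (fraction of total variance per component), `sdev`.
#' @export
fit_pca <- function(x, n_comp = 2) {
  X <- if (inherits(x, "observation_matrix")) x$X else
    sweep(as.matrix(x), 2, colMeans(as.matrix(x)))
  if (n_comp < 1 || n_comp > min(dim(X)))
    stop("n_comp must be in [1, min(dim(X))]")
  sv <- svd(X, nu = n_comp, nv = n_comp)
  for (j in seq_len(n_comp)) {
    i_max <- which.max(abs(sv$v[, j]))
    if (sv$v[i_max, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  d <- sv$d[seq_len(n_comp)]
  scores <- sweep(sv$u, 2, d, `*`)
  total <- sum(sv$d^2)
  list(scores = scores, loadings = sv$v, explained = d^2 / total,
       sdev = sv$d / sqrt(max(1, nrow(X) - 1)))
}
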