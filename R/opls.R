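#' Orthogonal projections to latent structures discriminant analysis
#'
#' Two-class OPLS-DA in the Trygg-Wold formulation: `n_ortho` components of
#' y-orthogonal variation are identified and deflated from X, then a single
#' predictive component is fitted against the dummy-coded response
#' (`positive_class` coded 1, the other class 0). With `n_ortho = 0` the
#' predictive scores coincide with the first component of PLS1. The fit
#' reports R2Y (explained class variance on the training data), the
#' sevenfold cross-validated Q2 (venetian-blind stratified folds, see
#' [q2_sevenfold()]), per-feature VIP and regression coefficients.
#'
#' `n_ortho = "auto"` grows the orthogonal part while the Q2 gain of one
#' more component is at least 0.01.
#'
#' @param x Numeric matrix (observations x features) or an
#'   `observation_matrix` (already centred/scaled).
#' @param y Two-level factor/character vector (ignored when `x` is an
#'   `observation_matrix`).
#' @param n_ortho Number of orthogonal components, or `"auto"`.
#' @param positive_class Class coded as 1 (default: last factor level).
#' @param folds Cross-validation folds for Q2 (default 7, reduced to n
#'   when n < folds).
#' @param cv_seed Seed for the fold assignment.
#' @return Object of class `oplsda_result` with scores, loadings, weights,
#'   `R2Y`, `Q2`, `press`, `sstot`, `cv_residuals`, `VIP`, `coefficients`,
#'   `n_ortho`, and the training data (for permutation testing).
#' @export
fit_oplsda <- function(x, y = NULL, n_ortho = 0, positive_class = NULL,
                       folds = 7, cv_seed = 1) {
  if (inherits(x, "observation_matrix")) {
    y <- x$y
    X <- x$X
  } else X <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2)
    stop("exactly 2 classes required (use fit_oplsda_ovr for multi-class)")
  if (min(table(y)) < 2) stop("each class needs at least 2 members")
  n <- nrow(X)
  if (n < 4) stop("at least 4 observations required")
  if (is.null(positive_class)) positive_class <- levels(y)[2]
  stopifnot(positive_class %in% levels(y))
  yd <- as.numeric(y == positive_class)

  if (identical(n_ortho, "auto")) {
    max_o <- max(0, min(dim(X)) - 2)
    q_prev <- q2_sevenfold(X, y, n_ortho = 0, folds = folds, seed = cv_seed,
                           positive_class = positive_class)$Q2
    n_ortho <- 0
    while (n_ortho < max_o) {
      q_next <- q2_sevenfold(X, y, n_ortho = n_ortho + 1, folds = folds,
                             seed = cv_seed, positive_class = positive_class)$Q2
      if (!is.finite(q_next) || q_next - q_prev < 0.01) break
      n_ortho <- n_ortho + 1
      q_prev <- q_next
    }
  }

  core <- opls_core(X, yd, n_ortho)
  cv <- q2_sevenfold(X, y, n_ortho = n_ortho, folds = folds, seed = cv_seed,
                     positive_class = positive_class)
  p_feat <- ncol(core$X_used)
  vip <- sqrt(p_feat) * abs(core$w[, 1]) / sqrt(sum(core$w^2))
  names(vip) <- colnames(X) %||% paste0("F", seq_len(ncol(X)))
  coefs <- core$b
  names(coefs) <- names(vip)
  structure(list(
    t_pred = core$t_pred, t_orth = core$t_orth, p_pred = core$p_pred,
    p_orth = core$p_orth, w = core$w, w_orth = core$w_orth,
    c_coef = core$c_coef, x_center = core$x_center, y_mean = core$y_mean,
    R2Y = core$R2Y, Q2 = cv$Q2, press = cv$press, sstot = cv$sstot,
    cv_residuals = cv$residuals, folds = cv$folds, cv_seed = cv_seed,
    VIP = vip, coefficients = coefs, n_ortho = n_ortho,
    levels = levels(y), positive_class = positive_class,
    X = X, y = y, fitted = core$fitted),
    class = "oplsda_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Trygg-Wold OPLS on a centred problem; yd is the 0/1 dummy.
opls_core <- function(X, yd, n_ortho) {
  x_center <- colMeans(X)
  Xc <- sweep(X, 2, x_center)
  y_mean <- mean(yd)
  yc <- yd - y_mean
  p <- ncol(Xc)
  W_o <- P_o <- matrix(0, p, 0)
  T_o <- matrix(0, nrow(Xc), 0)
  Xd <- Xc
  for (k in seq_len(n_ortho)) {
    w <- crossprod(Xd, yc) / sum(yc^2)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_ <- Xd %*% w
    pv <- crossprod(Xd, t_) / sum(t_^2)
    w_o <- pv - c(crossprod(w, pv)) * w
    nwo <- sqrt(sum(w_o^2))
    if (nwo < 1e-10) break  # no orthogonal variation left
    w_o <- w_o / nwo
    t_o <- Xd %*% w_o
    p_o <- crossprod(Xd, t_o) / sum(t_o^2)
    Xd <- Xd - t_o %*% t(p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
  }
  w <- crossprod(Xd, yc) / sum(yc^2)
  w <- w / sqrt(sum(w^2))
  t_pred <- Xd %*% w
  p_pred <- crossprod(Xd, t_pred) / sum(t_pred^2)
  c_coef <- c(crossprod(yc, t_pred)) / sum(t_pred^2)
  fitted <- c(t_pred * c_coef) + y_mean
  R2Y <- 1 - sum((yc - t_pred * c_coef)^2) / sum(yc^2)
  # coefficients on the training X scale: yhat = Xc %*% b + y_mean
  b <- w * c_coef
  for (k in rev(seq_len(ncol(W_o))))
    b <- b - W_o[, k, drop = FALSE] * c(crossprod(P_o[, k], b))
  list(w = w, t_pred = t_pred, p_pred = p_pred, c_coef = c_coef,
       w_orth = W_o, p_orth = P_o, t_orth = T_o, R2Y = R2Y,
       b = c(b), fitted = fitted, x_center = x_center, y_mean = y_mean,
       X_used = Xc)
}

opls_predict_core <- function(core, Xnew) {
  Xn <- sweep(Xnew, 2, core$x_center)
  if (ncol(core$w_orth)) {
    for (k in seq_len(ncol(core$w_orth))) {
      t_o <- Xn %*% core$w_orth[, k, drop = FALSE]
      Xn <- Xn - t_o %*% t(core$p_orth[, k, drop = FALSE])
    }
  }
  tp <- Xn %*% core$w
  c(tp * core$c_coef) + core$y_mean
}

#' Predict class membership from a fitted OPLS-DA model
#'
#' Orthogonal components are removed from the new data with the training
#' weights/loadings, then the predictive score is mapped to the dummy
#' response; the decision threshold is 0.5.
#'
#' @param object An `oplsda_result`.
#' @param newdata Matrix on the same feature space as the training data.
#' @param ... Unused.
#' @return `data.frame` with `y_score` and `class`.
#' @export
predict.oplsda_result <- function(object, newdata, ...) {
  core <- list(x_center = object$x_center, w_orth = object$w_orth,
               p_orth = object$p_orth, w = object$w, c_coef = object$c_coef,
               y_mean = object$y_mean)
  sc <- opls_predict_core(core, as.matrix(newdata))
  neg <- setdiff(object$levels, object$positive_class)
  data.frame(y_score = sc,
             class = ifelse(sc > 0.5, object$positive_class, neg))
}

#' @export
print.oplsda_result <- function(x, ...) {
  cat(sprintf("<oplsda_result> %s vs %s: R2Y=%.3f Q2=%.3f (1+%d components)\n",
              x$positive_class, setdiff(x$levels, x$positive_class),
              x$R2Y, x$Q2, x$n_ortho))
  invisible(x)
}

#' Sevenfold cross-validated Q2 for OPLS-DA
#'
#' Stratified venetian-blind fold assignment: observations are ordered by
#' class and (seed-permuted) index, and assigned to folds cyclically, so
#' folds are as class-balanced as possible and the assignment is
#' deterministic given the seed. For each fold the model is refit on the
#' remaining observations with the same number of orthogonal components
#' and the held-out responses are predicted;
#' `Q2 = 1 - PRESS / SS_tot` with `SS_tot` the corrected total sum of
#' squares of the dummy response. A training fold that would lose an
#' entire class raises an error.
#'
#' @param X Observations x features matrix.
#' @param y Two-level class vector.
#' @param n_ortho Number of orthogonal components.
#' @param folds Number of folds (default 7; reduced to n if larger).
#' @param seed Seed for the within-class permutation.
#' @param positive_class Class coded 1.
#' @return List with `Q2`, `press`, `sstot`, `residuals` (cross-validated,
#'   in input order), `folds`, `fold_id`.
#' @export
q2_sevenfold <- function(X, y, n_ortho = 0, folds = 7, seed = 1,
                         positive_class = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  n <- nrow(X)
  folds <- min(folds, n)
  if (is.null(positive_class)) positive_class <- levels(y)[2]
  yd <- as.numeric(y == positive_class)
  set.seed(seed)
  ord <- order(y, sample.int(n))         # class blocks, permuted within
  fold_id <- integer(n)
  fold_id[ord] <- rep_len(seq_len(folds), n)
  res <- numeric(n)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    ytr <- yd[!test]
    if (length(unique(ytr)) < 2)
      stop("fold assignment would leave a training set without one class; ",
           "reduce the number of folds")
    core <- opls_core(X[!test, , drop = FALSE], ytr, n_ortho)
    pred <- opls_predict_core(core, X[test, , drop = FALSE])
    res[test] <- yd[test] - pred
  }
  press <- sum(res^2)
  sstot <- sum((yd - mean(yd))^2)
  list(Q2 = 1 - press / sstot, press = press, sstot = sstot,
       residuals = res, folds = folds, fold_id = fold_id)
}

#' CV-ANOVA significance test of an OPLS-DA model
#'
#' F-test comparing the cross-validated residual sum of squares (PRESS)
#' against the corrected total sum of squares of the response, in the
#' Eriksson-style formulation: `F = ((SS_tot - PRESS) / df1) / (PRESS /
#' df2)` with `df1` the number of model components (predictive +
#' orthogonal) and `df2 = n - df1 - 1`; the p-value comes from the F
#' distribution. `PRESS >= SS_tot` (a model with no cross-validated
#' predictive ability) yields p = 1.
#'
#' @param model An `oplsda_result` (its stored cross-validation results
#'   are used).
#' @return List with `p_value`, `F`, `df1`, `df2`, `press`, `sstot`.
#' @export
cv_anova <- function(model) {
  stopifnot(inherits(model, "oplsda_result"))
  press <- model$press
  sstot <- model$sstot
  n <- nrow(model$X)
  df1 <- 1 + model$n_ortho
  df2 <- max(1, n - df1 - 1)
  if (press >= sstot)
    return(list(p_value = 1, F = 0, df1 = df1, df2 = df2,
                press = press, sstot = sstot))
  Fstat <- ((sstot - press) / df1) / (press / df2)
  list(p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE), F = Fstat,
       df1 = df1, df2 = df2, press = press, sstot = sstot)
}

#' Permutation test of an OPLS-DA model
#'
#' Refits the model `n_perm` times with permuted class labels and compares
#' the permuted Q2 values to the observed one:
#' `p = (1 + #{Q2_perm >= Q2_obs}) / (1 + n_perm)`, so p is never smaller
#' than `1 / (1 + n_perm)`.
#'
#' @param model A fitted `oplsda_result` (its stored training data,
#'   `n_ortho` and fold settings are reused).
#' @param n_perm Number of permutations (>= 20).
#' @param seed Seed for the permutations.
#' @return List with `p_value`, `q2_obs`, `null_q2`, `null_r2y`.
#' @export
permutation_test <- function(model, n_perm = 100, seed = 0) {
  stopifnot(inherits(model, "oplsda_result"), n_perm >= 20)
  set.seed(seed)
  yd <- as.numeric(model$y == model$positive_class)
  null_q2 <- null_r2y <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    yp <- sample(yd)
    cv <- q2_sevenfold(model$X, factor(yp, levels = c(0, 1)),
                       n_ortho = model$n_ortho, folds = model$folds,
                       seed = model$cv_seed, positive_class = "1")
    null_q2[b] <- cv$Q2
    null_r2y[b] <- opls_core(model$X, yp, model$n_ortho)$R2Y
  }
  p <- (1 + sum(null_q2 >= model$Q2)) / (1 + n_perm)
  list(p_value = p, q2_obs = model$Q2, null_q2 = null_q2, null_r2y = null_r2y)
}

#' Variable influence on projection (VIP) scores
#'
#' VIP over the predictive component:
#' `VIP_j = sqrt(p * (w_j / ||w||)^2)`, whose squared values average to 1
#' by construction. Features with VIP above `threshold` (conventionally
#' 1.0) are marked influential.
#'
#' @param model An `oplsda_result`.
#' @param threshold Selection threshold (default 1.0).
#' @return List with `vip` (named numeric) and `selected` (logical mask).
#' @export
vip_scores <- function(model, threshold = 1.0) {
  stopifnot(inherits(model, "oplsda_result"))
  list(vip = model$VIP, selected = model$VIP > threshold)
}

#' One-vs-rest OPLS-DA for more than two classes
#'
#' OPLS-DA is natively two-class; a multi-class tissue model (e.g.
#' myocardium / PVAT / artery) is fitted as one binary model per class,
#' each discriminating that class (coded 1) from all others.
#'
#' @inheritParams fit_oplsda
#' @return Named list of `oplsda_result`, one per class.
#' @export
fit_oplsda_ovr <- function(x, y = NULL, n_ortho = 0, folds = 7, cv_seed = 1) {
  if (inherits(x, "observation_matrix")) {
    y <- x$y
    x <- x$X
  }
  y <- factor(y)
  out <- lapply(levels(y), function(lv) {
    y2 <- factor(ifelse(y == lv, lv, "rest"), levels = c("rest", lv))
    fit_oplsda(x, y2, n_ortho = n_ortho, positive_class = lv, folds = folds,
               cv_seed = cv_seed)
  })
  stats::setNames(out, levels(y))
}

#' Exclude features by OPLS-DA coefficient toward a target class
#'
#' Given a tissue-level model whose positive class is the target tissue
#' (e.g. myocardium vs rest), excludes the features whose coefficient
#' toward the target class exceeds the `q`-quantile of the positive
#' coefficients. The empirical (inverse-ECDF, type 1) quantile is used so
#' the exclusion set shrinks monotonically to empty as `q` approaches 1.
#'
#' @param model An `oplsda_result` with the target class coded positive.
#' @param q Quantile in (0, 1).
#' @return Integer vector of excluded feature indices (named).
#' @export
exclude_features_by_coefficient <- function(model, q = 0.9) {
  stopifnot(inherits(model, "oplsda_result"))
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  b <- model$coefficients
  pos <- b[b > 0]
  if (!length(pos)) return(integer(0))
  thr <- stats::quantile(pos, q, type = 1, names = FALSE)
  which(b > thr)
}
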