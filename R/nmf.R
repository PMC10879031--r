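#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative pixels x features matrix `X ~ W H` with
#' `W >= 0` (pixels x k component abundances) and `H >= 0` (k x features
#' component spectra), using Lee-Seung multiplicative updates for the
#' Frobenius objective. Multiplicative updates are chosen because the
#' objective is guaranteed non-increasing across iterations, which makes
#' the implementation directly testable. Initialization is uniform random
#' scaled by `sqrt(mean(X) / k)`, fully determined by `seed`. On return,
#' rows of `H` are scaled to unit maximum with the scale moved into `W`
#' (which leaves `W %*% H` unchanged).
#'
#' @param X Non-negative numeric matrix (pixels x features).
#' @param k Rank (number of components), >= 1.
#' @param seed Integer seed for the random initialization (default 0).
#' @param max_iter Maximum iterations (default 500).
#' @param tol Stop when the decrease of the relative reconstruction error
#'   between iterations falls below this (default 1e-9).
#' @param method `"mu"` (multiplicative updates, default — objective
#'   provably non-increasing) or `"hals"` (hierarchical alternating least
#'   squares — converges considerably deeper per iteration, useful when a
#'   near-exact factorization is expected).
#' @param n_restarts Number of random restarts (seeds `seed`, `seed + 1`,
#'   ...); the factorization with the lowest relative error is returned.
#' @return Object of class `nmf_result`: `W`, `H`, `k`, `relative_error`
#'   (`||X - WH||_F / ||X||_F`), `error_trace`, `seed`, `n_iter`.
#' @export
run_nmf <- function(X, k, seed = 0, max_iter = 500, tol = 1e-9,
                    method = c("mu", "hals"), n_restarts = 1) {
  method <- match.arg(method)
  if (n_restarts > 1) {
    fits <- lapply(seq_len(n_restarts) - 1L, function(r)
      run_nmf(X, k, seed = seed + r, max_iter = max_iter, tol = tol,
              method = method, n_restarts = 1))
    errs <- vapply(fits, `[[`, numeric(1), "relative_error")
    return(fits[[which.min(errs)]])
  }
  run_nmf_single(X, k, seed, max_iter, tol, method)
}

run_nmf_single <- function(X, k, seed, max_iter, tol, method) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("X must be non-negative")
  stopifnot(k >= 1, k <= min(dim(X)))
  set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  scale0 <- sqrt(max(mean(X), .Machine$double.eps) / k)
  W <- matrix(stats::runif(n * k), n, k) * scale0
  H <- matrix(stats::runif(k * p), k, p) * scale0
  eps <- .Machine$double.eps
  normX <- sqrt(sum(X^2))
  if (normX == 0) normX <- eps
  err <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    if (method == "mu") {
      H <- H * (crossprod(W, X)) / (crossprod(W, W) %*% H + eps)
      W <- W * (X %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
    } else {
      WtX <- crossprod(W, X); WtW <- crossprod(W, W)
      for (j in seq_len(k)) {
        h <- H[j, ] + (WtX[j, ] - WtW[j, ] %*% H) / max(WtW[j, j], eps)
        H[j, ] <- pmax(h, 0)
      }
      XHt <- X %*% t(H); HHt <- tcrossprod(H, H)
      for (j in seq_len(k)) {
        w <- W[, j] + (XHt[, j] - W %*% HHt[, j]) / max(HHt[j, j], eps)
        W[, j] <- pmax(w, 0)
      }
    }
    e <- sqrt(sum((X - W %*% H)^2)) / normX
    err <- c(err, e)
    if (is.finite(prev) && prev - e < tol) break
    prev <- e
  }
  # unit-max row scaling of H, scale moved into W
  d <- apply(H, 1, max)
  d[d == 0] <- 1
  H <- H / d
  W <- sweep(W, 2, d, `*`)
  structure(list(W = W, H = H, k = as.integer(k),
                 relative_error = err[length(err)], error_trace = err,
                 seed = as.integer(seed), n_iter = length(err)),
            class = "nmf_result")
}

#' @export
print.nmf_result <- function(x, ...) {
  cat(sprintf("<nmf_result> k=%d, %d x %d, relative error %.3g (%d iterations)\n",
              x$k, nrow(x$W), ncol(x$H), x$relative_error, x$n_iter))
  invisible(x)
}

kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(X, 2, X[centers[1], ])^2)
  for (j in 2:k) {
    if (all(d2 <= 0)) {
      centers[j] <- sample.int(n, 1)
    } else {
      centers[j] <- sample.int(n, 1, prob = pmax(d2, 0))
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[centers[j], ])^2))
  }
  X[centers, , drop = FALSE]
}

mean_silhouette <- function(X, cl) {
  # standard silhouette on Euclidean distances; singletons score 0
  D <- as.matrix(stats::dist(X))
  ks <- sort(unique(cl))
  if (length(ks) < 2) return(NA_real_)
  s <- numeric(length(cl))
  for (i in seq_along(cl)) {
    own <- cl == cl[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- sum(D[i, own]) / (sum(own) - 1)
    b <- min(vapply(ks[ks != cl[i]], function(g) mean(D[i, cl == g]),
                    numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Select the NMF rank with a K-means criterion
#'
#' Runs K-means (k-means++ seeding, `nstart` restarts) on L2-row-normalized
#' pixel spectra for each candidate rank, and picks the rank maximizing the
#' mean silhouette score (ties resolve to the smallest rank). This treats
#' the number of well-separated pixel populations as the number of spatial
#' lipid components.
#'
#' @param X Non-negative pixels x features matrix (all-zero rows are
#'   dropped before clustering).
#' @param k_range Candidate ranks, a subset of `[2, min(dim(X)) - 1]`.
#' @param seed Integer seed (default 0).
#' @param nstart K-means restarts per rank (default 10).
#' @param max_pixels Cap on pixels used for the silhouette (deterministic
#'   subsample when exceeded).
#' @return Selected rank (integer), with the per-rank mean silhouettes in
#'   attribute `"silhouette"`.
#' @export
select_rank <- function(X, k_range = 2:6, seed = 0, nstart = 10,
                        max_pixels = 2000) {
  X <- as.matrix(X)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > min(dim(X)) - 1)
    stop("k_range must lie within [2, min(dim(X)) - 1]")
  rn <- sqrt(rowSums(X^2))
  Xn <- X[rn > 0, , drop = FALSE] / rn[rn > 0]
  if (nrow(Xn) <= max(k_range))
    stop("fewer non-empty pixels than the largest candidate rank")
  set.seed(seed)
  if (nrow(Xn) > max_pixels)
    Xn <- Xn[sample.int(nrow(Xn), max_pixels), , drop = FALSE]
  sil <- stats::setNames(numeric(length(k_range)), k_range)
  for (j in seq_along(k_range)) {
    k <- k_range[j]
    best <- NULL
    for (r in seq_len(nstart)) {
      C <- kmeanspp_centers(Xn, k)
      C <- C + matrix(stats::runif(length(C), 0, 1e-9), nrow(C)) # distinct
      km <- tryCatch(stats::kmeans(Xn, centers = C, iter.max = 100),
                     error = function(e) NULL)
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    sil[j] <- if (is.null(best)) -Inf else mean_silhouette(Xn, best$cluster)
  }
  k_sel <- k_range[which.max(sil)]   # which.max takes the first (smallest) tie
  structure(as.integer(k_sel), silhouette = sil)
}

#' Component abundance images from an NMF result
#'
#' Reshapes each column of `W` to the acquisition grid.
#'
#' @param result An [run_nmf()] result.
#' @param grid_shape `c(rows, cols)`.
#' @param coords Optional n x 2 matrix of 0-based `(row, col)` pixel
#'   coordinates for the rows of `W` (default: full grid in row-major
#'   order). Pixels not covered are 0.
#' @return List of `k` matrices.
#' @export
component_images <- function(result, grid_shape, coords = NULL) {
  stopifnot(inherits(result, "nmf_result"))
  n <- nrow(result$W)
  if (is.null(coords)) {
    if (n != prod(grid_shape))
      stop("W rows do not fill the grid; supply coords")
    rc <- arrayInd(seq_len(n), grid_shape)
    coords <- cbind(rc[, 1] - 1L, rc[, 2] - 1L)
  }
  stopifnot(nrow(coords) == n)
  lapply(seq_len(result$k), function(j) {
    img <- matrix(0, grid_shape[1], grid_shape[2])
    img[cbind(coords[, 1] + 1L, coords[, 2] + 1L)] <- result$W[, j]
    img
  })
}

#' Features with the largest weight in one NMF component
#'
#' @param result An [run_nmf()] result.
#' @param component Component index (1..k).
#' @param n Number of drivers (all features, ranked, when larger than the
#'   feature count).
#' @param feature_mz Optional m/z labels for the features.
#' @param annotations Optional annotation table (from [best_annotation()])
#'   joined on feature m/z.
#' @return `data.frame` with `feature`, `mz`, `weight` and, when
#'   annotations are given, `name` and `class`.
#' @export
top_drivers <- function(result, component, n = 10, feature_mz = NULL,
                        annotations = NULL) {
  stopifnot(inherits(result, "nmf_result"))
  if (component < 1 || component > result$k)
    stop("component index out of range")
  h <- result$H[component, ]
  ord <- order(h, decreasing = TRUE)[seq_len(min(n, length(h)))]
  out <- data.frame(feature = ord, mz = if (!is.null(feature_mz))
    feature_mz[ord] else NA_real_, weight = h[ord])
  if (!is.null(annotations) && !is.null(feature_mz)) {
    j <- match(round(out$mz, 6), round(annotations$feature_mz, 6))
    out$name <- annotations$name[j]
    out$class <- annotations$class[j]
  }
  out
}
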