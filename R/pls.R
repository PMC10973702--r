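#' Partial least squares by NIPALS
#'
#' Supervised dimensionality reduction decomposing the (column-centred)
#' predictor matrix as `X = Xs Xl' + E`, where `Xs` (samples x d) are scores,
#' `Xl` (features x d) loadings, and `E` the residual. Components are
#' extracted by NIPALS deflation so component scores have non-increasing
#' covariance with the label vector. For determinism each weight vector is
#' signed so its largest-magnitude entry is positive.
#'
#' @param X numeric matrix, samples x features (need not be centred; the
#'   model stores column means and centres internally).
#' @param y numeric or binary label vector.
#' @param d number of components, `1 <= d < min(samples, features)` columns.
#' @param tol inner-loop convergence tolerance.
#' @return class `pls_model`: `weights` (W), `loadings` (Xl = P), `scores`
#'   (Xs = T), `residual` (E), `rotation` (W(P'W)^-1, used for out-of-sample
#'   projection), `x_means`, `y_mean`, `d`.
#' @export
fit_pls_matrix <- function(X, y, d, tol = 1e-12) {
  X <- as.matrix(X)
  l <- nrow(X); m <- ncol(X)
  if (d < 1 || d >= m) stop("require 1 <= d < number of features", call. = FALSE)
  if (d > l) stop("more components than samples", call. = FALSE)
  y <- as.numeric(y)
  if (stats::var(y) == 0) stop("constant label vector", call. = FALSE)
  x_means <- colMeans(X)
  Xc <- sweep(X, 2, x_means)
  y_mean <- mean(y)
  u <- y - y_mean
  W <- matrix(0, m, d); P <- matrix(0, m, d); Tm <- matrix(0, l, d)
  E <- Xc
  for (h in seq_len(d)) {
    w <- drop(crossprod(E, u))
    nw <- sqrt(sum(w^2))
    if (nw < tol) stop("degenerate component ", h, call. = FALSE)
    w <- w / nw
    # sign convention: largest-magnitude weight entry positive
    s <- sign(w[which.max(abs(w))]); if (s < 0) w <- -w
    tt <- drop(E %*% w)
    p <- drop(crossprod(E, tt)) / sum(tt^2)
    W[, h] <- w; P[, h] <- p; Tm[, h] <- tt
    E <- E - tcrossprod(tt, p)
    q <- sum(u * tt) / sum(tt^2)
    u <- u - q * tt
  }
  rotation <- W %*% solve(crossprod(P, W))
  structure(list(weights = W, loadings = P, scores = Tm, residual = E,
                 rotation = rotation, x_means = x_means, y_mean = y_mean,
                 d = d, feature_names = colnames(X)),
            class = "pls_model")
}

#' Fit PLS on a feature table
#'
#' @param table a normalized, NA-free [feature_table()].
#' @param d number of components.
#' @return a `pls_model`; see [fit_pls_matrix()].
#' @export
fit_pls <- function(table, d) {
  stopifnot(inherits(table, "feature_table"))
  if (any(table$na_mask)) stop("table contains NA entries", call. = FALSE)
  fit_pls_matrix(table$values, table$labels, d)
}

#' Project samples onto fitted PLS components
#'
#' Uses only training-derived quantities (column means and the rotation
#' matrix); labels of the projected samples are never consulted, so the
#' projection is leakage-free inside cross-validation.
#'
#' @param model a `pls_model`.
#' @param X matrix or [feature_table()] with the training feature order.
#' @return samples x d score matrix.
#' @export
pls_transform <- function(model, X) {
  if (inherits(X, "feature_table")) {
    if (!is.null(model$feature_names) &&
        !identical(X$feature_names, model$feature_names))
      stop("feature names differ from training", call. = FALSE)
    X <- X$values
  }
  X <- as.matrix(X)
  if (ncol(X) != nrow(model$rotation)) stop("dimension mismatch", call. = FALSE)
  sweep(X, 2, model$x_means) %*% model$rotation
}

#' Serialize a PLS model to JSON
#' @param model a `pls_model`. @param path output file.
#' @return `path`, invisibly.
#' @export
write_pls_json <- function(model, path) {
  jsonlite::write_json(list(loadings = model$loadings, weights = model$weights,
                            rotation = model$rotation, x_means = model$x_means,
                            d = model$d),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
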