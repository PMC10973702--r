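#' Local sparse surrogate explanation
#'
#' Explains a single prediction by fitting an interpretable (sparse linear)
#' surrogate to the model in a neighbourhood of the explained sample: seeded
#' Gaussian perturbations around `x`, locality weights from an exponential
#' kernel on distance, a lightly ridge-regularized weighted least-squares
#' fit, and the `top_k` coefficients by magnitude reported. A positive
#' weight means increasing that feature increases the explained class's
#' propensity locally.
#'
#' @param model a classifier understood by [decision_values()], or a plain
#'   function `X -> numeric`.
#' @param x numeric vector, the sample to explain (training dimensionality).
#' @param n_perturbations neighbourhood size, default 1000.
#' @param kernel_width exponential-kernel width in standardized units,
#'   default `0.75 * sqrt(length(x))` (distance scales with sqrt(m)).
#' @param perturb_sd SD of the Gaussian jitter, default 1 (features are
#'   z-scored upstream).
#' @param top_k coefficients to report, default 10.
#' @param ridge ridge penalty stabilizing the local fit, default 1e-6.
#' @param seed integer seed.
#' @return data.frame of the top_k features: `feature`, `weight`, ordered by
#'   `|weight|` descending; attribute `"intercept"` carries the local offset.
#' @export
explain_local <- function(model, x, n_perturbations = 1000,
                          kernel_width = NULL, perturb_sd = 1,
                          top_k = 10, ridge = 1e-6, seed = 1L) {
  f <- if (is.function(model)) model else function(X) decision_values(model, X)
  m <- length(x)
  if (n_perturbations < top_k) stop("n_perturbations < top_k", call. = FALSE)
  if (is.null(kernel_width)) kernel_width <- 0.75 * sqrt(m)
  set.seed(seed)
  Z <- matrix(rnorm(n_perturbations * m, sd = perturb_sd), n_perturbations, m)
  if (all(Z == 0)) stop("degenerate perturbation spread", call. = FALSE)
  Xp <- sweep(Z, 2, x, "+")
  yp <- f(Xp)
  wts <- exp(-rowSums(Z^2) / kernel_width^2)
  D <- cbind(1, Z) # local coordinates centred at x
  A <- crossprod(D * wts, D) + diag(ridge, m + 1)
  beta <- drop(solve(A, crossprod(D * wts, yp)))
  coefs <- beta[-1]
  names(coefs) <- if (!is.null(names(x))) names(x) else sprintf("f%03d", seq_len(m))
  ord <- order(-abs(coefs))
  out <- data.frame(feature = names(coefs)[ord][seq_len(min(top_k, m))],
                    weight = unname(coefs[ord])[seq_len(min(top_k, m))],
                    stringsAsFactors = FALSE)
  attr(out, "intercept") <- beta[1]
  out
}

shap_model_fn <- function(model) {
  if (is.function(model)) model else function(X) decision_values(model, X)
}

#' Exact Shapley values by coalition enumeration
#'
#' The attribution of feature s is its average marginal contribution over all
#' coalitions T of the remaining features, weighted |T|! (M - |T| - 1)! / M!.
#' A coalition's prediction `f_x(T)` is the model output with features
#' outside T replaced by the background expectation (column means of the
#' background sample). Enumeration is 2^M model calls, so M is capped at 12.
#' Local accuracy holds exactly: the attributions plus the baseline sum to
#' the model output at `x`.
#'
#' @param model classifier or function `X -> numeric`.
#' @param x sample to explain.
#' @param background matrix whose column means define the "absent feature"
#'   replacement (typically the training set).
#' @return class `shap_result`: `phi` (named attributions), `baseline`
#'   (model output at the background means), `fx`, `additivity_residual`.
#' @export
exact_shapley <- function(model, x, background) {
  f <- shap_model_fn(model)
  M <- length(x)
  if (M > 12) stop("exact enumeration capped at 12 features", call. = FALSE)
  bg <- colMeans(as.matrix(background))
  # model value for every coalition (bitmask over features present from x)
  n_coal <- 2^M
  Xc <- matrix(rep(bg, each = n_coal), n_coal, M)
  masks <- matrix(FALSE, n_coal, M)
  for (j in seq_len(M)) masks[, j] <- bitwAnd(0:(n_coal - 1), bitwShiftL(1L, j - 1L)) > 0
  for (j in seq_len(M)) Xc[masks[, j], j] <- x[j]
  v <- f(Xc)
  sizes <- rowSums(masks)
  phi <- numeric(M)
  for (s in seq_len(M)) {
    without <- which(!masks[, s])
    Tsize <- sizes[without]
    w <- factorial(Tsize) * factorial(M - Tsize - 1) / factorial(M)
    with_idx <- without + as.integer(2^(s - 1))
    phi[s] <- sum(w * (v[with_idx] - v[without]))
  }
  names(phi) <- if (!is.null(names(x))) names(x) else sprintf("f%03d", seq_len(M))
  baseline <- v[1]
  fx <- v[n_coal]
  structure(list(phi = phi, baseline = baseline, fx = fx,
                 additivity_residual = abs(sum(phi) + baseline - fx)),
            class = "shap_result")
}

shapley_kernel_weight <- function(M, z) {
  (M - 1) / (choose(M, z) * z * (M - z))
}

#' Kernel-estimated Shapley values
#'
#' Weighted least squares over coalitions with the Shapley kernel weight
#' `(M-1) / (C(M,|z|) |z| (M-|z|))`, with the efficiency (additivity)
#' constraint imposed by eliminating the last attribution. When
#' `n_coalitions >= 2^M - 2`, all proper coalitions are enumerated and the
#' estimate equals the exact Shapley values up to numerical error; otherwise
#' coalitions are sampled by the kernel distribution over sizes.
#'
#' @param model classifier or function. @param x sample to explain.
#' @param background background matrix (column means used for absence).
#' @param n_coalitions sampled coalitions, `>= length(x) + 2`.
#' @param seed integer seed.
#' @return a `shap_result` (see [exact_shapley()]).
#' @export
kernel_shap <- function(model, x, background, n_coalitions = 2000, seed = 1L) {
  f <- shap_model_fn(model)
  M <- length(x)
  if (n_coalitions < M + 2) stop("n_coalitions too small", call. = FALSE)
  bg <- colMeans(as.matrix(background))
  baseline <- f(matrix(bg, 1)); fx <- f(matrix(x, 1))
  full <- 2^M - 2
  if (n_coalitions >= full) {
    masks <- matrix(FALSE, full, M)
    for (j in seq_len(M)) masks[, j] <- bitwAnd(1:(2^M - 2), bitwShiftL(1L, j - 1L)) > 0
  } else {
    set.seed(seed)
    sizes <- 1:(M - 1)
    pr <- shapley_kernel_weight(M, sizes) * choose(M, sizes)
    draw <- sample(sizes, n_coalitions, replace = TRUE, prob = pr / sum(pr))
    masks <- t(vapply(draw, function(sz) {
      z <- rep(FALSE, M); z[sample.int(M, sz)] <- TRUE; z
    }, logical(M)))
  }
  sizes <- rowSums(masks)
  w <- shapley_kernel_weight(M, sizes)
  Xc <- matrix(rep(bg, each = nrow(masks)), nrow(masks), M)
  for (j in seq_len(M)) Xc[masks[, j], j] <- x[j]
  v <- f(Xc)
  # efficiency constraint: phi_M = (fx - baseline) - sum(other phis)
  Zm <- masks[, -M, drop = FALSE] - masks[, M]
  yv <- v - baseline - masks[, M] * (fx - baseline)
  A <- crossprod(Zm * w, Zm)
  qrA <- qr(A)
  if (qrA$rank < ncol(Zm))
    stop("singular design; raise n_coalitions", call. = FALSE)
  phi_part <- drop(solve(qrA, crossprod(Zm * w, yv)))
  phi <- c(phi_part, (fx - baseline) - sum(phi_part))
  names(phi) <- if (!is.null(names(x))) names(x) else sprintf("f%03d", seq_len(M))
  structure(list(phi = phi, baseline = baseline, fx = fx,
                 additivity_residual = abs(sum(phi) + baseline - fx)),
            class = "shap_result")
}

#' @export
print.shap_result <- function(x, ...) {
  cat(sprintf("shap_result: f(x)=%.4f baseline=%.4f residual=%.2e\n",
              x$fx, x$baseline, x$additivity_residual))
  print(round(sort(x$phi, decreasing = TRUE), 4))
  invisible(x)
}

#' Summarize attributions over a set of explained samples
#'
#' Features are ranked by mean absolute attribution; per-feature
#' (value, attribution) pairs are exported for dependence analysis,
#' optionally paired with a colouring feature's values.
#'
#' @param results list of `shap_result` objects.
#' @param X matrix of the explained samples (same order), for dependence
#'   pairs; optional.
#' @param top_k ranking length, default 10.
#' @return `list(ranking = data.frame(feature, mean_abs_phi),
#'   dependence = named list of data.frames(value, phi))`. Empty ranking
#'   (with a warning) when all attributions are zero.
#' @export
summarize_attributions <- function(results, X = NULL, top_k = 10) {
  stopifnot(length(results) >= 1)
  Phi <- do.call(rbind, lapply(results, `[[`, "phi"))
  mabs <- colMeans(abs(Phi))
  if (all(mabs == 0)) {
    warning("all attributions are zero")
    return(list(ranking = data.frame(feature = character(0),
                                     mean_abs_phi = numeric(0)),
                dependence = list()))
  }
  ord <- order(-mabs)
  keep <- ord[seq_len(min(top_k, length(mabs)))]
  ranking <- data.frame(feature = colnames(Phi)[keep],
                        mean_abs_phi = unname(mabs[keep]),
                        stringsAsFactors = FALSE)
  dependence <- list()
  if (!is.null(X)) {
    X <- as.matrix(X)
    for (j in keep) {
      dependence[[colnames(Phi)[j]]] <-
        data.frame(value = X[, j], phi = Phi[, j])
    }
  }
  list(ranking = ranking, dependence = dependence)
}
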