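#' Fit a linear soft-margin SVM
#'
#' Maximum-margin linear separator via libsvm (e1071). The decision value for
#' a sample x is `w'x - b`, oriented so larger values mean more case-like
#' (class 1). Class weights default to inverse class frequency so unbalanced
#' draws do not bias the boundary.
#'
#' @param X numeric matrix, samples x features.
#' @param y binary labels (1 = case).
#' @param cost soft-margin regularization constant, default 1.
#' @param class_weights `"balanced"` (inverse frequency), a named vector, or
#'   `NULL` for unweighted.
#' @return class `linear_separator` with fields `w`, `b`.
#' @export
fit_linear_svm <- function(X, y, cost = 1, class_weights = "balanced") {
  X <- as.matrix(X)
  if (length(unique(y)) < 2) stop("need both classes", call. = FALSE)
  yf <- factor(y, levels = c(0, 1))
  cw <- NULL
  if (identical(class_weights, "balanced")) {
    tab <- table(yf)
    cw <- as.numeric(length(y) / (2 * tab)); names(cw) <- names(tab)
  } else if (!is.null(class_weights)) cw <- class_weights
  fit <- e1071::svm(X, yf, kernel = "linear", cost = cost, scale = FALSE,
                    class.weights = cw)
  # libsvm decision values are oriented toward the first class seen; recover
  # w, b and flip so positive means class 1
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- fit$rho
  if (fit$labels[1] == 1L) { # first level in the model is class "0"
    w <- -w; b <- -b
  }
  structure(list(w = w, b = b, levels = c(0L, 1L), svm = fit),
            class = "linear_separator")
}

#' Decision values of a fitted model
#'
#' Monotone in predicted class-1 (case) propensity; thresholding at 0 for
#' the linear separator, or 0.5 on the class-1 probability for the MLP,
#' reproduces [predict_class()].
#'
#' @param model a `linear_separator` or `mlp_model`.
#' @param X samples x features matrix.
#' @return numeric vector of decision values.
#' @export
decision_values <- function(model, X) UseMethod("decision_values")

#' @export
decision_values.linear_separator <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$w)) stop("dimension mismatch", call. = FALSE)
  drop(X %*% model$w) - model$b
}

#' Predict class labels (1 = case, 0 = control)
#' @param model a fitted classifier. @param X samples x features.
#' @return integer vector of 0/1 predictions.
#' @export
predict_class <- function(model, X) UseMethod("predict_class")

#' @export
predict_class.linear_separator <- function(model, X) {
  as.integer(decision_values(model, X) > 0)
}

#' Squared L2 norm of a model's flattened parameter vector
#'
#' Sum of squared weights and biases — the complexity term entering the
#' PAC-Bayes dropout bound.
#' @param model a fitted classifier.
#' @return non-negative scalar.
#' @export
theta_norm_sq <- function(model) UseMethod("theta_norm_sq")

#' @export
theta_norm_sq.linear_separator <- function(model) sum(model$w^2) + model$b^2

#' Convenience factory for [fit_linear_svm()]
#' @param cost soft-margin constant. @param class_weights see [fit_linear_svm()].
#' @return function `(X, y) -> linear_separator`.
#' @export
svm_factory <- function(cost = 1, class_weights = "balanced") {
  function(X, y) fit_linear_svm(X, y, cost, class_weights)
}

# ---- multilayer perceptron ------------------------------------------------

relu <- function(x) pmax(x, 0)

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Specify a multilayer perceptron
#'
#' A feedforward network with exactly two hidden layers (ReLU) and a
#' two-unit softmax output trained with class-weighted cross-entropy, Adam,
#' batch size 1 — the small-sample tabular recipe. Hidden widths default to
#' 32 and 16.
#'
#' @param hidden integer vector of the two hidden-layer widths.
#' @param epochs training passes, default 18.
#' @param batch_size default 1 (per-sample updates).
#' @param learning_rate Adam step size, default 0.001.
#' @param seed controls initialization and the per-epoch sample shuffle.
#' @return an `mlp_spec` list.
#' @export
mlp_spec <- function(hidden = c(32L, 16L), epochs = 18L, batch_size = 1L,
                     learning_rate = 0.001, seed = 1L) {
  stopifnot(length(hidden) == 2, all(hidden >= 1), epochs >= 0)
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "mlp_spec")
}

#' Single-perceptron forward rule
#'
#' The output of one unit: `f(w . y_prev + b)` for activation `f`. Exposed
#' for testing the forward computation in isolation.
#' @param w weight vector. @param y_prev previous-layer activations.
#' @param b bias. @param activation function, default identity.
#' @return scalar activation.
#' @export
perceptron_forward <- function(w, y_prev, b, activation = identity) {
  activation(sum(w * y_prev) + b)
}

mlp_init <- function(m, hidden, seed) {
  set.seed(seed)
  sizes <- c(m, hidden, 2L)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    # He-style scaling for the ReLU layers
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    # small positive bias keeps narrow ReLU layers from initializing dead
    b[[l]] <- rep(if (l < length(sizes) - 1) 0.01 else 0, sizes[l + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X) {
  A1 <- relu(sweep(X %*% par$W[[1]], 2, par$b[[1]], "+"))
  A2 <- relu(sweep(A1 %*% par$W[[2]], 2, par$b[[2]], "+"))
  Z3 <- sweep(A2 %*% par$W[[3]], 2, par$b[[3]], "+")
  list(A1 = A1, A2 = A2, Z3 = Z3, P = softmax_rows(Z3))
}

#' Train a multilayer perceptron
#'
#' Exactly `spec$epochs` passes over the data, per-sample (batch size 1)
#' Adam updates of the class-weighted cross-entropy, with a seeded shuffle
#' of sample order each epoch. No early stopping. Zero epochs returns the
#' seeded initial weights untouched.
#'
#' @param X samples x features matrix (finite). @param y binary labels.
#' @param spec an [mlp_spec()].
#' @return class `mlp_model`.
#' @export
fit_mlp <- function(X, y, spec = mlp_spec()) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite inputs", call. = FALSE)
  n <- nrow(X)
  # re-draw the seeded init (deterministically) if a whole ReLU layer starts
  # dead on the training data: no gradient could ever revive it
  par <- mlp_init(ncol(X), spec$hidden, spec$seed)
  for (attempt in seq_len(10)) {
    fw0 <- mlp_forward(par, X)
    if (max(fw0$A1) > 0 && max(fw0$A2) > 0) break
    par <- mlp_init(ncol(X), spec$hidden, spec$seed + 7919L * attempt)
  }
  set.seed(spec$seed) # epoch shuffles share one stream regardless of retries
  tab <- table(factor(y, levels = c(0, 1)))
  cw <- as.numeric(n / (2 * tab)) # inverse-frequency class weights
  names(cw) <- c("0", "1")
  lr <- spec$learning_rate; b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(b) b * 0); vb <- mb
  t <- 0
  if (spec$epochs > 0) {
    for (ep in seq_len(spec$epochs)) {
      ord <- sample(n)
      for (start in seq(1, n, by = spec$batch_size)) {
        idx <- ord[start:min(start + spec$batch_size - 1, n)]
        xb <- X[idx, , drop = FALSE]
        yb <- y[idx]
        fw <- mlp_forward(par, xb)
        # dL/dZ3 for weighted cross-entropy with one-hot targets
        Tg <- cbind(1 - yb, yb)
        wgt <- cw[as.character(yb)]
        dZ3 <- (fw$P - Tg) * wgt / length(idx)
        gW3 <- t(fw$A2) %*% dZ3; gb3 <- colSums(dZ3)
        dA2 <- dZ3 %*% t(par$W[[3]]); dZ2 <- dA2 * (fw$A2 > 0)
        gW2 <- t(fw$A1) %*% dZ2; gb2 <- colSums(dZ2)
        dA1 <- dZ2 %*% t(par$W[[2]]); dZ1 <- dA1 * (fw$A1 > 0)
        gW1 <- t(xb) %*% dZ1; gb1 <- colSums(dZ1)
        gW <- list(gW1, gW2, gW3); gb <- list(gb1, gb2, gb3)
        t <- t + 1
        for (l in 1:3) {
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW[[l]]
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW[[l]]^2
          par$W[[l]] <- par$W[[l]] - lr * (mW[[l]] / (1 - b1^t)) /
            (sqrt(vW[[l]] / (1 - b2^t)) + eps)
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb[[l]]
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb[[l]]^2
          par$b[[l]] <- par$b[[l]] - lr * (mb[[l]] / (1 - b1^t)) /
            (sqrt(vb[[l]] / (1 - b2^t)) + eps)
        }
      }
    }
  }
  structure(list(par = par, spec = spec, m = ncol(X)), class = "mlp_model")
}

#' @export
decision_values.mlp_model <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$m) stop("dimension mismatch", call. = FALSE)
  mlp_forward(model$par, X)$P[, 2] # class-1 probability
}

#' @export
predict_class.mlp_model <- function(model, X) {
  as.integer(decision_values(model, X) > 0.5)
}

#' @export
theta_norm_sq.mlp_model <- function(model) {
  sum(vapply(model$par$W, function(w) sum(w^2), 0)) +
    sum(vapply(model$par$b, function(b) sum(b^2), 0))
}

#' Convenience factory for [fit_mlp()]
#' @param spec an [mlp_spec()].
#' @return function `(X, y) -> mlp_model`.
#' @export
mlp_factory <- function(spec = mlp_spec()) function(X, y) fit_mlp(X, y, spec)

#' Serialize a fitted model to JSON for exact reload
#' @param model a `linear_separator` or `mlp_model`. @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  if (inherits(model, "linear_separator")) {
    obj <- list(type = "linear_separator", w = model$w, b = model$b)
  } else if (inherits(model, "mlp_model")) {
    obj <- list(type = "mlp_model", W = model$par$W, b = model$par$b,
                spec = unclass(model$spec), m = model$m)
  } else stop("unsupported model", call. = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
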