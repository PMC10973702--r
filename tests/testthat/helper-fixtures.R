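# fixtures built in code, shared across test files

# small clean table with planted effects on the first `n_effects` features
make_effect_table <- function(n_per_class = 50, n_regions = 10, delta = 1,
                              n_effects = 3, seed = 11L, normalized = TRUE) {
  eff <- lapply(seq_len(n_effects), function(j) list(feature = j, delta = delta))
  cfg <- sim_config(n_per_class = n_per_class, n_regions = n_regions,
                    effect_features = eff, heavy_tail_fraction = 0,
                    misdetect_prob = 0, outlier_prob = 0, seed = seed)
  tab <- simulate_table(cfg)
  if (normalized) renormalize(tab) else tab
}

# two linearly separable 2-D blobs
make_blobs <- function(n = 30, gap = 4, seed = 5L) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n), n, 2),
             matrix(rnorm(2 * n) + gap, n, 2))
  list(X = X, y = rep(c(0L, 1L), each = n))
}

# exact-enumeration Mann-Whitney oracle: distribution of U over all
# assignments of ranks, small n, no ties
mw_exact_p <- function(x_case, x_control) {
  n1 <- length(x_case); n2 <- length(x_control)
  pooled <- c(x_case, x_control)
  u_stat <- function(case_idx) {
    xc <- pooled[case_idx]; xo <- pooled[-case_idx]
    sum(outer(xc, xo, ">")) + 0.5 * sum(outer(xc, xo, "=="))
  }
  obs <- u_stat(seq_len(n1))
  all_u <- apply(utils::combn(n1 + n2, n1), 2, u_stat)
  mu <- n1 * n2 / 2
  mean(abs(all_u - mu) >= abs(obs - mu) - 1e-12)
}

# independent NIPALS reference, coded separately from the package path
# (power-iteration form on the y-deflated cross-product)
nipals_reference_scores <- function(X, y, d) {
  Xc <- scale(X, scale = FALSE)
  u <- y - mean(y)
  S <- matrix(0, nrow(X), d)
  for (h in seq_len(d)) {
    w <- t(Xc) %*% u
    w <- w / sqrt(sum(w^2))
    tt <- Xc %*% w
    p <- t(Xc) %*% tt / sum(tt^2)
    Xc <- Xc - tt %*% t(p)
    u <- u - drop(crossprod(u, tt) / sum(tt^2)) * tt
    S[, h] <- tt
  }
  S
}
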