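#' Route features to a parametric or non-parametric two-sample test
#'
#' Each feature is tested for normality with the Shapiro-Wilk test on the
#' pooled sample; features where normality is not rejected at `alpha` are
#' routed to the two-sample t-test, the rest to the Mann-Whitney U test.
#'
#' @param table an NA-free [feature_table()].
#' @param alpha routing significance level (default 0.05). `alpha = 0` routes
#'   everything to the t-test.
#' @return data.frame with `feature`, `normality_p`, `routed_test`.
#' @export
route_by_normality <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  if (any(table$na_mask)) stop("table contains NA entries", call. = FALSE)
  if (nrow(table$values) < 3) stop("need at least 3 subjects", call. = FALSE)
  p <- apply(table$values, 2, function(x) stats::shapiro.test(x)$p.value)
  data.frame(feature = table$feature_names,
             normality_p = unname(p),
             routed_test = ifelse(p >= alpha, "t-test", "mann-whitney"),
             stringsAsFactors = FALSE)
}

#' Pooled (or Welch) two-sample t-test
#'
#' Sign convention: the statistic is computed as control minus case, so a
#' positive statistic means the control group mean is larger.
#'
#' @param x_case,x_control numeric vectors, each with at least 2 values.
#' @param pooled use the pooled-variance statistic (default); `FALSE` gives
#'   the Welch variant.
#' @return `list(statistic, p_value, df)` with a two-sided p-value.
#' @export
two_sample_t <- function(x_case, x_control, pooled = TRUE) {
  if (length(x_case) < 2 || length(x_control) < 2)
    stop("each group needs >= 2 observations", call. = FALSE)
  if (stats::var(x_case) == 0 && stats::var(x_control) == 0 &&
      mean(x_case) == mean(x_control)) {
    return(list(statistic = 0, p_value = 1,
                df = length(x_case) + length(x_control) - 2))
  }
  ht <- stats::t.test(x_control, x_case, var.equal = pooled)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Two-sample t-test from printed summary moments
#'
#' Reconstructs the pooled-variance statistic from group means, SDs and sizes,
#' as needed to recompute the test column of a demographics table.
#'
#' @param mean1,sd1,n1 first group moments and size.
#' @param mean2,sd2,n2 second group moments and size.
#' @return `list(statistic, p_value, df)`; statistic is group2 minus group1.
#' @export
t_from_moments <- function(mean1, sd1, n1, mean2, sd2, n2) {
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  tt <- (mean2 - mean1) / (sp * sqrt(1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(statistic = tt, p_value = 2 * stats::pt(-abs(tt), df), df = df)
}

#' Mann-Whitney U test
#'
#' Two-sided. Exact enumeration for small samples without ties, normal
#' approximation with tie correction otherwise (the crossover follows the
#' standard rule at a combined n of 20).
#'
#' @param x_case,x_control numeric vectors.
#' @return `list(statistic, p_value)` where `statistic` is the U count for the
#'   case group (number of (case, control) pairs with case > control, ties
#'   counting one half).
#' @export
mann_whitney_u <- function(x_case, x_control) {
  if (!length(x_case) || !length(x_control))
    stop("each group needs >= 1 observation", call. = FALSE)
  ht <- suppressWarnings(stats::wilcox.test(x_case, x_control,
                                            exact = NULL, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = min(1, ht$p.value))
}

#' Run the routed univariate selection over every feature
#'
#' @param table an NA-free [feature_table()] with both classes present.
#' @param alpha Shapiro-Wilk routing level.
#' @param pooled pooled-variance t (default) or Welch.
#' @return data.frame: `feature`, `normality_p`, `routed_test`, `statistic`,
#'   `p_value`, one row per feature.
#' @export
univariate_selection <- function(table, alpha = 0.05, pooled = TRUE) {
  routing <- route_by_normality(table, alpha)
  case <- table$labels == 1L
  res <- lapply(seq_along(table$feature_names), function(j) {
    x1 <- table$values[case, j]
    x0 <- table$values[!case, j]
    if (routing$routed_test[j] == "t-test") {
      r <- two_sample_t(x1, x0, pooled = pooled)
    } else {
      r <- mann_whitney_u(x1, x0)
    }
    c(statistic = r$statistic, p_value = r$p_value)
  })
  res <- do.call(rbind, res)
  cbind(routing, data.frame(statistic = res[, "statistic"],
                            p_value = res[, "p_value"]))
}

#' Rank features by p-value and keep those under a threshold
#'
#' @param results data.frame with `feature` and `p_value` columns.
#' @param threshold keep features with `p_value < threshold`.
#' @param adjust optional p-value adjustment method passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); default `"none"`, matching raw-p
#'   ranking.
#' @return the selected rows in ascending p order (ties broken by feature
#'   name for determinism).
#' @export
rank_features <- function(results, threshold = 0.05, adjust = "none") {
  stopifnot(nrow(results) > 0)
  p <- stats::p.adjust(results$p_value, method = adjust)
  ord <- order(p, results$feature)
  out <- results[ord, , drop = FALSE]
  out$p_adjusted <- p[ord]
  out[out$p_adjusted < threshold, , drop = FALSE]
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction, df = 1 — the form that reproduces printed
#' sex-by-group statistics in demographic tables.
#'
#' @param counts 2x2 matrix of counts.
#' @return `list(statistic, p_value, df)`.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, df = 1L)
}
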