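#' Simulation configuration for synthetic sulcal feature tables
#'
#' Builds and validates the configuration driving [simulate_table()]. The
#' generator emulates the statistical structure of an automated
#' sulcal-morphometry extraction: per labelled cortical region three measures
#' (length, mean depth, maximum depth), mostly Gaussian features with a
#' minority carrying a long right tail, correlated depth measures within a
#' region, region-level misdetections (the labelling pipeline missing a
#' sulcus drops all three measures at once), and rare gross outliers.
#'
#' @param n_per_class subjects per diagnosis group (cases and controls).
#' @param n_regions number of sulcal regions; features = `n_regions * 3`.
#' @param measures measure names, in column order within each region.
#' @param effect_features named or two-column spec of planted effects: a list
#'   of `list(feature = <index>, delta = <standardized mean shift>)`, or
#'   `NULL` for a global null.
#' @param heavy_tail_fraction proportion of features receiving a one-sided
#'   lognormal contaminant (long right tail).
#' @param depth_correlation correlation between the mean-depth and max-depth
#'   columns of a region, induced by a shared latent factor.
#' @param misdetect_prob per-(subject, region) probability that the region is
#'   unmeasured (all its measures NA).
#' @param outlier_prob per-cell probability of a gross outlier at 6-10 SD.
#' @param seed integer seed; identical config + seed gives identical tables.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_per_class = 57,
                       n_regions = 49,
                       measures = c("length", "meandepth", "maxdepth"),
                       effect_features = NULL,
                       heavy_tail_fraction = 0.15,
                       depth_correlation = 0.7,
                       misdetect_prob = 0,
                       outlier_prob = 0,
                       seed = 1L) {
  if (!is.numeric(n_per_class) || n_per_class < 2)
    stop("n_per_class must be >= 2", call. = FALSE)
  if (!is.numeric(n_regions) || n_regions < 1)
    stop("n_regions must be >= 1", call. = FALSE)
  stopifnot(heavy_tail_fraction >= 0, heavy_tail_fraction <= 1,
            misdetect_prob >= 0, misdetect_prob <= 1,
            outlier_prob >= 0, outlier_prob <= 1,
            depth_correlation >= -1, depth_correlation <= 1)
  m <- n_regions * length(measures)
  if (!is.null(effect_features)) {
    for (ef in effect_features) {
      if (ef$feature < 1 || ef$feature > m)
        stop("effect feature index out of range", call. = FALSE)
    }
  }
  structure(list(
    n_per_class = as.integer(n_per_class),
    n_regions = as.integer(n_regions),
    measures = measures,
    effect_features = effect_features,
    heavy_tail_fraction = heavy_tail_fraction,
    depth_correlation = depth_correlation,
    misdetect_prob = misdetect_prob,
    outlier_prob = outlier_prob,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Construct a feature table
#'
#' The container used throughout the pipeline: a subjects-by-features numeric
#' matrix with binary labels (1 = case, 0 = control), an NA mask marking
#' misdetected entries, and a normalization flag.
#'
#' @param values numeric matrix, subjects x features.
#' @param labels binary integer vector, one per subject.
#' @param subject_ids character vector of identifiers.
#' @param feature_names `"<region>_<measure>"` strings.
#' @param normalized whether columns are z-scored.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, labels, subject_ids = NULL,
                          feature_names = NULL, normalized = FALSE) {
  values <- as.matrix(values)
  if (is.null(subject_ids)) subject_ids <- sprintf("S%04d", seq_len(nrow(values)))
  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names)) feature_names <- sprintf("f%03d", seq_len(ncol(values)))
  }
  stopifnot(length(labels) == nrow(values),
            length(subject_ids) == nrow(values),
            length(feature_names) == ncol(values),
            all(labels %in% c(0L, 1L)))
  dimnames(values) <- list(subject_ids, feature_names)
  structure(list(
    subject_ids = subject_ids,
    labels = as.integer(labels),
    values = values,
    feature_names = feature_names,
    na_mask = is.na(values),
    normalized = isTRUE(normalized)
  ), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d subjects x %d features (%d cases, %d controls)%s\n",
              nrow(x$values), ncol(x$values), sum(x$labels == 1L),
              sum(x$labels == 0L),
              if (x$normalized) ", normalized" else ""))
  cat(sprintf("  NA entries: %d\n", sum(x$na_mask)))
  invisible(x)
}

#' Simulate a sulcal-morphometry feature table
#'
#' Draws a case-control table under the generative model described in
#' [sim_config()]. All base features are unit-variance; planted effects shift
#' the case-group mean by `delta` standard deviations. Depth correlation is
#' induced by a shared per-region latent factor (length is independent of
#' depth). Heavy-tailed columns add a one-sided lognormal contaminant,
#' identically distributed in both groups. Misdetections act at region level;
#' outliers are injected per cell at 6-10 SD with random sign.
#'
#' @param config a [sim_config()].
#' @return a [feature_table()], unnormalized.
#' @export
simulate_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- 2L * config$n_per_class
  nm <- length(config$measures)
  m <- config$n_regions * nm
  labels <- rep(c(1L, 0L), each = config$n_per_class)
  region_names <- sprintf("region%03d", seq_len(config$n_regions))
  feature_names <- as.vector(t(outer(region_names, config$measures, paste, sep = "_")))

  rho <- config$depth_correlation
  X <- matrix(NA_real_, n, m)
  depth_idx <- which(config$measures %in% c("meandepth", "maxdepth"))
  for (r in seq_len(config$n_regions)) {
    latent <- rnorm(n)
    for (j in seq_len(nm)) {
      col <- (r - 1L) * nm + j
      if (j %in% depth_idx && abs(rho) <= 1) {
        # shared latent factor: corr(meandepth, maxdepth) = rho in expectation
        s <- sign(rho)
        a <- sqrt(abs(rho))
        X[, col] <- (if (s < 0 && j == depth_idx[2]) -a else a) * latent +
          sqrt(1 - abs(rho)) * rnorm(n)
      } else {
        X[, col] <- rnorm(n)
      }
    }
  }

  if (config$heavy_tail_fraction > 0) {
    n_ht <- round(config$heavy_tail_fraction * m)
    ht_cols <- sample.int(m, n_ht)
    for (col in ht_cols) {
      # one-sided lognormal contaminant -> long right tail in both groups
      X[, col] <- X[, col] + rlnorm(n, meanlog = 0, sdlog = 1) - exp(0.5)
    }
  } else {
    ht_cols <- integer(0)
  }

  if (!is.null(config$effect_features)) {
    for (ef in config$effect_features) {
      X[labels == 1L, ef$feature] <- X[labels == 1L, ef$feature] + ef$delta
    }
  }

  if (config$outlier_prob > 0) {
    hits <- which(matrix(runif(n * m) < config$outlier_prob, n, m))
    if (length(hits)) {
      X[hits] <- sample(c(-1, 1), length(hits), replace = TRUE) *
        runif(length(hits), 6, 10) * apply(X, 2, sd)[((hits - 1) %/% n) + 1]
    }
  }

  if (config$misdetect_prob > 0) {
    miss <- matrix(runif(n * config$n_regions) < config$misdetect_prob,
                   n, config$n_regions)
    for (r in seq_len(config$n_regions)) {
      cols <- (r - 1L) * nm + seq_len(nm)
      X[miss[, r], cols] <- NA_real_
    }
  }

  attr_tab <- feature_table(X, labels, feature_names = feature_names,
                            normalized = FALSE)
  attr(attr_tab, "heavy_tail_cols") <- ht_cols
  attr(attr_tab, "config") <- config
  attr_tab
}

#' Simulate demographic covariates with exact group moments
#'
#' Generates per-subject covariates (age, IQ, years of education, sex) for a
#' case-control cohort. Continuous covariates are affinely rescaled within
#' each group so the sample mean and SD equal the targets exactly, which lets
#' printed summary statistics of a demographics table be reconstructed as
#' test statistics.
#'
#' @param n_case,n_control group sizes.
#' @param targets named list per covariate of
#'   `list(case = c(mean, sd), control = c(mean, sd))`.
#' @param sex_counts optional `list(case = c(male, female), control = ...)`.
#' @param seed integer seed.
#' @return a data.frame with one row per subject.
#' @export
simulate_demographics <- function(n_case, n_control,
                                  targets = list(
                                    age = list(case = c(22.95, 5.64), control = c(24.79, 7.36)),
                                    education = list(case = c(12.41, 2.91), control = c(13.40, 2.54))
                                  ),
                                  sex_counts = list(case = c(35, 23), control = c(29, 27)),
                                  seed = 1L) {
  if (n_case < 2 || n_control < 2) stop("group sizes must be >= 2", call. = FALSE)
  set.seed(seed)
  out <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n_case + n_control)),
    group = rep(c("case", "control"), c(n_case, n_control)),
    stringsAsFactors = FALSE
  )
  rescale <- function(x, mu, sd) (x - mean(x)) / stats::sd(x) * sd + mu
  for (nm in names(targets)) {
    tg <- targets[[nm]]
    out[[nm]] <- c(rescale(rnorm(n_case), tg$case[1], tg$case[2]),
                   rescale(rnorm(n_control), tg$control[1], tg$control[2]))
  }
  if (!is.null(sex_counts)) {
    mk <- function(cnt, n) {
      v <- rep(c("M", "F"), c(cnt[1], cnt[2]))
      if (length(v) != n) v <- rep_len(v, n)
      sample(v)
    }
    out$sex <- c(mk(sex_counts$case, n_case), mk(sex_counts$control, n_control))
  }
  out
}

#' Write a feature table to CSV with a JSON config sidecar
#'
#' @param table a [feature_table()].
#' @param path output CSV path; header is
#'   `subject_id,label,<region>_<measure>...`, NA cells empty.
#' @param config optional [sim_config()] stored as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, config = NULL) {
  df <- data.frame(subject_id = table$subject_ids, label = table$labels,
                   table$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), paste0(path, ".json"),
                         auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @param normalized whether the stored columns are already z-scored (the CSV
#'   itself does not record this).
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, normalized = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE)
  feature_table(as.matrix(df[, -(1:2), drop = FALSE]),
                labels = df$label, subject_ids = df$subject_id,
                normalized = normalized)
}
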