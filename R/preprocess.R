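#' Preprocessing configuration
#'
#' Parameters of the exclusion cascade applied to a raw feature table:
#' subjects with too many misdetected regions are dropped, named regions are
#' removed, regions with any residual misdetection are removed, columns are
#' z-scored, and subjects with any extreme standardized value are dropped.
#'
#' @param max_misdetections_per_subject a subject is removed when its count of
#'   misdetected regions is strictly greater than this (default 18, about 15%
#'   of a 123-region atlas).
#' @param excluded_regions region names removed outright (the insulae are
#'   excluded in sulcal atlases for their shape-driven misdetection risk).
#' @param outlier_sd subjects with any |z| above this multiplier are removed
#'   after normalization (default 6).
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(max_misdetections_per_subject = 18L,
                              excluded_regions = c("insula_left", "insula_right"),
                              outlier_sd = 6) {
  stopifnot(max_misdetections_per_subject >= 0, outlier_sd > 0)
  structure(list(
    max_misdetections_per_subject = as.integer(max_misdetections_per_subject),
    excluded_regions = excluded_regions,
    outlier_sd = outlier_sd
  ), class = "preprocess_config")
}

region_of <- function(feature_names) sub("_[^_]+$", "", feature_names)

#' Apply the exclusion cascade to a raw feature table
#'
#' The rule order is fixed and canonical: (1) drop subjects whose misdetected
#' region count exceeds the threshold; (2) drop named regions; (3) drop any
#' region with a residual misdetection; (4) z-score each remaining column
#' (sample SD); (5) drop subjects with any |z| > `outlier_sd`. Normalization
#' statistics are computed once on the subjects surviving steps 1-3; outlier
#' removal does not trigger renormalization, so the ">6 SD" rule keeps its
#' meaning on the original standardization. The order matters: permuting
#' steps 4 and 5 changes which subjects survive.
#'
#' @param table an unnormalized [feature_table()].
#' @param config a [preprocess_config()].
#' @return `list(table = <clean feature_table>, report = <preprocess_report>)`;
#'   the returned table is NA-free. The report attributes every removal to
#'   exactly one rule and records the final shape.
#' @export
apply_exclusions <- function(table, config = preprocess_config()) {
  stopifnot(inherits(table, "feature_table"))
  if (table$normalized) stop("table is already normalized", call. = FALSE)
  regions <- region_of(table$feature_names)
  uniq_regions <- unique(regions)

  # step 1: subject-level misdetection count (a region counts once even though
  # all its measures are NA together)
  region_na <- sapply(uniq_regions, function(r) {
    cols <- which(regions == r)
    apply(table$na_mask[, cols, drop = FALSE], 1, any)
  })
  if (is.null(dim(region_na))) region_na <- matrix(region_na, nrow = 1)
  n_misdetect <- rowSums(region_na)
  drop_subj1 <- which(n_misdetect > config$max_misdetections_per_subject)
  keep_subj <- setdiff(seq_along(table$subject_ids), drop_subj1)
  if (!length(keep_subj)) stop("all subjects removed by misdetection rule", call. = FALSE)

  # step 2: named regions
  drop_named <- intersect(config$excluded_regions, uniq_regions)
  keep_feat <- which(!(regions %in% drop_named))

  # step 3: regions with residual NA among retained subjects
  sub_mask <- table$na_mask[keep_subj, keep_feat, drop = FALSE]
  sub_regions <- regions[keep_feat]
  resid <- unique(sub_regions[colSums(sub_mask) > 0])
  keep_feat2 <- keep_feat[!(sub_regions %in% resid)]
  if (!length(keep_feat2)) stop("all regions removed", call. = FALSE)

  X <- table$values[keep_subj, keep_feat2, drop = FALSE]

  # step 4: z-score with sample SD on surviving subjects
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv == 0)) {
    stop("zero-variance feature(s): ",
         paste(table$feature_names[keep_feat2][sdv == 0], collapse = ", "),
         call. = FALSE)
  }
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")

  # step 5: outlier subjects on the fixed standardization
  bad <- apply(abs(Z) > config$outlier_sd, 1, any)
  drop_out <- table$subject_ids[keep_subj][bad]
  Z <- Z[!bad, , drop = FALSE]
  if (!nrow(Z)) stop("all subjects removed by outlier rule", call. = FALSE)

  clean <- feature_table(Z,
                         labels = table$labels[keep_subj][!bad],
                         subject_ids = table$subject_ids[keep_subj][!bad],
                         feature_names = table$feature_names[keep_feat2],
                         normalized = TRUE)
  report <- structure(list(
    subjects_removed_misdetection = table$subject_ids[drop_subj1],
    regions_removed_named = drop_named,
    regions_removed_residual_na = resid,
    subjects_removed_outlier = drop_out,
    initial_shape = dim(table$values),
    final_shape = dim(Z),
    normalization = list(mean = mu, sd = sdv, sd_type = "sample")
  ), class = "preprocess_report")
  list(table = clean, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("preprocess_report: %d x %d -> %d x %d\n",
              x$initial_shape[1], x$initial_shape[2],
              x$final_shape[1], x$final_shape[2]))
  cat(sprintf("  subjects removed (misdetection > threshold): %d\n",
              length(x$subjects_removed_misdetection)))
  cat(sprintf("  regions removed (named): %d; (residual NA): %d\n",
              length(x$regions_removed_named), length(x$regions_removed_residual_na)))
  cat(sprintf("  subjects removed (outlier): %d\n", length(x$subjects_removed_outlier)))
  invisible(x)
}

#' Z-score every column of an NA-free feature table
#'
#' Columns are centred to mean 0 and scaled to sample SD 1. Idempotent up to
#' numerical tolerance.
#'
#' @param table an NA-free [feature_table()].
#' @return the normalized table.
#' @export
renormalize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (any(table$na_mask)) stop("table contains NA entries", call. = FALSE)
  sdv <- apply(table$values, 2, stats::sd)
  if (any(sdv == 0)) {
    stop("zero-variance feature(s): ",
         paste(table$feature_names[sdv == 0], collapse = ", "), call. = FALSE)
  }
  Z <- scale(table$values)
  feature_table(Z[, , drop = FALSE], table$labels, table$subject_ids,
                table$feature_names, normalized = TRUE)
}

#' Serialize a preprocess report to JSON
#' @param report a `preprocess_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_preprocess_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
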