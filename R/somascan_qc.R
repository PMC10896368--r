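#' Construct a proteomics dataset
#'
#' Container for a sample-by-aptamer RFU matrix with the plate, cohort and
#' scale-factor annotations needed by the QC rules. Values must be strictly
#' positive and finite; every sample maps to exactly one plate.
#'
#' @param rfu numeric matrix, samples in rows (rownames = sample IDs),
#'   aptamers in columns (colnames = aptamer IDs).
#' @param plate_of_sample named character vector: plate label per sample.
#' @param cohort cohort label.
#' @param calib_scale,median_scale aptamer-by-plate matrices of calibration
#'   and median scale factors (dimensionless).
#' @param replicate_groups optional named list of character vectors; each
#'   vector holds the sample IDs of one technical-replicate group.
#' @return an object of class \code{proteomics_dataset}.
#' @export
proteomics_dataset <- function(rfu, plate_of_sample, cohort = "cohort",
                               calib_scale = NULL, median_scale = NULL,
                               replicate_groups = list()) {
  if (is.null(rownames(rfu)) || is.null(colnames(rfu))) {
    stop("rfu must have sample rownames and aptamer colnames", call. = FALSE)
  }
  if (any(!is.finite(rfu)) || any(rfu <= 0)) {
    stop("rfu must be strictly positive and finite", call. = FALSE)
  }
  if (!all(rownames(rfu) %in% names(plate_of_sample))) {
    stop("every sample must map to exactly one plate", call. = FALSE)
  }
  structure(list(
    rfu = rfu,
    sample_ids = rownames(rfu),
    aptamer_ids = colnames(rfu),
    plate_of_sample = plate_of_sample[rownames(rfu)],
    cohort = cohort,
    calib_scale = calib_scale,
    median_scale = median_scale,
    replicate_groups = replicate_groups
  ), class = "proteomics_dataset")
}

#' @export
print.proteomics_dataset <- function(x, ...) {
  cat(sprintf("proteomics_dataset '%s': %d samples x %d aptamers, %d plates, %d replicate groups\n",
              x$cohort, nrow(x$rfu), ncol(x$rfu),
              length(unique(x$plate_of_sample)), length(x$replicate_groups)))
  invisible(x)
}

#' Flag aptamers by calibration-vs-median scale-factor discrepancy
#'
#' An aptamer is flagged when the maximum over plates of the absolute
#' difference between its calibration and median scale factors surpasses the
#' threshold (strictly).
#'
#' @param dataset a \code{proteomics_dataset} with both scale-factor matrices.
#' @param threshold flagging threshold on |calibration - median| (default 0.5).
#' @return character vector of flagged aptamer IDs.
#' @export
flag_scale_factor <- function(dataset, threshold = 0.5) {
  cs <- dataset$calib_scale
  ms <- dataset$median_scale
  if (is.null(cs) || is.null(ms)) {
    stop("scale factors missing for dataset '", dataset$cohort, "'", call. = FALSE)
  }
  if (any(is.na(cs)) || any(is.na(ms))) {
    bad <- which(is.na(cs) | is.na(ms), arr.ind = TRUE)[1, ]
    stop("missing scale factor for aptamer ", rownames(cs)[bad[1]],
         " on plate ", colnames(cs)[bad[2]], call. = FALSE)
  }
  max_diff <- apply(abs(cs - ms), 1, max)
  names(max_diff)[max_diff > threshold]
}

#' Flag aptamers with high replicate coefficient of variation
#'
#' Within each technical-replicate group the CV of the raw RFU values is
#' computed per aptamer; an aptamer is flagged when the median CV across
#' groups strictly exceeds the threshold. Groups of fewer than two usable
#' wells are skipped with a warning; if no usable group exists the rule is
#' skipped entirely (with a message) and nothing is flagged.
#'
#' @param dataset a \code{proteomics_dataset}.
#' @param threshold CV threshold (default 0.15).
#' @return character vector of flagged aptamer IDs.
#' @export
flag_high_cv <- function(dataset, threshold = 0.15) {
  groups <- dataset$replicate_groups
  usable <- list()
  for (g in groups) {
    g <- intersect(g, dataset$sample_ids)
    if (length(g) < 2) {
      warning("replicate group of size < 2 skipped", call. = FALSE)
      next
    }
    usable[[length(usable) + 1L]] <- g
  }
  if (length(usable) == 0) {
    message("no usable replicate groups; CV rule skipped")
    return(character(0))
  }
  cvs <- vapply(usable, function(g) {
    sub <- dataset$rfu[g, , drop = FALSE]
    apply(sub, 2, stats::sd) / colMeans(sub)
  }, numeric(length(dataset$aptamer_ids)))
  cvs <- matrix(cvs, nrow = length(dataset$aptamer_ids),
                dimnames = list(dataset$aptamer_ids, NULL))
  med_cv <- apply(cvs, 1, stats::median)
  names(med_cv)[med_cv > threshold]
}

# outlier indicator relative to Tukey fences computed over `x` (a vector):
# TRUE where x < Q1 - k*IQR or x > Q3 + k*IQR (strict, so a zero-IQR vector
# flags nothing).
.iqr_outlier <- function(x, k) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  x < q[1] - k * iqr | x > q[2] + k * iqr
}

#' Flag aptamers that are IQR outliers in most samples
#'
#' For every sample, Tukey fences (\code{k}-fold the interquartile range
#' beyond the quartiles) are computed over that sample's log10 RFU values
#' across aptamers; an aptamer is flagged when it falls outside the fences in
#' strictly more than \code{frac} of samples.
#'
#' @param dataset a \code{proteomics_dataset}.
#' @param k IQR multiplier (default 1.5).
#' @param frac fraction-of-samples threshold (default 0.85, strict).
#' @return character vector of flagged aptamer IDs.
#' @export
flag_iqr_outlier_aptamers <- function(dataset, k = 1.5, frac = 0.85) {
  logm <- log10_rfu(dataset)
  if (ncol(logm) < 4) stop("need at least 4 aptamers per sample", call. = FALSE)
  out <- t(apply(logm, 1, .iqr_outlier, k = k))  # samples x aptamers
  frac_out <- colMeans(out)
  dataset$aptamer_ids[frac_out > frac]
}

#' Flag samples that are IQR outliers in most aptamers
#'
#' Dual of \code{\link{flag_iqr_outlier_aptamers}}: fences per aptamer across
#' samples; a sample is flagged when outside the fences in strictly more than
#' \code{frac} of aptamers.
#'
#' @inheritParams flag_iqr_outlier_aptamers
#' @return character vector of flagged sample IDs.
#' @export
flag_iqr_outlier_samples <- function(dataset, k = 1.5, frac = 0.85) {
  logm <- log10_rfu(dataset)
  if (nrow(logm) < 4) stop("need at least 4 samples per aptamer", call. = FALSE)
  out <- apply(logm, 2, .iqr_outlier, k = k)  # samples x aptamers
  frac_out <- rowMeans(out)
  dataset$sample_ids[frac_out > frac]
}

# drop aptamers / samples from a dataset, keeping annotations in sync
.drop_from_dataset <- function(dataset, aptamers = character(0), samples = character(0)) {
  keep_a <- setdiff(dataset$aptamer_ids, aptamers)
  keep_s <- setdiff(dataset$sample_ids, samples)
  dataset$rfu <- dataset$rfu[keep_s, keep_a, drop = FALSE]
  dataset$sample_ids <- keep_s
  dataset$aptamer_ids <- keep_a
  dataset$plate_of_sample <- dataset$plate_of_sample[keep_s]
  if (!is.null(dataset$calib_scale)) dataset$calib_scale <- dataset$calib_scale[keep_a, , drop = FALSE]
  if (!is.null(dataset$median_scale)) dataset$median_scale <- dataset$median_scale[keep_a, , drop = FALSE]
  dataset$replicate_groups <- lapply(dataset$replicate_groups, intersect, keep_s)
  dataset$replicate_groups <- Filter(function(g) length(g) > 0, dataset$replicate_groups)
  dataset
}

#' Run the full aptamer- and sample-level QC
#'
#' Applies the exclusion rules in order: scale-factor, replicate CV,
#' aptamer-level IQR, non-human analytes, then the sample-level IQR rule on
#' the aptamer-filtered matrix. Each removed item is reported once, with the
#' reason of the first rule that caught it. The procedure is idempotent: a
#' second pass over the surviving matrix removes nothing.
#'
#' @param dataset a \code{proteomics_dataset}.
#' @param nonhuman_ids aptamer IDs targeting non-human proteins (removed
#'   unconditionally).
#' @param sf_threshold,cv_threshold,iqr_k,iqr_frac rule parameters, see the
#'   individual \code{flag_*} functions.
#' @return list with \code{dataset} (filtered) and \code{report} (a
#'   \code{qc_report}: removed aptamers/samples with reason codes, per-rule
#'   counts, surviving dimensions).
#' @export
run_qc <- function(dataset, nonhuman_ids = character(0),
                   sf_threshold = 0.5, cv_threshold = 0.15,
                   iqr_k = 1.5, iqr_frac = 0.85) {
  removed_aptamers <- data.frame(aptamer_id = character(0), reason = character(0),
                                 stringsAsFactors = FALSE)
  add_apt <- function(ids, reason) {
    ids <- setdiff(ids, removed_aptamers$aptamer_id)
    if (length(ids) > 0) {
      removed_aptamers <<- rbind(removed_aptamers,
                                 data.frame(aptamer_id = ids, reason = reason,
                                            stringsAsFactors = FALSE))
    }
    ids
  }

  ds <- dataset
  if (!is.null(ds$calib_scale) && !is.null(ds$median_scale)) {
    ds <- .drop_from_dataset(ds, aptamers = add_apt(flag_scale_factor(ds, sf_threshold), "SCALE_FACTOR"))
  }
  if (length(ds$replicate_groups) > 0) {
    ds <- .drop_from_dataset(ds, aptamers = add_apt(flag_high_cv(ds, cv_threshold), "CV"))
  }
  ds <- .drop_from_dataset(ds, aptamers = add_apt(flag_iqr_outlier_aptamers(ds, iqr_k, iqr_frac), "IQR_OUTLIER"))
  ds <- .drop_from_dataset(ds, aptamers = add_apt(intersect(nonhuman_ids, ds$aptamer_ids), "NONHUMAN"))

  bad_samples <- flag_iqr_outlier_samples(ds, iqr_k, iqr_frac)
  removed_samples <- data.frame(sample_id = bad_samples,
                                reason = rep("IQR_OUTLIER", length(bad_samples)),
                                stringsAsFactors = FALSE)
  ds <- .drop_from_dataset(ds, samples = bad_samples)

  if (length(ds$aptamer_ids) == 0 || length(ds$sample_ids) == 0) {
    stop("QC removed every aptamer or sample; nothing survives", call. = FALSE)
  }

  report <- structure(list(
    removed_aptamers = removed_aptamers,
    removed_samples = removed_samples,
    counts = c(table(factor(removed_aptamers$reason,
                            levels = c("SCALE_FACTOR", "CV", "IQR_OUTLIER", "NONHUMAN"))),
               SAMPLE_IQR_OUTLIER = nrow(removed_samples)),
    surviving = c(n_samples = length(ds$sample_ids), n_aptamers = length(ds$aptamer_ids)),
    input = c(n_samples = length(dataset$sample_ids), n_aptamers = length(dataset$aptamer_ids))
  ), class = "qc_report")

  list(dataset = ds, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$input["n_samples"], "x", x$input["n_aptamers"], "->",
      x$surviving["n_samples"], "x", x$surviving["n_aptamers"], "\n")
  print(x$counts)
  invisible(x)
}
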