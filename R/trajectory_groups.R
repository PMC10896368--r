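TRAJECTORY_GROUPS <- c(G1 = "linear_up", G2 = "up_down",
                       G3 = "linear_down", G4 = "down_up")

#' Classify one protein's pseudo-trajectory across the AD continuum
#'
#' Maps the sign pattern of the two adjacent-stage effect estimates
#' (beta1: controls vs asymptomatic, beta2: asymptomatic vs full biomarker
#' positive) to the four trajectory groups — G1 linear-up (+,+), G2 up-down
#' (+,-), G3 linear-down (-,-), G4 down-up (-,+) — requiring both pairwise
#' p-values below \code{alpha}. Anything else (including an exactly-zero
#' estimate with a significant p, which is flagged with a warning) is
#' \code{"unclassified"}.
#'
#' @param beta1,p1 estimate and p-value of the A-T- vs A+T- comparison
#'   (case = A+T-).
#' @param beta2,p2 estimate and p-value of the A+T- vs A+T+ comparison
#'   (case = A+T+).
#' @param alpha per-comparison significance level (default 0.05).
#' @return one of \code{"G1"}, \code{"G2"}, \code{"G3"}, \code{"G4"},
#'   \code{"unclassified"}.
#' @export
classify_trajectory <- function(beta1, p1, beta2, p2, alpha = 0.05) {
  if (!(p1 < alpha && p2 < alpha)) return("unclassified")
  if (beta1 == 0 || beta2 == 0) {
    warning("estimate exactly 0 with p < alpha; unclassified", call. = FALSE)
    return("unclassified")
  }
  if (beta1 > 0 && beta2 > 0) "G1"
  else if (beta1 > 0 && beta2 < 0) "G2"
  else if (beta1 < 0 && beta2 < 0) "G3"
  else "G4"
}

#' Pseudo-trajectory grouping of significant proteins
#'
#' Runs the three pairwise differential-abundance comparisons across the AD
#' continuum (A-T- vs A+T-, A+T- vs A+T+, A-T- vs A+T+) and classifies every
#' supplied survivor aptamer (typically the Bonferroni-significant set from
#' the three-stage meta-analysis) into the four trajectory groups.
#'
#' @param dataset a QC-passed \code{proteomics_dataset}.
#' @param records sample metadata with filled \code{at_status}; all three AT
#'   groups must be non-empty.
#' @param survivors aptamer IDs to classify.
#' @param alpha pairwise significance level (default 0.05).
#' @param n_sv surrogate variables per pairwise DAA (default 2).
#' @return list with \code{calls} (data frame: aptamer_id, beta/p for the
#'   three comparisons, group) and \code{counts} (named group counts).
#' @export
run_trajectories <- function(dataset, records, survivors, alpha = 0.05, n_sv = 2L) {
  present <- AT_LEVELS %in% records$at_status[records$sample_id %in% dataset$sample_ids]
  if (!all(present)) {
    stop("empty AT group(s): ", paste(AT_LEVELS[!present], collapse = ", "), call. = FALSE)
  }
  survivors <- intersect(survivors, dataset$aptamer_ids)

  d1 <- run_daa(dataset, records, group_case = "A+T-", group_control = "A-T-", n_sv = n_sv)
  d2 <- run_daa(dataset, records, group_case = "A+T+", group_control = "A+T-", n_sv = n_sv)
  d3 <- run_daa(dataset, records, group_case = "A+T+", group_control = "A-T-", n_sv = n_sv)

  i1 <- match(survivors, d1$aptamer_id)
  i2 <- match(survivors, d2$aptamer_id)
  i3 <- match(survivors, d3$aptamer_id)
  calls <- data.frame(
    aptamer_id = survivors,
    beta1 = d1$estimate[i1], p1 = d1$p[i1],
    beta2 = d2$estimate[i2], p2 = d2$p[i2],
    beta3 = d3$estimate[i3], p3 = d3$p[i3],
    stringsAsFactors = FALSE
  )
  calls$group <- vapply(seq_len(nrow(calls)), function(i) {
    classify_trajectory(calls$beta1[i], calls$p1[i], calls$beta2[i], calls$p2[i], alpha)
  }, character(1))
  counts <- table(factor(calls$group, levels = c(names(TRAJECTORY_GROUPS), "unclassified")))
  list(calls = calls, counts = counts)
}
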