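#' Combine p-values by Stouffer's Z method
#'
#' Each two-sided p-value is converted to a signed standard-normal quantile,
#' \code{z_i = qnorm(1 - p_i/2) * sign_i}, the z-scores are summed and divided
#' by \code{sqrt(k)}, and the combined two-sided p-value is the tail
#' probability of the combined z. Stouffer's method requires consistently
#' small p-values to yield a small combined p-value, so it is robust to a
#' single spuriously small input.
#'
#' @param p_values numeric p-values in (0, 1]; exact zeros are clamped to the
#'   smallest positive double with a warning.
#' @param directions effect-direction signs (+1/-1), one per p-value; mixed
#'   signs are an error (direction consistency is enforced upstream).
#' @return list with \code{z_combined} and \code{p_combined}.
#' @export
stouffer_combine <- function(p_values, directions) {
  if (length(p_values) != length(directions) || length(p_values) < 1) {
    stop("p_values and directions must have equal length >= 1", call. = FALSE)
  }
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  if (any(p_values == 0)) {
    warning("p-value of 0 clamped to smallest positive double", call. = FALSE)
    p_values[p_values == 0] <- .Machine$double.xmin
  }
  s <- sign(directions)
  if (any(s == 0)) stop("directions must be nonzero", call. = FALSE)
  if (length(unique(s)) > 1) stop("mixed effect directions; combine only consistent results", call. = FALSE)
  z <- stats::qnorm(p_values / 2, lower.tail = FALSE) * s
  z_combined <- sum(z) / sqrt(length(z))
  p_combined <- 2 * stats::pnorm(abs(z_combined), lower.tail = FALSE)
  list(z_combined = z_combined, p_combined = p_combined)
}

#' Three-stage discovery / replication / meta-analysis
#'
#' Implements the staged gating design: aptamers passing FDR < \code{alpha}
#' in stage 1 (discovery) are carried to stage 2 (replication), where FDR is
#' recomputed over only the stage-1 survivors (they are the only analytes
#' further tested); survivors with a direction-consistent estimate are
#' meta-analyzed by Stouffer's Z, and a stringent Bonferroni correction is
#' applied over the meta-analyzed set.
#'
#' @param stage1,stage2 \code{daa_result} tables for the same comparison,
#'   indexed by \code{aptamer_id} (stage 2 must cover the stage-1 analytes).
#' @param alpha FDR/Bonferroni significance level (default 0.05).
#' @return data frame of class \code{meta_result}, one row per aptamer tested
#'   in stage 1, with stage estimates and p-values, the conditional stage-2
#'   FDR, direction consistency, combined z / p / Bonferroni, and the gate
#'   flags \code{passes_stage1_fdr}, \code{passes_stage2_fdr},
#'   \code{passes_bonf}.
#' @export
run_three_stage <- function(stage1, stage2, alpha = 0.05) {
  m <- merge(
    data.frame(aptamer_id = stage1$aptamer_id, est1 = stage1$estimate,
               p1 = stage1$p, fdr1 = stage1$fdr, stringsAsFactors = FALSE),
    data.frame(aptamer_id = stage2$aptamer_id, est2 = stage2$estimate,
               p2 = stage2$p, stringsAsFactors = FALSE),
    by = "aptamer_id", all.x = TRUE
  )
  m <- m[order(m$aptamer_id), , drop = FALSE]
  rownames(m) <- NULL

  m$passes_stage1_fdr <- m$fdr1 < alpha
  if (!any(m$passes_stage1_fdr)) {
    warning("no stage-1 survivors at FDR < ", alpha, call. = FALSE)
  }

  # stage-2 FDR conditional on stage-1 survival
  m$fdr2 <- NA_real_
  surv1 <- which(m$passes_stage1_fdr & !is.na(m$p2))
  m$fdr2[surv1] <- bh_fdr(m$p2[surv1])
  m$passes_stage2_fdr <- !is.na(m$fdr2) & m$fdr2 < alpha

  m$direction_consistent <- !is.na(m$est2) & sign(m$est1) == sign(m$est2) &
    m$est1 != 0 & m$est2 != 0

  meta_idx <- which(m$passes_stage2_fdr & m$direction_consistent)
  m$z_combined <- NA_real_; m$p_combined <- NA_real_
  for (i in meta_idx) {
    sc <- stouffer_combine(c(m$p1[i], m$p2[i]), rep(sign(m$est1[i]), 2))
    m$z_combined[i] <- sc$z_combined
    m$p_combined[i] <- sc$p_combined
  }
  m$bonf_combined <- NA_real_
  m$bonf_combined[meta_idx] <- pmin(1, m$p_combined[meta_idx] * length(meta_idx))
  m$passes_bonf <- !is.na(m$bonf_combined) & m$bonf_combined < alpha

  class(m) <- c("meta_result", "data.frame")
  attr(m, "alpha") <- alpha
  m
}

#' Cross-platform concordance of a meta-analysis with an external study
#'
#' Pearson correlation of effect estimates and of signed -log10 p-values
#' between the meta-analyzed aptamers and an external differential-abundance
#' table from another platform, over the shared analytes. The meta effect
#' size is the mean of the stage-1 and stage-2 estimates; the signed -log10 p
#' carries the direction of the estimate so that the correlation respects
#' direction, not only magnitude.
#'
#' @param meta a \code{meta_result} table.
#' @param external a \code{daa_result} table from the external study.
#' @return list with \code{r_estimates}, \code{r_log10p}, \code{n_shared}.
#' @export
cross_platform_concordance <- function(meta, external) {
  analyzed <- meta[!is.na(meta$p_combined), , drop = FALSE]
  shared <- intersect(analyzed$aptamer_id, external$aptamer_id)
  if (length(shared) < 3) stop("need at least 3 shared aptamers", call. = FALSE)
  a <- analyzed[match(shared, analyzed$aptamer_id), ]
  b <- external[match(shared, external$aptamer_id), ]
  est_meta <- (a$est1 + a$est2) / 2
  slp <- function(p, est) -log10(pmax(p, .Machine$double.xmin)) * sign(est)
  list(
    r_estimates = stats::cor(est_meta, b$estimate),
    r_log10p = stats::cor(slp(a$p_combined, est_meta), slp(b$p, b$estimate)),
    n_shared = length(shared)
  )
}
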