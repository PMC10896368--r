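#' Estimate surrogate variables from expression residuals
#'
#' Residualizes each aptamer's log10 values on the known covariates (age, sex,
#' plate) and takes the first \code{n_sv} left singular vectors of the
#' residual matrix as surrogate variables — latent covariates absorbing
#' unmodeled technical and biological variation. Each surrogate is unit-norm
#' with a deterministic sign (first nonzero loading positive).
#'
#' @param log_matrix samples-by-aptamers matrix of log10 RFU values.
#' @param covariates data frame aligned with the rows of \code{log_matrix};
#'   all its columns enter the residualizing design (factors are expanded).
#' @param n_sv number of surrogate variables (default 2).
#' @param seed integer seed (default 2022); the decomposition is
#'   deterministic, the seed is fixed for interface stability.
#' @return samples-by-\code{n_sv} matrix (0 columns when \code{n_sv = 0}).
#' @export
estimate_surrogates <- function(log_matrix, covariates, n_sv = 2L, seed = 2022L) {
  if (n_sv < 0) stop("n_sv must be >= 0", call. = FALSE)
  if (n_sv == 0) {
    return(matrix(numeric(0), nrow = nrow(log_matrix), ncol = 0))
  }
  set.seed(seed)
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("covariates are not full rank", call. = FALSE)
  resid <- qr.resid(qx, log_matrix)
  max_rank <- min(dim(resid)) - 0L
  if (n_sv >= max_rank) {
    stop("n_sv must be smaller than the rank of the residual matrix", call. = FALSE)
  }
  sv <- svd(resid, nu = n_sv, nv = 0)$u
  for (j in seq_len(ncol(sv))) {
    nz <- which(abs(sv[, j]) > 1e-8)[1]
    if (!is.na(nz) && sv[nz, j] < 0) sv[, j] <- -sv[, j]
  }
  colnames(sv) <- paste0("SV", seq_len(ncol(sv)))
  sv
}

# Build the fixed-covariate design pieces shared by run_daa: Status + age +
# sex + plate one-hot (reference = first plate lexicographically). Columns
# that are constant in the analyzed subset (e.g. a single plate) are dropped.
.daa_design <- function(status, age, sex, plate, sv) {
  cols <- list("(Intercept)" = rep(1, length(status)), Status = status, age = age)
  if (length(unique(sex)) > 1) cols$sexM <- as.numeric(sex == "M")
  plate_levels <- sort(unique(plate))
  for (pl in plate_levels[-1]) {
    cols[[paste0("plate", pl)]] <- as.numeric(plate == pl)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (!is.null(sv) && ncol(sv) > 0) X <- cbind(X, sv)
  X
}

#' Per-aptamer differential abundance between two AT groups
#'
#' Ordinary least squares of log10 RFU on disease Status (case = 1,
#' control = 0) adjusted for age, sex, plate (one-hot, first plate as
#' reference) and \code{n_sv} surrogate variables estimated from the residual
#' matrix of the analyzed subset. Two-sided p-values come from the Status
#' t-statistic; Benjamini-Hochberg FDR and Bonferroni corrections are applied
#' across all tested aptamers. Aptamers with zero variance in the analyzed
#' subset are reported with estimate 0 and p = 1, flagged in
#' \code{zero_variance}.
#'
#' @param dataset a QC-passed \code{proteomics_dataset}.
#' @param records sample metadata with filled \code{at_status}, covering (a
#'   subset of) the dataset's samples.
#' @param group_case,group_control AT labels, e.g. \code{"A+T+"} vs
#'   \code{"A-T-"}.
#' @param n_sv number of surrogate variables (default 2).
#' @param sv_seed seed forwarded to \code{\link{estimate_surrogates}}.
#' @return data frame of class \code{daa_result}: \code{aptamer_id},
#'   \code{estimate} (log10 units), \code{se}, \code{t}, \code{p}, \code{fdr},
#'   \code{bonf}, \code{n_used}, \code{zero_variance}, \code{comparison}.
#' @export
run_daa <- function(dataset, records, group_case, group_control,
                    n_sv = 2L, sv_seed = 2022L) {
  stopifnot(inherits(dataset, "proteomics_dataset"))
  rec <- records[records$at_status %in% c(group_case, group_control), , drop = FALSE]
  rec <- rec[rec$sample_id %in% dataset$sample_ids, , drop = FALSE]
  n_case <- sum(rec$at_status == group_case)
  n_ctrl <- sum(rec$at_status == group_control)
  if (n_case == 0 || n_ctrl == 0) {
    stop("both AT groups must be non-empty after filtering", call. = FALSE)
  }
  Y <- log10(dataset$rfu[rec$sample_id, , drop = FALSE])
  status <- as.numeric(rec$at_status == group_case)

  sv <- if (n_sv > 0) {
    # Status is included in the residualizing design so that the surrogates
    # capture unmodeled variation orthogonal to the effect of interest (the
    # behaviour of the sva family of estimators); otherwise the leading
    # singular vector simply reconstructs the case/control contrast and
    # absorbs the signal.
    covs <- data.frame(status = status, age = rec$age, sex = rec$sex, plate = rec$plate)
    covs <- covs[, vapply(covs, function(c) length(unique(c)) > 1, logical(1)), drop = FALSE]
    estimate_surrogates(Y, covs, n_sv = n_sv, seed = sv_seed)
  } else NULL

  X <- .daa_design(status, rec$age, rec$sex, rec$plate, sv)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("singular design; collinear columns: ", paste(dropped, collapse = ", "),
         call. = FALSE)
  }
  df <- nrow(X) - ncol(X)
  coefs <- qr.coef(qx, Y)
  resid <- qr.resid(qx, Y)
  sigma2 <- colSums(resid^2) / df
  v_status <- chol2inv(chol(crossprod(X)))[2, 2]  # Status is column 2

  estimate <- coefs["Status", ]
  se <- sqrt(sigma2 * v_status)
  tstat <- estimate / se
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)

  zero_var <- apply(Y, 2, function(col) stats::var(col) == 0)
  estimate[zero_var] <- 0; se[zero_var] <- NA_real_
  tstat[zero_var] <- 0; p[zero_var] <- 1

  out <- data.frame(
    aptamer_id = dataset$aptamer_ids,
    estimate = unname(estimate),
    se = unname(se),
    t = unname(tstat),
    p = unname(p),
    fdr = unname(bh_fdr(p)),
    bonf = unname(bonferroni(p)),
    n_used = nrow(rec),
    zero_variance = unname(zero_var),
    comparison = paste(group_case, "vs", group_control),
    stringsAsFactors = FALSE
  )
  class(out) <- c("daa_result", "data.frame")
  attr(out, "comparison") <- c(case = group_case, control = group_control)
  out
}
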