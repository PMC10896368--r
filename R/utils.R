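#' @keywords internal
"_PACKAGE"

# Canonical ordering of the three analyzed biomarker groups along the disease
# continuum. The A-T+ pattern is never analyzed (and never simulated).
AT_LEVELS <- c("A-T-", "A+T-", "A+T+")

#' Check that a scalar is a finite number
#' @noRd
check_finite_scalar <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("field '", field, "' must be a single finite number", call. = FALSE)
  }
  invisible(x)
}

#' @noRd
check_finite_vec <- function(x, field) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x))) {
    stop("field '", field, "' must be finite numeric", call. = FALSE)
  }
  invisible(x)
}

# log10 of the RFU matrix; kept as a helper so the transform is applied in
# exactly one place.
log10_rfu <- function(dataset) log10(dataset$rfu)

#' Benjamini-Hochberg and Bonferroni wrappers (named for readability at call
#' sites; both delegate to stats::p.adjust).
#' @noRd
bh_fdr <- function(p) stats::p.adjust(p, method = "BH")

#' @noRd
bonferroni <- function(p) stats::p.adjust(p, method = "bonferroni")
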