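#' Dementia progression-rate model (CDR-SB slope)
#'
#' Fits a single pooled linear model over all longitudinal visits, regressing
#' CDR-SB on time in years with age, sex, predicted signature status, known
#' AT status and the initial CDR-SB as covariates, plus interaction terms
#' between time and predicted status and between age and predicted status.
#' The time-by-predicted-status coefficient is the headline output: the extra
#' CDR-SB points per year accrued by signature-positive individuals.
#'
#' Repeated measures per individual violate the independence assumption of
#' the pooled model; set \code{robust = TRUE} for cluster-robust (CR1,
#' clustered by individual) standard errors.
#'
#' @param visits longitudinal data frame: \code{sample_id}, \code{years}
#'   (from CSF draw), \code{cdr_sb}.
#' @param samples per-individual data frame: \code{sample_id}, \code{age},
#'   \code{sex}, \code{at_status}, \code{predicted_status} (logical or 0/1).
#' @param robust use cluster-robust standard errors (default FALSE, matching
#'   a plain pooled fit).
#' @return object of class \code{progression_fit}: \code{coefficients} data
#'   frame (term, estimate, se, p), \code{interaction} (the
#'   time-by-predicted-status row), \code{n_individuals},
#'   \code{n_observations}.
#' @export
fit_progression <- function(visits, samples, robust = FALSE) {
  d <- merge(visits, samples, by = "sample_id")
  d$predicted_status <- as.numeric(d$predicted_status)
  first <- d[order(d$sample_id, d$years), ]
  initial <- first[!duplicated(first$sample_id), c("sample_id", "cdr_sb")]
  names(initial)[2] <- "initial_cdr"
  d <- merge(d, initial, by = "sample_id")

  visits_per_id <- table(d$sample_id)
  enough <- names(visits_per_id)[visits_per_id >= 2]
  ok <- unique(d[d$sample_id %in% enough, c("sample_id", "predicted_status")])
  counts <- table(factor(ok$predicted_status, levels = c(0, 1)))
  if (any(counts < 10)) {
    stop("need >= 2 visits for >= 10 individuals in each predicted-status group",
         call. = FALSE)
  }

  form <- cdr_sb ~ years + predicted_status + years:predicted_status +
    age + age:predicted_status + sex + at_status + initial_cdr
  fit <- stats::lm(form, data = d)
  if (any(is.na(stats::coef(fit)))) {
    stop("singular design; collinear columns: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "),
         call. = FALSE)
  }

  cs <- summary(fit)$coefficients
  est <- cs[, "Estimate"]
  if (robust) {
    # CR1 cluster sandwich, clustered on individual
    X <- stats::model.matrix(fit)
    u <- stats::resid(fit)
    XtXinv <- chol2inv(chol(crossprod(X)))
    cl <- split(seq_len(nrow(X)), d$sample_id)
    meat <- Reduce(`+`, lapply(cl, function(i) {
      g <- crossprod(X[i, , drop = FALSE], u[i])
      tcrossprod(g)
    }))
    g_n <- length(cl)
    adj <- g_n / (g_n - 1) * (nrow(X) - 1) / (nrow(X) - ncol(X))
    V <- adj * XtXinv %*% meat %*% XtXinv
    se <- sqrt(diag(V))
    p <- 2 * stats::pt(abs(est / se), df = g_n - 1, lower.tail = FALSE)
  } else {
    se <- cs[, "Std. Error"]
    p <- cs[, "Pr(>|t|)"]
  }

  coef_df <- data.frame(term = rownames(cs), estimate = unname(est),
                        se = unname(se), p = unname(p),
                        stringsAsFactors = FALSE)
  structure(list(
    coefficients = coef_df,
    interaction = coef_df[coef_df$term == "years:predicted_status", ],
    n_individuals = length(unique(d$sample_id)),
    n_observations = nrow(d),
    robust = robust
  ), class = "progression_fit")
}

#' @export
print.progression_fit <- function(x, ...) {
  cat(sprintf("progression_fit: %d individuals, %d visits%s\n", x$n_individuals,
              x$n_observations, if (x$robust) " (cluster-robust SE)" else ""))
  cat(sprintf("time x predicted-status: beta = %.3f (se %.3f, p = %.3g)\n",
              x$interaction$estimate, x$interaction$se, x$interaction$p))
  invisible(x)
}

#' Kaplan-Meier time-to-conversion curves with log-rank test
#'
#' Product-limit survival estimates per group (probability of not yet having
#' converted to AD) with Greenwood pointwise 95% confidence intervals, plus
#' the two-group (or k-group) log-rank statistic and p-value. With no events
#' at all, the curves are constant 1 and the log-rank test is reported as NA.
#'
#' @param time follow-up years to conversion or censoring.
#' @param event logical/0-1: TRUE when the individual converted.
#' @param group group label per individual (e.g. predicted signature status).
#' @param conf_type confidence-interval transform passed to
#'   \code{survival::survfit} (\code{"log"} default).
#' @return object of class \code{km_result}: \code{curves} data frame (group,
#'   time, n_risk, n_event, surv, lower, upper), \code{logrank_chisq},
#'   \code{logrank_df}, \code{logrank_p}.
#' @export
km_curve <- function(time, event, group, conf_type = "log") {
  event <- as.integer(as.logical(event))
  group <- as.character(group)
  sf <- survival::survfit(survival::Surv(time, event) ~ group,
                          conf.type = conf_type)
  if (is.null(sf$strata)) {
    grp <- rep(unique(group), length(sf$time))
  } else {
    grp <- rep(sub("^group=", "", names(sf$strata)), sf$strata)
  }
  curves <- data.frame(group = grp, time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, surv = sf$surv,
                       lower = sf$lower, upper = sf$upper,
                       stringsAsFactors = FALSE)

  if (sum(event) == 0 || length(unique(group)) < 2) {
    lr_chisq <- NA_real_; lr_df <- NA_integer_; lr_p <- NA_real_
  } else {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    lr_chisq <- sd$chisq
    lr_df <- length(sd$n) - 1L
    lr_p <- stats::pchisq(sd$chisq, df = lr_df, lower.tail = FALSE)
  }
  structure(list(curves = curves, logrank_chisq = lr_chisq,
                 logrank_df = lr_df, logrank_p = lr_p),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("km_result: %d groups, log-rank chisq = %s (p = %s)\n",
              length(unique(x$curves$group)),
              format(x$logrank_chisq, digits = 4), format(x$logrank_p, digits = 3)))
  invisible(x)
}
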