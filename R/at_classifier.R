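#' Fit a two-component Gaussian mixture cut-point for a CSF biomarker
#'
#' Dichotomizes a quantitative biomarker (CSF A-beta-42 or pTau181) by
#' expectation-maximization of a two-component univariate Gaussian mixture.
#' The cut-point is the value between the two component means at which the
#' posterior membership probabilities are equal (not the midpoint of the
#' means, so unequal variances and weights are respected).
#'
#' @param values positive biomarker values (assay units), length >= 20.
#' @param direction \code{"low-is-positive"} (A-beta-42: amyloid-positive
#'   individuals have LOW CSF levels) or \code{"high-is-positive"} (pTau).
#' @param seed integer; kept for interface stability — the fit is initialized
#'   deterministically from the data (median split) so the result depends only
#'   on the data.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return object of class \code{mixture_cut}: component \code{means},
#'   \code{sds}, \code{weights} (ordered low mean first), \code{threshold}
#'   and \code{direction}.
#' @export
fit_mixture_cut <- function(values, direction = c("low-is-positive", "high-is-positive"),
                            seed = 1L, max_iter = 500L, tol = 1e-8) {
  direction <- match.arg(direction)
  values <- as.numeric(values)
  if (length(values) < 20) stop("need at least 20 values to fit a mixture", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  s_all <- stats::sd(values)
  if (s_all == 0) stop("degenerate mixture fit: all values equal; supply a fallback threshold", call. = FALSE)
  set.seed(seed)

  # deterministic initialization: split at the median
  med <- stats::median(values)
  lo <- values[values <= med]; hi <- values[values > med]
  mu <- c(mean(lo), mean(hi))
  sd2 <- c(max(stats::sd(lo), s_all / 20), max(stats::sd(hi), s_all / 20))
  w <- c(0.5, 0.5)

  loglik <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(values, mu[1], sd2[1])
    d2 <- w[2] * stats::dnorm(values, mu[2], sd2[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d1 / tot
    new_loglik <- sum(log(tot))
    w <- c(mean(r), mean(1 - r))
    if (min(w) < 1e-6) break
    mu <- c(sum(r * values) / sum(r), sum((1 - r) * values) / sum(1 - r))
    sd2 <- c(sqrt(sum(r * (values - mu[1])^2) / sum(r)),
             sqrt(sum((1 - r) * (values - mu[2])^2) / sum(1 - r)))
    sd2 <- pmax(sd2, s_all * 1e-8)
    if (is.finite(loglik) && abs(new_loglik - loglik) < tol) break
    loglik <- new_loglik
  }

  if (min(w) < 0.01 || min(sd2) <= s_all * 1e-6 || abs(mu[1] - mu[2]) < s_all * 1e-6) {
    stop("degenerate mixture fit (component collapse); consider a fixed fallback threshold",
         call. = FALSE)
  }
  ord <- order(mu)
  mu <- mu[ord]; sd2 <- sd2[ord]; w <- w[ord]

  # equal-posterior crossing between the means
  post_diff <- function(x) {
    log(w[1]) + stats::dnorm(x, mu[1], sd2[1], log = TRUE) -
      log(w[2]) - stats::dnorm(x, mu[2], sd2[2], log = TRUE)
  }
  eps <- (mu[2] - mu[1]) * 1e-6
  if (post_diff(mu[1] + eps) <= 0 || post_diff(mu[2] - eps) >= 0) {
    stop("degenerate mixture fit: no posterior crossing between component means; ",
         "consider a fixed fallback threshold", call. = FALSE)
  }
  threshold <- stats::uniroot(post_diff, c(mu[1] + eps, mu[2] - eps), tol = s_all * 1e-10)$root

  structure(list(means = mu, sds = sd2, weights = w,
                 threshold = threshold, direction = direction),
            class = "mixture_cut")
}

#' @export
print.mixture_cut <- function(x, ...) {
  cat(sprintf("mixture_cut (%s): means %.3g / %.3g, threshold %.4g\n",
              x$direction, x$means[1], x$means[2], x$threshold))
  invisible(x)
}

#' Assign AT biomarker groups from fitted mixture cuts
#'
#' A sample is amyloid-positive (A+) when its CSF A-beta-42 is strictly below
#' the A-beta-42 threshold, and tau-positive (T+) when its pTau is strictly
#' above the pTau threshold. A+T+ samples are biomarker-defined cases, A-T-
#' biomarker-negative controls, A+T- the asymptomatic intermediate stage. The
#' A-T+ pattern, which is never analyzed, is set to \code{"excluded"}, as are
#' samples with a missing biomarker.
#'
#' @param records sample metadata data frame with \code{abeta42} and
#'   \code{ptau} columns.
#' @param abeta_cut,ptau_cut \code{mixture_cut} objects fitted on the same
#'   cohort (A-beta-42 must use \code{low-is-positive}, pTau
#'   \code{high-is-positive}).
#' @param quiet suppress the per-group count message.
#' @return \code{records} with the \code{at_status} column filled in.
#' @export
assign_at <- function(records, abeta_cut, ptau_cut, quiet = FALSE) {
  stopifnot(inherits(abeta_cut, "mixture_cut"), inherits(ptau_cut, "mixture_cut"))
  if (abeta_cut$direction != "low-is-positive" || ptau_cut$direction != "high-is-positive") {
    stop("abeta cut must be low-is-positive and ptau cut high-is-positive", call. = FALSE)
  }
  a_pos <- records$abeta42 < abeta_cut$threshold
  t_pos <- records$ptau > ptau_cut$threshold
  status <- ifelse(is.na(a_pos) | is.na(t_pos), "excluded",
            ifelse(a_pos & t_pos, "A+T+",
            ifelse(a_pos & !t_pos, "A+T-",
            ifelse(!a_pos & !t_pos, "A-T-", "excluded"))))
  records$at_status <- status
  if (!quiet) {
    counts <- table(factor(status, levels = c(AT_LEVELS, "excluded")))
    message(sprintf("AT assignment (%s): %s",
                    paste(unique(records$cohort), collapse = ","),
                    paste(names(counts), counts, sep = "=", collapse = ", ")))
  }
  records
}
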