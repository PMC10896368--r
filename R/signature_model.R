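#' Stratified train/test split
#'
#' Splits sample IDs into disjoint train and test sets, stratified by AT
#' status; within each stratum \code{floor(fraction_train * n)} samples go to
#' training. Deterministic given the seed.
#'
#' @param records sample metadata with \code{sample_id} and \code{at_status}.
#' @param fraction_train fraction in (0, 1) (default 0.7).
#' @param seed integer seed.
#' @return list with \code{train} and \code{test} sample-ID vectors.
#' @export
split_train_test <- function(records, fraction_train = 0.7, seed = 1L) {
  if (fraction_train <= 0 || fraction_train >= 1) {
    stop("fraction_train must lie in (0, 1)", call. = FALSE)
  }
  set.seed(seed)
  train <- character(0)
  for (stratum in unique(records$at_status)) {
    ids <- records$sample_id[records$at_status == stratum]
    if (length(ids) < 2) stop("stratum '", stratum, "' has fewer than 2 samples", call. = FALSE)
    n_tr <- floor(fraction_train * length(ids))
    train <- c(train, sample(ids, n_tr))
  }
  list(train = sort(train), test = sort(setdiff(records$sample_id, train)))
}

#' Lasso selection of informative proteins
#'
#' L1-penalized logistic regression over a descending penalty grid with
#' k-fold cross-validation; the penalty maximizing the mean cross-validated
#' AUC is chosen and the proteins with nonzero coefficients at that penalty
#' are returned. The input matrix is expected to be standardized per protein
#' on the training data.
#'
#' @param x standardized samples-by-proteins training matrix.
#' @param y binary labels (1 = case).
#' @param n_folds number of CV folds (default 5).
#' @param seed integer seed controlling fold assignment.
#' @return list: \code{proteins} (selected, by decreasing |coefficient|),
#'   \code{coefficients} (penalized, named), \code{lambda} (chosen penalty),
#'   \code{cv_auc} (mean CV AUC at the chosen penalty).
#' @export
lasso_select <- function(x, y, n_folds = 5L, seed = 1L) {
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(n_folds), length(y)))
  fit <- glmnet::cv.glmnet(x, y, family = "binomial", type.measure = "auc",
                           foldid = foldid, standardize = FALSE)
  beta <- as.matrix(stats::coef(fit, s = "lambda.min"))[, 1]
  beta <- beta[setdiff(names(beta), "(Intercept)")]
  nz <- beta[beta != 0]
  if (length(nz) == 0) {
    stop("lasso selected no proteins at any penalty; consider weaker penalties",
         call. = FALSE)
  }
  nz <- nz[order(-abs(nz))]
  list(proteins = names(nz), coefficients = nz,
       lambda = fit$lambda.min, cv_auc = max(fit$cvm))
}

#' Greedy pruning of highly correlated proteins
#'
#' Walks the selected proteins in order of ascending priority p-value
#' (typically the meta-analysis p) and keeps a protein only if its absolute
#' Pearson correlation with every already-kept protein is at or below the
#' threshold, so no remaining pair exceeds it.
#'
#' @param selected protein IDs.
#' @param train_matrix samples-by-proteins abundance matrix covering
#'   \code{selected}.
#' @param r_threshold absolute-correlation threshold (default 0.8, strict).
#' @param priority_p optional named p-values used to order the greedy pass
#'   (ascending); unnamed/missing proteins keep the input order after the
#'   named ones.
#' @return pruned protein-ID vector (in greedy order).
#' @export
prune_correlated <- function(selected, train_matrix, r_threshold = 0.8,
                             priority_p = NULL) {
  if (length(selected) < 1) stop("selected set must be non-empty", call. = FALSE)
  if (length(selected) == 1) return(selected)
  if (!is.null(priority_p)) {
    pr <- priority_p[selected]
    pr[is.na(pr)] <- Inf
    selected <- selected[order(pr)]
  }
  r <- abs(stats::cor(train_matrix[, selected, drop = FALSE]))
  kept <- character(0)
  for (prot in selected) {
    if (all(r[prot, kept] <= r_threshold)) kept <- c(kept, prot)
  }
  kept
}

#' Restrict a protein set to those measured on another platform
#'
#' @param proteins protein IDs (order preserved).
#' @param platform_proteins proteins available on the target platform.
#' @return the intersection, in the order of \code{proteins}.
#' @export
restrict_to_platform <- function(proteins, platform_proteins) {
  if (length(platform_proteins) == 0) stop("platform list must be non-empty", call. = FALSE)
  out <- proteins[proteins %in% platform_proteins]
  if (length(out) == 0) stop("no proteins overlap the target platform", call. = FALSE)
  out
}

#' Freeze a sparse protein signature
#'
#' Fits an unpenalized multivariate logistic model on the restricted protein
#' set (standardized on the training data), drops proteins whose two-sided
#' coefficient p-value is at or above \code{alpha}, refits on the survivors,
#' and freezes the panel together with the standardization parameters and a
#' Youden-optimal probability cutoff derived from the training scores.
#'
#' @param proteins restricted candidate protein IDs.
#' @param train_matrix samples-by-proteins raw (log10) abundance matrix.
#' @param labels binary labels (1 = case).
#' @param alpha coefficient significance level (default 0.05).
#' @param ridge_fallback if TRUE, a complete-separation failure of the
#'   unpenalized fit falls back to a lightly ridge-penalized logistic fit
#'   (L2, fixed small penalty) keeping all candidate proteins — penalized
#'   fits give no valid coefficient p-values, so the p < alpha filter is
#'   skipped. Off by default: separation is reported as an error.
#' @param label free-text training metadata stored in the model.
#' @return object of class \code{signature_model}: \code{protein_ids},
#'   \code{intercept}, \code{coefficients} (standardized scale),
#'   \code{means}, \code{sds}, \code{cutoff}, \code{metadata}.
#' @export
freeze_signature <- function(proteins, train_matrix, labels, alpha = 0.05,
                             ridge_fallback = FALSE, label = "training") {
  if (length(proteins) < 1) stop("restricted set must be non-empty", call. = FALSE)
  X <- train_matrix[, proteins, drop = FALSE]
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance protein in training data", call. = FALSE)
  Z <- scale(X, center = mu, scale = sds)

  fit_glm <- function(zmat) {
    df <- data.frame(y = labels, zmat, check.names = FALSE)
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ ., data = df, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w))) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    if (sep || any(abs(stats::coef(fit)[-1]) > 25)) {
      stop("complete separation in signature refit; consider a ridge fallback",
           call. = FALSE)
    }
    fit
  }

  penalty <- "none"
  beta <- tryCatch({
    fit <- fit_glm(Z)
    coefs <- summary(fit)$coefficients
    keep <- rownames(coefs)[-1][coefs[-1, "Pr(>|z|)"] < alpha]
    keep <- gsub("^`|`$", "", keep)
    if (length(keep) == 0) {
      stop("no protein reached coefficient p < ", alpha, " in the multivariate model",
           call. = FALSE)
    }
    if (!identical(sort(keep), sort(proteins))) {
      proteins <- proteins[proteins %in% keep]
      mu <- mu[proteins]; sds <- sds[proteins]
      Z <- Z[, proteins, drop = FALSE]
      fit <- fit_glm(Z)
    }
    stats::coef(fit)
  }, error = function(e) {
    if (!ridge_fallback || !grepl("complete separation", conditionMessage(e))) stop(e)
    # lightly regularized L2 fit; no p-filter (penalized coefficients have no
    # valid Wald p-values), all candidate proteins retained
    penalty <<- "ridge(lambda=0.01)"
    rfit <- glmnet::glmnet(Z, labels, family = "binomial", alpha = 0,
                           lambda = 0.01, standardize = FALSE)
    b <- as.matrix(stats::coef(rfit))[, 1]
    stats::setNames(b, sub("^\\(Intercept\\)$", "(Intercept)", names(b)))
  })
  model <- structure(list(
    protein_ids = proteins,
    intercept = unname(beta["(Intercept)"]),
    coefficients = stats::setNames(unname(beta[-1]), proteins),
    means = mu,
    sds = sds,
    cutoff = NA_real_,
    metadata = list(label = label, alpha = alpha, penalty = penalty,
                    n_train = length(labels), n_case = sum(labels == 1))
  ), class = "signature_model")

  train_scores <- score_samples(model, train_matrix)
  model$cutoff <- evaluate(train_scores, labels)$threshold
  model
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("signature_model: %d proteins, cutoff %.3f (%s)\n",
              length(x$protein_ids), x$cutoff, x$metadata$label))
  print(round(x$coefficients, 3))
  invisible(x)
}

#' Score samples with a frozen signature model
#'
#' Standardizes the matrix by the model's stored means/SDs and returns the
#' inverse-logit of the linear predictor. Proteins missing from the matrix
#' are an error (no imputation).
#'
#' @param model a \code{signature_model}.
#' @param matrix samples-by-proteins raw (log10) abundance matrix.
#' @return numeric probability per sample.
#' @export
score_samples <- function(model, matrix) {
  missing <- setdiff(model$protein_ids, colnames(matrix))
  if (length(missing) > 0) {
    stop("proteins missing from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  Z <- scale(matrix[, model$protein_ids, drop = FALSE],
             center = model$means, scale = model$sds)
  stats::setNames(
    stats::plogis(model$intercept + drop(Z %*% model$coefficients)),
    rownames(matrix)
  )
}

#' Evaluate classification scores
#'
#' AUC via the rank statistic (ties counted half). If no threshold is given,
#' the Youden-optimal threshold (maximizing sensitivity + specificity - 1,
#' smallest threshold on ties, predicted positive when score >= threshold) is
#' chosen from the observed scores. Sensitivity, specificity, PPV and NPV are
#' reported at the used threshold.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels binary labels (1/TRUE = case); both classes must be present.
#' @param threshold optional fixed classification threshold.
#' @param label free-text dataset label carried into the report.
#' @return list of class \code{eval_report}: \code{auc}, \code{sensitivity},
#'   \code{specificity}, \code{ppv}, \code{npv}, \code{threshold},
#'   \code{n_case}, \code{n_control}, \code{label}.
#' @export
evaluate <- function(scores, labels, threshold = NULL, label = "") {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present", call. = FALSE)
  case <- scores[labels == 1]; ctrl <- scores[labels == 0]
  n1 <- length(case); n0 <- length(ctrl)
  r <- rank(c(case, ctrl))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  if (is.null(threshold)) {
    cand <- sort(unique(scores))
    j <- vapply(cand, function(t) mean(case >= t) + mean(ctrl < t) - 1, numeric(1))
    threshold <- cand[which(j == max(j))[1]]  # smallest threshold on ties
  }
  tp <- sum(case >= threshold); fn <- n1 - tp
  fp <- sum(ctrl >= threshold); tn <- n0 - fp
  structure(list(
    auc = auc,
    sensitivity = tp / n1,
    specificity = tn / n0,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    threshold = threshold,
    n_case = n1,
    n_control = n0,
    label = label
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report%s: AUC %.3f | sens %.3f spec %.3f ppv %.3f npv %.3f @ %.3f (n=%d/%d)\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$auc, x$sensitivity, x$specificity, x$ppv, x$npv, x$threshold,
              x$n_case, x$n_control))
  invisible(x)
}

#' Serialize / deserialize a frozen signature model as JSON
#'
#' @param model a \code{signature_model}.
#' @param path file path.
#' @return \code{read_signature_json} returns the \code{signature_model}.
#' @export
write_signature_json <- function(model, path) {
  jsonlite::write_json(
    list(protein_ids = model$protein_ids,
         intercept = model$intercept,
         coefficients = as.list(model$coefficients),
         means = as.list(model$means),
         sds = as.list(model$sds),
         cutoff = model$cutoff,
         metadata = model$metadata),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_signature_json
#' @export
read_signature_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    protein_ids = x$protein_ids,
    intercept = x$intercept,
    coefficients = unlist(x$coefficients),
    means = unlist(x$means),
    sds = unlist(x$sds),
    cutoff = x$cutoff,
    metadata = x$metadata
  ), class = "signature_model")
}
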