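test_that("stratified split obeys the floor rule and is deterministic", {
  rec <- data.frame(sample_id = sprintf("S%03d", 1:200),
                    at_status = rep(c("A+T+", "A-T-"), each = 100))
  sp <- split_train_test(rec, 0.7, seed = 1)
  expect_length(sp$train, 140)
  expect_length(sp$test, 60)
  tr_status <- rec$at_status[match(sp$train, rec$sample_id)]
  expect_equal(unname(table(tr_status)), c(70, 70), ignore_attr = TRUE)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, split_train_test(rec, 0.7, seed = 1))

  # floor rule at an extreme fraction: floor(0.999 * 100) = 99 per stratum
  sp99 <- split_train_test(rec, 0.999, seed = 2)
  expect_length(sp99$train, 198)
  expect_error(split_train_test(rec[1, ], 0.7), "fewer than 2")
  expect_error(split_train_test(rec, 1.5), "fraction_train")
})

# shared planted-signal world for the selection tests
make_signal_world <- function(n = 800, m = 500, n_info = 10, beta = 0.8, seed = 40) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, dimnames = list(sprintf("S%04d", 1:n),
                                               sprintf("P%04d", 1:m)))
  info <- sprintf("P%04d", 1:n_info)
  eta <- X[, info] %*% rep(beta, n_info)
  y <- rbinom(n, 1, plogis(drop(eta)))
  list(X = X, y = y, info = info)
}

test_that("lasso recovers planted informative proteins and rejects noise", {
  w <- make_signal_world()
  sel <- lasso_select(w$X, w$y, seed = 4)
  expect_gte(length(intersect(sel$proteins, w$info)), 9)
  expect_lte(length(setdiff(sel$proteins, w$info)), 5)
  expect_gt(sel$cv_auc, 0.85)

  # labels independent of the matrix: empty selection or chance-level CV AUC
  set.seed(41)
  y_null <- rbinom(nrow(w$X), 1, 0.5)
  got <- tryCatch(lasso_select(w$X, y_null, seed = 4),
                  error = function(e) list(cv_auc = 0.5, proteins = character(0)))
  expect_true(length(got$proteins) == 0 || got$cv_auc <= 0.60)
})

test_that("correlation pruning keeps the representative of each tight pair", {
  set.seed(42)
  n <- 300
  a <- rnorm(n)
  X <- cbind(A = a, B = a + rnorm(n, 0, 0.35), C = rnorm(n))
  # calibrate: r(A,B) ~ 0.94, r(B,C)/r(A,C) ~ 0
  X[, "C"] <- 0.9 * X[, "B"] + sqrt(1 - 0.81) * rnorm(n)  # r(B,C) ~ 0.9
  r <- cor(X)
  expect_gt(abs(r["A", "B"]), 0.8)
  expect_gt(abs(r["B", "C"]), 0.8)
  pr <- prune_correlated(c("A", "B", "C"), X,
                         priority_p = c(A = 1e-8, B = 1e-6, C = 1e-4))
  if (abs(r["A", "C"]) <= 0.8) {
    expect_identical(pr, c("A", "C"))  # chain rule: keep A (best p), drop B, keep C
  } else {
    expect_identical(pr, "A")
  }
  # no pair above threshold -> identity
  Y <- matrix(rnorm(3 * n), n, dimnames = list(NULL, c("A", "B", "C")))
  expect_identical(prune_correlated(c("A", "B", "C"), Y), c("A", "B", "C"))
  # a 0.95-correlated pair leaves one survivor
  Z <- cbind(A = a, B = a + rnorm(n, 0, 0.2))
  expect_length(prune_correlated(c("A", "B"), Z, priority_p = c(A = .01, B = .5)), 1)
})

test_that("platform restriction is an order-preserving intersection", {
  expect_identical(restrict_to_platform(c("b", "a"), c("a", "b", "c")), c("b", "a"))
  expect_identical(restrict_to_platform(c("a", "x", "b"), c("a", "b")), c("a", "b"))
  expect_error(restrict_to_platform(c("x", "y"), c("a", "b")), "overlap")
  expect_error(restrict_to_platform("a", character(0)), "non-empty")
})

test_that("freeze_signature drops nonsignificant proteins and freezes a cutoff", {
  set.seed(43)
  n <- 600
  X <- matrix(rnorm(n * 10), n,
              dimnames = list(NULL, c(sprintf("T%d", 1:5), sprintf("N%d", 1:5))))
  y <- rbinom(n, 1, plogis(X[, 1:5] %*% rep(0.9, 5)))
  model <- freeze_signature(colnames(X), X, y)
  expect_gte(sum(model$protein_ids %in% sprintf("T%d", 1:5)), 4)
  expect_lte(length(setdiff(model$protein_ids, sprintf("T%d", 1:5))), 1)
  expect_true(model$cutoff > 0 && model$cutoff < 1)

  # refreezing is deterministic
  model2 <- freeze_signature(colnames(X), X, y)
  expect_identical(model$coefficients, model2$coefficients)
  expect_identical(model$cutoff, model2$cutoff)

  # a perfectly separating protein triggers the separation error
  Xs <- cbind(S = c(rnorm(50, -5), rnorm(50, 5)), R = rnorm(100))
  ys <- rep(0:1, each = 50)
  expect_error(freeze_signature(colnames(Xs), Xs, ys), "separation")
  # ... unless the documented ridge fallback is enabled
  mr <- freeze_signature(colnames(Xs), Xs, ys, ridge_fallback = TRUE)
  expect_identical(mr$metadata$penalty, "ridge(lambda=0.01)")
  expect_gt(evaluate(score_samples(mr, Xs), ys)$auc, 0.99)
})

test_that("score_samples is plain standardized inverse-logit arithmetic", {
  model <- structure(list(
    protein_ids = c("p1", "p2"), intercept = -0.5,
    coefficients = c(p1 = 1.2, p2 = -0.7),
    means = c(p1 = 3, p2 = 4), sds = c(p1 = 0.5, p2 = 2),
    cutoff = 0.5, metadata = list()), class = "signature_model")
  X <- matrix(c(3.5, 4.2, 2.0, 6.0), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("p1", "p2")))
  want <- plogis(-0.5 + 1.2 * (X[, "p1"] - 3) / 0.5 - 0.7 * (X[, "p2"] - 4) / 2)
  expect_equal(unname(score_samples(model, X)), unname(want), tolerance = 1e-12)

  # all-zero coefficients, zero intercept -> probability one half
  m0 <- model; m0$coefficients[] <- 0; m0$intercept <- 0
  expect_equal(unname(score_samples(m0, X)), c(0.5, 0.5))
  # samples at the training means score inverse-logit(intercept)
  at_mean <- matrix(c(3, 4), 1, dimnames = list("s", c("p1", "p2")))
  expect_equal(unname(score_samples(model, at_mean)), plogis(-0.5))
  expect_error(score_samples(model, X[, 1, drop = FALSE]), "p2")

  # JSON round trip preserves the frozen model
  path <- tempfile(fileext = ".json")
  write_signature_json(model, path)
  back <- read_signature_json(path)
  expect_equal(back$coefficients, model$coefficients)
  expect_equal(unname(score_samples(back, X)), unname(want), tolerance = 1e-12)
})

test_that("evaluate matches the pair-counting oracle and Youden conventions", {
  # worked examples
  ev <- evaluate(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(ev$auc, 1)
  expect_equal(ev$sensitivity + ev$specificity - 1, 1)
  expect_equal(ev$ppv, 1); expect_equal(ev$npv, 1)
  expect_equal(evaluate(rep(0.3, 10), rep(0:1, 5))$auc, 0.5)
  expect_equal(evaluate(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))$auc, 0.75)

  set.seed(44)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    scores <- round(runif(n), 2)  # induce ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(evaluate(scores, labels)$auc, auc_pair_oracle(scores, labels),
                 tolerance = 1e-12)
  }

  # invariance under strictly monotone transforms of the scores
  scores <- runif(40); labels <- rbinom(40, 1, 0.5)
  if (length(unique(labels)) == 2) {
    expect_equal(evaluate(plogis(5 * scores), labels)$auc,
                 evaluate(scores, labels)$auc, tolerance = 1e-12)
  }
  expect_error(evaluate(runif(5), rep(1, 5)), "both classes")
})
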