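test_that("lasso shrinkage bounds and closed forms hold", {
  set.seed(61)
  n <- 40
  X <- scale(matrix(rnorm(n * 5), n, 5))
  y <- as.numeric(X[, 1] + 0.5 * X[, 2] + rnorm(n, sd = 0.3) > 0)
  lmax <- lasso_lambda_max(X, y)
  expect_equal(unname(fit_lasso(X, y, lmax * 1.0001)$weights), rep(0, 5))
  expect_gt(sum(fit_lasso(X, y, lmax * 0.99)$weights != 0), 0)
  # single standardized predictor: beta = soft-threshold of the OLS slope
  x1 <- X[, 1, drop = FALSE]
  ols <- coef(lm(y ~ x1))[2]
  for (lam in c(0, 0.05, 0.2)) {
    beta <- fit_lasso(x1, y, lam)$weights
    shrunk <- sign(ols) * max(abs(ols) * mean(x1^2) - lam, 0) / mean(x1^2)
    expect_equal(unname(beta), unname(shrunk), tolerance = 1e-7)
  }
  expect_error(fit_lasso(X, y, -1), ">= 0")
})

test_that("unpenalized fit matches ordinary least squares", {
  set.seed(62)
  X <- matrix(rnorm(60), 20, 3)
  y <- as.numeric(X[, 1] - X[, 3] + rnorm(20, sd = 0.2) > 0)
  fit <- fit_lasso(X, y, lambda = 0)
  ref <- coef(lm(y ~ X))
  expect_equal(unname(fit$weights), unname(ref[-1]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(ref[1]), tolerance = 1e-6)
})

test_that("coordinate descent agrees with glmnet on the shared objective", {
  set.seed(63)
  n <- 50
  X <- scale(matrix(rnorm(n * 8), n, 8))
  y <- as.numeric(X[, 2] + rnorm(n, sd = 0.5) > 0)
  lam <- lasso_lambda_max(X, y) * 0.3
  mine <- fit_lasso(X, y, lam)
  ref <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1, lambda = lam,
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-14)
  expect_equal(unname(mine$weights), as.numeric(ref$beta), tolerance = 1e-5)
  expect_equal(mine$intercept, as.numeric(ref$a0), tolerance = 1e-5)
})

test_that("panel sparsity is non-increasing in the penalty", {
  set.seed(64)
  X <- scale(matrix(rnorm(50 * 10), 50, 10))
  y <- as.numeric(X[, 1] + X[, 4] + rnorm(50, sd = 0.4) > 0)
  lmax <- lasso_lambda_max(X, y)
  grid <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 12))
  sizes <- vapply(grid, function(l) length(fit_lasso(X, y, l)$panel), 0L)
  expect_true(all(diff(sizes) >= 0))  # grid is decreasing in lambda
})

test_that("refit on the selected panel reproduces the scores", {
  set.seed(65)
  X <- scale(matrix(rnorm(60 * 6), 60, 6))
  colnames(X) <- paste0("f", 1:6)
  y <- as.numeric(X[, 1] + rnorm(60, sd = 0.4) > 0)
  lam <- lasso_lambda_max(X, y) * 0.2
  full <- fit_lasso(X, y, lam)
  refit <- fit_lasso(X[, full$panel, drop = FALSE], y, lam)
  expect_equal(predict(refit, X[, full$panel, drop = FALSE]),
               predict(full, X), tolerance = 1e-6)
})

test_that("cross-validated selection is deterministic and near-perfect on separable data", {
  set.seed(66)
  n <- 60
  X <- scale(matrix(rnorm(n * 6), n, 6))
  y <- as.numeric(X[, 1] > 0)  # perfectly separable by feature 1
  cv1 <- cv_select(X, y, seed = 5)
  cv2 <- cv_select(X, y, seed = 5)
  expect_identical(cv1$best_lambda, cv2$best_lambda)
  expect_identical(cv1$accuracy, cv2$accuracy)
  expect_gte(max(cv1$mean_accuracy), 0.95)
  expect_true("f1" %in% cv1$model$panel ||
                names(which.max(abs(cv1$model$weights))) == "f1")
})

test_that("ROC analysis matches hand-computed and brute-force AUC", {
  r <- roc_analysis(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), n_boot = 100)
  expect_equal(r$auc, 0.75)  # 3 of 4 pairs concordant
  # perfectly separated scores
  rp <- roc_analysis(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3),
                     n_boot = 100)
  expect_equal(rp$auc, 1.0)
  expect_equal(rp$youden$sensitivity, 1.0)
  expect_equal(rp$youden$specificity, 1.0)
  # ties get half credit
  rt <- roc_analysis(rep(2, 8), rep(c(0, 1), 4), n_boot = 50)
  expect_equal(rt$auc, 0.5)
  # brute-force oracle on a random <= 50-sample input
  set.seed(67)
  sc <- sample(seq(0, 1, 0.05), 40, replace = TRUE)  # forces some ties
  y <- rbinom(40, 1, 0.5)
  if (length(unique(y)) == 2) {
    expect_equal(roc_analysis(sc, y, n_boot = 50)$auc,
                 auc_bruteforce(sc, y), tolerance = 1e-12)
  }
  expect_error(roc_analysis(1:4, rep(1, 4)), "both classes")
})

test_that("ROC confidence interval and confusion matrix are coherent", {
  set.seed(68)
  scores <- c(rnorm(30, 0.3, 0.2), rnorm(30, 0.8, 0.2))
  y <- rep(c(0, 1), each = 30)
  r <- roc_analysis(scores, y, operating_threshold = 0.62, n_boot = 500,
                    seed = 4)
  expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
  expect_true(r$auc >= 0 && r$auc <= 1)
  cm <- r$confusion
  expect_equal(sum(cm), 60)
  expect_equal(r$accuracy, sum(diag(cm)) / sum(cm))
  # same seed, same interval
  r2 <- roc_analysis(scores, y, operating_threshold = 0.62, n_boot = 500,
                     seed = 4)
  expect_identical(r$ci, r2$ci)
})

test_that("panel models serialize to JSON with only nonzero features", {
  set.seed(69)
  X <- scale(matrix(rnorm(40 * 4), 40, 4))
  colnames(X) <- paste0("m", 1:4)
  y <- as.numeric(X[, 1] > 0)
  fit <- fit_lasso(X, y, lasso_lambda_max(X, y) * 0.5)
  path <- file.path(tempdir(), "panel.json")
  write_panel_model(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_setequal(back$features, fit$panel)
  expect_true(all(unlist(back$weights) != 0))
})
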