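soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Smallest penalty that zeroes every lasso weight
#'
#' `lambda_max = max_j |x_j'(y - mean(y))| / n` on the centred predictors.
#'
#' @param X predictor matrix.
#' @param y 0/1 response.
#' @return numeric penalty bound.
#' @export
lasso_lambda_max <- function(X, y) {
  X <- as.matrix(X)
  Xc <- sweep(X, 2, colMeans(X))
  max(abs(drop(crossprod(Xc, y - mean(y))))) / nrow(X)
}

#' Fit a lasso panel by cyclic coordinate descent
#'
#' Minimizes `(1/2n) ||y - b0 - X b||^2 + lambda ||b||_1` (squared loss on
#' a 0/1 class response, as is conventional for sparse diagnostic panels)
#' by cyclic coordinate descent on the centred problem, to a maximum
#' coefficient change of `tol` per sweep. Features whose weight is driven
#' to zero drop out of the reported panel.
#'
#' @param X numeric matrix, samples x candidate markers (standardized
#'   upstream by [log_autoscale()]).
#' @param y 0/1 response (or two-level factor; second level is coded 1).
#' @param lambda penalty `>= 0`.
#' @param threshold operating decision threshold stored on the model
#'   (scores above it call the case class); default 0.62.
#' @param tol convergence tolerance on the maximum coefficient update.
#' @param max_iter maximum coordinate-descent sweeps.
#' @param warm_start optional initial weight vector (used by the
#'   path/cross-validation driver).
#' @return an object of class `"PanelModel"`: `weights` (named, full
#'   length), `intercept`, `lambda`, `threshold`, `panel` (features with
#'   nonzero weight), `y_levels`.
#' @export
fit_lasso <- function(X, y, lambda, threshold = 0.62, tol = 1e-8,
                      max_iter = 100000L, warm_start = NULL) {
  if (lambda < 0) stop("lambda must be >= 0")
  X <- as.matrix(X)
  yb <- encode_binary(y)
  y01 <- yb$y01
  n <- nrow(X); p <- ncol(X)
  feature_ids <- colnames(X) %||% paste0("f", seq_len(p))
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  yc <- y01 - mean(y01)
  v <- colSums(Xc^2) / n
  beta <- if (is.null(warm_start)) numeric(p) else as.numeric(warm_start)
  beta <- .cd_lasso(Xc, yc, v, lambda, beta, tol, as.integer(max_iter))
  intercept <- mean(y01) - sum(xbar * beta)
  names(beta) <- feature_ids
  structure(list(weights = beta, intercept = intercept, lambda = lambda,
                 threshold = threshold,
                 panel = feature_ids[beta != 0],
                 y_levels = yb$levels),
            class = "PanelModel")
}

#' @export
print.PanelModel <- function(x, ...) {
  cat(sprintf(
    "<PanelModel> %d/%d nonzero weights, lambda=%.4g, threshold=%.2f\n",
    length(x$panel), length(x$weights), x$lambda, x$threshold))
  invisible(x)
}

#' Prediction scores of a lasso panel
#'
#' @param object a [fit_lasso()] model.
#' @param newdata matrix with the model's features as columns.
#' @param ... unused.
#' @return numeric score per sample (`intercept + X w`); near 1 means the
#'   case class.
#' @export
predict.PanelModel <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) &&
      all(names(object$weights) %in% colnames(newdata))) {
    newdata <- newdata[, names(object$weights), drop = FALSE]
  }
  drop(newdata %*% object$weights) + object$intercept
}

# Descending-lambda path with warm starts (internal CV driver).
lasso_path <- function(X, y, lambdas, tol = 1e-8) {
  ord <- order(lambdas, decreasing = TRUE)
  beta <- NULL
  fits <- vector("list", length(lambdas))
  for (k in ord) {
    fit <- fit_lasso(X, y, lambdas[k], tol = tol, warm_start = beta)
    beta <- fit$weights
    fits[[k]] <- fit
  }
  fits
}

#' Penalty selection by repeated stratified cross-validation
#'
#' Repeatedly splits the samples into training and held-out parts at
#' `split_ratio` (stratified by class; default ten repeats of a 9:1
#' split), fits the whole lasso path on each training part with warm
#' starts, and scores held-out accuracy with scores thresholded at 0.5
#' (the midpoint of the 0/1 coding). The best penalty is the most
#' accurate one, ties resolved toward the larger (sparser) penalty; the
#' returned model is refit on all data at that penalty.
#'
#' @param X standardized marker matrix.
#' @param y 0/1 response or two-level factor.
#' @param folds number of random splits (default 10).
#' @param split_ratio training fraction per split (default 0.9).
#' @param lambda_grid penalty grid; default 50 log-spaced values from
#'   `lambda_max` down to `lambda_max / 1000`.
#' @param seed integer seed controlling the splits.
#' @param threshold operating threshold stored on the refit model.
#' @return list with `best_lambda`, `lambda_grid`, `accuracy` (splits x
#'   penalties matrix), `mean_accuracy` (per penalty), `model` (the
#'   [fit_lasso()] refit).
#' @export
cv_select <- function(X, y, folds = 10L, split_ratio = 0.9,
                      lambda_grid = NULL, seed = 1L, threshold = 0.62) {
  if (folds < 2) stop("folds must be >= 2")
  X <- as.matrix(X)
  yb <- encode_binary(y)
  y01 <- yb$y01
  n <- nrow(X)
  if (is.null(lambda_grid)) {
    lmax <- lasso_lambda_max(X, y01)
    lambda_grid <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 50))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  acc <- matrix(NA_real_, folds, length(lambda_grid))
  idx0 <- which(y01 == 0); idx1 <- which(y01 == 1)
  if (length(idx0) < 2 || length(idx1) < 2) {
    stop("need at least 2 samples per class for stratified splits")
  }
  for (rep in seq_len(folds)) {
    train <- with_seed(substream_seed(seed, "cv", rep), {
      repeat {
        tr <- c(sample(idx0, max(1, round(split_ratio * length(idx0)))),
                sample(idx1, max(1, round(split_ratio * length(idx1)))))
        te <- setdiff(seq_len(n), tr)
        # stratification keeps both classes in train; re-draw if the
        # held-out part lost one
        if (length(unique(y01[te])) == 2) break
        message("resampling split ", rep, ": held-out part lacked a class")
      }
      tr
    })
    test <- setdiff(seq_len(n), train)
    fits <- lasso_path(X[train, , drop = FALSE], y01[train], lambda_grid)
    for (k in seq_along(lambda_grid)) {
      sc <- predict(fits[[k]], X[test, , drop = FALSE])
      acc[rep, k] <- mean(as.numeric(sc >= 0.5) == y01[test])
    }
  }
  mean_acc <- colMeans(acc)
  best <- which(mean_acc >= max(mean_acc) - 1e-12)[1]  # grid is descending
  model <- fit_lasso(X, y01, lambda_grid[best], threshold = threshold)
  model$y_levels <- yb$levels
  list(best_lambda = lambda_grid[best], lambda_grid = lambda_grid,
       accuracy = acc, mean_accuracy = mean_acc, model = model)
}

#' ROC evaluation of panel scores
#'
#' AUC by the rank (Mann-Whitney) statistic with half credit for ties; a
#' percentile 95% confidence interval from a stratified bootstrap; the
#' Youden-optimal cut-off (`J = sensitivity + specificity - 1`, ties
#' resolved toward higher specificity); and the confusion matrix plus
#' accuracy at a fixed operating threshold (scores `>=` threshold call
#' the case class).
#'
#' @param scores numeric prediction scores.
#' @param labels two-class labels (case = second level, or 1 for 0/1).
#' @param operating_threshold fixed decision threshold (default 0.62).
#' @param n_boot bootstrap replicates for the CI (default 2000).
#' @param seed integer seed for the bootstrap.
#' @return an object of class `"ROCResult"`: `auc`, `ci` (low, high),
#'   `youden` (threshold, sensitivity, specificity), `confusion` (2x2
#'   table at the operating threshold), `accuracy`, `curve` (data frame
#'   of threshold/sensitivity/specificity).
#' @export
roc_analysis <- function(scores, labels, operating_threshold = 0.62,
                         n_boot = 2000L, seed = 1L) {
  yb <- encode_binary(labels)
  y <- yb$y01
  if (length(unique(y)) < 2) stop("both classes must be present")
  stopifnot(length(scores) == length(y))
  auc <- auc_rank(scores, y)
  pos <- which(y == 1); neg <- which(y == 0)
  boot <- with_seed(substream_seed(seed, "bootstrap"), {
    vapply(seq_len(n_boot), function(b) {
      ip <- sample(pos, length(pos), replace = TRUE)
      ineg <- sample(neg, length(neg), replace = TRUE)
      auc_rank(c(scores[ip], scores[ineg]),
               c(rep(1, length(ip)), rep(0, length(ineg))))
    }, 0)
  })
  ci <- unname(stats::quantile(boot, c(0.025, 0.975)))
  thr <- c(-Inf, sort(unique(scores)))
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), 0)
  spec <- vapply(thr, function(t) mean(scores[neg] < t), 0)
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(spec[best])]
  pred <- as.integer(scores >= operating_threshold)
  confusion <- table(predicted = factor(pred, levels = c(0, 1),
                                        labels = yb$levels),
                     truth = factor(y, levels = c(0, 1),
                                    labels = yb$levels))
  structure(list(
    auc = auc, ci = ci,
    youden = list(threshold = thr[best], sensitivity = sens[best],
                  specificity = spec[best]),
    confusion = confusion,
    accuracy = mean(pred == y),
    operating_threshold = operating_threshold,
    curve = data.frame(threshold = thr, sensitivity = sens,
                       specificity = spec)),
    class = "ROCResult")
}

# Mann-Whitney AUC via midranks (ties get half credit).
auc_rank <- function(scores, y01) {
  r <- rank(scores)
  n1 <- sum(y01 == 1); n0 <- sum(y01 == 0)
  (sum(r[y01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf("<ROCResult> AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$auc, x$ci[1], x$ci[2]))
  cat(sprintf("  Youden cut-off %.3f: sens %.1f%%, spec %.1f%%\n",
              x$youden$threshold, 100 * x$youden$sensitivity,
              100 * x$youden$specificity))
  cat(sprintf("  accuracy %.1f%% at operating threshold %.2f\n",
              100 * x$accuracy, x$operating_threshold))
  invisible(x)
}

#' Serialize a panel model as JSON
#'
#' @param model a [fit_lasso()] model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_model <- function(model, path) {
  stopifnot(inherits(model, "PanelModel"))
  jsonlite::write_json(
    list(features = model$panel,
         weights = as.list(model$weights[model$panel]),
         intercept = model$intercept, lambda = model$lambda,
         threshold = model$threshold, y_levels = model$y_levels),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
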