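#' Fit a two-class PLS-DA model (NIPALS, single response)
#'
#' Partial least squares discriminant analysis with the class coded 0/1,
#' centred, and fitted as single-response PLS1 by NIPALS: for each
#' component the weight vector is the normalized covariance direction
#' `X'y / ||X'y||`, scores `t = Xw`, X is deflated by `t p'` and y by its
#' projection on `t`. The explained y sum of squares per component
#' (`SSY_a = q_a^2 t_a't_a`) is stored for the VIP computation. The sign
#' of each weight vector is fixed so its largest-magnitude entry is
#' positive.
#'
#' @param X numeric matrix, samples x features; expected to be
#'   column-scaled (e.g. the values of a `log_scaled` [peak_matrix()]).
#' @param y two-class labels (factor, character, or 0/1 numeric).
#' @param n_components number of latent components (default 2).
#' @param tol NIPALS convergence tolerance.
#' @param max_iter maximum NIPALS iterations per component.
#' @return an object of class `"PLSModel"`: `weights`, `loadings`,
#'   `scores`, `y_loadings`, `ssy` (explained y-SS per component),
#'   `feature_ids`, `y_levels`, `n_components`.
#' @export
fit_plsda <- function(X, y, n_components = 2L, tol = 1e-10, max_iter = 500L) {
  X <- as.matrix(X)
  yb <- encode_binary(y)
  if (length(unique(yb$y01)) < 2) stop("y must contain both classes")
  n <- nrow(X); p <- ncol(X)
  if (n_components > min(n - 1L, p)) {
    stop("n_components exceeds min(samples - 1, features)")
  }
  yc <- yb$y01 - mean(yb$y01)
  Xd <- X
  yd <- yc
  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- ssy <- numeric(n_components)
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(Xd, yd))
    # NIPALS refinement loop; converges in one pass for a single response
    for (it in seq_len(max_iter)) {
      nw <- sqrt(sum(w^2))
      if (nw == 0) stop("degenerate component: X carries no y covariance")
      w <- w / nw
      tt <- drop(Xd %*% w)
      qa <- sum(tt * yd) / sum(tt^2)
      w_new <- drop(crossprod(Xd, yd))
      if (sqrt(sum((w_new / sqrt(sum(w_new^2)) - w)^2)) < tol) break
      w <- w_new
    }
    imax <- which.max(abs(w))
    if (w[imax] < 0) w <- -w
    tt <- drop(Xd %*% w)
    tt2 <- sum(tt^2)
    pa <- drop(crossprod(Xd, tt)) / tt2
    qa <- sum(tt * yd) / tt2
    Xd <- Xd - tcrossprod(tt, pa)
    yd <- yd - qa * tt
    W[, a] <- w; P[, a] <- pa; Tm[, a] <- tt
    q[a] <- qa; ssy[a] <- qa^2 * tt2
  }
  structure(list(weights = W, loadings = P, scores = Tm, y_loadings = q,
                 ssy = ssy, n_components = n_components,
                 feature_ids = colnames(X) %||% paste0("f", seq_len(p)),
                 y_levels = yb$levels),
            class = "PLSModel")
}

encode_binary <- function(y) {
  if (is.numeric(y) && all(y %in% c(0, 1))) {
    return(list(y01 = as.numeric(y), levels = c("0", "1")))
  }
  f <- factor(y)
  if (nlevels(f) != 2) stop("y must have exactly two classes")
  list(y01 = as.numeric(f) - 1, levels = levels(f))
}

#' @export
print.PLSModel <- function(x, ...) {
  cat(sprintf("<PLSModel> %d components over %d features; y: %s vs %s\n",
              x$n_components, length(x$feature_ids),
              x$y_levels[1], x$y_levels[2]))
  cat("  explained y-SS per component:",
      paste(sprintf("%.3g", x$ssy), collapse = ", "), "\n")
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' Cumulative VIP over all fitted components:
#' `VIP_j = sqrt( p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a )`
#' where `p` is the number of features and `SSY_a` the y sum of squares
#' explained by component `a`. The mean of squared VIP scores is exactly 1,
#' so VIP > 1 flags features contributing more than average to the class
#' separation.
#'
#' @param model a fitted [fit_plsda()] model.
#' @return named numeric vector of VIP scores per feature.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "PLSModel"))
  if (sum(model$ssy) <= 0) stop("model explains no y variance")
  W <- model$weights
  wn <- sqrt(colSums(W^2))
  Wn2 <- sweep(W, 2, wn, "/")^2
  p <- nrow(W)
  vip <- sqrt(p * drop(Wn2 %*% model$ssy) / sum(model$ssy))
  names(vip) <- model$feature_ids
  vip
}
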