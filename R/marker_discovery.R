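#' Per-ion differential statistics (t-test with BH-FDR)
#'
#' Two-sided two-sample t-tests per ion on natural-log-transformed
#' normalized intensities (log stabilizes the multiplicative variance of
#' MS intensities), with Benjamini-Hochberg adjustment of the p-values.
#' Welch's unequal-variance form is the default; `var_equal = TRUE` gives
#' the pooled-variance Student form. An ion with zero variance in both
#' groups gets p = 1 when the group means are equal and p = 0 otherwise.
#'
#' @param X numeric matrix of tic-normalized intensities, samples x ions.
#' @param groups two-class labels aligned to rows.
#' @param case the label treated as the case class (defaults to the
#'   second factor level).
#' @param var_equal pooled-variance Student's t instead of Welch.
#' @param log_transform apply `ln(x + epsilon)` before testing.
#' @param epsilon offset for the log; default half the smallest nonzero
#'   value of `X`.
#' @return data frame with columns `p` and `q` (BH-adjusted), one row per
#'   ion.
#' @export
differential_stats <- function(X, groups, case = NULL, var_equal = FALSE,
                               log_transform = TRUE, epsilon = NULL) {
  X <- as.matrix(X)
  g <- split_groups(groups, case, nrow(X))
  if (sum(g$is_case) < 2 || sum(!g$is_case) < 2) {
    stop("need at least 2 samples per group")
  }
  if (log_transform) {
    if (any(X < 0)) stop("negative intensities cannot be log-transformed")
    if (is.null(epsilon)) {
      nz <- X[X > 0]
      epsilon <- if (length(nz)) min(nz) / 2 else 1
    }
    X <- log(X + epsilon)
  }
  A <- X[g$is_case, , drop = FALSE]
  B <- X[!g$is_case, , drop = FALSE]
  n1 <- nrow(A); n2 <- nrow(B)
  m1 <- colMeans(A); m2 <- colMeans(B)
  v1 <- colSums(sweep(A, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(B, 2, m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se == 0 | !is.finite(se)
  p[degenerate] <- ifelse(abs(m1 - m2)[degenerate] < .Machine$double.eps^0.5,
                          1, 0)
  data.frame(p = p, q = stats::p.adjust(p, method = "BH"))
}

split_groups <- function(groups, case, n) {
  if (length(groups) != n) stop("groups misaligned with matrix rows")
  f <- factor(groups)
  if (nlevels(f) != 2) stop("groups must have exactly two classes")
  if (is.null(case)) case <- levels(f)[2]
  if (!case %in% levels(f)) stop("case label not present in groups")
  list(is_case = f == case, case = case,
       control = setdiff(levels(f), case))
}

#' Per-ion fold change (case mean over control mean)
#'
#' Computed on the linear tic-normalized scale. Degenerate cases use
#' sentinels: control mean 0 with positive case mean gives `Inf`; both
#' means 0 gives 1.
#'
#' @inheritParams differential_stats
#' @return numeric vector of fold changes, one per ion.
#' @export
fold_changes <- function(X, groups, case = NULL) {
  X <- as.matrix(X)
  g <- split_groups(groups, case, nrow(X))
  mc <- colMeans(X[g$is_case, , drop = FALSE])
  m0 <- colMeans(X[!g$is_case, , drop = FALSE])
  fc <- mc / m0
  fc[m0 == 0 & mc > 0] <- Inf
  fc[m0 == 0 & mc == 0] <- 1
  fc
}

#' Stepwise marker-selection cascade
#'
#' Applies, in order and with strict inequalities, the three screening
#' stages used for fingerprint marker discovery: VIP > `vip` from the
#' PLS-DA model, BH-adjusted q < `fdr`, and fold change > `fc` or
#' < `1/fc`. Pass flags are monotone: an ion is evaluated at a stage only
#' if it survived all earlier stages.
#'
#' @param vip numeric VIP vector per ion.
#' @param stats data frame from [differential_stats()] (`p`, `q`).
#' @param fc numeric fold-change vector from [fold_changes()].
#' @param features optional data frame of per-ion descriptors
#'   (e.g. `bin_mz`, `polarity`); carried into the table.
#' @param thresholds list with elements `vip` (default 1.0), `fdr`
#'   (default 0.05) and `fc` (default 2.0).
#' @return a `MarkerTable`: data frame with per-ion statistics, direction
#'   (`"up"` iff fold change > 1), pass flags per stage, a `selected`
#'   column, an empty `annotation` slot, and a `stage_counts` attribute
#'   with the survivor count after each stage.
#' @export
select_markers <- function(vip, stats, fc, features = NULL,
                           thresholds = list(vip = 1.0, fdr = 0.05,
                                             fc = 2.0)) {
  m <- length(vip)
  if (nrow(stats) != m || length(fc) != m) {
    stop("vip, stats and fc must be aligned over the same ions")
  }
  if (!is.null(features) && nrow(features) != m) {
    stop("features misaligned with statistics")
  }
  th <- utils::modifyList(list(vip = 1.0, fdr = 0.05, fc = 2.0),
                          as.list(thresholds))
  pass_vip <- vip > th$vip
  pass_fdr <- pass_vip & stats$q < th$fdr
  pass_fc <- pass_fdr & (fc > th$fc | fc < 1 / th$fc)
  tab <- data.frame(
    feature_id = names(vip) %||% paste0("f", seq_len(m)),
    vip = as.numeric(vip),
    p_value = stats$p,
    q_value = stats$q,
    fold_change = fc,
    direction = ifelse(fc > 1, "up", "down"),
    pass_vip = pass_vip,
    pass_fdr = pass_fdr,
    pass_fc = pass_fc,
    selected = pass_fc,
    annotation = NA_character_,
    stringsAsFactors = FALSE)
  if (!is.null(features)) tab <- cbind(features, tab)
  attr(tab, "stage_counts") <- c(total = m, vip = sum(pass_vip),
                                 fdr = sum(pass_fdr), fc = sum(pass_fc))
  attr(tab, "thresholds") <- th
  class(tab) <- c("MarkerTable", "data.frame")
  tab
}

#' Run the full marker-discovery cascade on a normalized matrix
#'
#' Convenience wrapper: fits PLS-DA on the autoscaled matrix, computes
#' VIP, per-ion t-tests with BH-FDR and linear-scale fold changes, and
#' applies [select_markers()]. The same routine serves tissue (TNBC vs
#' PNT) and serum (TNBC vs HD) screens.
#'
#' @param pm a [peak_matrix()] at stage `"tic_normalized"` (QC rows are
#'   dropped automatically when `specimen` metadata is present).
#' @param case case-group label; control is the other group present.
#' @param n_components PLS-DA components for the VIP stage.
#' @param thresholds cascade thresholds, see [select_markers()].
#' @param var_equal pooled-variance t-test instead of Welch.
#' @return a `MarkerTable` (see [select_markers()]).
#' @export
discover_markers <- function(pm, case = "TNBC", n_components = 2L,
                             thresholds = list(vip = 1.0, fdr = 0.05,
                                               fc = 2.0),
                             var_equal = FALSE) {
  stopifnot(inherits(pm, "PeakMatrix"))
  if (pm$stage != "tic_normalized") {
    stop("discover_markers expects a tic_normalized matrix")
  }
  keep <- rep(TRUE, nrow(pm$values))
  if ("specimen" %in% names(pm$samples)) keep <- pm$samples$specimen != "qc"
  X <- pm$values[keep, , drop = FALSE]
  groups <- pm$samples$group[keep]
  scaled <- log_autoscale(subset_rows(pm, keep))
  pls <- fit_plsda(scaled$values, groups == case, n_components)
  vip <- vip_scores(pls)
  st <- differential_stats(X, groups, case = case, var_equal = var_equal)
  fc <- fold_changes(X, groups, case = case)
  select_markers(vip, st, fc,
                 features = data.frame(bin_mz = pm$bin_mz,
                                       polarity = pm$polarity),
                 thresholds = thresholds)
}

subset_rows <- function(pm, keep) {
  pm$values <- pm$values[keep, , drop = FALSE]
  pm$samples <- pm$samples[keep, , drop = FALSE]
  pm
}
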