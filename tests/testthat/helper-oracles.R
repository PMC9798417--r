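# Independent brute-force oracles used to cross-check the package's
# implementations, plus small fixture builders shared across test files.

# Benjamini-Hochberg step-up, computed directly as
# q_(i) = min_{j >= i} p_(j) * m / j on the sorted p-values.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# AUC by explicit concordant-pair counting with half credit for ties.
auc_bruteforce <- function(scores, y01) {
  pos <- scores[y01 == 1]
  neg <- scores[y01 == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# VIP recomputed directly from a model's stored weights and explained
# y sums of squares.
vip_bruteforce <- function(model) {
  p <- nrow(model$weights)
  out <- numeric(p)
  denom <- sum(model$ssy)
  for (j in seq_len(p)) {
    acc <- 0
    for (a in seq_len(model$n_components)) {
      wa <- model$weights[, a]
      acc <- acc + model$ssy[a] * (wa[j] / sqrt(sum(wa^2)))^2
    }
    out[j] <- sqrt(p * acc / denom)
  }
  out
}

# Small two-group serum-style cohort pushed through the full simulate ->
# average -> bin -> normalize path; returns the normalized matrix, the
# sample records, and the ground-truth marker map.
sim_serum_cohort <- function(n_case = 20, n_control = 20, n_ions = 200,
                             n_scans = 2, seed = 42, ...) {
  design <- cohort_design(n_patients = 2, points_per_tissue = 1,
                          n_tnbc_serum = n_case, n_hd_serum = n_control,
                          n_ions = n_ions, seed = seed, ...)
  cohort <- generate_cohort(design)
  ser <- cohort$records[cohort$records$batch == "serum" &
                          cohort$records$specimen == "serum", ]
  specs <- lapply(seq_len(nrow(ser)), function(i) {
    average_scans(generate_scan_set(ser[i, ], design, n_scans = n_scans))
  })
  names(specs) <- ser$sample_id
  pm <- tic_normalize(bin_to_matrix(specs, samples = ser))
  list(pm = pm, records = ser, truth = cohort$truth, design = design)
}

# Hand-built marker table for join-logic tests (bypasses the cascade).
fake_marker_table <- function(metabolite, fc, q, selected = TRUE) {
  n <- length(metabolite)
  tab <- data.frame(
    feature_id = paste0("f", seq_len(n)),
    bin_mz = 100 + seq_len(n),
    polarity = "positive",
    vip = 2, p_value = q, q_value = q,
    fold_change = fc,
    direction = ifelse(fc > 1, "up", "down"),
    pass_vip = TRUE, pass_fdr = TRUE, pass_fc = TRUE,
    selected = selected,
    annotation = paste(metabolite, "[M+H]+"),
    metabolite = metabolite,
    stringsAsFactors = FALSE)
  class(tab) <- c("MarkerTable", "data.frame")
  tab
}
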