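#' Describe a synthetic fingerprinting cohort
#'
#' A `CohortDesign` fixes everything the simulator needs: cohort sizes, the
#' ion set, which ions are true markers and at what fold change, and the
#' nuisance structure (per-sample total-signal variation, multiplicative
#' noise, per-patient offsets, run-order drift, QC spacing). The defaults
#' emulate a paired tumour/adjacent-normal tissue study (40 patients, 3
#' sampling points per tissue, 240 points in all) with a serum screening
#' cohort of 242 cases and 139 healthy donors, fingerprints of 2,000 ions
#' over m/z 50-1,000, and pooled QC injections every 30 runs.
#'
#' @param n_patients number of patients contributing paired tissues.
#' @param points_per_tissue sampling points collected per tissue specimen.
#' @param n_tnbc_serum,n_hd_serum serum cohort sizes (cases, healthy donors).
#' @param n_ions number of ions per fingerprint.
#' @param mz_range numeric length-2, low and high m/z of the fingerprint.
#' @param marker_spec data frame with columns `ion` (index into the ion set),
#'   `fc` (multiplicative fold change applied to the case group, `> 0`) and
#'   `direction` (`"up"` or `"down"`, consistent with `fc`). Default: 30
#'   markers, half at fold change 4 and half at 0.25, spread over the ion set.
#' @param tic_cv coefficient of variation of the per-sample total-signal
#'   scale factor (log-normal).
#' @param noise_sd per-scan multiplicative log-normal noise sd (natural-log
#'   scale).
#' @param patient_effect_sd sd of the per-patient random offset applied to
#'   all of a patient's ions on the log scale.
#' @param qc_every run-order spacing of pooled QC injections.
#' @param drift_slope per-run multiplicative drift factor (1 = no drift).
#' @param polarity acquisition polarity recorded on every sample.
#' @param seed integer root seed; all randomness in the simulator descends
#'   from it through named substreams.
#' @return an object of class `"CohortDesign"`.
#' @seealso [generate_cohort()], [generate_scan_set()], [generate_raster()]
#' @export
cohort_design <- function(n_patients = 40L,
                          points_per_tissue = 3L,
                          n_tnbc_serum = 242L,
                          n_hd_serum = 139L,
                          n_ions = 2000L,
                          mz_range = c(50, 1000),
                          marker_spec = default_marker_spec(n_ions),
                          tic_cv = 0.2,
                          noise_sd = 0.25,
                          patient_effect_sd = 0.1,
                          qc_every = 30L,
                          drift_slope = 1.0005,
                          polarity = c("positive", "negative"),
                          seed = 1L) {
  polarity <- match.arg(polarity)
  counts <- c(n_patients = n_patients, points_per_tissue = points_per_tissue,
              n_tnbc_serum = n_tnbc_serum, n_hd_serum = n_hd_serum,
              n_ions = n_ions, qc_every = qc_every)
  if (any(counts <= 0)) stop("all design counts must be > 0")
  if (length(mz_range) != 2 || mz_range[1] >= mz_range[2]) {
    stop("mz_range must be (low, high) with low < high")
  }
  marker_spec <- validate_marker_spec(marker_spec, n_ions)
  if (tic_cv < 0 || noise_sd < 0 || patient_effect_sd < 0) {
    stop("variability parameters must be >= 0")
  }
  if (drift_slope <= 0) stop("drift_slope must be > 0")
  structure(list(
    n_patients = as.integer(n_patients),
    points_per_tissue = as.integer(points_per_tissue),
    n_tnbc_serum = as.integer(n_tnbc_serum),
    n_hd_serum = as.integer(n_hd_serum),
    n_ions = as.integer(n_ions),
    mz_range = as.numeric(mz_range),
    marker_spec = marker_spec,
    tic_cv = tic_cv,
    noise_sd = noise_sd,
    patient_effect_sd = patient_effect_sd,
    qc_every = as.integer(qc_every),
    drift_slope = drift_slope,
    polarity = polarity,
    seed = as.integer(seed)
  ), class = "CohortDesign")
}

#' Default marker specification for a synthetic cohort
#'
#' Thirty marker ions spread evenly across the ion set: half up-regulated at
#' fold change 4, half down-regulated at fold change 0.25.
#'
#' @param n_ions number of ions in the fingerprint.
#' @param n_markers number of true markers.
#' @param fc_up,fc_down fold changes for up- and down-regulated markers.
#' @return a data frame with columns `ion`, `fc`, `direction`.
#' @export
default_marker_spec <- function(n_ions, n_markers = 30L,
                                fc_up = 4, fc_down = 0.25) {
  ion <- unique(round(seq(max(1, n_ions * 0.05), n_ions * 0.95,
                          length.out = n_markers)))
  up <- seq_along(ion) %% 2L == 1L
  data.frame(ion = as.integer(ion),
             fc = ifelse(up, fc_up, fc_down),
             direction = ifelse(up, "up", "down"))
}

validate_marker_spec <- function(ms, n_ions) {
  stopifnot(is.data.frame(ms), all(c("ion", "fc", "direction") %in% names(ms)))
  if (any(ms$fc <= 0)) stop("fold change multipliers must be > 0")
  if (any(ms$ion < 1) || any(ms$ion > n_ions)) {
    stop("marker ion indices must lie within 1..n_ions")
  }
  if (anyDuplicated(ms$ion)) stop("duplicate marker ion indices")
  if (!all(ms$direction == ifelse(ms$fc > 1, "up", "down"))) {
    stop("marker direction inconsistent with fold change")
  }
  ms$ion <- as.integer(ms$ion)
  ms
}

#' @export
print.CohortDesign <- function(x, ...) {
  cat(sprintf(paste0(
    "<CohortDesign> %d patients x 2 tissues x %d points (+%d/%d serum), ",
    "%d ions m/z %.0f-%.0f, %d markers, seed %d\n"),
    x$n_patients, x$points_per_tissue, x$n_tnbc_serum, x$n_hd_serum,
    x$n_ions, x$mz_range[1], x$mz_range[2], nrow(x$marker_spec), x$seed))
  invisible(x)
}

# Fixed ion m/z positions for a design: drawn once from the "ions" substream
# on a 0.025-Da grid so that adjacent ions can never share a +/-0.005 Da bin
# even after bounded m/z jitter.
ion_positions <- function(design) {
  grid <- seq(design$mz_range[1], design$mz_range[2], by = 0.025)
  if (length(grid) < design$n_ions) {
    stop("mz_range too narrow for n_ions at 0.025 Da spacing")
  }
  with_seed(substream_seed(design$seed, "ions"),
            sort(sample(grid, design$n_ions)))
}

# Baseline (log-scale) ion abundances spanning ~3 orders of magnitude.
baseline_log_intensity <- function(design) {
  with_seed(substream_seed(design$seed, "baseline"),
            stats::runif(design$n_ions, log(1e2), log(1e5)))
}

sample_id_hash <- function(id) {
  v <- utf8ToInt(id)
  h <- 0
  for (x in v) h <- (h * 131 + x) %% 2147483647
  as.integer(h)
}

#' Generate the sample manifest for a synthetic cohort
#'
#' Builds the full run list: a tissue batch of
#' `n_patients * 2 * points_per_tissue` paired tumour (TNBC) and
#' adjacent-normal (PNT) sampling points, and a serum batch of alternating
#' TNBC-case and healthy-donor samples, with a pooled QC injection after
#' every `qc_every` study samples in each batch. Run indices are 1-based
#' positions within a batch. The returned ground truth names the marker
#' ions, their fold changes and directions.
#'
#' @param design a [cohort_design()].
#' @return a list with elements `records` (data frame: `sample_id`,
#'   `specimen`, `group`, `patient_id`, `run_index`, `batch`, `polarity`)
#'   and `truth` (list with `markers`, the design's marker data frame, and
#'   `affected_group = "TNBC"`).
#' @examples
#' design <- cohort_design(n_patients = 4, n_tnbc_serum = 6, n_hd_serum = 4,
#'                         n_ions = 50)
#' cohort <- generate_cohort(design)
#' table(cohort$records$specimen)
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "CohortDesign"))
  tissue <- expand.grid(point = seq_len(design$points_per_tissue),
                        group = c("TNBC", "PNT"),
                        patient = seq_len(design$n_patients),
                        stringsAsFactors = FALSE)
  # acquisition order: all points of a patient together, alternating groups
  tissue <- tissue[order(tissue$patient, tissue$point, tissue$group), ]
  tissue_rec <- data.frame(
    sample_id = sprintf("T%02d_%s_p%d", tissue$patient, tissue$group,
                        tissue$point),
    specimen = "tissue",
    group = tissue$group,
    patient_id = sprintf("P%02d", tissue$patient),
    stringsAsFactors = FALSE)

  n_case <- design$n_tnbc_serum
  n_hd <- design$n_hd_serum
  serum_groups <- character(n_case + n_hd)
  # cases and healthy donors alternated while both remain, then the surplus
  k <- min(n_case, n_hd)
  serum_groups[seq_len(2 * k)] <- rep(c("TNBC", "HD"), k)
  if (n_case > k) serum_groups[(2 * k + 1):(n_case + n_hd)] <- "TNBC"
  if (n_hd > k) serum_groups[(2 * k + 1):(n_case + n_hd)] <- "HD"
  serum_rec <- data.frame(
    sample_id = sprintf("S%03d_%s", seq_along(serum_groups), serum_groups),
    specimen = "serum",
    group = serum_groups,
    patient_id = "",
    stringsAsFactors = FALSE)

  records <- rbind(insert_qc(tissue_rec, "tissue", design$qc_every),
                   insert_qc(serum_rec, "serum", design$qc_every))
  records$polarity <- design$polarity
  rownames(records) <- NULL
  list(records = records,
       truth = list(markers = design$marker_spec, affected_group = "TNBC"))
}

# Insert a pooled-QC record after every `every` study samples of one batch;
# run_index is the 1-based position in the resulting sequence.
insert_qc <- function(rec, batch, every) {
  n <- nrow(rec)
  n_qc <- n %/% every
  total <- n + n_qc
  qc_pos <- (seq_len(n_qc)) * (every + 1L)  # after each block of `every`
  is_qc <- seq_len(total) %in% qc_pos
  out <- data.frame(sample_id = character(total), specimen = character(total),
                    group = character(total), patient_id = character(total),
                    run_index = seq_len(total), batch = batch,
                    stringsAsFactors = FALSE)
  if (n_qc > 0) {
    out[is_qc, c("sample_id", "specimen", "group", "patient_id")] <-
      data.frame(sample_id = sprintf("QC_%s_%02d", batch, seq_len(n_qc)),
                 specimen = "qc", group = "QC", patient_id = "",
                 stringsAsFactors = FALSE)
  }
  out[!is_qc, c("sample_id", "specimen", "group", "patient_id")] <- rec
  out
}

#' Patient-level train/test split of tissue records
#'
#' Splits the tissue sampling points by patient so that all points of a
#' patient fall on the same side, mirroring how a classifier trained on
#' some patients is evaluated on unseen ones. With the default design
#' (40 patients, 3 points per tissue) and `n_train = 25`, the split is
#' 150 training and 90 test points.
#'
#' @param records a cohort manifest from [generate_cohort()].
#' @param n_train number of patients assigned to the training side.
#' @param seed integer seed for the random patient draw.
#' @return list with `train` and `test` data frames of tissue records
#'   (QC rows excluded).
#' @export
split_by_patient <- function(records, n_train = 25L, seed = 1L) {
  tis <- records[records$specimen == "tissue", ]
  patients <- unique(tis$patient_id)
  if (n_train >= length(patients)) stop("n_train must leave test patients")
  tr <- with_seed(substream_seed(seed, "cv"),
                  sample(patients, n_train))
  list(train = tis[tis$patient_id %in% tr, ],
       test = tis[!tis$patient_id %in% tr, ])
}

#' Simulate the scan set of one sample
#'
#' Produces `n_scans` centroided scans for one manifest record. Every scan
#' contains the design's full ion set at log-normal baseline abundances;
#' marker ions are multiplied by their fold change when the record belongs
#' to the affected (TNBC) group; all ions of a patient share a log-scale
#' random offset; each scan gets independent multiplicative noise and a
#' bounded m/z jitter (+/- 0.004 Da, so a true ion never leaves its
#' +/-0.005 Da bin); the whole sample is scaled by a log-normal TIC factor
#' and by the run-order drift factor `drift_slope^run_index`. QC records
#' are the deterministic mean profile of the pooled case/control groups
#' with drift only.
#'
#' @param record one row of the manifest from [generate_cohort()] (a list
#'   or single-row data frame).
#' @param design the [cohort_design()].
#' @param n_scans number of continuous scans to simulate (the averaging
#'   convention downstream is 10).
#' @return list of `n_scans` [spectrum()] objects.
#' @export
generate_scan_set <- function(record, design, n_scans = 10L) {
  stopifnot(inherits(design, "CohortDesign"), n_scans >= 1)
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1)
    record <- as.list(record)
  }
  mz0 <- ion_positions(design)
  log_base <- baseline_log_intensity(design)

  log_int <- log_base
  is_qc <- identical(record$specimen, "qc")
  ms <- design$marker_spec
  if (is_qc) {
    # pooled profile: equal-volume mix of affected and reference groups
    mix <- rep(1, design$n_ions)
    mix[ms$ion] <- (1 + ms$fc) / 2
    log_int <- log_int + log(mix)
  } else {
    if (identical(record$group, "TNBC")) {
      log_int[ms$ion] <- log_int[ms$ion] + log(ms$fc)
    }
    if (nzchar(record$patient_id %||% "")) {
      pidx <- as.integer(sub("\\D+", "", record$patient_id))
      log_int <- log_int +
        with_seed(substream_seed(design$seed, "patient", pidx),
                  stats::rnorm(1, 0, design$patient_effect_sd))
    }
  }

  drift <- design$drift_slope^(record$run_index %||% 0)
  sseed <- substream_seed(design$seed, "sample",
                          sample_id_hash(record$sample_id))
  with_seed(sseed, {
    tic_factor <- if (is_qc || design$tic_cv == 0) 1 else {
      sdlog <- sqrt(log(1 + design$tic_cv^2))
      exp(stats::rnorm(1, -sdlog^2 / 2, sdlog))
    }
    lapply(seq_len(n_scans), function(s) {
      noise <- if (is_qc || design$noise_sd == 0) 0 else {
        stats::rnorm(design$n_ions, 0, design$noise_sd)
      }
      jit <- stats::runif(design$n_ions, -0.004, 0.004)
      spectrum(mz0 + jit,
               exp(log_int + noise) * tic_factor * drift,
               design$polarity)
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a rectangular raster of line scans
#'
#' Emulates a desorption-electrospray imaging acquisition: the probe sweeps
#' left-to-right along horizontal lines at `raster_speed`, lines are spaced
#' `line_spacing` apart, and the spectrometer acquires `scan_rate` scans
#' per second. Each scan carries a single target ion whose intensity is
#' `pattern(x, y)` evaluated at the pixel centre.
#'
#' @param width_mm,height_mm raster extent in mm.
#' @param raster_speed probe speed along a line, mm/s.
#' @param line_spacing distance between adjacent lines, mm.
#' @param scan_rate scans per second (pixel width along-track is
#'   `raster_speed / scan_rate`).
#' @param pattern function of `(x, y)` in mm returning a non-negative
#'   intensity.
#' @param target_mz m/z of the simulated target ion.
#' @param polarity acquisition polarity.
#' @return a list of scans, each a list with `line` (0-based line index),
#'   `time` (seconds since line start), and `spectrum`.
#' @examples
#' r <- generate_raster(2, 2, raster_speed = 0.2, line_spacing = 0.2,
#'                      scan_rate = 1, pattern = function(x, y) 100)
#' length(r)  # 10 lines x 10 scans
#' @export
generate_raster <- function(width_mm, height_mm, raster_speed, line_spacing,
                            scan_rate, pattern,
                            target_mz = 175.119, polarity = "positive") {
  geom <- c(width_mm, height_mm, raster_speed, line_spacing, scan_rate)
  if (any(!is.finite(geom)) || any(geom <= 0)) {
    stop("all geometric parameters must be > 0")
  }
  n_lines <- ceiling(height_mm / line_spacing)
  pixel_width <- raster_speed / scan_rate
  n_cols <- ceiling(width_mm / pixel_width)
  out <- vector("list", n_lines * n_cols)
  k <- 1L
  for (r in seq_len(n_lines) - 1L) {
    y <- (r + 0.5) * line_spacing
    for (cc in seq_len(n_cols) - 1L) {
      x <- (cc + 0.5) * pixel_width
      out[[k]] <- list(line = r,
                       time = (cc + 0.5) / scan_rate,
                       spectrum = spectrum(target_mz, pattern(x, y), polarity))
      k <- k + 1L
    }
  }
  out
}

#' Write a cohort manifest as TSV
#'
#' @param records manifest data frame from [generate_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
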