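# Mass-bin construction shared by scan averaging and matrix building:
# sorted m/z values are cut into bins wherever the gap between neighbours
# exceeds 2 x tolerance (single linkage). Deterministic and independent of
# sample order.
gap_bin_assign <- function(mz_sorted, tolerance) {
  n <- length(mz_sorted)
  if (n == 0) return(integer(0))
  cumsum(c(1L, as.integer(diff(mz_sorted) > 2 * tolerance)))
}

#' Average a set of continuous scans into one spectrum
#'
#' Peaks from all scans are pooled and clustered with the same +/-`tolerance`
#' gap rule used for matrix binning; each cluster yields one averaged peak
#' whose m/z is the intensity-weighted mean of its members and whose
#' intensity is the cluster total divided by the number of scans (a peak
#' absent from a scan counts as zero there). Averaging identical scans is
#' therefore idempotent.
#'
#' @param scans list of [spectrum()] objects, all the same polarity.
#' @param tolerance half-width in Da of the mass clustering rule.
#' @return a single [spectrum()].
#' @examples
#' s <- spectrum(c(100, 200), c(8, 2), "positive")
#' average_scans(list(s, s))  # equals s
#' @export
average_scans <- function(scans, tolerance = 0.005) {
  stopifnot(length(scans) >= 1, all(vapply(scans, inherits, TRUE, "Spectrum")))
  pol <- unique(vapply(scans, function(s) s$polarity, ""))
  if (length(pol) != 1) stop("cannot average scans of mixed polarity")
  mz <- unlist(lapply(scans, `[[`, "mz"))
  int <- unlist(lapply(scans, `[[`, "intensity"))
  if (length(mz) == 0) return(spectrum(numeric(0), numeric(0), pol))
  ord <- order(mz)
  mz <- mz[ord]; int <- int[ord]
  bin <- gap_bin_assign(mz, tolerance)
  tot <- as.vector(rowsum(int, bin))
  wmz <- as.vector(rowsum(mz * int, bin))
  cnt <- as.vector(rowsum(rep(1, length(mz)), bin))
  # intensity-weighted mean m/z; plain mean if a cluster is all-zero
  out_mz <- ifelse(tot > 0, wmz / tot, as.vector(rowsum(mz, bin)) / cnt)
  spectrum(out_mz, tot / length(scans), pol)
}

#' Construct a PeakMatrix
#'
#' Container for a samples x mass-bin intensity matrix with per-sample
#' metadata, per-bin representative m/z, and a processing-stage tag that
#' enforces the raw -> tic_normalized -> log_scaled order.
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   bins in columns.
#' @param bin_mz strictly increasing representative m/z per bin.
#' @param samples data frame of sample metadata with a `sample_id` column
#'   aligned to the rows.
#' @param stage one of `"raw"`, `"tic_normalized"`, `"log_scaled"`.
#' @param polarity polarity tag applied to bin ids.
#' @param tolerance the binning tolerance that produced the matrix (Da).
#' @return an object of class `"PeakMatrix"`.
#' @export
peak_matrix <- function(values, bin_mz, samples, stage = "raw",
                        polarity = "positive", tolerance = 0.005) {
  stopifnot(is.matrix(values), ncol(values) == length(bin_mz))
  if (length(bin_mz) > 1 && any(diff(bin_mz) <= 0)) {
    stop("bin_mz must be strictly increasing")
  }
  stopifnot(stage %in% c("raw", "tic_normalized", "log_scaled"))
  stopifnot(is.data.frame(samples), nrow(samples) == nrow(values))
  rownames(values) <- samples$sample_id
  colnames(values) <- paste0(ifelse(polarity == "positive", "P", "N"),
                             sprintf("%.4f", bin_mz))
  structure(list(values = values, bin_mz = as.numeric(bin_mz),
                 samples = samples, stage = stage, polarity = polarity,
                 tolerance = tolerance),
            class = "PeakMatrix")
}

#' @export
print.PeakMatrix <- function(x, ...) {
  cat(sprintf("<PeakMatrix> %d samples x %d bins, stage=%s, %s mode\n",
              nrow(x$values), ncol(x$values), x$stage, x$polarity))
  invisible(x)
}

#' @export
dim.PeakMatrix <- function(x) dim(x$values)

#' Bin per-sample spectra into a samples x features matrix
#'
#' All observed m/z values across samples are pooled and clustered by
#' single linkage, starting a new mass bin wherever the gap between
#' neighbouring values exceeds `2 * tolerance`; each sample's peak
#' intensities are then summed into its matching bins (absent = 0). The
#' representative m/z of a bin is the intensity-weighted mean of its
#' member peaks.
#'
#' @param spectra named list of [spectrum()] objects, names are sample ids.
#' @param tolerance mass-bin half width in Da.
#' @param samples optional data frame of sample metadata with a
#'   `sample_id` column; rows are matched (and ordered) by the names of
#'   `spectra`.
#' @return a [peak_matrix()] at stage `"raw"`.
#' @export
bin_to_matrix <- function(spectra, tolerance = 0.005, samples = NULL) {
  if (length(spectra) == 0) stop("no spectra supplied")
  stopifnot(all(vapply(spectra, inherits, TRUE, "Spectrum")))
  if (is.null(names(spectra)) || anyDuplicated(names(spectra))) {
    stop("spectra must be uniquely named by sample id")
  }
  if (tolerance <= 0) stop("tolerance must be > 0")
  pol <- unique(vapply(spectra, function(s) s$polarity, ""))
  if (length(pol) != 1) {
    stop("mixed polarity: build one matrix per mode, then merge_polarities()")
  }
  ids <- names(spectra)
  mz <- unlist(lapply(spectra, `[[`, "mz"), use.names = FALSE)
  int <- unlist(lapply(spectra, `[[`, "intensity"), use.names = FALSE)
  src <- rep(seq_along(spectra),
             vapply(spectra, function(s) length(s$mz), 0L))
  if (length(mz) == 0) stop("all spectra are empty")
  ord <- order(mz)
  mz <- mz[ord]; int <- int[ord]; src <- src[ord]
  bin <- gap_bin_assign(mz, tolerance)
  n_bins <- max(bin)
  values <- matrix(0, nrow = length(spectra), ncol = n_bins)
  # sum duplicate (sample, bin) contributions
  agg <- rowsum(int, group = paste(src, bin))
  key <- do.call(rbind, strsplit(rownames(agg), " "))
  values[cbind(as.integer(key[, 1]), as.integer(key[, 2]))] <- agg[, 1]
  tot <- as.vector(rowsum(int, bin))
  wmz <- as.vector(rowsum(mz * int, bin))
  cnt <- as.vector(rowsum(rep(1, length(mz)), bin))
  bin_mz <- ifelse(tot > 0, wmz / tot, as.vector(rowsum(mz, bin)) / cnt)
  if (is.null(samples)) {
    samples <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  } else {
    stopifnot("sample_id" %in% names(samples))
    m <- match(ids, samples$sample_id)
    if (anyNA(m)) stop("sample metadata missing ids: ",
                       paste(ids[is.na(m)], collapse = ", "))
    samples <- samples[m, , drop = FALSE]
    rownames(samples) <- NULL
  }
  peak_matrix(values, bin_mz, samples, stage = "raw", polarity = pol,
              tolerance = tolerance)
}

#' Normalize each sample to its average total ion current
#'
#' Divides every row by that sample's mean bin intensity, so each
#' normalized row has mean 1. An all-zero row is left untouched with a
#' warning. With `tic = "sum"` the divisor is the row total instead.
#'
#' @param pm a raw [peak_matrix()].
#' @param tic `"mean"` (average TIC per bin, the default) or `"sum"`.
#' @return a [peak_matrix()] at stage `"tic_normalized"`.
#' @export
tic_normalize <- function(pm, tic = c("mean", "sum")) {
  stopifnot(inherits(pm, "PeakMatrix"))
  tic <- match.arg(tic)
  if (pm$stage != "raw") stop("tic_normalize expects a raw matrix")
  div <- if (tic == "mean") rowMeans(pm$values) else rowSums(pm$values)
  zero <- div == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero sample row(s) left unnormalized")
    div[zero] <- 1
  }
  pm$values <- pm$values / div
  pm$stage <- "tic_normalized"
  pm
}

#' Natural-log transform and autoscale a normalized matrix
#'
#' Applies `ln(value + epsilon)` and then centres each mass bin at zero
#' and scales it to unit standard deviation (sample sd, `n - 1`
#' denominator). Constant bins become all-zero columns. The default
#' `epsilon` is half the smallest nonzero intensity in the matrix, which
#' keeps the log defined at zeros without distorting observed peaks.
#'
#' @param pm a [peak_matrix()] at stage `"tic_normalized"`.
#' @param epsilon intensity offset added before the log; `NULL` for the
#'   default.
#' @return a [peak_matrix()] at stage `"log_scaled"`.
#' @export
log_autoscale <- function(pm, epsilon = NULL) {
  stopifnot(inherits(pm, "PeakMatrix"))
  if (pm$stage != "tic_normalized") {
    stop("log_autoscale expects a tic_normalized matrix")
  }
  v <- pm$values
  if (any(v < 0)) stop("negative intensities cannot be log-transformed")
  if (is.null(epsilon)) {
    nz <- v[v > 0]
    epsilon <- if (length(nz)) min(nz) / 2 else 1
  }
  lv <- log(v + epsilon)
  mu <- colMeans(lv)
  sdv <- apply(lv, 2, stats::sd)
  lv <- sweep(lv, 2, mu)
  const <- sdv == 0 | !is.finite(sdv)
  sdv[const] <- 1
  lv <- sweep(lv, 2, sdv, "/")
  lv[, const] <- 0
  pm$values <- lv
  pm$stage <- "log_scaled"
  pm$epsilon <- epsilon
  pm
}

#' Column-bind positive- and negative-mode matrices
#'
#' Matrices acquired in the two polarities are built separately and then
#' concatenated feature-wise; bin ids keep their polarity prefix.
#'
#' @param pos,neg [peak_matrix()] objects over the same samples (same
#'   order), stages equal.
#' @return a combined [peak_matrix()] with `polarity = "mixed"`.
#' @export
merge_polarities <- function(pos, neg) {
  stopifnot(inherits(pos, "PeakMatrix"), inherits(neg, "PeakMatrix"))
  if (!identical(pos$samples$sample_id, neg$samples$sample_id)) {
    stop("sample sets differ between polarities")
  }
  if (!identical(pos$stage, neg$stage)) stop("stages differ")
  values <- cbind(pos$values, neg$values)
  out <- pos
  out$values <- values
  out$bin_mz <- c(pos$bin_mz, neg$bin_mz)  # not globally increasing; ids carry mode
  out$polarity <- "mixed"
  class(out) <- "PeakMatrix"
  out
}

#' QC stability report
#'
#' Computes, over the pooled-QC rows of a matrix, the per-bin relative
#' standard deviation (percent, sd/mean) and the Spearman correlation of
#' each bin's QC intensity with run order as a drift statistic.
#'
#' @param pm a [peak_matrix()] whose `samples` carry `specimen` and
#'   `run_index` columns.
#' @param rsd_threshold percent RSD below which a bin counts as stable
#'   (default 30).
#' @return list with `per_bin` (data frame: `bin`, `bin_mz`, `rsd_pct`,
#'   `drift_rho`) and `summary` (`n_qc`, `frac_stable`, `median_rsd_pct`).
#' @export
qc_report <- function(pm, rsd_threshold = 30) {
  stopifnot(inherits(pm, "PeakMatrix"))
  s <- pm$samples
  if (!all(c("specimen", "run_index") %in% names(s))) {
    stop("sample metadata must carry 'specimen' and 'run_index'")
  }
  qc <- which(s$specimen == "qc")
  if (length(qc) < 2) stop("qc_report needs at least 2 QC samples")
  q <- pm$values[qc, , drop = FALSE]
  mu <- colMeans(q)
  sdv <- apply(q, 2, stats::sd)
  rsd <- ifelse(mu > 0, 100 * sdv / mu, NA_real_)
  run <- s$run_index[qc]
  rho <- apply(q, 2, function(col) {
    if (stats::sd(col) == 0) return(0)
    stats::cor(col, run, method = "spearman")
  })
  per_bin <- data.frame(bin = colnames(pm$values), bin_mz = pm$bin_mz,
                        rsd_pct = rsd, drift_rho = rho,
                        stringsAsFactors = FALSE)
  list(per_bin = per_bin,
       summary = list(n_qc = length(qc),
                      frac_stable = mean(rsd < rsd_threshold, na.rm = TRUE),
                      median_rsd_pct = stats::median(rsd, na.rm = TRUE)))
}

#' Write a PeakMatrix as TSV with a JSON sidecar
#'
#' The TSV holds the intensity matrix (sample ids in the first column,
#' bin ids as header) at full double precision; the sidecar
#' `<path>.json` records stage, polarity, tolerance, bin m/z values and
#' the sample metadata, so [read_peak_matrix()] restores the object
#' bit-identically.
#'
#' @param pm a [peak_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_peak_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "PeakMatrix"))
  m <- pm$values
  df <- data.frame(sample_id = rownames(m),
                   apply(m, 2, function(x) sprintf("%.17g", x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(stage = pm$stage, polarity = pm$polarity,
               tolerance = pm$tolerance,
               bin_mz = sprintf("%.17g", pm$bin_mz),
               bin_id = colnames(m),
               samples = pm$samples)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a PeakMatrix written by [write_peak_matrix()]
#'
#' @param path TSV path (the `<path>.json` sidecar must sit beside it).
#' @return a [peak_matrix()].
#' @export
read_peak_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character")
  values <- vapply(df[-1], as.numeric, numeric(nrow(df)))
  if (!is.matrix(values)) values <- matrix(values, nrow = nrow(df))
  samples <- as.data.frame(meta$samples, stringsAsFactors = FALSE)
  pm <- peak_matrix(values, as.numeric(meta$bin_mz), samples,
                    stage = meta$stage, polarity = meta$polarity,
                    tolerance = meta$tolerance)
  colnames(pm$values) <- meta$bin_id
  pm
}
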