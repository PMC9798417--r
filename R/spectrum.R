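#' Construct a centroided mass spectrum
#'
#' A `Spectrum` is one scan's centroided peak list: strictly increasing
#' m/z values, non-negative intensities, and an acquisition polarity.
#'
#' @param mz numeric vector of m/z values, strictly increasing.
#' @param intensity numeric vector of peak intensities, same length,
#'   all `>= 0`.
#' @param polarity `"positive"` or `"negative"`.
#' @return an object of class `"Spectrum"`.
#' @examples
#' spectrum(c(89.0244, 175.1190), c(1200, 540), "positive")
#' @export
spectrum <- function(mz, intensity, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have the same length")
  }
  if (length(mz) > 1 && any(diff(mz) <= 0)) {
    ord <- order(mz)
    mz <- mz[ord]
    intensity <- intensity[ord]
    if (any(diff(mz) <= 0)) stop("mz values must be strictly increasing")
  }
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(mz = mz, intensity = intensity, polarity = polarity),
            class = "Spectrum")
}

#' @export
print.Spectrum <- function(x, ...) {
  cat(sprintf("<Spectrum> %d peaks, %s mode, m/z %s\n",
              length(x$mz), x$polarity,
              if (length(x$mz)) sprintf("%.4f-%.4f", min(x$mz), max(x$mz))
              else "(empty)"))
  invisible(x)
}

#' @export
length.Spectrum <- function(x) length(x$mz)

#' Read a two-column peak-list CSV as a Spectrum
#'
#' The dialect is a plain CSV with columns `mz` and `intensity` (header
#' optional; headerless files are taken as m/z, intensity in that order).
#'
#' @param path file path.
#' @param polarity acquisition polarity of the scan.
#' @return a [spectrum()].
#' @export
read_peaklist_csv <- function(path, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.csv(path, header = has_header)
  if (has_header) {
    if (!all(c("mz", "intensity") %in% names(df))) {
      stop("peak-list CSV must have columns 'mz' and 'intensity'")
    }
    spectrum(df$mz, df$intensity, polarity)
  } else {
    spectrum(df[[1]], df[[2]], polarity)
  }
}

#' Write a Spectrum as a two-column peak-list CSV
#'
#' @param x a [spectrum()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_peaklist_csv <- function(x, path) {
  stopifnot(inherits(x, "Spectrum"))
  df <- data.frame(mz = sprintf("%.17g", x$mz),
                   intensity = sprintf("%.17g", x$intensity))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read centroided scans from an mzML file
#'
#' Requires the Bioconductor package \pkg{mzR}. Each scan becomes one
#' [spectrum()]; polarity is taken from the scan header (1 = positive,
#' 0 = negative) and falls back to `default_polarity` when the file does
#' not record it.
#'
#' @param path mzML file path.
#' @param default_polarity polarity used when the header omits it.
#' @return a list of [spectrum()] objects.
#' @export
read_spectra_mzml <- function(path,
                              default_polarity = c("positive", "negative")) {
  default_polarity <- match.arg(default_polarity)
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the 'mzR' package")
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  lapply(seq_along(pk), function(i) {
    pol <- default_polarity
    if ("polarity" %in% names(hdr) && !is.na(hdr$polarity[i]) &&
        hdr$polarity[i] %in% c(0L, 1L)) {
      pol <- if (hdr$polarity[i] == 1L) "positive" else "negative"
    }
    spectrum(pk[[i]][, 1], pk[[i]][, 2], pol)
  })
}
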