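#' Reconstruct a target-ion image from raster line scans
#'
#' Maps each scan of a line-by-line raster acquisition to a pixel: the
#' row is the scan's line index and the column is
#' `floor(scan_time * raster_speed / pixel_width)`, with the pixel width
#' defaulting to the line spacing (square pixels). A pixel's intensity is
#' the sum of peak intensities within `target_mz +/- tolerance` in its
#' scan; multiple scans landing on one pixel are averaged, and pixels no
#' scan reaches stay 0. Row 0 is the first scanned line and column 0 the
#' scan start (origin top-left).
#'
#' @param raster list of scans as produced by [generate_raster()]: each a
#'   list with `line` (0-based), `time` (s) and `spectrum`.
#' @param raster_speed probe speed in mm/s.
#' @param line_spacing line spacing in mm.
#' @param target_mz m/z of the ion to image.
#' @param tolerance absolute mass window half-width in Da (default 0.01).
#' @param pixel_width along-track pixel width in mm; default
#'   `line_spacing`.
#' @return an object of class `"IonImage"`: `pixels` (rows x cols
#'   matrix), `pixel_size`, `target_mz`, `tolerance`, `origin`
#'   (`"top-left"`).
#' @export
reconstruct_image <- function(raster, raster_speed, line_spacing,
                              target_mz, tolerance = 0.01,
                              pixel_width = line_spacing) {
  if (length(raster) == 0) stop("raster is empty")
  if (raster_speed <= 0 || line_spacing <= 0 || pixel_width <= 0) {
    stop("speed and spacing must be > 0")
  }
  lines <- vapply(raster, function(s) s$line, 0)
  times <- vapply(raster, function(s) s$time, 0)
  if (any(times < 0)) stop("negative scan time")
  cols <- floor(times * raster_speed / pixel_width)
  n_rows <- max(lines) + 1L
  n_cols <- max(cols) + 1L
  total <- matrix(0, n_rows, n_cols)
  count <- matrix(0L, n_rows, n_cols)
  for (k in seq_along(raster)) {
    sp <- raster[[k]]$spectrum
    hit <- abs(sp$mz - target_mz) <= tolerance
    r <- lines[k] + 1L
    cc <- cols[k] + 1L
    total[r, cc] <- total[r, cc] + sum(sp$intensity[hit])
    count[r, cc] <- count[r, cc] + 1L
  }
  pixels <- total
  nonzero <- count > 0
  pixels[nonzero] <- total[nonzero] / count[nonzero]
  structure(list(pixels = pixels, pixel_size = pixel_width,
                 line_spacing = line_spacing, target_mz = target_mz,
                 tolerance = tolerance, origin = "top-left"),
            class = "IonImage")
}

#' @export
print.IonImage <- function(x, ...) {
  cat(sprintf(
    "<IonImage> %d x %d pixels (%.2f mm), m/z %.4f +/- %.3g Da\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$target_mz,
    x$tolerance))
  invisible(x)
}

#' Write an ion image as a TSV matrix with JSON metadata
#'
#' @param img an [reconstruct_image()] result.
#' @param path output TSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_ion_image <- function(img, path) {
  stopifnot(inherits(img, "IonImage"))
  utils::write.table(img$pixels, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(pixel_size_mm = img$pixel_size, target_mz = img$target_mz,
         tolerance_da = img$tolerance, origin = img$origin,
         rows = nrow(img$pixels), cols = ncol(img$pixels)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
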