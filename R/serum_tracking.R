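#' Track tissue-derived markers in serum
#'
#' Cross-specimen validation: the annotated tissue markers are looked up
#' in the serum marker table by metabolite id. A marker is retained when
#' its serum q-value is below `fdr`, its serum fold-change direction
#' matches the tissue direction, and the serum fold change is itself
#' beyond the `fc` / `1/fc` bounds. Ions without an annotation cannot be
#' joined and are counted as skipped.
#'
#' @param tissue,serum `MarkerTable`s annotated with
#'   [annotate_markers()] (must carry a `metabolite` column).
#' @param fdr serum significance bound (default 0.05).
#' @param fc serum fold-change bound (default 2.0).
#' @return data frame of class `"TrackedMarkers"` with one row per
#'   tissue-selected metabolite found in serum: tissue and serum fold
#'   changes and directions, serum q-value, `consistent` (directions
#'   agree and serum FC beyond bounds) and `retained` (consistent and
#'   serum q below `fdr`); attribute `n_skipped_unannotated` counts
#'   tissue survivors without an annotation.
#' @export
track_markers <- function(tissue, serum, fdr = 0.05, fc = 2.0) {
  for (tab in list(tissue, serum)) {
    if (!"metabolite" %in% names(tab)) {
      stop("marker tables must be annotated (run annotate_markers first)")
    }
  }
  tsel <- tissue[tissue$selected, , drop = FALSE]
  skipped <- sum(is.na(tsel$metabolite))
  tsel <- tsel[!is.na(tsel$metabolite), , drop = FALSE]
  sann <- serum[!is.na(serum$metabolite), , drop = FALSE]
  m <- match(tsel$metabolite, sann$metabolite)
  found <- !is.na(m)
  tsel <- tsel[found, , drop = FALSE]
  srow <- sann[m[found], , drop = FALSE]
  dir_match <- tsel$direction == srow$direction
  fc_beyond <- srow$fold_change > fc | srow$fold_change < 1 / fc
  out <- data.frame(
    metabolite = tsel$metabolite,
    tissue_fc = tsel$fold_change,
    tissue_direction = tsel$direction,
    serum_fc = srow$fold_change,
    serum_direction = srow$direction,
    serum_q = srow$q_value,
    consistent = dir_match & fc_beyond,
    retained = dir_match & fc_beyond & srow$q_value < fdr,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_skipped_unannotated") <- skipped
  class(out) <- c("TrackedMarkers", "data.frame")
  out
}

#' Single-point serum concentration estimate
#'
#' Estimates a metabolite's concentration by comparing its normalized
#' intensity in a sample with the normalized intensity produced by a
#' standard of known concentration spiked into serum:
#' `concentration = standard_concentration * sample / standard`.
#'
#' @param sample_norm_intensity normalized intensity in the sample.
#' @param standard_norm_intensity normalized intensity of the spiked
#'   standard (`> 0`).
#' @param standard_concentration spiked concentration, in micromolar.
#' @return estimated concentration in micromolar.
#' @examples
#' estimate_concentration(0.5, 1.0, 10)  # 5 uM
#' @export
estimate_concentration <- function(sample_norm_intensity,
                                   standard_norm_intensity,
                                   standard_concentration) {
  if (any(standard_norm_intensity <= 0)) {
    stop("standard intensity must be > 0")
  }
  standard_concentration * sample_norm_intensity / standard_norm_intensity
}
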