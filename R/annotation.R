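# Monoisotopic masses of the supported elements (Da) and the electron mass.
# Singly charged adduct m/z values are ion masses, i.e. neutral sums
# corrected by the electron carried away (positive mode) or gained
# (negative mode).
.element_masses <- c(
  C = 12, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
  P = 30.97376151, S = 31.97207069, Cl = 34.96885268,
  Na = 22.98976928, K = 38.96370668
)
.electron_mass <- 0.00054857990907

#' Parse a molecular formula into element counts
#'
#' Supports the elements C, H, N, O, P, S, Cl, Na, K with optional counts
#' (`C6H12O6`, `C3H8NO6P`).
#'
#' @param formula formula string.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  parts <- parts[nzchar(parts)]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("unparsable formula: ", formula)
  }
  el <- sub("[0-9]*$", "", parts)
  ct <- as.integer(ifelse(grepl("[0-9]+$", parts),
                          sub("^[A-Za-z]+", "", parts), "1"))
  bad <- setdiff(el, names(.element_masses))
  if (length(bad)) stop("unknown element symbol(s): ",
                        paste(bad, collapse = ", "))
  counts <- tapply(ct, el, sum)
  out <- stats::setNames(as.integer(counts), names(counts))
  out
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula formula string or parsed element-count vector.
#' @return mass in Da.
#' @examples
#' monoisotopic_mass("C6H12O6")  # 180.0634
#' @export
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  sum(.element_masses[names(counts)] * counts)
}

#' Supported adduct rules
#'
#' The singly charged adducts considered for annotation, in the priority
#' order used for tie-breaking: positive mode `[M+H]+`, `[M+Na]+`,
#' `[M+K]+`, `[M-H2O+H]+`, `[M+2Na-H]+`, `[M+2K-H]+`, `[M+NH4]+`;
#' negative mode `[M-H]-`, `[M+Na-2H]-`, `[M+K-2H]-`, `[M+Cl]-`. Mass
#' deltas are computed from the element masses with electron correction
#' (e.g. the proton is 1.007276 Da).
#'
#' @return data frame with columns `label`, `polarity`, `delta` (Da),
#'   `priority`.
#' @export
adduct_rules <- function() {
  em <- .element_masses
  e <- .electron_mass
  pos <- data.frame(
    label = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M-H2O+H]+", "[M+2Na-H]+",
              "[M+2K-H]+", "[M+NH4]+"),
    polarity = "positive",
    delta = c(em["H"] - e,
              em["Na"] - e,
              em["K"] - e,
              -(2 * em["H"] + em["O"]) + em["H"] - e,
              2 * em["Na"] - em["H"] - e,
              2 * em["K"] - em["H"] - e,
              em["N"] + 4 * em["H"] - e),
    stringsAsFactors = FALSE)
  neg <- data.frame(
    label = c("[M-H]-", "[M+Na-2H]-", "[M+K-2H]-", "[M+Cl]-"),
    polarity = "negative",
    delta = c(-em["H"] + e,
              em["Na"] - 2 * em["H"] + e,
              em["K"] - 2 * em["H"] + e,
              em["Cl"] + e),
    stringsAsFactors = FALSE)
  out <- rbind(pos, neg)
  out$priority <- stats::ave(seq_len(nrow(out)), out$polarity,
                             FUN = seq_along)
  rownames(out) <- NULL
  out
}

#' Theoretical m/z of an adduct ion
#'
#' Sums the monoisotopic element masses of the neutral formula and applies
#' the adduct's mass delta (which includes the electron-mass correction).
#'
#' @param formula molecular formula of the neutral metabolite.
#' @param adduct adduct label (see [adduct_rules()]) or one row of the
#'   rules table.
#' @return theoretical m/z in Da.
#' @examples
#' theoretical_mz("C6H14N4O2", "[M+H]+")  # arginine, 175.1190
#' theoretical_mz("C6H12O6", "[M+K]+")    # glucose,  219.0265
#' @export
theoretical_mz <- function(formula, adduct) {
  if (is.character(adduct)) {
    rules <- adduct_rules()
    row <- rules[rules$label == adduct, ]
    if (nrow(row) != 1) stop("unknown adduct label: ", adduct)
    adduct <- row
  }
  mass <- monoisotopic_mass(formula)
  mz <- mass + adduct$delta
  if (mz <= 0) stop("adduct delta exceeds the neutral mass")
  unname(mz)
}

#' Load a metabolite reference table
#'
#' Reads a TSV with columns `name`, `formula`, `human` (logical flag for a
#' reported presence in humans). The package ships a small table of
#' metabolites recurrent in tissue/serum fingerprinting studies under
#' `system.file("extdata", "metabolites.tsv", package = "metafinger")`.
#'
#' @param path TSV path; default the bundled table.
#' @return data frame with `name`, `formula`, `human`, `monoisotopic_mass`.
#' @export
load_metabolite_db <- function(path = system.file("extdata",
                                                  "metabolites.tsv",
                                                  package = "metafinger")) {
  db <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  stopifnot(all(c("name", "formula", "human") %in% names(db)))
  db$human <- as.logical(db$human)
  db$monoisotopic_mass <- vapply(db$formula, monoisotopic_mass, 0)
  rownames(db) <- NULL
  db
}

#' Annotate one observed ion against a metabolite database
#'
#' Enumerates every (metabolite, polarity-eligible adduct) pair, keeps the
#' pairs whose theoretical m/z lies within `tolerance_ppm` of the observed
#' value, drops metabolites without a reported human presence, and sorts
#' by absolute ppm error (ties broken by adduct priority).
#'
#' @param observed_mz observed ion m/z.
#' @param polarity `"positive"` or `"negative"`.
#' @param db metabolite table from [load_metabolite_db()].
#' @param tolerance_ppm mass tolerance in ppm (default 5.0).
#' @return data frame of candidates: `name`, `formula`, `adduct`,
#'   `theoretical_mz`, `ppm_error` (may have zero rows).
#' @export
annotate_ion <- function(observed_mz, polarity = c("positive", "negative"),
                         db, tolerance_ppm = 5.0) {
  polarity <- match.arg(polarity)
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be > 0")
  empty <- data.frame(name = character(0), formula = character(0),
                      adduct = character(0), theoretical_mz = numeric(0),
                      ppm_error = numeric(0), stringsAsFactors = FALSE)
  if (is.null(db) || nrow(db) == 0) return(empty)
  db <- db[db$human, , drop = FALSE]
  if (nrow(db) == 0) return(empty)
  if (is.null(db$monoisotopic_mass)) {
    db$monoisotopic_mass <- vapply(db$formula, monoisotopic_mass, 0)
  }
  rules <- adduct_rules()
  rules <- rules[rules$polarity == polarity, ]
  grid <- expand.grid(i = seq_len(nrow(db)), j = seq_len(nrow(rules)))
  theo <- db$monoisotopic_mass[grid$i] + rules$delta[grid$j]
  ppm <- (observed_mz - theo) / theo * 1e6
  keep <- abs(ppm) <= tolerance_ppm & theo > 0
  if (!any(keep)) return(empty)
  out <- data.frame(name = db$name[grid$i[keep]],
                    formula = db$formula[grid$i[keep]],
                    adduct = rules$label[grid$j[keep]],
                    theoretical_mz = theo[keep],
                    ppm_error = ppm[keep],
                    priority = rules$priority[grid$j[keep]],
                    stringsAsFactors = FALSE)
  out <- out[order(abs(out$ppm_error), out$priority), ]
  out$priority <- NULL
  rownames(out) <- NULL
  out
}

#' First-order isotope-ratio plausibility check
#'
#' The expected first-isotope ratio (M+1 over M) of a formula is
#' approximated from natural isotope abundances as
#' `nC * 0.0107/0.9893 + nH * 0.000115 + nN * 0.00364` (carbon-13
#' dominates; deuterium and nitrogen-15 are small corrections). A
#' candidate passes when the observed ratio is within
#' `rel_tolerance * expected` of the expectation.
#'
#' @param formula candidate molecular formula.
#' @param observed_ratio observed M+1/M intensity ratio (`>= 0`).
#' @param rel_tolerance relative tolerance (default 0.3).
#' @return list with `pass` (logical), `expected`, `observed`.
#' @export
isotope_check <- function(formula, observed_ratio, rel_tolerance = 0.3) {
  if (is.null(formula) || is.na(formula) || !nzchar(formula)) {
    stop("candidate has no molecular formula")
  }
  if (observed_ratio < 0) stop("observed isotope ratio must be >= 0")
  counts <- parse_formula(formula)
  getc <- function(e) if (e %in% names(counts)) counts[[e]] else 0L
  expected <- getc("C") * 0.0107 / 0.9893 +
    getc("H") * 0.000115 + getc("N") * 0.00364
  pass <- abs(observed_ratio - expected) <= rel_tolerance * expected
  list(pass = pass, expected = expected, observed = observed_ratio)
}

#' Annotate the selected rows of a marker table
#'
#' Runs [annotate_ion()] on each cascade survivor and records the top
#' candidate as `"name adduct"` in the `annotation` column, plus the bare
#' metabolite name in a `metabolite` column (used by the serum-tracking
#' join). Non-survivors keep `NA`.
#'
#' @param markers a `MarkerTable` from [select_markers()] with a `bin_mz`
#'   column.
#' @param db metabolite table from [load_metabolite_db()].
#' @param tolerance_ppm ppm tolerance (default 5.0).
#' @return the marker table with `annotation` and `metabolite` filled in.
#' @export
annotate_markers <- function(markers, db, tolerance_ppm = 5.0) {
  stopifnot(inherits(markers, "MarkerTable"), "bin_mz" %in% names(markers))
  markers$metabolite <- NA_character_
  for (i in which(markers$selected)) {
    cand <- annotate_ion(markers$bin_mz[i], markers$polarity[i], db,
                         tolerance_ppm)
    if (nrow(cand)) {
      markers$annotation[i] <- paste(cand$name[1], cand$adduct[1])
      markers$metabolite[i] <- cand$name[1]
    }
  }
  markers
}
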