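# Deterministic substream seeding: one root seed fans out to named stages so
# that, e.g., ion-position generation is reproducible independently of how
# many samples were simulated before it.

.stage_offsets <- c(
  ions        = 101L,
  baseline    = 211L,
  cohort      = 307L,
  patient     = 401L,
  sample      = 503L,
  scan        = 601L,
  raster      = 701L,
  cv          = 809L,
  bootstrap   = 907L
)

#' Derive a reproducible substream seed
#'
#' Maps a root seed, a named stage, and an integer index to a seed in
#' `[0, 2^31 - 2]`. Used internally so each simulated sample (or fold,
#' or bootstrap replicate) has its own deterministic stream.
#'
#' @param seed integer root seed.
#' @param stage one of the named stages (e.g. `"sample"`, `"cv"`).
#' @param index non-negative integer distinguishing draws within a stage.
#' @return an integer seed.
#' @keywords internal
substream_seed <- function(seed, stage, index = 0L) {
  stopifnot(stage %in% names(.stage_offsets))
  off <- .stage_offsets[[stage]]
  # affine hash mod a Mersenne prime keeps results in 32-bit integer range
  m <- 2147483647
  x <- (as.double(seed) %% m)
  x <- (x * 48271 + off) %% m
  x <- (x * 48271 + as.double(index)) %% m
  as.integer(x)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
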