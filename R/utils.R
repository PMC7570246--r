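#' Round half away from zero
#'
#' Display rounding used throughout the package for methylation-rate tables:
#' ties go up in magnitude (58.695 -> 58.70), unlike [base::round()]'s
#' round-half-even. Internal computations always keep full precision; this is
#' applied only when values are reported.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # snap to 9 decimals first so binary representation error just below a
  # .5 boundary (e.g. 16.455 stored as 16.4549999...) does not flip the tie
  sign(x) * floor(round(abs(x) * p, 9) + 0.5) / p
}

# Derive a per-stage seed from the pipeline's global seed. The derivation
# depends only on (seed, stage name), so adding a stage never perturbs the
# randomness of existing stages. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  ch <- utf8ToInt(stage)
  h <- sum(ch * seq_along(ch))
  as.integer((as.numeric(seed) %% 65521 * 48271 + h * 7919 + 1) %% 2147483647)
}

# Sniff the field delimiter of a delimited text file (comma default,
# tab auto-detected).
sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) >
      lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

`%||%` <- function(a, b) if (is.null(a)) b else a
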