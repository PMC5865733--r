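#' Round half away from zero
#'
#' Rounds to `digits` decimal places with exact halves moved away from zero,
#' the convention used for all reported RPKM, TE and region-ratio values.
#' Base R's `round()` rounds halves to even, which disagrees with how the
#' reported tables were produced (e.g. 0.125 must print as 0.13, not 0.12).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return numeric vector rounded half-away-from-zero.
#' @export
#' @examples
#' round_half_up(0.125, 2)  # 0.13
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Format a numeric value with two decimals
#'
#' Reporting-layer formatter: half-away-from-zero rounding, fixed two
#' decimal places, as printed in all result tables.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return character vector.
#' @export
format_2dp <- function(x, digits = 2) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

#' Strip the splice-variant suffix from a transcript identifier
#'
#' Transcript models are identified as `<gene>.<n>` where the terminal
#' dot-number indexes the splice variant (e.g. `Glyma.06G324400.2`).
#' The gene identifier is the transcript identifier with that terminal
#' suffix removed. Identifiers without a terminal `.<number>` are passed
#' through unchanged with a warning.
#'
#' @param transcript_id character vector of transcript identifiers.
#' @param warn warn on identifiers lacking a variant suffix (default TRUE).
#' @return character vector of gene identifiers.
#' @export
#' @examples
#' gene_id_of("Glyma.06G324400.2")  # "Glyma.06G324400"
gene_id_of <- function(transcript_id, warn = TRUE) {
  has_suffix <- grepl("\\.[0-9]+$", transcript_id)
  if (warn && any(!has_suffix)) {
    warning(sum(!has_suffix),
            " identifier(s) lack a terminal splice-variant suffix; passed through verbatim")
  }
  out <- transcript_id
  out[has_suffix] <- sub("\\.[0-9]+$", "", transcript_id[has_suffix])
  out
}

# the k-mer index uses data.table keyed-join syntax internally
.datatable.aware <- TRUE

# deterministic small-integer sub-seed for a library, kept well below 2^31
.library_seed <- function(seed, stage_index, type, replicate) {
  (as.integer(seed) %% 1000000L) * 2000L +
    stage_index * 101L + (type == "FP") * 13L + replicate * 7L
}
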