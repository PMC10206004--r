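# MoCA -> MMSE crosswalk. The bundled table is a synthetic, monotone
# equipercentile-style crosswalk standing in for a published conversion
# table (see inst/extdata/moca_mmse_crosswalk_synthetic.csv); it preserves
# the structural properties scoring relies on: both endpoints map to
# themselves and the mapping is non-decreasing, with MoCA reading lower
# than MMSE through the middle of the range.

.crosswalk_env <- new.env(parent = emptyenv())

moca_crosswalk <- function() {
  if (is.null(.crosswalk_env$tab)) {
    path <- system.file("extdata", "moca_mmse_crosswalk_synthetic.csv",
                        package = "notescore")
    tab <- utils::read.csv(path)
    stopifnot(identical(tab$moca, 0:30), all(diff(tab$mmse) >= 0))
    .crosswalk_env$tab <- tab
  }
  .crosswalk_env$tab
}

#' Convert a MoCA raw score to its MMSE equivalent
#'
#' Looks the score up in the bundled crosswalk table. MMSE scores pass
#' through [mmse_equivalent()] unchanged.
#'
#' @param raw integer MoCA score, 0-30
#' @return integer MMSE equivalent
#' @examples
#' convert_moca_to_mmse(30)  # 30: ceiling maps to ceiling
#' @export
convert_moca_to_mmse <- function(raw) {
  if (any(is.na(raw)) || any(raw < 0 | raw > 30) || any(raw != floor(raw))) {
    stop_contract("MoCA raw score must be an integer in 0-30")
  }
  tab <- moca_crosswalk()
  tab$mmse[match(raw, tab$moca)]
}

#' MMSE-equivalent score for a cognitive assessment record
#'
#' @param instrument `"MMSE"` or `"MoCA"` (vectorized)
#' @param raw_score integer raw score, 0-30
#' @return integer MMSE-equivalent scores
#' @export
mmse_equivalent <- function(instrument, raw_score) {
  if (any(!instrument %in% c("MMSE", "MoCA"))) {
    stop_contract("instrument must be MMSE or MoCA")
  }
  if (any(is.na(raw_score)) || any(raw_score < 0 | raw_score > 30)) {
    stop_contract("raw score must be in 0-30")
  }
  out <- as.integer(raw_score)
  is_moca <- instrument == "MoCA"
  if (any(is_moca)) out[is_moca] <- convert_moca_to_mmse(raw_score[is_moca])
  out
}
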