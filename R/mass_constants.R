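#' Monoisotopic isotope masses used by the dimethyl channel arithmetic
#'
#' Monoisotopic masses in Dalton for the atoms involved in dimethyl
#' labeling chemistry, pinned in the package so the channel mass
#' arithmetic does not depend on any external library's element tables.
#'
#' @return Named numeric vector with elements `H`, `D` (deuterium, 2H),
#'   `C12`, `C13`, `N`, `O`, each in Da to at least 6 decimals.
#' @examples
#' isotope_table()[["D"]] - isotope_table()[["H"]]
#' @export
isotope_table <- function() {
  c(
    H   = 1.0078250319,
    D   = 2.0141017781,
    C12 = 12.0000000000,
    C13 = 13.0033548378,
    N   = 14.0030740052,
    O   = 15.9949146221
  )
}

#' Dimethyl multiplexing channel mass shifts
#'
#' Mass arithmetic of the three-plex dimethyl labeling scheme used for
#' multiplexed DIA (mDIA). The reference channel Delta0 carries light
#' dimethylation of the peptide N-terminus or lysine: an addition of
#' C2H4 from two rounds of reductive methylation with CH2O/NaBH3CN.
#' The Delta4 channel uses CD2O and is spaced `4 * (m(D) - m(H))` from
#' Delta0; the Delta8 channel uses 13CD2O with NaBD3CN and is spaced
#' `2 * (m(13C) - m(12C)) + 6 * (m(D) - m(H))`.
#'
#' @param channel One of 0, 4 or 8. Channel 0 returns the absolute
#'   fixed-modification mass of light dimethylation; channels 4 and 8
#'   return their spacing from channel 0.
#' @param digits Decimals used for the `display` element (default 4,
#'   the precision at which these values are conventionally printed).
#' @return A list with `channel`, `mass_da` (full precision) and
#'   `display` (rounded to `digits`).
#' @examples
#' dimethyl_shift(0)$display  # 28.0313
#' dimethyl_shift(4)$display  # 4.0251
#' dimethyl_shift(8)$display  # 8.0444
#' @export
dimethyl_shift <- function(channel, digits = 4) {
  if (length(channel) != 1L || !channel %in% c(0, 4, 8)) {
    stop("`channel` must be one of 0, 4, 8", call. = FALSE)
  }
  m <- isotope_table()
  dH <- m[["D"]] - m[["H"]]
  dC <- m[["C13"]] - m[["C12"]]
  mass <- switch(as.character(channel),
    "0" = 2 * m[["C12"]] + 4 * m[["H"]],
    "4" = 4 * dH,
    "8" = 2 * dC + 6 * dH
  )
  list(channel = channel, mass_da = mass, display = round(mass, digits))
}

#' All three dimethyl channel masses at display precision
#'
#' @return Named numeric vector `c(delta0=, delta4=, delta8=)` rounded
#'   to 4 decimals: the fixed-modification mass and the two channel
#'   spacings.
#' @export
dimethyl_channel_masses <- function() {
  c(
    delta0 = dimethyl_shift(0)$display,
    delta4 = dimethyl_shift(4)$display,
    delta8 = dimethyl_shift(8)$display
  )
}
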