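# Default C-H stretching sub-band windows (cm^-1). The lipid-weighted and
# protein-weighted windows overlap by 5 cm^-1 (2930-2935), reproduced as
# published rather than "fixed". The full-range window covers both
# sub-bands plus a margin.
CH_NEGATIVE_WINDOW <- c(2800, 2935)
CH_POSITIVE_WINDOW <- c(2930, 3010)
CH_FULL_WINDOW <- c(2800, 3030)

#' Lipid-weighted C-H "negative image" of a cell scan
#'
#' Maps the chord-baselined intensity of the 2800-2935 cm^-1 part of the
#' C-H stretching band, dominated by the lipid CH2 signal. The nucleus
#' contains very few lipids and appears dark with high contrast, hence
#' "negative image". The chord baseline guards the map against broadband
#' NV photoluminescence cross-talk.
#'
#' @param cube A [hyper_cube()] whose axis covers the window.
#' @param window Override of the sub-band window (cm^-1).
#' @return An [intensity_map()].
#' @export
negative_image <- function(cube, window = CH_NEGATIVE_WINDOW) {
  band_map(cube, window, baseline = "linear_endpoints")
}

#' Protein-weighted C-H "positive image" of a cell scan
#'
#' Maps the 2930-3010 cm^-1 part of the C-H stretching band, dominated by
#' the protein (and compact DNA) signal. The nucleus appears bright; since
#' protein signal is relatively high everywhere in the cell, the contrast
#' is lower than in the negative image.
#'
#' @inheritParams negative_image
#' @return An [intensity_map()].
#' @export
positive_image <- function(cube, window = CH_POSITIVE_WINDOW) {
  band_map(cube, window, baseline = "linear_endpoints")
}

#' Full-range C-H stretching band intensity map
#'
#' Standard full-band C-H mapping over 2800-3030 cm^-1 (chord-baselined),
#' the conventional cell image that does not differentiate the nucleus.
#'
#' @inheritParams negative_image
#' @return An [intensity_map()].
#' @export
full_ch_image <- function(cube, window = CH_FULL_WINDOW) {
  band_map(cube, window, baseline = "linear_endpoints")
}
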