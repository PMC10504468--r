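# Hue mapping of base pairs by imaginary center.

#' Hue for an imaginary center
#'
#' Maps the imaginary center c of a base pair to a hue (degrees on the
#' standard 360-degree color circle):
#'
#'     H(c) = (floor(c / 9) + 160 * c) mod 360
#'
#' Because centers are half-integers, consecutive centers advance the hue by
#' 80 degrees (plus the occasional 1-degree offset from the floor term), so
#' even the smallest center shift of 0.5 -- a 1-nt bulge between two helices
#' -- produces clearly distinct colors. The term `160 * c mod 360` cycles
#' through nine base hues (multiples of 40 degrees); the slowly growing
#' `floor(c / 9)` offset term detunes successive traversals of that cycle.
#'
#' @param c Imaginary center(s); positive half-integers (the smallest pair
#'   (1, 2) has c = 1.5).
#' @return Hue(s) in degrees, in `[0, 360)`.
#' @examples
#' hue_for_center(c(1.5, 2.0)) # 240, 320: one 80-degree step
#' @export
hue_for_center <- function(c) {
  if (!is.numeric(c) || any(!is.finite(c)) || any(c <= 0))
    stop("`c` must be positive and finite", call. = FALSE)
  (floor(c / 9) + 160 * c) %% 360
}

#' Default color of unpaired nucleotides
#' @return A hex color string.
#' @export
unpaired_color <- function() "#B0B0B0"

.hue_to_hex <- function(hue) {
  grDevices::hsv(h = (hue %% 360) / 360, s = 0.75, v = 0.88)
}

#' Per-nucleotide colors of a structure
#'
#' Both nucleotides of a base pair receive the pair's hue (rendered at fixed
#' saturation and value), so helices read as blocks of one color and pairs
#' with equal imaginary centers -- e.g. two perfectly aligned helices --
#' share a color across the whole figure. Unpaired positions get a neutral
#' gray.
#'
#' @param pt A `pair_table`.
#' @param unpaired Hex color used for unpaired positions.
#' @return A character vector of hex colors, one per position, with the
#'   numeric hue per position (`NA` where unpaired) in attribute `"hue"`.
#' @export
nucleotide_colors <- function(pt, unpaired = unpaired_color()) {
  stopifnot(inherits(pt, "pair_table"))
  cols <- rep(unpaired, pt$n)
  hues <- rep(NA_real_, pt$n)
  pr <- base_pairs(pt)
  if (nrow(pr)) {
    h <- hue_for_center(pr$center)
    hex <- .hue_to_hex(h)
    cols[pr$i] <- hex
    cols[pr$j] <- hex
    hues[pr$i] <- h
    hues[pr$j] <- h
  }
  attr(cols, "hue") <- hues
  cols
}
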