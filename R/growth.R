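#' Daily body-mass growth from feed intake
#'
#' Growth is driven purely by ingested feed through the feed conversion
#' efficiency: `W' = W + FCE * S`.  There is no maintenance or metabolic
#' loss term, so mass is non-decreasing; this is a deliberate model
#' limitation (see the methods vignette).
#'
#' @param mass Body mass, grams (vectorized).
#' @param intake Feed ingested over the day, grams.
#' @param fce Feed conversion efficiency (default 1: 1 g feed -> 1 g mass).
#' @return Updated mass, grams.
#' @export
#' @examples
#' daily_growth(38.53, 1.0)  # 39.53
daily_growth <- function(mass, intake, fce = 1.0) {
  stopifnot(all(intake >= 0), fce > 0)
  mass + intake * fce
}

#' Total length from body mass (allometric inverse)
#'
#' Inverts the length-mass allometry `W = a * TL^b`: `TL = (W / a)^(1/b)`.
#' The fitted coefficients are for mass in grams and length in
#' centimetres (a 38.53 g fish is 14.08 cm).
#'
#' @param mass Body mass, grams (vectorized).
#' @param a,b Allometric coefficients (defaults fitted for rainbow trout).
#' @return Total length in centimetres.
#' @export
length_from_mass <- function(mass, a = 0.0209, b = 2.843) {
  stopifnot(all(mass > 0), a > 0, b > 0)
  (mass / a)^(1 / b)
}

#' Body mass from total length
#'
#' Forward allometry `W = a * TL^b` (grams from centimetres); exact
#' inverse of [length_from_mass()].
#'
#' @param tl_cm Total length, centimetres.
#' @inheritParams length_from_mass
#' @return Body mass in grams.
#' @export
mass_from_length <- function(tl_cm, a = 0.0209, b = 2.843) {
  stopifnot(all(tl_cm > 0), a > 0, b > 0)
  a * tl_cm^b
}

#' Daily satiation cap
#'
#' The maximum feed a fish will ingest in one day, a fixed fraction of its
#' body mass (default 4%).  Once intake reaches this cap the fish drops to
#' standard swimming mode and ignores remaining feed.  The same linear
#' operator doubles as the daily-ration rule when applied to school
#' biomass with the ration fraction.
#'
#' @param mass Body mass, grams (vectorized).
#' @param fraction Fraction of body mass (default 0.04).
#' @return Satiation cap in grams of feed.
#' @export
#' @examples
#' smax_intake(38.53)  # 1.5412
smax_intake <- function(mass, fraction = 0.04) {
  stopifnot(all(mass >= 0), fraction > 0)
  fraction * mass
}
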