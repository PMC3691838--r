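#' Corneal-surface isodose fractions of the plaque base dose
#'
#' Fixed fractions of the prescribed tumour-base dose reaching the corneal
#' surface in each zone, from the published Ru-106 plaque isodose
#' simulation: 0.44\% directly adjacent to the plaque, 0.12\% in the
#' central third, 0.015\% in the distal third. These are constants of the
#' published plaque geometry; full beta-dosimetry modelling is out of
#' scope.
#'
#' @return named numeric vector (adjacent, central, distal), strictly
#'   decreasing.
#' @export
zoneFractions <- function()
  c(adjacent = 0.0044, central = 0.0012, distal = 0.00015)

#' Per-zone corneal surface doses from the prescribed base dose
#'
#' Zone dose = prescribed dose x zone fraction, rounded to 2 decimal
#' places half away from zero. Linear in the prescribed dose before
#' rounding; calculated doses decrease strictly from the adjacent to the
#' distal zone.
#'
#' @param prescribedGy dose to the tumour base in the applicator zone, Gy
#'   (> 0; vectorised).
#' @param fractions zone fractions, see \code{\link{zoneFractions}}.
#' @return data.frame: prescribed_gy, adjacent_gy, central_gy, distal_gy.
#' @export
calculatedDoses <- function(prescribedGy, fractions = zoneFractions()) {
  if (any(!is.finite(prescribedGy)) || any(prescribedGy <= 0))
    stop("prescribed dose must be positive")
  stopifnot(all(diff(fractions) < 0), all(fractions > 0), all(fractions < 1))
  data.frame(
    prescribed_gy = prescribedGy,
    adjacent_gy = roundHalfAway(prescribedGy * fractions[["adjacent"]], 2),
    central_gy = roundHalfAway(prescribedGy * fractions[["central"]], 2),
    distal_gy = roundHalfAway(prescribedGy * fractions[["distal"]], 2))
}

#' Treatment duration from prescribed dose and dose rate
#'
#' @param prescribedGy dose to the tumour base, Gy (> 0).
#' @param doseRateGyPerH applicator-zone dose rate, Gy/h (> 0).
#' @return hours, rounded to 2 decimal places half away from zero.
#' @export
treatmentDurationHours <- function(prescribedGy, doseRateGyPerH) {
  if (any(!is.finite(doseRateGyPerH)) || any(doseRateGyPerH <= 0))
    stop("dose rate must be positive")
  if (any(!is.finite(prescribedGy)) || any(prescribedGy <= 0))
    stop("prescribed dose must be positive")
  roundHalfAway(prescribedGy / doseRateGyPerH, 2)
}
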