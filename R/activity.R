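#' Volumetric enzyme activity from a chromogenic assay reading
#'
#' Activity in U L^-1 from the absorbance change of substrate oxidation
#' (e.g. ABTS at 420 nm for laccases):
#'
#'   U L^-1 = (dA * V_t * 1e6) / (epsilon * d * V_s)
#'
#' One unit (U) transforms 1 umol of substrate per minute per litre. With
#' the extinction coefficient in M^-1 cm^-1, dA/(epsilon d) is a molar rate;
#' the 1e6 factor converts mol to umol so the result lands on the U L^-1
#' scale. V_t / V_s corrects for the dilution of the sample in the cuvette
#' (both in the same volume unit).
#'
#' @param delta_abs Absorbance change per minute (AU min^-1), >= 0.
#' @param V_t Total reaction volume (mL), positive.
#' @param V_s Sample volume in the reaction (mL), positive.
#' @param epsilon Molar extinction coefficient (M^-1 cm^-1), positive.
#'   The default 36000 is the widely used ABTS radical-cation coefficient at
#'   420 nm; it is an external constant and should be set to the value
#'   calibrated for the assay at hand.
#' @param path Cuvette path length (cm), positive; default 1.
#' @return Activity in U L^-1 (vectorized).
#' @examples
#' volumetric_activity(0.36, V_t = 1, V_s = 0.02) # 500 U/L
#' @export
volumetric_activity <- function(delta_abs, V_t, V_s, epsilon = 36000,
                                path = 1) {
  if (any(epsilon <= 0)) stop("'epsilon' must be positive")
  if (any(path <= 0)) stop("'path' must be positive")
  if (any(V_t <= 0) || any(V_s <= 0)) stop("volumes must be positive")
  if (any(delta_abs < 0)) stop("'delta_abs' must be non-negative")
  (delta_abs * V_t * 1e6) / (epsilon * path * V_s)
}

#' Relative enzyme activity
#'
#' Percentage of activity recovered relative to the initial activity
#' (100%). Values above 100 are legitimate (apparent activation during
#' storage is occasionally observed) and are not clamped.
#'
#' @param E Measured activity (U L^-1).
#' @param E0 Initial activity (U L^-1), positive.
#' @return Relative activity in percent (vectorized).
#' @examples
#' relative_activity(8287.75, 16575.50) # 50
#' @export
relative_activity <- function(E, E0) {
  if (any(E0 <= 0)) stop("'E0' must be positive")
  if (any(E < 0)) stop("'E' must be non-negative")
  100 * E / E0
}

#' Specific enzyme activity
#'
#' Activity per milligram of protein, U mg^-1.
#'
#' @param activity Volumetric activity (U L^-1), >= 0.
#' @param protein Protein concentration (mg L^-1), positive.
#' @return Specific activity in U mg^-1 (vectorized).
#' @examples
#' specific_activity(16575.50, 21.847) # ~758.7 U/mg
#' @export
specific_activity <- function(activity, protein) {
  if (any(protein <= 0)) stop("'protein' must be positive")
  if (any(activity < 0)) stop("'activity' must be non-negative")
  activity / protein
}
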