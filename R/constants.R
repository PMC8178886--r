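#' Physical constants for deactivation thermodynamics
#'
#' Returns the gas constant, Planck constant and Boltzmann constant used by
#' the Eyring-type expressions in [gibbs()] and [thermo_table()].
#'
#' The default `"pinned"` set uses the truncated precision conventional in
#' accelerated-stability reports (R = 8.314 J mol^-1 K^-1,
#' h = 6.626e-34 J s, k_b = 1.38e-23 J K^-1), which keeps derived tables
#' bit-stable against hand calculation at that precision. `"codata"`
#' switches to full-precision CODATA 2018 values.
#'
#' @param mode `"pinned"` (default) or `"codata"`.
#' @return A list with elements `R` (J mol^-1 K^-1), `h` (J s),
#'   `k_b` (J K^-1) and `mode`.
#' @examples
#' physical_constants()$R
#' @export
physical_constants <- function(mode = c("pinned", "codata")) {
  mode <- match.arg(mode)
  if (mode == "pinned") {
    list(R = 8.314, h = 6.626e-34, k_b = 1.38e-23, mode = mode)
  } else {
    list(R = 8.31446261815324, h = 6.62607015e-34, k_b = 1.380649e-23,
         mode = mode)
  }
}

# days per month used for any month <-> second conversion (30 calendar days)
DAYS_PER_MONTH <- 30
SECONDS_PER_MONTH <- DAYS_PER_MONTH * 24 * 3600
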