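#' Fit a first-order deactivation constant from one storage isotherm
#'
#' Ordinary least squares of ln(E/E0) on storage time. Under first-order
#' deactivation E(t) = E0 exp(-k_d t), so the slope magnitude is the
#' deactivation rate constant k_d.
#'
#' The regression includes a free intercept by default: the initial activity
#' is itself a noisy measurement, and forcing the line through ln(1) = 0
#' propagates its error into the slope. `intercept = FALSE` fits through the
#' origin for sensitivity checks.
#'
#' A non-positive fitted k_d (activity constant or increasing over storage,
#' as happens for refrigerated isotherms of very stable enzymes) is not an
#' error; the fit is returned with `no_deactivation = TRUE` and such
#' isotherms are excluded from the Arrhenius regression by
#' [arrhenius_fit()].
#'
#' @param time Storage times (months), at least two distinct values.
#' @param activity Activities (U L^-1), strictly positive (the log is taken).
#' @param E0 Initial activity (U L^-1), positive scalar.
#' @param temperature Optional storage temperature label (K), carried into
#'   the result.
#' @param intercept Fit a free intercept (default `TRUE`).
#' @return An object of class `"isotherm_fit"`: a list with `kd` (month^-1),
#'   `intercept`, `r_squared`, `n_points`, `temperature`,
#'   `no_deactivation`, and the underlying `lm` fit.
#' @examples
#' t <- 1:6
#' fit_kd(t, 1000 * exp(-0.1 * t), E0 = 1000)
#' @export
fit_kd <- function(time, activity, E0, temperature = NA_real_,
                   intercept = TRUE) {
  stopifnot(length(time) == length(activity))
  if (!is.numeric(E0) || length(E0) != 1L || E0 <= 0)
    stop("'E0' must be a positive scalar")
  keep <- is.finite(time) & is.finite(activity)
  time <- time[keep]; activity <- activity[keep]
  if (any(activity <= 0))
    stop("all activities must be strictly positive (log of E/E0 is taken)")
  if (length(unique(time)) < 2L)
    stop("at least two distinct times are required")
  y <- log(activity / E0)
  fit <- if (intercept) stats::lm(y ~ time) else stats::lm(y ~ time + 0)
  slope <- unname(stats::coef(fit)[["time"]])
  b0 <- if (intercept) unname(stats::coef(fit)[["(Intercept)"]]) else 0
  # R^2 degenerates when y is constant; report 1 for a perfectly flat exact
  # fit rather than NaN
  r2 <- if (stats::var(y) == 0) 1 else
    suppressWarnings(summary(fit)$r.squared)
  structure(list(
    kd = -slope,
    intercept = b0,
    r_squared = r2,
    n_points = length(time),
    temperature = temperature,
    no_deactivation = -slope <= 0,
    fit = fit
  ), class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat("First-order deactivation fit",
      if (is.finite(x$temperature)) sprintf("at %.2f K", x$temperature),
      "\n")
  cat(sprintf("  k_d = %.4g month^-1  (R^2 = %.4f, n = %d)\n",
              x$kd, x$r_squared, x$n_points))
  if (x$no_deactivation)
    cat("  note: k_d <= 0 -- no deactivation observed over storage\n")
  invisible(x)
}

#' Half-life from a first-order deactivation constant
#'
#' t_1/2 = ln(2) / k_d, the storage time at which activity falls to half its
#' initial value.
#'
#' @param kd Deactivation constant(s), month^-1, strictly positive.
#' @return Half-life in months (vectorized).
#' @examples
#' half_life(0.055) # ~12.6 months
#' @export
half_life <- function(kd) {
  if (any(!is.finite(kd) | kd <= 0))
    stop("half-life is undefined for k_d <= 0 (no deactivation observed)")
  log(2) / kd
}

#' Arrhenius regression of deactivation constants on temperature
#'
#' Fits ln(k_d) = ln(A) - E_d / (R T) by least squares over isotherms, giving
#' the deactivation energy E_d = -slope * R and frequency factor A.
#'
#' Isotherms with k_d <= 0 carry no information about the thermally
#' activated deactivation step and are dropped with a warning; at least
#' three positive-k_d isotherms at distinct temperatures are required for a
#' reportable E_d.
#'
#' @param isotherms Either a list of `"isotherm_fit"` objects (with
#'   temperatures set) or a data.frame with columns `temperature` (K) and
#'   `kd` (month^-1).
#' @param constants Output of [physical_constants()].
#' @return An object of class `"arrhenius_fit"`: `Ed` (J mol^-1), `ln_A`
#'   (A in month^-1), `r_squared`, `n_isotherms`, `temperature`, `kd`, and
#'   the underlying `lm` fit.
#' @examples
#' d <- data.frame(temperature = c(240.98, 277.40, 297.53, 303.27, 309.58),
#'                 kd = c(0.003, 0.015, 0.055, 0.135, 0.400))
#' arrhenius_fit(d)
#' @export
arrhenius_fit <- function(isotherms, constants = physical_constants()) {
  if (is.data.frame(isotherms)) {
    temperature <- isotherms$temperature
    kd <- isotherms$kd
  } else {
    temperature <- vapply(isotherms, `[[`, numeric(1), "temperature")
    kd <- vapply(isotherms, `[[`, numeric(1), "kd")
  }
  stopifnot(length(temperature) == length(kd))
  pos <- is.finite(kd) & kd > 0 & is.finite(temperature)
  if (any(!pos))
    warning(sprintf(
      "%d isotherm(s) with k_d <= 0 excluded from the Arrhenius regression",
      sum(!pos)))
  temperature <- temperature[pos]; kd <- kd[pos]
  if (length(kd) < 3L)
    stop("at least 3 isotherms with positive k_d are required")
  if (length(unique(temperature)) < length(temperature))
    stop("isotherm temperatures must be distinct")
  inv_T <- 1 / temperature
  fit <- stats::lm(log(kd) ~ inv_T)
  slope <- unname(stats::coef(fit)[["inv_T"]])
  structure(list(
    Ed = -slope * constants$R,
    ln_A = unname(stats::coef(fit)[["(Intercept)"]]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    n_isotherms = length(kd),
    temperature = temperature,
    kd = kd,
    constants = constants,
    fit = fit
  ), class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat("Arrhenius fit of ln(k_d) on 1/T\n")
  cat(sprintf("  E_d  = %.2f kJ mol^-1\n", x$Ed / 1000))
  cat(sprintf("  ln A = %.3f  (A in month^-1)\n", x$ln_A))
  cat(sprintf("  R^2  = %.4f over %d isotherms\n",
              x$r_squared, x$n_isotherms))
  invisible(x)
}

#' Enthalpy of deactivation
#'
#' Delta H = E_d - R T.
#'
#' @param Ed Deactivation energy, J mol^-1.
#' @param temperature Absolute temperature(s), K.
#' @param constants Output of [physical_constants()].
#' @return Enthalpy change in kJ mol^-1 (vectorized over `temperature`).
#' @examples
#' enthalpy(41400, 297.53) # ~38.93 kJ/mol
#' @export
enthalpy <- function(Ed, temperature, constants = physical_constants()) {
  (Ed - constants$R * temperature) / 1000
}

#' Gibbs free energy of deactivation
#'
#' Delta G = -R T ln(k_d h / (k_b T)), the transition-state (Eyring) free
#' energy of the inactivation step.
#'
#' The expression is dimensionally sensitive to the unit k_d enters in.
#' Accelerated-stability reports for stored biologics conventionally feed
#' k_d in the study's native time unit (here month^-1); that is mode
#' `"month"`, the default. Mode `"second"` first converts k_d to s^-1 using
#' 30-day months, which is the SI-consistent reading and yields
#' substantially larger Delta G. The choice is a convention, not a fit, and
#' is recorded in the output of [thermo_table()].
#'
#' @param kd Deactivation constant(s), month^-1, strictly positive.
#' @param temperature Absolute temperature(s), K.
#' @param constants Output of [physical_constants()].
#' @param kd_unit `"month"` (default) or `"second"`.
#' @return Gibbs energy change in kJ mol^-1.
#' @examples
#' gibbs(0.055, 297.53) # ~80.04 kJ/mol
#' @export
gibbs <- function(kd, temperature, constants = physical_constants(),
                  kd_unit = c("month", "second")) {
  kd_unit <- match.arg(kd_unit)
  if (any(!is.finite(kd) | kd <= 0))
    stop("Gibbs energy is undefined for k_d <= 0")
  k <- if (kd_unit == "second") kd / SECONDS_PER_MONTH else kd
  -constants$R * temperature *
    log(k * constants$h / (constants$k_b * temperature)) / 1000
}

#' Entropy of deactivation
#'
#' Delta S = (Delta H - Delta G) / T, in J mol^-1 K^-1 with enthalpy and
#' Gibbs energy supplied in kJ mol^-1.
#'
#' @param dH Enthalpy change, kJ mol^-1.
#' @param dG Gibbs energy change, kJ mol^-1.
#' @param temperature Absolute temperature(s), K.
#' @return Entropy change in J mol^-1 K^-1.
#' @examples
#' entropy(38.93, 80.04, 297.53) # ~ -138.2
#' @export
entropy <- function(dH, dG, temperature) {
  (dH - dG) * 1000 / temperature
}

#' Accelerated-stability thermodynamic table
#'
#' Combines per-temperature deactivation constants with a deactivation
#' energy into the standard accelerated-stability report: half-life,
#' enthalpy, Gibbs energy and entropy of inactivation at every storage
#' temperature.
#'
#' @param temperature Storage temperatures, K.
#' @param kd Deactivation constants, month^-1 (same length).
#' @param Ed Deactivation energy, J mol^-1 (scalar); `NA` when fewer than
#'   three isotherms are available, in which case the E_d-dependent columns
#'   (`dH_kJ_mol`, `dS_J_mol_K`) are `NA` and the table is flagged.
#' @param constants Output of [physical_constants()].
#' @param kd_unit Passed to [gibbs()].
#' @return A data.frame with columns `temperature_K`, `kd_per_month`,
#'   `t_half_months`, `dH_kJ_mol`, `dG_kJ_mol`, `dS_J_mol_K`, plus
#'   attributes `kd_unit` and `constants_mode`.
#' @examples
#' thermo_table(c(240.98, 297.53), c(0.003, 0.055), Ed = 41400)
#' @export
thermo_table <- function(temperature, kd, Ed,
                         constants = physical_constants(),
                         kd_unit = c("month", "second")) {
  kd_unit <- match.arg(kd_unit)
  stopifnot(length(temperature) == length(kd))
  if (!is.numeric(Ed) || length(Ed) != 1L)
    stop("'Ed' must be a scalar (possibly NA)")
  t_half <- ifelse(kd > 0, log(2) / kd, NA_real_)
  dG <- ifelse(kd > 0,
               gibbs(pmax(kd, .Machine$double.xmin), temperature,
                     constants, kd_unit),
               NA_real_)
  if (is.na(Ed)) {
    dH <- rep(NA_real_, length(temperature))
    dS <- rep(NA_real_, length(temperature))
  } else {
    dH <- enthalpy(Ed, temperature, constants)
    dS <- entropy(dH, dG, temperature)
  }
  out <- data.frame(
    temperature_K = temperature,
    kd_per_month = kd,
    t_half_months = t_half,
    dH_kJ_mol = dH,
    dG_kJ_mol = dG,
    dS_J_mol_K = dS
  )
  attr(out, "kd_unit") <- kd_unit
  attr(out, "constants_mode") <- constants$mode
  attr(out, "Ed_J_mol") <- Ed
  attr(out, "incomplete") <- is.na(Ed)
  out
}

#' Predict half-life at an arbitrary temperature from an Arrhenius fit
#'
#' Evaluates k_d(T) = exp(ln A - E_d / (R T)) and returns
#' t_1/2 = ln(2)/k_d(T). Strictly decreasing in T whenever E_d > 0.
#'
#' @param temperature Temperatures (K) at which to predict.
#' @param arrhenius An `"arrhenius_fit"` object.
#' @return Predicted half-lives in months.
#' @examples
#' d <- data.frame(temperature = c(240.98, 277.40, 297.53, 303.27, 309.58),
#'                 kd = c(0.003, 0.015, 0.055, 0.135, 0.400))
#' predict_half_life(277.40, arrhenius_fit(d))
#' @export
predict_half_life <- function(temperature, arrhenius) {
  stopifnot(inherits(arrhenius, "arrhenius_fit"))
  kd <- exp(arrhenius$ln_A -
              arrhenius$Ed / (arrhenius$constants$R * temperature))
  log(2) / kd
}
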