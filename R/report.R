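#' Fit a complete accelerated-stability analysis from a measurement table
#'
#' The full pipeline behind the accelerated-stability report: for every
#' storage temperature, the per-month stratified mean activity is computed
#' (batches as strata), a first-order deactivation constant is fitted, the
#' positive constants enter an Arrhenius regression for the deactivation
#' energy, and the thermodynamic table (half-life, enthalpy, Gibbs energy,
#' entropy of inactivation) is assembled.
#'
#' @param study Measurement data.frame with columns `batch`,
#'   `temperature_K`, `month`, `activity_UL` (e.g. from
#'   [generate_study()] or [read_study_csv()]).
#' @param E0 Initial activity (U L^-1). Default: the mean of the month-0
#'   records if present, else the generator truth attribute, else an error.
#' @param confidence Confidence level for stratified means; default 0.95.
#' @param constants Output of [physical_constants()].
#' @param kd_unit Passed to [thermo_table()].
#' @return An object of class `"stability_analysis"`: `isotherms` (list of
#'   [fit_kd()] results), `arrhenius` (or `NULL` with fewer than 3
#'   usable isotherms), `thermo` (the report table), `means`
#'   (per-temperature, per-month stratified means with CI half-widths and
#'   relative activity), `E0`, and a `provenance` list (config echo).
#' @examples
#' study <- generate_study(study_spec(seed = 3))
#' fit_stability_study(study)
#' @export
fit_stability_study <- function(study, E0 = NULL, confidence = 0.95,
                                constants = physical_constants(),
                                kd_unit = c("month", "second")) {
  kd_unit <- match.arg(kd_unit)
  need <- c("batch", "temperature_K", "month", "activity_UL")
  miss <- setdiff(need, names(study))
  if (length(miss) > 0)
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (nrow(study) == 0) stop("empty measurement table")
  if (is.null(E0)) {
    truth <- attr(study, "truth")
    E0 <- if (any(study$month == 0)) {
      mean(study$activity_UL[study$month == 0])
    } else if (!is.null(truth)) {
      truth$initial_activity_mean
    } else stop("'E0' is required when the table has no month-0 records")
  }
  temps <- sort(unique(study$temperature_K))
  batches <- sort(unique(study$batch))
  means <- list(); isotherms <- list()
  for (Tk in temps) {
    d <- study[study$temperature_K == Tk & study$month > 0, ]
    months <- sort(unique(d$month))
    rows <- lapply(months, function(m) {
      dm <- d[d$month == m, ]
      n_b <- table(factor(dm$batch, levels = batches))
      # equal-weight strata: the stratified design samples batches of equal
      # size, so population weights are uniform across batches present
      est <- stratified_mean_ci(dm$activity_UL,
                                as.character(dm$batch),
                                stats::setNames(rep(1e6, length(batches)),
                                                as.character(batches)),
                                confidence)
      data.frame(temperature_K = Tk, month = m, mean_UL = est$mean,
                 ci_halfwidth_UL = est$ci_halfwidth,
                 relative_pct = relative_activity(max(est$mean, 0), E0),
                 n = nrow(dm))
    })
    tab <- do.call(rbind, rows)
    means[[format(Tk)]] <- tab
    ok <- tab$mean_UL > 0
    isotherms[[format(Tk)]] <-
      if (sum(ok) >= 2 && length(unique(tab$month[ok])) >= 2)
        fit_kd(tab$month[ok], tab$mean_UL[ok], E0, temperature = Tk)
      else NULL
  }
  isotherms <- Filter(Negate(is.null), isotherms)
  fits <- data.frame(
    temperature = vapply(isotherms, `[[`, numeric(1), "temperature"),
    kd = vapply(isotherms, `[[`, numeric(1), "kd"))
  usable <- fits$kd > 0
  arr <- if (sum(usable) >= 3)
    suppressWarnings(arrhenius_fit(fits, constants)) else NULL
  thermo <- thermo_table(fits$temperature, fits$kd,
                         Ed = if (is.null(arr)) NA_real_ else arr$Ed,
                         constants = constants, kd_unit = kd_unit)
  structure(list(isotherms = isotherms, arrhenius = arr, thermo = thermo,
                 means = do.call(rbind, c(means, make.row.names = FALSE)),
                 E0 = E0,
                 provenance = list(confidence = confidence,
                                   kd_unit = kd_unit,
                                   constants_mode = constants$mode,
                                   n_records = nrow(study))),
            class = "stability_analysis")
}

#' @export
print.stability_analysis <- function(x, ...) {
  cat("Accelerated-stability analysis\n")
  cat(sprintf("  E0 = %.2f U/L, %d isotherm(s)\n", x$E0,
              length(x$isotherms)))
  if (!is.null(x$arrhenius))
    cat(sprintf("  E_d = %.2f kJ/mol (R^2 = %.3f)\n",
                x$arrhenius$Ed / 1000, x$arrhenius$r_squared))
  else cat("  E_d not reportable (< 3 isotherms with positive k_d)\n")
  print(x$thermo, digits = 4)
  invisible(x)
}

#' Write the thermodynamic report table to CSV
#'
#' Emits the accelerated-stability table (temperature, k_d, half-life,
#' enthalpy, Gibbs energy, entropy) with a comment header recording the
#' k_d-unit convention and constants mode, so the file is
#' self-describing.
#'
#' @param analysis A `"stability_analysis"` or a [thermo_table()]
#'   data.frame.
#' @param file Output CSV path.
#' @return Invisibly, `file`.
#' @export
write_thermo_csv <- function(analysis, file) {
  tab <- if (inherits(analysis, "stability_analysis")) analysis$thermo
         else analysis
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# kd_unit=%s constants=%s",
                     attr(tab, "kd_unit"), attr(tab, "constants_mode")),
             con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(file)
}

#' Read a thermodynamic report table written by [write_thermo_csv()]
#'
#' @param file CSV path.
#' @return The table as a data.frame (comment header skipped).
#' @export
read_thermo_csv <- function(file) {
  utils::read.csv(file, comment.char = "#")
}

#' Packaged accelerated-stability example inputs
#'
#' Path to the packaged CSV of per-temperature deactivation constants and
#' deactivation energy for a year-long laccase-concentrate stability study
#' (columns `temperature_K`, `kd_per_month`; attribute row for
#' `Ed_kJ_mol` in the header comment), usable directly with
#' [thermo_table()].
#'
#' @return A list with `temperature_K`, `kd_per_month` (vectors) and
#'   `Ed_J_mol` (scalar).
#' @examples
#' inp <- stability_example_inputs()
#' thermo_table(inp$temperature_K, inp$kd_per_month, inp$Ed_J_mol)
#' @export
stability_example_inputs <- function() {
  path <- system.file("extdata", "accelerated_stability_inputs.csv",
                      package = "enzstab", mustWork = TRUE)
  first <- readLines(path, n = 1)
  Ed <- as.numeric(sub("^# *Ed_J_mol=", "", first))
  tab <- utils::read.csv(path, comment.char = "#")
  list(temperature_K = tab$temperature_K,
       kd_per_month = tab$kd_per_month, Ed_J_mol = Ed)
}
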