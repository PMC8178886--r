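#' Hanes-Woolf linearization fit of Michaelis-Menten kinetics
#'
#' Regresses S/V0 on S. Under V0 = Vmax S / (Km + S) this line has slope
#' 1/Vmax and intercept Km/Vmax, so Vmax = 1/slope and Km =
#' intercept/slope. The linearization is exact on noiseless data and gives
#' robust starting values for the nonlinear fit of [mm_nls_fit()].
#'
#' @param S Substrate concentrations (mM), strictly positive, >= 3 distinct
#'   values.
#' @param V0 Initial velocities (mM min^-1), strictly positive.
#' @return An object of class `"mm_fit"` with `Vmax`, `Km`, their standard
#'   deviations (delta-method from the linear fit), `method =
#'   "hanes-woolf"`, `rss` (on the velocity scale) and the underlying `lm`.
#' @examples
#' S <- c(0.1, 0.3, 1, 3)
#' hanes_woolf_fit(S, 0.0102 * S / (0.0466 + S))
#' @export
hanes_woolf_fit <- function(S, V0) {
  stopifnot(length(S) == length(V0))
  if (any(S <= 0)) stop("substrate concentrations must be positive")
  if (any(V0 <= 0)) stop("velocities must be positive for the linearization")
  if (length(unique(S)) < 3)
    stop("at least 3 distinct substrate concentrations are required")
  y <- S / V0
  fit <- stats::lm(y ~ S)
  slope <- unname(stats::coef(fit)[["S"]])
  b0 <- unname(stats::coef(fit)[["(Intercept)"]])
  if (slope <= 0)
    stop("non-saturating data: Hanes-Woolf slope <= 0, cannot estimate Vmax")
  Vmax <- 1 / slope
  Km <- b0 / slope
  # delta-method SDs from the (intercept, slope) covariance; exact data
  # legitimately produce a perfect linear fit
  V <- suppressWarnings(stats::vcov(fit))
  g_V <- c(0, -1 / slope^2)             # dVmax/d(b0, slope)
  g_K <- c(1 / slope, -b0 / slope^2)    # dKm/d(b0, slope)
  Vmax_sd <- sqrt(drop(t(g_V) %*% V %*% g_V))
  Km_sd <- sqrt(drop(t(g_K) %*% V %*% g_K))
  pred <- Vmax * S / (Km + S)
  structure(list(Vmax = Vmax, Km = Km, Vmax_sd = Vmax_sd, Km_sd = Km_sd,
                 method = "hanes-woolf", rss = sum((V0 - pred)^2),
                 converged = TRUE, S = S, V0 = V0, fit = fit),
            class = "mm_fit")
}

#' Nonlinear least-squares Michaelis-Menten fit
#'
#' Minimizes sum( (V0 - Vmax S / (Km + S))^2 ) by Levenberg-Marquardt,
#' started from a Hanes-Woolf linearization (or user-supplied values).
#' Unweighted least squares; parameter SDs come from the curvature at the
#' optimum.
#'
#' @param S Substrate concentrations (mM).
#' @param V0 Initial velocities (mM min^-1).
#' @param start Optional starting values: an `"mm_fit"` object or a list
#'   with positive `Vmax` and `Km`. Defaults to [hanes_woolf_fit()].
#' @param max_iter Iteration budget; default 200.
#' @param tol Convergence tolerance on the relative offset; default 1e-10.
#' @return An `"mm_fit"` object (`method = "nls"`) with `Vmax`, `Km`,
#'   their SDs, `rss`, `converged`, and the underlying `nls` fit. On
#'   non-convergence the starting values are echoed with
#'   `converged = FALSE`.
#' @examples
#' S <- c(0.1, 0.3, 1, 3)
#' mm_nls_fit(S, 0.0102 * S / (0.0466 + S))
#' @export
mm_nls_fit <- function(S, V0, start = NULL, max_iter = 200, tol = 1e-10) {
  stopifnot(length(S) == length(V0))
  if (is.null(start)) start <- hanes_woolf_fit(S, V0)
  init <- list(Vmax = start$Vmax, Km = start$Km)
  if (init$Vmax <= 0 || init$Km <= 0)
    stop("starting values for Vmax and Km must be positive")
  dat <- data.frame(S = S, V0 = V0)
  fit <- tryCatch(
    minpack.lm::nlsLM(V0 ~ Vmax * S / (Km + S), data = dat, start = init,
                      lower = c(Vmax = 0, Km = 0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = max_iter, ftol = tol)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    warning("nonlinear fit did not converge: ", conditionMessage(fit),
            "; echoing starting values")
    return(structure(list(Vmax = init$Vmax, Km = init$Km,
                          Vmax_sd = NA_real_, Km_sd = NA_real_,
                          method = "nls", rss = NA_real_,
                          converged = FALSE, S = S, V0 = V0, fit = NULL),
                     class = "mm_fit"))
  }
  co <- summary(fit)$coefficients
  structure(list(Vmax = co["Vmax", "Estimate"], Km = co["Km", "Estimate"],
                 Vmax_sd = co["Vmax", "Std. Error"],
                 Km_sd = co["Km", "Std. Error"],
                 method = "nls", rss = sum(stats::resid(fit)^2),
                 converged = TRUE, S = S, V0 = V0, fit = fit),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit (%s)\n", x$method))
  cat(sprintf("  Vmax = %.5g +/- %.2g mM min^-1\n", x$Vmax, x$Vmax_sd))
  cat(sprintf("  Km   = %.5g +/- %.2g mM\n", x$Km, x$Km_sd))
  if (!is.na(x$rss)) cat(sprintf("  RSS  = %.3g\n", x$rss))
  if (!x$converged) cat("  warning: fit did not converge\n")
  invisible(x)
}
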