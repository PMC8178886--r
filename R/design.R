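#' Pooled standard deviation across pilot groups
#'
#' Combined variance estimator under homogeneity of variances, as used to
#' pool a pilot study's per-temperature activity SDs into a single planning
#' value: sqrt( sum((n_i - 1) s_i^2) / sum(n_i - 1) ).
#'
#' @param groups A data.frame with columns `n` (replicate count, >= 2) and
#'   `sd` (sample standard deviation), one row per pilot group.
#' @return The pooled standard deviation (same unit as the inputs).
#' @examples
#' pooled_sd(data.frame(n = c(11, 6), sd = c(5, 10))) # sqrt(50)
#' @export
pooled_sd <- function(groups) {
  stopifnot(is.data.frame(groups), all(c("n", "sd") %in% names(groups)))
  if (any(groups$n < 2))
    stop("every pilot group needs at least 2 replicates")
  if (any(groups$sd < 0)) stop("standard deviations must be non-negative")
  sqrt(sum((groups$n - 1) * groups$sd^2) / sum(groups$n - 1))
}

#' Required total sample size for estimating a stratified mean
#'
#' Normal-approximation sample size for a mean with absolute precision `d`
#' (confidence-interval half-width) under simple/stratified random sampling
#' with proportional allocation: n0 = (z * sd / d)^2, corrected for the
#' finite population as n = ceiling(n0 / (1 + n0 / N)).
#'
#' The standard-normal quantile (z = 1.96 at 95%) is used rather than
#' Student's t: the design targets the large-sample estimator its precision
#' statement implies. With `sd = 0` the defined minimum — one vial per
#' stratum — is returned.
#'
#' @param N Population size (total vials across strata). `Inf` drops the
#'   finite-population correction.
#' @param sd Planning standard deviation (e.g. from [pooled_sd()]), U L^-1.
#' @param d Target precision: CI half-width, U L^-1, positive.
#' @param confidence Confidence level in (0, 1); default 0.95.
#' @param n_strata Number of strata (lower bound on n); default 1.
#' @return Integer total sample size n.
#' @examples
#' required_sample_size(N = 1200, sd = 96.6, d = 21.8) # 71
#' @export
required_sample_size <- function(N, sd, d, confidence = 0.95,
                                 n_strata = 1L) {
  if (d <= 0) stop("'d' (precision) must be positive")
  if (confidence <= 0 || confidence >= 1)
    stop("'confidence' must be in (0, 1)")
  if (sd < 0) stop("'sd' must be non-negative")
  if (is.finite(N) && N < n_strata)
    stop("population smaller than the number of strata")
  if (sd == 0) return(as.integer(n_strata))
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  n0 <- (z * sd / d)^2
  n <- if (is.finite(N)) ceiling(n0 / (1 + n0 / N)) else ceiling(n0)
  as.integer(max(n, n_strata))
}

#' Proportional allocation of a sample across strata
#'
#' Allocates n_h proportional to stratum sizes N_h, integerized by the
#' largest-remainder method (ties broken toward the lower stratum index) so
#' that the allocation conserves n exactly.
#'
#' @param n Total sample size, `n <= sum(strata_sizes)`.
#' @param strata_sizes Stratum population sizes N_h.
#' @return Integer vector n_h with `sum(n_h) == n`.
#' @examples
#' allocate_proportional(71, c(400, 400, 400)) # 24 24 23
#' @export
allocate_proportional <- function(n, strata_sizes) {
  stopifnot(length(strata_sizes) >= 1, all(strata_sizes > 0))
  if (n > sum(strata_sizes))
    stop("sample size exceeds the population")
  if (n < 0) stop("'n' must be non-negative")
  quota <- n * strata_sizes / sum(strata_sizes)
  n_h <- floor(quota)
  rem <- n - sum(n_h)
  if (rem > 0) {
    # largest remainders first; ties to the lower stratum index
    ord <- order(-(quota - n_h), seq_along(quota))
    take <- ord[seq_len(rem)]
    n_h[take] <- n_h[take] + 1
  }
  # never exceed a stratum; push overflow to the next stratum with room
  over <- which(n_h > strata_sizes)
  while (length(over) > 0) {
    excess <- n_h[over] - strata_sizes[over]
    n_h[over] <- strata_sizes[over]
    room <- which(n_h < strata_sizes)
    for (i in seq_len(sum(excess))) {
      j <- room[which.max(strata_sizes[room] - n_h[room])]
      n_h[j] <- n_h[j] + 1
      room <- which(n_h < strata_sizes)
    }
    over <- which(n_h > strata_sizes)
  }
  as.integer(n_h)
}

#' Draw a stratified simple random sample of vial ids
#'
#' Uniform sampling without replacement within each stratum, reproducible
#' under a seed. Vials are identified by (stratum, id) pairs where ids run
#' 1..N_h within each stratum.
#'
#' @param strata_sizes Stratum population sizes N_h.
#' @param n_h Per-stratum sample sizes (e.g. from
#'   [allocate_proportional()]), `n_h <= strata_sizes` elementwise.
#' @param seed Optional integer seed for reproducibility.
#' @return A data.frame with columns `stratum` and `vial_id`.
#' @examples
#' draw_sample(c(4, 4), c(2, 2), seed = 1)
#' @export
draw_sample <- function(strata_sizes, n_h, seed = NULL) {
  stopifnot(length(strata_sizes) == length(n_h))
  if (any(n_h > strata_sizes)) stop("n_h exceeds a stratum size")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  picks <- lapply(seq_along(strata_sizes), function(h) {
    ids <- sort(sample.int(strata_sizes[h], n_h[h]))
    data.frame(stratum = h, vial_id = ids)
  })
  do.call(rbind, picks)
}

#' Stratified mean and confidence interval
#'
#' Estimates the population mean as sum(W_h * ybar_h) with W_h = N_h / N,
#' with variance sum( W_h^2 (1 - n_h/N_h) s_h^2 / n_h ) (finite-population
#' corrected) and a normal-quantile half-width.
#'
#' @param values Observed values.
#' @param stratum Stratum label per observation (matched against
#'   `names(strata_sizes)` if named, else against stratum indices 1..H).
#' @param strata_sizes Stratum population sizes N_h.
#' @param confidence Confidence level; default 0.95.
#' @return A list with `mean`, `ci_halfwidth`, `se`, and a data.frame
#'   `strata` (per-stratum n_h, mean, sd, weight).
#' @examples
#' v <- c(10, 12, 11, 20, 22, 21)
#' stratified_mean_ci(v, rep(1:2, each = 3), c(50, 50))
#' @export
stratified_mean_ci <- function(values, stratum, strata_sizes,
                               confidence = 0.95) {
  stopifnot(length(values) == length(stratum))
  labels <- if (!is.null(names(strata_sizes))) names(strata_sizes)
            else as.character(seq_along(strata_sizes))
  stratum <- as.character(stratum)
  if (!all(stratum %in% labels))
    stop("observation stratum labels not found among strata_sizes")
  N <- sum(strata_sizes)
  W <- strata_sizes / N
  per <- lapply(seq_along(labels), function(h) {
    y <- values[stratum == labels[h]]
    n_h <- length(y)
    if (n_h > strata_sizes[h]) stop("more observations than vials in stratum")
    list(n_h = n_h, mean = mean(y),
         sd = if (n_h >= 2) stats::sd(y) else NA_real_)
  })
  n_h <- vapply(per, `[[`, numeric(1), "n_h")
  if (any(n_h == 0)) stop("every stratum needs at least one observation")
  m_h <- vapply(per, `[[`, numeric(1), "mean")
  s_h <- vapply(per, `[[`, numeric(1), "sd")
  est <- sum(W * m_h)
  need_var <- n_h < strata_sizes  # a fully enumerated stratum adds no variance
  if (any(need_var & n_h < 2))
    stop("a stratum variance is required but n_h < 2")
  vterm <- ifelse(need_var, W^2 * (1 - n_h / strata_sizes) * s_h^2 / n_h, 0)
  v <- sum(vterm)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  list(mean = est, ci_halfwidth = z * sqrt(v), se = sqrt(v),
       strata = data.frame(stratum = labels, N_h = strata_sizes,
                           n_h = n_h, mean = m_h, sd = s_h, weight = W))
}

#' Apply the sampling stop rule to a relative-activity trace
#'
#' The schedule is truncated at the first month at which the stratified-mean
#' relative activity falls below `threshold` (default 25% remaining, i.e.
#' ~75% loss). If truncation leaves fewer than `min_times` sampling times
#' and the schedule allows, sampling is extended toward `min_times` — unless
#' activity at the truncation point has already collapsed below
#' `collapse_floor` (default 10% remaining), in which case further sampling
#' is pointless and the trace ends at the crossing month.
#'
#' @param relative Relative activity (%) at each scheduled month.
#' @param schedule Scheduled sampling months (strictly increasing), same
#'   length as `relative`.
#' @param threshold Stop threshold, % remaining; default 25.
#' @param min_times Minimum number of sampling times to aim for; default 5.
#' @param collapse_floor Remaining-activity floor (%) below which the
#'   minimum-times extension is abandoned; default 10.
#' @return The months actually sampled (a prefix of `schedule`).
#' @examples
#' sched <- c(1:6, 8, 10, 12)
#' apply_stop_rule(rep(90, 9), sched)            # full schedule
#' apply_stop_rule(c(4.8, rep(1, 8)), sched)     # month 1 only
#' @export
apply_stop_rule <- function(relative, schedule, threshold = 25,
                            min_times = 5, collapse_floor = 10) {
  stopifnot(length(relative) == length(schedule))
  if (any(diff(schedule) <= 0)) stop("schedule must be strictly increasing")
  below <- which(relative < threshold)
  if (length(below) == 0) return(schedule)
  cut <- below[1]
  keep <- cut
  if (relative[cut] >= collapse_floor)
    keep <- min(max(cut, min_times), length(schedule))
  schedule[seq_len(keep)]
}

#' Summarize a storage-temperature log in kelvin
#'
#' Converts a temperature log to kelvin and returns its mean and standard
#' deviation, the per-condition summary reported alongside a year-long
#' stability study.
#'
#' @param readings Numeric temperature readings.
#' @param unit `"K"` or `"C"`; mixed units are not accepted, convert first.
#' @return A list with `mean_K` and `sd_K`.
#' @examples
#' summarize_temperature_log(c(24.7, 25.3, 25.0), unit = "C")
#' @export
summarize_temperature_log <- function(readings, unit = c("K", "C")) {
  unit <- match.arg(unit)
  if (!is.numeric(readings) || length(readings) < 1)
    stop("'readings' must be a non-empty numeric vector")
  K <- if (unit == "C") readings + 273.15 else readings
  if (any(K < 0)) stop("temperatures below absolute zero; check 'unit'")
  list(mean_K = mean(K), sd_K = if (length(K) > 1) stats::sd(K) else 0)
}
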