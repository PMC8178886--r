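test_that("pooled_sd matches the hand formula and respects bounds", {
  expect_equal(pooled_sd(data.frame(n = c(3, 3), sd = c(10, 10))), 10)
  # sqrt( (10*25 + 5*100) / 15 ) = sqrt(50)
  expect_equal(pooled_sd(data.frame(n = c(11, 6), sd = c(5, 10))),
               sqrt(50), tolerance = 1e-12)
  g <- data.frame(n = c(4, 7, 5), sd = c(3, 9, 6))
  p <- pooled_sd(g)
  expect_gte(p, min(g$sd)); expect_lte(p, max(g$sd))
  expect_error(pooled_sd(data.frame(n = c(1, 5), sd = c(1, 1))),
               "at least 2")
})

test_that("pooled_sd is consistent for groups drawn from one normal", {
  set.seed(42)
  true_sd <- 96.6
  ests <- replicate(400, {
    g <- data.frame(n = c(15, 15, 15),
                    sd = replicate(3, sd(rnorm(15, 0, true_sd))))
    pooled_sd(g)
  })
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - true_sd), 3 * se + 0.02 * true_sd)
})

test_that("required_sample_size applies the fpc and defined minima", {
  expect_identical(required_sample_size(1200, 96.6, 21.8), 71L)
  expect_identical(required_sample_size(Inf, 96.6, 21.8), 76L)
  expect_identical(required_sample_size(1200, 0, 21.8, n_strata = 3), 3L)
  expect_error(required_sample_size(1200, 96.6, 0), "positive")
  expect_error(required_sample_size(2, 96.6, 21.8, n_strata = 3),
               "smaller")
})

test_that("required_sample_size is monotone in precision and sd", {
  d_grid <- c(5, 10, 21.8, 50, 100)
  n_d <- vapply(d_grid, function(d)
    required_sample_size(1200, 96.6, d), integer(1))
  expect_true(all(diff(n_d) <= 0))
  sd_grid <- c(10, 50, 96.6, 150, 300)
  n_s <- vapply(sd_grid, function(s)
    required_sample_size(1200, s, 21.8), integer(1))
  expect_true(all(diff(n_s) >= 0))
})

test_that("proportional allocation conserves n with largest remainders", {
  expect_identical(allocate_proportional(71, c(400, 400, 400)),
                   c(24L, 24L, 23L))
  expect_identical(allocate_proportional(30, c(100, 100, 100)),
                   c(10L, 10L, 10L))
  set.seed(7)
  for (i in 1:20) {
    sizes <- sample(5:50, 4)
    n <- sample.int(sum(sizes), 1)
    a <- allocate_proportional(n, sizes)
    expect_identical(sum(a), n)
    expect_true(all(a <= sizes))
  }
  expect_error(allocate_proportional(10, c(2, 3)), "exceeds")
})

test_that("draw_sample is reproducible, exhaustive, and uniform", {
  full <- draw_sample(c(3, 3), c(3, 3), seed = 5)
  expect_identical(full$vial_id, rep(1:3, 2))
  expect_identical(draw_sample(c(10, 10), c(4, 4), seed = 11),
                   draw_sample(c(10, 10), c(4, 4), seed = 11))
  # inclusion frequency of each vial ~ n_h / N_h
  set.seed(99)
  counts <- integer(8)
  reps <- 4000
  for (i in seq_len(reps)) {
    s <- draw_sample(8, 2)
    counts[s$vial_id] <- counts[s$vial_id] + 1
  }
  p <- 2 / 8
  se <- sqrt(p * (1 - p) / reps)
  expect_true(all(abs(counts / reps - p) < 3.5 * se))
})

test_that("stratified mean is design-unbiased and its variance estimator
           matches exhaustive enumeration", {
  # toy population: 3 strata of 4 vials, full enumeration of n_h = 2 draws
  pop <- list(c(10, 12, 14, 16), c(30, 31, 32, 33), c(50, 55, 60, 65))
  sizes <- c(4, 4, 4)
  true_mean <- mean(unlist(pop))
  combos <- subsets_of(4, 2)
  ests <- c(); vars <- c()
  for (i1 in combos) for (i2 in combos) for (i3 in combos) {
    y <- c(pop[[1]][i1], pop[[2]][i2], pop[[3]][i3])
    st <- rep(1:3, each = 2)
    r <- stratified_mean_ci(y, st, sizes)
    ests <- c(ests, r$mean); vars <- c(vars, r$se^2)
  }
  expect_equal(mean(ests), true_mean, tolerance = 1e-12)
  # E[v_hat] equals the exact design variance of the estimator
  design_var <- mean((ests - mean(ests))^2)
  expect_equal(mean(vars), design_var, tolerance = 1e-10)
})

test_that("stratified mean handles degenerate and self-weighting cases", {
  r <- stratified_mean_ci(rep(7, 6), rep(1:3, each = 2), c(10, 10, 10))
  expect_equal(r$mean, 7)
  expect_equal(r$ci_halfwidth, 0)
  # equal strata and equal n_h: stratified mean == grand mean
  y <- c(1, 5, 2, 8, 3, 9)
  r2 <- stratified_mean_ci(y, rep(1:3, each = 2), c(50, 50, 50))
  expect_equal(r2$mean, mean(y))
  expect_error(
    stratified_mean_ci(c(1, 2, 3), c(1, 1, 2), c(10, 10)),
    "n_h < 2")
})

test_that("stop rule truncates, extends to five, or abandons on collapse", {
  sched <- c(1:6, 8, 10, 12)
  expect_equal(apply_stop_rule(rep(90, 9), sched), sched)
  expect_equal(apply_stop_rule(c(4.83, rep(1, 8)), sched), 1)
  expect_equal(apply_stop_rule(c(80, 40, 20, 15, 10, 8, 5, 3, 2),
                               sched), c(1, 2, 3, 4, 5))
  expect_equal(apply_stop_rule(c(80, 60, 40, 30, 28, 24, 20, 10, 5),
                               sched), c(1, 2, 3, 4, 5, 6))
  expect_error(apply_stop_rule(c(50, 50), c(2, 1)), "increasing")
})

test_that("temperature log summaries convert and reject bad input", {
  r <- summarize_temperature_log(rep(25, 10), unit = "C")
  expect_equal(r$mean_K, 298.15)
  expect_equal(r$sd_K, 0)
  set.seed(3)
  log_c <- rnorm(365, 24.99, 0.25)
  rk <- summarize_temperature_log(log_c, unit = "C")
  expect_equal(rk$mean_K, mean(log_c) + 273.15, tolerance = 1e-12)
  expect_lt(abs(rk$sd_K - 0.25), 0.05)
  expect_error(summarize_temperature_log(c("20", "K")), "numeric")
  expect_error(summarize_temperature_log(c(-30, 25), unit = "K"),
               "absolute zero")
})
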