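test_that("RFI normalization follows the background-subtracted ratio", {
  expect_equal(compute_rfi(90, 10, 90, 10), 1)
  expect_equal(compute_rfi(10, 10, 90, 10), 0)
  expect_equal(compute_rfi(50, 10, 90, 10), 0.5)
  expect_error(compute_rfi(50, 10, 30, 30, trace_id = "t9"), "t9")
})

test_that("noiseless recovery fits return the programmed rate and half-time", {
  tt <- seq(0, 20, by = 0.5)
  trace <- data.frame(time_s = tt,
                      rfi = 1 - 0.8 * exp(-0.3466 * tt))
  fit <- fit_recovery(trace, window = 20)
  expect_true(fit$fit_ok)
  expect_equal(fit$k, 0.3466, tolerance = 0.01 * 0.3466)
  expect_equal(fit$t_half, 2.000, tolerance = 0.01)
  expect_equal(fit$FRFI_0, 0.2, tolerance = 1e-3)
})

test_that("half-time follows ln(2)/k for fitted rate constants", {
  # the printed wild-type and truncation-mutant half-times
  expect_equal(log(2) / 0.28907, 2.398, tolerance = 5e-4)
  fit <- fit_recovery(frap_rfi(simulate_frap_series(
    frap_sim_config(n_traces = 1, rate_constant_k = 0.28907,
                    noise_sd = 0))$series), window = 20)
  expect_equal(fit$t_half, 2.398, tolerance = 1e-3)
  expect_equal(fit$t_half * fit$k, log(2), tolerance = 1e-12)
})

test_that("too few points or flat traces are flagged as fit failures", {
  short <- data.frame(time_s = seq(0, 2, by = 0.5), rfi = rep(0.5, 5))
  expect_false(fit_recovery(short, window = 20)$fit_ok)
})

test_that("immobile fraction formula, bounds and monotonicity", {
  expect_equal(immobile_fraction(0.2, 1), 0)
  expect_equal(immobile_fraction(0.2, 0.2), 1)
  expect_error(immobile_fraction(1.1, 1.2), "FRFI_0")
  expect_warning(imf <- immobile_fraction(0.2, 1.2), "outside")
  expect_lt(imf, 0)
  # strictly decreasing in FRFI_f at fixed FRFI_0
  ff <- seq(0.25, 0.95, by = 0.1)
  vals <- vapply(ff, function(f) immobile_fraction(0.2, f), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("round trip: noiseless simulated FRAP recovers k and IMf", {
  cfg <- frap_sim_config(n_traces = 2L, noise_sd = 0, bleach_depth = 0.2,
                         plateau = 0.496, rate_constant_k = log(2) / 2.4)
  sim <- simulate_frap_series(cfg)
  res <- frap_analyze(sim$series, window = 20)$results
  expect_true(all(!res$excluded))
  expect_equal(res$k, rep(log(2) / 2.4, 2), tolerance = 0.01)
  expect_equal(res$immobile_fraction,
               rep(sim$truth$immobile_fraction[1], 2), tolerance = 0.01)
})

test_that("slow recoveries beyond the acquisition time are excluded", {
  tt <- seq(0, 45, by = 0.5)
  slow <- data.frame(trace_id = 1L, time_s = tt,
                     rfi = 1 - 0.8 * exp(-0.01 * tt))
  fast <- data.frame(trace_id = 2L, time_s = tt,
                     rfi = 1 - 0.8 * exp(-0.3 * tt))
  fits <- rbind(
    data.frame(trace_id = 1L, as.data.frame(
      fit_recovery(slow, window = 45)[c("k", "t_half", "fit_ok")])),
    data.frame(trace_id = 2L, as.data.frame(
      fit_recovery(fast, window = 45)[c("k", "t_half", "fit_ok")])))
  expect_equal(fits$t_half[1], log(2) / 0.01, tolerance = 0.5)
  flt <- filter_frap_results(rbind(fits, fits[2, ], fits[2, ]), t_max = 45)
  expect_true(flt$excluded[1])
  expect_match(flt$exclude_reason[1], "45")
  expect_false(any(flt$excluded[-1]))
})

test_that("identical half-times produce no ROUT exclusions", {
  res <- data.frame(trace_id = 1:6, t_half = rep(2.5, 6), fit_ok = TRUE)
  flt <- filter_frap_results(res)
  expect_false(any(flt$excluded))
})

test_that("cumulative curves equal brute-force recomputation", {
  # single trace: mean equals the trace, sem 0
  one <- data.frame(trace_id = 1L, time_s = 0:5, rfi = c(1, 2, 3, 4, 5, 6))
  cc1 <- cumulative_curve(one)
  expect_equal(cc1$mean, c(1, 2, 3, 4, 5, 6))
  expect_equal(cc1$sem, rep(0, 6))
  # two traces: mean is the average, sem is |difference|/2
  two <- rbind(one, data.frame(trace_id = 2L, time_s = 0:5,
                               rfi = c(3, 2, 5, 4, 7, 6)))
  cc2 <- cumulative_curve(two)
  expect_equal(cc2$mean, (one$rfi + c(3, 2, 5, 4, 7, 6)) / 2)
  expect_equal(cc2$sem, abs(one$rfi - c(3, 2, 5, 4, 7, 6)) / 2)
  # 20 seeded traces against direct recomputation
  sim <- simulate_frap_series(frap_sim_config(n_traces = 20L, seed = 12L))
  ser <- frap_rfi(sim$series)
  cc <- cumulative_curve(ser)
  wide <- matrix(ser$rfi[order(ser$trace_id, ser$time_s)],
                 ncol = 20)
  expect_equal(cc$mean, unname(rowMeans(wide)), tolerance = 1e-12)
  expect_equal(cc$sem, unname(apply(wide, 1, sd) / sqrt(20)),
               tolerance = 1e-12)
  expect_error(cumulative_curve(ser, include = integer(0)), "no included")
})
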