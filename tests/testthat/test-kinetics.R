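test_that("preprocessing subtracts baseline and smooths with edge shrink", {
  pt <- preprocess_trace(c(0, 3, 6, 9), 0.75)
  expect_equal(pt$raw, c(0, 3, 6, 9))
  expect_equal(pt$values, c(1.5, 3, 6, 7.5))
  expect_equal(pt$times, c(0, 0.75, 1.5, 2.25))

  const <- preprocess_trace(rep(7, 10), 0.75)
  expect_equal(const$raw, rep(0, 10))
  expect_equal(const$values, rep(0, 10))

  expect_error(preprocess_trace(c(1, 2), 0.75), "shorter than 3")
})

test_that("smoothing reduces white-noise variance", {
  set.seed(8)
  tr <- preprocess_trace(rnorm(200), 0.75)
  expect_lt(stats::var(tr$values), stats::var(tr$raw))
})

test_that("noiseless logistic assembly is recovered essentially exactly", {
  tl <- seq(0, 16) * 0.75
  vals <- rm3(100 / (1 + exp(-0.5 * (tl - 5))))
  trace <- structure(list(times = tl, values = vals,
                          peak_index = length(tl)),
                     class = "intensity_trace")
  fit <- fit_assembly(trace)
  expect_true(fit$fit_ok)
  expect_equal(fit$amplitude, 100, tolerance = 0.01)
  expect_equal(fit$rate, 0.5, tolerance = 0.01)
  expect_equal(fit$t_half, 5, tolerance = 0.01)
})

test_that("degenerate assembly segments are flagged, not errors", {
  decreasing <- preprocess_trace(seq(100, 20, by = -10), 0.75)
  f1 <- fit_assembly(decreasing)
  expect_false(f1$fit_ok)
  short <- structure(list(times = (0:8) * 0.75,
                          values = c(0, 1, 10, 50, 90, 70, 50, 30, 20),
                          peak_index = 2L), class = "intensity_trace")
  f2 <- fit_assembly(short)
  expect_false(f2$fit_ok)
  expect_match(f2$reason, "4 points")
})

test_that("noiseless exponential disassembly is recovered with exact t-half", {
  tt <- seq(0, 14) * 0.75
  trace <- structure(list(times = tt, values = rm3(100 * exp(-0.2 * tt)),
                          peak_index = 1L), class = "intensity_trace")
  fit <- fit_disassembly(trace)
  expect_true(fit$fit_ok)
  expect_equal(fit$rate, 0.2, tolerance = 0.002)
  expect_equal(fit$t_half, log(2) / 0.2, tolerance = 0.02)  # 3.4657 s
})

test_that("flat post-peak segments are flagged as no-decay", {
  flat <- structure(list(times = (0:9) * 0.75,
                         values = c(0, 50, 100, rep(100, 7)),
                         peak_index = 3L), class = "intensity_trace")
  expect_false(fit_disassembly(flat)$fit_ok)
})

test_that("kinetics summary combines fits, duration and lifetime", {
  asm <- list(amplitude = 100, rate = 0.8, t_half = 3, residual_norm = 0,
              fit_ok = TRUE, reason = NA_character_)
  dis <- list(amplitude = 100, rate = 0.3, t_half = 18, residual_norm = 0,
              fit_ok = TRUE, reason = NA_character_)
  row <- summarize_kinetics(16L, asm, dis)
  expect_equal(row$lifetime_s, 15)
  expect_equal(row$duration_frames, 16L)

  track <- data.frame(track_id = 7L, frame = 5:20)
  row2 <- summarize_kinetics(track, asm, dis)
  expect_equal(row2$duration_frames, 16L)
  expect_equal(row2$track_id, 7L)

  bad <- list(amplitude = NA, rate = NA, t_half = NA, residual_norm = NA,
              fit_ok = FALSE, reason = "no assembly phase")
  row3 <- summarize_kinetics(track, bad, dis)
  expect_false(row3$fit_ok)
  expect_true(is.na(row3$lifetime_s))
  expect_equal(row3$duration_frames, 16L)  # retained for duration stats
  expect_match(row3$reason, "no assembly")
})

test_that("rates, half-times and lifetime are scale equivariant", {
  tr <- simulate_kinetic_trace(amplitude = 500, steepness = 0.8,
                               decay_rate = 0.3, lifetime = 17,
                               noise_sd = 20, seed = 2L)
  p1 <- preprocess_trace(tr$values, 0.75)
  p2 <- preprocess_trace(tr$values * 4.2, 0.75)
  a1 <- fit_assembly(p1); a2 <- fit_assembly(p2)
  d1 <- fit_disassembly(p1); d2 <- fit_disassembly(p2)
  expect_equal(a2$rate, a1$rate, tolerance = 1e-5)
  expect_equal(a2$t_half, a1$t_half, tolerance = 1e-5)
  expect_equal(a2$amplitude, 4.2 * a1$amplitude, tolerance = 1e-4)
  expect_equal(d2$rate, d1$rate, tolerance = 1e-5)
  expect_equal(d2$t_half, d1$t_half, tolerance = 1e-5)
})

test_that("parameter recovery over a seeded noisy ensemble stays tight", {
  # noise corresponds to pixel-level SNR ~10 after MFI mask averaging
  set.seed(42)
  res <- t(vapply(1:120, function(i) {
    A <- runif(1, 480, 520)
    s <- runif(1, 0.6, 1.0)
    d <- runif(1, 0.12, 0.2)
    L <- runif(1, 15, 20)
    tr <- simulate_kinetic_trace(A, s, d, L, noise_sd = A / 30)
    pt <- preprocess_trace(tr$values, 0.75)
    fa <- fit_assembly(pt)
    fd <- fit_disassembly(pt)
    c(ok = fa$fit_ok && fd$fit_ok,
      es = abs(fa$rate - s) / s,
      ed = abs(fd$rate - d) / d,
      eL = abs(fd$t_half - fa$t_half - L) / L)
  }, numeric(4)))
  ok <- res[, "ok"] == 1
  expect_gt(mean(ok), 0.95)
  expect_lt(median(res[ok, "es"]), 0.10)
  expect_lt(median(res[ok, "ed"]), 0.10)
  expect_lt(median(res[ok, "eL"]), 0.10)
})

test_that("median assembly half-time is unbiased over a noisy ensemble", {
  # fixed-parameter logistic traces at trace-level SNR 10
  set.seed(7)
  th_hat <- vapply(1:100, function(i) {
    tl <- seq(0, 16) * 0.75
    vals <- rm3(100 / (1 + exp(-0.5 * (tl - 5))) + rnorm(length(tl), 0, 10))
    trace <- structure(list(times = tl, values = vals,
                            peak_index = which.max(vals)),
                       class = "intensity_trace")
    f <- fit_assembly(trace)
    if (isTRUE(f$fit_ok)) f$t_half else NA_real_
  }, numeric(1))
  expect_lt(abs(median(th_hat, na.rm = TRUE) - 5) / 5, 0.05)
})

test_that("lifetime is non-negative whenever both fits succeed", {
  set.seed(31)
  for (i in 1:25) {
    tr <- simulate_kinetic_trace(amplitude = 500,
                                 steepness = runif(1, 0.6, 1.0),
                                 decay_rate = runif(1, 0.12, 0.2),
                                 lifetime = runif(1, 15, 20),
                                 noise_sd = 40)
    pt <- preprocess_trace(tr$values, 0.75)
    fa <- fit_assembly(pt)
    fd <- fit_disassembly(pt)
    if (isTRUE(fa$fit_ok) && isTRUE(fd$fit_ok)) {
      expect_gte(fd$t_half - fa$t_half, 0)
    }
  }
})
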