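#' Relative fluorescence intensity of a bleached ROI
#'
#' Background-subtracts the bleached-ROI integrated intensity and
#' normalizes it to the first pre-bleach frame:
#' `RFI = (I_t - I_bgt) / (I_pre - I_bgpre)`.
#'
#' @param I_t bleached-ROI integrated intensity at each time point.
#' @param I_bgt background-ROI integrated intensity at each time point.
#' @param I_pre bleached-ROI integrated intensity at the initial pre-bleach
#'   frame.
#' @param I_bgpre background-ROI integrated intensity at the initial
#'   pre-bleach frame.
#' @param trace_id optional identifier used in error messages.
#' @return numeric vector of RFI values.
#' @export
compute_rfi <- function(I_t, I_bgt, I_pre, I_bgpre, trace_id = NULL) {
  denom <- I_pre - I_bgpre
  if (!is.finite(denom) || denom == 0) {
    stop(sprintf(
      "zero pre-bleach denominator (I_pre - I_bgpre) for trace %s",
      if (is.null(trace_id)) "<unnamed>" else as.character(trace_id)))
  }
  (I_t - I_bgt) / denom
}

#' Fit an exponential-plateau recovery curve to a FRAP trace
#'
#' Least-squares fit of `Y(t) = Ym - (Ym - Y0) * exp(-k t)` to the
#' post-bleach RFI values with `t <= window` (time 0 at the first
#' post-bleach frame).  The recovery half-time is `log(2)/k`.  `FRFI_0` is
#' the fitted curve at t = 0 and `FRFI_f` the fitted curve at the window
#' end, the two quantities entering [immobile_fraction()].
#'
#' @param trace data frame with `time_s` and `rfi` columns (see
#'   [frap_rfi()]); pre-bleach rows (negative times) are ignored.
#' @param window analysis window in seconds (typically 15 or 20).
#' @return list: `k` (1/s), `Ym`, `FRFI_0`, `FRFI_f`, `t_half` (s),
#'   `fit_ok`, `reason`.  Optimizer failure, fewer than 6 points in the
#'   window, or a rate at its bounds yield `fit_ok = FALSE`.
#' @export
fit_recovery <- function(trace, window = 20) {
  stopifnot(all(c("time_s", "rfi") %in% names(trace)))
  sel <- trace$time_s >= 0 & trace$time_s <= window
  tt <- trace$time_s[sel]
  y <- trace$rfi[sel]
  bad <- function(reason) list(k = NA_real_, Ym = NA_real_,
                               FRFI_0 = NA_real_, FRFI_f = NA_real_,
                               t_half = NA_real_, fit_ok = FALSE,
                               reason = reason)
  if (length(tt) < 6) return(bad("fewer than 6 post-bleach points in window"))
  y0_0 <- y[1]
  ym_0 <- min(max(mean(utils::tail(y, 3)), y0_0 + 1e-3), 1.5)
  gap <- ym_0 - y
  posg <- gap > 1e-4
  k0 <- if (sum(posg) >= 2) {
    sl <- stats::coef(stats::lm(log(gap[posg]) ~ tt[posg]))[2]
    if (is.finite(sl) && sl < 0) -sl else 0.1
  } else 0.1
  k0 <- min(max(k0, 2e-3), 5)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ Ym - (Ym - Y0) * exp(-k * tt),
      start = list(Y0 = y0_0, Ym = ym_0, k = k0),
      lower = c(Y0 = -1, Ym = 1e-6, k = 1e-3),
      upper = c(Y0 = 1.5, Ym = 1.5, k = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad("optimizer failure"))
  cf <- stats::coef(fit)
  if (at_bound(cf[["k"]], 1e-3, 10)) return(bad("rate constant at bound"))
  k <- cf[["k"]]; ym <- cf[["Ym"]]; y0 <- cf[["Y0"]]
  list(k = k, Ym = ym,
       FRFI_0 = y0,
       FRFI_f = ym - (ym - y0) * exp(-k * window),
       t_half = log(2) / k,
       fit_ok = TRUE, reason = NA_character_)
}

#' Immobile fraction from fitted FRAP curve values
#'
#' `IMf = 1 - (FRFI_f - FRFI_0) / (1 - FRFI_0)`: the fraction of the
#' bleached fluorescence that has not recovered by the end of the analysis
#' window.  Values outside \[0, 1\] are reported as-is with a warning (no
#' clipping).
#'
#' @param FRFI_0 fitted RFI at t = 0 (must be < 1: there must be bleach
#'   depth to recover from).
#' @param FRFI_f fitted RFI at the window end.
#' @return the immobile fraction.
#' @export
immobile_fraction <- function(FRFI_0, FRFI_f) {
  if (any(FRFI_0 >= 1)) {
    stop("FRFI_0 >= 1: no bleach depth, immobile fraction undefined")
  }
  imf <- 1 - (FRFI_f - FRFI_0) / (1 - FRFI_0)
  out_of_range <- imf < 0 | imf > 1
  if (any(out_of_range)) {
    warning(sprintf("%d immobile fraction value(s) outside [0, 1]",
                    sum(out_of_range)))
  }
  imf
}

# Robust scale: 68.27th percentile of absolute residuals with the
# small-sample correction N/(N - K).
rsdr_scale <- function(resid, n_params = 1L) {
  n <- length(resid)
  as.numeric(stats::quantile(abs(resid), 0.6827, names = FALSE)) *
    n / max(1L, n - n_params)
}

#' Robust outlier detection (ROUT) on a single sample
#'
#' Identifies outliers from a robust constant-model fit: the location is
#' estimated by minimizing a Lorentzian merit function (iterating with the
#' robust standard deviation of the residuals, the 68.27th percentile of
#' their absolute values with a small-sample correction), each point gets a
#' two-tailed t-distribution tail probability for its scaled residual, and
#' points are selected by a false-discovery-rate scan at rate `Q` from the
#' most extreme residual inward (the i-th most extreme point is flagged
#' while its p-value is below `i * Q / n`; the scan stops at the first
#' point that fails).  The procedure is deterministic and invariant to the
#' order of the values.  Borderline calls may differ from closed-source
#' implementations of the same published procedure.
#'
#' @param values numeric vector (n >= 3; smaller samples return no
#'   outliers with a warning).
#' @param Q false-discovery coefficient (default 0.01, i.e. 1%).
#' @return logical mask, `TRUE` for outliers.
#' @export
rout_outliers <- function(values, Q = 0.01) {
  n <- length(values)
  mask <- rep(FALSE, n)
  if (n < 3) {
    warning("ROUT needs at least 3 values; returning no outliers")
    return(mask)
  }
  m <- stats::median(values)
  s <- rsdr_scale(values - m)
  if (s > 0) {
    for (it in 1:50) {
      m_new <- stats::optimize(
        function(mm) sum(log1p(((values - mm) / s)^2)),
        interval = range(values))$minimum
      s_new <- rsdr_scale(values - m_new)
      done <- abs(m_new - m) < 1e-10 * (1 + abs(m))
      m <- m_new
      if (s_new <= 0) break
      s <- s_new
      if (done) break
    }
  }
  resid <- values - m
  s <- rsdr_scale(resid)
  if (s <= 0) {
    # degenerate spread: any point off the fitted location is an outlier
    return(abs(resid) > 0)
  }
  p <- 2 * stats::pt(abs(resid) / s, df = n - 1L, lower.tail = FALSE)
  ord <- order(p)
  for (i in seq_len(n)) {
    if (p[ord[i]] < Q * i / n) mask[ord[i]] <- TRUE else break
  }
  mask
}

#' Apply exclusion rules to fitted FRAP results
#'
#' Flags results whose half-time exceeds the acquisition time (default
#' 45 s), then runs ROUT (at coefficient `Q`) on the remaining half-times.
#' Failed fits are flagged first.  Excluded traces carry a reason and are
#' meant to be dropped from cumulative curves as well.
#'
#' @param results data frame with at least `trace_id`, `t_half` and
#'   `fit_ok` columns (see [frap_analyze()]).
#' @param t_max maximum admissible half-time in seconds.
#' @param Q ROUT false-discovery coefficient.
#' @return `results` with logical `excluded` and character
#'   `exclude_reason` columns.
#' @export
filter_frap_results <- function(results, t_max = 45, Q = 0.01) {
  stopifnot(nrow(results) >= 1)
  excluded <- rep(FALSE, nrow(results))
  reason <- rep(NA_character_, nrow(results))

  bad_fit <- !results$fit_ok
  excluded[bad_fit] <- TRUE
  reason[bad_fit] <- "fit failure"

  over <- !excluded & results$t_half > t_max
  excluded[over] <- TRUE
  reason[over] <- sprintf("t_half > %g s", t_max)

  rem <- which(!excluded)
  if (length(rem) >= 3) {
    out <- rout_outliers(results$t_half[rem], Q)
    excluded[rem[out]] <- TRUE
    reason[rem[out]] <- "ROUT outlier"
  }
  results$excluded <- excluded
  results$exclude_reason <- reason
  results
}

#' Cumulative FRAP recovery curve (mean and s.e.m.)
#'
#' Pointwise mean and standard error of the mean over the included traces,
#' which must share a common time grid.
#'
#' @param series long data frame with `trace_id`, `time_s` and `rfi`
#'   columns.
#' @param include trace ids to include (default: all).
#' @return data frame `time_s`, `mean`, `sem`, `n`.
#' @export
cumulative_curve <- function(series, include = unique(series$trace_id)) {
  ser <- series[series$trace_id %in% include, , drop = FALSE]
  if (nrow(ser) == 0) stop("no included traces: cannot build mean curve")
  grids <- split(ser$time_s, ser$trace_id)
  ref <- grids[[1]]
  same <- vapply(grids, function(g) length(g) == length(ref) &&
                   all(g == ref), logical(1))
  if (!all(same)) stop("included traces do not share a common time grid")
  vals <- split(ser$rfi, ser$time_s)
  tt <- as.numeric(names(vals))
  ordt <- order(tt)
  data.frame(
    time_s = tt[ordt],
    mean = vapply(vals, mean, numeric(1))[ordt],
    sem = vapply(vals, function(v) {
      if (length(v) < 2) 0 else stats::sd(v) / sqrt(length(v))
    }, numeric(1))[ordt],
    n = vapply(vals, length, integer(1))[ordt],
    row.names = NULL
  )
}

#' Full FRAP analysis of a series of traces
#'
#' Normalizes each trace to RFI, fits the exponential-plateau recovery in
#' the analysis window, derives half-times and immobile fractions, applies
#' the half-time cutoff and ROUT exclusion rules, and builds the
#' cumulative mean +/- s.e.m. curve over the surviving traces.
#'
#' @param series FRAP series data frame (see [simulate_frap_series()]); an
#'   `rfi` column is computed with [frap_rfi()] if absent.
#' @param window fit window in seconds (15 or 20 in typical use).
#' @param t_max half-time cutoff in seconds.
#' @param Q ROUT false-discovery coefficient.
#' @return list with `results` (per-trace data frame: `trace_id`, `k`,
#'   `Ym`, `FRFI_0`, `FRFI_f`, `t_half`, `immobile_fraction`, `fit_ok`,
#'   `excluded`, `exclude_reason`) and `curve` (see [cumulative_curve()]).
#' @export
frap_analyze <- function(series, window = 20, t_max = 45, Q = 0.01) {
  if (!"rfi" %in% names(series)) series <- frap_rfi(series)
  fits <- lapply(split(series, series$trace_id), function(tr) {
    f <- fit_recovery(tr, window = window)
    imf <- if (isTRUE(f$fit_ok) && f$FRFI_0 < 1) {
      suppressWarnings(immobile_fraction(f$FRFI_0, f$FRFI_f))
    } else NA_real_
    data.frame(trace_id = tr$trace_id[1], k = f$k, Ym = f$Ym,
               FRFI_0 = f$FRFI_0, FRFI_f = f$FRFI_f, t_half = f$t_half,
               immobile_fraction = imf, fit_ok = f$fit_ok,
               reason = f$reason)
  })
  results <- do.call(rbind, fits)
  rownames(results) <- NULL
  results <- filter_frap_results(results, t_max = t_max, Q = Q)
  curve <- cumulative_curve(series,
                            include = results$trace_id[!results$excluded])
  list(results = results, curve = curve)
}
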