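#' Preprocess a punctae MFI trace for kinetics fitting
#'
#' Subtracts the first-frame MFI from all frames (so the trace starts at
#' zero) and applies a centred three-frame running average, shrinking the
#' window to the available neighbours at both ends (a window of two at the
#' first and last point).  The peak index is the first occurrence of the
#' maximum of the smoothed trace.
#'
#' @param mfi_trace numeric vector of per-frame MFI values.
#' @param frame_interval frame interval in seconds.
#' @return list of class `intensity_trace` with `times` (seconds, starting
#'   at 0), `values` (baseline-subtracted, smoothed), `raw`
#'   (baseline-subtracted, unsmoothed) and `peak_index` (1-based index into
#'   `values`).
#' @export
preprocess_trace <- function(mfi_trace, frame_interval) {
  n <- length(mfi_trace)
  if (n < 3) stop("trace shorter than 3 frames cannot be preprocessed")
  v <- mfi_trace - mfi_trace[1]
  sm <- running_mean3(v)
  structure(list(
    times = (seq_len(n) - 1) * frame_interval,
    values = sm,
    raw = v,
    peak_index = which.max(sm)
  ), class = "intensity_trace")
}

fit_bounds <- c(lower = 1e-3, upper = 1e2)  # rate bounds, 1/s

# centred 3-frame running average with shrink-to-available-neighbours ends
running_mean3 <- function(v) {
  n <- length(v)
  vapply(seq_len(n), function(i) mean(v[max(1, i - 1):min(n, i + 1)]),
         numeric(1))
}

at_bound <- function(x, lower, upper, rel = 1e-4) {
  x <= lower * (1 + rel) || x >= upper * (1 - rel)
}

failed_fit <- function(reason) {
  list(amplitude = NA_real_, rate = NA_real_, t_half = NA_real_,
       residual_norm = NA_real_, fit_ok = FALSE, reason = reason)
}

#' Fit the logistic assembly phase of an intensity trace
#'
#' Least-squares fit of `A / (1 + exp(-s (t - t_half))) + C` to the
#' smoothed trace from its start through the peak; the model is passed
#' through the same three-frame running average as the data so the filter
#' does not bias the steepness, and the small baseline `C` absorbs the
#' first-frame MFI subtraction (the trace is pinned to zero at a frame
#' where the adhesion already carries some intensity).  The assembly rate
#' is the logistic steepness `s` (1/s); `t_half` is the time the fitted
#' logistic component crosses half its amplitude, constrained to lie
#' between 0 and the peak time.
#'
#' @param trace an [preprocess_trace()] result.
#' @return list with `amplitude`, `rate` (1/s), `t_half` (s),
#'   `residual_norm`, `fit_ok`, and a failure `reason` (NA when ok).
#'   Degenerate segments (fewer than 4 points, no rise, rate at its
#'   bounds, optimizer failure) return `fit_ok = FALSE` rather than
#'   raising an error.
#' @export
fit_assembly <- function(trace) {
  pk <- trace$peak_index
  if (pk < 4) {
    return(failed_fit(if (pk == 1) "no assembly phase (trace peaks at start)"
                      else "fewer than 4 points before peak"))
  }
  # when affordable, drop the peak point itself: its running-average window
  # straddles the decay side and would bias the steepness
  end <- if (pk >= 5 && pk < length(trace$values)) pk - 1L else pk
  tt <- trace$times[1:end]
  y <- trace$values[1:end]
  a0 <- max(y)
  if (a0 <= 0) return(failed_fit("no assembly phase (non-positive values)"))
  t10 <- tt[which(y >= 0.1 * a0)[1]]
  t90 <- tt[which(y >= 0.9 * a0)[1]]
  s0 <- if (is.finite(t90 - t10) && t90 > t10) 4 / (t90 - t10) else
    4 / (tt[pk] - tt[1] + 1e-9)
  s0 <- min(max(s0, 2 * fit_bounds["lower"]), 0.5 * fit_bounds["upper"])
  th0 <- tt[which(y >= 0.5 * a0)[1]]
  fit <- NULL
  for (start in list(list(A = a0, s = as.numeric(s0), th = th0, C = 0),
                     list(A = a0, s = 2 * as.numeric(s0),
                          th = th0 / 2 + 0.1, C = 0))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ running_mean3(A / (1 + exp(-s * (tt - th))) + C),
        start = start,
        lower = c(A = 1e-9, s = fit_bounds[["lower"]], th = 0,
                  C = -3 * a0),
        upper = c(A = 10 * a0, s = fit_bounds[["upper"]],
                  th = trace$times[pk], C = 0.3 * a0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(failed_fit("optimizer failure"))
  cf <- stats::coef(fit)
  if (at_bound(cf[["s"]], fit_bounds[["lower"]], fit_bounds[["upper"]])) {
    return(failed_fit("assembly rate at bound"))
  }
  list(amplitude = cf[["A"]], rate = cf[["s"]], t_half = cf[["th"]],
       residual_norm = sqrt(sum(stats::resid(fit)^2)),
       fit_ok = TRUE, reason = NA_character_)
}

#' Fit the exponential disassembly phase of an intensity trace
#'
#' Least-squares fit of `A * exp(-s max(0, t - t_onset)) + C` to the
#' smoothed trace from the peak to the end.  Two nuisance parameters make
#' the exponential-decay rate identifiable on real traces: the onset is
#' fitted as a bounded lag after the peak (because the intensity commonly
#' plateaus before disassembly starts, and under noise the trace maximum
#' is a poor estimator of the disassembly onset), and a small baseline
#' `C` absorbs the first-frame MFI subtraction, which forces the observed
#' decay to approach the (negative of the) punctae's nucleation intensity
#' rather than zero.  With no plateau and a zero baseline the model
#' reduces to a pure exponential from the peak.  The disassembly rate is
#' the decay constant `s` (1/s); `t_half` is `t_onset + log(2)/s`, the
#' time the decaying component falls to half its onset value.
#'
#' @inheritParams fit_assembly
#' @return same structure as [fit_assembly()], plus `t_onset` (s).
#' @export
fit_disassembly <- function(trace) {
  pk <- trace$peak_index
  n <- length(trace$values)
  if (n - pk + 1 < 4) return(failed_fit("fewer than 4 points after peak"))
  tau <- trace$times[pk:n] - trace$times[pk]
  y <- trace$values[pk:n]
  a0 <- max(y)
  if (a0 <= 0) return(failed_fit("non-positive peak value"))
  tau_max <- tau[length(tau)]
  lag0 <- tau[max(which(y >= 0.9 * a0))]
  lag_hi <- max(tau_max - 3 * (tau[2] - tau[1]), 0)  # keep >= 4 decay points
  lag0 <- min(lag0, lag_hi)
  dec <- y <= 0.9 * a0 & y > 0.01 * a0
  s0 <- if (sum(dec) >= 2) {
    sl <- stats::coef(stats::lm(log(y[dec]) ~ tau[dec]))[2]
    if (is.finite(sl) && sl < 0) -sl else fit_bounds[["lower"]] * 2
  } else fit_bounds[["lower"]] * 2
  s0 <- min(max(s0, 2 * fit_bounds["lower"]), 0.5 * fit_bounds["upper"])
  # the data were smoothed with a 3-frame running average, which rounds the
  # plateau-to-decay shoulder; pass the model through the same filter so the
  # kink does not bias the rate (a pure exponential is rate-invariant under
  # the filter, so decay-only segments are unaffected)
  fit <- NULL
  for (start in list(list(A = a0, s = as.numeric(s0), lag = lag0, C = 0),
                     list(A = a0, s = as.numeric(s0), lag = 0, C = 0),
                     list(A = a0, s = 2 * as.numeric(s0),
                          lag = lag_hi / 2, C = 0))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ running_mean3(A * exp(-s * pmax(0, tau - lag)) + C),
        start = start,
        lower = c(A = 1e-9, s = fit_bounds[["lower"]], lag = 0,
                  C = -3 * a0),
        upper = c(A = 10 * a0, s = fit_bounds[["upper"]], lag = lag_hi,
                  C = 0.3 * a0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(failed_fit("optimizer failure"))
  cf <- stats::coef(fit)
  if (at_bound(cf[["s"]], fit_bounds[["lower"]], fit_bounds[["upper"]])) {
    return(failed_fit("decay rate at bound"))
  }
  if (cf[["A"]] < 0.3 * a0) {
    return(failed_fit("no decay phase (flat post-peak segment)"))
  }
  t_onset <- trace$times[pk] + cf[["lag"]]
  list(amplitude = cf[["A"]], rate = cf[["s"]],
       t_half = t_onset + log(2) / cf[["s"]],
       t_onset = t_onset,
       residual_norm = sqrt(sum(stats::resid(fit)^2)),
       fit_ok = TRUE, reason = NA_character_)
}

#' Summarize per-track kinetics
#'
#' Combines a track's duration with its assembly and disassembly fits.
#' The adhesion lifetime is the time the fitted intensity stays above half
#' of its maximum: the difference between the disassembly and assembly
#' half-times.  Tracks with a failed fit carry `NA` lifetime and rates (a
#' reason is recorded) but keep their duration.
#'
#' @param track data frame of one track's detections (uses `track_id` and
#'   the number of rows as duration), or a single integer duration.
#' @param assembly result of [fit_assembly()].
#' @param disassembly result of [fit_disassembly()].
#' @return one-row data frame: `track_id`, `duration_frames`,
#'   `assembly_rate`, `assembly_t_half_s`, `disassembly_rate`,
#'   `disassembly_t_half_s`, `lifetime_s`, `fit_ok`, `reason`.
#' @export
summarize_kinetics <- function(track, assembly, disassembly) {
  if (is.data.frame(track)) {
    id <- if ("track_id" %in% names(track)) track$track_id[1] else NA_integer_
    dur <- nrow(track)
  } else {
    id <- NA_integer_
    dur <- as.integer(track)
  }
  ok <- isTRUE(assembly$fit_ok) && isTRUE(disassembly$fit_ok)
  reason <- if (ok) NA_character_ else
    paste(stats::na.omit(c(assembly$reason, disassembly$reason)),
          collapse = "; ")
  data.frame(
    track_id = id,
    duration_frames = dur,
    assembly_rate = if (ok) assembly$rate else NA_real_,
    assembly_t_half_s = if (ok) assembly$t_half else NA_real_,
    disassembly_rate = if (ok) disassembly$rate else NA_real_,
    disassembly_t_half_s = if (ok) disassembly$t_half else NA_real_,
    lifetime_s = if (ok) disassembly$t_half - assembly$t_half else NA_real_,
    fit_ok = ok,
    reason = reason
  )
}

#' Kinetics for every track in a movie
#'
#' Runs [preprocess_trace()], [fit_assembly()], [fit_disassembly()] and
#' [summarize_kinetics()] over each track's channel-1 MFI trace.
#'
#' @param tracks data frame of tracked detections with `track_id`, `frame`
#'   and `mfi_ch1` columns (e.g. filtered output of [link_tracks()] on
#'   [detect_stack()] detections).
#' @param frame_interval frame interval in seconds.
#' @return data frame with one row per track, as [summarize_kinetics()].
#' @export
track_kinetics <- function(tracks, frame_interval) {
  if (nrow(tracks) == 0) {
    return(summarize_kinetics(data.frame(track_id = integer(0)),
                              failed_fit("x"), failed_fit("x"))[0, ])
  }
  res <- lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    trace <- preprocess_trace(tr$mfi_ch1, frame_interval)
    summarize_kinetics(tr, fit_assembly(trace), fit_disassembly(trace))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$track_id), , drop = FALSE]
}
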