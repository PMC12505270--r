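#' Simulate FRAP intensity series with ground truth
#'
#' Generates seeded photobleaching experiments on the raw integrated-density
#' scale.  Each trace has `n_prebleach` pre-bleach frames followed by
#' post-bleach frames every `frame_interval` seconds for `post_duration`
#' seconds; time 0 is the first post-bleach frame (pre-bleach frames carry
#' negative times).  The underlying relative fluorescence intensity is 1
#' before the bleach and recovers as
#' `RFI(t) = plateau - (plateau - bleach_depth) * exp(-k t)` afterwards,
#' with additive Gaussian noise of sd `noise_sd`.  Bleached-ROI and
#' background-ROI integrated densities consistent with that RFI are emitted
#' so that the normalization of [compute_rfi()] is exercised end to end;
#' the first pre-bleach frame is the normalization reference and therefore
#' has RFI exactly 1.
#'
#' @param config a [frap_sim_config()] object.
#' @return list with `series` (data frame: `trace_id`, `frame` 0-based,
#'   `time_s`, `phase` in `pre`/`post`, `I_t`, `I_bg`) and `truth` (one row
#'   per trace: `trace_id`, `k`, `t_half_s = log(2)/k`, `bleach_depth`,
#'   `plateau`, `immobile_fraction`).
#' @export
simulate_frap_series <- function(config) {
  stopifnot(inherits(config, "frap_sim_config"))
  if (config$post_duration < config$frame_interval) {
    stop("post_duration must be at least one frame_interval of imaging")
  }
  with_sim_seed(config$seed, simulate_frap_impl(config))
}

simulate_frap_impl <- function(cfg) {
  dt <- cfg$frame_interval
  t_pre <- -(cfg$n_prebleach:1) * dt
  t_post <- seq(0, cfg$post_duration, by = dt)
  times <- c(t_pre, t_post)
  n_t <- length(times)
  phase <- rep(c("pre", "post"), c(length(t_pre), length(t_post)))

  series <- vector("list", cfg$n_traces)
  truth <- vector("list", cfg$n_traces)
  for (i in seq_len(cfg$n_traces)) {
    rfi <- ifelse(times < 0, 1,
                  cfg$plateau - (cfg$plateau - cfg$bleach_depth) *
                    exp(-cfg$rate_constant_k * pmax(times, 0)))
    if (cfg$noise_sd > 0) {
      rfi <- rfi + stats::rnorm(n_t, 0, cfg$noise_sd)
    }
    rfi[1] <- 1  # first pre-bleach frame defines the normalization

    i_pre_net <- stats::runif(1, 2e4, 5e4)   # pre-bleach ROI above background
    i_bg <- stats::runif(1, 500, 1500)       # constant background ROI level
    series[[i]] <- data.frame(
      trace_id = i,
      frame = seq_len(n_t) - 1L,
      time_s = times,
      phase = phase,
      I_t = rfi * i_pre_net + i_bg,
      I_bg = i_bg
    )
    truth[[i]] <- data.frame(
      trace_id = i,
      k = cfg$rate_constant_k,
      t_half_s = log(2) / cfg$rate_constant_k,
      bleach_depth = cfg$bleach_depth,
      plateau = cfg$plateau,
      immobile_fraction = 1 - (cfg$plateau - cfg$bleach_depth) /
        (1 - cfg$bleach_depth)
    )
  }
  list(series = do.call(rbind, series), truth = do.call(rbind, truth))
}

#' Normalize a FRAP series to relative fluorescence intensity
#'
#' Applies [compute_rfi()] per trace using the first pre-bleach frame as the
#' normalization reference.
#'
#' @param series a FRAP series data frame as produced by
#'   [simulate_frap_series()] (columns `trace_id`, `frame`, `time_s`,
#'   `phase`, `I_t`, `I_bg`).
#' @return the series with an `rfi` column appended.
#' @export
frap_rfi <- function(series) {
  stopifnot(all(c("trace_id", "time_s", "I_t", "I_bg") %in% names(series)))
  out <- lapply(split(series, series$trace_id), function(tr) {
    tr <- tr[order(tr$time_s), , drop = FALSE]
    tr$rfi <- compute_rfi(tr$I_t, tr$I_bg, tr$I_t[1], tr$I_bg[1],
                          trace_id = tr$trace_id[1])
    tr
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
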