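# Shared punctae intensity model: logistic rise to a peak, exponential decay
# after it.  `th` is the logistic midpoint, `t_peak` the rise/decay handover.
PLATEAU_FACTOR <- stats::plogis(5)  # amplitude fraction reached at the peak

puncta_profile <- function(t, amplitude, steepness, decay_rate, th, t_peak) {
  a_pk <- amplitude * stats::plogis(steepness * (t_peak - th))
  ifelse(t <= t_peak,
         amplitude * stats::plogis(steepness * (t - th)),
         a_pk * exp(-decay_rate * (t - t_peak)))
}

# Solve the profile timing for one punctae.  The programmed lifetime is the
# full width at half maximum of the un-truncated intensity profile: `t_up`
# is the time the profile crosses half its peak on the way up (essentially
# the logistic midpoint) and the matching downward crossing is
# t_up + lifetime (= t_peak + log(2)/decay_rate).
puncta_timing <- function(amplitude, steepness, decay_rate, lifetime,
                          edge_fraction, t_up = 0) {
  g <- PLATEAU_FACTOR
  th <- t_up - stats::qlogis(g / 2) / steepness
  t_peak <- t_up + lifetime - log(2) / decay_rate
  if (t_peak - th < 5 / steepness) {
    return(NULL)  # lifetime too short for these rates; caller redraws
  }
  a_pk_frac <- stats::plogis(steepness * (t_peak - th))
  t_birth <- th + stats::qlogis(edge_fraction) / steepness
  t_death <- t_peak + log(a_pk_frac / edge_fraction) / decay_rate
  list(th = th, t_peak = t_peak, t_birth = t_birth, t_death = t_death,
       t_up = t_up, t_down = t_up + lifetime)
}

#' Simulate a two-channel adhesion timelapse movie with ground truth
#'
#' Renders a seeded synthetic fluorescence timelapse: a convex cell body
#' translating at constant speed over a uniform background, carrying
#' diffraction-limited punctae (isotropic 2D Gaussians) whose amplitude
#' follows a logistic assembly, plateau, and exponential disassembly.  A
#' configured fraction of punctae also emit in channel 2 (co-localization).
#' Optional Poisson shot noise and Gaussian read noise are applied.
#'
#' Each punctae is rendered only between its programmed birth and death
#' frames, defined as the span over which its amplitude exceeds
#' `edge_fraction` of the peak; the ground-truth lifetime is the full
#' width at half maximum of the un-truncated profile, the time it spends
#' above half its peak.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `stack` (a [timelapse_stack()] with channels
#'   `ch1`, `ch2`) and `truth`, a data frame with one row per punctae: `id`,
#'   sub-pixel `row`/`col`, 0-based `birth_frame`/`death_frame`, `amplitude`,
#'   `assembly_steepness` (1/s), `decay_rate` (1/s), `lifetime_s`,
#'   `t_half_a_s`, `t_peak_s`, `t_half_d_s`, logical `coloc`, and
#'   `cell_speed_um_s`.
#' @examples
#' cfg <- sim_config(n_frames = 60L, n_punctae = 5L,
#'                   noise = list(poisson_on = FALSE, gaussian_sd = 0))
#' sim <- simulate_timelapse(cfg)
#' dim(sim$stack$ch1)
#' @export
simulate_timelapse <- function(config) {
  validate_sim_config(config)
  with_sim_seed(config$seed, simulate_timelapse_impl(config))
}

simulate_timelapse_impl <- function(cfg) {
  H <- cfg$image_shape[1]; W <- cfg$image_shape[2]
  nf <- cfg$n_frames; dt <- cfg$frame_interval
  f <- cfg$edge_fraction
  g <- PLATEAU_FACTOR
  hf <- (g + f) / 2

  # cell geometry: ellipse translating along the column axis
  ay <- 0.26 * H
  ax <- 0.19 * W
  vpx <- cfg$cell_speed * dt / cfg$pixel_size        # px per frame
  total_px <- vpx * (nf - 1)
  crow <- H / 2
  ccol0 <- (W - total_px) / 2
  if (ccol0 - ax < 2 || ccol0 + total_px + ax > W - 2) {
    stop("cell path does not fit in the field: reduce cell_speed, ",
         "n_frames or increase image width")
  }
  ccol <- ccol0 + vpx * (0:(nf - 1))

  n <- cfg$n_punctae
  n_coloc <- round(cfg$coloc_fraction * n)
  coloc <- rep(FALSE, n)
  if (n > 0 && n_coloc > 0) coloc[sample.int(n, n_coloc)] <- TRUE

  truth <- vector("list", n)
  placed <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    tim <- NULL
    for (try in 1:100) {
      A <- stats::runif(1, cfg$amplitude_range[1], cfg$amplitude_range[2])
      s <- stats::runif(1, cfg$assembly_steepness_range[1],
                        cfg$assembly_steepness_range[2])
      dr <- if (coloc[i] && !is.null(cfg$decay_rate_range_coloc))
        cfg$decay_rate_range_coloc else cfg$decay_rate_range
      d <- stats::runif(1, dr[1], dr[2])
      lr <- if (coloc[i] && !is.null(cfg$lifetime_range_coloc))
        cfg$lifetime_range_coloc else cfg$lifetime_range
      L <- stats::runif(1, lr[1], lr[2])
      tim0 <- puncta_timing(A, s, d, L, f)
      if (is.null(tim0)) next
      pre <- tim0$t_up - tim0$t_birth
      post <- tim0$t_death - tim0$t_up
      lo <- 2 * dt + pre
      hi <- (nf - 3) * dt - post
      if (hi <= lo) {
        stop("movie too short for the programmed punctae spans: ",
             "increase n_frames or shorten lifetime_range")
      }
      t_up <- stats::runif(1, lo, hi)
      tim <- puncta_timing(A, s, d, L, f, t_up)
      break
    }
    if (is.null(tim)) {
      stop("could not draw a consistent kinetic profile: lifetime_range is ",
           "too short for the configured steepness/decay ranges")
    }

    # place within the cell footprint at the punctae's mid-life
    mid_frame <- min(nf - 1, max(0, round((tim$t_birth + tim$t_death) / 2 / dt)))
    ok <- FALSE
    for (try in 1:2000) {
      theta <- stats::runif(1, 0, 2 * pi)
      q <- sqrt(stats::runif(1))
      prow <- crow + 0.8 * ay * q * sin(theta)
      pcol <- ccol[mid_frame + 1] + 0.8 * ax * q * cos(theta)
      if (nrow(placed) == 0 ||
          min(sqrt((placed[, 1] - prow)^2 + (placed[, 2] - pcol)^2)) >=
            cfg$min_separation) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf(paste0(
        "unable to place %d non-overlapping punctae with min_separation = ",
        "%g px inside the cell region; reduce n_punctae or min_separation"),
        n, cfg$min_separation))
    }
    placed <- rbind(placed, c(prow, pcol))

    truth[[i]] <- data.frame(
      id = i,
      row = prow - 1, col = pcol - 1,  # 0-based, matching detections
      birth_frame = ceiling(tim$t_birth / dt),
      death_frame = floor(tim$t_death / dt),
      amplitude = A,
      assembly_steepness = s,
      decay_rate = d,
      lifetime_s = L,
      t_half_a_s = tim$t_up,
      t_peak_s = tim$t_peak,
      t_half_d_s = tim$t_down,
      th = tim$th,
      coloc = coloc[i],
      cell_speed_um_s = cfg$cell_speed
    )
  }
  truth <- if (n > 0) do.call(rbind, truth) else data.frame()

  # render clean channels
  sigma <- cfg$punctae_sigma
  wr <- ceiling(4 * sigma)
  rows2 <- ((1:H) - crow)^2 / ay^2
  ch1 <- array(0, dim = c(H, W, nf))
  ch2 <- array(0, dim = c(H, W, nf))
  for (fr in seq_len(nf)) {
    cols2 <- ((1:W) - ccol[fr])^2 / ax^2
    cell <- outer(rows2, cols2, `+`) <= 1
    base1 <- cfg$background_level + cfg$cell_level * cell
    base2 <- cfg$background_level + 0.6 * cfg$cell_level * cell
    t_now <- (fr - 1) * dt
    if (n > 0) {
      alive <- which(truth$birth_frame <= fr - 1 & truth$death_frame >= fr - 1)
      for (i in alive) {
        amp <- puncta_profile(t_now, truth$amplitude[i],
                              truth$assembly_steepness[i],
                              truth$decay_rate[i],
                              truth$th[i], truth$t_peak_s[i])
        prow <- placed[i, 1]  # 1-based render coordinates
        pcol <- placed[i, 2]
        r0 <- max(1, floor(prow) - wr)
        r1 <- min(H, ceiling(prow) + wr)
        c0 <- max(1, floor(pcol) - wr)
        c1 <- min(W, ceiling(pcol) + wr)
        spot <- amp * exp(-(outer(((r0:r1) - prow)^2,
                                  ((c0:c1) - pcol)^2, `+`)) /
                            (2 * sigma^2))
        base1[r0:r1, c0:c1] <- base1[r0:r1, c0:c1] + spot
        if (truth$coloc[i]) {
          base2[r0:r1, c0:c1] <- base2[r0:r1, c0:c1] + spot
        }
      }
    }
    ch1[, , fr] <- base1
    ch2[, , fr] <- base2
  }

  if (isTRUE(cfg$noise$poisson_on)) {
    ch1[] <- stats::rpois(length(ch1), ch1)
    ch2[] <- stats::rpois(length(ch2), ch2)
  }
  if (cfg$noise$gaussian_sd > 0) {
    ch1[] <- ch1 + stats::rnorm(length(ch1), 0, cfg$noise$gaussian_sd)
    ch2[] <- ch2 + stats::rnorm(length(ch2), 0, cfg$noise$gaussian_sd)
    ch1[ch1 < 0] <- 0
    ch2[ch2 < 0] <- 0
  }

  truth$th <- NULL
  list(
    stack = timelapse_stack(ch1 = ch1, ch2 = ch2,
                            frame_interval = dt,
                            pixel_size = cfg$pixel_size),
    truth = truth
  )
}

#' Simulate a single punctae intensity trace
#'
#' Generates one mean-fluorescence-intensity trace following the same
#' kinetic model as [simulate_timelapse()] (logistic assembly, plateau,
#' exponential disassembly) without rendering images, for fast validation
#' of the curve-fitting stage.  The trace starts at the frame the profile
#' first exceeds `edge_fraction` of its peak; with the small default edge
#' fraction nearly the whole assembly phase is visible.
#'
#' @param amplitude peak amplitude (intensity units above baseline).
#' @param steepness logistic assembly steepness (1/s).
#' @param decay_rate exponential decay rate (1/s).
#' @param lifetime programmed lifetime in seconds (time the profile spends
#'   above half its peak).
#' @param frame_interval sampling interval in seconds.
#' @param edge_fraction visibility truncation fraction of peak amplitude.
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @param baseline constant added to all values.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return list with `times` (seconds, starting at 0), `values`, and
#'   `truth` (programmed parameters, with half-crossing times relative to
#'   the first sample).
#' @export
simulate_kinetic_trace <- function(amplitude = 500, steepness = 0.8,
                                   decay_rate = 0.16, lifetime = 17.5,
                                   frame_interval = 0.75,
                                   edge_fraction = 0.02,
                                   noise_sd = 0, baseline = 0,
                                   seed = NULL) {
  tim <- puncta_timing(amplitude, steepness, decay_rate, lifetime,
                       edge_fraction, t_up = 0)
  if (is.null(tim)) {
    stop("lifetime too short for the requested steepness/decay rates")
  }
  # shift time origin to the first visible frame
  shift <- tim$t_birth
  n_pts <- floor((tim$t_death - tim$t_birth) / frame_interval) + 1
  times <- (seq_len(n_pts) - 1) * frame_interval
  clean <- puncta_profile(times + shift, amplitude, steepness, decay_rate,
                          tim$th, tim$t_peak)
  add_noise <- function() {
    if (noise_sd > 0) clean + stats::rnorm(n_pts, 0, noise_sd) else clean
  }
  values <- if (is.null(seed)) add_noise() else with_sim_seed(seed, add_noise())
  list(
    times = times,
    values = values + baseline,
    truth = list(amplitude = amplitude, steepness = steepness,
                 decay_rate = decay_rate, lifetime = lifetime,
                 t_half_a = tim$t_up - shift,
                 t_peak = tim$t_peak - shift,
                 t_half_d = tim$t_down - shift)
  )
}
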