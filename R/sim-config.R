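#' Configuration for the synthetic timelapse simulator
#'
#' Builds a validated configuration for [simulate_timelapse()].  Defaults
#' emulate a typical acquisition of a single migrating *Dictyostelium* cell
#' expressing a fluorescently tagged adhesion marker: frames every 750 ms for
#' 3 minutes, diffraction-limited punctae whose intensity follows a logistic
#' rise, plateau and exponential decay with programmed lifetimes of 15-20 s,
#' an optional second channel marking a co-localizing protein, and a convex
#' cell body translating at constant speed.
#'
#' Punctae become visible (are rendered) from the frame their programmed
#' amplitude first exceeds `edge_fraction` of the peak amplitude until the
#' frame it last does; outside that span the adhesion does not exist.  The
#' programmed lifetime is the full width at half maximum of the
#' un-truncated intensity profile — the time it spends above half its peak
#' — which is the quantity the downstream kinetics fits recover as the gap
#' between the assembly and disassembly half-times.
#'
#' @param image_shape integer length-2, image height and width in pixels.
#' @param n_frames number of frames.
#' @param frame_interval frame interval in seconds.
#' @param pixel_size pixel size in micrometres per pixel.
#' @param n_punctae number of punctae to place.
#' @param punctae_sigma Gaussian PSF sigma in pixels.
#' @param amplitude_range length-2 numeric, uniform range of peak amplitudes
#'   (intensity counts above local background).
#' @param assembly_steepness_range length-2, logistic steepness range (1/s).
#' @param decay_rate_range length-2, exponential decay rate range (1/s).
#' @param lifetime_range length-2, programmed lifetime range in seconds.
#' @param lifetime_range_coloc optional length-2 lifetime range used for the
#'   channel-2-positive subpopulation; `NULL` uses `lifetime_range` for all.
#' @param decay_rate_range_coloc optional length-2 decay-rate range for the
#'   channel-2-positive subpopulation; `NULL` uses `decay_rate_range`.
#' @param coloc_fraction fraction of punctae that also emit in channel 2.
#' @param cell_speed cell translation speed in micrometres per second.
#' @param background_level camera background offset (counts).
#' @param cell_level additional cytoplasmic signal over the cell body
#'   (counts above background).
#' @param noise list with elements `poisson_on` (logical) and `gaussian_sd`
#'   (additive read noise sd in counts).
#' @param min_separation minimum centre-to-centre distance between punctae
#'   in pixels.
#' @param edge_fraction fraction of peak amplitude at which a punctae
#'   appears and disappears (its visibility truncation level).
#' @param seed integer seed; the same configuration and seed reproduce the
#'   simulation bit for bit.
#'
#' @return a list of class `sim_config`.
#' @seealso [simulate_timelapse()], [frap_sim_config()]
#' @export
sim_config <- function(image_shape = c(192L, 256L),
                       n_frames = 240L,
                       frame_interval = 0.75,
                       pixel_size = 0.11,
                       n_punctae = 40L,
                       punctae_sigma = 2,
                       amplitude_range = c(480, 520),
                       assembly_steepness_range = c(0.6, 1.0),
                       decay_rate_range = c(0.12, 0.2),
                       lifetime_range = c(15, 20),
                       lifetime_range_coloc = NULL,
                       decay_rate_range_coloc = NULL,
                       coloc_fraction = 0.5,
                       cell_speed = 0.05,
                       background_level = 100,
                       cell_level = 150,
                       noise = list(poisson_on = TRUE, gaussian_sd = 3),
                       min_separation = 10,
                       edge_fraction = 0.5,
                       seed = 1L) {
  cfg <- list(
    image_shape = as.integer(image_shape),
    n_frames = as.integer(n_frames),
    frame_interval = frame_interval,
    pixel_size = pixel_size,
    n_punctae = as.integer(n_punctae),
    punctae_sigma = punctae_sigma,
    amplitude_range = amplitude_range,
    assembly_steepness_range = assembly_steepness_range,
    decay_rate_range = decay_rate_range,
    lifetime_range = lifetime_range,
    lifetime_range_coloc = lifetime_range_coloc,
    decay_rate_range_coloc = decay_rate_range_coloc,
    coloc_fraction = coloc_fraction,
    cell_speed = cell_speed,
    background_level = background_level,
    cell_level = cell_level,
    noise = noise,
    min_separation = min_separation,
    edge_fraction = edge_fraction,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$image_shape) == 2L, all(cfg$image_shape >= 32L),
    cfg$n_frames >= 3L,
    cfg$frame_interval > 0,
    cfg$pixel_size > 0,
    cfg$n_punctae >= 0L,
    cfg$punctae_sigma > 0,
    cfg$coloc_fraction >= 0, cfg$coloc_fraction <= 1,
    cfg$cell_speed >= 0,
    cfg$background_level >= 0,
    cfg$min_separation > 0,
    cfg$edge_fraction > 0, cfg$edge_fraction < 1,
    is.list(cfg$noise), is.logical(cfg$noise$poisson_on),
    cfg$noise$gaussian_sd >= 0
  )
  for (nm in c("amplitude_range", "assembly_steepness_range",
               "decay_rate_range", "lifetime_range")) {
    rg <- cfg[[nm]]
    if (length(rg) != 2L || rg[1] > rg[2] || rg[1] <= 0) {
      stop(sprintf("'%s' must be length 2 with 0 < min <= max", nm))
    }
  }
  for (nm in c("lifetime_range_coloc", "decay_rate_range_coloc")) {
    rg <- cfg[[nm]]
    if (!is.null(rg) &&
        (length(rg) != 2L || rg[1] > rg[2] || rg[1] <= 0)) {
      stop(sprintf("'%s' must be length 2 with 0 < min <= max", nm))
    }
  }
  invisible(cfg)
}

#' Configuration for the synthetic FRAP simulator
#'
#' Builds a validated configuration for [simulate_frap_series()].  Defaults
#' mirror a photobleaching experiment on a single adhesion punctae: frames
#' every 500 ms, three pre-bleach frames, 45 s of post-bleach imaging, and a
#' recovery with half-time 2.4 s whose plateau leaves an immobile fraction
#' of 0.63.
#'
#' @param n_traces number of bleached punctae to simulate.
#' @param frame_interval frame interval in seconds.
#' @param n_prebleach number of pre-bleach frames (>= 1).
#' @param post_duration duration of post-bleach imaging in seconds.
#' @param bleach_depth relative fluorescence intensity (RFI) at the first
#'   post-bleach frame.
#' @param plateau asymptotic RFI of the recovery.
#' @param rate_constant_k recovery rate constant in 1/s.
#' @param noise_sd additive Gaussian noise sd on the RFI scale.
#' @param roi_size bleach region edge length in micrometres (bookkeeping
#'   only; intensities are simulated as ROI-integrated densities).
#' @param seed integer seed.
#'
#' @return a list of class `frap_sim_config`.
#' @export
frap_sim_config <- function(n_traces = 50L,
                            frame_interval = 0.5,
                            n_prebleach = 3L,
                            post_duration = 45,
                            bleach_depth = 0.2,
                            plateau = 0.496,
                            rate_constant_k = log(2) / 2.4,
                            noise_sd = 0.05,
                            roi_size = 1,
                            seed = 1L) {
  cfg <- list(
    n_traces = as.integer(n_traces),
    frame_interval = frame_interval,
    n_prebleach = as.integer(n_prebleach),
    post_duration = post_duration,
    bleach_depth = bleach_depth,
    plateau = plateau,
    rate_constant_k = rate_constant_k,
    noise_sd = noise_sd,
    roi_size = roi_size,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_traces >= 1L,
    cfg$frame_interval > 0,
    cfg$n_prebleach >= 1L,
    cfg$bleach_depth >= 0, cfg$bleach_depth <= cfg$plateau,
    cfg$plateau <= 1.5,
    cfg$rate_constant_k > 0,
    cfg$noise_sd >= 0
  )
  class(cfg) <- "frap_sim_config"
  cfg
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_sim_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}
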