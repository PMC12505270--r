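#' Assemble a full pipeline configuration
#'
#' Bundles the simulation and analysis settings for [run_pipeline()].
#' Biological replicates are emulated by independent simulations whose
#' seeds are derived deterministically from the top-level `seed`.
#'
#' @param sim a [sim_config()] for the timelapse simulator.
#' @param n_replicates number of biological replicates (independent
#'   movies).
#' @param detection a [detection_params()] list.
#' @param max_displacement linking gate in pixels.
#' @param coloc_ratio,coloc_frac thresholds of [classify_channel2()].
#' @param frap optional [frap_sim_config()]; `NULL` skips the FRAP stage.
#' @param frap_window,frap_tmax FRAP fit window and half-time cutoff (s).
#' @param rout_q ROUT false-discovery coefficient used throughout.
#' @param seed top-level integer seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            n_replicates = 2L,
                            detection = detection_params(),
                            max_displacement = 3,
                            coloc_ratio = 1.5,
                            coloc_frac = 0.5,
                            frap = frap_sim_config(),
                            frap_window = 20,
                            frap_tmax = 45,
                            rout_q = 0.01,
                            seed = 1L) {
  structure(list(sim = sim, n_replicates = as.integer(n_replicates),
                 detection = detection, max_displacement = max_displacement,
                 coloc_ratio = coloc_ratio, coloc_frac = coloc_frac,
                 frap = frap, frap_window = frap_window,
                 frap_tmax = frap_tmax, rout_q = rout_q,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' [pipeline_config()] (with `sim`, `detection` and `frap` given as nested
#' mappings of the corresponding constructor arguments).
#'
#' @param path path to a YAML file.
#' @return a `pipeline_config` list.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$sim)) args$sim <- do.call(sim_config, raw$sim)
  if (!is.null(raw$detection)) {
    args$detection <- do.call(detection_params, raw$detection)
  }
  if (!is.null(raw$frap)) args$frap <- do.call(frap_sim_config, raw$frap)
  do.call(pipeline_config, args)
}

analysis_metrics <- c("lifetime_s", "duration_frames",
                      "assembly_rate", "disassembly_rate")

#' Run the full adhesion-dynamics pipeline on simulated replicates
#'
#' For each replicate: simulates a two-channel movie, detects and links
#' punctae, applies the first/last-frame and minimum-duration track
#' filters, classifies channel-2 co-localization, extracts per-track
#' kinetics (duration, assembly/disassembly rates, lifetime), and tracks
#' whole-cell migration speed.  Pooled across replicates, the channel-2
#' positive and negative populations are compared (Wilcoxon rank-sum with
#' ROUT pre-filtering, median with 95% CI) for each kinetic metric, with
#' SuperPlot tables for replicate-level context.  When at least three
#' replicates are available, per-cell mean adhesion duration is correlated
#' with migration speed.  An optional FRAP stage simulates and analyses a
#' recovery experiment.  Identical configurations (including seed) produce
#' identical outputs.
#'
#' @param config a [pipeline_config()] (or path to a YAML file for
#'   [load_pipeline_config()]).
#' @param out_dir optional output directory; when given, writes
#'   `tracks.csv`, `kinetics.csv`, `cells.csv`, `comparison.csv`,
#'   `superplot.csv`, `correlations.csv`, `frap_results.csv`,
#'   `frap_curve.csv` and `manifest.json`.
#' @return invisibly, a list with `tracks`, `kinetics`, `cells`,
#'   `comparisons`, `superplot`, `correlations`, `frap`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))

  all_tracks <- list()
  all_kin <- list()
  cells <- list()
  counts <- list()
  for (rep_i in seq_len(config$n_replicates)) {
    rep_seed <- config$seed + 997L * (rep_i - 1L)
    sim_cfg <- config$sim
    sim_cfg$seed <- rep_seed
    sim <- simulate_timelapse(sim_cfg)
    stage <- function(what, value) {
      counts[[sprintf("replicate_%d", rep_i)]][[what]] <<- value
    }

    det <- detect_stack(sim$stack, channel = 1L, params = config$detection)
    stage("detections", nrow(det))
    tracks <- link_tracks(det, max_displacement = config$max_displacement)
    stage("tracks_linked", length(unique(tracks$track_id)))
    tracks <- filter_tracks(tracks, n_frames_total = n_frames(sim$stack))
    stage("tracks_after_filter", length(unique(tracks$track_id)))

    coloc <- coloc_calls(tracks, sim$stack,
                         ratio_threshold = config$coloc_ratio,
                         frame_fraction_threshold = config$coloc_frac)
    stage("tracks_coloc_positive", sum(coloc$coloc_label == "positive"))

    kin <- track_kinetics(tracks, frame_interval = sim$stack$frame_interval)
    kin <- merge(kin, coloc[, c("track_id", "coloc_label")], by = "track_id")
    kin$replicate <- rep_i
    stage("kinetics_fit_ok", sum(kin$fit_ok))

    speed <- track_cell_speed(sim$stack)
    cells[[rep_i]] <- data.frame(replicate = rep_i,
                                 mean_speed_um_s = speed$mean_speed,
                                 n_frames_segmented = nrow(speed$trajectory))

    tracks$replicate <- rep_i
    tracks$mask <- NULL
    all_tracks[[rep_i]] <- merge(
      tracks, coloc[, c("track_id", "coloc_label")], by = "track_id")
    all_kin[[rep_i]] <- kin
  }
  tracks <- do.call(rbind, all_tracks)
  kinetics <- do.call(rbind, all_kin)
  cells <- do.call(rbind, cells)
  rownames(tracks) <- rownames(kinetics) <- rownames(cells) <- NULL

  # pooled group comparisons, channel-2 positive vs negative
  comparisons <- list()
  superplot <- list()
  for (metric in analysis_metrics) {
    vals <- kinetics[[metric]]
    keep <- is.finite(vals)
    pos <- vals[keep & kinetics$coloc_label == "positive"]
    neg <- vals[keep & kinetics$coloc_label == "negative"]
    cmp <- tryCatch(
      wilcoxon_compare(pos, neg, labels = c("positive", "negative"),
                       Q = config$rout_q),
      error = function(e) NULL)
    if (!is.null(cmp)) {
      tb <- cmp$table
      tb$metric <- metric
      tb$p_value <- cmp$p_value
      comparisons[[metric]] <- tb
    }
    sp <- superplot_table(vals[keep],
                          kinetics$replicate[keep],
                          kinetics$coloc_label[keep])
    pts <- sp$points
    pts$metric <- metric
    pts$layer <- "point"
    mns <- data.frame(value = sp$replicate_means$mean,
                      replicate = sp$replicate_means$replicate,
                      group = sp$replicate_means$group,
                      metric = metric, layer = "replicate_mean")
    superplot[[metric]] <- rbind(pts, mns)
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons) else
    data.frame()
  superplot <- do.call(rbind, superplot)
  rownames(comparisons) <- rownames(superplot) <- NULL

  # per-cell duration vs migration speed correlation (needs >= 3 cells)
  correlations <- data.frame()
  if (nrow(cells) >= 3) {
    mean_dur <- stats::aggregate(duration_frames ~ replicate,
                                 data = kinetics, FUN = mean)
    mrg <- merge(mean_dur, cells, by = "replicate")
    cr <- tryCatch(
      linreg_correlate(mrg$mean_speed_um_s, mrg$duration_frames),
      error = function(e) NULL)
    if (!is.null(cr)) {
      correlations <- data.frame(
        x = "mean_speed_um_s", y = "mean_duration_frames",
        slope = cr$slope, intercept = cr$intercept,
        r_squared = cr$r_squared, p_value = cr$p_value, n = cr$n)
    }
  }

  frap <- NULL
  if (!is.null(config$frap)) {
    frap_cfg <- config$frap
    frap_cfg$seed <- config$seed + 499L
    frap_sim <- simulate_frap_series(frap_cfg)
    frap <- frap_analyze(frap_sim$series, window = config$frap_window,
                         t_max = config$frap_tmax, Q = config$rout_q)
    counts$frap <- list(traces = nrow(frap$results),
                        excluded = sum(frap$results$excluded))
  }

  manifest <- list(
    package = "adhesiondyn",
    version = as.character(utils::packageVersion("adhesiondyn")),
    seed = config$seed,
    n_replicates = config$n_replicates,
    frame_interval_s = config$sim$frame_interval,
    pixel_size_um = config$sim$pixel_size,
    counts = counts,
    config = unclass_deep(config)
  )

  out <- list(tracks = tracks, kinetics = kinetics, cells = cells,
              comparisons = comparisons, superplot = superplot,
              correlations = correlations, frap = frap,
              manifest = manifest)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    wcsv <- function(df, name) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
    wcsv(tracks, "tracks.csv")
    wcsv(kinetics, "kinetics.csv")
    wcsv(cells, "cells.csv")
    wcsv(comparisons, "comparison.csv")
    wcsv(superplot, "superplot.csv")
    wcsv(correlations, "correlations.csv")
    if (!is.null(frap)) {
      wcsv(frap$results, "frap_results.csv")
      wcsv(frap$curve, "frap_curve.csv")
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

# strip S3 classes recursively so configs serialize cleanly to JSON
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
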