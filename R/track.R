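#' Link per-frame detections into punctae tracks
#'
#' Frame-to-frame nearest-neighbour linking: for each consecutive frame
#' pair, candidate pairs within `max_displacement` pixels are assigned
#' greedily by increasing distance (ties broken by lower detection index,
#' so the result is deterministic and independent of detection order).
#' Unmatched detections start new tracks; there is no gap closing, so every
#' track covers strictly consecutive frames and each detection belongs to
#' exactly one track.
#'
#' @param detections data frame of detections with at least `frame` (0-based)
#'   `row` and `col` columns, e.g. from [detect_stack()].
#' @param max_displacement linking gate in pixels.
#' @return the detections with a `track_id` column, ordered by track and
#'   frame.
#' @export
link_tracks <- function(detections, max_displacement = 3) {
  if (nrow(detections) == 0) {
    detections$track_id <- integer(0)
    return(detections)
  }
  det <- detections[order(detections$frame), , drop = FALSE]
  det$track_id <- NA_integer_
  frames <- sort(unique(det$frame))
  next_id <- 1L
  prev_idx <- integer(0)
  prev_frame <- NULL
  for (fr in frames) {
    cur_idx <- which(det$frame == fr)
    if (!is.null(prev_frame) && fr == prev_frame + 1 && length(prev_idx)) {
      dmat <- sqrt(outer(det$row[prev_idx], det$row[cur_idx], `-`)^2 +
                   outer(det$col[prev_idx], det$col[cur_idx], `-`)^2)
      cand <- which(dmat <= max_displacement, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dmat[cand], cand[, 1], cand[, 2])
        used_p <- logical(length(prev_idx))
        used_c <- logical(length(cur_idx))
        for (k in ord) {
          p <- cand[k, 1]; cc <- cand[k, 2]
          if (used_p[p] || used_c[cc]) next
          used_p[p] <- TRUE
          used_c[cc] <- TRUE
          det$track_id[cur_idx[cc]] <- det$track_id[prev_idx[p]]
        }
      }
    }
    new <- cur_idx[is.na(det$track_id[cur_idx])]
    if (length(new)) {
      det$track_id[new] <- seq.int(next_id, length.out = length(new))
      next_id <- next_id + length(new)
    }
    prev_idx <- cur_idx
    prev_frame <- fr
  }
  det <- det[order(det$track_id, det$frame), , drop = FALSE]
  rownames(det) <- NULL
  det[, c("track_id", setdiff(names(det), "track_id"))]
}

#' Apply track-level quality filters
#'
#' Removes tracks that touch the first or last frame of the movie (their
#' full history is unobserved) and tracks lasting eight frames or fewer.
#' The operation preserves track order and is idempotent.
#'
#' @param tracks data frame with `track_id` and 0-based `frame` columns.
#' @param n_frames_total total number of frames in the movie.
#' @param min_duration tracks with `duration <= min_duration` frames are
#'   removed (default 8).
#' @return the filtered tracks data frame.
#' @export
filter_tracks <- function(tracks, n_frames_total, min_duration = 8L) {
  if (nrow(tracks) == 0) return(tracks)
  stats_by <- split(tracks$frame, tracks$track_id)
  bad <- vapply(stats_by, function(fr) {
    any(fr == 0L) || any(fr == n_frames_total - 1L) ||
      length(fr) <= min_duration
  }, logical(1))
  keep_ids <- as.integer(names(stats_by))[!bad]
  out <- tracks[tracks$track_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Track durations in frames
#'
#' @param tracks data frame with `track_id` and `frame` columns.
#' @return data frame `track_id`, `duration` (number of detections).
#' @export
track_durations <- function(tracks) {
  if (nrow(tracks) == 0) {
    return(data.frame(track_id = integer(0), duration = integer(0)))
  }
  tb <- table(tracks$track_id)
  data.frame(track_id = as.integer(names(tb)),
             duration = as.integer(tb))
}

#' Extract a per-frame mean-intensity trace for one track
#'
#' Computes the mean of the raw channel intensity over the track's mask in
#' each of its frames.
#'
#' @param track data frame of one track's detections (columns `frame`,
#'   `mask`).
#' @param stack a [timelapse_stack()].
#' @param channel channel index (1 or 2).
#' @return numeric vector of MFI values, one per track frame.
#' @export
extract_mfi <- function(track, stack, channel = 1L) {
  arr <- get_channel(stack, channel)
  track <- track[order(track$frame), , drop = FALSE]
  vapply(seq_len(nrow(track)), function(i) {
    m <- track$mask[[i]]
    if (length(m) == 0) {
      stop(sprintf("empty mask in frame %d of track", track$frame[i]))
    }
    mean(arr[, , track$frame[i] + 1L][m])
  }, numeric(1))
}

#' Track the whole-cell centroid and compute migration speed
#'
#' Segments the cell in every frame by automatic (Otsu) thresholding of the
#' raw channel, keeps the largest connected component after hole filling,
#' and records its centroid.  The per-interval speed is the centroid
#' displacement times `pixel_size` divided by `frame_interval`; the mean
#' speed is the arithmetic mean over intervals between consecutively
#' segmented frames.
#'
#' @param stack a [timelapse_stack()].
#' @param frame_interval frame interval in seconds (defaults to the stack
#'   calibration).
#' @param pixel_size pixel size in micrometres (defaults to the stack
#'   calibration).
#' @param channel channel used for segmentation.
#' @return list with `trajectory` (data frame `frame`, `row`, `col` in
#'   0-based pixels) and `mean_speed` in micrometres per second.
#' @export
track_cell_speed <- function(stack, frame_interval = stack$frame_interval,
                             pixel_size = stack$pixel_size, channel = 1L) {
  arr <- get_channel(stack, channel)
  nf <- dim(arr)[3]
  cent <- matrix(NA_real_, nf, 2)
  for (fr in seq_len(nf)) {
    img <- arr[, , fr]
    thr <- otsu_threshold(img)
    if (!is.finite(thr)) next
    bin <- img > thr
    if (!any(bin)) next
    bin <- EBImage::imageData(EBImage::fillHull(EBImage::Image(bin * 1))) > 0.5
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bin * 1)))
    sizes <- tabulate(lab[lab > 0])
    big <- which.max(sizes)
    idx <- which(lab == big)
    cent[fr, 1] <- mean((idx - 1L) %% nrow(img)) # 0-based rows
    cent[fr, 2] <- mean((idx - 1L) %/% nrow(img))
  }
  lost <- sum(is.na(cent[, 1]))
  if (lost > 0.2 * nf) {
    stop(sprintf("cell mask lost in %d of %d frames (> 20%%)", lost, nf))
  }
  seg <- which(!is.na(cent[, 1]))
  pairs <- which(diff(seg) == 1L)
  speeds <- sqrt(diff(cent[seg, 1])^2 + diff(cent[seg, 2])^2)[pairs] *
    pixel_size / frame_interval
  list(
    trajectory = data.frame(frame = seg - 1L,
                            row = cent[seg, 1], col = cent[seg, 2]),
    mean_speed = if (length(speeds)) mean(speeds) else 0
  )
}
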