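# Dilate a set of linear pixel indices by a disc of the given radius,
# working on a padded bounding box for speed.  Returns linear indices.
dilate_mask <- function(mask, dim_hw, radius) {
  H <- dim_hw[1]; W <- dim_hw[2]
  rows <- (mask - 1L) %% H + 1L
  cols <- (mask - 1L) %/% H + 1L
  r0 <- max(1L, min(rows) - radius); r1 <- min(H, max(rows) + radius)
  c0 <- max(1L, min(cols) - radius); c1 <- min(W, max(cols) + radius)
  sub <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
  sub[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- 1
  kern <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(sub), kern)) > 0.5
  sel <- which(dil, arr.ind = TRUE)
  (sel[, 2] + c0 - 2L) * H + (sel[, 1] + r0 - 1L)
}

#' Classify one track as channel-2 positive or negative
#'
#' Quantitative surrogate for visual co-localization scoring: in each frame
#' the channel-2 signal over the punctae mask is compared with the local
#' background in an annulus around it (mask dilated by 3 px minus mask
#' dilated by 1 px, excluding any other punctae masks).  The track is
#' called positive when the mask/annulus intensity ratio reaches
#' `ratio_threshold` in at least `frame_fraction_threshold` of its frames.
#'
#' @param track data frame of one track's detections (`frame`, `mask`).
#' @param stack a two-channel [timelapse_stack()].
#' @param ratio_threshold minimum mask/annulus MFI ratio counted as
#'   positive in a frame.
#' @param frame_fraction_threshold minimum fraction of positive frames for
#'   a positive call.
#' @param exclude_masks optional list indexed by frame number (0-based,
#'   as character names) of pixel indices to exclude from annuli, normally
#'   the union of all other punctae masks in that frame.
#' @return list of class `coloc_call`: `track_id`, `label`
#'   (`"positive"`/`"negative"`), per-frame `ratio`, `fraction_positive`.
#' @export
classify_channel2 <- function(track, stack, ratio_threshold = 1.5,
                              frame_fraction_threshold = 0.5,
                              exclude_masks = NULL) {
  ch2 <- get_channel(stack, 2L)
  dhw <- dim(ch2)[1:2]
  track <- track[order(track$frame), , drop = FALSE]
  ratio <- rep(NA_real_, nrow(track))
  for (i in seq_len(nrow(track))) {
    m <- track$mask[[i]]
    fr <- track$frame[i]
    outer_ring <- dilate_mask(m, dhw, 3L)
    inner <- dilate_mask(m, dhw, 1L)
    ann <- setdiff(outer_ring, inner)
    if (!is.null(exclude_masks)) {
      ex <- exclude_masks[[as.character(fr)]]
      if (!is.null(ex)) ann <- setdiff(ann, ex)
    }
    if (length(ann) == 0) next
    img <- ch2[, , fr + 1L]
    ann_mfi <- mean(img[ann])
    if (ann_mfi <= 0) next
    ratio[i] <- mean(img[m]) / ann_mfi
  }
  frac <- if (all(is.na(ratio))) 0 else
    mean(ratio >= ratio_threshold, na.rm = TRUE)
  structure(list(
    track_id = if ("track_id" %in% names(track)) track$track_id[1] else NA,
    label = if (frac >= frame_fraction_threshold) "positive" else "negative",
    ratio = ratio,
    fraction_positive = frac
  ), class = "coloc_call")
}

#' Classify every track in a movie
#'
#' Runs [classify_channel2()] on each track, excluding all other tracks'
#' masks from each annulus.
#'
#' @param tracks data frame of tracked detections (`track_id`, `frame`,
#'   `mask`).
#' @param stack a two-channel [timelapse_stack()].
#' @inheritParams classify_channel2
#' @return data frame `track_id`, `coloc_label`, `fraction_positive`.
#' @export
coloc_calls <- function(tracks, stack, ratio_threshold = 1.5,
                        frame_fraction_threshold = 0.5) {
  if (nrow(tracks) == 0) {
    return(data.frame(track_id = integer(0), coloc_label = character(0),
                      fraction_positive = numeric(0)))
  }
  all_masks <- lapply(split(tracks$mask, tracks$frame),
                      function(l) unique(unlist(l)))
  res <- lapply(split(tracks, tracks$track_id), function(tr) {
    own <- split(tr$mask, tr$frame)
    ex <- all_masks[names(all_masks) %in% names(own)]
    ex <- mapply(function(a, o) setdiff(a, unlist(o)),
                 ex, own[names(ex)], SIMPLIFY = FALSE)
    call <- classify_channel2(tr, stack, ratio_threshold,
                              frame_fraction_threshold, exclude_masks = ex)
    data.frame(track_id = tr$track_id[1], coloc_label = call$label,
               fraction_positive = call$fraction_positive)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$track_id), , drop = FALSE]
}
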