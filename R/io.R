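#' Calibrated timelapse image stack
#'
#' Container for a one- or two-channel fluorescence timelapse.  Channels are
#' numeric arrays of dimension height x width x frames holding raw camera
#' counts; `frame_interval` (seconds) and `pixel_size` (micrometres/pixel)
#' carry the acquisition calibration.  Frame `k` (0-based) is acquired at
#' time `k * frame_interval`.
#'
#' @param ch1 numeric 3D array, height x width x frames.
#' @param ch2 optional second channel with identical dimensions.
#' @param frame_interval frame interval in seconds.
#' @param pixel_size pixel size in micrometres per pixel.
#' @return list of class `timelapse_stack`.
#' @export
timelapse_stack <- function(ch1, ch2 = NULL, frame_interval, pixel_size) {
  stopifnot(is.array(ch1), length(dim(ch1)) == 3L,
            frame_interval > 0, pixel_size > 0)
  if (!is.null(ch2)) stopifnot(identical(dim(ch1), dim(ch2)))
  structure(list(ch1 = ch1, ch2 = ch2,
                 frame_interval = frame_interval,
                 pixel_size = pixel_size),
            class = "timelapse_stack")
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$ch1)
  cat(sprintf(
    "timelapse_stack: %d x %d px, %d frames, %d channel(s), %g s/frame, %g um/px\n",
    d[1], d[2], d[3], if (is.null(x$ch2)) 1L else 2L,
    x$frame_interval, x$pixel_size))
  invisible(x)
}

n_frames <- function(stack) dim(stack$ch1)[3]

get_channel <- function(stack, channel) {
  ch <- if (channel == 1) stack$ch1 else stack$ch2
  if (is.null(ch)) {
    stop("channel-2 stack missing: supply a two-channel stack or ",
         "run in single-channel mode (channel = 1)")
  }
  ch
}

#' Write a timelapse stack as 16-bit multi-page TIFF files
#'
#' Writes one file per channel (`ch1.tif`, `ch2.tif`) into `dir`.  Counts
#' are stored as 16-bit samples; values are clipped to \[0, 65535\].
#'
#' @param stack a [timelapse_stack()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_timelapse <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (ch in c(1L, 2L)) {
    arr <- if (ch == 1) stack$ch1 else stack$ch2
    if (is.null(arr)) next
    pages <- lapply(seq_len(dim(arr)[3]), function(k) {
      m <- arr[, , k]
      m[m < 0] <- 0
      m[m > 65535] <- 65535
      m / 65535
    })
    path <- file.path(dir, sprintf("ch%d.tif", ch))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a timelapse stack from multi-page TIFF files
#'
#' Inverse of [write_timelapse()]: reads `ch1` (and optionally `ch2`)
#' multi-page TIFFs back into a calibrated [timelapse_stack()] on the raw
#' count scale.
#'
#' @param ch1_path path to the channel-1 TIFF.
#' @param ch2_path optional path to the channel-2 TIFF.
#' @param frame_interval frame interval in seconds.
#' @param pixel_size pixel size in micrometres per pixel.
#' @return a [timelapse_stack()].
#' @export
read_timelapse <- function(ch1_path, ch2_path = NULL,
                           frame_interval, pixel_size) {
  read_one <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * 65535
    arr
  }
  ch1 <- read_one(ch1_path)
  ch2 <- if (!is.null(ch2_path)) read_one(ch2_path) else NULL
  timelapse_stack(ch1 = ch1, ch2 = ch2,
                  frame_interval = frame_interval, pixel_size = pixel_size)
}
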