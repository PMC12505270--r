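test_that("a stationary spot over 20 frames forms one track", {
  det <- do.call(rbind, lapply(0:19, function(f) {
    data.frame(frame = f, row = 30, col = 40)
  }))
  tracks <- link_tracks(det, max_displacement = 3)
  expect_equal(length(unique(tracks$track_id)), 1L)
  expect_equal(nrow(tracks), 20L)
})

test_that("well-separated spots are never merged", {
  det <- do.call(rbind, lapply(0:9, function(f) {
    data.frame(frame = f, row = c(20, 20), col = c(20, 50))
  }))
  tracks <- link_tracks(det, max_displacement = 5)
  expect_equal(length(unique(tracks$track_id)), 2L)
  by_track <- split(tracks$col, tracks$track_id)
  expect_true(all(vapply(by_track, function(v) length(unique(v)) == 1,
                         logical(1))))
})

test_that("a moving spot within the gate stays a single track", {
  det <- do.call(rbind, lapply(0:14, function(f) {
    data.frame(frame = f, row = 20 + 2 * f, col = 30)
  }))
  tracks <- link_tracks(det, max_displacement = 5)
  expect_equal(length(unique(tracks$track_id)), 1L)
  tr <- tracks[order(tracks$frame), ]
  expect_equal(tr$row, 20 + 2 * (0:14))
})

test_that("linking is invariant to detection order within frames", {
  set.seed(5)
  det <- do.call(rbind, lapply(0:9, function(f) {
    data.frame(frame = f, row = c(10, 25, 40) + 0.2 * f,
               col = c(30, 32, 34))
  }))
  t1 <- link_tracks(det, max_displacement = 3)
  det_shuf <- det[sample(nrow(det)), ]
  t2 <- link_tracks(det_shuf, max_displacement = 3)
  key <- function(tr) {
    unname(sort(vapply(split(tr, tr$track_id), function(d) {
      paste(d$frame, round(d$row, 6), round(d$col, 6), collapse = ";")
    }, character(1))))
  }
  expect_equal(key(t1), key(t2))
})

test_that("track filters drop first/last-frame and short tracks exactly", {
  n_total <- 60L
  tracks <- tracks_from_spans(list(
    0:14,    # touches first frame -> removed
    10:17,   # 8 frames -> removed
    20:28,   # 9 frames -> kept
    30:49,   # 20 frames -> kept
    45:59    # touches last frame -> removed
  ))
  kept <- filter_tracks(tracks, n_total)
  expect_setequal(unique(kept$track_id), c(3L, 4L))
  durs <- track_durations(kept)
  expect_setequal(durs$duration, c(9L, 20L))
  # idempotence
  expect_identical(filter_tracks(kept, n_total), kept)
})

test_that("MFI extraction reproduces constant regions and flags empty masks", {
  arr <- array(200, dim = c(32, 32, 5))
  stk <- timelapse_stack(ch1 = arr, frame_interval = 0.75, pixel_size = 0.1)
  mask <- which(matrix(seq_len(32 * 32), 32, 32) %in% 1:40)
  track <- data.frame(track_id = 1L, frame = 0:4)
  track$mask <- replicate(5, mask, simplify = FALSE)
  expect_equal(extract_mfi(track, stk, 1), rep(200, 5))
  track$mask[[3]] <- integer(0)
  expect_error(extract_mfi(track, stk, 1), "frame 2")
})

test_that("two-channel MFI: a channel-2-dark punctae reads background there", {
  cfg <- small_sim_config(n_punctae = 4L, coloc_fraction = 0)
  sim <- simulate_timelapse(cfg)
  det <- detect_stack(sim$stack)
  tracks <- filter_tracks(link_tracks(det), n_frames_total = cfg$n_frames)
  expect_gt(nrow(tracks), 0)
  one <- tracks[tracks$track_id == tracks$track_id[1], ]
  ch2_trace <- extract_mfi(one, sim$stack, channel = 2)
  # punctae sit on the cell body: channel 2 reads background + cytoplasm
  expect_true(all(ch2_trace <= cfg$background_level +
                    0.6 * cfg$cell_level + 1e-6))
})

test_that("cell speed is exact for programmed translations", {
  # stationary cell
  stk0 <- square_stack(rep(0, 10), rep(0, 10))
  expect_equal(track_cell_speed(stk0)$mean_speed, 0)
  # 1 px/frame sideways, pixel 0.1 um, interval 0.75 s
  stk1 <- square_stack(rep(0, 12), rep(1, 12), frame_interval = 0.75,
                       pixel_size = 0.1)
  expect_equal(track_cell_speed(stk1)$mean_speed, 0.1 / 0.75,
               tolerance = 1e-10)
})

test_that("random-walk cell speed matches the brute-force oracle", {
  set.seed(17)
  steps_r <- sample(0:1, 15, replace = TRUE)
  steps_c <- sample(0:2, 15, replace = TRUE)
  stk <- square_stack(steps_r, steps_c, h = 64, w = 64)
  res <- track_cell_speed(stk)
  # displacement between frames k and k+1 is exactly (steps_r[k], steps_c[k])
  manual <- mean(sqrt(steps_r[1:14]^2 + steps_c[1:14]^2)) * 0.1 / 0.75
  expect_equal(res$mean_speed, manual, tolerance = 1e-10)
})

test_that("losing the cell mask in too many frames raises an error", {
  stk <- square_stack(rep(0, 10), rep(0, 10))
  stk$ch1[, , 1:3] <- 10  # constant frames: no segmentable cell
  expect_error(track_cell_speed(stk), "20%")
})
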