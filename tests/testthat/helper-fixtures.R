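# shared fixtures and independent oracles, built in code at test time

# the same centred 3-frame running average the pipeline applies
rm3 <- function(v) {
  vapply(seq_along(v), function(i) {
    mean(v[max(1, i - 1):min(length(v), i + 1)])
  }, numeric(1))
}

# small, fast simulator configuration for unit tests
small_sim_config <- function(...) {
  args <- list(image_shape = c(128L, 160L), n_frames = 90L,
               n_punctae = 8L,
               noise = list(poisson_on = FALSE, gaussian_sd = 0),
               cell_speed = 0.03, seed = 11L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# render one noiseless Gaussian spot on a constant background
spot_frame <- function(h = 64, w = 64, row = 32.3, col = 40.7,
                       amplitude = 500, background = 100, sigma = 2) {
  background + amplitude *
    exp(-(outer((1:h - row)^2, (1:w - col)^2, `+`)) / (2 * sigma^2))
}

# stack whose only object is a bright square translating by integer steps
square_stack <- function(steps_row, steps_col, h = 48, w = 48,
                         frame_interval = 0.75, pixel_size = 0.1) {
  nf <- length(steps_row)
  arr <- array(10, dim = c(h, w, nf))
  r0 <- 10; c0 <- 10
  for (k in seq_len(nf)) {
    rr <- r0 + sum(steps_row[seq_len(k - 1)])
    cc <- c0 + sum(steps_col[seq_len(k - 1)])
    arr[rr:(rr + 7), cc:(cc + 7), k] <- 200
  }
  timelapse_stack(ch1 = arr, frame_interval = frame_interval,
                  pixel_size = pixel_size)
}

# build a tracks data frame from a list of 0-based frame spans
tracks_from_spans <- function(spans) {
  do.call(rbind, lapply(seq_along(spans), function(i) {
    fr <- spans[[i]]
    data.frame(track_id = i, frame = fr,
               row = 10 * i + 0 * fr, col = 20 + 0 * fr)
  }))
}

# exact two-sided rank-sum p-value by full enumeration of group assignments
enum_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)])
  combos <- utils::combn(n, na)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# independent stepwise transcription of the ROUT procedure: grid-search
# robust location under a Lorentzian merit with iterated robust scale,
# t-tail p-values, then the FDR scan from the most extreme point inward
oracle_rout <- function(values, Q = 0.01) {
  n <- length(values)
  grid <- seq(min(values), max(values), length.out = 4001)
  s <- as.numeric(quantile(abs(values - median(values)), 0.6827,
                           names = FALSE)) * n / (n - 1)
  if (s == 0) return(values != median(values))
  m <- median(values)
  for (it in 1:60) {
    merit <- vapply(grid, function(mm) {
      sum(log1p(((values - mm) / s)^2))
    }, numeric(1))
    m_new <- grid[which.min(merit)]
    s_new <- as.numeric(quantile(abs(values - m_new), 0.6827,
                                 names = FALSE)) * n / (n - 1)
    conv <- abs(m_new - m) < 1e-9 * (1 + abs(m))
    m <- m_new
    if (s_new <= 0) break
    s <- s_new
    if (conv) break
  }
  resid <- values - m
  s <- as.numeric(quantile(abs(resid), 0.6827, names = FALSE)) * n / (n - 1)
  if (s <= 0) return(abs(resid) > 0)
  p <- 2 * pt(abs(resid) / s, df = n - 1, lower.tail = FALSE)
  mask <- rep(FALSE, n)
  ord <- order(p)
  for (i in seq_len(n)) {
    if (p[ord[i]] < Q * i / n) mask[ord[i]] <- TRUE else break
  }
  mask
}
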