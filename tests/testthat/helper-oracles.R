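# Independent fixture builders and brute-force oracles used across the
# suite. Everything here is deliberately written as plain loops / closed
# forms, separate from the package's own code paths.

# Analytic straight-ridge frame: intensity exp(-d^2 / (2 sigma^2)) where d
# is the perpendicular distance to the infinite line through `center` at
# `angle` (pixel coordinates, 0-based, y down).
ridge_frame <- function(nrow_px, ncol_px, center, angle, sigma = 1.5,
                        amp = 1) {
  x <- matrix(seq_len(ncol_px) - 1, nrow_px, ncol_px, byrow = TRUE)
  y <- matrix(seq_len(nrow_px) - 1, nrow_px, ncol_px)
  d <- (x - center[1]) * sin(angle) - (y - center[2]) * cos(angle)
  amp * exp(-d^2 / (2 * sigma^2))
}

# Brute-force image-moment orientation over the inscribed disc of a square
# window: direct double loop, no vectorized moment code shared with the
# package.
brute_force_orientation <- function(frame, center, window_px) {
  h <- (window_px - 1) / 2
  cx <- round(center[1]); cy <- round(center[2])
  sw <- 0; sx <- 0; sy <- 0
  for (xx in (cx - h):(cx + h)) for (yy in (cy - h):(cy + h)) {
    if (xx < 0 || yy < 0 || xx > ncol(frame) - 1 || yy > nrow(frame) - 1)
      next
    if ((xx - cx)^2 + (yy - cy)^2 > (window_px / 2)^2) next
    w <- frame[yy + 1, xx + 1]
    sw <- sw + w; sx <- sx + w * xx; sy <- sy + w * yy
  }
  xb <- sx / sw; yb <- sy / sw
  m20 <- 0; m02 <- 0; m11 <- 0
  for (xx in (cx - h):(cx + h)) for (yy in (cy - h):(cy + h)) {
    if (xx < 0 || yy < 0 || xx > ncol(frame) - 1 || yy > nrow(frame) - 1)
      next
    if ((xx - cx)^2 + (yy - cy)^2 > (window_px / 2)^2) next
    w <- frame[yy + 1, xx + 1]
    m20 <- m20 + w * (xx - xb)^2
    m02 <- m02 + w * (yy - yb)^2
    m11 <- m11 + w * (xx - xb) * (yy - yb)
  }
  th <- 0.5 * atan2(2 * m11 / sw, (m20 - m02) / sw)
  if (th >= pi / 2) th <- th - pi
  th
}

# Brute-force motility summary: plain loops over the raw per-frame values.
brute_force_motility <- function(tip_x, tip_y, length_um, valid,
                                 interval_s, thr) {
  n <- length(tip_x)
  speeds <- c(); dldt <- c()
  for (i in seq_len(n - 1)) {
    if (valid[i] && valid[i + 1]) {
      speeds <- c(speeds, sqrt((tip_x[i + 1] - tip_x[i])^2 +
                                 (tip_y[i + 1] - tip_y[i])^2) / interval_s)
      dldt <- c(dldt, (length_um[i + 1] - length_um[i]) / interval_s)
    }
  }
  prot <- dldt[dldt > thr]; retr <- dldt[dldt < -thr]
  lens <- length_um[valid]
  list(avg_speed = mean(speeds),
       is_motile = mean(speeds) > thr,
       pct_time_motile = 100 * sum(speeds > thr) / length(speeds),
       avg_length = mean(lens), max_length = max(lens),
       prot = if (length(prot)) median(prot) else NA_real_,
       retr = if (length(retr)) median(retr) else NA_real_)
}

# Random per-frame series table shaped like build_df_series() output.
random_series <- function(id, n = 30, interval_s = 5, gap_prob = 0.1) {
  valid <- runif(n) > gap_prob
  valid[sample(n, 2)] <- TRUE  # keep at least two valid frames
  tibble::tibble(
    df_id = id, frame = seq_len(n), time_s = (seq_len(n) - 1) * interval_s,
    valid = valid,
    length_um = ifelse(valid, 2 + cumsum(rnorm(n, sd = 0.1)), NA_real_),
    tip_x_um = ifelse(valid, cumsum(rnorm(n, sd = 0.08)), NA_real_),
    tip_y_um = ifelse(valid, cumsum(rnorm(n, sd = 0.08)), NA_real_),
    tip_fluor = ifelse(valid, runif(n, 1, 3), NA_real_)) |>
    dplyr::mutate(tip_fluor_norm = tip_fluor /
                    min(tip_fluor[valid], na.rm = TRUE))
}

# Paired FTIP/DCTM table for correlation tests: white noise, optionally
# coupled as dctm(t) = ftip(t - lag) + noise, both 3-point smoothed.
synthetic_pair <- function(id, n = 60, lag = NULL, noise_sd = 0) {
  f_raw <- rnorm(n)
  d_raw <- if (is.null(lag)) rnorm(n)
           else c(rep(0, lag), f_raw[seq_len(n - lag)]) +
             rnorm(n, sd = noise_sd)
  tibble::tibble(df_id = id, frame = seq_len(n),
                 ftip = moving_average3(f_raw + 2),
                 dctm = moving_average3(d_raw),
                 dctm_raw = d_raw)
}

# A single-filopodium rendered scene with fluorescence leading motility.
coupled_scene <- function(lag, seed, n_frames = 60) {
  sc <- scene_params(
    width_px = 96L, height_px = 72L, n_frames = n_frames,
    filopodia = list(filo_params(
      base_xy = c(12, 36),
      length_model = length_ou(2.5, 60, 0.4),
      lag_frames = lag, gain = 8, fluor_baseline = 1,
      fluor_noise_sd = 0.05)))
  simulate_scene(sc, seed = seed)
}

# Full pipeline: rendered movie -> centerlines -> series -> CCF peak.
pipeline_peak <- function(ds, max_offset = 6) {
  cfg <- pipeline_config()
  curves <- trace_centerlines(ds$geometry, ds$tracks, cfg)
  lens <- centerline_lengths(curves)
  series <- build_df_series(ds$tip_channel, ds$tracks, lens)
  paired <- pair_series(series)
  ccf_peaks(compute_ccf(paired, max_offset))
}
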