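test_that("motility threshold is one pixel per interval", {
  expect_identical(motility_threshold(0.064, 5), 0.0128)
  expect_identical(motility_threshold(0.064, 1), 0.064)
  expect_identical(motility_threshold(0.128, 5), 0.0256)
  expect_error(motility_threshold(0, 5), "positive")
  expect_error(motility_threshold(0.064, -5), "positive")
})

test_that("instantaneous speeds skip gap-spanning intervals", {
  # one-pixel step at 0.064 um in 5 s
  expect_equal(instantaneous_speeds(c(0, 0.064), c(0, 0), 5), 0.0128)
  expect_equal(instantaneous_speeds(rep(1, 5), rep(2, 5), 5), rep(0, 4))
  # gap at frame 3 of 5: only pairs (1,2) and (4,5) survive
  x <- c(0, 0.1, NA, 0.3, 0.45)
  got <- instantaneous_speeds(x, rep(0, 5), 5)
  expect_length(got, 2)
  expect_equal(got, c(0.1, 0.15) / 5)
  expect_error(instantaneous_speeds(c(1, NA, NA), c(1, NA, NA), 5),
               "2 valid")
})

test_that("motility summary matches hand-derived protrusion/retraction medians", {
  # dL/dt = 0.02, 0.03, -0.02, 0.005 um/s; tip moves along x by the same
  # magnitudes so speeds = |dL/dt|
  dt <- 5
  dL <- c(0.02, 0.03, -0.02, 0.005) * dt
  len <- 2 + cumsum(c(0, dL))
  tipx <- cumsum(c(0, abs(dL)))
  series <- tibble::tibble(
    df_id = "a", frame = 1:5, time_s = (0:4) * dt, valid = TRUE,
    length_um = len, tip_x_um = tipx, tip_y_um = 0,
    tip_fluor = c(2, 4, 8, 2, 3), tip_fluor_norm = c(1, 2, 4, 1, 1.5))
  ms <- summarize_motility(series, 0.0128)
  expect_equal(ms$median_protrusion_rate_um_s, 0.025)
  expect_equal(ms$median_retraction_rate_um_s, -0.02)
  expect_equal(ms$pct_time_motile, 75)
  expect_equal(ms$avg_tip_speed_um_s, mean(c(0.02, 0.03, 0.02, 0.005)))
  expect_true(ms$is_motile)
  expect_equal(ms$avg_length_um, mean(len))
  expect_equal(ms$max_length_um, max(len))
})

test_that("still filopodia report zero motility and undefined rates", {
  series <- tibble::tibble(
    df_id = "a", frame = 1:5, time_s = (0:4) * 5, valid = TRUE,
    length_um = 2, tip_x_um = 1, tip_y_um = 1,
    tip_fluor = 3, tip_fluor_norm = 1)
  ms <- summarize_motility(series, 0.0128)
  expect_equal(ms$avg_tip_speed_um_s, 0)
  expect_false(ms$is_motile)
  expect_equal(ms$pct_time_motile, 0)
  expect_true(is.na(ms$median_protrusion_rate_um_s))
  expect_true(is.na(ms$median_retraction_rate_um_s))
  # constant positive growth: protrusion defined, retraction undefined
  grow <- dplyr::mutate(series, length_um = 2 + 0.1 * (frame - 1),
                        tip_x_um = length_um)
  mg <- summarize_motility(grow, 0.0128)
  expect_equal(mg$median_protrusion_rate_um_s, 0.02)
  expect_true(is.na(mg$median_retraction_rate_um_s))
})

test_that("summaries agree exactly with a brute-force reimplementation", {
  set.seed(2024)
  for (i in 1:100) {
    s <- random_series(sprintf("df%03d", i))
    ms <- summarize_motility(s, 0.0128)
    bf <- brute_force_motility(s$tip_x_um, s$tip_y_um, s$length_um,
                               s$valid, 5, 0.0128)
    expect_identical(ms$avg_tip_speed_um_s, bf$avg_speed)
    expect_identical(ms$is_motile, bf$is_motile)
    expect_identical(ms$pct_time_motile, bf$pct_time_motile)
    expect_identical(ms$avg_length_um, bf$avg_length)
    expect_identical(ms$max_length_um, bf$max_length)
    expect_identical(ms$median_protrusion_rate_um_s, bf$prot)
    expect_identical(ms$median_retraction_rate_um_s, bf$retr)
  }
})

test_that("time reversal swaps protrusion and retraction, keeps speed", {
  set.seed(5)
  s <- random_series("a", gap_prob = 0)
  rev_s <- s |>
    dplyr::mutate(length_um = rev(length_um), tip_x_um = rev(tip_x_um),
                  tip_y_um = rev(tip_y_um), tip_fluor = rev(tip_fluor),
                  tip_fluor_norm = rev(tip_fluor_norm))
  a <- summarize_motility(s, 0.0128)
  b <- summarize_motility(rev_s, 0.0128)
  expect_equal(b$avg_tip_speed_um_s, a$avg_tip_speed_um_s)
  expect_equal(b$pct_time_motile, a$pct_time_motile)
  expect_equal(b$median_protrusion_rate_um_s,
               -a$median_retraction_rate_um_s)
  expect_equal(b$median_retraction_rate_um_s,
               -a$median_protrusion_rate_um_s)
})

test_that("percent motile counts the motile fraction", {
  ms <- tibble::tibble(is_motile = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(percent_motile(ms), 75)
  expect_equal(percent_motile(dplyr::mutate(ms, is_motile = FALSE)), 0)
  expect_equal(percent_motile(dplyr::mutate(ms, is_motile = TRUE)), 100)
  expect_error(percent_motile(ms[0, ]), "empty")
})

test_that("tip ROI disc matches an exhaustive pixel scan", {
  # uniform frame: mean is the constant
  fr <- matrix(7, 40, 40)
  expect_equal(tip_roi_intensity(fr, c(20, 20), 384, 0.064), 7)
  # pixel membership: 384 nm at 64 nm pixels = 6 px radius
  set.seed(8)
  fr2 <- matrix(runif(1600), 40, 40)
  for (tip in list(c(20, 20), c(20.4, 19.3), c(2, 35))) {
    vals <- c()
    for (xx in 0:39) for (yy in 0:39)
      if ((xx - tip[1])^2 + (yy - tip[2])^2 <= 6^2)
        vals <- c(vals, fr2[yy + 1, xx + 1])
    expect_equal(tip_roi_intensity(fr2, tip, 384, 0.064), mean(vals))
  }
  # fully masked ROI -> NA with a warning, not zero
  msk <- matrix(FALSE, 40, 40)
  expect_warning(got <- tip_roi_intensity(fr2, c(20, 20), 384, 0.064, msk),
                 "empty")
  expect_true(is.na(got))
})

test_that("fluorescence normalization divides by the valid minimum", {
  expect_equal(normalize_tip_fluorescence(c(2, 4, 8)), c(1, 2, 4))
  expect_equal(normalize_tip_fluorescence(c(5, 5, 5)), c(1, 1, 1))
  expect_equal(normalize_tip_fluorescence(c(3, NA, 6)), c(1, NA, 2))
  # idempotent once the minimum is 1
  v <- c(1, 2.2, 4)
  expect_identical(normalize_tip_fluorescence(v), v)
  expect_error(normalize_tip_fluorescence(c(0, 1)), "minimum")
  expect_error(normalize_tip_fluorescence(c(NA_real_, NA_real_)), "valid")
})

test_that("fluorescence variance uses the n-1 estimator over valid frames", {
  expect_equal(fluorescence_variance(c(2, 2, 2)), 0)
  expect_equal(fluorescence_variance(c(1, 3)), 2)
  expect_equal(fluorescence_variance(c(1, 2, 1, 2)), 1 / 3)
  expect_equal(fluorescence_variance(c(1, NA, 3)), 2)
  expect_error(fluorescence_variance(c(1, NA)), "2 valid")
})

test_that("sinusoidal length dynamics recover the analytic rate median", {
  # L(t) = L0 + A sin(w t): dL/dt over 5 s steps has an analytic median
  A <- 0.5; period <- 60; dt <- 5
  n <- 1200
  t_s <- (seq_len(n) - 1) * dt
  L <- 2 + A * sin(2 * pi * t_s / period)
  rates <- diff(L) / dt
  thr <- 0.0128
  analytic_median <- median(rates[rates > thr])
  series <- tibble::tibble(
    df_id = "a", frame = seq_len(n), time_s = t_s, valid = TRUE,
    length_um = L, tip_x_um = L, tip_y_um = 0, tip_fluor = 1,
    tip_fluor_norm = 1)
  ms <- summarize_motility(series, thr)
  expect_equal(ms$median_protrusion_rate_um_s, analytic_median,
               tolerance = 0.05)
  expect_equal(ms$median_retraction_rate_um_s, -analytic_median,
               tolerance = 0.05)
})

test_that("fold-change bins normalize to the baseline mean", {
  t_s <- (0:23) * 5
  # constant series -> all bins 1
  fc <- fold_change_bins(rep(3, 24), t_s, c(0, 30), 30)
  expect_true(all(fc$fold_change == 1))
  # doubled signal after baseline
  v <- c(rep(0.01, 6), rep(0.02, 18))
  fc2 <- fold_change_bins(v, t_s, c(0, 30), 30)
  expect_equal(fc2$fold_change, rep(2, 3))
  # empty bin stays undefined
  v3 <- c(rep(1, 6), rep(NA, 6), rep(2, 12))
  fc3 <- fold_change_bins(v3, t_s, c(0, 30), 30)
  expect_true(is.na(fc3$fold_change[1]))
  expect_equal(fc3$fold_change[2:3], c(2, 2))
  expect_error(fold_change_bins(c(0, 0, 1), c(0, 5, 10), c(0, 10), 5),
               "positive")
})

test_that("per-frame series assembly flags gaps and normalizes fluorescence", {
  sc <- scene_params(n_frames = 4, width_px = 96, height_px = 48,
                     filopodia = list(filo_params(
                       base_xy = c(12, 24),
                       length_model = length_constant(2.5))))
  ds <- simulate_scene(sc, seed = 3)
  tracks <- ds$tracks[-2, ]  # drop frame 2: interior gap
  curves <- trace_centerlines(ds$geometry, tracks, pipeline_config())
  series <- build_df_series(ds$tip_channel, tracks,
                            centerline_lengths(curves))
  expect_equal(nrow(series), 4)  # gap frame present but invalid
  expect_false(series$valid[series$frame == 2])
  expect_true(all(series$tip_fluor_norm[series$valid] >= 1))
  expect_equal(min(series$tip_fluor_norm[series$valid]), 1)
})
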