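#' Length-dynamics models for synthetic filopodia
#'
#' Constructors for the stochastic (or deterministic) length trajectory of a
#' simulated filopodium, consumed by [simulate_length_series()]:
#'
#' * `length_constant(L0)`: fixed length.
#' * `length_sinusoid(L0, A, period_s)`: `L(t) = L0 + A sin(2 pi t / period)`.
#' * `length_ou(mean_um, tau_s, sd_um)`: Ornstein-Uhlenbeck process with
#'   stationary mean `mean_um`, relaxation time `tau_s` and stationary
#'   standard deviation `sd_um`, simulated with its exact discretization.
#' * `length_two_state(protrude_um_s, retract_um_s, dwell_s, L0)`: alternating
#'   protrusion/retraction epochs with exponential dwell times of mean
#'   `dwell_s`, growing at `protrude_um_s` and shrinking at `retract_um_s`.
#'
#' @param L0,mean_um micrometres.
#' @param A amplitude, micrometres.
#' @param period_s,tau_s,dwell_s seconds.
#' @param sd_um micrometres.
#' @param protrude_um_s,retract_um_s positive rates, um/s.
#' @return a length-model list with a `kind` field.
#' @name length_models
NULL

#' @rdname length_models
#' @export
length_constant <- function(L0) list(kind = "constant", L0 = L0)

#' @rdname length_models
#' @export
length_sinusoid <- function(L0, A, period_s)
  list(kind = "sinusoid", L0 = L0, A = A, period_s = period_s)

#' @rdname length_models
#' @export
length_ou <- function(mean_um, tau_s, sd_um)
  list(kind = "ou", mean_um = mean_um, tau_s = tau_s, sd_um = sd_um)

#' @rdname length_models
#' @export
length_two_state <- function(protrude_um_s, retract_um_s, dwell_s, L0)
  list(kind = "two_state", protrude_um_s = protrude_um_s,
       retract_um_s = retract_um_s, dwell_s = dwell_s, L0 = L0)

#' Simulate a filopodium length trajectory
#'
#' Lengths that would fall below a small positive floor (0.2 um) are clipped
#' there with a warning: a filopodium of zero length has no geometry.
#'
#' @param model a model from [length_models].
#' @param n_frames number of frames.
#' @param interval_s frame interval, seconds.
#' @param seed optional integer seed (stochastic models).
#' @return tibble with `frame`, `time_s`, `length_um` and `rate_um_s`
#'   (length change per interval, aligned at the later frame; `NA` first).
#' @export
simulate_length_series <- function(model, n_frames, interval_s, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t_s <- (seq_len(n_frames) - 1) * interval_s
  L <- switch(
    model$kind,
    constant = rep(model$L0, n_frames),
    sinusoid = model$L0 + model$A * sin(2 * pi * t_s / model$period_s),
    ou = {
      rho <- exp(-interval_s / model$tau_s)
      innov_sd <- model$sd_um * sqrt(1 - rho^2)
      l <- numeric(n_frames)
      l[1] <- model$mean_um + model$sd_um * stats::rnorm(1)
      for (i in seq_len(n_frames - 1))
        l[i + 1] <- model$mean_um + rho * (l[i] - model$mean_um) +
          innov_sd * stats::rnorm(1)
      l
    },
    two_state = {
      l <- numeric(n_frames); l[1] <- model$L0
      state <- 1  # 1 = protruding, -1 = retracting
      t_switch <- stats::rexp(1, 1 / model$dwell_s)
      tt <- 0
      for (i in seq_len(n_frames - 1)) {
        rate <- if (state > 0) model$protrude_um_s else -model$retract_um_s
        l[i + 1] <- l[i] + rate * interval_s
        tt <- tt + interval_s
        if (tt >= t_switch) {
          state <- -state; tt <- 0
          t_switch <- stats::rexp(1, 1 / model$dwell_s)
        }
      }
      l
    },
    stop("unknown length model kind: ", model$kind, call. = FALSE))
  if (any(L < 0.2)) {
    warning("length trajectory clipped at 0.2 um floor")
    L <- pmax(L, 0.2)
  }
  tibble::tibble(frame = seq_len(n_frames), time_s = t_s, length_um = L,
                 rate_um_s = c(NA_real_, diff(L) / interval_s))
}

#' Parameters of one synthetic filopodium
#'
#' Geometry is a constant-curvature arc emanating from the dendrite edge:
#' tangent angle `orientation + curvature_per_um * s` at arc length `s`.
#' Tip fluorescence is coupled to future motility with a programmable lag:
#' `F(t) = baseline + gain * M(t + lag) + noise`, where `M` is the length
#' change per interval (um/s), so that fluorescence enrichment leads
#' motility by `lag_frames` frames.
#'
#' @param base_xy base pixel coordinate `c(x, y)` (0-based); on the dendrite
#'   edge in scene use.
#' @param orientation initial tangent angle, radians (0 = +x).
#' @param length_model a model from [length_models].
#' @param curvature_per_um signed curvature, 1/um; `|curvature| * L` must
#'   stay below pi (no self-crossing).
#' @param lag_frames nonnegative integer lag of motility behind fluorescence.
#' @param gain coupling gain mapping motility (um/s) onto fluorescence.
#' @param fluor_baseline,fluor_noise_sd baseline and additive Gaussian noise
#'   of the tip-factor series (arbitrary intensity units).
#' @return a `filo_params` list.
#' @export
filo_params <- function(base_xy, orientation = 0,
                        length_model = length_constant(2.5),
                        curvature_per_um = 0,
                        lag_frames = 0L, gain = 1,
                        fluor_baseline = 1, fluor_noise_sd = 0) {
  stopifnot(lag_frames >= 0)
  structure(list(base_xy = base_xy, orientation = orientation,
                 length_model = length_model,
                 curvature_per_um = curvature_per_um,
                 lag_frames = as.integer(lag_frames), gain = gain,
                 fluor_baseline = fluor_baseline,
                 fluor_noise_sd = fluor_noise_sd),
            class = "filo_params")
}

#' Parameters of a synthetic scene
#'
#' A scene is a fixed field of view holding a straight dendrite shaft (a
#' vertical band at the left image edge) and one or more filopodia rendered
#' as ridges of Gaussian cross-section along their true centerlines.
#' Rendering evaluates distance-to-centerline on a 3x supersampled grid and
#' box-downsamples, avoiding aliasing bias in orientation estimates. Camera
#' noise is additive Gaussian plus optional Poisson shot noise.
#'
#' @param width_px,height_px field of view, pixels.
#' @param pixel_size_um,interval_s,n_frames calibration and duration;
#'   defaults mirror a TIRF acquisition at 100x (0.064 um pixels, 5 s
#'   interval, 5 min).
#' @param filopodia list of [filo_params()].
#' @param shaft_width_px,shaft_intensity dendrite band geometry/intensity.
#' @param ridge_intensity peak intensity of the filopodium ridge.
#' @param psf_sigma_px Gaussian cross-section (and tip spot) sigma, pixels.
#' @param noise_sd additive Gaussian noise sigma (ridge peak = 1 scale).
#' @param poisson_scale optional photons per intensity unit for shot noise
#'   (`NULL` = none).
#' @param mask_threshold_frac mask = noise-free intensity above this
#'   fraction of the frame peak.
#' @param tracking_jitter_px isotropic Gaussian jitter added to the exported
#'   base/tip tracks (0 = exact manual tracking surrogate).
#' @return a `scene_params` list.
#' @export
scene_params <- function(width_px = 128L, height_px = 96L,
                         pixel_size_um = 0.064, interval_s = 5,
                         n_frames = 60L,
                         filopodia = list(
                           filo_params(base_xy = c(12, 48),
                                       length_model = length_ou(2.5, 60, 0.4))),
                         shaft_width_px = 12, shaft_intensity = 0.8,
                         ridge_intensity = 1, psf_sigma_px = 1.5,
                         noise_sd = 0.1, poisson_scale = NULL,
                         mask_threshold_frac = 0.02,
                         tracking_jitter_px = 0) {
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size_um = pixel_size_um, interval_s = interval_s,
                 n_frames = as.integer(n_frames), filopodia = filopodia,
                 shaft_width_px = shaft_width_px,
                 shaft_intensity = shaft_intensity,
                 ridge_intensity = ridge_intensity,
                 psf_sigma_px = psf_sigma_px, noise_sd = noise_sd,
                 poisson_scale = poisson_scale,
                 mask_threshold_frac = mask_threshold_frac,
                 tracking_jitter_px = tracking_jitter_px),
            class = "scene_params")
}

#' True centerline of a constant-curvature filopodium
#'
#' Closed-form arc: points of the curve with tangent angle
#' `orientation + kappa * s` at arc length `s`, in pixel units.
#'
#' @param base_xy base `c(x, y)`, pixels.
#' @param orientation initial tangent angle, radians.
#' @param kappa_per_px signed curvature, 1/pixel.
#' @param length_px arc length, pixels.
#' @param n_points number of sample points.
#' @return list with `x`, `y` (pixels), `tip` (`c(x, y)`), `s` (pixels).
#' @export
arc_centerline <- function(base_xy, orientation, kappa_per_px, length_px,
                           n_points = NULL) {
  if (is.null(n_points))
    n_points <- max(32L, as.integer(ceiling(2 * length_px)))
  s <- seq(0, length_px, length.out = n_points)
  if (abs(kappa_per_px) < 1e-12) {
    x <- base_xy[1] + s * cos(orientation)
    y <- base_xy[2] + s * sin(orientation)
  } else {
    th <- orientation + kappa_per_px * s
    x <- base_xy[1] + (sin(th) - sin(orientation)) / kappa_per_px
    y <- base_xy[2] - (cos(th) - cos(orientation)) / kappa_per_px
  }
  list(x = x, y = y, tip = c(x[n_points], y[n_points]), s = s)
}

#' Render one synthetic frame
#'
#' @param scene a [scene_params()].
#' @param centerlines list of centerline point sets (as from
#'   [arc_centerline()]), one per filopodium present in this frame.
#' @param tip_spots optional tibble with `x`, `y`, `amp`: Gaussian spots
#'   (sigma = `psf_sigma_px`) added on top, used for the tip-factor channel.
#' @param fill_frac multiplier on shaft+ridge intensity (the tip-factor
#'   channel renders the cell as a dim fill).
#' @param frame_index frame number used in error messages.
#' @return list with `frame` (noise-free row x col intensity matrix) and
#'   `mask` (logical matrix).
#' @export
render_frame <- function(scene, centerlines, tip_spots = NULL,
                         fill_frac = 1, frame_index = NA_integer_) {
  cell <- render_cell_field(scene, centerlines, frame_index)
  frame <- cell * fill_frac
  if (!is.null(tip_spots))
    frame <- frame + render_spot_field(scene, tip_spots)
  mask <- cell > scene$mask_threshold_frac * max(cell)
  list(frame = frame, mask = mask)
}

# shaft + ridges, supersampled then box-downsampled; the expensive part
render_cell_field <- function(scene, centerlines,
                              frame_index = NA_integer_) {
  W <- scene$width_px; H <- scene$height_px
  ss <- 3L  # supersampling factor
  # supersample pixel-center coordinates in pixel units
  gx <- (seq_len(W * ss) - 0.5) / ss - 0.5
  gy <- (seq_len(H * ss) - 0.5) / ss - 0.5
  img <- matrix(0, H * ss, W * ss)

  # dendrite shaft: vertical band [0, shaft_width) in x
  img[, gx < scene$shaft_width_px] <- scene$shaft_intensity

  sig <- scene$psf_sigma_px
  for (cl in centerlines) {
    if (any(cl$x < 0 | cl$x > W - 1 | cl$y < 0 | cl$y > H - 1))
      stop("centerline exits the frame bounds at frame ", frame_index,
           call. = FALSE)
    bb_x <- which(gx >= min(cl$x) - 5 * sig & gx <= max(cl$x) + 5 * sig)
    bb_y <- which(gy >= min(cl$y) - 5 * sig & gy <= max(cl$y) + 5 * sig)
    if (length(bb_x) == 0 || length(bb_y) == 0) next
    d2 <- matrix(Inf, length(bb_y), length(bb_x))
    for (k in seq_along(cl$x))
      d2 <- pmin(d2, outer((gy[bb_y] - cl$y[k])^2, (gx[bb_x] - cl$x[k])^2, "+"))
    img[bb_y, bb_x] <- pmax(img[bb_y, bb_x],
                            scene$ridge_intensity * exp(-d2 / (2 * sig^2)))
  }
  downsample_box(img, ss)
}

# Gaussian tip spots only (cheap, small bounding boxes)
render_spot_field <- function(scene, tip_spots) {
  W <- scene$width_px; H <- scene$height_px
  ss <- 3L
  gx <- (seq_len(W * ss) - 0.5) / ss - 0.5
  gy <- (seq_len(H * ss) - 0.5) / ss - 0.5
  img <- matrix(0, H * ss, W * ss)
  sig <- scene$psf_sigma_px
  for (k in seq_len(nrow(tip_spots))) {
    sx <- tip_spots$x[k]; sy <- tip_spots$y[k]
    bb_x <- which(gx >= sx - 5 * sig & gx <= sx + 5 * sig)
    bb_y <- which(gy >= sy - 5 * sig & gy <= sy + 5 * sig)
    d2 <- outer((gy[bb_y] - sy)^2, (gx[bb_x] - sx)^2, "+")
    img[bb_y, bb_x] <- img[bb_y, bb_x] +
      tip_spots$amp[k] * exp(-d2 / (2 * sig^2))
  }
  downsample_box(img, ss)
}

# box-average downsampling by integer factor
downsample_box <- function(img, f) {
  H <- nrow(img) / f; W <- ncol(img) / f
  dim(img) <- c(f, H * f * W)
  a <- colMeans(img)
  dim(a) <- c(H, f, W)
  a <- aperm(a, c(2, 1, 3))
  dim(a) <- c(f, H * W)
  out <- colMeans(a)
  dim(out) <- c(H, W)
  out
}

add_camera_noise <- function(frame, noise_sd, poisson_scale = NULL) {
  if (!is.null(poisson_scale))
    frame <- matrix(stats::rpois(length(frame),
                                 pmax(frame, 0) * poisson_scale),
                    nrow(frame)) / poisson_scale
  if (noise_sd > 0)
    frame <- frame + matrix(stats::rnorm(length(frame), sd = noise_sd),
                            nrow(frame))
  pmax(frame, 0)
}

#' Tip-factor fluorescence coupled to future motility
#'
#' `F(t) = baseline + gain * M(t + lag) + eps`, `eps ~ N(0, noise_sd^2)`:
#' the fluorescence series leads the motility series by `lag_frames` frames,
#' so a lagged cross-correlation of the pair peaks at offset `-lag_frames`.
#'
#' @param motility numeric motility series `M` (um/s), length `m`.
#' @param lag_frames nonnegative integer lag (< `m`).
#' @param gain,baseline affine coupling parameters.
#' @param noise_sd Gaussian noise sigma.
#' @param seed optional integer seed.
#' @return numeric vector of length `m - lag_frames`.
#' @export
simulate_tip_factor <- function(motility, lag_frames, gain = 1,
                                baseline = 1, noise_sd = 0, seed = NULL) {
  m <- length(motility)
  if (lag_frames < 0 || lag_frames >= m)
    stop("`lag_frames` must be in [0, length(motility))", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_out <- m - lag_frames
  baseline + gain * motility[seq_len(n_out) + lag_frames] +
    stats::rnorm(n_out, sd = noise_sd)
}

#' Simulate a full scene with ground truth
#'
#' Generates length trajectories and tip-factor series for every
#' filopodium, renders the geometry (space-filler) channel and the
#' tip-factor channel frame by frame, and assembles exact base/tip tracks.
#' Length series are simulated for `n_frames + max(lag)` frames so the
#' coupled fluorescence is defined over the whole movie.
#'
#' @param scene a [scene_params()].
#' @param seed integer seed controlling all randomness.
#' @return list with `geometry` and `tip_channel` ([filo_movie()]s, both
#'   carrying the cell mask), `tracks` (tibble, possibly jittered), and
#'   `truth`: per-filopodium tibble rows of frame, true length, tip
#'   position, tip-factor value and programmed lag.
#' @export
simulate_scene <- function(scene, seed = 1L) {
  set.seed(seed)
  nf <- scene$n_frames
  fp_list <- scene$filopodia
  ids <- sprintf("df%02d", seq_along(fp_list))

  per_filo <- purrr::map2(fp_list, ids, function(fp, id) {
    lag <- fp$lag_frames
    ls <- simulate_length_series(fp$length_model, nf + lag,
                                 scene$interval_s)
    # motility input to the coupling: length change per interval, um/s
    rate <- ls$rate_um_s
    rate[1] <- 0
    ftip_true <- simulate_tip_factor(rate, lag, gain = fp$gain,
                                     baseline = fp$fluor_baseline,
                                     noise_sd = fp$fluor_noise_sd)
    kappa_px <- fp$curvature_per_um * scene$pixel_size_um
    len_px <- ls$length_um[seq_len(nf)] / scene$pixel_size_um
    cls <- purrr::map(len_px, function(L)
      arc_centerline(fp$base_xy, fp$orientation, kappa_px, L))
    tibble::tibble(
      df_id = id, frame = seq_len(nf),
      length_um = ls$length_um[seq_len(nf)],
      base_x = fp$base_xy[1], base_y = fp$base_xy[2],
      tip_x = purrr::map_dbl(cls, ~ .x$tip[1]),
      tip_y = purrr::map_dbl(cls, ~ .x$tip[2]),
      tip_factor = ftip_true[seq_len(nf)],
      lag_frames = fp$lag_frames,
      centerline = cls)
  }) |> dplyr::bind_rows()

  geom <- array(0, dim = c(nf, scene$height_px, scene$width_px))
  tipc <- array(0, dim = c(nf, scene$height_px, scene$width_px))
  mask <- array(FALSE, dim = dim(geom))
  for (t in seq_len(nf)) {
    rows <- per_filo[per_filo$frame == t, ]
    cell <- render_cell_field(scene, rows$centerline, frame_index = t)
    spots <- render_spot_field(scene, tibble::tibble(
      x = rows$tip_x, y = rows$tip_y, amp = rows$tip_factor))
    geom[t, , ] <- add_camera_noise(cell, scene$noise_sd,
                                    scene$poisson_scale)
    tipc[t, , ] <- add_camera_noise(0.25 * cell + spots, scene$noise_sd,
                                    scene$poisson_scale)
    mask[t, , ] <- cell > scene$mask_threshold_frac * max(cell)
  }

  tracks <- per_filo[c("df_id", "frame", "base_x", "base_y",
                       "tip_x", "tip_y")]
  if (scene$tracking_jitter_px > 0) {
    nr2 <- nrow(tracks) * 4L
    jit <- stats::rnorm(nr2, sd = scene$tracking_jitter_px)
    tracks$base_x <- tracks$base_x + jit[seq_len(nrow(tracks))]
    tracks$base_y <- tracks$base_y + jit[seq_len(nrow(tracks)) + nrow(tracks)]
    tracks$tip_x <- tracks$tip_x + jit[seq_len(nrow(tracks)) + 2L * nrow(tracks)]
    tracks$tip_y <- tracks$tip_y + jit[seq_len(nrow(tracks)) + 3L * nrow(tracks)]
  }
  truth <- per_filo[setdiff(names(per_filo), "centerline")]

  list(geometry = filo_movie(geom, scene$pixel_size_um, scene$interval_s,
                             mask),
       tip_channel = filo_movie(tipc, scene$pixel_size_um,
                                scene$interval_s, mask),
       tracks = validate_tracks(tracks),
       truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits `movie.tif` (geometry channel), `tip.tif` (tip-factor channel),
#' `mask.tif`, `tracks.csv` and `truth.json` into `out_dir`, in exactly the
#' formats [read_movie()] and [read_tracks()] ingest. Identical scene and
#' seed reproduce byte-identical files.
#'
#' @param scene a [scene_params()].
#' @param seed integer seed.
#' @param out_dir output directory (created if needed).
#' @return invisible list of written paths plus the in-memory dataset.
#' @export
make_dataset <- function(scene, seed, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_scene(scene, seed)
  paths <- list(
    movie = file.path(out_dir, "movie.tif"),
    tip = file.path(out_dir, "tip.tif"),
    mask = file.path(out_dir, "mask.tif"),
    tracks = file.path(out_dir, "tracks.csv"),
    truth = file.path(out_dir, "truth.json"))
  write_stack(ds$geometry$frames, paths$movie)
  write_stack(ds$tip_channel$frames, paths$tip)
  write_stack(ds$geometry$mask * 1, paths$mask)
  write_tracks(ds$tracks, paths$tracks)
  jsonlite::write_json(
    list(pixel_size_um = scene$pixel_size_um,
         interval_s = scene$interval_s, seed = seed,
         truth = ds$truth),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(dataset = ds)))
}
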