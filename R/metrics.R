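#' Substantive-motility threshold
#'
#' One pixel of displacement per frame interval, in um/s: displacements
#' below this are indistinguishable from tracking error. At 100x (0.064 um
#' effective pixels) and a 5 s interval this is 0.0128 um/s.
#'
#' @param pixel_size_um pixel size, micrometres (> 0).
#' @param interval_s frame interval, seconds (> 0).
#' @return threshold in um/s.
#' @export
motility_threshold <- function(pixel_size_um, interval_s) {
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0 ||
      !is.finite(interval_s) || interval_s <= 0)
    stop("calibration values must be positive", call. = FALSE)
  pixel_size_um / interval_s
}

#' Mean fluorescence in a circular tip ROI
#'
#' Mean intensity over the disc of the given physical radius around the
#' tracked tip, with non-cell background omitted when a mask is supplied.
#' Disc membership is by pixel-center distance (no partial-pixel
#' weighting). An ROI left empty after masking yields `NA` with a warning,
#' never a silent zero.
#'
#' @param frame intensity matrix (row x col).
#' @param tip_xy tip pixel coordinate `c(x, y)` (0-based).
#' @param radius_nm ROI radius, nanometres (default 384).
#' @param pixel_size_um pixel size, micrometres.
#' @param mask optional logical matrix (`TRUE` = cell).
#' @return mean intensity, or `NA` if no in-bounds cell pixel falls in the
#'   disc.
#' @export
tip_roi_intensity <- function(frame, tip_xy, radius_nm = 384,
                              pixel_size_um, mask = NULL) {
  r_px <- radius_nm / 1000 / pixel_size_um
  cx <- tip_xy[1]; cy <- tip_xy[2]
  nr <- nrow(frame); nc <- ncol(frame)
  xs <- max(0, floor(cx - r_px)):min(nc - 1, ceiling(cx + r_px))
  ys <- max(0, floor(cy - r_px)):min(nr - 1, ceiling(cy + r_px))
  if (length(xs) == 0 || length(ys) == 0 || cx < -r_px || cy < -r_px ||
      cx > nc - 1 + r_px || cy > nr - 1 + r_px) {
    warning("tip ROI does not intersect the frame")
    return(NA_real_)
  }
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  inside <- (X - cx)^2 + (Y - cy)^2 <= r_px^2
  if (!is.null(mask)) inside <- inside & mask[ys + 1, xs + 1, drop = FALSE]
  vals <- frame[ys + 1, xs + 1, drop = FALSE][inside]
  if (length(vals) == 0) {
    warning("tip ROI empty after masking; returning NA")
    return(NA_real_)
  }
  mean(vals)
}

#' Normalize tip fluorescence by its temporal minimum
#'
#' Divides each value by the series minimum over valid (finite) frames,
#' normalizing for expression level; the result is >= 1 at every valid
#' frame. `NA` entries are preserved.
#'
#' @param raw numeric fluorescence series (may contain `NA`).
#' @return normalized series of the same length.
#' @export
normalize_tip_fluorescence <- function(raw) {
  v <- raw[is.finite(raw)]
  if (length(v) == 0) stop("no valid fluorescence values", call. = FALSE)
  m <- min(v)
  if (m <= 0) stop("non-positive minimum fluorescence; cannot normalize",
                   call. = FALSE)
  raw / m
}

#' Temporal variance of normalized tip fluorescence
#'
#' Sample variance (n - 1 denominator) over valid frames: a measure of the
#' spread of tip enrichment over the imaging period.
#'
#' @param normalized numeric series (may contain `NA`).
#' @return variance.
#' @export
fluorescence_variance <- function(normalized) {
  v <- normalized[is.finite(normalized)]
  if (length(v) < 2) stop("need >= 2 valid values for a variance",
                          call. = FALSE)
  stats::var(v)
}

#' Assemble the per-frame series of one or more filopodia
#'
#' Joins per-frame centerline lengths, tracked tip positions (converted to
#' micrometres) and tip-ROI fluorescence from the fluorescence channel into
#' the tidy per-frame table all metrics consume. Frames missing from a
#' track are retained as invalid rows so that no metric ever differences
#' across a gap.
#'
#' @param movie fluorescence-channel [filo_movie()] (with optional mask).
#' @param tracks validated track tibble.
#' @param lengths per-frame length tibble from [centerline_lengths()].
#' @param roi_radius_nm tip ROI radius, nanometres.
#' @return tibble with `df_id`, `frame`, `time_s`, `valid`, `length_um`,
#'   `tip_x_um`, `tip_y_um`, `tip_fluor`, `tip_fluor_norm`.
#' @export
build_df_series <- function(movie, tracks, lengths, roi_radius_nm = 384) {
  tracks <- validate_tracks(tracks)
  tr <- tracks |>
    dplyr::mutate(
      tip_fluor = purrr::pmap_dbl(
        list(.data$frame, .data$tip_x, .data$tip_y),
        function(f, tx, ty) {
          fr <- movie_frame(movie, f)
          tip_roi_intensity(fr$frame, c(tx, ty), roi_radius_nm,
                            movie$pixel_size_um, fr$mask)
        }),
      tip_x_um = .data$tip_x * movie$pixel_size_um,
      tip_y_um = .data$tip_y * movie$pixel_size_um)
  full <- tr |>
    dplyr::left_join(lengths, by = c("df_id", "frame")) |>
    dplyr::group_by(.data$df_id) |>
    tidyr::complete(frame = tidyr::full_seq(.data$frame, 1L)) |>
    dplyr::ungroup() |>
    dplyr::mutate(frame = as.integer(.data$frame))
  full |>
    dplyr::group_by(.data$df_id) |>
    dplyr::mutate(tip_fluor_norm = normalize_tip_fluorescence(.data$tip_fluor)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      time_s = (.data$frame - 1) * movie$interval_s,
      valid = is.finite(.data$length_um) & is.finite(.data$tip_x_um)) |>
    dplyr::select(dplyr::all_of(c(
      "df_id", "frame", "time_s", "valid", "length_um",
      "tip_x_um", "tip_y_um", "tip_fluor", "tip_fluor_norm")))
}

#' Instantaneous tip speeds of one filopodium
#'
#' Euclidean tip displacement per frame interval (um/s) for each pair of
#' consecutive valid frames; pairs spanning an invalid frame (a gap in the
#' track) are omitted rather than bridged.
#'
#' @param tip_x_um,tip_y_um per-frame tip position, micrometres.
#' @param interval_s frame interval, seconds.
#' @param valid optional logical validity flags (default: finite positions).
#' @return numeric vector of per-interval speeds (um/s).
#' @export
instantaneous_speeds <- function(tip_x_um, tip_y_um, interval_s,
                                 valid = NULL) {
  if (is.null(valid)) valid <- is.finite(tip_x_um) & is.finite(tip_y_um)
  if (sum(valid) < 2) stop("need >= 2 valid frames", call. = FALSE)
  n <- length(tip_x_um)
  ok <- valid[-n] & valid[-1]
  d <- sqrt(diff(tip_x_um)^2 + diff(tip_y_um)^2)[ok]
  d / interval_s
}

#' Consecutive-pair rates of a per-frame series
#'
#' `diff(x)/interval` restricted to pairs of consecutive valid frames.
#' @param x per-frame values.
#' @param interval_s frame interval, seconds.
#' @param valid logical validity flags (default: finite values).
#' @return numeric vector of rates (per second).
#' @export
interval_rates <- function(x, interval_s, valid = is.finite(x)) {
  n <- length(x)
  ok <- valid[-n] & valid[-1]
  diff(x)[ok] / interval_s
}

#' Motility and fluorescence summary of one filopodium
#'
#' Computes, over the valid frames of one per-frame series:
#' average tip speed (mean of instantaneous speeds); motile classification
#' (average speed strictly greater than the threshold); percent time motile
#' (percent of intervals with instantaneous speed above threshold); average
#' and maximum centerline length; median protrusion rate (median of length
#' change rates exceeding `+threshold`; `NA` if none qualify) and median
#' retraction rate (median of rates below `-threshold`; `NA` if none); and
#' the temporal variance of min-normalized tip fluorescence. Undefined
#' values are reported as `NA`, never zero.
#'
#' @param series per-frame tibble of one filopodium (see
#'   [build_df_series()]).
#' @param threshold_um_s motility threshold, um/s (see
#'   [motility_threshold()]).
#' @param interval_s frame interval, seconds; defaults to the spacing of
#'   `series$time_s`.
#' @return one-row tibble (see [write_metrics_table()] for the columns).
#' @export
summarize_motility <- function(series, threshold_um_s,
                               interval_s = NULL) {
  stopifnot(length(unique(series$df_id)) == 1)
  if (is.null(interval_s))
    interval_s <- diff(series$time_s[1:2])
  valid <- series$valid
  speeds <- instantaneous_speeds(series$tip_x_um, series$tip_y_um,
                                 interval_s, valid)
  dldt <- interval_rates(series$length_um, interval_s,
                         valid & is.finite(series$length_um))
  prot <- dldt[dldt > threshold_um_s]
  retr <- dldt[dldt < -threshold_um_s]
  len <- series$length_um[valid & is.finite(series$length_um)]
  avg_speed <- mean(speeds)
  fl <- series$tip_fluor_norm[valid]
  tibble::tibble(
    df_id = series$df_id[1],
    n_frames = sum(valid),
    avg_tip_speed_um_s = avg_speed,
    is_motile = avg_speed > threshold_um_s,
    pct_time_motile = 100 * sum(speeds > threshold_um_s) / length(speeds),
    avg_length_um = if (length(len)) mean(len) else NA_real_,
    max_length_um = if (length(len)) max(len) else NA_real_,
    median_protrusion_rate_um_s =
      if (length(prot)) stats::median(prot) else NA_real_,
    median_retraction_rate_um_s =
      if (length(retr)) stats::median(retr) else NA_real_,
    fluor_variance =
      if (sum(is.finite(fl)) >= 2) fluorescence_variance(fl) else NA_real_)
}

#' Summaries for every filopodium in a series table
#'
#' @param series per-frame tibble from [build_df_series()].
#' @param threshold_um_s motility threshold, um/s.
#' @param interval_s frame interval, seconds.
#' @return one-row-per-filopodium tibble.
#' @export
summarize_motility_all <- function(series, threshold_um_s,
                                   interval_s = NULL) {
  series |>
    dplyr::group_split(.data$df_id) |>
    purrr::map(summarize_motility, threshold_um_s = threshold_um_s,
               interval_s = interval_s) |>
    dplyr::bind_rows()
}

#' Percent of the population classified motile
#'
#' @param summaries metrics tibble with an `is_motile` column.
#' @return percentage in `[0, 100]`.
#' @export
percent_motile <- function(summaries) {
  if (nrow(summaries) == 0) stop("empty summary set", call. = FALSE)
  100 * mean(summaries$is_motile)
}

#' Fold change of a per-frame quantity in time bins after a baseline
#'
#' Means of `values` over successive bins of `bin_len_s` seconds starting
#' at the end of the baseline window, each divided by the baseline mean
#' (e.g. tip speed in 2.5 or 5 min bins relative to the pre-stimulation /
#' pre-treatment mean). Bins with no valid value yield `NA`.
#'
#' @param values per-frame quantity.
#' @param times_s frame times, seconds.
#' @param baseline_window `c(t0, t1)`: baseline is `t0 <= t < t1`.
#' @param bin_len_s bin length, seconds.
#' @return tibble with `bin`, `t_start_s`, `t_end_s`, `fold_change`.
#' @export
fold_change_bins <- function(values, times_s, baseline_window, bin_len_s) {
  stopifnot(length(values) == length(times_s))
  in_base <- times_s >= baseline_window[1] & times_s < baseline_window[2] &
    is.finite(values)
  if (!any(in_base)) stop("baseline window contains no valid value",
                          call. = FALSE)
  base_mean <- mean(values[in_base])
  if (!is.finite(base_mean) || base_mean <= 0)
    stop("baseline mean must be positive", call. = FALSE)
  t0 <- baseline_window[2]
  t_max <- max(times_s)
  n_bins <- max(0L, ceiling((t_max - t0) / bin_len_s + 1e-9))
  purrr::map(seq_len(n_bins), function(b) {
    lo <- t0 + (b - 1) * bin_len_s; hi <- t0 + b * bin_len_s
    sel <- times_s >= lo & times_s < hi & is.finite(values)
    tibble::tibble(bin = b, t_start_s = lo, t_end_s = hi,
                   fold_change = if (any(sel)) mean(values[sel]) / base_mean
                                 else NA_real_)
  }) |> dplyr::bind_rows()
}
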