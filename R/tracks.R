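#' Read manual base/tip tracks from CSV
#'
#' The CSV must carry a header with columns `df_id`, `frame`, `base_x`,
#' `base_y`, `tip_x`, `tip_y`. Coordinates are real-valued 0-based pixel
#' positions (x = column, y = row); `frame` is a 1-based integer frame index.
#' Rows are sorted by (`df_id`, `frame`); a duplicated (`df_id`, `frame`)
#' pair is an error. Interior frame gaps (a filopodium disappearing and
#' reappearing is not expected, but missing records are tolerated) are
#' accepted and recorded: downstream metrics never difference across a gap.
#'
#' @param path path to the track CSV.
#' @return a tibble with columns `df_id` (character), `frame` (integer),
#'   `base_x`, `base_y`, `tip_x`, `tip_y` (double), carrying an attribute
#'   `gaps`: a tibble of (`df_id`, `frame`) interior frames with no record.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("track file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_tracks(raw)
}

#' Validate (and canonicalize) a track table
#'
#' @param tracks a data frame with the columns described in [read_tracks()].
#' @return the canonicalized tibble (see [read_tracks()]).
#' @export
validate_tracks <- function(tracks) {
  need <- c("df_id", "frame", "base_x", "base_y", "tip_x", "tip_y")
  missing_cols <- setdiff(need, names(tracks))
  if (length(missing_cols) > 0)
    stop("track table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tr <- tibble::as_tibble(tracks)[need]
  for (cc in need[-1]) {
    v <- tr[[cc]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(v))
      if (anyNA(v) && !anyNA(tr[[cc]]))
        stop("non-numeric values in column ", cc, call. = FALSE)
      tr[[cc]] <- v
    }
    if (anyNA(tr[[cc]]))
      stop("missing/non-numeric values in column ", cc, call. = FALSE)
  }
  tr$df_id <- as.character(tr$df_id)
  tr$frame <- as.integer(tr$frame)
  tr <- dplyr::arrange(tr, .data$df_id, .data$frame)
  dup <- duplicated(tr[c("df_id", "frame")])
  if (any(dup)) {
    d <- tr[dup, ]
    stop(sprintf("duplicate track row(s), e.g. df_id=%s frame=%d",
                 d$df_id[1], d$frame[1]), call. = FALSE)
  }
  attr(tr, "gaps") <- track_gaps(tr)
  tr
}

#' Interior frame gaps of a track table
#'
#' For each filopodium, frames strictly between its first and last tracked
#' frame that have no record. Metric operations treat each maximal contiguous
#' run independently and never difference across these frames.
#'
#' @param tracks a validated track tibble.
#' @return tibble with columns `df_id`, `frame`.
#' @export
track_gaps <- function(tracks) {
  tracks |>
    dplyr::group_by(.data$df_id) |>
    dplyr::reframe(frame = setdiff(seq(min(.data$frame), max(.data$frame)),
                                   .data$frame)) |>
    dplyr::mutate(frame = as.integer(.data$frame))
}

#' Write a track table to CSV
#' @param tracks track tibble (see [read_tracks()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write / read a per-filopodium metrics table
#'
#' Column order is stable and documented: `df_id`, `n_frames`,
#' `avg_tip_speed_um_s`, `is_motile`, `pct_time_motile`, `avg_length_um`,
#' `max_length_um`, `median_protrusion_rate_um_s`,
#' `median_retraction_rate_um_s`, `fluor_variance`. Undefined metric values
#' are written as `NA`, never coerced to zero. Full double precision is
#' retained so that a write/read round trip reproduces values to better than
#' 1e-9 relative.
#'
#' @param metrics one-row-per-filopodium tibble from [summarize_motility_all()].
#' @param path CSV path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_metrics_table <- function(metrics, path) {
  cols <- metric_table_columns()
  missing_cols <- setdiff(cols, names(metrics))
  if (length(missing_cols) > 0)
    stop("metrics table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- as.data.frame(metrics[cols])
  old <- options(digits = 17); on.exit(options(old))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  if (!file.exists(path)) stop("metrics file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$df_id <- as.character(df$df_id)
  tibble::as_tibble(df)
}

metric_table_columns <- function() {
  c("df_id", "n_frames", "avg_tip_speed_um_s", "is_motile",
    "pct_time_motile", "avg_length_um", "max_length_um",
    "median_protrusion_rate_um_s", "median_retraction_rate_um_s",
    "fluor_variance")
}
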