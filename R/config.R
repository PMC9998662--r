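#' Pipeline configuration
#'
#' Bundles every tunable constant of the pipeline. Defaults reflect the
#' acquisition regime the analysis was designed for (0.064 um pixels imaged
#' on a 5 s interval): the motility threshold, when left `NULL`, is derived
#' at use as one pixel displacement per frame interval via
#' [motility_threshold()]; the tip ROI is a 384 nm radius disc; the tangent
#' field is estimated on a 15 x 15 pixel window; the block bootstrap shuffles
#' eight-timepoint blocks over 1,000 randomized datasets.
#'
#' @param motility_threshold_um_s motility threshold in um/s, or `NULL` to
#'   derive `pixel_size_um / interval_s` from the movie calibration.
#' @param roi_radius_nm tip ROI radius in nanometres.
#' @param angle_window_px odd window size (pixels, >= 3) for the
#'   intensity-weighted tangent angle.
#' @param ccf_max_offset_frames largest frame offset (each direction) of the
#'   cross-correlation profile.
#' @param block_len_frames block length (frames, >= 2) of the block bootstrap.
#' @param n_randomizations number of randomized datasets (>= 1).
#' @param rng_seed integer seed used by stochastic stages.
#' @param centerline_tol_px convergence tolerance of the centerline
#'   relaxation: maximal node displacement between iterations, pixels.
#' @param centerline_max_iter iteration cap of the centerline relaxation.
#'
#' @return an object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(motility_threshold_um_s = NULL,
                            roi_radius_nm = 384,
                            angle_window_px = 15L,
                            ccf_max_offset_frames = 12L,
                            block_len_frames = 8L,
                            n_randomizations = 1000L,
                            rng_seed = 1L,
                            centerline_tol_px = 0.05,
                            centerline_max_iter = 50L) {
  cfg <- list(
    motility_threshold_um_s = motility_threshold_um_s,
    roi_radius_nm = roi_radius_nm,
    angle_window_px = as.integer(angle_window_px),
    ccf_max_offset_frames = as.integer(ccf_max_offset_frames),
    block_len_frames = as.integer(block_len_frames),
    n_randomizations = as.integer(n_randomizations),
    rng_seed = as.integer(rng_seed),
    centerline_tol_px = centerline_tol_px,
    centerline_max_iter = as.integer(centerline_max_iter))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  w <- cfg$angle_window_px
  if (is.na(w) || w < 3L || w %% 2L == 0L)
    stop("`angle_window_px` must be an odd integer >= 3", call. = FALSE)
  if (cfg$block_len_frames < 2L)
    stop("`block_len_frames` must be >= 2", call. = FALSE)
  if (cfg$n_randomizations < 1L)
    stop("`n_randomizations` must be >= 1", call. = FALSE)
  if (!is.null(cfg$motility_threshold_um_s) &&
      cfg$motility_threshold_um_s <= 0)
    stop("`motility_threshold_um_s` must be positive (or NULL to derive)",
         call. = FALSE)
  if (cfg$roi_radius_nm <= 0) stop("`roi_radius_nm` must be positive",
                                   call. = FALSE)
  if (cfg$ccf_max_offset_frames < 1L)
    stop("`ccf_max_offset_frames` must be >= 1", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x))
    cat(sprintf("  %s = %s\n", k,
                if (is.null(x[[k]])) "(derived)" else format(x[[k]])))
  invisible(x)
}

#' Write / read a pipeline configuration as a key=value file
#'
#' A plain-text `key=value` document, one entry per line, echoed into
#' pipeline outputs for provenance. A derived (NULL) motility threshold is
#' written as the literal `derived`.
#'
#' @param cfg a [pipeline_config()].
#' @param path file path.
#' @return `path` invisibly (write); a `pipeline_config` (read).
#' @export
write_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    sprintf("%s=%s", k,
            if (is.null(v)) "derived" else format(v, digits = 17))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  cfg <- pipeline_config()
  for (p in kv) {
    k <- trimws(p[1]); v <- trimws(paste(p[-1], collapse = "="))
    if (!k %in% names(cfg)) stop("unknown config key: ", k, call. = FALSE)
    cfg[[k]] <- if (identical(v, "derived")) NULL
                else if (k %in% c("angle_window_px", "ccf_max_offset_frames",
                                  "block_len_frames", "n_randomizations",
                                  "rng_seed", "centerline_max_iter"))
                  as.integer(v)
                else as.numeric(v)
  }
  validate_config(cfg)
}
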