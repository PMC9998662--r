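#' Calibrated time-lapse movie container
#'
#' A `filo_movie` holds a single-channel fluorescence time-lapse as a 3-D
#' array (time x row x col) together with its spatial and temporal
#' calibration, and optionally a per-frame boolean cell mask (`TRUE` = cell).
#' All downstream operations consume this container, never file paths.
#'
#' Pixel coordinates throughout the package are 0-based, with `x` the column
#' index (rightward) and `y` the row index (downward); physical positions are
#' `pixel * pixel_size_um` micrometres. Intensities are arbitrary nonnegative
#' units; every analysis step is invariant to uniform intensity rescaling.
#'
#' @param frames numeric 3-D array, `time x row x col`, nonnegative.
#' @param pixel_size_um pixel edge length in micrometres (> 0).
#' @param interval_s time between frames in seconds (> 0).
#' @param mask optional logical array with the same extents as `frames`.
#'
#' @return An object of class `filo_movie`.
#' @export
filo_movie <- function(frames, pixel_size_um, interval_s, mask = NULL) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a 3-D array (time x row x col)", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  if (!is.numeric(interval_s) || length(interval_s) != 1L ||
      !is.finite(interval_s) || interval_s <= 0)
    stop("`interval_s` must be a single positive number", call. = FALSE)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(frames)))
      stop("`mask` extents must match `frames` (time x row x col)",
           call. = FALSE)
    storage.mode(mask) <- "logical"
  }
  structure(
    list(frames = frames, pixel_size_um = pixel_size_um,
         interval_s = interval_s, mask = mask),
    class = "filo_movie")
}

#' @export
print.filo_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<filo_movie> %d frames, %d x %d px, %.4g um/px, %.4g s/frame%s\n",
    d[1], d[2], d[3], x$pixel_size_um, x$interval_s,
    if (is.null(x$mask)) "" else ", masked"))
  invisible(x)
}

#' Number of frames in a movie
#' @param movie a [filo_movie()].
#' @return integer frame count.
#' @export
n_frames <- function(movie) dim(movie$frames)[1]

#' Extract one frame (and its mask) from a movie
#'
#' @param movie a [filo_movie()].
#' @param t frame index (1-based).
#' @return a list with `frame` (row x col matrix) and `mask` (matrix or NULL).
#' @export
movie_frame <- function(movie, t) {
  stopifnot(t >= 1, t <= n_frames(movie))
  list(frame = movie$frames[t, , ],
       mask = if (is.null(movie$mask)) NULL else movie$mask[t, , ])
}

#' Read a calibrated movie from a multi-frame TIFF
#'
#' Frames are read in acquisition order. An optional mask TIFF (any nonzero
#' pixel = cell) must match the movie frame-for-frame.
#'
#' @param path path to a multi-frame single-channel TIFF.
#' @param pixel_size_um,interval_s calibration (see [filo_movie()]).
#' @param mask_path optional path to a mask TIFF with identical extents.
#' @return a [filo_movie()].
#' @export
read_movie <- function(path, pixel_size_um, interval_s, mask_path = NULL) {
  if (!file.exists(path)) stop("movie file not found: ", path, call. = FALSE)
  frames <- tiff_to_stack(path)
  mask <- NULL
  if (!is.null(mask_path)) {
    if (!file.exists(mask_path))
      stop("mask file not found: ", mask_path, call. = FALSE)
    m <- tiff_to_stack(mask_path)
    if (!identical(dim(m), dim(frames)))
      stop(sprintf("mask extents (%s) do not match movie (%s)",
                   paste(dim(m), collapse = "x"),
                   paste(dim(frames), collapse = "x")), call. = FALSE)
    mask <- m > 0
  }
  filo_movie(frames, pixel_size_um, interval_s, mask)
}

#' Write a movie's frames (or mask) to a multi-frame TIFF
#'
#' Intensities are stored as 16-bit samples scaled to the stack maximum;
#' absolute intensity scale is not preserved, which is immaterial here since
#' every analysis step is invariant to uniform intensity rescaling.
#'
#' @param stack 3-D numeric or logical array (time x row x col).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  top <- max(stack, 1e-12)
  pages <- lapply(seq_len(dim(stack)[1]),
                  function(t) pmin(pmax(stack[t, , ] / top, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

# multi-frame TIFF -> time x row x col array
tiff_to_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # first sample of multi-sample page
    p
  })
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L)
    stop("TIFF pages differ in size: ", path, call. = FALSE)
  aperm(simplify2array(pages), c(3, 1, 2))
}
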