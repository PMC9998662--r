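#' Intensity-weighted local tangent angle
#'
#' Orientation of the long axis of the local intensity distribution at a
#' pixel, from the intensity-weighted second central moments of pixel
#' coordinates over a square window centered on the pixel:
#' `theta = 1/2 * atan2(2*mu11, mu20 - mu02)`, returned in `[-pi/2, pi/2)`
#' (orientation is defined modulo pi). The moments are taken over the disc
#' inscribed in the window (pixel-center distance <= `window_px / 2`): a
#' rotationally symmetric domain, unlike the raw square, clips a curved
#' ridge symmetrically about the local normal at every orientation and so
#' avoids an orientation-dependent curvature bias. The estimate is
#' invariant to uniform rescaling of intensity within the window. Window
#' pixels outside the image are excluded from the moments (no padding).
#'
#' @param frame intensity matrix (row x col).
#' @param center pixel coordinate `c(x, y)` (0-based, x = column); the window
#'   is centered on the nearest integer pixel.
#' @param window_px odd window size, default 15.
#' @return list with `theta` (radians, `NA` if degenerate) and `degenerate`
#'   (`TRUE` for zero total intensity or an isotropic patch, in which case
#'   callers fall back to the local chord direction).
#' @export
local_tangent_angle <- function(frame, center, window_px = 15L) {
  stopifnot(window_px >= 3L, window_px %% 2L == 1L)
  h <- (window_px - 1L) %/% 2L
  cx <- round(center[1]); cy <- round(center[2])
  nr <- nrow(frame); nc <- ncol(frame)
  xs <- (cx - h):(cx + h)
  ys <- (cy - h):(cy + h)
  xs <- xs[xs >= 0 & xs <= nc - 1L]
  ys <- ys[ys >= 0 & ys <= nr - 1L]
  if (length(xs) * length(ys) < ceiling(window_px^2 / 2))
    stop("tangent window falls mostly outside the frame at (",
         center[1], ", ", center[2], ")", call. = FALSE)
  patch <- frame[ys + 1L, xs + 1L, drop = FALSE]
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
  # inscribed-disc domain: symmetric clipping at every ridge orientation
  patch[(X - cx)^2 + (Y - cy)^2 > (window_px / 2)^2] <- 0
  w <- sum(patch)
  if (!is.finite(w) || w <= 0)
    return(list(theta = NA_real_, degenerate = TRUE))
  xbar <- sum(patch * X) / w
  ybar <- sum(patch * Y) / w
  mu20 <- sum(patch * (X - xbar)^2) / w
  mu02 <- sum(patch * (Y - ybar)^2) / w
  mu11 <- sum(patch * (X - xbar) * (Y - ybar)) / w
  msum <- mu20 + mu02
  if (msum <= 0 ||
      (abs(mu11) <= 1e-9 * msum && abs(mu20 - mu02) <= 1e-9 * msum))
    return(list(theta = NA_real_, degenerate = TRUE))
  th <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  if (th >= pi / 2) th <- th - pi
  list(theta = th, degenerate = FALSE)
}

#' Continue a modulo-pi orientation sequence into a signed angle
#'
#' Orientations are only defined modulo pi; the centerline ODE needs a
#' continuous signed tangent angle. Each successive angle is adjusted by a
#' multiple of pi to minimize the jump from its predecessor; the first
#' element is anchored within pi/2 of `anchor` (the base-to-tip chord
#' direction in pipeline use).
#'
#' @param theta numeric vector of orientations (radians); `NA` entries are
#'   carried forward from the previous continued value.
#' @param anchor reference angle for the first element (default: the first
#'   orientation itself).
#' @return numeric vector of continued angles.
#' @export
continue_branch <- function(theta, anchor = theta[1]) {
  if (length(theta) == 0) stop("empty orientation sequence", call. = FALSE)
  out <- numeric(length(theta))
  prev <- anchor
  for (i in seq_along(theta)) {
    ti <- theta[i]
    if (is.na(ti)) ti <- prev
    out[i] <- ti + pi * round((prev - ti) / pi)
    prev <- out[i]
  }
  out
}

#' Trace a filopodial centerline between tracked base and tip
#'
#' Reconstructs the unit-speed centerline curve `(x(s), y(s))` of one
#' filopodium in one frame by iterative relaxation of the two-point
#' boundary-value problem
#' \deqn{x'' = -\sin\theta\,\theta', \qquad y'' = \cos\theta\,\theta',}
#' with Dirichlet conditions pinning the endpoints to the tracked base and
#' tip. Starting from the straight chord, each iteration (i) samples the
#' intensity-weighted tangent field ([local_tangent_angle()]) at the current
#' nodes, (ii) continues the orientation branch anchored to the chord
#' direction, (iii) solves the discretized ODE (second-order central finite
#' differences on a uniform arc-length grid), and (iv) re-parameterizes to
#' uniform arc length, until the maximal node displacement drops below
#' `tol_px` pixels. Degenerate (isotropic) patches fall back to the local
#' chord direction of the current iterate.
#'
#' @param frame intensity matrix (row x col).
#' @param base_xy,tip_xy pixel coordinates `c(x, y)` (0-based) of the
#'   tracked base and tip; they must be more than one pixel apart.
#' @param pixel_size_um micrometres per pixel.
#' @param window_px tangent-field window size (odd).
#' @param tol_px convergence tolerance: maximal node displacement, pixels.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   last iterate in its `condition$curve`.
#' @return a tibble of class `filo_centerline` with columns `node`, `s_um`,
#'   `x_um`, `y_um`, `theta` and attributes `length_um`, `converged`,
#'   `n_iter`, `pixel_size_um`, `max_disp_px_trace`.
#' @export
solve_centerline <- function(frame, base_xy, tip_xy, pixel_size_um,
                             window_px = 15L, tol_px = 0.05,
                             max_iter = 50L) {
  base_xy <- as.numeric(base_xy); tip_xy <- as.numeric(tip_xy)
  chord <- tip_xy - base_xy
  chord_len <- sqrt(sum(chord^2))
  if (!is.finite(chord_len) || chord_len <= 1)
    stop("degenerate input: base and tip coincide (separation <= 1 px)",
         call. = FALSE)
  if (!all(is.finite(frame)))
    stop("frame contains non-finite intensities", call. = FALSE)

  n <- max(16L, as.integer(ceiling(2 * chord_len)))
  tfrac <- seq(0, 1, length.out = n)
  x <- base_xy[1] + tfrac * chord[1]
  y <- base_xy[2] + tfrac * chord[2]
  anchor <- atan2(chord[2], chord[1])
  disp_trace <- numeric(0)
  converged <- FALSE
  theta_c <- rep(anchor, n)

  for (iter in seq_len(max_iter)) {
    # local chord directions of the current iterate (degeneracy fallback)
    dxl <- c(x[2] - x[1], x[-1] - x[-n]); dxl[n] <- x[n] - x[n - 1]
    dyl <- c(y[2] - y[1], y[-1] - y[-n]); dyl[n] <- y[n] - y[n - 1]
    local_dir <- atan2(dyl, dxl)

    theta_raw <- vapply(seq_len(n), function(i) {
      a <- local_tangent_angle(frame, c(x[i], y[i]), window_px)
      if (a$degenerate) local_dir[i] else a$theta
    }, numeric(1))
    theta_c <- continue_branch(theta_raw, anchor)

    seg <- sqrt(diff(x)^2 + diff(y)^2)
    len <- sum(seg)
    h <- len / (n - 1)
    dth <- c(theta_c[2] - theta_c[1],
             (theta_c[3:n] - theta_c[1:(n - 2)]) / 2,
             theta_c[n] - theta_c[n - 1]) / h
    fx <- -sin(theta_c) * dth
    fy <- cos(theta_c) * dth

    x_new <- solve_dirichlet(fx, h, base_xy[1], tip_xy[1])
    y_new <- solve_dirichlet(fy, h, base_xy[2], tip_xy[2])

    rp <- reparam_arclength(x_new, y_new, n)
    disp <- max(sqrt((rp$x - x)^2 + (rp$y - y)^2))
    disp_trace <- c(disp_trace, disp)
    x <- rp$x; y <- rp$y
    if (disp < tol_px) { converged <- TRUE; break }
  }

  s_px <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  curve <- tibble::tibble(
    node = seq_len(n) - 1L,
    s_um = s_px * pixel_size_um,
    x_um = x * pixel_size_um,
    y_um = y * pixel_size_um,
    theta = theta_c)
  attr(curve, "length_um") <- s_px[n] * pixel_size_um
  attr(curve, "converged") <- converged
  attr(curve, "n_iter") <- length(disp_trace)
  attr(curve, "pixel_size_um") <- pixel_size_um
  attr(curve, "max_disp_px_trace") <- disp_trace
  class(curve) <- c("filo_centerline", class(curve))
  if (!converged) {
    cond <- structure(
      class = c("filotrace_no_convergence", "error", "condition"),
      list(message = sprintf(
             "centerline relaxation did not converge in %d iterations (last max displacement %.3g px)",
             max_iter, disp_trace[length(disp_trace)]),
           call = sys.call(-1), curve = curve))
    stop(cond)
  }
  curve
}

# tridiagonal Dirichlet solve of u'' = f on a uniform grid of spacing h
solve_dirichlet <- function(f, h, u0, uN) {
  n <- length(f)
  if (n == 2L) return(c(u0, uN))
  m <- n - 2L
  rhs <- f[2:(n - 1)] * h^2
  rhs[1] <- rhs[1] - u0
  rhs[m] <- rhs[m] - uN
  # Thomas algorithm, constant stencil (1, -2, 1)
  cp <- numeric(m); dp <- numeric(m)
  cp[1] <- 1 / -2
  dp[1] <- rhs[1] / -2
  if (m > 1) for (i in 2:m) {
    denom <- -2 - cp[i - 1]
    cp[i] <- 1 / denom
    dp[i] <- (rhs[i] - dp[i - 1]) / denom
  }
  u <- numeric(m)
  u[m] <- dp[m]
  if (m > 1) for (i in (m - 1):1) u[i] <- dp[i] - cp[i] * u[i + 1]
  c(u0, u, uN)
}

# resample a polyline to n nodes uniform in arc length
reparam_arclength <- function(x, y, n) {
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  if (s[length(s)] <= 0) return(list(x = x, y = y))
  su <- seq(0, s[length(s)], length.out = n)
  list(x = stats::approx(s, x, xout = su, ties = "ordered")$y,
       y = stats::approx(s, y, xout = su, ties = "ordered")$y)
}

#' Arc length of a centerline curve
#'
#' Sum of Euclidean node-to-node distances, in micrometres: the distance
#' from base to tip along the centerline.
#'
#' @param curve a `filo_centerline` tibble (or any data frame with `x_um`,
#'   `y_um`).
#' @return length in micrometres.
#' @export
curve_length <- function(curve) {
  if (nrow(curve) < 2) stop("curve needs at least 2 nodes", call. = FALSE)
  sum(sqrt(diff(curve$x_um)^2 + diff(curve$y_um)^2))
}

#' Trace centerlines for every tracked filopodium and frame
#'
#' Runs [solve_centerline()] for each row of the track table against the
#' matching movie frame and stacks the node tables.
#'
#' @param movie a [filo_movie()].
#' @param tracks a validated track tibble ([read_tracks()]).
#' @param config a [pipeline_config()].
#' @return tibble with columns `df_id`, `frame`, `node`, `s_um`, `x_um`,
#'   `y_um`, `theta`, `converged`.
#' @export
trace_centerlines <- function(movie, tracks, config = pipeline_config()) {
  tracks <- validate_tracks(tracks)
  purrr::pmap(tracks, function(df_id, frame, base_x, base_y, tip_x, tip_y) {
    fr <- movie_frame(movie, frame)$frame
    cv <- solve_centerline(fr, c(base_x, base_y), c(tip_x, tip_y),
                           movie$pixel_size_um,
                           window_px = config$angle_window_px,
                           tol_px = config$centerline_tol_px,
                           max_iter = config$centerline_max_iter)
    dplyr::mutate(tibble::as_tibble(cv), df_id = df_id, frame = frame,
                  converged = attr(cv, "converged"), .before = 1)
  }) |>
    dplyr::bind_rows()
}

#' Per-frame centerline lengths
#'
#' @param curves node table from [trace_centerlines()].
#' @return tibble with `df_id`, `frame`, `length_um`.
#' @export
centerline_lengths <- function(curves) {
  curves |>
    dplyr::group_by(.data$df_id, .data$frame) |>
    dplyr::summarise(
      length_um = sum(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2)),
      .groups = "drop")
}
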