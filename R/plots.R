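#' Plot cross-correlation profiles
#'
#' CCF versus time offset, one line per filopodium, colored by TCS
#' membership when `labels` are supplied; negative offsets mean
#' fluorescence enrichment precedes motility.
#'
#' @param profiles tibble from [compute_ccf()].
#' @param interval_s frame interval used to express offsets in seconds
#'   (default: offsets stay in frames).
#' @param labels optional [cluster_tcs()] table.
#' @return a ggplot object.
#' @export
plot_ccf <- function(profiles, interval_s = 1, labels = NULL) {
  df <- dplyr::mutate(profiles, offset_t = .data$offset * interval_s)
  if (!is.null(labels))
    df <- dplyr::left_join(df, labels[c("df_id", "tcs")], by = "df_id")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$offset_t, .data$ccf,
                                        group = .data$df_id)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::labs(
      x = if (interval_s == 1) "offset (frames)" else "offset (s)",
      y = "cross-correlation (FTIP vs DCTM)") +
    ggplot2::theme_minimal()
  if (is.null(labels)) p + ggplot2::geom_line(alpha = 0.6)
  else p + ggplot2::geom_line(ggplot2::aes(color = .data$tcs), alpha = 0.7) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#d95f02",
                                           `FALSE` = "grey50"),
                                name = "TCS")
}

#' Plot a per-frame filopodium series
#'
#' Length and normalized tip fluorescence over time, faceted per quantity.
#'
#' @param series tibble from [build_df_series()].
#' @return a ggplot object.
#' @export
plot_series <- function(series) {
  long <- series |>
    dplyr::select(dplyr::all_of(c("df_id", "time_s", "length_um",
                                  "tip_fluor_norm"))) |>
    tidyr::pivot_longer(c("length_um", "tip_fluor_norm"),
                        names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$value,
                                     color = .data$df_id)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Autoplot a TCS bootstrap report
#'
#' Histogram of randomized TCS mean peak CCFs with the observed value
#' marked.
#'
#' @param object a [bootstrap_tcs()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot tcs_bootstrap
#' @export
autoplot.tcs_bootstrap <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$null_peak)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "white") +
    ggplot2::geom_vline(xintercept = object$observed_tcs_mean_peak,
                        color = "#d95f02", linewidth = 1) +
    ggplot2::labs(x = "randomized TCS mean peak CCF", y = "frequency",
                  subtitle = sprintf("bootstrap p = %.4g", object$p_value)) +
    ggplot2::theme_minimal()
}

#' Autoplot a centerline over its frame
#'
#' @param object a [solve_centerline()] result.
#' @param frame optional intensity matrix to show underneath (pixel units).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot filo_centerline
#' @export
autoplot.filo_centerline <- function(object, frame = NULL, ...) {
  px <- attr(object, "pixel_size_um")
  p <- ggplot2::ggplot()
  if (!is.null(frame)) {
    img <- tidyr::expand_grid(y = seq_len(nrow(frame)) - 1L,
                              x = seq_len(ncol(frame)) - 1L)
    img$intensity <- as.vector(t(frame))
    p <- p + ggplot2::geom_raster(
      data = img, ggplot2::aes(.data$x * px, .data$y * px,
                               fill = .data$intensity)) +
      ggplot2::scale_fill_viridis_c(guide = "none")
  }
  p + ggplot2::geom_path(data = tidy(object),
                         ggplot2::aes(.data$x_um, .data$y_um),
                         color = "red") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}
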