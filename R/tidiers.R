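#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a TCS block-bootstrap report
#'
#' One row per randomized dataset: the randomized TCS mean peak CCF and
#' whether it reached the observed value.
#'
#' @param x a [bootstrap_tcs()] result.
#' @param ... unused.
#' @return tibble with `draw`, `null_peak`, `exceeds_observed`.
#' @method tidy tcs_bootstrap
#' @export
tidy.tcs_bootstrap <- function(x, ...) {
  tibble::tibble(
    draw = seq_along(x$null_peaks),
    null_peak = x$null_peaks,
    exceeds_observed = x$null_peaks >= x$observed_tcs_mean_peak)
}

#' Glance at a TCS block-bootstrap report
#'
#' @param x a [bootstrap_tcs()] result.
#' @param ... unused.
#' @return one-row tibble with the observed TCS mean peak, TCS size,
#'   bootstrap p-value and the randomization settings.
#' @method glance tcs_bootstrap
#' @export
glance.tcs_bootstrap <- function(x, ...) {
  tibble::tibble(
    observed_tcs_mean_peak = x$observed_tcs_mean_peak,
    n_tcs = sum(x$labels$tcs),
    n_df = nrow(x$labels),
    p_value = x$p_value,
    n_randomizations = x$n_randomizations,
    block_len = x$block_len,
    method = x$method,
    seed = x$seed)
}

#' Tidy a centerline curve
#'
#' @param x a [solve_centerline()] result.
#' @param ... unused.
#' @return the node tibble with plain tibble class.
#' @method tidy filo_centerline
#' @export
tidy.filo_centerline <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' Glance at a centerline curve
#'
#' @param x a [solve_centerline()] result.
#' @param ... unused.
#' @return one-row tibble with length, node count, convergence state and
#'   iteration count.
#' @method glance filo_centerline
#' @export
glance.filo_centerline <- function(x, ...) {
  tibble::tibble(
    length_um = attr(x, "length_um"),
    n_nodes = nrow(x),
    converged = attr(x, "converged"),
    n_iter = attr(x, "n_iter"))
}
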