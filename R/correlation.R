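#' Three-point moving average with gap handling
#'
#' Centered three-point mean; at the ends of the series (and of every
#' maximal run of valid values) the available two-point mean is used. `NA`
#' entries break the window: values are never averaged across a gap, and
#' gaps stay `NA`.
#'
#' @param x numeric series (may contain `NA`).
#' @return smoothed series of the same length.
#' @export
moving_average3 <- function(x) {
  n <- length(x)
  if (n < 3) stop("series shorter than 3", call. = FALSE)
  if (!anyNA(x))
    return(c((x[1] + x[2]) / 2,
             (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3,
             (x[n - 1] + x[n]) / 2))
  out <- rep(NA_real_, length(x))
  valid <- is.finite(x)
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    idx <- starts[j]:ends[j]
    n <- length(idx)
    out[idx] <- vapply(seq_len(n), function(i)
      mean(x[idx[max(1, i - 1):min(n, i + 1)]]), numeric(1))
  }
  out
}

#' Direction-corrected tip movement (DCTM)
#'
#' Signed rate of length change per frame interval (um/s, positive =
#' protrusion, negative = retraction), smoothed with a three-point moving
#' average. The rate of the pair (t-1, t) is aligned at frame t; the first
#' frame, and any frame whose pair spans a gap, is `NA`.
#'
#' @param length_um per-frame centerline length, micrometres (gaps as `NA`).
#' @param interval_s frame interval, seconds.
#' @return per-frame smoothed signed rate (um/s), same length as input.
#' @export
dctm <- function(length_um, interval_s) {
  if (sum(is.finite(length_um)) < 2)
    stop("need >= 2 valid lengths", call. = FALSE)
  raw <- c(NA_real_, diff(length_um) / interval_s)
  moving_average3(raw)
}

#' Build the paired FTIP / DCTM series for the lead-lag analysis
#'
#' For each filopodium: tip fluorescence (already min-normalized) and DCTM,
#' each smoothed with the three-point moving average, aligned on the frame
#' index.
#'
#' @param series per-frame tibble from [build_df_series()].
#' @param interval_s frame interval, seconds; defaults to the `time_s`
#'   spacing.
#' @return tibble with `df_id`, `frame`, `ftip`, `dctm` (both smoothed)
#'   and `dctm_raw` (unsmoothed signed rate, the series the block
#'   bootstrap shuffles before re-applying the identical analysis).
#' @export
pair_series <- function(series, interval_s = NULL) {
  if (is.null(interval_s)) interval_s <- diff(series$time_s[1:2])
  series |>
    dplyr::group_by(.data$df_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(
      ftip = moving_average3(ifelse(.data$valid, .data$tip_fluor_norm,
                                    NA_real_)),
      dctm_raw = {
        len <- ifelse(.data$valid, .data$length_um, NA_real_)
        c(NA_real_, diff(len) / interval_s)
      },
      dctm = moving_average3(.data$dctm_raw)) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("df_id", "frame", "ftip", "dctm",
                                  "dctm_raw")))
}

#' Significance bound of a cross-correlation peak
#'
#' `2 / sqrt(n - |offset|)`: a peak cross-correlation exceeding this bound
#' at its offset is called significant.
#'
#' @param n number of paired valid timepoints.
#' @param offset integer frame offset.
#' @return the bound.
#' @export
significance_bound <- function(n, offset) {
  if (any(n <= abs(offset)))
    stop("need n > |offset| for a significance bound", call. = FALSE)
  2 / sqrt(n - abs(offset))
}

# Pearson correlation of (ftip(t + tau), dctm(t)) over finite pairs
lagged_cor <- function(ftip, dctm, tau) {
  n <- length(ftip)
  if (tau >= 0) { f <- ftip[(1 + tau):n]; d <- dctm[1:(n - tau)] }
  else { f <- ftip[1:(n + tau)]; d <- dctm[(1 - tau):n] }
  if (anyNA(f) || anyNA(d)) {
    ok <- is.finite(f) & is.finite(d)
    if (sum(ok) < 3) return(c(NA_real_, sum(ok)))
    f <- f[ok]; d <- d[ok]
  } else if (length(f) < 3) return(c(NA_real_, length(f)))
  m <- length(f)
  fc <- f - sum(f) / m
  dc <- d - sum(d) / m
  sf <- sqrt(sum(fc * fc)); sd_ <- sqrt(sum(dc * dc))
  if (sf == 0 || sd_ == 0) return(c(NA_real_, m))
  c(sum(fc * dc) / (sf * sd_), m)
}

#' Cross-correlation profile of tip fluorescence versus motility
#'
#' `CCF(tau) = cor(ftip(t + tau), dctm(t))` over the overlapping valid
#' frames, for integer offsets `tau` in `[-K, K]`: a peak at negative
#' offset means fluorescence enrichment precedes motility, at positive
#' offset that it follows motility. Offsets with a zero-variance overlap
#' are undefined (`NA`) and excluded from the peak search.
#'
#' @param ftip,dctm aligned per-frame series (smoothed; `NA` = invalid).
#' @param max_offset largest offset `K`, frames; requires
#'   `n > max_offset + 2` paired valid timepoints.
#' @return tibble with `offset`, `ccf`, `n_overlap`, `sig_bound`, carrying
#'   attributes `n_pairs`, `peak_value`, `peak_offset`.
#' @export
ccf_profile <- function(ftip, dctm, max_offset) {
  stopifnot(length(ftip) == length(dctm))
  n_pairs <- sum(is.finite(ftip) & is.finite(dctm))
  if (n_pairs <= max_offset + 2)
    stop("series too short for max_offset (need n > K + 2)", call. = FALSE)
  offs <- (-max_offset):max_offset
  cc <- vapply(offs, function(tau) lagged_cor(ftip, dctm, tau), numeric(2))
  prof <- tibble::tibble(
    offset = offs,
    ccf = cc[1, ],
    n_overlap = as.integer(cc[2, ]),
    sig_bound = ifelse(n_pairs > abs(offs),
                       2 / sqrt(n_pairs - abs(offs)), NA_real_))
  ok <- is.finite(prof$ccf)
  if (any(ok)) {
    best <- max(prof$ccf[ok])
    cand <- which(ok & prof$ccf >= best - 1e-12)
    pk <- cand[which.min(abs(offs[cand]))]  # ties: smallest |offset|
    attr(prof, "peak_value") <- prof$ccf[pk]
    attr(prof, "peak_offset") <- offs[pk]
  } else {
    attr(prof, "peak_value") <- NA_real_
    attr(prof, "peak_offset") <- NA_integer_
  }
  attr(prof, "n_pairs") <- n_pairs
  prof
}

#' Cross-correlation profiles for every filopodium
#'
#' @param paired tibble from [pair_series()].
#' @param max_offset largest offset, frames.
#' @return tibble with `df_id`, `offset`, `ccf`, `n_overlap`, `sig_bound`.
#' @export
compute_ccf <- function(paired, max_offset) {
  paired |>
    dplyr::group_split(.data$df_id) |>
    purrr::map(function(g) {
      p <- ccf_profile(g$ftip, g$dctm, max_offset)
      dplyr::mutate(p, df_id = g$df_id[1], .before = 1)
    }) |>
    dplyr::bind_rows()
}

#' Peak summary of cross-correlation profiles
#'
#' One row per filopodium: peak CCF value, its offset (ties resolved to the
#' smallest |offset|), the number of paired timepoints, and whether the
#' peak clears the `2/sqrt(n - |offset|)` significance bound.
#'
#' @param profiles tibble from [compute_ccf()].
#' @return tibble with `df_id`, `n_pairs`, `peak_value`, `peak_offset`,
#'   `sig_bound`, `significant`.
#' @export
ccf_peaks <- function(profiles) {
  profiles |>
    dplyr::group_by(.data$df_id) |>
    dplyr::summarise(
      n_pairs = max(.data$n_overlap + abs(.data$offset)),
      peak_value = max(.data$ccf, na.rm = TRUE),
      peak_offset = {
        ok <- is.finite(.data$ccf)
        cand <- which(ok & .data$ccf >= max(.data$ccf[ok]) - 1e-12)
        .data$offset[cand[which.min(abs(.data$offset[cand]))]]
      },
      .groups = "drop") |>
    dplyr::mutate(
      sig_bound = 2 / sqrt(.data$n_pairs - abs(.data$peak_offset)),
      significant = .data$peak_value > .data$sig_bound)
}

#' Identify the top-correlating subcluster (TCS)
#'
#' Agglomerative hierarchical clustering (Euclidean distance, Ward
#' linkage) of the per-filopodium CCF-versus-offset vectors; the tree is
#' cut into the number of clusters (2-4) maximizing the mean silhouette
#' width, and the cluster with the highest mean peak CCF is labeled the
#' top-correlating subcluster. If all profiles are identical a single
#' cluster containing every filopodium is returned with a warning.
#'
#' @param profiles tibble from [compute_ccf()]; every filopodium must have
#'   a finite CCF at every offset.
#' @param k_range candidate cluster counts.
#' @return [ccf_peaks()] tibble with added `cluster` and `tcs` columns.
#' @export
cluster_tcs <- function(profiles, k_range = 2:4) {
  wide <- profiles |>
    dplyr::select(dplyr::all_of(c("df_id", "offset", "ccf"))) |>
    tidyr::pivot_wider(names_from = "offset", values_from = "ccf")
  if (nrow(wide) < 2) stop("need >= 2 profiles to cluster", call. = FALSE)
  m <- as.matrix(wide[-1])
  if (anyNA(m))
    stop("profiles contain undefined CCF values; cannot cluster",
         call. = FALSE)
  peaks <- ccf_peaks(profiles)
  res <- tcs_from_matrix(m, peaks$peak_value[match(wide$df_id,
                                                   peaks$df_id)],
                         k_range)
  labels <- tibble::tibble(df_id = wide$df_id, cluster = res$cluster,
                           tcs = res$tcs)
  dplyr::left_join(peaks, labels, by = "df_id")
}

# clustering core shared with the bootstrap fast path: rows of `m` are CCF
# profile vectors; returns cluster ids, TCS membership, TCS mean peak
tcs_from_matrix <- function(m, peak_values, k_range = 2:4) {
  d <- stats::dist(m)
  if (max(d) < 1e-12) {
    warning("all CCF profiles identical: single cluster, all TCS")
    return(list(cluster = rep(1L, nrow(m)), tcs = rep(TRUE, nrow(m)),
                mean_peak = mean(peak_values)))
  }
  if (nrow(m) == 2L) {
    cl <- 1:2  # two discordant profiles: one per cluster
  } else {
    hc <- stats::hclust(d, method = "ward.D2")
    k_range <- k_range[k_range < nrow(m) & k_range >= 2]
    if (length(k_range) == 0) k_range <- 2L
    sil <- vapply(k_range, function(k) {
      cl <- stats::cutree(hc, k)
      if (length(unique(cl)) < 2) return(-Inf)
      mean(cluster::silhouette(cl, d)[, 3])
    }, numeric(1))
    cl <- stats::cutree(hc, k_range[which.max(sil)])
  }
  mp <- vapply(split(peak_values, cl), mean, numeric(1))
  tcs_cl <- as.integer(names(mp)[which.max(mp)])
  list(cluster = as.integer(cl), tcs = cl == tcs_cl,
       mean_peak = unname(mp[as.character(tcs_cl)]))
}

#' Block-randomize a motility series against fluorescence
#'
#' Partitions the series into consecutive blocks of `block_len` valid
#' timepoints (final partial block kept intact) and permutes the block
#' order uniformly at random, preserving the value multiset and short-range
#' autocorrelation within blocks. Invalid (`NA`) positions stay in place;
#' only valid values move. The paired fluorescence series is untouched.
#'
#' @param x numeric series (the DCTM side of a pair).
#' @param block_len block length, frames (>= 2).
#' @return series of the same length with valid values block-permuted.
#' @export
block_randomize <- function(x, block_len) {
  stopifnot(block_len >= 2)
  idx <- which(is.finite(x))
  nv <- length(idx)
  if (nv < 2 * block_len)
    stop("series too short for block randomization (need >= 2 blocks)",
         call. = FALSE)
  blocks <- split(x[idx], ceiling(seq_len(nv) / block_len))
  out <- x
  out[idx] <- unlist(blocks[sample(length(blocks))], use.names = FALSE)
  out
}

#' Block-bootstrap significance of the TCS coupling
#'
#' Runs the observed pipeline once (CCF profiles, TCS by hierarchical
#' clustering, mean peak CCF of the TCS), then repeats it on
#' `n_randomizations` randomized datasets in which each filopodium's raw
#' motility series is block-shuffled against its fluorescence series and
#' the identical analysis (three-point smoothing, CCF, TCS selection) is
#' re-applied. Shuffling the raw rather than the smoothed series keeps
#' observed and randomized datasets exchangeable under independence. The
#' bootstrap p-value is the fraction of randomized TCS mean peaks greater
#' than or equal to the observed one, floored at `1/n_randomizations` so a
#' p of exactly zero is never reported.
#'
#' Two randomized-TCS policies are available: `"recluster"` (default)
#' applies the identical clustering analysis to every randomized dataset,
#' so observed and null statistics are exchangeable under independence;
#' `"fixed_k"` instead constrains the randomized TCS to the observed TCS
#' cardinality, taking the top-k filopodia by peak CCF (a deliberately
#' conservative variant).
#'
#' @param paired tibble from [pair_series()].
#' @param max_offset largest CCF offset, frames.
#' @param block_len shuffle block length, frames (default 8).
#' @param n_randomizations number of randomized datasets (default 1000).
#' @param seed integer seed; identical seeds give identical reports.
#' @param method `"recluster"` or `"fixed_k"`.
#' @return object of class `tcs_bootstrap`: a list with
#'   `observed_tcs_mean_peak`, `null_peaks`, `p_value`, `labels` (observed
#'   [cluster_tcs()] table), `seed`, `block_len`, `n_randomizations`,
#'   `method`, `max_offset`.
#' @export
bootstrap_tcs <- function(paired, max_offset, block_len = 8L,
                          n_randomizations = 1000L, seed = 1L,
                          method = c("recluster", "fixed_k")) {
  method <- match.arg(method)
  ids <- sort(unique(paired$df_id))
  if (length(ids) < 2)
    stop("need >= 2 filopodia for the TCS bootstrap", call. = FALSE)
  paired <- dplyr::arrange(paired, .data$df_id, .data$frame)
  labels <- cluster_tcs(compute_ccf(paired, max_offset))
  obs <- mean(labels$peak_value[labels$tcs])
  k_obs <- sum(labels$tcs)

  if (!"dctm_raw" %in% names(paired))
    stop("`paired` must carry the unsmoothed `dctm_raw` column ",
         "(see pair_series())", call. = FALSE)
  offs <- (-max_offset):max_offset
  ftip_l <- split(paired$ftip, paired$df_id)[ids]
  draw_l <- split(paired$dctm_raw, paired$df_id)[ids]
  set.seed(seed)
  null_peaks <- vapply(seq_len(n_randomizations), function(r) {
    m <- t(vapply(seq_along(ids), function(i) {
      d_rnd <- moving_average3(block_randomize(draw_l[[i]], block_len))
      vapply(offs, function(tau) lagged_cor(ftip_l[[i]], d_rnd, tau)[1],
             numeric(1))
    }, numeric(length(offs))))
    if (anyNA(m))
      stop("randomized CCF profile undefined; series degenerate",
           call. = FALSE)
    pk <- apply(m, 1, max)
    if (method == "recluster")
      suppressWarnings(tcs_from_matrix(m, pk))$mean_peak
    else
      mean(sort(pk, decreasing = TRUE)[seq_len(min(k_obs, length(pk)))])
  }, numeric(1))

  p <- max(sum(null_peaks >= obs), 1L) / n_randomizations
  structure(list(observed_tcs_mean_peak = obs, null_peaks = null_peaks,
                 p_value = p, labels = labels, seed = seed,
                 block_len = as.integer(block_len),
                 n_randomizations = as.integer(n_randomizations),
                 method = method, max_offset = as.integer(max_offset)),
            class = "tcs_bootstrap")
}

#' @export
print.tcs_bootstrap <- function(x, ...) {
  cat(sprintf(
    "<tcs_bootstrap> observed TCS mean peak %.3f; %d/%d null >= observed (p = %.4g); block %d, method %s\n",
    x$observed_tcs_mean_peak, sum(x$null_peaks >= x$observed_tcs_mean_peak),
    x$n_randomizations, x$p_value, x$block_len, x$method))
  invisible(x)
}

#' Per-filopodium z-scores of a series
#'
#' Subtracts the filopodium mean and divides by its standard deviation
#' (valid frames only), removing expression-level differences before
#' pooled scatter analyses.
#'
#' @param x numeric series (may contain `NA`).
#' @return z-scored series.
#' @export
z_score <- function(x) {
  v <- is.finite(x)
  (x - mean(x[v])) / stats::sd(x[v])
}
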