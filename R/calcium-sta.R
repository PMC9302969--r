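# Spike-triggered averaging of dendritic calcium line scans, alpha-function
# amplitude extraction, and the distance profile of backpropagating-spike
# evoked transients.

#' Line-scan recording container
#'
#' A fractional-fluorescence trace recorded at a single dendritic site,
#' with the somatic spike times of the same cell.
#'
#' @param dff Fluorescence trace, percent dF/F0.
#' @param sample_rate Samples per second.
#' @param distance_um Radial distance of the scan site from the soma, um.
#' @param spike_times Somatic action-potential times, s (within the trace).
#' @param cell_id Cell label.
#' @return A `linescan_recording` object.
#' @export
linescan_recording <- function(dff, sample_rate, distance_um, spike_times,
                               cell_id = NA_character_) {
  if (distance_um < 0) stop("distance_um must be >= 0")
  span <- (length(dff) - 1) / sample_rate
  if (any(spike_times < 0 | spike_times > span))
    stop("spike_times must lie within the trace")
  structure(list(dff = dff, sample_rate = sample_rate,
                 distance_um = distance_um, spike_times = sort(spike_times),
                 cell_id = cell_id),
            class = "linescan_recording")
}

#' Spike-triggered average of a calcium trace
#'
#' Averages dF/F0 segments aligned to somatic spikes, subtracting the mean
#' of the pre-spike window per segment as baseline. Spikes whose window
#' (or whose post-window up to the next spike, when
#' `truncate_overlaps = TRUE`) is incomplete are dropped and counted.
#'
#' @param rec A [linescan_recording].
#' @param window Numeric `c(pre_s, post_s)`: seconds before and after the
#'   spike (pre is given as a positive number).
#' @param min_spikes Minimum usable spikes (default 10).
#' @param truncate_overlaps Drop the overlapping tail of a segment when the
#'   next spike falls inside the post window (the truncated samples are
#'   averaged over fewer segments).
#' @return A list of class `calcium_sta`: `sta` (trace), `time_s` (relative
#'   to the spike), `n_spikes` (used), `n_dropped`, `distance_um`,
#'   `cell_id`.
#' @export
spike_triggered_average <- function(rec, window = c(0.2, 0.5),
                                    min_spikes = 10,
                                    truncate_overlaps = TRUE) {
  stopifnot(inherits(rec, "linescan_recording"))
  sr <- rec$sample_rate
  n_pre <- round(window[1] * sr)
  n_post <- round(window[2] * sr)
  len <- n_pre + n_post + 1
  n <- length(rec$dff)
  idx0 <- round(rec$spike_times * sr) + 1

  acc <- numeric(len)
  cnt <- numeric(len)
  used <- 0; dropped <- 0
  for (k in seq_along(idx0)) {
    i0 <- idx0[k]
    if (i0 - n_pre < 1 || i0 + n_post > n) { dropped <- dropped + 1; next }
    seg <- rec$dff[(i0 - n_pre):(i0 + n_post)]
    base <- mean(seg[seq_len(n_pre)])
    keep <- rep(TRUE, len)
    if (truncate_overlaps && k < length(idx0)) {
      gap <- idx0[k + 1] - i0          # samples to the next spike
      if (gap <= n_post) keep[(n_pre + 1 + gap):len] <- FALSE
    }
    acc[keep] <- acc[keep] + seg[keep] - base
    cnt[keep] <- cnt[keep] + 1
    used <- used + 1
  }
  if (used < min_spikes)
    stop(sprintf("insufficient data: %d usable spikes (< %d)", used, min_spikes))
  sta <- acc / pmax(cnt, 1)
  structure(list(sta = sta, time_s = (seq_len(len) - 1 - n_pre) / sr,
                 n_spikes = used, n_dropped = dropped,
                 distance_um = rec$distance_um, cell_id = rec$cell_id),
            class = "calcium_sta")
}

#' Alpha-function amplitude of an STA transient
#'
#' Fits the alpha kernel to the post-spike portion of a spike-triggered
#' average and reports the peak of the fitted curve (less biased by noise
#' than the raw maximum) as the transient amplitude.
#'
#' @param sta A `calcium_sta` object (from [spike_triggered_average]).
#' @param n_starts,seed Multi-start controls for the kernel fit.
#' @return A list of class `sta_point`: `distance_um`, `amplitude`
#'   (fitted-peak percent dF/F0), `fit` (list `A`, `tau_r`, `tau_d` in ms),
#'   `n_spikes`, `flagged` (TRUE when the fit failed; amplitude `NA`).
#' @export
sta_amplitude <- function(sta, n_starts = 8, seed = 1) {
  stopifnot(inherits(sta, "calcium_sta"))
  post <- sta$sta[sta$time_s >= 0]
  dt_ms <- 1000 * diff(sta$time_s[1:2])
  kin <- tryCatch(fit_chr2_kinetics(post, dt_ms, n_starts, seed),
                  error = function(e) NULL)
  if (is.null(kin)) {
    return(structure(list(distance_um = sta$distance_um,
                          amplitude = NA_real_, fit = NULL,
                          n_spikes = sta$n_spikes, cell_id = sta$cell_id,
                          flagged = TRUE),
                     class = "sta_point"))
  }
  structure(list(distance_um = sta$distance_um,
                 amplitude = kin$gain,
                 fit = list(A = attr(kin, "A"), tau_r = kin$tau_r,
                            tau_d = kin$tau_d),
                 n_spikes = sta$n_spikes, cell_id = sta$cell_id,
                 flagged = FALSE),
            class = "sta_point")
}

sta_points_df <- function(points) {
  if (is.data.frame(points)) return(points)
  do.call(rbind, lapply(points, function(p)
    data.frame(distance_um = p$distance_um, amplitude = p$amplitude,
               n_spikes = if (is.null(p$n_spikes)) NA_integer_ else p$n_spikes,
               cell_id = if (is.null(p$cell_id)) NA_character_ else p$cell_id,
               flagged = isTRUE(p$flagged))))
}

#' Moving-average distance profile of transient amplitudes
#'
#' Centered moving average (default 35 um window) of STA amplitude versus
#' distance from the soma, evaluated at the data points themselves. Edge
#' windows shrink to the available data rather than padding.
#'
#' @param points A list of `sta_point` objects or a data.frame with
#'   columns `distance_um`, `amplitude` (flagged/NA points are dropped).
#' @param window_um Moving-average window, um.
#' @return A list of class `distance_profile`: `distance_um`, `smoothed`
#'   (both sorted by distance), `window_um`, `n_points`.
#' @export
distance_profile <- function(points, window_um = 35) {
  d <- sta_points_df(points)
  d <- d[!is.na(d$amplitude) & !d$flagged, ]
  if (nrow(d) < 5) stop("insufficient data: need >= 5 usable points")
  if (diff(range(d$distance_um)) < 2 * window_um)
    stop("insufficient data: points must span at least two windows")
  d <- d[order(d$distance_um), ]
  sm <- vapply(d$distance_um, function(x) {
    mean(d$amplitude[abs(d$distance_um - x) <= window_um / 2])
  }, numeric(1))
  structure(list(distance_um = d$distance_um, smoothed = sm,
                 window_um = window_um, n_points = nrow(d)),
            class = "distance_profile")
}

#' Breakpoint of a distance profile
#'
#' Operationalizes the visually read "knee" of the amplitude-distance
#' profile: the first distance at which the smoothed profile falls more
#' than `drop_frac` below the plateau median. The plateau is taken as the
#' profile between `plateau_start_um` (beyond the proximal
#' surface-to-volume rise) and the profile maximum region.
#'
#' @param profile A `distance_profile`.
#' @param drop_frac Fractional drop defining the breakpoint (default 0.1).
#' @param plateau_start_um Distances below this are excluded from the
#'   plateau estimate (default 20 um).
#' @return Breakpoint distance in um (`NA` if the profile never drops).
#' @export
profile_breakpoint <- function(profile, drop_frac = 0.1,
                               plateau_start_um = 20) {
  stopifnot(inherits(profile, "distance_profile"))
  x <- profile$distance_um
  y <- profile$smoothed
  # stay half a smoothing window clear of the proximal rise: smoothed
  # values closer than that still average in rising-limb points
  margin <- plateau_start_um + profile$window_um / 2
  upper <- max(x[which.max(y)], margin + profile$window_um)
  plateau <- y[x >= margin & x <= upper]
  if (length(plateau) == 0) plateau <- y[x >= plateau_start_um]
  if (length(plateau) == 0) plateau <- y
  ref <- stats::median(plateau)
  below <- which(x > margin & y < (1 - drop_frac) * ref)
  if (length(below) == 0) return(NA_real_)
  x[below[1]]
}

#' Proximal-distal amplitude comparison
#'
#' Compares transient amplitudes proximal versus distal to a boundary
#' (default 70 um). With cell labels present, per-cell medians are formed
#' on each side and compared pairwise (Wilcoxon signed-rank across cells
#' having both); without labels, a rank-sum test across points.
#'
#' @param points As for [distance_profile]; a `cell_id` column/field
#'   enables the paired per-cell analysis.
#' @param boundary_um Proximal/distal boundary, um.
#' @return List of class `proximal_distal_test`: `median_pct_difference`
#'   (median of `(distal - proximal)/proximal * 100`), `p_value`, `n`
#'   (cells or points per side), `paired`.
#' @export
proximal_distal_test <- function(points, boundary_um = 70) {
  d <- sta_points_df(points)
  d <- d[!is.na(d$amplitude) & !d$flagged, ]
  prox <- d[d$distance_um <= boundary_um, ]
  dist <- d[d$distance_um > boundary_um, ]
  if (nrow(prox) < 3 || nrow(dist) < 3)
    stop("insufficient data: need >= 3 points on each side of the boundary")
  paired <- !all(is.na(d$cell_id))
  if (paired) {
    cells <- intersect(unique(prox$cell_id), unique(dist$cell_id))
    if (length(cells) < 3) {
      paired <- FALSE
    } else {
      pm <- vapply(cells, function(cl)
        stats::median(prox$amplitude[prox$cell_id == cl]), numeric(1))
      dm <- vapply(cells, function(cl)
        stats::median(dist$amplitude[dist$cell_id == cl]), numeric(1))
      pct <- (dm - pm) / pm * 100
      tst <- stats::wilcox.test(dm, pm, paired = TRUE, exact = FALSE)
      return(structure(list(median_pct_difference = stats::median(pct),
                            p_value = tst$p.value, n = length(cells),
                            paired = TRUE),
                       class = "proximal_distal_test"))
    }
  }
  pct <- (stats::median(dist$amplitude) - stats::median(prox$amplitude)) /
    stats::median(prox$amplitude) * 100
  tst <- stats::wilcox.test(dist$amplitude, prox$amplitude, exact = FALSE)
  structure(list(median_pct_difference = pct, p_value = tst$p.value,
                 n = c(proximal = nrow(prox), distal = nrow(dist)),
                 paired = FALSE),
            class = "proximal_distal_test")
}
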