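# Slow-wave and sleep-spindle detection in LFP recordings, and peri-event
# conditional firing rates with percentile confidence bands. All detection
# thresholds are expressed in standard deviations of the analyzed signal,
# making the detectors invariant to amplitude rescaling.

#' LFP recording container
#'
#' @param signal LFP trace, mV.
#' @param sample_rate Samples per second (>= 200 for spindle analysis).
#' @param site_id Site label.
#' @param sleep_stage_mask Optional logical vector (same length): samples
#'   in the analyzed sleep stages. SD baselines and detections are
#'   restricted to masked-in samples.
#' @return An `lfp_recording` object.
#' @export
lfp_recording <- function(signal, sample_rate, site_id = NA_character_,
                          sleep_stage_mask = NULL) {
  if (!is.null(sleep_stage_mask) &&
      length(sleep_stage_mask) != length(signal))
    stop("sleep_stage_mask must match the signal length")
  structure(list(signal = signal, sample_rate = sample_rate,
                 site_id = site_id, sleep_stage_mask = sleep_stage_mask),
            class = "lfp_recording")
}

#' Event set container
#'
#' @param kind `"slow_wave"` or `"spindle"`.
#' @param start_times,peak_times,end_times Event boundaries and peak, s.
#' @param amplitudes Event amplitudes (detector-specific units).
#' @param config The configuration list that produced the events.
#' @return An `event_set` object (data.frame-like list).
#' @export
event_set <- function(kind, start_times, peak_times, end_times, amplitudes,
                      config = list()) {
  if (length(peak_times) > 0 &&
      (any(start_times > peak_times) || any(peak_times > end_times)))
    stop("events must satisfy start <= peak <= end")
  structure(list(kind = kind, start_times = start_times,
                 peak_times = peak_times, end_times = end_times,
                 amplitudes = amplitudes, config = config),
            class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("%s events: n = %d\n", x$kind, length(x$peak_times)))
  invisible(x)
}

#' @export
length.event_set <- function(x) length(x$peak_times)

masked <- function(lfp) {
  if (is.null(lfp$sleep_stage_mask)) rep(TRUE, length(lfp$signal))
  else as.logical(lfp$sleep_stage_mask)
}

bandpass_zero_phase <- function(x, sample_rate, low, high, order = 2) {
  ny <- sample_rate / 2
  bf <- signal::butter(order, c(low, high) / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# analytic-signal envelope via the FFT construction
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Detect slow waves in an LFP recording
#'
#' Standard half-wave pipeline: zero-phase band-pass at `band` (default
#' 0.5-4 Hz); candidate half-waves between consecutive zero crossings of
#' the filtered trace; keep candidates of duration within
#' `duration_range`; discard artifacts whose amplitude exceeds
#' `artifact_sd` standard deviations above the mean candidate amplitude;
#' finally retain the `top_fraction` of the surviving candidates with the
#' highest amplitudes (floor of the count). Both polarities are candidates;
#' amplitude is the absolute filtered extremum.
#'
#' @param lfp An [lfp_recording] of at least 60 s.
#' @param band Band edges, Hz.
#' @param duration_range Half-wave duration bounds, s.
#' @param artifact_sd Artifact rejection threshold (SDs above the mean
#'   amplitude).
#' @param top_fraction Fraction of surviving candidates retained (by
#'   amplitude).
#' @param filter_order Butterworth order of the band-pass (applied
#'   forward-backward).
#' @return An [event_set] of kind `"slow_wave"`.
#' @export
detect_slow_waves <- function(lfp, band = c(0.5, 4),
                              duration_range = c(0.25, 2),
                              artifact_sd = 5, top_fraction = 0.3,
                              filter_order = 2) {
  stopifnot(inherits(lfp, "lfp_recording"))
  sr <- lfp$sample_rate
  if (length(lfp$signal) < 60 * sr) stop("recording must be >= 60 s")
  cfg <- list(band = band, duration_range = duration_range,
              artifact_sd = artifact_sd, top_fraction = top_fraction,
              filter_order = filter_order)
  filt <- bandpass_zero_phase(lfp$signal, sr, band[1], band[2], filter_order)
  m <- masked(lfp)

  s <- sign(filt)
  zc <- which(s[-1] * s[-length(s)] < 0)   # last sample before each crossing
  if (length(zc) < 2) return(event_set("slow_wave", numeric(0), numeric(0),
                                       numeric(0), numeric(0), cfg))
  starts <- zc[-length(zc)] + 1
  ends <- zc[-1]
  dur <- (ends - starts + 1) / sr
  keep <- dur >= duration_range[1] & dur <= duration_range[2]
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0) return(event_set("slow_wave", numeric(0),
                                            numeric(0), numeric(0),
                                            numeric(0), cfg))
  peak_idx <- mapply(function(a, b) {
    seg <- filt[a:b]; a + which.max(abs(seg)) - 1
  }, starts, ends)
  amp <- abs(filt[peak_idx])
  inmask <- m[peak_idx]
  starts <- starts[inmask]; ends <- ends[inmask]
  peak_idx <- peak_idx[inmask]; amp <- amp[inmask]

  ok <- amp <= mean(amp) + artifact_sd * stats::sd(amp)
  starts <- starts[ok]; ends <- ends[ok]; peak_idx <- peak_idx[ok]
  amp <- amp[ok]
  n_keep <- floor(top_fraction * length(amp))
  sel <- order(amp, decreasing = TRUE)[seq_len(n_keep)]
  sel <- sort(sel)
  event_set("slow_wave", (starts[sel] - 1) / sr, (peak_idx[sel] - 1) / sr,
            (ends[sel] - 1) / sr, amp[sel], cfg)
}

#' Detect sleep spindles in an LFP recording
#'
#' Hilbert-envelope pipeline: zero-phase band-pass at `band` (default
#' 10-17 Hz) and envelope extraction; candidate events where the envelope
#' exceeds `detect_sd` SDs above its mean, with boundaries where it falls
#' back to `edge_sd` SDs; keep durations within `duration_range`; reject
#' events whose envelope in the control band (default 20-30 Hz) exceeds
#' `control_sd` SDs above its own mean anywhere inside the event. An
#' optional site screen requires the spindle-band power fraction to exceed
#' `min_band_power` of total power. Event waveforms, when requested, come
#' from a 4-pole 4-25 Hz Butterworth filter.
#'
#' @param lfp An [lfp_recording] (`sample_rate >= 200`).
#' @param band Spindle band, Hz.
#' @param detect_sd,edge_sd Detection and boundary thresholds (SDs above
#'   the envelope mean).
#' @param duration_range Event duration bounds, s.
#' @param control_band,control_sd Control band (Hz) and rejection
#'   threshold.
#' @param min_band_power If non-`NULL`, minimum fraction of total signal
#'   power in the spindle band for the site to be analyzed at all (returns
#'   an empty set otherwise).
#' @return An [event_set] of kind `"spindle"`.
#' @export
detect_spindles <- function(lfp, band = c(10, 17), detect_sd = 3,
                            edge_sd = 0.5, duration_range = c(0.5, 3),
                            control_band = c(20, 30), control_sd = 4.5,
                            min_band_power = NULL) {
  stopifnot(inherits(lfp, "lfp_recording"))
  sr <- lfp$sample_rate
  if (sr < 200) stop("sample_rate must be >= 200 Hz for spindle analysis")
  cfg <- list(band = band, detect_sd = detect_sd, edge_sd = edge_sd,
              duration_range = duration_range, control_band = control_band,
              control_sd = control_sd, min_band_power = min_band_power)
  m <- masked(lfp)
  x <- lfp$signal

  filt <- bandpass_zero_phase(x, sr, band[1], band[2], 2)
  if (!is.null(min_band_power)) {
    frac <- stats::var(filt[m]) / stats::var(x[m])
    if (frac < min_band_power)
      return(event_set("spindle", numeric(0), numeric(0), numeric(0),
                       numeric(0), cfg))
  }
  env <- hilbert_envelope(filt)
  mu <- mean(env[m]); sdv <- stats::sd(env[m])
  hi <- env > mu + detect_sd * sdv
  lo <- env > mu + edge_sd * sdv

  cenv <- hilbert_envelope(bandpass_zero_phase(x, sr, control_band[1],
                                               control_band[2], 2))
  cmu <- mean(cenv[m]); csd <- stats::sd(cenv[m])

  # candidate cores: runs of supra-threshold envelope, then expand to the
  # boundary threshold
  r <- rle(hi)
  ends_all <- cumsum(r$lengths)
  starts_all <- ends_all - r$lengths + 1
  cores <- which(r$values)
  ev_s <- integer(0); ev_e <- integer(0); ev_p <- integer(0)
  ev_a <- numeric(0)
  last_end <- -Inf
  for (ci in cores) {
    a <- starts_all[ci]; b <- ends_all[ci]
    if (a <= last_end) next            # merged into the previous event
    while (a > 1 && lo[a - 1]) a <- a - 1
    while (b < length(lo) && lo[b + 1]) b <- b + 1
    last_end <- b
    if (!m[a + which.max(env[a:b]) - 1]) next
    dur <- (b - a + 1) / sr
    if (dur < duration_range[1] || dur > duration_range[2]) next
    if (any(cenv[a:b] > cmu + control_sd * csd)) next
    p <- a + which.max(env[a:b]) - 1
    ev_s <- c(ev_s, a); ev_e <- c(ev_e, b); ev_p <- c(ev_p, p)
    ev_a <- c(ev_a, env[p])
  }
  event_set("spindle", (ev_s - 1) / sr, (ev_p - 1) / sr, (ev_e - 1) / sr,
            ev_a, cfg)
}

#' Spindle-band waveform for reporting
#'
#' The wide-band (4-pole, 4-25 Hz Butterworth, zero-phase) filtered signal
#' used to display detected spindle waveforms.
#'
#' @param lfp An [lfp_recording].
#' @return Filtered trace, same length as the signal.
#' @export
spindle_waveform <- function(lfp) {
  bandpass_zero_phase(lfp$signal, lfp$sample_rate, 4, 25, 4)
}

#' Peri-event conditional firing rate with a percentile confidence band
#'
#' Peri-trigger spike histogram normalized to spikes/s, with a null band
#' from the flanking windows: bin rates at lags of at least `flank_from_s`
#' on both sides of the trigger are pooled, and the band is their
#' `(alpha/2, 1 - alpha/2)` percentiles (99% band by default). A
#' modulation locked to the trigger shows as central bins leaving the
#' band.
#'
#' The defaults (20 ms bins over a +/-2.5 s window with the null flank at
#' |lag| >= 1 s) give 150 flank bins, enough for the empirical 0.5/99.5
#' percentiles (inverse-ECDF estimator) to hold the per-bin false-exit
#' rate of a stationary train below 2%.
#'
#' @param spike_times Spike times, s.
#' @param triggers Trigger (event peak) times, s (>= 50 required).
#' @param bin_s Bin width, s.
#' @param window Half-width of the analysis window, s (window spans
#'   `-window..window`).
#' @param flank_from_s Smallest |lag| included in the null flank, s.
#' @param alpha Two-sided tail probability of the band (default 0.01).
#' @return A `conditional_rate`: list with `bin_centers`, `rate`,
#'   `ci_low`, `ci_high`, `n_triggers`.
#' @export
conditional_rate <- function(spike_times, triggers, bin_s = 0.02,
                             window = 2.5, flank_from_s = 1, alpha = 0.01) {
  if (length(triggers) == 0) stop("no triggers")
  if (length(triggers) < 50)
    warning("fewer than 50 triggers; the percentile band will be noisy")
  edges <- seq(-window, window, by = bin_s)
  centers <- edges[-1] - bin_s / 2
  counts <- numeric(length(centers))
  # per-trigger binning (pooled); rates are spikes/s averaged over triggers
  for (tr in triggers) {
    rel <- spike_times - tr
    rel <- rel[rel >= -window & rel < window]
    if (length(rel) > 0) {
      ix <- floor((rel + window) / bin_s) + 1
      ix <- ix[ix >= 1 & ix <= length(centers)]
      tab <- tabulate(ix, nbins = length(centers))
      counts <- counts + tab
    }
  }
  rate <- counts / (length(triggers) * bin_s)
  flank <- abs(centers) >= flank_from_s
  qs <- stats::quantile(rate[flank], c(alpha / 2, 1 - alpha / 2),
                        names = FALSE, type = 1)
  structure(list(bin_centers = centers, rate = rate,
                 ci_low = qs[1], ci_high = qs[2],
                 n_triggers = length(triggers)),
            class = "conditional_rate")
}

#' @export
print.conditional_rate <- function(x, ...) {
  cat(sprintf("Conditional rate: %d triggers, %d bins, 99%% band [%.2f, %.2f] spk/s\n",
              x$n_triggers, length(x$bin_centers), x$ci_low, x$ci_high))
  invisible(x)
}
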