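# Sinusoidal sweep protocols and cross-correlation estimation of phase and
# magnitude per frequency. The estimator follows the cross-correlation
# (CCF) recipe used for patch-clamp sweep data: the phase comes from the
# location of the CCF peak (parabolically interpolated), the magnitude
# from its height.

#' Default stimulation frequency grid
#'
#' Twelve frequencies spanning 0.2-20 Hz. The exact published set of sweep
#' frequencies is not specified beyond its range; this grid is the package
#' default and is a configuration choice.
#' @return Numeric vector of frequencies (Hz).
#' @export
default_frequency_grid <- function() {
  c(0.2, 0.4, 0.6, 0.8, 1, 2, 3, 5, 7, 10, 15, 20)
}

#' Build a concatenated sinusoidal sweep protocol
#'
#' For each frequency, picks the smallest allowed duration holding a whole
#' number of cycles (3 or 5 s by default); if none qualifies, the smallest
#' integer number of whole cycles totalling at least the shortest allowed
#' duration. For LED modalities, the command rides on the LED voltage
#' threshold so that the minimum of the sinusoid touches the threshold:
#' `command = threshold + offset + amplitude*sin(2*pi*f*t)` with
#' `offset = amplitude` by default.
#'
#' @param frequencies Frequencies in Hz (strictly increasing after sort).
#' @param amplitude Sinusoid amplitude (mV for voltage clamp; LED command
#'   volts-equivalent units for optogenetic sweeps).
#' @param sample_rate Samples per second.
#' @param modality One of `"voltage_clamp_electrical"`, `"led_proximal"`,
#'   `"led_full_field"`.
#' @param allowed_durations Candidate segment durations, s.
#' @param offset Baseline offset above the LED threshold (LED modalities
#'   only); defaults to `amplitude`.
#' @param led_threshold LED activation threshold (command units).
#' @return A `sweep_protocol` object: list with `segments` (data.frame of
#'   `frequency`, `duration_s`, `amplitude`, `offset`), `sample_rate`,
#'   `modality`, `led_threshold`, and the full `command` trace.
#' @export
build_sweep <- function(frequencies, amplitude = 2,
                        sample_rate = 10000,
                        modality = c("voltage_clamp_electrical",
                                     "led_proximal", "led_full_field"),
                        allowed_durations = c(3, 5),
                        offset = NULL, led_threshold = 40) {
  modality <- match.arg(modality)
  if (length(frequencies) == 0) stop("empty frequency list")
  if (any(frequencies <= 0)) stop("frequencies must be > 0")
  frequencies <- sort(frequencies)
  is_led <- modality != "voltage_clamp_electrical"
  if (is.null(offset)) offset <- if (is_led) amplitude else 0

  dur1 <- function(f) {
    ok <- allowed_durations[abs(allowed_durations * f -
                                  round(allowed_durations * f)) < 1e-9]
    if (length(ok) > 0) return(min(ok))
    ceiling(min(allowed_durations) * f) / f
  }
  durations <- vapply(frequencies, dur1, numeric(1))
  segs <- data.frame(frequency = frequencies, duration_s = durations,
                     amplitude = amplitude, offset = offset)

  cmd <- unlist(lapply(seq_len(nrow(segs)), function(i) {
    n <- round(segs$duration_s[i] * sample_rate)
    t <- (seq_len(n) - 1) / sample_rate
    s <- amplitude * sin(2 * pi * segs$frequency[i] * t)
    if (is_led) led_threshold + offset + s else s
  }))

  structure(list(segments = segs, sample_rate = sample_rate,
                 modality = modality, led_threshold = led_threshold,
                 command = cmd),
            class = "sweep_protocol")
}

#' @export
print.sweep_protocol <- function(x, ...) {
  cat(sprintf("Sweep protocol (%s): %d frequencies, %.1f s total, %g Hz sampling\n",
              x$modality, nrow(x$segments), sum(x$segments$duration_s),
              x$sample_rate))
  invisible(x)
}

#' Bundle a sweep protocol with recorded traces
#'
#' @param protocol A `sweep_protocol`.
#' @param response Response trace (pA), same length as the command.
#' @param command Optional command trace; defaults to the protocol's.
#' @param holding_potential Holding potential, mV.
#' @param cell_id,condition Labels.
#' @return A `sweep_recording` object.
#' @export
sweep_recording <- function(protocol, response, command = protocol$command,
                            holding_potential = NA_real_,
                            cell_id = NA_character_,
                            condition = NA_character_) {
  stopifnot(inherits(protocol, "sweep_protocol"))
  n_exp <- sum(round(protocol$segments$duration_s * protocol$sample_rate))
  if (length(command) != n_exp || length(response) != n_exp)
    stop("command/response length does not match the protocol")
  structure(list(protocol = protocol, command = command, response = response,
                 holding_potential = holding_potential, cell_id = cell_id,
                 condition = condition),
            class = "sweep_recording")
}

circular_ccf <- function(x, y) {
  # c[l] = (1/n) sum_t x[t] * y[t + l], circular; lags 0..n-1
  n <- length(x)
  Re(stats::fft(Conj(stats::fft(x)) * stats::fft(y), inverse = TRUE)) / n^2
}

#' Estimate phase and magnitude for one sweep segment
#'
#' Cross-correlates one whole-cycle sinusoidal command segment with its
#' response. The first cycle is discarded as settling transient, the
#' remainder truncated to whole cycles, and the circular CCF (mean lagged
#' product) computed. The phase comes from the CCF peak location within
#' half a period of zero lag, refined by parabolic interpolation; ties
#' break toward the smaller absolute lag. Sign conventions are chosen so
#' estimates match the forward models directly: for the electrical
#' modality the phase is positive when the clamp current leads the voltage
#' command (matching [somatic_phase]); for LED modalities the phase is the
#' positive delay of the photocurrent behind the LED command, after
#' subtracting the half-cycle antiphase correction for the inward (sign
#' inverted) ChR2 current (matching [optogenetic_model]).
#'
#' Magnitudes: electrical, impedance `|Z| = amplitude^2 / (2*max CCF)` in
#' GOhm (for a mV command and pA response), calibrated so a pure resistor
#' is recovered exactly; LED, response amplitude per unit of LED command
#' modulation.
#'
#' @param command_seg,response_seg Command and response traces for one
#'   frequency segment.
#' @param f Segment frequency, Hz.
#' @param sample_rate Samples per second.
#' @param modality As in [build_sweep].
#' @param discard_cycles Number of initial cycles dropped (default 1).
#' @return List with `phase` (cycles, in (-0.5, 0.5]) and `magnitude`.
#' @export
estimate_transfer_segment <- function(command_seg, response_seg, f,
                                      sample_rate,
                                      modality = "voltage_clamp_electrical",
                                      discard_cycles = 1) {
  period <- sample_rate / f
  n_total <- floor(length(command_seg) / period + 1e-9)
  if (n_total < 1) stop("segment shorter than one cycle")
  # discard the settling transient, but never the last remaining cycle
  # (the lowest frequency holds a single cycle in the standard protocol)
  discard_cycles <- min(discard_cycles, n_total - 1)
  n_keep <- length(command_seg) - round(discard_cycles * period)
  n_cyc <- floor(n_keep / period + 1e-9)
  n <- round(n_cyc * period)
  idx <- seq(length(command_seg) - n + 1, length(command_seg))
  x <- command_seg[idx] - mean(command_seg[idx])
  y <- response_seg[idx] - mean(response_seg[idx])
  if (all(y == 0)) stop("undefined phase: response is identically zero")

  cc <- circular_ccf(x, y)
  half <- floor(period / 2)
  lags <- ifelse(seq_len(n) - 1 <= n / 2, seq_len(n) - 1, seq_len(n) - 1 - n)
  cand <- which(abs(lags) <= half)
  # ties toward smaller |lag|
  best <- cand[order(-cc[cand], abs(lags[cand]))][1]

  # parabolic interpolation around the discrete peak (circular neighbors)
  ip <- function(k) ((k - 1) %% n) + 1
  y0 <- cc[best]; ym <- cc[ip(best - 1)]; yp <- cc[ip(best + 1)]
  denom <- ym - 2 * y0 + yp
  delta <- if (abs(denom) > 0) 0.5 * (ym - yp) / denom else 0
  delta <- max(min(delta, 0.5), -0.5)
  lag_samples <- lags[best] + delta
  peak_val <- y0 - 0.25 * (ym - yp) * delta
  lag_s <- lag_samples / sample_rate

  cmd_amp <- sqrt(2 * mean(x^2))
  if (modality == "voltage_clamp_electrical") {
    phase <- -f * lag_s
    magnitude <- cmd_amp^2 / (2 * peak_val)
  } else {
    phase <- f * lag_s - 0.5
    magnitude <- 2 * peak_val / cmd_amp   # response amplitude per unit command
  }
  phase <- phase - round(phase)                       # wrap to (-0.5, 0.5]
  if (phase <= -0.5) phase <- phase + 1
  list(phase = phase, magnitude = magnitude)
}

#' Transfer curve from one or several sweep recordings
#'
#' Segments each recording per its protocol, runs
#' [estimate_transfer_segment] per frequency, and (for several recordings)
#' aggregates across cells as mean +/- SEM per frequency.
#'
#' @param rec A `sweep_recording` or a list of them (same protocol
#'   frequencies).
#' @param discard_cycles Passed to [estimate_transfer_segment].
#' @return A `transfer_curve`: data.frame with columns `frequency_hz`,
#'   `phase_cycles`, `phase_sem`, `magnitude`, `magnitude_sem`, `n`.
#' @export
sweep_to_transfer_curve <- function(rec, discard_cycles = 1) {
  recs <- if (inherits(rec, "sweep_recording")) list(rec) else rec
  stopifnot(all(vapply(recs, inherits, logical(1), "sweep_recording")))
  per_rec <- lapply(recs, function(r) {
    p <- r$protocol
    ends <- cumsum(round(p$segments$duration_s * p$sample_rate))
    starts <- c(1, utils::head(ends, -1) + 1)
    t(vapply(seq_len(nrow(p$segments)), function(i) {
      est <- estimate_transfer_segment(r$command[starts[i]:ends[i]],
                                       r$response[starts[i]:ends[i]],
                                       p$segments$frequency[i],
                                       p$sample_rate, p$modality,
                                       discard_cycles)
      c(est$phase, est$magnitude)
    }, numeric(2)))
  })
  freqs <- recs[[1]]$protocol$segments$frequency
  ph <- sapply(per_rec, function(m) m[, 1])
  mg <- sapply(per_rec, function(m) m[, 2])
  ph <- matrix(ph, nrow = length(freqs))
  mg <- matrix(mg, nrow = length(freqs))
  n <- ncol(ph)
  sem <- function(m) if (n > 1) apply(m, 1, stats::sd) / sqrt(n) else rep(0, nrow(m))
  out <- data.frame(frequency_hz = freqs,
                    phase_cycles = rowMeans(ph), phase_sem = sem(ph),
                    magnitude = rowMeans(mg), magnitude_sem = sem(mg),
                    n = n)
  class(out) <- c("transfer_curve", "data.frame")
  attr(out, "modality") <- recs[[1]]$protocol$modality
  out
}

#' Construct a transfer curve directly from values
#'
#' Convenience constructor (e.g. for curves computed from a closed-form
#' model) producing the same object as [sweep_to_transfer_curve].
#'
#' @param frequency_hz Frequencies, Hz.
#' @param phase_cycles Phases, cycles.
#' @param magnitude Optional magnitudes (GOhm or pA per unit command).
#' @param phase_sem,magnitude_sem Optional per-frequency SEMs.
#' @param n Number of cells aggregated.
#' @param modality Modality label.
#' @return A `transfer_curve`.
#' @export
transfer_curve <- function(frequency_hz, phase_cycles, magnitude = NA_real_,
                           phase_sem = 0, magnitude_sem = 0, n = 1,
                           modality = "voltage_clamp_electrical") {
  out <- data.frame(frequency_hz = frequency_hz, phase_cycles = phase_cycles,
                    phase_sem = phase_sem, magnitude = magnitude,
                    magnitude_sem = magnitude_sem, n = n)
  class(out) <- c("transfer_curve", "data.frame")
  attr(out, "modality") <- modality
  out
}
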