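# Synthetic-data generators: every input modality of the analysis pipeline
# with known ground truth, as a pure function of (configuration, seed).
# These emulate the study conditions (sweep protocols, illumination
# regimes, line-scan statistics, sleep LFP, evoked-synaptic trial blocks)
# so that each estimation stage can be validated end to end.

#' Synthetic voltage-perturbation sweep recordings
#'
#' Simulates somatic voltage-clamp sweep experiments: the standard
#' concatenated sinusoidal command (2 mV by default) applied to an
#' isopotential quasi-linear membrane, plus additive Gaussian current
#' noise. A settling pre-roll of the first-frequency sinusoid is simulated
#' and discarded so the recording starts near periodic steady state (the
#' lowest frequency holds a single cycle in the standard protocol and has
#' no discardable transient cycle).
#'
#' @param truth A [qlin_params] object (the generating membrane).
#' @param n_cells Number of simulated cells.
#' @param noise_sd Additive current noise SD, pA.
#' @param seed Integer seed; the output is a pure function of
#'   (arguments, seed).
#' @param frequencies Sweep frequencies, Hz.
#' @param amplitude Command amplitude, mV.
#' @param sample_rate Samples per second.
#' @param holding_potential Label stored on the recordings, mV.
#' @param settle_s Settling pre-roll, s.
#' @param param_jitter_sd Optional per-cell lognormal jitter SD applied to
#'   `gamma_R`, `tau_m` and the `mu` terms (0 = identical cells).
#' @return List with `recordings` (list of `sweep_recording`) and `truth`
#'   (generating parameters, noise level, seed).
#' @export
gen_sweep_dataset <- function(truth, n_cells = 1, noise_sd = 0, seed = 1,
                              frequencies = default_frequency_grid(),
                              amplitude = 2, sample_rate = 10000,
                              holding_potential = NA_real_, settle_s = 5,
                              param_jitter_sd = 0) {
  stopifnot(inherits(truth, "qlin_params"))
  set.seed(seed)
  prot <- build_sweep(frequencies, amplitude, sample_rate,
                      "voltage_clamp_electrical")
  f1 <- prot$segments$frequency[1]
  n_pre <- round(settle_s * sample_rate)
  t_pre <- (seq_len(n_pre) - n_pre - 1) / sample_rate
  pre <- amplitude * sin(2 * pi * f1 * t_pre)
  cmd_full <- c(pre, prot$command)
  dt <- 1000 / sample_rate

  recordings <- lapply(seq_len(n_cells), function(i) {
    p <- truth
    if (param_jitter_sd > 0) {
      jit <- exp(stats::rnorm(4, 0, param_jitter_sd))
      p <- qlin_params(mu_n = truth$mu_n * jit[1], mu_h = truth$mu_h * jit[2],
                       tau_n = truth$tau_n, tau_h = truth$tau_h,
                       gamma_R = truth$gamma_R * jit[3],
                       tau_m = truth$tau_m * jit[3],
                       amp_scale = truth$amp_scale)
      p$tau_m <- truth$tau_m * jit[4]
    }
    i_full <- simulate_isopotential_clamp(p, cmd_full, dt)
    resp <- i_full[-seq_len(n_pre)]
    if (noise_sd > 0) resp <- resp + stats::rnorm(length(resp), 0, noise_sd)
    sweep_recording(prot, resp, holding_potential = holding_potential,
                    cell_id = sprintf("cell%02d", i))
  })
  list(recordings = recordings,
       truth = list(params = truth, noise_sd = noise_sd, seed = seed,
                    param_jitter_sd = param_jitter_sd))
}

#' Synthetic optogenetic sweep recordings (proximal and full-field)
#'
#' Simulates the optogenetic interrogation experiment: a sinusoidally
#' modulated LED drives ChR2 photocurrent (inward, thresholded alpha-kernel
#' convolution) uniformly over the illuminated proximal segment of a
#' quasi-linear compartmental cable; the somatic clamp current is recorded.
#' Both illumination extents are generated from one membrane truth.
#'
#' @param truth A [qlin_params] object (dendritic membrane).
#' @param r_prox,r_full Illuminated electrotonic extents.
#' @param kin A [chr2_kinetics] object.
#' @param gains Named numeric `c(proximal = ..., full_field = ...)` LED
#'   drive gains (photocurrent density per unit supra-threshold command).
#' @param noise_sd Additive somatic current noise SD.
#' @param seed Integer seed.
#' @param frequencies Sweep frequencies, Hz.
#' @param amplitude LED modulation amplitude (command units).
#' @param sample_rate Samples per second of the stored sweep.
#' @param disc A [cable_discretization] (simulation mesh/step).
#' @param settle_s Settling pre-roll, s.
#' @return List with `recordings` (named list `proximal`, `full_field` of
#'   `sweep_recording`) and `truth`.
#' @export
gen_optogenetic_dataset <- function(truth, r_prox = 0.58, r_full = 1.06,
                                    kin = chr2_kinetics(2.3, 14, 1),
                                    gains = c(proximal = 1, full_field = 1),
                                    noise_sd = 0, seed = 1,
                                    frequencies = default_frequency_grid(),
                                    amplitude = 0.5, sample_rate = 2000,
                                    disc = cable_discretization(400, 5, 0.25),
                                    settle_s = 5) {
  stopifnot(inherits(truth, "qlin_params"), inherits(kin, "chr2_kinetics"))
  set.seed(seed)
  sim_rate <- 1000 / disc$dt
  if (abs(sim_rate / sample_rate - round(sim_rate / sample_rate)) > 1e-9)
    stop("disc$dt must subdivide the sample interval evenly")
  dec <- round(sim_rate / sample_rate)

  one <- function(r, label, gain) {
    prot <- build_sweep(frequencies, amplitude, sim_rate,
                        if (label == "proximal") "led_proximal"
                        else "led_full_field")
    f1 <- prot$segments$frequency[1]
    n_pre <- round(settle_s * sim_rate)
    t_pre <- (seq_len(n_pre) - n_pre - 1) / sim_rate
    pre <- prot$led_threshold + prot$segments$offset[1] +
      amplitude * sin(2 * pi * f1 * t_pre)
    cmd_full <- c(pre, prot$command)
    drive <- gain * chr2_photocurrent(cmd_full, kin, disc$dt)
    illum <- illumination(r, if (label == "proximal") "proximal"
                          else "full_field")
    resp_full <- simulate_cable_clamp(truth, disc, drive, illum)
    resp <- resp_full[-seq_len(n_pre)]
    # store at the recording sample rate
    keep <- seq(1, length(resp), by = dec)
    prot_rec <- build_sweep(frequencies, amplitude, sample_rate,
                            if (label == "proximal") "led_proximal"
                            else "led_full_field")
    cmd_rec <- prot$command[keep]
    resp <- resp[keep]
    if (noise_sd > 0) resp <- resp + stats::rnorm(length(resp), 0, noise_sd)
    sweep_recording(prot_rec, resp, command = cmd_rec,
                    condition = label)
  }
  recs <- list(proximal = one(r_prox, "proximal", gains[["proximal"]]),
               full_field = one(r_full, "full_field",
                                gains[["full_field"]]))
  list(recordings = recs,
       truth = list(params = truth, r_prox = r_prox, r_full = r_full,
                    kin = kin, gains = gains, noise_sd = noise_sd,
                    seed = seed))
}

#' Synthetic dendritic line-scan dataset
#'
#' Emulates two-photon line scans of spike-evoked calcium transients along
#' a dendrite: somatic spikes from a pacemaker-like (jittered-regular)
#' point process; per-site transient amplitude following a trapezoidal
#' distance profile (linear rise to `rise_end_um` reflecting the
#' surface-to-volume ratio of thick proximal dendrites, plateau to
#' `breakpoint_um`, then linear decay as backpropagation fails); traces as
#' spike-convolved alpha transients plus Gaussian noise.
#'
#' @param n_sites Number of scan sites (distances uniform over
#'   `distance_range_um`, multiple cells round-robin over `n_cells`).
#' @param plateau_amp Plateau transient amplitude, percent dF/F0.
#' @param rise_end_um,breakpoint_um Trapezoid knots, um.
#' @param decay_slope Fractional amplitude loss per um beyond the
#'   breakpoint (trapezoid profile).
#' @param profile `"trapezoid"` (rise, plateau, linear decay),
#'   `"step"` (plateau proximal to the breakpoint, reduced by `step_frac`
#'   beyond it), or `"flat"` (every site at `plateau_amp`; null mode).
#' @param step_frac Fractional reduction of the distal step (step profile).
#' @param n_cells Number of cells the sites are attributed to.
#' @param rate_hz Mean firing rate of the pacemaker.
#' @param isi_cv Coefficient of variation of the inter-spike intervals.
#' @param duration_s Scan duration per site, s.
#' @param sample_rate Line-scan sampling rate, Hz.
#' @param noise_sd Additive noise SD, percent dF/F0.
#' @param tau_r,tau_d Transient kinetics, ms.
#' @param distance_range_um Range of scan distances, um.
#' @param seed Integer seed.
#' @return List with `recordings` (list of [linescan_recording]) and
#'   `truth` (including per-site true amplitudes).
#' @export
gen_calcium_dataset <- function(n_sites = 40, plateau_amp = 20,
                                rise_end_um = 20, breakpoint_um = 70,
                                decay_slope = 0.025,
                                profile = c("trapezoid", "step", "flat"),
                                step_frac = 0.3,
                                n_cells = 7, rate_hz = 5, isi_cv = 0.1,
                                duration_s = 30, sample_rate = 500,
                                noise_sd = 2, tau_r = 20, tau_d = 250,
                                distance_range_um = c(2, 130), seed = 1) {
  profile <- match.arg(profile)
  set.seed(seed)
  dists <- sort(stats::runif(n_sites, distance_range_um[1],
                             distance_range_um[2]))
  cells <- sprintf("cell%02d", rep_len(seq_len(n_cells), n_sites))
  true_amp <- function(d) {
    if (profile == "flat") return(plateau_amp)
    if (profile == "step")
      return(if (d <= breakpoint_um) plateau_amp
             else plateau_amp * (1 - step_frac))
    if (d <= rise_end_um) return(plateau_amp * d / rise_end_um)
    if (d <= breakpoint_um) return(plateau_amp)
    max(plateau_amp * (1 - decay_slope * (d - breakpoint_um)), 0)
  }
  amps <- vapply(dists, true_amp, numeric(1))
  dt_ms <- 1000 / sample_rate
  tker <- seq(0, 6 * tau_d, by = dt_ms)
  ker <- alpha_kernel(tker, 1, tau_r, tau_d)
  ker <- ker / max(ker)                     # unit peak: amplitude = peak dF/F0

  recordings <- lapply(seq_len(n_sites), function(i) {
    # pacemaker: gamma-distributed ISIs with the requested CV
    shp <- 1 / isi_cv^2
    isi <- stats::rgamma(ceiling(duration_s * rate_hz * 2), shape = shp,
                         rate = shp * rate_hz)
    st <- cumsum(isi)
    st <- st[st < duration_s - 6 * tau_d / 1000]
    n <- round(duration_s * sample_rate)
    impulses <- numeric(n)
    impulses[pmin(round(st * sample_rate) + 1, n)] <- 1
    clean <- amps[i] * stats::convolve(c(impulses, numeric(length(ker))),
                                       rev(ker), type = "open")[seq_len(n)]
    dff <- clean + stats::rnorm(n, 0, noise_sd)
    linescan_recording(dff, sample_rate, dists[i], st, cells[i])
  })
  list(recordings = recordings,
       truth = list(distance_um = dists, amplitude = amps, cell_id = cells,
                    plateau_amp = plateau_amp, rise_end_um = rise_end_um,
                    breakpoint_um = breakpoint_um, decay_slope = decay_slope,
                    profile = profile, step_frac = step_frac,
                    tau_r = tau_r, tau_d = tau_d,
                    noise_sd = noise_sd, seed = seed))
}

pink_noise <- function(n, sample_rate, exponent = 1) {
  # spectrally shaped white noise: amplitude ~ f^(-exponent/2)
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1))                 # avoid DC blowup
  f <- pmin(f, n - f + 1)
  shape <- f^(-exponent / 2)
  x <- Re(stats::fft(X * shape, inverse = TRUE) / n)
  (x - mean(x)) / stats::sd(x)
}

#' Synthetic sleep LFP with planted slow waves, spindles and spike trains
#'
#' Pink-noise background LFP with planted half-cosine slow-wave events and
#' Hanning-windowed spindle-band bursts, plus two spike trains: a
#' TAN-like train whose rate is modulated around slow-wave peaks by a
#' biphasic template (a pause flanked by two excitation lobes) and an
#' unmodulated SPN-like train.
#'
#' @param duration_s Recording length, s.
#' @param sample_rate Samples per second.
#' @param n_slow_waves,n_spindles Numbers of planted events (placed at
#'   random, non-overlapping).
#' @param sw_duration_s Slow-wave half-cosine duration, s.
#' @param sw_amp_sd Slow-wave amplitude, in SDs of the 0.5-4 Hz filtered
#'   background.
#' @param spindle_freq_hz,spindle_duration_s Spindle carrier and duration.
#' @param spindle_amp_sd Spindle amplitude in SDs of the 10-17 Hz envelope
#'   of the background.
#' @param tan_rate_hz,spn_rate_hz Baseline firing rates.
#' @param tan_modulation List with `pause_depth` (0-1), `pause_width_s`,
#'   `excitation_gain`, `excitation_offset_s`, `excitation_width_s`; set
#'   `pause_depth = 0, excitation_gain = 1` for an unmodulated TAN.
#' @param noise_exponent Spectral exponent of the background (1 = pink).
#' @param seed Integer seed.
#' @return List with `lfp` ([lfp_recording]), `spikes` (list `tan`,
#'   `spn`), `true_events` (list of [event_set]s `slow_wave`, `spindle`)
#'   and `truth` (the full configuration).
#' @export
gen_lfp_dataset <- function(duration_s = 600, sample_rate = 500,
                            n_slow_waves = 270, n_spindles = 30,
                            sw_duration_s = 0.8, sw_amp_sd = 8,
                            spindle_freq_hz = 13, spindle_duration_s = 1,
                            spindle_amp_sd = 6,
                            tan_rate_hz = 5, spn_rate_hz = 2,
                            tan_modulation = list(pause_depth = 0.9,
                                                  pause_width_s = 0.2,
                                                  excitation_gain = 1.6,
                                                  excitation_offset_s = 0.35,
                                                  excitation_width_s = 0.15),
                            noise_exponent = 1, seed = 1) {
  set.seed(seed)
  n <- round(duration_s * sample_rate)
  bg <- pink_noise(n, sample_rate, noise_exponent)

  sw_sd <- stats::sd(bandpass_zero_phase(bg, sample_rate, 0.5, 4))
  sp_env <- hilbert_envelope(bandpass_zero_phase(bg, sample_rate, 10, 17))
  sp_mu <- mean(sp_env)
  sp_sd <- stats::sd(sp_env)

  # jittered-grid placement: k equal slots over the usable span, one event
  # per slot, jittered within the slot minus a guard band; same-kind events
  # never overlap and the count is exact
  place_events <- function(k, span_s) {
    if (k == 0) return(numeric(0))
    usable <- duration_s - 4
    slot <- usable / k
    if (slot < span_s + 0.3)
      stop("too many events for the requested duration")
    jit <- stats::runif(k, 0, slot - span_s - 0.3)
    2 + (seq_len(k) - 1) * slot + span_s / 2 + 0.15 + jit
  }
  sw_peaks <- place_events(n_slow_waves, sw_duration_s)
  sp_peaks <- place_events(n_spindles, spindle_duration_s)

  # half-cosine slow-wave template with soft (tapered) edges; scaled so its
  # amplitude AFTER the 0.5-4 Hz detection filter equals sw_amp_sd
  # background SDs (the stated SNR refers to the detection band)
  len <- round(sw_duration_s * sample_rate)
  u <- seq(0, pi, length.out = len)
  tpl <- sin(u)
  edge <- round(0.08 * len)
  taper <- 0.5 * (1 - cos(pi * seq_len(edge) / edge))
  tpl[seq_len(edge)] <- tpl[seq_len(edge)] * taper
  tpl[(len - edge + 1):len] <- tpl[(len - edge + 1):len] * rev(taper)
  pad <- numeric(10 * sample_rate)
  tpl_gain <- max(abs(bandpass_zero_phase(c(pad, tpl, pad), sample_rate,
                                          0.5, 4)))
  sw_scale <- sw_amp_sd * sw_sd / tpl_gain

  x <- bg
  for (t0 in sw_peaks) {
    i0 <- round((t0 - sw_duration_s / 2) * sample_rate) + 1
    x[i0:(i0 + len - 1)] <- x[i0:(i0 + len - 1)] + sw_scale * tpl
  }
  for (t0 in sp_peaks) {
    i0 <- round((t0 - spindle_duration_s / 2) * sample_rate) + 1
    len2 <- round(spindle_duration_s * sample_rate)
    tt <- seq_len(len2) / sample_rate
    # Tukey window (25% tapers): waxing-waning edges around a plateau at
    # the nominal amplitude
    u <- (seq_len(len2) - 1) / (len2 - 1)
    a <- 0.25
    win <- rep(1, len2)
    lo <- u < a / 2
    hi <- u > 1 - a / 2
    win[lo] <- 0.5 * (1 + cos(pi * (2 * u[lo] / a - 1)))
    win[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - u[hi]) / a - 1)))
    # burst envelope peaks spindle_amp_sd background-envelope SDs above the
    # background-envelope mean (thresholds are mean-referenced)
    x[i0:(i0 + len2 - 1)] <- x[i0:(i0 + len2 - 1)] +
      (sp_mu + spindle_amp_sd * sp_sd) * win *
        sin(2 * pi * spindle_freq_hz * tt)
  }

  tan_rate_fun <- function(t) {
    r <- rep(1, length(t))
    tm <- tan_modulation
    for (t0 in sw_peaks) {
      d <- t - t0
      r <- r * (1 - tm$pause_depth * exp(-d^2 / (2 * tm$pause_width_s^2)))
      r <- r + (tm$excitation_gain - 1) *
        (exp(-(d - tm$excitation_offset_s)^2 / (2 * tm$excitation_width_s^2)) +
         exp(-(d + tm$excitation_offset_s)^2 / (2 * tm$excitation_width_s^2)))
    }
    pmax(r, 0) * tan_rate_hz
  }
  # inhomogeneous Poisson by thinning
  rmax <- tan_rate_hz * (1 + 2 * max(0, tan_modulation$excitation_gain - 1) + 1)
  cand <- cumsum(stats::rexp(ceiling(duration_s * rmax * 1.5), rmax))
  cand <- cand[cand < duration_s]
  tan_spikes <- cand[stats::runif(length(cand)) < tan_rate_fun(cand) / rmax]
  spn_spikes <- cumsum(stats::rexp(ceiling(duration_s * spn_rate_hz * 1.5),
                                   spn_rate_hz))
  spn_spikes <- spn_spikes[spn_spikes < duration_s]

  cfg <- list(duration_s = duration_s, sample_rate = sample_rate,
              sw_duration_s = sw_duration_s, sw_amp_sd = sw_amp_sd,
              spindle_freq_hz = spindle_freq_hz,
              spindle_duration_s = spindle_duration_s,
              spindle_amp_sd = spindle_amp_sd, tan_rate_hz = tan_rate_hz,
              spn_rate_hz = spn_rate_hz, tan_modulation = tan_modulation,
              noise_exponent = noise_exponent, seed = seed)
  list(lfp = lfp_recording(x, sample_rate, site_id = "synthetic"),
       spikes = list(tan = tan_spikes, spn = spn_spikes),
       true_events = list(
         slow_wave = event_set("slow_wave", sw_peaks - sw_duration_s / 2,
                               sw_peaks, sw_peaks + sw_duration_s / 2,
                               rep(sw_amp_sd * sw_sd, length(sw_peaks)), cfg),
         spindle = event_set("spindle", sp_peaks - spindle_duration_s / 2,
                             sp_peaks, sp_peaks + spindle_duration_s / 2,
                             rep(spindle_amp_sd * sp_sd, length(sp_peaks)),
                             cfg)),
       truth = cfg)
}

#' Synthetic evoked-synaptic trial blocks
#'
#' Alpha-shaped EPSP (or EPSC) responses in paired-pulse trial blocks with
#' a known paired-pulse ratio, per-cell amplitude variability, and a
#' multiplicative drug-effect factor applied to the post-condition blocks.
#'
#' @param amp Mean first-pulse amplitude (mV for EPSP, pA magnitude for
#'   EPSC).
#' @param ppr True paired-pulse ratio (second/first).
#' @param drug_factor Multiplicative factor on post-drug amplitudes
#'   (e.g. 0.84 for a 16% reduction).
#' @param n_trials Trials per block.
#' @param n_cells Number of cells (pre/post pairs).
#' @param noise_sd Additive trace noise SD.
#' @param cell_cv Lognormal between-cell amplitude CV.
#' @param mode `"EPSP"` or `"EPSC"`.
#' @param paired If `TRUE`, two pulses 100 ms apart; else a single pulse.
#' @param tau_r,tau_d Response kinetics, ms.
#' @param sample_rate,trial_s Trace sampling and duration.
#' @param resting_mV Baseline potential for EPSP traces (EPSC baseline is
#'   0 pA).
#' @param spike_fraction Fraction of trials contaminated with a spike
#'   (a brief +80 mV deflection; EPSP mode only).
#' @param seed Integer seed.
#' @return List with `pre` and `post` (lists of [trial_block]) and `truth`.
#' @export
gen_epsp_dataset <- function(amp = 1.5, ppr = 0.7, drug_factor = 1,
                             n_trials = 25, n_cells = 11, noise_sd = 0.3,
                             cell_cv = 0.2, mode = "EPSP", paired = FALSE,
                             tau_r = 3, tau_d = 15, sample_rate = 10000,
                             trial_s = 0.4, resting_mV = -60,
                             spike_fraction = 0, seed = 1) {
  set.seed(seed)
  stim <- if (paired) c(0.05, 0.15) else 0.1
  n <- round(trial_s * sample_rate)
  tms <- (seq_len(n) - 1) / sample_rate * 1000    # ms
  shape <- function(t0_ms, a) {
    k <- alpha_kernel(pmax(tms - t0_ms, 0), 1, tau_r, tau_d)
    a * k / max(k)
  }
  sgn <- if (mode == "EPSC") -1 else 1
  base <- if (mode == "EPSP") resting_mV else 0
  cell_amp <- amp * exp(stats::rnorm(n_cells, 0, cell_cv))

  make_block <- function(a1, condition, cell) {
    tr <- t(vapply(seq_len(n_trials), function(i) {
      y <- shape(stim[1] * 1000, a1)
      if (paired) y <- y + shape(stim[2] * 1000, a1 * ppr)
      y <- base + sgn * y + stats::rnorm(n, 0, noise_sd)
      if (mode == "EPSP" && spike_fraction > 0 &&
          stats::runif(1) < spike_fraction) {
        i_sp <- round((stim[1] + 0.01) * sample_rate)
        y[i_sp:(i_sp + 20)] <- y[i_sp:(i_sp + 20)] + 80
      }
      y
    }, numeric(n)))
    trial_block(tr, sample_rate, stim, mode = mode,
                cell_id = cell, condition = condition)
  }
  pre <- lapply(seq_len(n_cells), function(i)
    make_block(cell_amp[i], "pre", sprintf("cell%02d", i)))
  post <- lapply(seq_len(n_cells), function(i)
    make_block(cell_amp[i] * drug_factor, "post", sprintf("cell%02d", i)))
  list(pre = pre, post = post,
       truth = list(amp = amp, ppr = ppr, drug_factor = drug_factor,
                    cell_amp = cell_amp, noise_sd = noise_sd, mode = mode,
                    paired = paired, seed = seed))
}
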