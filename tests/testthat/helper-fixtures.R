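# Shared fixtures and small utilities for the test suite.

# published somatic parameter set with subhertz resonance (-70 mV holding)
resonant_params <- function() cin_presets()[["soma_m70"]]$params
# published amplifying-only somatic set (-55 mV holding)
amplifying_params <- function() cin_presets()[["soma_m55"]]$params

passive_params <- function(tau_m = 26.1, amp_scale = 1) {
  qlin_params(mu_n = 0, mu_h = 0, tau_n = 1, tau_h = 1, gamma_R = 1,
              tau_m = tau_m, amp_scale = amp_scale)
}

test_kin <- function() chr2_kinetics(tau_r = 2.3, tau_d = 14, gain = 1)

# peak-time matching of detected vs planted events
peak_match <- function(det, truth, tol = 0.2) {
  c(recall = sum(vapply(truth, function(t0) any(abs(det - t0) < tol),
                        logical(1))) / length(truth),
    precision = sum(vapply(det, function(t0) any(abs(truth - t0) < tol),
                           logical(1))) / length(det))
}

# interval-overlap matching (plateau events have arbitrary peak position)
overlap_match <- function(det_s, det_e, tru_s, tru_e) {
  hit_t <- vapply(seq_along(tru_s), function(i)
    any(det_s < tru_e[i] & det_e > tru_s[i]), logical(1))
  hit_d <- vapply(seq_along(det_s), function(i)
    any(tru_s < det_e[i] & tru_e > det_s[i]), logical(1))
  c(recall = mean(hit_t), precision = mean(hit_d))
}

# steady-state cable phase by direct simulation of one frequency
simulated_cable_phase <- function(params, illum, f, disc,
                                  discard_s = max(1.5, 1 / f),
                                  n_cycles = 2) {
  sr <- 1000 / disc$dt
  t <- seq(0, discard_s + n_cycles / f, by = 1 / sr)
  drive <- sin(2 * pi * f * t)
  out <- simulate_cable_clamp(params, disc, drive, illum)
  # response phase is minus the delay
  -fit_sinusoid(out, f, sr, discard_s = discard_s)$phase
}

rel_err <- function(a, b) abs(a / b - 1)
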