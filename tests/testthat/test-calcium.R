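# Spike-triggered calcium analysis: STA construction, alpha-amplitude
# extraction, distance profile, proximal/distal comparison.

make_clean_recording <- function(amp = 10, n_spikes = 20, sr = 500,
                                 tau_r = 20, tau_d = 250, dist = 50,
                                 noise_sd = 0, seed = 1, cell = "c1") {
  set.seed(seed)
  isi <- 2.5
  st <- (seq_len(n_spikes)) * isi
  dur <- max(st) + 2
  n <- round(dur * sr)
  imp <- numeric(n)
  imp[round(st * sr) + 1] <- 1
  tk <- seq(0, 6 * tau_d, by = 1000 / sr)
  ker <- alpha_kernel(tk, 1, tau_r, tau_d)
  ker <- ker / max(ker)
  dff <- amp * stats::convolve(c(imp, numeric(length(ker))), rev(ker),
                               type = "open")[seq_len(n)]
  if (noise_sd > 0) dff <- dff + rnorm(n, 0, noise_sd)
  linescan_recording(dff, sr, dist, st, cell)
}

test_that("STA of identical noiseless transients reproduces the transient
           and its fitted amplitude equals the analytic peak", {
  rec <- make_clean_recording(amp = 12)
  sta <- spike_triggered_average(rec, window = c(0.2, 1))
  # tiny residue from the tail of the preceding transient is tolerated
  expect_equal(max(sta$sta), 12, tolerance = 1e-3)
  expect_lt(max(abs(sta$sta[sta$time_s < 0])), 0.02)

  pt <- sta_amplitude(sta)
  expect_false(pt$flagged)
  expect_equal(pt$amplitude, 12, tolerance = 2e-3)
})

test_that("STA amplitude scales linearly with the underlying transient", {
  r1 <- make_clean_recording(amp = 5)
  r2 <- make_clean_recording(amp = 15)
  a1 <- sta_amplitude(spike_triggered_average(r1, c(0.2, 1)))$amplitude
  a2 <- sta_amplitude(spike_triggered_average(r2, c(0.2, 1)))$amplitude
  expect_equal(a2 / a1, 3, tolerance = 1e-6)
})

test_that("pure-noise STA amplitude shrinks as 1/sqrt(n_spikes)", {
  sr <- 500
  sta_rms <- function(n_spikes, seed) {
    set.seed(seed)
    dur <- n_spikes * 1.2 + 2
    n <- round(dur * sr)
    rec <- linescan_recording(rnorm(n), sr, 50,
                              seq_len(n_spikes) * 1.2, "c1")
    sta <- spike_triggered_average(rec, window = c(0.1, 0.4))
    sqrt(mean(sta$sta[sta$time_s >= 0]^2))
  }
  r10 <- mean(vapply(1:8, function(s) sta_rms(10, s), numeric(1)))
  r90 <- mean(vapply(1:8, function(s) sta_rms(90, s), numeric(1)))
  expect_equal(r10 / r90, 3, tolerance = 0.35)
})

test_that("overlapping post-spike windows are truncated and spikes without
           a full window are dropped with counts reported", {
  sr <- 500
  st <- c(0.05, 1, 1.3, 3)     # first spike lacks the 0.2 s pre-window
  n <- round(4.5 * sr)
  rec <- linescan_recording(numeric(n), sr, 20, st, "c1")
  sta <- spike_triggered_average(rec, window = c(0.2, 0.5), min_spikes = 2)
  expect_equal(sta$n_dropped, 1)
  expect_equal(sta$n_spikes, 3)
  expect_error(spike_triggered_average(rec, window = c(0.2, 0.5),
                                       min_spikes = 10),
               "insufficient")
})

test_that("flat traces are flagged by the amplitude fit and excluded from
           profiles", {
  sr <- 500
  rec <- linescan_recording(numeric(10 * sr), sr, 30,
                            seq(0.5, 9, by = 0.5), "c1")
  pt <- sta_amplitude(spike_triggered_average(rec, c(0.2, 0.5)))
  expect_true(pt$flagged)
  expect_true(is.na(pt$amplitude))
})

test_that("distance profile: flat data give a flat profile; the moving
           average recovers the plateau and breakpoint of a trapezoid", {
  flat <- data.frame(distance_um = seq(5, 120, length.out = 20),
                     amplitude = rep(7, 20), flagged = FALSE,
                     cell_id = NA)
  prof <- distance_profile(flat)
  expect_equal(prof$smoothed, rep(7, 20))

  set.seed(61)
  cal <- gen_calcium_dataset(n_sites = 60, noise_sd = 1.5, seed = 6)
  pts <- data.frame(distance_um = cal$truth$distance_um,
                    amplitude = cal$truth$amplitude + rnorm(60, 0, 1.5),
                    flagged = FALSE, cell_id = NA)
  prof <- distance_profile(pts)
  bp <- profile_breakpoint(prof)
  expect_gt(bp, 60)
  expect_lt(bp, 80)

  expect_error(distance_profile(flat[1:3, ]), "insufficient")
})

test_that("end-to-end: analyzed line scans recover the trapezoid breakpoint
           within 10 um of the generating truth", {
  for (s in c(9, 12)) {
    cal <- gen_calcium_dataset(n_sites = 60, duration_s = 30, seed = s)
    pts <- lapply(cal$recordings, function(r)
      sta_amplitude(spike_triggered_average(r, c(0.2, 1))))
    prof <- distance_profile(pts)
    bp <- profile_breakpoint(prof)
    expect_gt(bp, cal$truth$breakpoint_um - 10)
    expect_lt(bp, cal$truth$breakpoint_um + 10)
  }
})

test_that("proximal-distal comparison: null on identical distributions,
           detection of a planted step reduction, error on one-sided data", {
  set.seed(15)
  null_pts <- data.frame(distance_um = runif(30, 5, 130),
                         amplitude = rnorm(30, 10, 1),
                         flagged = FALSE, cell_id = NA)
  res0 <- proximal_distal_test(null_pts)
  expect_gt(res0$p_value, 0.05)
  expect_lt(abs(res0$median_pct_difference), 15)

  detected <- vapply(1:10, function(s) {
    cal <- gen_calcium_dataset(n_sites = 40, profile = "step",
                               step_frac = 0.3, noise_sd = 1,
                               duration_s = 20, seed = 40 + s)
    pts <- data.frame(distance_um = cal$truth$distance_um,
                      amplitude = cal$truth$amplitude *
                        exp(rnorm(40, 0, 0.1)),
                      cell_id = cal$truth$cell_id, flagged = FALSE)
    res <- proximal_distal_test(pts)
    (res$p_value < 0.05) &&
      res$median_pct_difference > -40 && res$median_pct_difference < -20
  }, logical(1))
  expect_gte(mean(detected), 0.8)

  onesided <- null_pts[null_pts$distance_um <= 70, ]
  expect_error(proximal_distal_test(onesided), "insufficient")
})
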