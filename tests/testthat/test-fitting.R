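# Parameter fitting: ChR2 kinetics, somatic and cable models, ANCOVA.

test_that("ChR2 kinetics fit: exact noiseless recovery, 5% recovery under
           averaged-trial noise, failure on a flat trace", {
  tt <- seq(0, 150, by = 0.1)
  pulse <- -alpha_kernel(tt, 30, 2.3, 14)      # inward pulse average
  kin <- fit_chr2_kinetics(pulse, 0.1)
  expect_lt(rel_err(kin$tau_r, 2.3), 1e-3)
  expect_lt(rel_err(kin$tau_d, 14), 1e-3)

  # 5% single-trial noise averaged over 250 trials
  set.seed(11)
  peak <- max(abs(pulse))
  noisy <- pulse + rnorm(length(pulse), 0, 0.05 * peak / sqrt(250))
  kin2 <- fit_chr2_kinetics(noisy, 0.1)
  expect_lt(rel_err(kin2$tau_r, 2.3), 0.05)
  expect_lt(rel_err(kin2$tau_d, 14), 0.05)

  expect_error(fit_chr2_kinetics(rep(1, 500), 0.1), "fit failure")
})

test_that("somatic model round-trip: noiseless curves from the published
           parameter sets are recovered with the scale pinned", {
  f <- default_frequency_grid()
  for (nm in c("soma_m55", "soma_m70", "soma_ttx")) {
    pr <- cin_presets()[[nm]]
    pp <- pr$params
    tc <- transfer_curve(f, somatic_phase(f, pp), somatic_impedance(f, pp))
    fit <- fit_soma_model(tc, pr$scheme, fixed = list(gamma_R = pp$gamma_R))
    est <- fit$params
    expect_lt(rel_err(est$mu_n, pp$mu_n), 0.01)
    expect_lt(rel_err(est$tau_n, pp$tau_n), 0.01)
    expect_lt(rel_err(est$tau_m, pp$tau_m), 0.01)
    expect_lt(rel_err(est$amp_scale, pp$amp_scale), 0.01)
    if (pr$scheme == "amplifying_plus_resonant") {
      expect_lt(rel_err(est$mu_h, pp$mu_h), 0.01)
      expect_lt(rel_err(est$tau_h, pp$tau_h), 0.01)
    }
  }
})

test_that("slow restorative kinetics far above the sampled band leave only
           mu_h/tau_h identifiable (documented degeneracy)", {
  f <- default_frequency_grid()
  pr <- cin_presets()[["soma_zd7288"]]
  pp <- pr$params
  tc <- transfer_curve(f, somatic_phase(f, pp), somatic_impedance(f, pp))
  fit <- fit_soma_model(tc, pr$scheme, fixed = list(gamma_R = pp$gamma_R))
  est <- fit$params
  expect_lt(rel_err(est$mu_n, pp$mu_n), 0.01)
  expect_lt(rel_err(est$tau_n, pp$tau_n), 0.01)
  expect_lt(rel_err(est$tau_m, pp$tau_m), 0.01)
  expect_lt(rel_err(est$mu_h / est$tau_h, pp$mu_h / pp$tau_h), 0.02)
})

test_that("the free somatic fit recovers the model only up to the exact
           scale symmetry: invariant ratios match the truth", {
  f <- default_frequency_grid()
  pp <- amplifying_params()
  tc <- transfer_curve(f, somatic_phase(f, pp), somatic_impedance(f, pp))
  fit <- fit_soma_model(tc, "amplifying_only", lambda = 1)
  est <- fit$params
  expect_lt(rel_err(est$mu_n / est$gamma_R, pp$mu_n / pp$gamma_R), 0.01)
  expect_lt(rel_err(est$tau_m / est$gamma_R, pp$tau_m / pp$gamma_R), 0.01)
  expect_lt(rel_err(est$tau_n, pp$tau_n), 0.01)
  expect_lt(rel_err(est$amp_scale / est$gamma_R,
                    pp$amp_scale / pp$gamma_R), 0.01)
})

test_that("a passive curve fitted with the amplifying scheme returns a
           negligible mu_n", {
  f <- default_frequency_grid()
  pas <- passive_params(tau_m = 30, amp_scale = 1)
  tc <- transfer_curve(f, somatic_phase(f, pas), somatic_impedance(f, pas))
  fit <- fit_soma_model(tc, "amplifying_only", fixed = list(gamma_R = 1))
  expect_lt(abs(fit$params$mu_n), 0.02)
  expect_lt(rel_err(fit$params$tau_m, 30), 0.01)
})

test_that("noisy replicate fits bracket the generating parameters", {
  f <- default_frequency_grid()
  pp <- amplifying_params()
  truth_phase <- somatic_phase(f, pp)
  ests <- t(vapply(1:10, function(i) {
    set.seed(300 + i)
    tc <- transfer_curve(f, truth_phase + rnorm(length(f), 0, 0.004))
    fit <- fit_soma_model(tc, "amplifying_only",
                          fixed = list(gamma_R = pp$gamma_R),
                          n_starts = 12, seed = i)
    c(fit$params$mu_n, fit$params$tau_n, fit$params$tau_m)
  }, numeric(3)))
  truth <- c(pp$mu_n, pp$tau_n, pp$tau_m)
  for (j in 1:3) {
    expect_lt(min(ests[, j]), truth[j] + 0.05 * abs(truth[j]))
    expect_gt(max(ests[, j]), truth[j] - 0.05 * abs(truth[j]))
  }
})

test_that("fit is invariant to frequency-grid permutation", {
  f <- default_frequency_grid()
  pp <- amplifying_params()
  tc1 <- transfer_curve(f, somatic_phase(f, pp))
  set.seed(1)
  perm <- sample(length(f))
  tc2 <- transfer_curve(f[perm], somatic_phase(f[perm], pp))
  f1 <- fit_soma_model(tc1, "amplifying_only",
                       fixed = list(gamma_R = pp$gamma_R))
  f2 <- fit_soma_model(tc2, "amplifying_only",
                       fixed = list(gamma_R = pp$gamma_R))
  expect_equal(f1$params$mu_n, f2$params$mu_n, tolerance = 1e-6)
  expect_equal(f1$params$tau_m, f2$params$tau_m, tolerance = 1e-6)
})

test_that("uniform magnitude rescaling only moves the profiled impedance
           scale", {
  f <- default_frequency_grid()
  pp <- amplifying_params()
  tc1 <- transfer_curve(f, somatic_phase(f, pp), somatic_impedance(f, pp))
  tc2 <- transfer_curve(f, somatic_phase(f, pp),
                        10 * somatic_impedance(f, pp))
  f1 <- fit_soma_model(tc1, "amplifying_only",
                       fixed = list(gamma_R = pp$gamma_R), lambda = 1)
  f2 <- fit_soma_model(tc2, "amplifying_only",
                       fixed = list(gamma_R = pp$gamma_R), lambda = 1)
  expect_equal(f2$params$mu_n, f1$params$mu_n, tolerance = 1e-4)
  expect_equal(f2$params$amp_scale / f1$params$amp_scale, 10,
               tolerance = 1e-6)
})

test_that("passive cable round-trip: illuminated extent and membrane time
           constant recovered from noiseless optogenetic phases", {
  f <- default_frequency_grid()
  kin <- test_kin()
  for (nm in c("dend_passive_proximal", "dend_passive_fullfield")) {
    pr <- cin_presets()[[nm]]
    ph <- optogenetic_model(f, pr$params, illumination(pr$extent_r),
                            kin)$phase
    tc <- transfer_curve(f, ph, modality = "led_proximal")
    fit <- fit_cable_model(tc, kin, "passive")
    expect_lt(rel_err(fit$extent_r, pr$extent_r), 0.02)
    expect_lt(rel_err(fit$params$tau_m, pr$params$tau_m), 0.02)
  }
})

test_that("a doubled illumination extent is recovered as a doubled fit", {
  f <- default_frequency_grid()
  kin <- test_kin()
  pas <- passive_params(tau_m = 30)
  r0 <- 0.5
  fits <- lapply(c(r0, 2 * r0), function(r) {
    ph <- optogenetic_model(f, pas, illumination(r), kin)$phase
    fit_cable_model(transfer_curve(f, ph, modality = "led_proximal"),
                    kin, "passive")
  })
  expect_lt(rel_err(fits[[2]]$extent_r / fits[[1]]$extent_r, 2), 0.1)
})

test_that("quasi-linear cable round-trip recovers the published dendritic
           sets with the scale pinned", {
  f <- default_frequency_grid()
  kin <- test_kin()
  for (nm in c("dend_qlin_proximal", "dend_qlin_fullfield")) {
    pr <- cin_presets()[[nm]]
    ph <- optogenetic_model(f, pr$params, illumination(pr$extent_r),
                            kin)$phase
    tc <- transfer_curve(f, ph, modality = "led_proximal")
    fit <- fit_cable_model(tc, kin, "quasi_linear",
                           fixed = list(gamma_R = pr$params$gamma_R),
                           n_starts = 48)
    expect_lt(rel_err(fit$extent_r, pr$extent_r), 0.05)
    expect_lt(rel_err(fit$params$mu_n, pr$params$mu_n), 0.05)
    expect_lt(rel_err(fit$params$mu_h, pr$params$mu_h), 0.05)
    expect_lt(rel_err(fit$params$tau_h, pr$params$tau_h), 0.05)
    expect_lt(rel_err(fit$params$tau_m, pr$params$tau_m), 0.05)
  }
})

test_that("a passive-scheme fit of resonant dendritic data leaves a
           systematic residual at the lowest frequencies", {
  f <- default_frequency_grid()
  kin <- test_kin()
  pr <- cin_presets()[["dend_qlin_proximal"]]
  ph <- optogenetic_model(f, pr$params, illumination(pr$extent_r),
                          kin)$phase
  tc <- transfer_curve(f, ph, modality = "led_proximal")
  fit <- fit_cable_model(tc, kin, "passive")
  pred <- chr2_transfer(f, fit$kin)$phase +
    cable_phase(f, fit$params, illumination(fit$extent_r))
  resid <- ph - pred
  # the resonant dip at 0.4 Hz cannot be captured: residual there dominates
  expect_gt(abs(resid[f == 0.4]), 2 * stats::median(abs(resid)))
  expect_lt(resid[f == 0.4], 0)
})

test_that("curve ANCOVA: identical groups, strong offsets, and pure slope
           differences behave as designed", {
  f <- rep(c(0.25, 0.5, 1, 2, 4), each = 4)
  y0 <- 0.1 * log(f) + 0.02 * log(f)^2
  ga <- data.frame(f = f, y = y0)
  cmp0 <- compare_curves_ancova(ga, ga)
  expect_gt(cmp0$p_group, 0.99)

  set.seed(21)
  noise <- 0.01
  f10 <- rep(c(0.25, 0.5, 1, 2, 4), each = 10)
  base <- 0.1 * log(f10)
  ga <- data.frame(f = f10, y = base + rnorm(length(f10), 0, noise))
  gb <- data.frame(f = f10, y = base + 5 * noise +
                     rnorm(length(f10), 0, noise))
  cmp1 <- compare_curves_ancova(ga, gb)
  expect_lt(cmp1$p_group, 0.001)

  # slope-only difference on a balanced grid centered on ln f = 0
  gb2 <- data.frame(f = f10, y = base + 0.05 * log(f10) +
                      rnorm(length(f10), 0, noise))
  cmp2 <- compare_curves_ancova(ga, gb2)
  expect_lt(cmp2$p_interaction, 0.001)
  expect_gt(cmp2$p_group, 0.01)

  expect_error(compare_curves_ancova(ga[1:2, ], gb), ">= 3 points")
})
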