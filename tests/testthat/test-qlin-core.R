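# Closed-form quasi-linear models: admittance, somatic phase/impedance,
# propagation constant, cable transfer, ChR2 kinetics, alpha kernel.

test_that("admittance components reduce correctly at DC and match the
           independently computed complex evaluation at 1 Hz", {
  pas <- passive_params()
  c0 <- admittance_components(0, pas)
  expect_equal(c0$alpha, 1)
  expect_equal(c0$beta, 0)

  pp <- resonant_params()
  cdc <- admittance_components(0, pp)
  expect_equal(cdc$alpha, pp$gamma_R + pp$mu_n + pp$mu_h)
  expect_equal(cdc$beta, 0)

  # frozen from two independent complex evaluations (R and a second
  # implementation) of y(1 Hz) for the resonant somatic parameter set
  c1 <- admittance_components(1, pp)
  expect_equal(c1$alpha, 2.5385406889618567, tolerance = 1e-12)
  expect_equal(c1$beta, 0.18018742464555304, tolerance = 1e-12)
})

test_that("passive membrane reduces to alpha = 1, beta = 2*pi*f*tau", {
  pas <- passive_params(tau_m = 26.1)
  f <- c(0.2, 1, 5, 20)
  cc <- admittance_components(f, pas)
  expect_equal(cc$alpha, rep(1, 4), tolerance = 1e-14)
  expect_equal(cc$beta, 2 * pi * f * 0.0261, tolerance = 1e-14)
})

test_that("somatic phase: passive limits, resonant negative lobe, and
           agreement with direct complex arg", {
  pas <- passive_params(tau_m = 26.1)
  expect_equal(somatic_phase(1e8, pas), 0.25, tolerance = 1e-7)
  expect_equal(somatic_phase(1 / (2 * pi * 0.0261), pas), 0.125,
               tolerance = 1e-12)

  pp <- resonant_params()
  expect_lt(somatic_phase(0.2, pp), 0)          # subhertz negative lobe
  expect_equal(somatic_phase(0.2, pp), -0.03473832, tolerance = 1e-6)

  f <- exp(seq(log(0.1), log(20), length.out = 50))
  cc <- admittance_components(f, pp)
  expect_equal(somatic_phase(f, pp), atan2(cc$beta, cc$alpha) / (2 * pi),
               tolerance = 1e-12)
})

test_that("somatic impedance: DC anchor, passive monotonicity, resonance
           peak near 1 Hz for the -70 mV set", {
  pas <- passive_params(tau_m = 26.1, amp_scale = 2)
  expect_equal(somatic_impedance(0, pas), 2)
  f <- seq(0.1, 20, by = 0.1)
  expect_true(all(diff(somatic_impedance(f, pas)) < 0))

  pp <- resonant_params()
  fgrid <- exp(seq(log(0.1), log(20), length.out = 4000))
  fpk <- fgrid[which.max(somatic_impedance(fgrid, pp))]
  expect_gt(fpk, 0.5)
  expect_lt(fpk, 1.5)

  expect_error(somatic_impedance(1, qlin_params(gamma_R = 1, tau_m = 10)),
               "amp_scale")
})

test_that("phase zero crossing sits below the impedance peak", {
  pp <- resonant_params()
  zc <- uniroot(function(f) admittance_components(f, pp)$beta,
                c(0.1, 5))$root
  fgrid <- exp(seq(log(0.1), log(20), length.out = 4000))
  fpk <- fgrid[which.max(somatic_impedance(fgrid, pp))]
  expect_lt(zc, fpk)
  expect_lte(zc, 1)
})

test_that("making mu_n less negative reduces the somatic phase at every
           frequency (amplifying membrane, the TTX situation)", {
  pp <- amplifying_params()
  weaker <- qlin_params(mu_n = pp$mu_n / 2, mu_h = 0,
                        tau_n = pp$tau_n, tau_h = 1,
                        gamma_R = pp$gamma_R, tau_m = pp$tau_m)
  f <- exp(seq(log(0.1), log(20), length.out = 40))
  expect_true(all(somatic_phase(f, weaker) < somatic_phase(f, pp)))
})

test_that("propagation constant is the principal root with the stated
           identities and sign convention", {
  expect_equal(propagation_constant(list(alpha = 1, beta = 0)),
               list(p = 1, q = 0))
  set.seed(42)
  for (i in 1:25) {
    comp <- list(alpha = runif(1, -3, 6), beta = runif(1, -5, 5))
    pc <- propagation_constant(comp)
    expect_gt(pc$p, 0)
    expect_equal(pc$p^2 - pc$q^2, comp$alpha, tolerance = 1e-10)
    expect_equal(2 * pc$p * pc$q, comp$beta, tolerance = 1e-10)
    if (comp$beta != 0) expect_equal(sign(pc$q), sign(comp$beta))
  }
  expect_error(propagation_constant(list(alpha = 0, beta = 0)), "degenerate")
})

test_that("cable phase limits: r -> 0 gives zero, r -> Inf gives the
           semi-infinite value, and the two analytic forms agree", {
  pp <- resonant_params()
  f <- c(0.2, 1, 5, 20)
  ph_small <- cable_phase(f, pp, illumination(1e-9))
  expect_equal(ph_small, rep(0, 4), tolerance = 1e-6)

  pc <- propagation_constant(admittance_components(f, pp))
  expect_equal(cable_phase(f, pp, illumination(Inf)),
               atan2(pc$q, pc$p) / (2 * pi), tolerance = 1e-12)
  expect_equal(cable_phase(f, pp, illumination(50)),
               atan2(pc$q, pc$p) / (2 * pi), tolerance = 1e-10)

  # second form: -(1/2pi) * Arg((1 - exp(-gamma r)) / gamma)
  for (r in c(0.3, 1, 2.5)) {
    g <- complex(real = pc$p, imaginary = pc$q)
    alt <- -Arg((1 - exp(-g * r)) / g) / (2 * pi)
    expect_equal(cable_phase(f, pp, illumination(r)), alt,
                 tolerance = 1e-12)
  }
})

test_that("resonant low-frequency regime: beta < 0 propagates to a
           negative cable phase", {
  pp <- resonant_params()
  f0 <- 0.2
  expect_lt(admittance_components(f0, pp)$beta, 0)
  expect_lt(cable_phase(f0, pp, illumination(0.6)), 0)
})

test_that("cable amplitude: passive DC anchor, semi-infinite limit, and
           monotone growth with illuminated extent", {
  pas <- passive_params()
  for (r in c(0.3, 1, 2)) {
    expect_equal(cable_amplitude(0, pas, illumination(r)), 1 - exp(-r),
                 tolerance = 1e-12)
  }
  pp <- resonant_params()
  pc <- propagation_constant(admittance_components(2, pp))
  expect_equal(cable_amplitude(2, pp, illumination(Inf)),
               1 / Mod(complex(real = pc$p, imaginary = pc$q)),
               tolerance = 1e-12)
  rs <- seq(0.1, 4, by = 0.1)
  for (f in c(0.2, 0.6, 2)) {
    amp <- vapply(rs, function(r)
      cable_amplitude(f, pp, illumination(r)), numeric(1))
    expect_true(all(diff(amp) > -1e-12))
  }
  # at high frequency the complex exponential spirals: departures from
  # monotone growth exist but are bounded by the decay envelope exp(-p*r)
  pc20 <- propagation_constant(admittance_components(20, pp))
  amp20 <- vapply(rs, function(r)
    cable_amplitude(20, pp, illumination(r)), numeric(1))
  dips <- pmax(-diff(amp20), 0)
  expect_true(all(dips < exp(-pc20$p * rs[-length(rs)]) / Mod(
    complex(real = pc20$p, imaginary = pc20$q))))
})

test_that("ChR2 transfer: DC normalization, quarter-cycle crossing at the
           resonant denominator zero, continuity and monotonicity", {
  kin <- chr2_kinetics(1, 10, 1)
  ct0 <- chr2_transfer(0, kin)
  expect_equal(ct0$amplitude, 1)
  expect_equal(ct0$phase, 0)

  fstar <- 1000 / (2 * pi * sqrt(1 * 10))   # tau in ms
  expect_equal(chr2_transfer(fstar, kin)$phase, 0.25, tolerance = 1e-12)

  f <- seq(0, 100, by = 0.25)
  ph <- chr2_transfer(f, kin)$phase
  expect_true(all(diff(ph) > 0))
  expect_true(all(abs(diff(ph)) < 0.02))    # no branch jumps
})

test_that("ChR2 transfer matches a DFT of the sampled alpha kernel", {
  kin <- chr2_kinetics(1, 10, 1)
  dt <- 0.01
  tk <- seq(0, 400, by = dt)
  k <- alpha_kernel(tk, 1, 1, 10)
  K <- fft(k)
  n <- length(k)
  fgrid <- (0:(n - 1)) / (n * dt / 1000)
  for (f_target in c(2, 5, 20)) {
    i <- which.min(abs(fgrid - f_target))
    H <- K[i] / K[1]
    ct <- chr2_transfer(fgrid[i], kin)
    expect_equal(ct$amplitude, Mod(H), tolerance = 1e-3)
    expect_equal(ct$phase, -Arg(H) / (2 * pi), tolerance = 1e-3)
  }
})

test_that("optogenetic model composes phases additively and collapses to
           the cable model for instantaneous kinetics", {
  pp <- resonant_params()
  il <- illumination(0.58)
  kin <- test_kin()
  f <- c(0.4, 2, 10, 20)
  m <- optogenetic_model(f, pp, il, kin)
  expect_equal(m$phase, chr2_transfer(f, kin)$phase + cable_phase(f, pp, il),
               tolerance = 1e-14)

  fast <- chr2_kinetics(1e-5, 2e-5, 1)
  mf <- optogenetic_model(f, pp, il, fast)
  expect_equal(mf$phase, cable_phase(f, pp, il), tolerance = 1e-4)

  # an amplifying+resonant dendrite shifts the low-frequency phase below
  # the passive variant's
  pas <- passive_params(tau_m = pp$tau_m)
  expect_lt(optogenetic_model(0.4, pp, il, kin)$phase,
            optogenetic_model(0.4, pas, il, kin)$phase)
})

test_that("alpha kernel: zero at origin, analytic peak location and value", {
  expect_equal(alpha_kernel(0, 2, 1, 10), 0)
  tstar <- alpha_kernel_peak_time(1, 10)
  expect_equal(tstar, (1 * 10 / 9) * log(10), tolerance = 1e-12)
  tt <- seq(0, 60, by = 1e-3)
  v <- alpha_kernel(tt, 1, 1, 10)
  expect_equal(tt[which.max(v)], tstar, tolerance = 1e-3)
  expect_equal(max(v), exp(-tstar / 10) - exp(-tstar), tolerance = 1e-6)
  expect_error(alpha_kernel(1, 1, 10, 10), "tau_r < tau_d")
})

test_that("parameter construction rejects invalid and DC-unstable sets", {
  expect_error(qlin_params(tau_n = -1), "tau_n")
  expect_error(qlin_params(gamma_R = 0), "gamma_R")
  expect_error(qlin_params(mu_n = -5, gamma_R = 2), "DC-unstable")
  expect_error(chr2_kinetics(10, 5), "tau_r < tau_d")
  expect_error(illumination(0), "extent_r")
})
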