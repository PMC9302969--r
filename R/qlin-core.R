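#' Complex quasi-linear admittance
#'
#' The normalized admittance of a quasi-linear membrane,
#' `y(f) = gamma_R + i*w*tau_m + mu_n/(1 + i*w*tau_n) + mu_h/(1 + i*w*tau_h)`
#' with `w = 2*pi*f` (time constants converted from ms to s internally).
#' All somatic quantities (phase, impedance) derive from this function.
#'
#' @param f Frequency, Hz (vectorized, `f >= 0`).
#' @param params A [qlin_params] object.
#' @return Complex vector `y(f)`.
#' @export
qlin_admittance <- function(f, params) {
  stopifnot(inherits(params, "qlin_params"))
  if (any(!is.finite(f)) || any(f < 0)) stop("f must be finite and >= 0")
  w <- 2 * pi * f
  params$gamma_R + 1i * w * (params$tau_m / 1000) +
    params$mu_n / (1 + 1i * w * (params$tau_n / 1000)) +
    params$mu_h / (1 + 1i * w * (params$tau_h / 1000))
}

#' Real and imaginary parts of the normalized admittance
#'
#' Returns `alpha(f) = Re y(f)` and `beta(f) = Im y(f)`. At `f = 0`,
#' `alpha = gamma_R + mu_n + mu_h` and `beta = 0` exactly.
#'
#' @inheritParams qlin_admittance
#' @return A list with numeric vectors `alpha` and `beta`.
#' @export
admittance_components <- function(f, params) {
  y <- qlin_admittance(f, params)
  list(alpha = Re(y), beta = Im(y))
}

#' Somatic phase delay of a quasi-linear membrane
#'
#' Phase of the clamp-current response of an isopotential quasi-linear
#' membrane to a sinusoidal voltage command, in cycles:
#' `(1/(2*pi)) * atan2(beta, alpha)`. Positive values mean the current
#' leads the voltage (the paper-standard "phase delay" plotted against
#' frequency); negative values in the subhertz range are the signature of
#' resonance.
#'
#' @inheritParams qlin_admittance
#' @return Phase in cycles, in (-0.5, 0.5).
#' @export
somatic_phase <- function(f, params) {
  y <- qlin_admittance(f, params)
  if (any(Mod(y) == 0)) stop("degenerate model: y(f) = 0")
  Arg(y) / (2 * pi)
}

#' Somatic impedance magnitude
#'
#' `|Z(f)| = amp_scale / |y(f)|` in GOhm. Requires `amp_scale` to be set in
#' `params`.
#'
#' @inheritParams qlin_admittance
#' @return Impedance magnitude, GOhm.
#' @export
somatic_impedance <- function(f, params) {
  if (is.null(params$amp_scale))
    stop("somatic_impedance requires params$amp_scale")
  params$amp_scale / Mod(qlin_admittance(f, params))
}

#' Propagation constant of the quasi-linear cable
#'
#' The complex propagation constant `gamma = sqrt(alpha + i*beta)`
#' (principal root, `Re gamma > 0`), returned as `p = Re gamma`,
#' `q = Im gamma`. `q` inherits the sign of `beta`; `p^2 - q^2 = alpha` and
#' `2*p*q = beta` hold by construction.
#'
#' @param comp A list with components `alpha`, `beta` (as from
#'   [admittance_components]).
#' @return A list with numeric vectors `p` and `q`.
#' @export
propagation_constant <- function(comp) {
  z <- comp$alpha + 1i * comp$beta
  if (any(Mod(z) == 0)) stop("degenerate model: alpha + i*beta = 0")
  g <- sqrt(z)
  # principal branch of sqrt() already has Re >= 0; guard exact-negative-real
  flip <- Re(g) < 0
  g[flip] <- -g[flip]
  list(p = Re(g), q = Im(g))
}

#' Dendritic phase delay under partial illumination
#'
#' Phase delay contributed by a semi-infinite quasi-linear cable whose
#' proximal segment of electrotonic length `r` is driven by a spatially
#' uniform sinusoidal current density, measured at the (clamped) somatic
#' end:
#' `phi_d = (1/(2*pi)) * (atan2(q, p) - atan2(sin(q*r), exp(p*r) - cos(q*r)))`
#' which equals `-(1/(2*pi)) * Arg((1 - exp(-gamma*r))/gamma)`.
#'
#' @inheritParams qlin_admittance
#' @param illum An [illumination] object (`extent_r` may be `Inf`).
#' @return Phase in cycles.
#' @export
cable_phase <- function(f, params, illum) {
  stopifnot(inherits(illum, "illumination"))
  r <- illum$extent_r
  if (r <= 0) stop("illumination extent must be > 0")
  pc <- propagation_constant(admittance_components(f, params))
  p <- pc$p; q <- pc$q
  if (is.infinite(r)) return(atan2(q, p) / (2 * pi))
  (atan2(q, p) - atan2(sin(q * r), exp(p * r) - cos(q * r))) / (2 * pi)
}

#' Dendritic amplitude under partial illumination
#'
#' Modulus counterpart of [cable_phase]: the relative amplitude of the
#' somatic current, `|1 - exp(-gamma*r)| / |gamma|` (dimensionless; any
#' physical gain is applied by the caller). Nondecreasing in `r` at fixed
#' frequency: illuminating more membrane recruits more current.
#'
#' @inheritParams cable_phase
#' @return Relative amplitude (dimensionless).
#' @export
cable_amplitude <- function(f, params, illum) {
  stopifnot(inherits(illum, "illumination"))
  r <- illum$extent_r
  if (r <= 0) stop("illumination extent must be > 0")
  pc <- propagation_constant(admittance_components(f, params))
  g <- complex(real = pc$p, imaginary = pc$q)
  if (is.infinite(r)) return(1 / Mod(g))
  Mod(1 - exp(-g * r)) / Mod(g)
}

#' ChR2 kinetic transfer function
#'
#' Amplitude attenuation and phase delay introduced by channelrhodopsin-2
#' kinetics, from the Fourier transform of the alpha-function impulse
#' response. The amplitude is normalized to 1 at DC; the phase is computed
#' with `atan2` and unwrapped so it is continuous, nondecreasing in `f`,
#' and passes through exactly 0.25 cycles at
#' `f = 1/(2*pi*sqrt(tau_r*tau_d))` (where the denominator vanishes).
#'
#' @param f Frequency, Hz (vectorized).
#' @param kin A [chr2_kinetics] object.
#' @return A list with numeric vectors `amplitude` (normalized to DC) and
#'   `phase` (cycles).
#' @export
chr2_transfer <- function(f, kin) {
  stopifnot(inherits(kin, "chr2_kinetics"))
  w <- 2 * pi * f
  tr <- kin$tau_r / 1000
  td <- kin$tau_d / 1000
  den <- 1 - tr * td * w^2
  num <- w * (tr + td)
  amplitude <- 1 / sqrt(den^2 + num^2)
  # atan2 in [0, pi) here since num >= 0; division by 2*pi gives a phase in
  # [0, 0.5) that is already continuous through the den = 0 crossing.
  phase <- atan2(num, den) / (2 * pi)
  list(amplitude = amplitude, phase = phase)
}

#' Full optogenetic forward model
#'
#' The composite transfer of sinusoidal LED drive to somatic clamp current:
#' ChR2 kinetics in series with the partially illuminated quasi-linear
#' cable. Phases add; amplitudes multiply (with the kinetics gain).
#'
#' @inheritParams cable_phase
#' @param kin A [chr2_kinetics] object.
#' @return A list with numeric vectors `amplitude` and `phase` (cycles).
#' @export
optogenetic_model <- function(f, params, illum, kin) {
  ct <- chr2_transfer(f, kin)
  list(amplitude = ct$amplitude * cable_amplitude(f, params, illum) * kin$gain,
       phase = ct$phase + cable_phase(f, params, illum))
}

#' Alpha-function kernel
#'
#' `A * (exp(-t/tau_d) - exp(-t/tau_r))`: zero at `t = 0`, positive for
#' positive `A`, peaking at `t* = tau_r*tau_d/(tau_d - tau_r) *
#' log(tau_d/tau_r)`. Used as the ChR2 photocurrent impulse response and
#' as the template for spike-triggered calcium transients.
#'
#' @param t Time, ms (vectorized, `t >= 0`).
#' @param A Amplitude scale.
#' @param tau_r Rise time constant, ms.
#' @param tau_d Decay time constant, ms (`tau_d > tau_r`).
#' @return Kernel values at `t`.
#' @export
alpha_kernel <- function(t, A, tau_r, tau_d) {
  if (tau_r <= 0 || tau_d <= tau_r) stop("require 0 < tau_r < tau_d")
  A * (exp(-t / tau_d) - exp(-t / tau_r))
}

#' Peak time of the alpha kernel
#'
#' @inheritParams alpha_kernel
#' @return Peak location in ms.
#' @export
alpha_kernel_peak_time <- function(tau_r, tau_d) {
  if (tau_r <= 0 || tau_d <= tau_r) stop("require 0 < tau_r < tau_d")
  tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
}
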