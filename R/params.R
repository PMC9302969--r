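#' Quasi-linear membrane parameter set
#'
#' Bundles the parameters of a quasi-linear (linearized) membrane model:
#' the dimensionless amplifying and resonant conductance parameters
#' (`mu_n`, `mu_h`), their activation time constants, the total conductance
#' relative to leak (`gamma_R`), the membrane time constant and an optional
#' impedance scale. Negative `mu_n` (a regenerative current such as the
#' persistent sodium current, linearized around the holding potential)
#' produces amplification; positive `mu_h` with a slow time constant (the
#' HCN current) produces subhertz resonance.
#'
#' Construction enforces DC stability of the linearized membrane:
#' `gamma_R + mu_n + mu_h > 0`. A membrane violating this bound has a
#' negative zero-frequency conductance and its linearization is unstable.
#'
#' @param mu_n Dimensionless amplification parameter (typically <= 0).
#' @param mu_h Dimensionless resonance parameter (typically >= 0).
#' @param tau_n Activation time constant of the amplifying term, ms.
#' @param tau_h Activation time constant of the resonant term, ms.
#' @param gamma_R Total membrane conductance relative to leak (> 0).
#' @param tau_m Membrane time constant, ms.
#' @param amp_scale Optional impedance scale in GOhm; the measured impedance
#'   is `amp_scale / |y(f)|` where `y` is the normalized admittance.
#'
#' @return An object of class `qlin_params`.
#' @examples
#' passive <- qlin_params(mu_n = 0, mu_h = 0, tau_n = 1, tau_h = 1,
#'                        gamma_R = 1, tau_m = 26, amp_scale = 1)
#' @export
qlin_params <- function(mu_n = 0, mu_h = 0, tau_n = 1, tau_h = 1,
                        gamma_R = 1, tau_m = 20, amp_scale = NULL) {
  stopifnot(is.numeric(mu_n), is.numeric(mu_h), length(mu_n) == 1L,
            length(mu_h) == 1L, is.finite(mu_n), is.finite(mu_h))
  if (!is.finite(tau_n) || tau_n <= 0) stop("tau_n must be > 0")
  if (!is.finite(tau_h) || tau_h <= 0) stop("tau_h must be > 0")
  if (!is.finite(tau_m) || tau_m <= 0) stop("tau_m must be > 0")
  if (!is.finite(gamma_R) || gamma_R <= 0) stop("gamma_R must be > 0")
  if (gamma_R + mu_n + mu_h <= 0)
    stop("DC-unstable parameter set: gamma_R + mu_n + mu_h must be > 0")
  if (!is.null(amp_scale)) {
    if (!is.finite(amp_scale) || amp_scale <= 0)
      stop("amp_scale must be > 0 when given")
  }
  structure(list(mu_n = mu_n, mu_h = mu_h, tau_n = tau_n, tau_h = tau_h,
                 gamma_R = gamma_R, tau_m = tau_m, amp_scale = amp_scale),
            class = "qlin_params")
}

#' @export
print.qlin_params <- function(x, ...) {
  cat("Quasi-linear membrane parameters\n")
  cat(sprintf("  mu_n = %.4g  (tau_n = %.4g ms)\n", x$mu_n, x$tau_n))
  cat(sprintf("  mu_h = %.4g  (tau_h = %.4g ms)\n", x$mu_h, x$tau_h))
  cat(sprintf("  gamma_R = %.4g, tau_m = %.4g ms\n", x$gamma_R, x$tau_m))
  if (!is.null(x$amp_scale))
    cat(sprintf("  amp_scale = %.4g GOhm\n", x$amp_scale))
  invisible(x)
}

#' Channelrhodopsin-2 photocurrent kinetics
#'
#' Rise and decay time constants of the ChR2 photocurrent impulse response
#' (an alpha-type kernel) together with a gain giving current per unit of
#' LED command above threshold.
#'
#' @param tau_r Rise time constant, ms (`0 < tau_r < tau_d`).
#' @param tau_d Decay time constant, ms.
#' @param gain Steady-state current magnitude per unit LED drive
#'   (sign-free; the photocurrent itself is inward).
#' @return An object of class `chr2_kinetics`.
#' @export
chr2_kinetics <- function(tau_r, tau_d, gain = 1) {
  if (!is.finite(tau_r) || !is.finite(tau_d) || tau_r <= 0 || tau_d <= tau_r)
    stop("require 0 < tau_r < tau_d")
  if (!is.finite(gain) || gain < 0) stop("gain must be >= 0")
  structure(list(tau_r = tau_r, tau_d = tau_d, gain = gain),
            class = "chr2_kinetics")
}

#' Illumination extent specification
#'
#' The illuminated dendritic segment extends from the soma to electrotonic
#' distance `extent_r` (in units of the cable space constant). `Inf` means
#' the whole (semi-infinite) cable is illuminated.
#'
#' @param extent_r Electrotonic length of the illuminated segment (> 0).
#' @param label `"proximal"` or `"full_field"`.
#' @return An object of class `illumination`.
#' @export
illumination <- function(extent_r, label = c("proximal", "full_field")) {
  label <- match.arg(label)
  if (is.na(extent_r) || extent_r <= 0) stop("extent_r must be > 0")
  structure(list(extent_r = extent_r, label = label), class = "illumination")
}

#' Reference quasi-linear parameter sets for cholinergic interneurons
#'
#' Published fits of the quasi-linear model to mouse cholinergic
#' interneuron somata (electrical voltage perturbation at -55 and -70 mV,
#' and under TTX or ZD7288) and dendrites (optogenetic proximal and
#' full-field illumination). Time constants are in ms, `amp_scale` in GOhm,
#' `extent_r` dimensionless (electrotonic units).
#'
#' @return A named list; each element is a list with components `params`
#'   (a [qlin_params] object, where defined), `extent_r` (or `NA`), and
#'   `scheme` (`"amplifying_only"`, `"amplifying_plus_resonant"`, or
#'   `"passive"`).
#' @examples
#' cin_presets()[["soma_m70"]]$params
#' @export
cin_presets <- function() {
  list(
    soma_m55 = list(
      params = qlin_params(mu_n = -3.9189, mu_h = 0, tau_n = 28, tau_h = 1,
                           gamma_R = 5.4296, tau_m = 41.8, amp_scale = 2.4728),
      extent_r = NA_real_, scheme = "amplifying_only"),
    soma_m70 = list(
      params = qlin_params(mu_n = -3.3854, mu_h = 1.5863, tau_n = 11.6,
                           tau_h = 1077.8, gamma_R = 5.8722, tau_m = 26.1,
                           amp_scale = 1.4229),
      extent_r = NA_real_, scheme = "amplifying_plus_resonant"),
    soma_ttx = list(
      params = qlin_params(mu_n = -2.0178, mu_h = 0, tau_n = 31.7, tau_h = 1,
                           gamma_R = 3.4610, tau_m = 19.4, amp_scale = 1.3809),
      extent_r = NA_real_, scheme = "amplifying_only"),
    soma_zd7288 = list(
      params = qlin_params(mu_n = -1.8988, mu_h = 0.4844, tau_n = 13.4,
                           tau_h = 9107.5, gamma_R = 2.6111, tau_m = 17.2,
                           amp_scale = 0.8323),
      extent_r = NA_real_, scheme = "amplifying_plus_resonant"),
    dend_passive_proximal = list(
      params = qlin_params(mu_n = 0, mu_h = 0, tau_n = 1, tau_h = 1,
                           gamma_R = 1, tau_m = 35.8),
      extent_r = 0.4360, scheme = "passive"),
    dend_passive_fullfield = list(
      params = qlin_params(mu_n = 0, mu_h = 0, tau_n = 1, tau_h = 1,
                           gamma_R = 1, tau_m = 26.8),
      extent_r = 1.0651, scheme = "passive"),
    dend_qlin_proximal = list(
      params = qlin_params(mu_n = -1.4763, mu_h = 3.4400, tau_n = 60.0,
                           tau_h = 551.2, gamma_R = 3.3405, tau_m = 33.6),
      extent_r = 0.5788, scheme = "amplifying_plus_resonant"),
    dend_qlin_fullfield = list(
      params = qlin_params(mu_n = -0.8885, mu_h = 1.6646, tau_n = 49.2,
                           tau_h = 403.3, gamma_R = 3.8850, tau_m = 45.3),
      extent_r = 1.0646, scheme = "amplifying_plus_resonant")
  )
}
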