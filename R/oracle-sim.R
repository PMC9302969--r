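# Time-domain realizations of the quasi-linear physics. These are the
# brute-force counterparts of the closed-form models: an isopotential
# clamp integrator, a compartmental cable, and a ChR2 photocurrent
# convolution. They serve as numerical oracles for the frequency-domain
# formulas and as the backbone of the synthetic-data generators.

#' Cable discretization settings
#'
#' @param n_compartments Number of compartments (>= 50).
#' @param total_length Total electrotonic length of the cable (units of the
#'   space constant). Must exceed the illuminated extent; >= 5 recommended
#'   so the sealed distal end approximates a semi-infinite cable (end
#'   effects decay as `exp(-2*p*L)`).
#' @param dt Time step, ms. Must satisfy `dt < min(tau_n, tau_h, tau_m)/20`
#'   for the parameter set in use (checked at simulation time).
#' @return An object of class `cable_discretization`.
#' @export
cable_discretization <- function(n_compartments = 400, total_length = 5,
                                 dt = 0.25) {
  if (n_compartments < 50) stop("n_compartments must be >= 50")
  if (total_length <= 0) stop("total_length must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  structure(list(n_compartments = as.integer(n_compartments),
                 total_length = total_length, dt = dt),
            class = "cable_discretization")
}

check_dt <- function(dt, params) {
  taus <- params$tau_m
  if (params$mu_n != 0) taus <- c(taus, params$tau_n)
  if (params$mu_h != 0) taus <- c(taus, params$tau_h)
  lim <- min(taus) / 20
  if (dt >= lim)
    stop(sprintf("dt = %g ms too coarse for this parameter set (need < %g ms)",
                 dt, lim))
  invisible(TRUE)
}

#' Isopotential voltage-clamp simulation of a quasi-linear membrane
#'
#' Integrates the clamp current of an isopotential quasi-linear membrane
#' driven by an arbitrary voltage-command perturbation `v(t)` (mV around
#' the holding potential):
#' `i(t) = (1/amp_scale) * (gamma_R*v + tau_m*dv/dt + w_n + w_h)`,
#' `tau_k * dw_k/dt = mu_k * v - w_k`. The gating variables are advanced
#' with an exact exponential update (piecewise-linear `v`), so the scheme
#' is unconditionally stable despite the stiffness of slow resonant time
#' constants. The steady-state sinusoidal response matches the closed-form
#' admittance [qlin_admittance].
#'
#' @param params A [qlin_params] object (must carry `amp_scale` for pA
#'   units; with `amp_scale = 1` the output is in admittance-normalized
#'   units).
#' @param v_command Voltage command trace, mV.
#' @param dt Sample interval, ms.
#' @return Clamp current trace (pA when `amp_scale` is in GOhm and `v` in
#'   mV), same length as `v_command`.
#' @export
simulate_isopotential_clamp <- function(params, v_command, dt) {
  stopifnot(inherits(params, "qlin_params"))
  if (any(!is.finite(v_command))) stop("v_command must be finite")
  check_dt(dt, params)
  n <- length(v_command)
  amp <- if (is.null(params$amp_scale)) 1 else params$amp_scale

  # Exact exponential update for w' = (mu*v - w)/tau with v linear on each
  # step reduces to a first-order recursive filter in the step-midpoint
  # command; stats::filter runs it in C.
  gate <- function(mu, tau) {
    if (mu == 0) return(numeric(n))
    a <- exp(-dt / tau)
    # midpoint value of v on the step ending at sample k (v itself at k=1)
    vm <- c(v_command[1], (v_command[-1] + v_command[-n]) / 2)
    drive <- mu * (1 - a) * vm
    as.numeric(stats::filter(drive, a, method = "recursive"))
  }
  w_n <- gate(params$mu_n, params$tau_n)
  w_h <- gate(params$mu_h, params$tau_h)

  dv <- numeric(n)
  if (n > 2) dv[2:(n - 1)] <- (v_command[3:n] - v_command[1:(n - 2)]) / (2 * dt)
  if (n > 1) {
    dv[1] <- (v_command[2] - v_command[1]) / dt
    dv[n] <- (v_command[n] - v_command[n - 1]) / dt
  }
  (params$gamma_R * v_command + params$tau_m * dv + w_n + w_h) / amp
}

#' Compartmental voltage-clamp simulation of a quasi-linear cable
#'
#' Simulates a uniform quasi-linear cable, clamped at the somatic end
#' (perturbation 0 mV) and sealed at the distal end, driven by a
#' per-compartment current density. Integration is Crank-Nicolson with the
#' gating variables eliminated algebraically each step, so one constant
#' tridiagonal system (factored once) is solved per time step; the scheme
#' is A-stable for any `dt`. For sinusoidal drive restricted to the
#' proximal `extent_r`, the steady-state phase of the somatic axial current
#' converges to [cable_phase] as the mesh and cable length are refined.
#'
#' @param params A [qlin_params] object.
#' @param disc A [cable_discretization] object.
#' @param drive Either a numeric matrix (`n_compartments` x time) of drive
#'   current density, or a numeric vector (a common time course applied to
#'   all illuminated compartments).
#' @param illum An [illumination] object; drive is applied only to
#'   compartments whose electrotonic position is `<= extent_r`.
#' @return Somatic axial current trace (arbitrary linear units), one value
#'   per time sample.
#' @export
simulate_cable_clamp <- function(params, disc, drive, illum) {
  stopifnot(inherits(params, "qlin_params"),
            inherits(disc, "cable_discretization"),
            inherits(illum, "illumination"))
  check_dt(disc$dt, params)
  N <- disc$n_compartments
  L <- disc$total_length
  if (is.finite(illum$extent_r) && illum$extent_r >= L)
    stop("total_length must exceed the illuminated extent")
  dx <- L / N
  h <- disc$dt
  x <- (seq_len(N) - 0.5) * dx          # compartment centers, soma at x = 0
  lit <- x <= illum$extent_r

  if (is.matrix(drive)) {
    if (nrow(drive) != N) stop("drive matrix must have n_compartments rows")
    S <- drive
    S[!lit, ] <- 0
    nt <- ncol(drive)
  } else {
    nt <- length(drive)
    S <- matrix(0, N, nt)
    S[lit, ] <- rep(drive, each = sum(lit))
  }

  # Crank-Nicolson step with gate elimination:
  #   w+ = a w + b (V + V+),  a = (1-h/2tau)/(1+h/2tau), b = (h mu/2tau)/(1+h/2tau)
  gc <- function(mu, tau) {
    d <- 1 + h / (2 * tau)
    list(a = (1 - h / (2 * tau)) / d, b = (h * mu / (2 * tau)) / d)
  }
  gn <- gc(params$mu_n, params$tau_n)
  gh <- gc(params$mu_h, params$tau_h)
  bsum <- gn$b + gh$b
  tm <- params$tau_m
  gR <- params$gamma_R

  # Discrete Laplacian (electrotonic units), Dirichlet V=0 at soma face,
  # Neumann (sealed) at the distal face.
  main <- rep(-2, N); main[N] <- -1
  Lap <- Matrix::bandSparse(N, N,
                            k = c(-1, 0, 1),
                            diagonals = list(rep(1, N - 1), main,
                                             rep(1, N - 1))) / dx^2
  I <- Matrix::Diagonal(N)
  M <- (tm / h + gR / 2 + bsum / 2) * I - Lap / 2
  Mfac <- Matrix::lu(M)
  B <- (tm / h - gR / 2 - bsum / 2) * I + Lap / 2

  V <- numeric(N)
  wn <- numeric(N)
  wh <- numeric(N)
  out <- numeric(nt)
  out[1] <- 0
  s_prev <- S[, 1]
  for (k in 2:nt) {
    s_now <- S[, k]
    rhs <- as.numeric(B %*% V) -
      ((1 + gn$a) * wn + (1 + gh$a) * wh) / 2 + (s_prev + s_now) / 2
    Vn <- as.numeric(Matrix::solve(Mfac, rhs))
    wn <- gn$a * wn + gn$b * (V + Vn)
    wh <- gh$a * wh + gh$b * (V + Vn)
    V <- Vn
    # axial current into the clamped somatic node ~ (V_1 - 0)/dx
    out[k] <- V[1] / dx
    s_prev <- s_now
  }
  out
}

#' ChR2 photocurrent from an LED command
#'
#' Thresholds the LED command at the device voltage threshold, convolves
#' the supra-threshold drive with the unit-area alpha kernel of the ChR2
#' kinetics, and returns the inward (negative) photocurrent density. The
#' inversion is why downstream phase estimation of optogenetic recordings
#' applies a half-cycle antiphase correction.
#'
#' @param led_command LED command trace (same units as `threshold`),
#'   non-negative.
#' @param kin A [chr2_kinetics] object.
#' @param dt Sample interval, ms.
#' @param threshold LED activation threshold (default 40 mV command units).
#' @return Photocurrent density trace (negative-going), same length as
#'   `led_command`.
#' @export
chr2_photocurrent <- function(led_command, kin, dt, threshold = 40) {
  stopifnot(inherits(kin, "chr2_kinetics"))
  if (any(led_command < 0)) stop("led_command must be >= 0")
  x <- pmax(led_command - threshold, 0)
  n <- length(x)
  # kernel truncated at 10 decay constants, normalized to unit area so the
  # DC gain of the convolution equals kin$gain
  tk <- seq(0, 10 * kin$tau_d, by = dt)
  ker <- alpha_kernel(tk, 1, kin$tau_r, kin$tau_d)
  ker <- ker / sum(ker)
  y <- stats::convolve(c(x, numeric(length(ker))), rev(ker), type = "open")
  -kin$gain * y[seq_len(n)]
}

#' Fit a single-frequency sinusoid to a steady-state trace
#'
#' Linear regression on sine/cosine basis at a known frequency; used to
#' extract steady-state amplitude and phase from simulated traces.
#'
#' @param trace Numeric trace.
#' @param f Frequency, Hz.
#' @param sample_rate Samples per second.
#' @param discard_s Initial transient to drop, s.
#' @return List with `amplitude`, `phase` (cycles, phase of
#'   `A*sin(2*pi*f*t + phi)` with `t = 0` at the start of the
#'   \emph{undiscarded} trace), and `offset`.
#' @export
fit_sinusoid <- function(trace, f, sample_rate, discard_s = 0) {
  n <- length(trace)
  t <- (seq_len(n) - 1) / sample_rate
  keep <- t >= discard_s
  tt <- t[keep]
  y <- trace[keep]
  X <- cbind(1, sin(2 * pi * f * tt), cos(2 * pi * f * tt))
  cf <- unname(stats::lm.fit(X, y)$coefficients)
  list(amplitude = sqrt(cf[2]^2 + cf[3]^2),
       phase = atan2(cf[3], cf[2]) / (2 * pi),
       offset = cf[1])
}
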