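# Plain-text persistence: CSV for traces and tables, JSON sidecars for
# configuration and ground truth. Every writer embeds units; every
# round-trip read(write(x)) reproduces the object.

#' Write / read a transfer curve as CSV
#'
#' Columns: `frequency_hz`, `phase_cycles`, `phase_sem`, `magnitude`,
#' `magnitude_sem`, `n`; the modality is stored in a leading comment line.
#'
#' @param curve A `transfer_curve`.
#' @param path File path.
#' @return `write_transfer_curve` returns `path` invisibly;
#'   `read_transfer_curve` returns a `transfer_curve`.
#' @export
write_transfer_curve <- function(curve, path) {
  stopifnot(inherits(curve, "transfer_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# modality: %s", attr(curve, "modality")), con)
  utils::write.csv(as.data.frame(curve), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transfer_curve
#' @export
read_transfer_curve <- function(path) {
  first <- readLines(path, n = 1)
  modality <- sub("^# modality: ", "", first)
  d <- utils::read.csv(path, comment.char = "#")
  transfer_curve(d$frequency_hz, d$phase_cycles, d$magnitude,
                 d$phase_sem, d$magnitude_sem, d$n, modality)
}

#' Write / read an event set as CSV
#'
#' Columns: `kind`, `start_s`, `peak_s`, `end_s`, `amplitude`.
#'
#' @param events An `event_set`.
#' @param path File path.
#' @export
write_event_set <- function(events, path) {
  stopifnot(inherits(events, "event_set"))
  d <- data.frame(kind = rep(events$kind, length(events$peak_times)),
                  start_s = events$start_times, peak_s = events$peak_times,
                  end_s = events$end_times, amplitude = events$amplitudes)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_set
#' @export
read_event_set <- function(path) {
  d <- utils::read.csv(path)
  kind <- if (nrow(d) > 0) d$kind[1] else "slow_wave"
  event_set(kind, d$start_s, d$peak_s, d$end_s, d$amplitude)
}

#' Write / read a conditional firing rate as CSV
#'
#' Columns: `bin_center_s`, `rate_hz`, `ci_low`, `ci_high`.
#'
#' @param cr A `conditional_rate`.
#' @param path File path.
#' @export
write_conditional_rate <- function(cr, path) {
  stopifnot(inherits(cr, "conditional_rate"))
  d <- data.frame(bin_center_s = cr$bin_centers, rate_hz = cr$rate,
                  ci_low = cr$ci_low, ci_high = cr$ci_high)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_conditional_rate
#' @export
read_conditional_rate <- function(path) {
  d <- utils::read.csv(path)
  structure(list(bin_centers = d$bin_center_s, rate = d$rate_hz,
                 ci_low = d$ci_low[1], ci_high = d$ci_high[1],
                 n_triggers = NA_integer_),
            class = "conditional_rate")
}

#' Summarize fit results as a parameter table
#'
#' Collects one or several `fit_result` objects into the standard
#' parameter-table layout (one row per fitted curve) and optionally writes
#' it as CSV.
#'
#' @param fits Named list of `fit_result` objects (names become the
#'   `curve_label` column).
#' @param path Optional CSV path.
#' @return A data.frame with columns `curve_label`, `mu_n`, `mu_h`,
#'   `tau_n_ms`, `tau_h_ms`, `gamma_R`, `tau_ms`, `r`, `amp_GOhm`,
#'   `residual`.
#' @export
fit_results_table <- function(fits, path = NULL) {
  stopifnot(all(vapply(fits, inherits, logical(1), "fit_result")))
  rows <- lapply(names(fits), function(nm) {
    ft <- fits[[nm]]
    p <- ft$params
    data.frame(curve_label = nm,
               mu_n = if ("mu_n" %in% c(ft$free_names, names(ft$fixed)))
                 p$mu_n else NA_real_,
               mu_h = if ("mu_h" %in% c(ft$free_names, names(ft$fixed)))
                 p$mu_h else NA_real_,
               tau_n_ms = if (p$mu_n != 0) p$tau_n else NA_real_,
               tau_h_ms = if (p$mu_h != 0) p$tau_h else NA_real_,
               gamma_R = p$gamma_R, tau_ms = p$tau_m,
               r = if (is.null(ft$extent_r)) NA_real_ else ft$extent_r,
               amp_GOhm = if (is.null(p$amp_scale)) NA_real_ else p$amp_scale,
               residual = ft$residual_norm)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Write / read a sampled trace as CSV with a units header
#'
#' Columns `time_s`, `value`; sample rate and units in comment lines.
#'
#' @param x Numeric trace.
#' @param sample_rate Samples per second.
#' @param units Unit string (e.g. `"pA"`).
#' @param path File path.
#' @export
write_trace_csv <- function(x, sample_rate, units, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sample_rate_hz: %.10g", sample_rate),
               sprintf("# units: %s", units)), con)
  d <- data.frame(time_s = (seq_along(x) - 1) / sample_rate, value = x)
  utils::write.csv(d, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  if (!grepl("^# units:", hdr[2])) stop("missing units field in ", path)
  d <- utils::read.csv(path, comment.char = "#")
  list(value = d$value,
       sample_rate = as.numeric(sub("^# sample_rate_hz: ", "", hdr[1])),
       units = sub("^# units: ", "", hdr[2]))
}
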