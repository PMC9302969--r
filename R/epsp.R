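# Trial-averaged synaptic response amplitude, paired-pulse ratio, and
# paired drug-effect statistics.

#' Trial block of evoked synaptic responses
#'
#' @param traces Trial-by-time numeric matrix (mV for EPSP, pA for EPSC).
#' @param sample_rate Samples per second.
#' @param stim_times Stimulus times within the trial, s (1 pulse, or 2
#'   pulses 100 ms apart for paired-pulse blocks).
#' @param mode `"EPSP"` or `"EPSC"`.
#' @param baseline_window Length of the pre-stimulus baseline, s.
#' @param peak_window Post-stimulus window searched for the peak, s
#'   (start and end offsets after the pulse).
#' @param cell_id,condition Labels.
#' @return A `trial_block` object.
#' @export
trial_block <- function(traces, sample_rate, stim_times,
                        mode = c("EPSP", "EPSC"),
                        baseline_window = 0.01,
                        peak_window = c(0.005, 0.05),
                        cell_id = NA_character_, condition = NA_character_) {
  mode <- match.arg(mode)
  traces <- as.matrix(traces)
  dur <- ncol(traces) / sample_rate
  if (length(stim_times) == 2 &&
      abs(diff(stim_times) - 0.1) > 1e-9)
    stop("paired blocks must have stimuli 100 ms apart")
  if (length(stim_times) > 2 || length(stim_times) < 1)
    stop("blocks carry 1 or 2 stimuli")
  if (any(stim_times + peak_window[2] > dur) ||
      any(stim_times - baseline_window < 0))
    stop("baseline/peak windows fall outside the trace")
  structure(list(traces = traces, sample_rate = sample_rate,
                 stim_times = stim_times, mode = mode,
                 baseline_window = baseline_window,
                 peak_window = peak_window,
                 cell_id = cell_id, condition = condition),
            class = "trial_block")
}

reject_spiking_trials <- function(block, spike_threshold) {
  if (block$mode != "EPSP") return(rep(TRUE, nrow(block$traces)))
  apply(block$traces, 1, function(tr) all(tr < spike_threshold))
}

amplitude_one_pulse <- function(block, stim_t, keep, peak_halfwin = 5e-4) {
  sr <- block$sample_rate
  i_stim <- round(stim_t * sr) + 1
  i_base <- seq(i_stim - round(block$baseline_window * sr), i_stim - 1)
  i_peak <- seq(i_stim + round(block$peak_window[1] * sr),
                i_stim + round(block$peak_window[2] * sr))
  mtr <- colMeans(block$traces[keep, , drop = FALSE])
  base <- mean(mtr[i_base])
  seg <- mtr[i_peak] - base
  if (block$mode == "EPSC") seg <- -seg
  # locate the peak on a lightly smoothed mean trace (1 ms boxcar), then
  # report the mean over +/- peak_halfwin around it: far less sensitive to
  # sample-level noise spikes than a raw maximum
  k <- max(1L, round(1e-3 * sr))
  sm <- stats::filter(seg, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- -Inf
  ctr <- which.max(sm)
  hw <- max(0L, round(peak_halfwin * sr))
  win <- seq(max(1, ctr - hw), min(length(seg), ctr + hw))
  mean(seg[win])
}

#' Trial-averaged response amplitude
#'
#' Mean response amplitude of a trial block: mean-trace peak within the
#' peak window minus mean-trace baseline before the (first) pulse. EPSP
#' trials containing a spike (any sample above `spike_threshold`) are
#' rejected and counted.
#'
#' @param block A [trial_block].
#' @param spike_threshold Spike rejection threshold for EPSP mode, mV.
#' @param min_trials Minimum usable trials.
#' @return List with `amplitude`, `n_trials` (used), `n_rejected`.
#' @export
trial_average_response <- function(block, spike_threshold = -20,
                                   min_trials = 5) {
  stopifnot(inherits(block, "trial_block"))
  keep <- reject_spiking_trials(block, spike_threshold)
  if (sum(keep) < min_trials)
    stop(sprintf("insufficient data: %d usable trials (< %d)",
                 sum(keep), min_trials))
  amp <- amplitude_one_pulse(block, block$stim_times[1], keep)
  list(amplitude = amp, n_trials = sum(keep), n_rejected = sum(!keep))
}

#' Paired-pulse ratio
#'
#' Ratio of the second to the first mean response amplitude of a
#' paired-pulse block. The second-pulse baseline is measured in the 10 ms
#' immediately preceding the second stimulus, which removes the residual
#' decay of the first response.
#'
#' @param block A paired [trial_block] (two stimuli, 100 ms apart).
#' @param spike_threshold,min_trials As in [trial_average_response].
#' @param noise_floor First-pulse amplitudes at or below this value raise
#'   an undefined-ratio error.
#' @return List with `ppr`, `amp1`, `amp2`, `n_trials`.
#' @export
paired_pulse_ratio <- function(block, spike_threshold = -20, min_trials = 5,
                               noise_floor = 0) {
  stopifnot(inherits(block, "trial_block"))
  if (length(block$stim_times) != 2) stop("paired block required")
  keep <- reject_spiking_trials(block, spike_threshold)
  if (sum(keep) < min_trials)
    stop(sprintf("insufficient data: %d usable trials (< %d)",
                 sum(keep), min_trials))
  a1 <- amplitude_one_pulse(block, block$stim_times[1], keep)
  a2 <- amplitude_one_pulse(block, block$stim_times[2], keep)
  if (a1 <= noise_floor) stop("undefined ratio: first response at noise floor")
  list(ppr = a2 / a1, amp1 = a1, amp2 = a2, n_trials = sum(keep))
}

#' Paired drug-effect test across cells
#'
#' Per-cell percent change of the trial-averaged amplitude between matched
#' pre- and post-drug blocks, with a two-tailed Wilcoxon signed-rank test.
#' Unmatched cells are dropped with a warning.
#'
#' @param pre_blocks,post_blocks Lists of [trial_block]s; matching is by
#'   `cell_id`.
#' @param min_cells Minimum matched cells.
#' @param ... Passed to [trial_average_response].
#' @return A `drug_effect`: list with `per_cell` (data.frame `cell_id`,
#'   `pre`, `post`, `pct_change`), `median_pct_change`, `p_value`, `n`.
#' @export
paired_drug_test <- function(pre_blocks, post_blocks, min_cells = 5, ...) {
  amp_by_cell <- function(blocks) {
    ids <- vapply(blocks, `[[`, character(1), "cell_id")
    amps <- vapply(blocks, function(b)
      trial_average_response(b, ...)$amplitude, numeric(1))
    stats::setNames(amps, ids)
  }
  pre <- amp_by_cell(pre_blocks)
  post <- amp_by_cell(post_blocks)
  cells <- intersect(names(pre), names(post))
  dropped <- setdiff(union(names(pre), names(post)), cells)
  if (length(dropped) > 0)
    warning(sprintf("dropping unmatched cells: %s",
                    paste(dropped, collapse = ", ")))
  if (length(cells) < min_cells)
    stop(sprintf("need >= %d cells with both conditions", min_cells))
  if (any(pre[cells] <= 0))
    stop("pre-drug amplitudes must be > 0 for percent change")
  pct <- (post[cells] - pre[cells]) / pre[cells] * 100
  tst <- stats::wilcox.test(post[cells], pre[cells], paired = TRUE,
                            exact = FALSE)
  p <- if (all(post[cells] == pre[cells])) 1 else tst$p.value
  structure(list(per_cell = data.frame(cell_id = cells, pre = pre[cells],
                                       post = post[cells], pct_change = pct,
                                       row.names = NULL),
                 median_pct_change = stats::median(pct),
                 p_value = p, n = length(cells)),
            class = "drug_effect")
}

#' @export
print.drug_effect <- function(x, ...) {
  cat(sprintf("Drug effect: median change %.1f%% (n = %d cells, p = %.3g)\n",
              x$median_pct_change, x$n, x$p_value))
  invisible(x)
}
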