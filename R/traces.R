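#' Correction and baseline configuration
#'
#' @param r Neuropil contamination ratio subtracted from the measured soma
#'   signal (default 0.7). One global value is used; it may need adjustment
#'   for other preparations.
#' @param exclusion_margin Minimum fractional excess of somatic over
#'   neuropil baseline for a cell to be analyzable (default 0.03, i.e. 3%).
#' @param indicator `"fast"` or `"slow"`; sets the F0 window via
#'   [baseline_window_s()] (2 s fast, 1 s slow).
#' @param baseline_window Override for the F0 window, seconds.
#' @return An object of class `correction_config`.
#' @export
correction_config <- function(r = 0.7, exclusion_margin = 0.03,
                              indicator = c("fast", "slow"),
                              baseline_window = NULL) {
  indicator <- match.arg(indicator)
  if (r < 0 || r > 1) stop("r must be in [0, 1]", call. = FALSE)
  if (exclusion_margin < 0)
    stop("exclusion_margin must be >= 0", call. = FALSE)
  structure(list(
    r = r, exclusion_margin = exclusion_margin, indicator = indicator,
    baseline_window = if (is.null(baseline_window))
      baseline_window_s(indicator) else baseline_window
  ), class = "correction_config")
}

#' Subtractive neuropil correction
#'
#' `F_corrected(t) = F_measured(t) - r * F_neuropil(t)`, elementwise.
#' At `r = 0` the correction is the identity; it is linear in `r`.
#'
#' @param raw Measured somatic trace (vector) or matrix (cells x frames).
#' @param neuropil Neuropil trace, one value per frame.
#' @param r Contamination ratio (default 0.7).
#' @return Corrected trace(s), same shape as `raw`.
#' @export
neuropil_correct <- function(raw, neuropil, r = 0.7) {
  if (is.matrix(raw)) {
    if (ncol(raw) != length(neuropil))
      stop("raw and neuropil lengths differ", call. = FALSE)
    return(sweep(raw, 2, r * neuropil, "-"))
  }
  if (length(raw) != length(neuropil))
    stop("raw and neuropil lengths differ", call. = FALSE)
  raw - r * neuropil
}

#' Baseline-over-neuropil exclusion rule
#'
#' A cell is analyzable only when its (uncorrected) baseline fluorescence
#' exceeds the surrounding neuropil baseline by more than the margin
#' (default 3%); otherwise F0 cannot be reliably estimated and the cell is
#' dropped from all downstream statistics. Baselines are the means over the
#' pre-stimulus windows of all trials.
#'
#' @param raw Measured somatic trace over a session.
#' @param neuropil Neuropil trace over the same session.
#' @param protocol A [stimulus_protocol()].
#' @param config A [correction_config()].
#' @return Logical: `TRUE` to keep, `FALSE` to exclude. Attribute
#'   `"reason"` holds a short explanation for excluded cells; a
#'   data-quality warning is raised when the neuropil baseline is
#'   non-positive.
#' @export
exclusion_filter <- function(raw, neuropil, protocol,
                             config = correction_config()) {
  fpt <- n_frames_per_trial(protocol)
  bidx <- baseline_frames(protocol, 1, config$baseline_window)
  idx <- rep(bidx, n_trials_total(protocol)) +
    rep(fpt * (seq_len(n_trials_total(protocol)) - 1), each = length(bidx))
  raw_base <- mean(raw[idx])
  np_base <- mean(neuropil[idx])
  if (np_base <= 0)
    warning("non-positive neuropil baseline; exclusion decision based on ",
            "raw means only", call. = FALSE)
  keep <- raw_base > (1 + config$exclusion_margin) * np_base
  if (!keep)
    attr(keep, "reason") <- sprintf(
      "baseline %.4g not > %.4g (neuropil %.4g + %g%% margin)",
      raw_base, (1 + config$exclusion_margin) * np_base, np_base,
      100 * config$exclusion_margin)
  keep
}

#' Per-trial dF/F0 of a corrected trace
#'
#' For each trial, F0 is the mean of the corrected trace over the baseline
#' window immediately before grating onset (frames whose start times fall
#' in `[onset - w, onset)`), and `dff(t) = (F(t) - F0) / F0` over that
#' trial's frames.
#'
#' @param corrected Corrected session trace (vector over all frames).
#' @param protocol A [stimulus_protocol()].
#' @param config A [correction_config()]; supplies the window length.
#' @return A list with `dff` (vector over all session frames), `f0`
#'   (per-trial baseline), and `excluded` (`TRUE` when any trial's F0 is
#'   non-positive, making the baseline unreliable).
#' @export
compute_dff <- function(corrected, protocol, config = correction_config()) {
  nt <- n_trials_total(protocol)
  fpt <- n_frames_per_trial(protocol)
  if (length(corrected) != nt * fpt)
    stop("trace length does not match the protocol's frame count",
         call. = FALSE)
  bidx <- baseline_frames(protocol, 1, config$baseline_window)
  m <- matrix(corrected, fpt, nt)          # one column per trial
  f0 <- colMeans(m[bidx, , drop = FALSE])
  dmat <- sweep(sweep(m, 2, f0, "-"), 2, f0, "/")
  dmat[, f0 <= 0] <- NA_real_
  dff <- as.vector(dmat)
  excluded <- any(f0 <= 0)
  if (excluded)
    warning("non-positive F0 in at least one trial; cell flagged excluded",
            call. = FALSE)
  list(dff = dff, f0 = f0, excluded = excluded)
}

#' Process a population of measured traces to dF/F0
#'
#' Applies the exclusion rule, subtracts the scaled neuropil trace, and
#' computes per-trial dF/F0 for every kept cell.
#'
#' @param measured Matrix of measured somatic traces, cells x frames.
#' @param neuropil Neuropil trace (one per session) or matrix matching
#'   `measured` (one per cell).
#' @param protocol A [stimulus_protocol()].
#' @param config A [correction_config()].
#' @return A list with `dff` (cells x frames, NA rows for excluded cells),
#'   `f0` (cells x trials), `kept` (logical per cell), and
#'   `exclusion_reason` (character per cell, NA when kept).
#' @export
process_traces <- function(measured, neuropil, protocol,
                           config = correction_config()) {
  n_cells <- nrow(measured)
  np_mat <- if (is.matrix(neuropil)) neuropil
            else matrix(neuropil, n_cells, ncol(measured), byrow = TRUE)
  dff <- matrix(NA_real_, n_cells, ncol(measured))
  f0 <- matrix(NA_real_, n_cells, n_trials_total(protocol))
  kept <- logical(n_cells)
  reason <- rep(NA_character_, n_cells)
  for (i in seq_len(n_cells)) {
    keep <- exclusion_filter(measured[i, ], np_mat[i, ], protocol, config)
    if (!keep) {
      reason[i] <- attr(keep, "reason")
      next
    }
    corrected <- neuropil_correct(measured[i, ], np_mat[i, ], config$r)
    res <- suppressWarnings(compute_dff(corrected, protocol, config))
    if (res$excluded) {
      reason[i] <- "non-positive F0"
      next
    }
    kept[i] <- TRUE
    dff[i, ] <- res$dff
    f0[i, ] <- res$f0
  }
  list(dff = dff, f0 = f0, kept = kept, exclusion_reason = reason)
}
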