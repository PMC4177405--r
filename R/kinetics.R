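#' Gate a cell for kinetics analysis
#'
#' Decay kinetics are measured on trial-averaged responses (five trials by
#' default). Baseline mean and SD are computed over the pre-stimulus window
#' (2 s for fast, 1 s for slow indicators); the cell is gated in when its
#' mean response during the last 1 s of the grating exceeds the baseline by
#' at least `sd_gate` baseline SDs. With exactly zero baseline SD
#' (noise-free traces), the gate degenerates to mean response > baseline.
#'
#' @param avg_trace Trial-averaged full-trial trace (dF/F0 or raw units;
#'   the criterion is relative), length `n_frames_per_trial(protocol)`.
#' @param protocol A [stimulus_protocol()].
#' @param indicator `"fast"` or `"slow"` (sets the baseline window).
#' @param sd_gate Gate threshold in baseline SDs (default 5).
#' @param response_window Window before grating offset over which the
#'   response is averaged, seconds (default 1).
#' @return A list with `gated_in`, `baseline_mean`, `baseline_sd`,
#'   `response_mean`.
#' @export
gate_cell <- function(avg_trace, protocol, indicator = c("fast", "slow"),
                      sd_gate = 5, response_window = 1) {
  indicator <- match.arg(indicator)
  fr <- protocol$frame_rate
  fpt <- n_frames_per_trial(protocol)
  if (length(avg_trace) < fpt)
    stop("avg_trace shorter than one trial", call. = FALSE)
  w <- baseline_window_s(indicator)
  onset <- round(fr * protocol$blank_duration)
  bidx <- (onset - round(fr * w) + 1):onset
  base_mean <- mean(avg_trace[bidx])
  base_sd <- stats::sd(avg_trace[bidx])
  ridx <- (fpt - round(fr * response_window) + 1):fpt
  resp <- mean(avg_trace[ridx])
  gated <- if (base_sd == 0) resp > base_mean
           else resp >= base_mean + sd_gate * base_sd
  list(gated_in = gated, baseline_mean = base_mean,
       baseline_sd = base_sd, response_mean = resp)
}

#' Half-decay time after the last response peak
#'
#' The peak is the maximum of the baseline-subtracted trace over the
#' grating window; when the response is modulated at the grating frequency
#' the "last peak" is taken as the maximum within the final grating cycle
#' of the window. Starting from that peak, the first sample pair
#' bracketing half the peak value is found and the crossing time is
#' linearly interpolated; the half-decay is crossing time minus peak time.
#' (Referencing from the peak, not the grating offset, keeps the quantity
#' well defined for fast indicators, whose trace can fall below half peak
#' between the last response peak and the end of the grating.)
#'
#' @param avg_trace Trial-averaged full-trial trace.
#' @param protocol A [stimulus_protocol()].
#' @param baseline_mean Baseline to subtract (from [gate_cell()]).
#' @param last_cycle Restrict the peak search to the final grating cycle
#'   (default TRUE when the protocol has >= 2 cycles per stimulus).
#' @return Half-decay time in seconds, or `NA` (with a warning) when the
#'   trace never falls to half peak before the trial ends.
#' @export
half_decay_time <- function(avg_trace, protocol, baseline_mean,
                            last_cycle = NULL) {
  fr <- protocol$frame_rate
  fpt <- n_frames_per_trial(protocol)
  x <- avg_trace - baseline_mean
  sidx <- stim_frames_rel(protocol)
  if (is.null(last_cycle))
    last_cycle <- protocol$stim_duration * protocol$temporal_frequency >= 2
  search <- sidx
  if (last_cycle) {
    cyc <- round(fr / protocol$temporal_frequency)
    search <- sidx[(length(sidx) - cyc + 1):length(sidx)]
  }
  pk_idx <- search[which.max(x[search])]
  peak <- x[pk_idx]
  if (peak <= 0) {
    warning("non-positive peak; half-decay undefined", call. = FALSE)
    return(NA_real_)
  }
  ref_idx <- pk_idx
  half <- peak / 2
  ## first bracketing pair after the peak sample
  below <- which(x <= half)
  below <- below[below > ref_idx]
  if (!length(below)) {
    warning("trace never reaches half peak before the trial ends; ",
            "half-decay undefined", call. = FALSE)
    return(NA_real_)
  }
  j <- below[1]
  i <- j - 1
  ## linear interpolation between samples i and j
  t_i <- (i - 1) / fr
  frac <- (x[i] - half) / (x[i] - x[j])
  t_cross <- t_i + frac / fr
  ## reference: the later of the last grating sample and the peak sample
  t_ref <- (ref_idx - 1) / fr
  t_cross - t_ref
}

#' Trial-averaged response including the post-stimulus tail
#'
#' Like [direction_average()], but each trial segment is extended by
#' `post_s` seconds into the following trial's blank period, so that the
#' decay after grating offset is observable. Trials without a successor
#' (the session's last trial) are dropped from the average.
#'
#' @inheritParams direction_average
#' @param post_s Post-stimulus extension, seconds (at most the blank
#'   duration).
#' @return Numeric vector of length `n_frames_per_trial(protocol) +
#'   round(frame_rate * post_s)`.
#' @export
direction_average_extended <- function(dff, protocol, direction_index,
                                       post_s = protocol$blank_duration) {
  if (post_s > protocol$blank_duration + 1e-9)
    stop("post_s cannot exceed the next trial's blank duration",
         call. = FALSE)
  tt <- trial_table(protocol)
  fpt <- n_frames_per_trial(protocol)
  n_post <- round(protocol$frame_rate * post_s)
  len <- fpt + n_post
  trials <- tt$trial[tt$direction_index == direction_index]
  trials <- trials[(trials - 1) * fpt + len <= length(dff)]
  if (!length(trials))
    stop("no trial of this direction has a post-stimulus tail",
         call. = FALSE)
  seg <- vapply(trials, function(tr) dff[(tr - 1) * fpt + seq_len(len)],
                numeric(len))
  rowMeans(seg)
}

#' Summarize half-decay times by group
#'
#' @param half_decays Named list (one numeric vector per group, e.g.
#'   indicator or mouse line) of per-cell half-decay times; `NA`s
#'   (undefined estimates) are dropped.
#' @return Data frame with `group`, `mean_s`, `sd_s` (sample SD; 0 with an
#'   `n1` flag when a group has a single cell), `n`, `n1`.
#' @export
summarize_half_decay <- function(half_decays) {
  groups <- lapply(half_decays, function(v) v[!is.na(v)])
  keep <- lengths(groups) > 0
  if (!all(keep)) {
    warning("dropping empty group(s): ",
            paste(names(groups)[!keep], collapse = ", "), call. = FALSE)
    groups <- groups[keep]
  }
  data.frame(
    group = names(groups),
    mean_s = vapply(groups, mean, numeric(1)),
    sd_s = vapply(groups, function(v) if (length(v) > 1) stats::sd(v) else 0,
                  numeric(1)),
    n = lengths(groups),
    n1 = lengths(groups) == 1L,
    row.names = NULL
  )
}

#' Peak-normalized average transients per group
#'
#' Each trace has its baseline subtracted and is divided by its peak, so
#' every normalized trace peaks at 1; traces are then averaged within each
#' group. Traces with non-positive peaks are skipped with a warning.
#'
#' @param traces_by_group Named list of lists of numeric traces.
#' @param baselines_by_group Matching structure of baseline values; 0 used
#'   when missing.
#' @return Named list of average normalized traces (each with attribute
#'   `n_cells`).
#' @export
peak_normalized_transients <- function(traces_by_group,
                                       baselines_by_group = NULL) {
  out <- list()
  for (g in names(traces_by_group)) {
    trs <- traces_by_group[[g]]
    bls <- if (is.null(baselines_by_group)) rep(0, length(trs))
           else baselines_by_group[[g]]
    normed <- list()
    for (i in seq_along(trs)) {
      x <- trs[[i]] - bls[[i]]
      pk <- max(x)
      if (pk <= 0) {
        warning("skipping trace with non-positive peak in group ", g,
                call. = FALSE)
        next
      }
      normed[[length(normed) + 1]] <- x / pk
    }
    if (!length(normed)) next
    avg <- colMeans(do.call(rbind, normed))
    attr(avg, "n_cells") <- length(normed)
    out[[g]] <- avg
  }
  out
}

#' Kinetics analysis of a population
#'
#' For every responsive cell, averages the trials at its preferred
#' direction, applies the gate, and estimates the half-decay time.
#'
#' @param dff Matrix cells x frames of session dF/F0.
#' @param results Data frame from [analyze_population()].
#' @param protocol A [stimulus_protocol()].
#' @param indicator `"fast"` or `"slow"`.
#' @return Data frame with `cell`, `gated_in`, `half_decay_s`,
#'   `baseline_mean`, `baseline_sd`.
#' @export
kinetics_analysis <- function(dff, results, protocol,
                              indicator = c("fast", "slow")) {
  indicator <- match.arg(indicator)
  out <- data.frame(cell = results$cell, gated_in = FALSE,
                    half_decay_s = NA_real_, baseline_mean = NA_real_,
                    baseline_sd = NA_real_)
  for (i in which(results$kept & results$responsive)) {
    avg <- tryCatch(
      direction_average_extended(dff[i, ], protocol,
                                 results$preferred_index[i]),
      error = function(e) direction_average(dff[i, ], protocol,
                                            results$preferred_index[i]))
    g <- gate_cell(avg, protocol, indicator)
    out$gated_in[i] <- g$gated_in
    out$baseline_mean[i] <- g$baseline_mean
    out$baseline_sd[i] <- g$baseline_sd
    if (g$gated_in)
      out$half_decay_s[i] <- suppressWarnings(
        half_decay_time(avg, protocol, g$baseline_mean))
  }
  out
}
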