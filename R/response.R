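#' Per-trial period means of dF/F0
#'
#' Collapses a cell's session dF/F0 to one scalar per trial per period:
#' the time-mean over the grating frames (`stim_mean`) and over the blank
#' frames (`blank_mean`) of each trial.
#'
#' @param dff Session dF/F0 trace (vector over all frames).
#' @param protocol A [stimulus_protocol()].
#' @return Data frame with `trial`, `direction_index`, `direction_deg`,
#'   `stim_mean`, `blank_mean`.
#' @export
period_means <- function(dff, protocol) {
  if (length(dff) != n_frames_total(protocol))
    stop("dff length does not match the protocol's frame count",
         call. = FALSE)
  if (anyNA(dff))
    stop("dff contains missing frames; period table would be incomplete",
         call. = FALSE)
  tt <- trial_table(protocol)
  fpt <- n_frames_per_trial(protocol)
  m <- matrix(dff, fpt, nrow(tt))          # one column per trial
  sidx <- stim_frames_rel(protocol)
  tt$stim_mean <- colMeans(m[sidx, , drop = FALSE])
  tt$blank_mean <- colMeans(m[-sidx, , drop = FALSE])
  tt[, c("trial", "direction_index", "direction_deg",
         "stim_mean", "blank_mean")]
}

#' One-way fixed-effects ANOVA
#'
#' Classical one-way ANOVA from sums of squares: the F statistic is the
#' between-group mean square over the within-group mean square, with
#' `(k - 1, N - k)` degrees of freedom. When the within-group variance is
#' exactly zero but group means differ, the separation is infinitely
#' significant and `p = 0` is returned by convention; when every value is
#' identical the data are degenerate and an error is raised.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups,
#'   each with >= 2 samples).
#' @return A list with `F`, `p`, `df1`, `df2`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2)
    stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2))
    stop("each group needs at least 2 samples", call. = FALSE)
  all_v <- unlist(groups)
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  gm <- mean(all_v)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1
  df2 <- N - k
  if (ssw == 0) {
    if (ssb == 0)
      stop("degenerate data: all values identical", call. = FALSE)
    return(list(F = Inf, p = 0, df1 = df1, df2 = df2))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

## ANOVA groups for the responsiveness test: blank period means of every
## trial form one group; each direction's stimulus-period means form one
## group each (k = n_directions + 1).
anova_groups <- function(cell_table) {
  dirs <- sort(unique(cell_table$direction_index))
  c(list(blank = cell_table$blank_mean),
    lapply(dirs, function(d)
      cell_table$stim_mean[cell_table$direction_index == d]))
}

#' Classify a cell as visually responsive
#'
#' A cell is visually responsive when (a) its trial-mean dF/F0 exceeds
#' `dff_threshold` during at least one stimulus period (direction), and
#' (b) a one-way ANOVA across the blank and the direction periods rejects
#' at `alpha`. Degenerate ANOVA input yields non-responsive with a
#' warning.
#'
#' @param cell_table Output of [period_means()] for one cell.
#' @param alpha ANOVA significance level (default 0.01).
#' @param dff_threshold Period-mean dF/F0 threshold (default 0.05).
#' @return A list with `responsive`, `anova_p`, `max_period_dff`.
#' @export
classify_responsive <- function(cell_table, alpha = 0.01,
                                dff_threshold = 0.05) {
  dir_means <- tapply(cell_table$stim_mean, cell_table$direction_index,
                      mean)
  max_period <- max(dir_means)
  p <- tryCatch(one_way_anova(anova_groups(cell_table))$p,
                error = function(e) {
                  warning("degenerate ANOVA input; cell marked ",
                          "non-responsive", call. = FALSE)
                  NA_real_
                })
  responsive <- isTRUE(max_period > dff_threshold && !is.na(p) && p < alpha)
  list(responsive = responsive, anova_p = p, max_period_dff = max_period)
}

#' Preferred direction of a cell
#'
#' The direction with the maximal trial-mean stimulus-period dF/F0; exact
#' ties are broken toward the lowest direction index.
#'
#' @param cell_table Output of [period_means()] for one cell.
#' @return A list with `direction_index` and `direction_deg`.
#' @export
preferred_direction <- function(cell_table) {
  dirs <- sort(unique(cell_table$direction_index))
  dir_means <- vapply(dirs, function(d)
    mean(cell_table$stim_mean[cell_table$direction_index == d]), numeric(1))
  best <- dirs[which.max(dir_means)]   # which.max takes the first maximum
  list(direction_index = best,
       direction_deg = cell_table$direction_deg[
         match(best, cell_table$direction_index)])
}

#' Trial-averaged response to one direction
#'
#' Averages a cell's full-trial dF/F0 segments (blank + grating) across
#' the trials of one direction.
#'
#' @param dff Session dF/F0 trace.
#' @param protocol A [stimulus_protocol()].
#' @param direction_index Direction (1-based).
#' @return Numeric vector of length `n_frames_per_trial(protocol)`.
#' @export
direction_average <- function(dff, protocol, direction_index) {
  tt <- trial_table(protocol)
  trials <- tt$trial[tt$direction_index == direction_index]
  fpt <- n_frames_per_trial(protocol)
  seg <- vapply(trials, function(tr) {
    start <- (tr - 1) * fpt
    dff[start + seq_len(fpt)]
  }, numeric(fpt))
  rowMeans(seg)
}

## Frame indices (trial-relative) of the stimulus window.
stim_frames_rel <- function(protocol) {
  nb <- round(protocol$frame_rate * protocol$blank_duration)
  ns <- round(protocol$frame_rate * protocol$stim_duration)
  nb + seq_len(ns)
}

#' Peak dF/F0 of the preferred response
#'
#' Maximum of the trial-averaged dF/F0 over the stimulus window at the
#' cell's preferred direction.
#'
#' @inheritParams direction_average
#' @return Scalar dF/F0.
#' @export
peak_response <- function(dff, protocol, direction_index) {
  avg <- direction_average(dff, protocol, direction_index)
  max(avg[stim_frames_rel(protocol)])
}

#' Population average of preferred responses, maxima aligned
#'
#' For every cell whose preferred-response peak exceeds `min_peak`
#' (default dF/F0 > 1), the trial-averaged preferred trace is shifted by a
#' whole number of frames so that its maximum lands on the nearest of the
#' `anchors` (seconds after grating onset), then traces are averaged
#' across cells. A centered `smooth`-sample moving average is applied for
#' the display trace; the raw average is returned alongside.
#'
#' @param traces List of trial-averaged full-trial dF/F0 traces (one per
#'   cell, preferred direction).
#' @param protocol A [stimulus_protocol()].
#' @param min_peak Minimum peak dF/F0 for inclusion.
#' @param anchors Candidate alignment time points, seconds after grating
#'   onset.
#' @param smooth Moving-average width, samples (odd).
#' @return A list with `average`, `smoothed`, `n_cells`, `shifts`
#'   (frames), or `NULL` when no cell qualifies.
#' @export
mean_preferred_response <- function(traces, protocol, min_peak = 1,
                                    anchors = c(1, 2, 3, 4), smooth = 3) {
  fpt <- n_frames_per_trial(protocol)
  fr <- protocol$frame_rate
  onset <- round(fr * protocol$blank_duration)
  aligned <- list()
  shifts <- integer(0)
  for (tr in traces) {
    pk <- max(tr)
    if (!(pk > min_peak)) next
    i_max <- which.max(tr)
    t_max <- (i_max - 1 - onset) / fr       # seconds after grating onset
    anchor <- anchors[which.min(abs(anchors - t_max))]
    shift <- as.integer(round((anchor - t_max) * fr))
    out <- rep(NA_real_, fpt)
    src <- seq_len(fpt) - shift
    ok <- src >= 1 & src <= fpt
    out[ok] <- tr[src[ok]]
    aligned[[length(aligned) + 1]] <- out
    shifts <- c(shifts, shift)
  }
  if (!length(aligned)) return(NULL)
  mat <- do.call(rbind, aligned)
  avg <- colMeans(mat, na.rm = TRUE)
  sm <- as.numeric(stats::filter(avg, rep(1 / smooth, smooth),
                                 sides = 2))
  list(average = avg, smoothed = sm, n_cells = length(aligned),
       shifts = shifts)
}

#' Amplitude spectrum of preferred-stimulus responses
#'
#' For each cell, the mean-subtracted dF/F0 over the grating window is
#' Fourier transformed (rectangular window, no zero padding; frequency
#' resolution `1 / stim_duration`). Amplitudes are one-sided and scaled so
#' that the sum of squared amplitudes equals the mean-subtracted signal
#' energy (Parseval). The median across cells is taken per frequency bin;
#' the peak is the largest non-DC bin.
#'
#' @param traces List of per-cell dF/F0 traces over the grating window, or
#'   a single numeric vector.
#' @param protocol A [stimulus_protocol()].
#' @return A list with `frequency` (Hz), `amplitude` (median across
#'   cells), `peak_frequency` (Hz), and `per_cell` (matrix cells x bins).
#' @export
response_spectrum <- function(traces, protocol) {
  if (is.numeric(traces)) traces <- list(traces)
  if (protocol$stim_duration * protocol$temporal_frequency < 2)
    stop("stimulus window shorter than 2 grating cycles: frequency ",
         "resolution too coarse", call. = FALSE)
  amps <- lapply(traces, function(x) {
    n <- length(x)
    X <- stats::fft(x - mean(x))
    half <- floor(n / 2)
    a <- numeric(half + 1)
    a[1] <- Mod(X[1]) / sqrt(n)
    for (k in seq_len(half)) {
      a[k + 1] <- if (n %% 2 == 0 && k == half) Mod(X[k + 1]) / sqrt(n)
                  else sqrt(2 / n) * Mod(X[k + 1])
    }
    a
  })
  mat <- do.call(rbind, amps)
  med <- apply(mat, 2, stats::median)
  n <- length(traces[[1]])
  freq <- (0:floor(n / 2)) * protocol$frame_rate / n
  list(frequency = freq, amplitude = med,
       peak_frequency = freq[-1][which.max(med[-1])],
       per_cell = mat)
}

#' Analyze a population dF/F0 matrix
#'
#' Runs [period_means()], [classify_responsive()],
#' [preferred_direction()] and [peak_response()] for every kept cell.
#'
#' @param dff Matrix cells x frames (NA rows allowed for excluded cells).
#' @param protocol A [stimulus_protocol()].
#' @param kept Logical per cell; defaults to rows without NA.
#' @param alpha,dff_threshold Passed to [classify_responsive()].
#' @return Data frame with one row per cell: `cell`, `kept`, `responsive`,
#'   `anova_p`, `max_period_dff`, `preferred_index`, `preferred_deg`,
#'   `peak_dff`.
#' @export
analyze_population <- function(dff, protocol,
                               kept = !apply(is.na(dff), 1, any),
                               alpha = 0.01, dff_threshold = 0.05) {
  n_cells <- nrow(dff)
  out <- data.frame(cell = seq_len(n_cells), kept = kept,
                    responsive = FALSE, anova_p = NA_real_,
                    max_period_dff = NA_real_,
                    preferred_index = NA_integer_,
                    preferred_deg = NA_real_, peak_dff = NA_real_)
  for (i in which(kept)) {
    ct <- period_means(dff[i, ], protocol)
    cl <- classify_responsive(ct, alpha, dff_threshold)
    pref <- preferred_direction(ct)
    out$responsive[i] <- cl$responsive
    out$anova_p[i] <- cl$anova_p
    out$max_period_dff[i] <- cl$max_period_dff
    out$preferred_index[i] <- pref$direction_index
    out$preferred_deg[i] <- pref$direction_deg
    out$peak_dff[i] <- peak_response(dff[i, ], protocol,
                                     pref$direction_index)
  }
  out
}

#' Population summaries across fields of view
#'
#' The responsive fraction is computed per field of view over its
#' analyzable (kept) cells and summarized as mean and sample (n-1) SD
#' across fields. The response distribution is the peak preferred-stimulus
#' dF/F0 of responsive cells.
#'
#' @param results Data frame from [analyze_population()], plus a `fov`
#'   column assigning each cell to one field of view.
#' @return A list with `per_fov` (data frame `fov`, `n_cells`,
#'   `fraction_responsive`), `fraction_mean`, `fraction_sd`, and
#'   `peak_dff_responsive` (numeric vector).
#' @export
population_summaries <- function(results) {
  if (is.null(results$fov))
    stop("results need a 'fov' column", call. = FALSE)
  keep <- results[results$kept, ]
  fovs <- split(keep, keep$fov)
  empty <- vapply(fovs, function(f) nrow(f) == 0, logical(1))
  if (any(empty)) {
    warning("dropping field(s) of view with no analyzable cells",
            call. = FALSE)
    fovs <- fovs[!empty]
  }
  per_fov <- data.frame(
    fov = names(fovs),
    n_cells = vapply(fovs, nrow, integer(1)),
    fraction_responsive = vapply(fovs, function(f) mean(f$responsive),
                                 numeric(1)),
    row.names = NULL
  )
  list(per_fov = per_fov,
       fraction_mean = mean(per_fov$fraction_responsive),
       fraction_sd = stats::sd(per_fov$fraction_responsive),
       peak_dff_responsive = keep$peak_dff[keep$responsive])
}
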