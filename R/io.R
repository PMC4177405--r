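## Sidecar path for a TIFF stack: movie.tif -> movie.yaml
sidecar_path <- function(path) sub("\\.tiff?$", ".yaml", path)

#' Write a movie as multi-page TIFF with a metadata sidecar
#'
#' One 16-bit page per frame; pixel size, frame rate and the intensity
#' scale factor go to a YAML sidecar next to the TIFF. Stacks holding
#' 16-bit integer data (values in 0..65535) round trip losslessly;
#' floating-point data are quantized to 16 bits of their full scale.
#'
#' @param stack A [frame_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- stack$data
  is_int <- max(abs(d - round(d))) < 1e-9 && min(d) >= 0 && max(d) <= 65535
  scale <- if (is_int) 65535 else max(d)
  pages <- lapply(seq_len(dim(d)[3]), function(k)
    pmin(pmax(d[, , k] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  yaml::write_yaml(list(pixel_size_um = stack$pixel_size,
                        frame_rate_hz = stack$frame_rate,
                        intensity_scale = scale,
                        n_frames = dim(d)[3]),
                   sidecar_path(path))
  invisible(path)
}

#' Read a movie written by [write_stack()]
#' @param path TIFF path (sidecar YAML expected alongside).
#' @return A [frame_stack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path))
    stop("stack file not found: ", path, call. = FALSE)
  meta_path <- sidecar_path(path)
  if (!file.exists(meta_path))
    stop("sidecar metadata not found: ", meta_path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop("malformed TIFF '", path, "': ",
                           conditionMessage(e), call. = FALSE))
  meta <- yaml::read_yaml(meta_path)
  scale <- meta$intensity_scale
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    pk <- pages[[k]] * scale
    if (scale == 65535) pk <- round(pk)
    arr[, , k] <- pk
  }
  frame_stack(arr, meta$pixel_size_um, meta$frame_rate_hz)
}

protocol_keys <- c("blank_duration", "stim_duration", "n_directions",
                   "temporal_frequency", "spatial_frequency",
                   "frame_rate", "n_trials_per_direction")

#' Read/write a stimulus protocol as YAML
#'
#' The file holds the protocol constants (`blank_duration`,
#' `stim_duration`, `n_directions`, `temporal_frequency`,
#' `spatial_frequency`, `frame_rate`, `n_trials_per_direction`); unknown
#' keys are rejected with a message.
#'
#' @param path YAML file path.
#' @return For `read_protocol`, a [stimulus_protocol()] (the session
#'   trial table is available via [trial_table()]).
#' @export
read_protocol <- function(path) {
  if (!file.exists(path))
    stop("protocol file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), protocol_keys)
  if (length(unknown))
    stop("unknown protocol key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(stimulus_protocol, vals)
}

#' @rdname read_protocol
#' @param protocol A [stimulus_protocol()].
#' @export
write_protocol <- function(protocol, path) {
  yaml::write_yaml(unclass(protocol)[protocol_keys], path)
  invisible(path)
}

#' Read/write an ROI set as a tabular file
#'
#' CSV with columns `id`, `kind`, `x`, `y`, `inner_r`, `outer_r` (um).
#'
#' @param rois A [roi_set()].
#' @param path CSV path.
#' @export
write_rois <- function(rois, path) {
  df <- data.frame(
    id = seq_along(rois$rois),
    kind = vapply(rois$rois, `[[`, character(1), "kind"),
    x = vapply(rois$rois, `[[`, numeric(1), "center_x"),
    y = vapply(rois$rois, `[[`, numeric(1), "center_y"),
    inner_r = vapply(rois$rois, `[[`, numeric(1), "inner_radius"),
    outer_r = vapply(rois$rois, `[[`, numeric(1), "outer_radius"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rois
#' @param pixel_size,image_size Image geometry the ROIs apply to.
#' @export
read_rois <- function(path, pixel_size, image_size) {
  if (!file.exists(path))
    stop("ROI file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("id", "kind", "x", "y", "inner_r", "outer_r")
  if (!all(need %in% names(df)))
    stop("ROI table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  rois <- lapply(seq_len(nrow(df)), function(i)
    roi(df$x[i], df$y[i], df$outer_r[i], df$inner_r[i], df$kind[i]))
  roi_set(rois, pixel_size, image_size)
}

#' Write/read a traces table
#'
#' Long-format CSV: one row per (cell, frame) with the raw, neuropil,
#' corrected and dF/F0 values.
#'
#' @param measured,neuropil,corrected,dff Matrices/vectors over the
#'   session (cells x frames; `neuropil` a vector).
#' @param path CSV path.
#' @export
write_traces <- function(measured, neuropil, corrected, dff, path) {
  n_cells <- nrow(measured); nf <- ncol(measured)
  df <- data.frame(
    cell = rep(seq_len(n_cells), each = nf),
    frame = rep(seq_len(nf), n_cells),
    raw = as.vector(t(measured)),
    neuropil = rep(neuropil, n_cells),
    corrected = as.vector(t(corrected)),
    dff = as.vector(t(dff)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  if (!file.exists(path))
    stop("traces file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  cells <- sort(unique(df$cell))
  nf <- sum(df$cell == cells[1])
  to_mat <- function(col) {
    m <- matrix(NA_real_, length(cells), nf)
    for (i in seq_along(cells)) m[i, ] <- df[[col]][df$cell == cells[i]]
    m
  }
  list(measured = to_mat("raw"),
       neuropil = df$neuropil[df$cell == cells[1]],
       corrected = to_mat("corrected"), dff = to_mat("dff"))
}

#' Default analysis run configuration
#'
#' @param ... Overrides of the default fields: `mode` ("simulate" or
#'   "stack"), `seed`, `indicator`, `r`, `exclusion_margin`, `alpha`,
#'   `dff_threshold`, `n_cells`, `tuned_fraction`, `protocol` (named list
#'   of [stimulus_protocol()] overrides), `stack_path`, `roi_path`.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(mode = "simulate", seed = 1, indicator = "fast",
              r = 0.7, exclusion_margin = 0.03, alpha = 0.01,
              dff_threshold = 0.05, n_cells = 30, tuned_fraction = 0.5,
              protocol = list(), stack_path = NULL, roi_path = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  utils::modifyList(cfg, over)
}

#' Run the full functional-imaging pipeline
#'
#' Orchestrates the analysis in acquisition order: obtain measured traces
#' (simulate a session, or extract from a movie and ROI set), apply the
#' baseline-over-neuropil exclusion rule, subtract the scaled neuropil,
#' compute per-trial dF/F0, classify responsive cells, estimate kinetics,
#' and write results, summaries, the resolved configuration and a stage
#' log to `out_dir`. Deterministic given the config seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `results`, `kinetics`, `summaries`,
#'   `dff`, `protocol` and the output `paths`.
#' @export
pipeline_run <- function(config = run_config(), out_dir = tempfile("run")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  protocol <- do.call(stimulus_protocol, config$protocol)
  cfg_ana <- correction_config(r = config$r,
                               exclusion_margin = config$exclusion_margin,
                               indicator = config$indicator)
  if (config$mode == "simulate") {
    sim <- simulate_population(config$n_cells, protocol,
                               indicator = config$indicator,
                               tuned_fraction = config$tuned_fraction,
                               seed = config$seed)
    measured <- sim$measured
    neuropil <- sim$neuropil_measured
  } else {
    stack <- read_stack(config$stack_path)
    rois <- read_rois(config$roi_path, stack$pixel_size,
                      dim(stack$data)[1])
    measured <- t(vapply(rois$rois, function(r) extract_trace(stack, r),
                         numeric(dim(stack$data)[3])))
    neuropil <- t(vapply(seq_along(rois$rois), function(i)
      neuropil_trace(stack, rois, i), numeric(dim(stack$data)[3])))
  }
  logf("extracted: %d cells, %d frames", nrow(measured), ncol(measured))

  proc <- process_traces(measured, neuropil, protocol, cfg_ana)
  logf("excluded: %d of %d cells", sum(!proc$kept), nrow(measured))
  corrected <- neuropil_correct(measured,
                                if (is.matrix(neuropil)) colMeans(neuropil)
                                else neuropil, cfg_ana$r)

  results <- analyze_population(proc$dff, protocol, kept = proc$kept,
                                alpha = config$alpha,
                                dff_threshold = config$dff_threshold)
  results$fov <- "fov1"
  logf("responsive: %d of %d analyzable cells",
       sum(results$responsive), sum(results$kept))

  kin <- kinetics_analysis(proc$dff, results, protocol, config$indicator)
  logf("gated for kinetics: %d cells", sum(kin$gated_in))
  summ <- population_summaries(results)

  paths <- list(
    results = file.path(out_dir, "results.csv"),
    kinetics = file.path(out_dir, "kinetics.csv"),
    traces = file.path(out_dir, "traces.csv"),
    summary = file.path(out_dir, "summary.yaml"),
    config = file.path(out_dir, "config.yaml"))
  utils::write.csv(results, paths$results, row.names = FALSE)
  utils::write.csv(kin, paths$kinetics, row.names = FALSE)
  write_traces(measured,
               if (is.matrix(neuropil)) colMeans(neuropil) else neuropil,
               corrected, proc$dff, paths$traces)
  yaml::write_yaml(list(
    n_cells = nrow(measured),
    n_excluded = sum(!proc$kept),
    n_responsive = sum(results$responsive),
    n_gated = sum(kin$gated_in),
    fraction_responsive_mean = summ$fraction_mean,
    fraction_responsive_sd = summ$fraction_sd,
    half_decay_mean_s = mean(kin$half_decay_s, na.rm = TRUE)),
    paths$summary)
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))],
                   paths$config)
  invisible(list(results = results, kinetics = kin, summaries = summ,
                 dff = proc$dff, protocol = protocol, paths = paths))
}
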