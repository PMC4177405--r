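# Traces here are trial-shaped vectors (blank + stimulus, optionally a
# post-stimulus tail), built directly to known shapes.

make_decay_trace <- function(protocol, tau, post_s = 4, peak = 1) {
  fr <- protocol$frame_rate
  fpt <- n_frames_per_trial(protocol)
  n_post <- round(fr * post_s)
  t <- (seq_len(fpt + n_post) - 1) / fr
  onset <- protocol$blank_duration
  offset <- onset + protocol$stim_duration
  t_peak <- (fpt - 1) / fr           # last stimulus sample
  x <- numeric(fpt + n_post)
  stim <- t >= onset & t <= t_peak
  x[stim] <- peak * (t[stim] - onset) / (t_peak - onset)  # ramp to peak
  x[t > t_peak] <- peak * exp(-(t[t > t_peak] - t_peak) / tau)
  x
}

test_that("the 5-SD gate admits driven cells and rejects flat ones", {
  p <- stimulus_protocol()
  set.seed(11)
  noise <- rnorm(n_frames_per_trial(p), sd = 0.01)
  driven <- noise
  driven[popcal:::stim_frames_rel(p)] <- driven[
    popcal:::stim_frames_rel(p)] + 0.5
  g <- gate_cell(driven, p, "fast")
  expect_true(g$gated_in)
  expect_gt(g$response_mean, g$baseline_mean + 5 * g$baseline_sd)
  expect_false(gate_cell(noise, p, "fast")$gated_in)
  # noise-free case degenerates to mean response > baseline
  flat <- rep(1, n_frames_per_trial(p))
  expect_false(gate_cell(flat, p, "fast")$gated_in)
  step <- flat
  step[popcal:::stim_frames_rel(p)] <- 1.2
  expect_true(gate_cell(step, p, "fast")$gated_in)
})

test_that("half-decay of exponential tails matches tau * ln 2", {
  p <- stimulus_protocol()
  for (tau in c(0.1, 0.2, 0.5, 1.0, 2.0)) {
    x <- make_decay_trace(p, tau, post_s = max(4, 3 * tau))
    est <- half_decay_time(x, p, baseline_mean = 0)
    oracle <- dense_half_decay(function(t) exp(-t / tau) * (t >= 0),
                               t_max = 10 * tau)
    expect_equal(oracle, tau * log(2), tolerance = 1e-3)
    tol <- max(1 / p$frame_rate, 0.02 * tau * log(2))
    expect_lt(abs(est - tau * log(2)), tol)
    expect_lt(abs(est - oracle), tol)
  }
})

test_that("linear ramps decay to half peak in exactly half the ramp time", {
  p <- stimulus_protocol()
  fr <- p$frame_rate
  fpt <- n_frames_per_trial(p)
  x <- numeric(fpt + 60)
  x[fpt] <- 1                              # peak at last stimulus sample
  ramp <- seq(1, 0, length.out = fr + 1)   # to baseline over 1 s
  x[fpt:(fpt + fr)] <- ramp
  expect_equal(half_decay_time(x, p, baseline_mean = 0,
                               last_cycle = FALSE), 0.5,
               tolerance = 1e-12)
})

test_that("traces clamped at peak give an undefined half-decay", {
  p <- stimulus_protocol()
  x <- numeric(n_frames_per_trial(p) + 60)
  x[popcal:::stim_frames_rel(p)] <- 1
  x[(n_frames_per_trial(p) + 1):length(x)] <- 1   # never decays
  expect_warning(hd <- half_decay_time(x, p, baseline_mean = 0),
                 "undefined")
  expect_true(is.na(hd))
})

test_that("half-decay is invariant under affine brightness transforms", {
  p <- stimulus_protocol()
  x <- make_decay_trace(p, 0.5)
  h0 <- half_decay_time(x, p, baseline_mean = 0)
  for (ab in list(c(2, 0), c(0.5, 10), c(3, -4))) {
    y <- ab[1] * x + ab[2]
    expect_equal(half_decay_time(y, p, baseline_mean = ab[2]), h0,
                 tolerance = 1e-12)
  }
})

test_that("estimator bias shrinks as the frame rate grows", {
  tau <- 0.3
  true_hd <- tau * log(2)
  bias <- vapply(c(15, 30, 60), function(fr) {
    p <- stimulus_protocol(frame_rate = fr)
    x <- make_decay_trace(p, tau)
    abs(half_decay_time(x, p, baseline_mean = 0) - true_hd)
  }, numeric(1))
  expect_true(all(diff(bias) <= 1e-9))
})

test_that("half-decay summaries report mean, sample SD and counts", {
  s <- summarize_half_decay(list(fast = c(0.1, 0.3), single = 0.2))
  expect_equal(s$mean_s, c(0.2, 0.2))
  expect_equal(s$sd_s[1], sqrt(0.02), tolerance = 1e-12)  # 0.1414
  expect_equal(s$sd_s[2], 0)
  expect_equal(s$n, c(2L, 1L))
  expect_equal(s$n1, c(FALSE, TRUE))
  expect_warning(s2 <- summarize_half_decay(list(a = c(0.2), b = NA_real_)),
                 "empty")
  expect_equal(s2$group, "a")
})

test_that("peak normalization yields unit peaks and preserves ordering", {
  p <- stimulus_protocol()
  fast <- make_decay_trace(p, 0.2)
  slow <- make_decay_trace(p, 1.0)
  out <- peak_normalized_transients(list(f = list(fast, 2 * fast),
                                         s = list(slow)))
  expect_equal(max(out$f), 1.0)
  expect_equal(max(out$s), 1.0)
  # identical up to scale: the average equals each normalized trace
  expect_equal(out$f, structure(fast / max(fast), n_cells = 2L))
  # slower decay stays above the faster one after the peak
  i_pk <- which.max(out$f)
  post <- (i_pk + 2):(i_pk + 20)
  expect_true(all(out$s[post] >= out$f[post]))
  expect_warning(peak_normalized_transients(list(g = list(-fast))),
                 "non-positive")
})

test_that("simulated fast populations decay faster than slow ones", {
  p <- stimulus_protocol(n_trials_per_direction = 5)
  means <- sapply(c("fast", "slow"), function(ind) {
    sim <- simulate_population(8, p, scene = scene_model(n_cells = 8),
                               indicator = ind, tuned_fraction = 1,
                               seed = 31)
    proc <- process_traces(sim$measured, sim$neuropil_measured, p,
                           correction_config(indicator = ind))
    res <- analyze_population(proc$dff, p)
    kin <- kinetics_analysis(proc$dff, res, p, ind)
    mean(kin$half_decay_s, na.rm = TRUE)
  })
  expect_lt(means["fast"], means["slow"])
})
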