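test_that("zero-rate tuning yields zero spikes in every trial", {
  p <- tiny_protocol()
  tun <- tuning_model(baseline_rate = 0, peak_rate = 0, is_tuned = FALSE)
  sp <- generate_spike_trains(tun, p, seed = 1)
  expect_length(sp$times, 0)
  expect_true(all(lengths(spikes_by_trial(sp)) == 0))
})

test_that("homogeneous spike counts match the rate integral", {
  # 5 spikes/s over one 8 s trial: E[count] = 40; Monte Carlo mean across
  # 1000 seeded repeats must fall within 3 standard errors of 40
  p <- stimulus_protocol(n_directions = 1, n_trials_per_direction = 1)
  tun <- tuning_model(baseline_rate = 5, peak_rate = 5, is_tuned = FALSE)
  counts <- vapply(1:1000, function(s)
    length(generate_spike_trains(tun, p, seed = s)$times), numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 40), 3 * se)
})

test_that("spike generation is deterministic under a fixed seed", {
  p <- tiny_protocol()
  tun <- tuning_model(preferred_direction = 45)
  a <- generate_spike_trains(tun, p, seed = 42)
  b <- generate_spike_trains(tun, p, seed = 42)
  expect_identical(a$times, b$times)
  sim1 <- simulate_population(3, p, scene = tiny_scene(n_cells = 3),
                              seed = 7)
  sim2 <- simulate_population(3, p, scene = tiny_scene(n_cells = 3),
                              seed = 7)
  expect_identical(sim1$measured, sim2$measured)
  expect_identical(sim1$ground_truth$cyto, sim2$ground_truth$cyto)
})

test_that("tuned rates modulate at the grating frequency and direction", {
  p <- stimulus_protocol()
  tun <- tuning_model(preferred_direction = 90, tuning_width = 4,
                      baseline_rate = 1, peak_rate = 20,
                      modulation_depth = 0.5)
  rate <- popcal:::rate_function(tun, p)
  tt <- trial_table(p)
  pref_trial <- tt$trial[tt$direction_deg == 90][1]
  t_on <- tt$stim_start[pref_trial]
  # sinusoid phase: rate at modulation peak (t + 0.25 s) > at trough
  expect_gt(rate(t_on + 0.25), rate(t_on + 0.75))
  # preferred direction drives harder than orthogonal
  orth_trial <- tt$trial[tt$direction_deg == 0][1]
  expect_gt(rate(t_on + 0.25), rate(tt$stim_start[orth_trial] + 0.25))
  # blank periods sit at baseline
  expect_equal(rate(tt$blank_start[pref_trial] + 1), 1)
})

test_that("kernel half-decay equals the model value on a dense grid", {
  for (spec in list(c(0.02, 0.14), c(0.08, 0.51), c(0.05, 1.0))) {
    kin <- kinetics_model(rise_time = spec[1], decay_half_time = spec[2],
                          amplitude_per_spike = 0.2)
    k <- fluorescence_kernel(kin)
    hd <- dense_half_decay(k$fn, t_max = 10 * spec[2] + 1)
    expect_equal(hd, spec[2], tolerance = 2e-3)
  }
})

test_that("fluorescence is baseline plus linear superposition of kernels", {
  p <- tiny_protocol()
  kin <- indicator_preset("fast")
  # no spikes: constant baseline
  f0 <- spikes_to_fluorescence(numeric(0), kin, p)
  expect_equal(f0, rep(kin$baseline_fluorescence, n_frames_total(p)))
  # single spike: post-peak half-decay within one frame of the model value
  f1 <- spikes_to_fluorescence(2.0, kin, p)
  d1 <- f1 - kin$baseline_fluorescence
  pk <- which.max(d1)
  t <- frame_times(p)
  below <- which(d1 <= d1[pk] / 2 & seq_along(d1) > pk)[1]
  hd_lo <- t[below - 1] - t[pk]
  hd_hi <- t[below] - t[pk]
  expect_lte(hd_lo, kin$decay_half_time + 1 / p$frame_rate)
  expect_gte(hd_hi, kin$decay_half_time - 1 / p$frame_rate)
  # two simultaneous spikes: exactly twice the single transient
  f2 <- spikes_to_fluorescence(c(2.0, 2.0), kin, p)
  expect_equal(f2 - kin$baseline_fluorescence, 2 * d1, tolerance = 1e-12)
})

test_that("measurement composition adds scaled neuropil and nothing else", {
  p <- tiny_protocol()
  sc0 <- tiny_scene(contamination_ratio_true = 0, noise_sd_frac = 0)
  cyto <- matrix(rnorm(4 * n_frames_total(p), 100, 5), 4)
  npil <- rep(80, n_frames_total(p))
  m0 <- compose_measurement(cyto, npil, sc0)
  expect_identical(m0$measured, cyto)
  sc7 <- tiny_scene(contamination_ratio_true = 0.7, noise_sd_frac = 0)
  m7 <- compose_measurement(cyto, npil, sc7)
  expect_equal(m7$measured, cyto + 0.7 * 80, tolerance = 1e-12)
  expect_error(compose_measurement(cyto, npil[-1], sc0), "frame grid")
})

test_that("scene defaults describe a 512 px / 250 um field of view", {
  sc <- scene_model()
  expect_equal(sc$image_size, 512L)
  expect_equal(sc$field_of_view, 250)
  expect_equal(sc$contamination_ratio_true, 0.7)
})

test_that("rendered movies invert to the composed traces", {
  p <- tiny_protocol()
  sc <- tiny_scene(noise_sd_frac = 0)
  sim <- simulate_population(4, p, scene = sc, tuned_fraction = 1,
                             seed = 5)
  mv <- render_movie(sim, seed = 9)
  d <- dim(mv$stack$data)
  expect_equal(d, c(128, 128, n_frames_total(p)))
  expect_equal(mv$stack$pixel_size, 60 / 128)
  for (i in seq_len(4)) {
    tr <- extract_trace(mv$stack, mv$rois$rois[[i]])
    expect_gt(cor(tr, sim$measured[i, ]), 0.999)
  }
  # at default noise the neuropil ROI still tracks the true neuropil field
  scn <- tiny_scene()
  simn <- simulate_population(4, p, scene = scn, tuned_fraction = 1,
                              seed = 5)
  mvn <- render_movie(simn, seed = 9)
  np <- neuropil_trace(mvn$stack, mvn$rois, 1, radius = 20)
  expect_gt(cor(np, simn$ground_truth$neuropil), 0.95)
})

test_that("soma placement refuses impossible densities", {
  sc <- scene_model(field_of_view = 30, image_size = 64, n_cells = 50)
  expect_error(place_cells(sc, seed = 1, max_tries = 50),
               "non-overlapping")
})

test_that("histology generator honors the labeled fraction limits", {
  h0 <- generate_histology_image(n_cells = 12, labeled_fraction = 0,
                                 image_size = 256, seed = 2)
  expect_false(any(h0$truth$labeled))
  # empty green channel: only background and noise remain
  expect_lt(max(h0$green), 0.15)
  h1 <- generate_histology_image(n_cells = 12, labeled_fraction = 1,
                                 image_size = 256, seed = 2)
  expect_true(all(h1$truth$labeled))
  expect_equal(nrow(h1$truth), 12)
})
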