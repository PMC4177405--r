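test_that("period means collapse each trial to stimulus/blank scalars", {
  p <- tiny_protocol()
  pm0 <- period_means(rep(0, n_frames_total(p)), p)
  expect_equal(pm0$stim_mean, rep(0, 4))
  expect_equal(pm0$blank_mean, rep(0, 4))
  # dff = 1 during direction 2 stimulus frames only
  x <- rep(0, n_frames_total(p))
  tt <- trial_table(p)
  for (tr in tt$trial[tt$direction_index == 2])
    x[trial_frames(p, tr, "stim")] <- 1
  pm <- period_means(x, p)
  expect_equal(pm$stim_mean[pm$direction_index == 2], c(1, 1))
  expect_equal(pm$stim_mean[pm$direction_index == 1], c(0, 0))
  expect_equal(pm$blank_mean, rep(0, 4))
  expect_error(period_means(x[-1], p), "frame count")
})

test_that("one-way ANOVA matches the sums-of-squares oracle exactly", {
  fixtures <- list(
    list(g = list(c(1, 2), c(1, 2), c(1, 2))),
    list(g = list(c(0.1, 0.5, 0.3), c(0.9, 1.2), c(-0.2, 0.4, 0.1, 0.0))),
    list(g = split(rnorm(45), rep(1:9, each = 5))))
  set.seed(8)
  for (f in fixtures) {
    res <- one_way_anova(f$g)
    # independent route: stats::oneway.test with equal variances
    df <- data.frame(v = unlist(f$g),
                     grp = factor(rep(seq_along(f$g), lengths(f$g))))
    ref <- oneway.test(v ~ grp, df, var.equal = TRUE)
    expect_equal(res$F, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
    expect_equal(res$df1, unname(ref$parameter[1]))
    expect_equal(res$df2, unname(ref$parameter[2]))
  }
  # identically distributed groups cannot look significant
  expect_gt(one_way_anova(list(c(1, 2), c(1, 2), c(1, 2)))$p, 0.5)
})

test_that("degenerate ANOVA input follows the stated conventions", {
  # zero within-group variance with unequal means: p = 0
  res <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_equal(res$p, 0)
  expect_equal(res$F, Inf)
  # all values identical: degenerate-data error
  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "degenerate")
  expect_error(one_way_anova(list(c(1, 2))), "2 groups")
  expect_error(one_way_anova(list(c(1, 2), 3)), "2 samples")
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(123)
  ps <- replicate(4000, one_way_anova(split(rnorm(45),
                                            rep(1:9, each = 5)))$p)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("responsiveness needs both the dF/F threshold and the ANOVA", {
  p <- stimulus_protocol()
  set.seed(5)
  # strong, reliable response in one direction
  x <- trace_with_stim(p, base = 0, lvl = 0, trials = integer(0))
  tt <- trial_table(p)
  resp_trials <- tt$trial[tt$direction_index == 3]
  x[unlist(lapply(resp_trials, trial_frames, protocol = p,
                  period = "stim"))] <- 0.5
  x <- x + rnorm(length(x), sd = 0.01)
  cl <- classify_responsive(period_means(x, p))
  expect_true(cl$responsive)
  expect_lt(cl$anova_p, 0.01)
  # same reliability but amplitude capped at 0.04: never responsive
  x2 <- x / 12.5
  cl2 <- classify_responsive(period_means(x2, p))
  expect_false(cl2$responsive)
  expect_lt(cl2$max_period_dff, 0.05)
  expect_lt(cl2$anova_p, 0.01)     # significant but sub-threshold
  # constant dff across all periods: degenerate -> non-responsive
  expect_warning(
    cl3 <- classify_responsive(period_means(rep(0.2,
                                                n_frames_total(p)), p)),
    "degenerate")
  expect_false(cl3$responsive)
})

test_that("responsiveness is monotone in response scale", {
  p <- stimulus_protocol()
  set.seed(6)
  x <- rep(0, n_frames_total(p))
  tt <- trial_table(p)
  for (tr in tt$trial[tt$direction_index == 1])
    x[trial_frames(p, tr, "stim")] <- 0.07
  x <- x + rnorm(length(x), sd = 0.02)
  base_cl <- classify_responsive(period_means(x, p))
  if (base_cl$responsive) {
    for (c_scale in c(1.5, 3, 10)) {
      # scale the stimulus-locked signal, keep the noise fixed
      xs <- x
      for (tr in tt$trial[tt$direction_index == 1]) {
        idx <- trial_frames(p, tr, "stim")
        xs[idx] <- xs[idx] + (c_scale - 1) * 0.07
      }
      expect_true(classify_responsive(period_means(xs, p))$responsive)
    }
  }
})

test_that("preferred direction takes the maximal mean with low-index ties", {
  p <- stimulus_protocol()
  x <- rep(0, n_frames_total(p))
  tt <- trial_table(p)
  for (tr in tt$trial[tt$direction_index == 5])
    x[trial_frames(p, tr, "stim")] <- 1
  pref <- preferred_direction(period_means(x, p))
  expect_equal(pref$direction_index, 5)
  expect_equal(pref$direction_deg, 180)
  # exact two-way tie between directions 2 and 6: lower index wins
  for (tr in tt$trial[tt$direction_index == 2])
    x[trial_frames(p, tr, "stim")] <- 1
  x[x == 1] <- 1  # identical means by construction
  pref2 <- preferred_direction(period_means(x, p))
  expect_equal(pref2$direction_index, 2)
})

test_that("preferred-response averaging aligns maxima to anchors", {
  p <- stimulus_protocol()
  fpt <- n_frames_per_trial(p)
  onset <- 60
  make_trace <- function(t_peak_s, peak = 2) {
    x <- rep(0, fpt)
    i <- onset + round(t_peak_s * 15) + 1
    x[i] <- peak
    x
  }
  # maximum already at 2.0 s: no shift
  r1 <- mean_preferred_response(list(make_trace(2)), p)
  expect_equal(r1$shifts, 0L)
  # maximum at 2.4 s: aligned to the 2 s anchor (nearest)
  r2 <- mean_preferred_response(list(make_trace(2.4)), p)
  expect_equal(r2$shifts, as.integer(round(-0.4 * 15)))
  expect_equal(which.max(r2$average), onset + 2 * 15 + 1)
  # averaging identical traces returns the trace itself
  tr <- make_trace(1.0)
  rN <- mean_preferred_response(rep(list(tr), 5), p)
  expect_equal(rN$average, tr)
  expect_equal(rN$n_cells, 5)
  # sub-threshold peaks yield an empty result
  expect_null(mean_preferred_response(list(0.5 * tr), p))
})

test_that("spectra resolve the grating frequency and respect Parseval", {
  p <- stimulus_protocol()
  t <- (0:59) / 15
  tone <- sin(2 * pi * 1 * t)
  sp <- response_spectrum(tone, p)
  expect_equal(sp$peak_frequency, 1)
  expect_equal(sp$frequency[2] - sp$frequency[1], 0.25)
  # constant trace: all non-DC amplitudes vanish
  sp0 <- response_spectrum(rep(3, 60), p)
  expect_equal(max(sp0$amplitude), 0, tolerance = 1e-12)
  # Parseval: sum of squared amplitudes = mean-subtracted energy
  set.seed(9)
  for (k in 1:5) {
    x <- rnorm(60)
    spx <- response_spectrum(x, p)
    expect_equal(sum(spx$amplitude^2), sum((x - mean(x))^2),
                 tolerance = 1e-6)
  }
  short <- stimulus_protocol(stim_duration = 1, blank_duration = 1)
  expect_error(response_spectrum(rep(1, 15), short), "cycles")
})

test_that("population summaries use per-FOV fractions with sample SD", {
  res <- data.frame(cell = 1:20, kept = TRUE,
                    responsive = c(rep(c(TRUE, rep(FALSE, 4)), 2),
                                   rep(c(TRUE, TRUE, FALSE, FALSE,
                                         FALSE), 2)),
                    peak_dff = runif(20),
                    fov = rep(c("a", "b"), each = 10))
  s <- population_summaries(res)
  expect_equal(s$per_fov$fraction_responsive, c(0.2, 0.4))
  expect_equal(s$fraction_mean, 0.3)
  expect_equal(s$fraction_sd, sqrt(0.02), tolerance = 1e-12) # 0.1414
  expect_length(s$peak_dff_responsive, 6)
  # all-responsive limit
  res$responsive <- TRUE
  s2 <- population_summaries(res)
  expect_equal(s2$fraction_mean, 1)
  expect_equal(s2$fraction_sd, 0)
})
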