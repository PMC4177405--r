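# Shared fixtures: small protocols and scenes keep the suite fast while
# preserving the default timing structure where it matters.

default_protocol <- function() stimulus_protocol()

# 2 directions x 2 trials: 8 s trials, 480 frames per session
tiny_protocol <- function(n_directions = 2, n_trials = 2)
  stimulus_protocol(n_directions = n_directions,
                    n_trials_per_direction = n_trials)

tiny_scene <- function(..., n_cells = 4)
  scene_model(field_of_view = 60, image_size = 128, n_cells = n_cells, ...)

# Constant-valued session trace except for chosen frames
constant_trace <- function(protocol, value = 1) {
  rep(value, n_frames_total(protocol))
}

# Independent dense-grid half-decay oracle: builds the same decay shape on
# a 1 kHz grid and interpolates the half crossing there.
dense_half_decay <- function(decay_fn, t_max = 10, dt = 1e-4) {
  t <- seq(0, t_max, by = dt)
  x <- decay_fn(t)
  pk <- max(x)
  j <- which(x <= pk / 2 & t > t[which.max(x)])[1]
  i <- j - 1
  t[i] + (x[i] - pk / 2) / (x[i] - x[j]) * dt - t[which.max(x)]
}

# Session trace that is `base` everywhere and `base * lvl` during the
# stimulus frames of the given trials.
trace_with_stim <- function(protocol, base, lvl, trials) {
  x <- rep(base, n_frames_total(protocol))
  for (tr in trials)
    x[trial_frames(protocol, tr, "stim")] <- base * lvl
  x
}
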