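# Shared synthetic fixtures, built in code at test time.

small_config <- function(seed = 1L, n_trials = 3, duration_s = 2,
                         movements = default_movements(), noise_rms = 0.1) {
  synth_config(movements = movements, n_trials = n_trials,
               duration_s = duration_s, noise_rms = noise_rms, seed = seed)
}

# Four movements, two strong with distinct channel patterns and two weak with
# amplitudes near the noise floor, under slow force fluctuation: exercises the
# weak-signal discrimination mechanism the nonlinear-scaling features target
# (multiplicative within-class amplitude variability that log scaling
# stabilizes).
weak_movement_config <- function(seed = 1L, n_trials = 6, duration_s = 5,
                                 force_jitter_sd = 0.5) {
  movs <- c("S1", "S2", "W1", "W2")
  amps <- matrix(c(1.0, 0.6,
                   0.6, 1.0,
                   0.06, 0.06,
                   0.10, 0.10),
                 ncol = 2, byrow = TRUE, dimnames = list(movs, NULL))
  synth_config(movements = movs, amplitudes = amps, n_trials = n_trials,
               duration_s = duration_s, noise_rms = 0.05,
               force_jitter_sd = force_jitter_sd, seed = seed)
}

# Trial-level label permutation preserving the (movement, trial_index)
# balance: within each trial_index, movement labels are permuted across
# trials.
shuffle_trial_labels <- function(fm) {
  key <- paste(fm$label, fm$trial)
  for (t in unique(fm$trial)) {
    labs <- unique(fm$label[fm$trial == t])
    newlabs <- sample(labs)
    map <- stats::setNames(newlabs, labs)
    sel <- fm$trial == t
    fm$label[sel] <- unname(map[fm$label[sel]])
  }
  fm
}

random_window <- function(n = 500) {
  stats::rnorm(n, sd = stats::runif(1, 0.05, 2))
}
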