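# shared fixtures: everything is generated in code at test time

# low-noise simulation conditions used for learnability checks
test_sim_params <- function(effect_size = 3) {
  sim_params(effect_size = effect_size, noise_sd = 0.05, drift_sd = 0.02)
}

# a small labeled segment set built from simulated series
make_segments <- function(n_deceptive, n_truthful, effect_size = 3,
                          seed = 42) {
  build_segments(simulate_dataset(n_deceptive, n_truthful,
                                  test_sim_params(effect_size),
                                  seed = seed))
}

# fast training settings for tests: few epochs, small batches, no
# validation split (the data used in tests are strongly separable)
fast_control <- function(epochs = 2L, batch = 8L) {
  train_config(max_epochs = epochs, batch_size = batch,
               validation_fraction = 0)
}

# oracle statistic for the simulator: mean skin-conductance elevation in
# relevant windows minus comparison windows, averaged per chart
sc_elevation <- function(rec) {
  sc <- rec$channels$skin_conductance
  ev <- rec$events
  win <- function(onset) mean(extract_window(sc, onset))
  rel <- ev$onset_s[ev$kind == "relevant"]
  cmp <- ev$onset_s[ev$kind == "comparison"]
  mean(vapply(rel, win, numeric(1))) - mean(vapply(cmp, win, numeric(1)))
}
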