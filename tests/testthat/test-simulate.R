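test_that("simulation is deterministic in (args, seed) and varies with seed", {
  p <- sim_params()
  a <- simulate_chart("deceptive", p, seed = 7)
  b <- simulate_chart("deceptive", p, seed = 7)
  expect_identical(a, b)
  c <- simulate_chart("deceptive", p, seed = 8)
  expect_false(identical(a$channels$ppg, c$channels$ppg))
  # structure is seed-invariant
  expect_identical(a$events, c$events)
})

test_that("dataset counts follow the series/chart/question-set structure", {
  ds <- simulate_dataset(0, 1, sim_params(), seed = 1)
  expect_length(ds$recordings, 3L)
  expect_identical(nrow(ds$manifest), 3L)
  segs <- build_segments(ds)
  expect_identical(length(segs), 9L)
  expect_true(all(segs$label == "truthful"))

  two <- simulate_dataset(1, 0, sim_params(), seed = 2)
  two2 <- simulate_dataset(1, 0, sim_params(), seed = 3)
  expect_identical(two$manifest, two2$manifest)
  expect_false(identical(two$recordings[[1]]$channels,
                         two2$recordings[[1]]$channels))
})

test_that("noiseless skin-conductance transients peak at tonic + amplitude", {
  # amplitude jitter off, noise and drift off: the relevant-question
  # transient of pair 3 peaks at tonic (8) + gain (1.5) x amplitude (1),
  # up to kernel discretization and tails of earlier responses
  p <- sim_params(effect_size = 0, noise_sd = 0, drift_sd = 0,
                  amp_jitter_sd = 0)
  rec <- simulate_chart("deceptive", p, seed = 1)
  ev <- rec$events
  onset <- ev$onset_s[ev$kind == "relevant" & ev$pair_id == 3]
  w <- extract_window(rec$channels$skin_conductance, onset)
  # closed-form peak of the normalized bi-exponential is 1 by construction;
  # dense evaluation confirms the discrete max matches
  tt <- seq(0, 20, by = 1 / 400)
  expect_equal(max(response_kernel(tt, 0.75, 4)), 1, tolerance = 1e-6)
  expect_equal(max(w), 8 + 1.5, tolerance = 0.01)
})

test_that("zero effect size makes relevant and comparison responses indistinguishable", {
  p <- sim_params(effect_size = 0, truthful_ratio = 1)
  dd <- replicate(60, NA_real_)
  for (i in seq_along(dd))
    dd[i] <- sc_elevation(simulate_chart("deceptive", p, seed = 1000 + i))
  se <- sd(dd) / sqrt(length(dd))
  expect_lt(abs(mean(dd)), 3 * se)
})

test_that("the relevant-vs-comparison contrast increases with effect size", {
  # Monte-Carlo oracle over >= 100 series: per-series mean skin-conductance
  # elevation must rise strictly with effect_size, tolerance 3 SE
  series_stat <- function(es, seed) {
    p <- sim_params(effect_size = es)
    mean(vapply(1:3, function(j)
      sc_elevation(simulate_chart("deceptive", p,
                                  seed = derive_seed(seed, j))),
      numeric(1)))
  }
  n <- 34
  stats <- sapply(c(0, 1, 2), function(es)
    vapply(seq_len(n), function(i) series_stat(es, 500 * es + i),
           numeric(1)))
  m <- colMeans(stats)
  se <- apply(stats, 2, sd) / sqrt(n)
  expect_lt(abs(m[1]), 3 * se[1])                      # ~0 at zero effect
  expect_gt(m[2] - m[1], 3 * sqrt(se[1]^2 + se[2]^2))  # strictly increasing
  expect_gt(m[3] - m[2], 3 * sqrt(se[2]^2 + se[3]^2))
})

test_that("all traces are finite with exact chart length", {
  for (cond in c("deceptive", "truthful")) {
    rec <- simulate_chart(cond, sim_params(), seed = 77)
    for (ch in rec$channels) {
      expect_true(all(is.finite(ch)))
      expect_length(ch, 9600L)
    }
  }
})

test_that("invalid simulation parameters are rejected", {
  expect_error(sim_params(effect_size = -1), "nonnegative")
  expect_error(sim_params(heart_rate_hz = 0), "positive")
  expect_error(sim_params(chart_duration_s = 100), "too short")
  expect_error(sim_params(truthful_ratio = 1.5), "truthful_ratio")
})
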