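test_that("the default architecture derives the printed shape chain", {
  arch <- arch_config()
  expect_identical(css_shape_chain(arch), c(1792L, 861L, 406L, 188L, 89L))
  expect_identical(arch$time_steps, 89L)
  expect_identical(arch$merged_features, 50L)
  expect_identical(arch$flatten_len, 4450L)
})

test_that("conv/pool arithmetic is validated at configuration time", {
  # pooling floors odd lengths, so 1793 also lands on 89 steps
  expect_identical(arch_config(input_len = 1793L)$time_steps, 89L)
  # 1808 -> 90 steps: refused, reporting the derived length
  expect_error(arch_config(input_len = 1808L), "90 time steps")
  expect_error(arch_config(conv_filters = c(70, 50)), "equal length")
  expect_error(arch_config(dropout_rates = c(1, .5, .25, .25)),
               "dropout_rates")
})

test_that("softmax outputs are normalized probabilities", {
  m <- css_build(seed = 1)
  segs <- make_segments(1, 0, seed = 8)
  pm <- predict(m, segs, type = "matrix")
  expect_identical(dim(pm), c(9L, 2L))
  expect_true(all(abs(rowSums(pm) - 1) < 1e-6))
  expect_true(all(pm >= 0 & pm <= 1))
  p <- predict_proba(m, segs)
  expect_equal(p, unname(pm[, "deceptive"]))
})

test_that("inference is deterministic (dropout disabled)", {
  m <- css_build(seed = 2)
  segs <- make_segments(1, 0, seed = 9)
  expect_identical(predict(m, segs), predict(m, segs))
})

test_that("the five branches have identical parameter counts and merge to 50 features", {
  m <- css_build(seed = 3)
  s <- summary(m)
  expect_length(s$parameters_per_branch, 5L)
  expect_length(unique(s$parameters_per_branch), 1L)
  # 4 conv blocks per branch
  expect_length(m$weights$conv[[1]], 4L)
  # merged feature width = 5 branches x 10 filters = LSTM input size
  expect_identical(nrow(m$weights$lstm$Wx), 50L)
})

test_that("training rejects invalid inputs", {
  segs <- make_segments(1, 1, seed = 12)
  only_dec <- segs[which(segs$label == "deceptive")]
  expect_error(css_fit(only_dec, control = fast_control()), "single class")
  expect_error(css_fit(segs, arch = arch_config(input_len = 896L,
                                                expected_time_steps = NULL),
                       control = fast_control()),
               "does not match")
})

test_that("training is seeded and reproducible", {
  segs <- make_segments(1, 1, seed = 13)
  ctl <- fast_control(epochs = 1L)
  f1 <- css_fit(segs, control = ctl, seed = 99)
  f2 <- css_fit(segs, control = ctl, seed = 99)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$training$train_loss, f2$training$train_loss)
  expect_identical(predict(f1, segs), predict(f2, segs))
})

test_that("separable synthetic data are fit to low cross-entropy", {
  # strongly separated segments (effect size 3, low noise); the training
  # loss must collapse and never diverge or go non-finite
  segs <- make_segments(4, 4, seed = 14)   # 72 segments
  fit <- css_fit(segs, control = fast_control(), seed = 7)
  tl <- fit$training$train_loss
  expect_true(all(is.finite(tl)))
  expect_lte(tl[length(tl)], tl[1])        # non-divergence contract
  expect_lt(tl[length(tl)], 0.3)
  # held-out deceptive segments from fresh series score above 0.5
  held <- make_segments(1, 1, seed = 15)
  p <- predict_proba(fit, held)
  expect_true(all(p[held$label == "deceptive"] > 0.5))
  expect_true(all(p[held$label == "truthful"] < 0.5))
})

test_that("labels uncorrelated with the signal are classified at chance", {
  # relabel so each true class holds exactly half of each label: the
  # labels then carry zero information about the planted contrast, and a
  # model trained on them must classify held-out data at chance level
  # (within 3 binomial SEs)
  segs <- make_segments(2, 2, seed = 16)
  shuffled <- segs
  shuffled$label <- with_seed(1, {
    lab <- character(length(segs))
    for (cl in unique(segs$label)) {
      idx <- sample(which(segs$label == cl))
      lab[idx] <- rep_len(c("deceptive", "truthful"), length(idx))
    }
    lab
  })
  fit <- css_fit(shuffled, control = fast_control(epochs = 1L), seed = 5)
  held <- make_segments(2, 2, seed = 17)
  acc <- mean((predict_proba(fit, held) > 0.5) ==
                (held$label == "deceptive"))
  n <- length(held)
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / n) + 1e-9)
})
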