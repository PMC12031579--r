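test_that("Utah cut-offs map to series-score thresholds 6 and 3", {
  th <- compute_thresholds(scoring_config())
  expect_identical(unname(th), c(6, 3))
  expect_gte(th[["threshold_1"]], th[["threshold_2"]])
})

test_that("the threshold map is affine with endpoint preservation", {
  # Utah midpoint maps to the score-range midpoint
  mid <- scoring_config(utah_cutoff_deception = 0, utah_cutoff_truth = 0)
  expect_equal(unname(compute_thresholds(mid)), c(4.5, 4.5))
  # endpoints map to endpoints: -18 -> 0, +18 -> 9
  ends <- scoring_config(utah_cutoff_deception = 18, utah_cutoff_truth = -18)
  expect_equal(unname(compute_thresholds(ends)), c(9, 0))
  # linearity in the cut-off
  f <- function(cut) compute_thresholds(
    scoring_config(utah_cutoff_deception = cut,
                   utah_cutoff_truth = -18))[["threshold_1"]]
  cuts <- c(-18, -9, 0, 4.5, 9, 18)
  expect_equal(vapply(cuts, f, numeric(1)), (cuts + 18) / 36 * 9)
  expect_error(scoring_config(utah_min = 18, utah_max = 18), "utah_min")
})

test_that("score_series sums probabilities and applies the decision bands", {
  s <- score_series(rep(1, 9))
  expect_equal(s$score, 9)
  expect_identical(s$decision, "deception")
  s <- score_series(rep(0, 9))
  expect_equal(s$score, 0)
  expect_identical(s$decision, "non_deception")
  s <- score_series(rep(0.5, 9))
  expect_equal(s$score, 4.5)
  expect_identical(s$decision, "inconclusive")
  # boundary values are inconclusive (ties go to no decision)
  expect_identical(score_series(c(rep(1, 6), rep(0, 3)))$decision,
                   "inconclusive")
  expect_identical(score_series(c(rep(1, 3), rep(0, 6)))$decision,
                   "inconclusive")
  expect_error(score_series(rep(0.5, 8)), "expected 9")
  expect_error(score_series(c(rep(0.5, 8), 1.2)), "\\[0, 1\\]")
})

test_that("raising one probability never moves the decision toward non_deception", {
  rank <- c(non_deception = 1, inconclusive = 2, deception = 3)
  set.seed(7)
  for (i in 1:30) {
    pr <- runif(9)
    j <- sample(9, 1)
    hi <- pr
    hi[j] <- runif(1, pr[j], 1)
    expect_gte(rank[[score_series(hi)$decision]],
               rank[[score_series(pr)$decision]])
  }
})

test_that("stored decisions are consistent with stored score and thresholds", {
  set.seed(8)
  for (i in 1:20) {
    s <- score_series(runif(9))
    redo <- if (s$score > s$threshold_1) "deception"
            else if (s$score < s$threshold_2) "non_deception"
            else "inconclusive"
    expect_identical(s$decision, redo)
    expect_equal(s$score, sum(s$probabilities))
  }
})

test_that("decide_dataset tallies correct/incorrect/inconclusive per group", {
  pt <- data.frame(
    series_id = rep(c("a", "b", "c"), each = 9),
    prob = c(rep(1, 9), rep(7 / 9, 9), rep(1 / 9, 9)))
  gt <- data.frame(series_id = c("a", "b", "c"),
                   ground_truth = c("deceptive", "deceptive", "truthful"))
  dec <- decide_dataset(pt, gt)
  cn <- dec$counts
  expect_identical(cn$correct[cn$group == "deceptive"], 2L)
  expect_identical(cn$incorrect[cn$group == "deceptive"], 0L)
  expect_identical(cn$correct[cn$group == "truthful"], 1L)

  # a mid-band deceptive series is inconclusive, never incorrect
  dec <- decide_dataset(
    data.frame(series_id = rep("a", 9), prob = rep(0.5, 9)),
    data.frame(series_id = "a", ground_truth = "deceptive"))
  expect_identical(dec$counts$inconclusive[1], 1L)
  expect_identical(dec$counts$incorrect[1], 0L)

  # a truthful series scoring high counts as incorrect for its group
  dec <- decide_dataset(
    data.frame(series_id = rep("t", 9), prob = rep(8 / 9, 9)),
    data.frame(series_id = "t", ground_truth = "truthful"))
  expect_identical(dec$counts$incorrect[dec$counts$group == "truthful"], 1L)

  # unknown ground truth: reported but excluded from counts, with warning
  expect_warning(
    dec <- decide_dataset(
      data.frame(series_id = rep(c("a", "u"), each = 9),
                 prob = rep(1, 18)),
      data.frame(series_id = "a", ground_truth = "deceptive")),
    "without ground truth")
  expect_identical(nrow(dec$series), 2L)
  expect_identical(sum(dec$counts$n), 1L)
})
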