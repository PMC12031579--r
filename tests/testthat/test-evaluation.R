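test_that("stratified 10-fold split of 702 items balances folds and classes", {
  lab <- rep(c("deceptive", "truthful"), c(378, 324))
  fold <- kfold_split(seq_len(702), k = 10, labels = lab, seed = 3)
  sizes <- tabulate(fold, 10)
  expect_identical(sum(sizes), 702L)
  expect_true(all(sizes %in% c(70L, 71L)))
  # every item lands in exactly one fold (partition property)
  expect_identical(sort(unique(fold)), 1:10)
  expect_length(fold, 702L)
  # per-class balance within one
  per_class <- table(fold, lab)
  expect_true(all(apply(per_class, 2, function(x) diff(range(x))) <= 1))
})

test_that("unstratified splits also balance and partition", {
  fold <- kfold_split(letters[1:23], k = 5, seed = 9)
  expect_true(all(tabulate(fold, 5) %in% 4:5))
  expect_error(kfold_split(1:5, k = 10), "fewer items")
})

test_that("series-level splitting never separates a series' question sets", {
  segs <- make_segments(6, 6, effect_size = 1, seed = 20)
  sid <- unique(segs$meta$series_id)
  slab <- segs$label[match(sid, segs$meta$series_id)]
  sfold <- kfold_split(sid, k = 4, labels = slab, seed = 2)
  fold <- sfold[match(segs$meta$series_id, sid)]
  expect_true(all(tapply(fold, segs$meta$series_id,
                         function(f) length(unique(f))) == 1L))
})

test_that("classification metrics follow the standard definitions", {
  expect_equal(unname(classification_metrics(
    rep("deceptive", 3), rep("deceptive", 3))), c(1, 1, 1))
  pred <- c(rep("deceptive", 4), rep("truthful", 6))
  truth <- c(rep("deceptive", 3), "truthful", "deceptive", rep("truthful", 5))
  # TP=3 FP=1 FN=1 TN=5
  expect_equal(unname(classification_metrics(pred, truth)),
               c(0.75, 0.75, 0.75))
  expect_warning(
    m <- classification_metrics(rep("truthful", 4),
                                c("deceptive", "deceptive", "truthful",
                                  "truthful")),
    "undefined")
  expect_equal(unname(m), c(0, 0, 0))
  expect_error(classification_metrics("deceptive", rep("deceptive", 2)),
               "equal length")
})

test_that("cross-validation partitions, reports mean +/- sd, and is seeded", {
  segs <- make_segments(2, 2, seed = 22)   # 36 question sets
  ctl <- fast_control(epochs = 1L)
  cv <- cross_validate(segs, control = ctl, k = 4, unit = "question_set",
                       seed = 6)
  expect_identical(sort(unique(cv$fold)), 1:4)
  expect_identical(sum(tabulate(cv$fold, 4)), length(segs))
  expect_identical(nrow(cv$per_fold), 4L)
  expect_true(all(cv$per_fold$recall >= 0 & cv$per_fold$recall <= 1))
  for (m in c("recall", "precision", "f1")) {
    row <- cv$mean_sd[cv$mean_sd$metric == m, ]
    expect_gte(row$mean, min(cv$per_fold[[m]]))
    expect_lte(row$mean, max(cv$per_fold[[m]]))
    # sd uses the n-1 denominator
    expect_equal(row$sd, sd(cv$per_fold[[m]]))
  }
  # pooled decision table covers every complete series
  expect_identical(sum(cv$decision_table$counts$n), 4L)
  # determinism: identical seed, identical report
  cv2 <- cross_validate(segs, control = ctl, k = 4, unit = "question_set",
                        seed = 6)
  expect_identical(cv$per_fold, cv2$per_fold)
  expect_identical(cv$probabilities, cv2$probabilities)
})

test_that("series-unit cross-validation keeps held-out series unseen", {
  segs <- make_segments(3, 3, seed = 23)   # 6 series, 54 sets
  cv <- cross_validate(segs, control = fast_control(epochs = 1L), k = 3,
                       unit = "series", seed = 4)
  # all nine sets of a series share one fold (leakage guard)
  expect_true(all(tapply(cv$fold, segs$meta$series_id,
                         function(f) length(unique(f))) == 1L))
  expect_identical(sum(cv$decision_table$counts$n), 6L)
})
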