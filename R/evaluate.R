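#' Seeded, optionally stratified k-fold partition
#'
#' Shuffles the items and deals them into `k` folds whose sizes differ by
#' at most one. When `labels` is supplied the split is stratified: each
#' class is divided as evenly as possible and class remainders are placed
#' on the currently smallest folds, so both the per-class and the total
#' fold sizes stay balanced.
#'
#' @param items vector of item identifiers (any type; length n >= k).
#' @param k number of folds.
#' @param labels optional per-item labels for stratification.
#' @param seed integer seed for the shuffles.
#' @return integer vector of fold assignments (1..k), parallel to `items`.
#' @export
kfold_split <- function(items, k = 10L, labels = NULL, seed = 1L) {
  n <- length(items)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (n < k)
    stop(sprintf("fewer items (%d) than folds (%d)", n, k), call. = FALSE)
  if (!is.null(labels) && length(labels) != n)
    stop("labels must parallel items", call. = FALSE)
  with_seed(seed, {
    fold <- integer(n)
    if (is.null(labels)) {
      fold[sample.int(n)] <- rep_len(seq_len(k), n)
    } else {
      totals <- integer(k)
      classes <- names(sort(table(labels), decreasing = TRUE))
      for (cl in classes) {
        idx <- sample(which(labels == cl))
        m <- length(idx)
        base <- m %/% k
        counts <- rep(base, k)
        r <- m - base * k
        if (r > 0) {
          # remainder goes to the folds that are currently smallest
          ord <- order(totals, sample.int(k))
          counts[ord[seq_len(r)]] <- counts[ord[seq_len(r)]] + 1L
        }
        fold[idx] <- rep(seq_len(k), times = counts)
        totals <- totals + counts
      }
    }
    fold
  })
}

#' Recall, precision and F1 for deception detection
#'
#' The deceptive class is the positive class: recall = TP/(TP+FN),
#' precision = TP/(TP+FP), F1 their harmonic mean. Degenerate 0/0 ratios
#' are reported as 0 with a warning.
#'
#' @param predicted,truth equal-length vectors of `"deceptive"` /
#'   `"truthful"` labels (factors or characters).
#' @param positive label treated as positive.
#' @return named numeric vector `c(recall=, precision=, f1=)`.
#' @export
classification_metrics <- function(predicted, truth,
                                   positive = "deceptive") {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length", call. = FALSE)
  tp <- sum(predicted == positive & truth == positive)
  fp <- sum(predicted == positive & truth != positive)
  fn <- sum(predicted != positive & truth == positive)
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (0/0); reporting 0", call. = FALSE)
      0
    } else num / den
  }
  recall <- safe(tp, tp + fn, "recall")
  precision <- safe(tp, tp + fp, "precision")
  f1 <- if (recall + precision == 0) {
    warning("f1 undefined (0/0); reporting 0", call. = FALSE)
    0
  } else 2 * recall * precision / (recall + precision)
  c(recall = recall, precision = precision, f1 = f1)
}

#' k-fold cross-validation of the full scoring system
#'
#' For each fold, trains the classifier on the remaining folds, predicts
#' the held-out question sets, and computes recall/precision/F1 at the
#' question-set level; fold metrics are aggregated as mean and sd (n-1
#' denominator). The held-out probabilities of all folds are then pooled
#' and every complete series is scored and tabulated with
#' [decide_dataset()], so the decision table is computed entirely
#' out-of-fold.
#'
#' With `unit = "series"` (the default) all nine question sets of a series
#' share a fold, so no model is ever tested on a series it trained on.
#' `unit = "question_set"` splits at the individual question-set level,
#' mirroring a plain 9:1 split of the pooled data. Both splits are
#' stratified by label.
#'
#' @param segments labeled `"css_segments"` (see [build_segments()]).
#' @param arch an [arch_config()].
#' @param control a [train_config()]; per-fold training seeds are derived
#'   from `seed`.
#' @param scoring a [scoring_config()].
#' @param k number of folds (10 for a 9:1 train:test ratio).
#' @param unit grouping unit of the split.
#' @param seed master seed for fold assignment and per-fold training.
#' @return A `"css_cv"`: `$per_fold` metrics, `$mean_sd` summary,
#'   `$decision_table`, `$probabilities` (pooled out-of-fold), `$fold`
#'   (per-segment assignment).
#' @export
cross_validate <- function(segments, arch = arch_config(),
                           control = train_config(),
                           scoring = scoring_config(), k = 10L,
                           unit = c("series", "question_set"), seed = 1L) {
  stopifnot(inherits(segments, "css_segments"))
  unit <- match.arg(unit)
  n <- length(segments)
  lab <- segments$label

  if (unit == "series") {
    sid <- unique(segments$meta$series_id)
    slab <- vapply(sid, function(s)
      lab[match(s, segments$meta$series_id)], character(1))
    sfold <- kfold_split(sid, k = k, labels = slab,
                         seed = derive_seed(seed, 1L))
    fold <- sfold[match(segments$meta$series_id, sid)]
  } else {
    fold <- kfold_split(seq_len(n), k = k, labels = lab,
                        seed = derive_seed(seed, 1L))
  }

  per_fold <- vector("list", k)
  probs <- numeric(n)
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- which(fold != f)
    fit <- tryCatch(
      css_fit(segments[train], arch = arch, control = control,
              seed = derive_seed(seed, 2L, f)),
      error = function(e)
        stop("fold ", f, ": ", conditionMessage(e), call. = FALSE))
    p <- predict(fit, segments[test], type = "prob")
    probs[test] <- p
    pred <- ifelse(p > 0.5, "deceptive", "truthful")
    m <- classification_metrics(pred, lab[test])
    per_fold[[f]] <- data.frame(fold = f, n_test = length(test),
                                recall = m[["recall"]],
                                precision = m[["precision"]],
                                f1 = m[["f1"]])
  }
  per_fold <- do.call(rbind, per_fold)
  mean_sd <- data.frame(
    metric = c("recall", "precision", "f1"),
    mean = vapply(c("recall", "precision", "f1"),
                  function(m) mean(per_fold[[m]]), numeric(1)),
    sd = vapply(c("recall", "precision", "f1"),
                function(m) sd(per_fold[[m]]), numeric(1)))

  # pooled out-of-fold decision table over complete series
  meta <- segments$meta
  cnt <- table(meta$series_id)
  complete <- names(cnt)[cnt == scoring$n_question_sets]
  if (length(complete) < length(cnt))
    warning(length(cnt) - length(complete),
            " series without a full set of question-set probabilities were excluded from the decision table")
  keep <- meta$series_id %in% complete
  decision_table <- if (any(keep)) {
    decide_dataset(
      data.frame(series_id = meta$series_id[keep], prob = probs[keep]),
      data.frame(series_id = meta$series_id, ground_truth = lab),
      config = scoring)
  } else NULL

  structure(list(k = k, unit = unit, per_fold = per_fold,
                 mean_sd = mean_sd, decision_table = decision_table,
                 probabilities = probs, fold = fold, seed = seed,
                 arch = arch, control = control),
            class = "css_cv")
}

#' @export
print.css_cv <- function(x, digits = 4, ...) {
  cat(sprintf("<css_cv> %d-fold cross-validation (unit: %s, seed %d)\n",
              x$k, x$unit, x$seed))
  for (i in seq_len(nrow(x$mean_sd)))
    cat(sprintf("  %-9s %.*f +/- %.*f\n", x$mean_sd$metric[i],
                digits, x$mean_sd$mean[i], digits, x$mean_sd$sd[i]))
  if (!is.null(x$decision_table)) {
    cat("  series decisions (pooled out-of-fold):\n")
    print(x$decision_table$counts, row.names = FALSE)
  }
  invisible(x)
}
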