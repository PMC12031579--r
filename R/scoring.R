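#' Series scoring configuration
#'
#' The nine question-set probabilities of a series sum to a score in
#' `[0, 9]`. Decision thresholds come from the Utah numerical scoring
#' scale, where three relevant questions over three charts each contribute
#' up to +/-2 points (total range -18..+18) and +/-6 are the deception /
#' truth cut-offs. Those cut-offs are mapped affinely onto the score range,
#' giving thresholds 6 and 3 with the defaults.
#'
#' @param utah_cutoff_deception,utah_cutoff_truth Utah-scale cut-offs
#'   (+6 / -6).
#' @param utah_min,utah_max Utah total-score range (-18 / +18).
#' @param score_min,score_max series-score range (0 / 9).
#' @param n_question_sets question sets per series (9).
#' @return A `"scoring_config"`.
#' @export
scoring_config <- function(utah_cutoff_deception = 6,
                           utah_cutoff_truth = -6,
                           utah_min = -18, utah_max = 18,
                           score_min = 0, score_max = 9,
                           n_question_sets = 9L) {
  if (utah_min >= utah_max) stop("utah_min must be < utah_max", call. = FALSE)
  if (score_min >= score_max)
    stop("score_min must be < score_max", call. = FALSE)
  if (utah_cutoff_deception < utah_min || utah_cutoff_deception > utah_max ||
      utah_cutoff_truth < utah_min || utah_cutoff_truth > utah_max)
    stop("cut-offs must lie within the Utah range", call. = FALSE)
  if (utah_cutoff_truth > utah_cutoff_deception)
    stop("truth cut-off must not exceed the deception cut-off", call. = FALSE)
  if (n_question_sets < 1L)
    stop("n_question_sets must be positive", call. = FALSE)
  structure(list(utah_cutoff_deception = utah_cutoff_deception,
                 utah_cutoff_truth = utah_cutoff_truth,
                 utah_min = utah_min, utah_max = utah_max,
                 score_min = score_min, score_max = score_max,
                 n_question_sets = as.integer(n_question_sets)),
            class = "scoring_config")
}

#' Map the Utah cut-offs onto the series-score range
#'
#' Each cut-off `c` maps affinely:
#' `(c - utah_min) / (utah_max - utah_min) * (score_max - score_min)
#'  + score_min`, so the Utah endpoints map to the score endpoints
#' (-18 -> 0, +18 -> 9). With the default configuration the deception
#' cut-off (+6) yields threshold 1 = 6 and the truth cut-off (-6) yields
#' threshold 2 = 3.
#'
#' @param config a [scoring_config()].
#' @return named numeric vector `c(threshold_1=, threshold_2=)` with
#'   `threshold_1 >= threshold_2`.
#' @export
compute_thresholds <- function(config = scoring_config()) {
  stopifnot(inherits(config, "scoring_config"))
  map <- function(cutoff)
    (cutoff - config$utah_min) / (config$utah_max - config$utah_min) *
      (config$score_max - config$score_min) + config$score_min
  c(threshold_1 = map(config$utah_cutoff_deception),
    threshold_2 = map(config$utah_cutoff_truth))
}

#' Score one examination series
#'
#' Sums the nine question-set deception probabilities and issues the
#' three-way decision: `deception` when the score is strictly above
#' threshold 1, `non_deception` when strictly below threshold 2, and
#' `inconclusive` otherwise (scores exactly on a threshold fall in the
#' inconclusive band — the conservative reading of "above"/"below").
#'
#' @param probabilities numeric vector of exactly
#'   `config$n_question_sets` values in `[0, 1]`.
#' @param config a [scoring_config()].
#' @param series_id optional identifier carried into the result.
#' @return A `"series_score"`: probabilities, score, both thresholds and
#'   the decision.
#' @export
score_series <- function(probabilities, config = scoring_config(),
                         series_id = NA_character_) {
  stopifnot(inherits(config, "scoring_config"))
  if (length(probabilities) != config$n_question_sets)
    stop(sprintf("expected %d question-set probabilities, got %d",
                 config$n_question_sets, length(probabilities)),
         call. = FALSE)
  if (any(!is.finite(probabilities)) || any(probabilities < 0) ||
      any(probabilities > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  th <- compute_thresholds(config)
  score <- sum(probabilities)
  decision <- if (score > th[["threshold_1"]]) "deception"
              else if (score < th[["threshold_2"]]) "non_deception"
              else "inconclusive"
  structure(list(series_id = series_id,
                 probabilities = as.numeric(probabilities),
                 score = score,
                 threshold_1 = th[["threshold_1"]],
                 threshold_2 = th[["threshold_2"]],
                 decision = decision),
            class = "series_score")
}

#' @export
print.series_score <- function(x, ...) {
  cat(sprintf("<series_score>%s score %.3f (thresholds %.4g / %.4g): %s\n",
              if (is.na(x$series_id)) "" else paste0(" ", x$series_id),
              x$score, x$threshold_1, x$threshold_2, x$decision))
  invisible(x)
}

#' Score every series of a dataset and tabulate decisions
#'
#' Applies [score_series()] per series and counts, within each
#' ground-truth group, how many series were decided correctly,
#' incorrectly, or left inconclusive. Inconclusive outcomes are counted
#' separately, never as correct or incorrect. Series with unknown ground
#' truth are scored and reported but excluded from the counts, with a
#' warning.
#'
#' @param prob_table data frame with columns `series_id` and `prob`, nine
#'   rows per series (question sets in any order).
#' @param ground_truth data frame with columns `series_id` and
#'   `ground_truth` (a manifest as produced by [simulate_dataset()] works;
#'   duplicated series rows are collapsed).
#' @param config a [scoring_config()].
#' @return A `"css_decisions"`: `$series` (one row per series: score,
#'   decision, ground truth) and `$counts` (per-group correct / incorrect /
#'   inconclusive tallies).
#' @export
decide_dataset <- function(prob_table, ground_truth,
                           config = scoring_config()) {
  stopifnot(all(c("series_id", "prob") %in% names(prob_table)),
            all(c("series_id", "ground_truth") %in% names(ground_truth)))
  gt <- unique(ground_truth[, c("series_id", "ground_truth")])
  if (anyDuplicated(gt$series_id))
    stop("conflicting ground truth for some series", call. = FALSE)
  ids <- unique(prob_table$series_id)
  rows <- lapply(ids, function(sid) {
    pr <- prob_table$prob[prob_table$series_id == sid]
    ss <- score_series(pr, config, series_id = sid)
    truth <- gt$ground_truth[gt$series_id == sid]
    if (!length(truth)) truth <- "unknown"
    data.frame(series_id = sid, score = ss$score, decision = ss$decision,
               ground_truth = truth)
  })
  series <- do.call(rbind, rows)
  if (any(series$ground_truth == "unknown"))
    warning(sum(series$ground_truth == "unknown"),
            " series without ground truth excluded from the decision counts")
  known <- series[series$ground_truth != "unknown", , drop = FALSE]
  counts <- do.call(rbind, lapply(c("deceptive", "truthful"), function(g) {
    sub <- known[known$ground_truth == g, , drop = FALSE]
    want <- if (g == "deceptive") "deception" else "non_deception"
    data.frame(group = g, n = nrow(sub),
               correct = sum(sub$decision == want),
               incorrect = sum(sub$decision != want &
                                 sub$decision != "inconclusive"),
               inconclusive = sum(sub$decision == "inconclusive"))
  }))
  structure(list(series = series, counts = counts,
                 thresholds = compute_thresholds(config)),
            class = "css_decisions")
}

#' @export
print.css_decisions <- function(x, ...) {
  cat(sprintf("<css_decisions> %d series (thresholds %.4g / %.4g)\n",
              nrow(x$series), x$thresholds[1], x$thresholds[2]))
  print(x$counts, row.names = FALSE)
  invisible(x)
}
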