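#' Extract a fixed-length question window from a trace
#'
#' Onsets are converted to 0-based sample indices by
#' `floor(onset_s * 40)`; the window covers `floor(window_s * 40)` samples
#' from that index.
#'
#' @param trace numeric vector sampled at 40 Hz.
#' @param onset_s window start, seconds from trace start.
#' @param window_s window length in seconds (default the canonical 22.4 s
#'   scoring window, 896 samples).
#' @return numeric vector of `floor(window_s * 40)` samples.
#' @export
extract_window <- function(trace, onset_s, window_s = css_question_window()) {
  fs <- css_sampling_rate()
  start <- floor(onset_s * fs)
  len <- floor(window_s * fs)
  if (start < 0) stop("onset before trace start", call. = FALSE)
  if (start + len > length(trace))
    stop(sprintf(
      "window exceeds trace end: need samples [%d, %d) but trace has %d",
      start, start + len, length(trace)), call. = FALSE)
  trace[(start + 1L):(start + len)]
}

#' Join two signal segments with a discontinuity-removing offset
#'
#' Concatenates `second` after `first` after shifting it by a constant so
#' that its first sample equals the last sample of `first`: the two samples
#' at the junction are exactly equal, removing the boundary discontinuity
#' that plain concatenation of two separately recorded windows would
#' create. The operation is translation-equivariant in its first argument:
#' `offset_join(a + c, b) == offset_join(a, b) + c`.
#'
#' @param first,second non-empty numeric vectors.
#' @return numeric vector of length `length(first) + length(second)`.
#' @examples
#' offset_join(c(1, 2, 3), c(10, 11))  # 1 2 3 3 4
#' @export
offset_join <- function(first, second) {
  if (!length(first) || !length(second))
    stop("offset_join requires non-empty segments", call. = FALSE)
  delta <- first[length(first)] - second[1]
  out <- c(first, second + delta)
  # pin the junction sample: (x + delta) can differ from the target by one
  # ulp, and the continuity contract is exact equality
  out[length(first) + 1L] <- first[length(first)]
  out
}

# per-channel z-standardization; constant channels map to all zeros
standardize_channel <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s < 1e-12) return(numeric(length(x)))
  (x - mean(x)) / s
}

#' Build the classifier input for one question set
#'
#' For each of the five channels, the 22.4 s comparison-question window and
#' the 22.4 s relevant-question window are extracted (comparison first),
#' offset-joined into one continuous 1792-sample segment, and z-standardized
#' per channel (mean 0, sd 1; constant channels become all zeros so
#' arbitrary device units never reach the network).
#'
#' @param recording a [session_recording()].
#' @param pair_id which question pair (1--3).
#' @param label `"deceptive"`, `"truthful"` or `"unknown"`.
#' @param series_id series identifier carried along for scoring.
#' @return A `"question_set_segment"`: list with the 5 x 1792 matrix `x`
#'   (rows in canonical channel order), identifiers and `label`.
#' @export
build_question_set <- function(recording, pair_id, label = "unknown",
                               series_id = NA_character_) {
  rec <- validate_session_recording(recording)
  ev <- rec$events
  comp <- ev[ev$kind == "comparison" & !is.na(ev$pair_id) &
               ev$pair_id == pair_id, ]
  rel <- ev[ev$kind == "relevant" & !is.na(ev$pair_id) &
              ev$pair_id == pair_id, ]
  if (nrow(comp) != 1L || nrow(rel) != 1L)
    stop("pair not found: pair_id ", pair_id, " in chart ", rec$chart_id,
         call. = FALSE)
  if (!label %in% c("deceptive", "truthful", "unknown"))
    stop("invalid label: ", label, call. = FALSE)
  x <- t(vapply(rec$channels, function(tr) {
    standardize_channel(offset_join(extract_window(tr, comp$onset_s),
                                    extract_window(tr, rel$onset_s)))
  }, numeric(css_segment_len())))
  structure(list(series_id = series_id, chart_id = rec$chart_id,
                 pair_id = as.integer(pair_id), x = x, label = label),
            class = "question_set_segment")
}

#' Build all question-set segments of a dataset
#'
#' Applies [build_question_set()] to every (chart, pair) combination of a
#' dataset, labeling each set with its series ground truth (all nine sets
#' of a deceptive series are deceptive-labeled).
#'
#' @param recordings list of [session_recording()] objects, or the list
#'   returned by [simulate_dataset()] / [read_dataset()] (in which case
#'   `manifest` is taken from it).
#' @param manifest manifest data frame (see [write_dataset()]).
#' @return A `"css_segments"` container: `x` is a `5 x 1792 x n` array,
#'   `label` a character vector, `meta` a data frame with `series_id`,
#'   `chart_id`, `pair_id`.
#' @export
build_segments <- function(recordings, manifest = NULL) {
  if (is.list(recordings) && !is.null(recordings$manifest)) {
    manifest <- recordings$manifest
    recordings <- recordings$recordings
  }
  validate_manifest(manifest)
  segs <- list()
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    row <- manifest[manifest$chart_id == rec$chart_id, ]
    if (nrow(row) != 1L)
      stop("chart ", rec$chart_id, " not in manifest", call. = FALSE)
    lab <- row$ground_truth
    for (p in session_pairs(rec))
      segs[[length(segs) + 1L]] <-
        build_question_set(rec, p, label = lab, series_id = row$series_id)
  }
  as_css_segments(segs)
}

as_css_segments <- function(segs) {
  n <- length(segs)
  x <- array(0, dim = c(5L, css_segment_len(), n),
             dimnames = list(css_channels(), NULL, NULL))
  for (i in seq_len(n)) x[, , i] <- segs[[i]]$x
  meta <- data.frame(
    series_id = vapply(segs, `[[`, character(1), "series_id"),
    chart_id = vapply(segs, `[[`, character(1), "chart_id"),
    pair_id = vapply(segs, `[[`, integer(1), "pair_id"))
  structure(list(x = x,
                 label = vapply(segs, `[[`, character(1), "label"),
                 meta = meta),
            class = "css_segments")
}

#' @export
print.css_segments <- function(x, ...) {
  tab <- table(factor(x$label, c("truthful", "deceptive", "unknown")))
  cat(sprintf("<css_segments> %d question sets (5 x %d each): %d truthful, %d deceptive, %d unknown; %d series\n",
              dim(x$x)[3], dim(x$x)[2], tab[1], tab[2], tab[3],
              length(unique(x$meta$series_id))))
  invisible(x)
}

#' @export
`[.css_segments` <- function(x, i, ...) {
  structure(list(x = x$x[, , i, drop = FALSE], label = x$label[i],
                 meta = x$meta[i, , drop = FALSE]),
            class = "css_segments")
}

#' @export
length.css_segments <- function(x) dim(x$x)[3]

#' Persist preprocessed segments
#'
#' Convenience serialization of a `"css_segments"` container (used by the
#' CLI between `preprocess` and `train`/`evaluate`).
#'
#' @param segments a `"css_segments"` object.
#' @param path file path.
#' @return `path` / the restored object.
#' @export
write_segments <- function(segments, path) {
  stopifnot(inherits(segments, "css_segments"))
  saveRDS(segments, path, version = 2)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  s <- readRDS(path)
  stopifnot(inherits(s, "css_segments"))
  s
}
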