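#' Construct an annotated polygraph session recording
#'
#' A session recording holds one chart: five synchronized physiological
#' traces sampled at 40 Hz plus the question-onset annotations needed for
#' scoring. Channels are always kept in the canonical order `ppg`,
#' `blood_pressure`, `resp_thoracic`, `resp_abdominal`, `skin_conductance`.
#'
#' @param chart_id character scalar identifying the chart.
#' @param channels named list of five equal-length numeric traces, one per
#'   canonical channel (device units are arbitrary).
#' @param events data frame of question events with columns `onset_s`
#'   (seconds from trace start), `kind` (`"comparison"`, `"relevant"` or
#'   `"irrelevant"`) and `pair_id` (integer 1--3 linking each comparison
#'   question to its relevant question; `NA` for irrelevant questions).
#'   May have zero rows.
#' @param sampling_rate_hz sampling rate; must be 40. Other rates are
#'   rejected rather than resampled.
#' @return An object of class `"session_recording"`.
#' @seealso [read_session()], [write_session()], [simulate_chart()]
#' @export
session_recording <- function(chart_id, channels, events,
                              sampling_rate_hz = css_sampling_rate()) {
  rec <- structure(
    list(chart_id = as.character(chart_id)[1],
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         channels = channels,
         events = as.data.frame(events)),
    class = "session_recording")
  validate_session_recording(rec)
}

validate_session_recording <- function(rec) {
  want <- css_channels()
  if (!is.list(rec$channels))
    stop("channels must be a named list of numeric traces", call. = FALSE)
  for (ch in want)
    if (is.null(rec$channels[[ch]]))
      stop(sprintf("channel %s absent", ch), call. = FALSE)
  extra <- setdiff(names(rec$channels), want)
  if (length(extra))
    stop("unknown channel(s): ", paste(extra, collapse = ", "), call. = FALSE)
  rec$channels <- rec$channels[want]  # enforce canonical order
  lens <- vapply(rec$channels, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("channel length mismatch: ",
         paste(sprintf("%s=%d", want, lens), collapse = ", "), call. = FALSE)
  if (!identical(as.numeric(rec$sampling_rate_hz), 40))
    stop("sampling_rate_hz must be 40, got ", rec$sampling_rate_hz,
         call. = FALSE)

  ev <- rec$events
  need <- c("onset_s", "kind", "pair_id")
  if (!all(need %in% names(ev)))
    stop("events must have columns onset_s, kind, pair_id", call. = FALSE)
  if (nrow(ev)) {
    bad <- setdiff(unique(ev$kind), c("comparison", "relevant", "irrelevant"))
    if (length(bad))
      stop("invalid event kind: ", paste(bad, collapse = ", "), call. = FALSE)
    if (any(diff(ev$onset_s) <= 0))
      stop("event onsets must be strictly increasing", call. = FALSE)
    n <- lens[1]
    win <- floor(css_question_window() * 40)
    last_ok <- (n - win) / 40
    if (any(ev$onset_s < 0) || any(ev$onset_s > last_ok))
      stop(sprintf(
        "event out of range: onsets must lie in [0, %.3f] s so the %.1f s question window fits the %d-sample trace",
        last_ok, css_question_window(), n), call. = FALSE)
    # every annotated pair must be a complete (comparison, relevant) couple
    prs <- ev[ev$kind != "irrelevant", , drop = FALSE]
    if (nrow(prs)) {
      if (anyNA(prs$pair_id))
        stop("comparison/relevant events require a pair_id", call. = FALSE)
      for (p in unique(prs$pair_id)) {
        kk <- prs$kind[prs$pair_id == p]
        if (!identical(sort(kk), c("comparison", "relevant")))
          stop("pair ", p,
               " must contain exactly one comparison and one relevant event",
               call. = FALSE)
      }
    }
  }
  rec
}

# pair ids present in a recording (sorted)
session_pairs <- function(rec) {
  ev <- rec$events
  sort(unique(ev$pair_id[ev$kind == "comparison"]))
}

#' @export
print.session_recording <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat(sprintf("<session_recording> chart %s: %d samples/channel (%.1f s at %g Hz), %d events (%d question pairs)\n",
              x$chart_id, n, n / x$sampling_rate_hz, x$sampling_rate_hz,
              nrow(x$events), length(session_pairs(x))))
  invisible(x)
}

sidecar_path <- function(path) sub("\\.[^./\\\\]+$", "", path)

#' Write a session recording to disk
#'
#' One chart is stored as two human-inspectable text files: a tab-delimited
#' trace table `<path>` (column 1 = sample index, columns 2--6 = the five
#' channels in canonical order, printed with 17 significant digits so the
#' read/write round trip is bit-exact) and a JSON sidecar `<stem>.json`
#' carrying the chart id, sampling rate and event annotations.
#'
#' @param recording a [session_recording()].
#' @param path output file path for the trace table (conventionally `.tsv`).
#' @return `path`, invisibly.
#' @export
write_session <- function(recording, path) {
  rec <- validate_session_recording(recording)
  vals <- unlist(rec$channels, use.names = FALSE)
  if (!all(is.finite(vals)))
    stop("non-finite sample in channel ",
         css_channels()[which.max(vapply(rec$channels,
                                         function(x) any(!is.finite(x)),
                                         logical(1)))],
         call. = FALSE)
  n <- length(rec$channels[[1]])
  cols <- c(list(format(seq_len(n) - 1L)),
            lapply(rec$channels, function(x) sprintf("%.17g", x)))
  lines <- c(paste(c("index", css_channels()), collapse = "\t"),
             do.call(paste, c(cols, sep = "\t")))
  writeLines(lines, path)

  side <- list(chart_id = rec$chart_id,
               sampling_rate_hz = rec$sampling_rate_hz,
               events = rec$events)
  jsonlite::write_json(side, paste0(sidecar_path(path), ".json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  invisible(path)
}

#' Read a session recording from disk
#'
#' Reads the trace table and JSON sidecar written by [write_session()] and
#' re-validates every invariant (all five channels present, equal lengths,
#' 40 Hz, in-range strictly increasing events). Nothing is dropped or
#' coerced silently; a malformed file raises an error naming the offending
#' field.
#'
#' @param path path to the trace table written by [write_session()].
#' @return A [session_recording()].
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sp <- paste0(sidecar_path(path), ".json")
  if (!file.exists(sp)) stop("annotation sidecar missing: ", sp, call. = FALSE)
  tab <- read.delim(path, check.names = FALSE)
  for (ch in css_channels())
    if (!ch %in% names(tab))
      stop(sprintf("channel %s absent", ch), call. = FALSE)
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  ev <- side$events
  if (is.null(ev) || length(ev) == 0L || (is.data.frame(ev) && !nrow(ev)))
    ev <- data.frame(onset_s = numeric(), kind = character(),
                     pair_id = integer())
  ev$pair_id <- as.integer(ev$pair_id)
  session_recording(chart_id = side$chart_id,
                    channels = lapply(tab[css_channels()], as.numeric),
                    events = ev,
                    sampling_rate_hz = side$sampling_rate_hz)
}

#' Write or read a full simulated dataset
#'
#' A dataset directory holds one trace table + sidecar per chart plus a
#' `manifest.tsv` linking charts to series (three charts per series), with
#' columns `series_id`, `participant_id`, `chart_id`, `chart_index` and
#' `ground_truth` (`deceptive`, `truthful` or `unknown`).
#'
#' @param recordings list of [session_recording()] objects.
#' @param manifest data frame as described above, one row per chart.
#' @param dir dataset directory (created if needed).
#' @return `dir` (write) or a `list(recordings=, manifest=)` (read).
#' @export
write_dataset <- function(recordings, manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  validate_manifest(manifest)
  for (rec in recordings)
    write_session(rec, file.path(dir, paste0(rec$chart_id, ".tsv")))
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  mp <- file.path(dir, "manifest.tsv")
  if (!file.exists(mp)) stop("manifest.tsv missing in ", dir, call. = FALSE)
  manifest <- read.delim(mp, colClasses = c(chart_index = "integer"))
  validate_manifest(manifest)
  recordings <- lapply(manifest$chart_id, function(cid)
    read_session(file.path(dir, paste0(cid, ".tsv"))))
  list(recordings = recordings, manifest = manifest)
}

validate_manifest <- function(manifest) {
  need <- c("series_id", "participant_id", "chart_id", "chart_index",
            "ground_truth")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  cnt <- table(manifest$series_id)
  if (any(cnt != 3L))
    stop("every series must have exactly 3 charts; offending series: ",
         paste(names(cnt)[cnt != 3L], collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(manifest$ground_truth),
                 c("deceptive", "truthful", "unknown"))
  if (length(bad))
    stop("invalid ground_truth value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(manifest)
}
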