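#' Simulation parameters for synthetic polygraph sessions
#'
#' The generator emulates the structure of a CQT examination (three
#' comparison/relevant question pairs per chart, three charts per series)
#' and the premise that deceptive examinees respond more strongly to
#' relevant than to comparison questions while truthful examinees respond
#' at most as strongly.
#'
#' Under `condition = "deceptive"` the expected arousal amplitude of a
#' relevant question is `(1 + effect_size)` times that of a comparison
#' question; under `"truthful"` it is `truthful_ratio` (<= 1) times.
#'
#' @param effect_size multiplier on the relevant-question response under
#'   deception; 0 means no signal. Default 1 (relevant responses twice the
#'   comparison amplitude), a clearly supra-threshold differential of the
#'   kind the CQT premise assumes.
#' @param noise_sd additive white-noise level, as a fraction of each
#'   channel's nominal response scale.
#' @param drift_sd slow baseline wander: standard deviation of a random
#'   walk per square-root second, same per-channel scaling as `noise_sd`.
#' @param heart_rate_hz pulse rate of the photoplethysmogram (default 1.2,
#'   i.e. 72 bpm).
#' @param resp_rate_hz respiration rate (default 0.25, i.e. 15 breaths/min).
#' @param scr_rise_s,scr_decay_s rise and decay time constants of the
#'   phasic skin-conductance response kernel (defaults 0.75 s / 4 s).
#' @param response_latency_s delay between question onset and the start of
#'   the physiological response (default 1.5 s).
#' @param chart_duration_s chart length in seconds (default 240).
#' @param inter_question_gap_s spacing between a comparison question and
#'   its paired relevant question (default 25 s).
#' @param truthful_ratio relevant/comparison amplitude ratio under the
#'   truthful condition (default 0.8, must be <= 1).
#' @param amp_jitter_sd log-normal sd of per-event amplitude jitter
#'   (default 0.15); set to 0 for perfectly repeatable response sizes.
#' @param seed default master seed used when none is passed explicitly.
#' @return A validated list of class `"sim_params"`.
#' @export
sim_params <- function(effect_size = 1, noise_sd = 0.1, drift_sd = 0.05,
                       heart_rate_hz = 1.2, resp_rate_hz = 0.25,
                       scr_rise_s = 0.75, scr_decay_s = 4.0,
                       response_latency_s = 1.5, chart_duration_s = 240,
                       inter_question_gap_s = 25, truthful_ratio = 0.8,
                       amp_jitter_sd = 0.15, seed = 1L) {
  p <- list(effect_size = effect_size, noise_sd = noise_sd,
            drift_sd = drift_sd, heart_rate_hz = heart_rate_hz,
            resp_rate_hz = resp_rate_hz, scr_rise_s = scr_rise_s,
            scr_decay_s = scr_decay_s,
            response_latency_s = response_latency_s,
            chart_duration_s = chart_duration_s,
            inter_question_gap_s = inter_question_gap_s,
            truthful_ratio = truthful_ratio, amp_jitter_sd = amp_jitter_sd,
            seed = as.integer(seed))
  pos <- c("heart_rate_hz", "resp_rate_hz", "scr_rise_s", "scr_decay_s",
           "response_latency_s", "chart_duration_s", "inter_question_gap_s")
  for (f in pos)
    if (!is.numeric(p[[f]]) || p[[f]] <= 0)
      stop(f, " must be positive", call. = FALSE)
  for (f in c("effect_size", "noise_sd", "drift_sd", "amp_jitter_sd"))
    if (!is.numeric(p[[f]]) || p[[f]] < 0)
      stop(f, " must be nonnegative", call. = FALSE)
  if (p$truthful_ratio <= 0 || p$truthful_ratio > 1)
    stop("truthful_ratio must be in (0, 1]", call. = FALSE)
  # 3 pairs at lead-in 20 s, comparison->relevant gap, pair spacing 2*gap;
  # the last relevant window must fit inside the chart.
  last_onset <- 20 + 4 * p$inter_question_gap_s + p$inter_question_gap_s
  if (last_onset + css_question_window() > p$chart_duration_s)
    stop("chart_duration_s too short to hold 3 question pairs plus windows",
         call. = FALSE)
  structure(p, class = "sim_params")
}

#' Unit-peak bi-exponential response kernel
#'
#' `r(t) = (exp(-t/decay) - exp(-t/rise)) / peak` for `t >= 0`, 0 before,
#' normalized so its maximum is exactly 1. This is the standard
#' phenomenological shape of a phasic sympathetic response (fast rise,
#' slow recovery); `r(0) = 0` and `r -> 0` as `t -> Inf`.
#'
#' @param t time since response start, seconds (vectorized).
#' @param rise_s,decay_s rise and decay time constants; `decay_s` should
#'   exceed `rise_s`.
#' @return numeric vector of kernel values in `[0, 1]`.
#' @export
response_kernel <- function(t, rise_s, decay_s) {
  if (rise_s <= 0 || decay_s <= 0) stop("time constants must be positive")
  if (abs(decay_s - rise_s) < 1e-12) {
    v <- ifelse(t >= 0, (t / rise_s) * exp(1 - t / rise_s), 0)
    return(pmax(v, 0))
  }
  tpk <- rise_s * decay_s / (decay_s - rise_s) * log(decay_s / rise_s)
  pk <- exp(-tpk / decay_s) - exp(-tpk / rise_s)
  v <- ifelse(t >= 0, (exp(-t / decay_s) - exp(-t / rise_s)) / pk, 0)
  pmax(v, 0)
}

# sum of event-locked kernels: amplitudes `amp` at `onset_s + latency`
event_response <- function(t, onset_s, amp, latency, rise_s, decay_s) {
  out <- numeric(length(t))
  for (i in seq_along(onset_s))
    out <- out + amp[i] * response_kernel(t - onset_s[i] - latency,
                                          rise_s, decay_s)
  out
}

#' Simulate one annotated polygraph chart
#'
#' Generates a 240 s (by default) five-channel recording containing one
#' irrelevant question and three (comparison, relevant) question pairs,
#' with the comparison question always preceding its paired relevant
#' question. Each question elicits a sympathetic-arousal response of
#' amplitude proportional to the condition: comparison questions have unit
#' expected amplitude, relevant questions `1 + effect_size` times that
#' under deception and `truthful_ratio` times under truth.
#'
#' Channel morphologies follow standard arousal phenomenology:
#' \itemize{
#'   \item skin conductance: constant tonic level plus event-locked
#'     bi-exponential transients (amplitude increases with arousal);
#'   \item PPG: a harmonic pulse train at `heart_rate_hz` whose envelope
#'     drops by an arousal-proportional fraction (peripheral
#'     vasoconstriction);
#'   \item blood pressure: baseline plus a slow arousal-proportional rise;
#'   \item thoracic/abdominal respiration: sinusoids at `resp_rate_hz`
#'     (abdominal lagged 0.3 rad) with arousal-proportional amplitude
#'     suppression.
#' }
#' All responses start `response_latency_s` after question onset; white
#' noise and random-walk drift are added to every channel.
#'
#' @param condition `"deceptive"` or `"truthful"`.
#' @param params a [sim_params()] object.
#' @param seed integer seed; identical `(condition, params, seed)` produce
#'   bit-identical recordings.
#' @param chart_id identifier stored in the recording.
#' @return A [session_recording()].
#' @export
simulate_chart <- function(condition = c("deceptive", "truthful"),
                           params = sim_params(), seed = params$seed,
                           chart_id = "chart1") {
  condition <- match.arg(condition)
  stopifnot(inherits(params, "sim_params"))
  with_seed(seed, simulate_chart_impl(condition, params, chart_id))
}

simulate_chart_impl <- function(condition, p, chart_id) {
  fs <- css_sampling_rate()
  n <- round(p$chart_duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  gap <- p$inter_question_gap_s

  comp_on <- 20 + (0:2) * 2 * gap
  rel_on <- comp_on + gap
  events <- data.frame(
    onset_s = c(5, as.vector(rbind(comp_on, rel_on))),
    kind = c("irrelevant",
             rep(c("comparison", "relevant"), times = 3)),
    pair_id = c(NA_integer_, rep(1:3, each = 2)))

  rel_gain <- if (condition == "deceptive") 1 + p$effect_size
              else p$truthful_ratio
  jit <- function(k) exp(rnorm(k, 0, p$amp_jitter_sd))
  amp <- numeric(nrow(events))
  amp[events$kind == "irrelevant"] <- 0.3 * jit(sum(events$kind == "irrelevant"))
  amp[events$kind == "comparison"] <- jit(3)
  amp[events$kind == "relevant"] <- rel_gain * jit(3)

  lat <- p$response_latency_s
  # fast electrodermal kernel and a slower cardiovascular/respiratory one
  a_scr <- event_response(t, events$onset_s, amp, lat, p$scr_rise_s,
                          p$scr_decay_s)
  a_slow <- event_response(t, events$onset_s, amp, lat, 1.5, 8)
  a_bp <- event_response(t, events$onset_s, amp, lat, 2, 10)

  phi <- runif(1, 0, 2 * pi)
  pulse <- 0.6 * sin(2 * pi * p$heart_rate_hz * t + phi) +
    0.25 * sin(4 * pi * p$heart_rate_hz * t + phi - 0.8) +
    0.08 * sin(6 * pi * p$heart_rate_hz * t + phi - 1.2)
  phr <- runif(1, 0, 2 * pi)

  clean <- list(
    ppg = exp(-0.35 * a_slow) * pulse,
    blood_pressure = 80 + 6 * a_bp,
    resp_thoracic = exp(-0.3 * a_slow) * sin(2 * pi * p$resp_rate_hz * t + phr),
    resp_abdominal = 0.9 * exp(-0.3 * a_slow) *
      sin(2 * pi * p$resp_rate_hz * t + phr - 0.3),
    skin_conductance = 8 + 1.5 * a_scr)

  # per-channel nominal scales so noise_sd/drift_sd are unitless fractions
  scale <- c(ppg = 0.5, blood_pressure = 2.0, resp_thoracic = 0.3,
             resp_abdominal = 0.3, skin_conductance = 0.3)
  channels <- lapply(css_channels(), function(ch) {
    x <- clean[[ch]] + rnorm(n, 0, p$noise_sd * scale[[ch]])
    if (p$drift_sd > 0)
      x <- x + cumsum(rnorm(n, 0, p$drift_sd * scale[[ch]] / sqrt(fs)))
    x
  })
  names(channels) <- css_channels()
  session_recording(chart_id, channels, events)
}

#' Simulate a full dataset of examination series
#'
#' Produces `n_deceptive_series + n_truthful_series` series of three charts
#' each (so nine question sets per series). Question-set labels inherit the
#' series condition: every set of a deceptive series is labeled deceptive.
#' With 42 deceptive and 36 truthful series this reproduces the reference
#' study size of 78 series, 234 charts and 702 question sets (378
#' deceptive-labeled, 324 truthful-labeled).
#'
#' Per-chart seeds are derived deterministically from `seed`, so the same
#' call always yields byte-identical traces.
#'
#' @param n_deceptive_series,n_truthful_series nonnegative counts.
#' @param params a [sim_params()].
#' @param seed master seed.
#' @return `list(recordings=, manifest=)` as accepted by [write_dataset()]
#'   and [build_segments()].
#' @export
simulate_dataset <- function(n_deceptive_series, n_truthful_series,
                             params = sim_params(), seed = params$seed) {
  stopifnot(n_deceptive_series >= 0, n_truthful_series >= 0)
  cond <- c(rep("deceptive", n_deceptive_series),
            rep("truthful", n_truthful_series))
  recordings <- list()
  rows <- list()
  for (s in seq_along(cond)) {
    sid <- sprintf("S%03d", s)
    for (j in 1:3) {
      cid <- sprintf("%s_C%d", sid, j)
      rec <- simulate_chart(cond[s], params,
                            seed = derive_seed(seed, s, j), chart_id = cid)
      recordings[[length(recordings) + 1L]] <- rec
      rows[[length(rows) + 1L]] <- data.frame(
        series_id = sid, participant_id = sprintf("P%03d", s),
        chart_id = cid, chart_index = j, ground_truth = cond[s])
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(series_id = character(), participant_id = character(),
               chart_id = character(), chart_index = integer(),
               ground_truth = character())
  list(recordings = recordings, manifest = manifest)
}
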