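#' Thresholds for the firing-pattern taxonomy
#'
#' @param delay_ms Minimum first-spike latency for the delayed type, ms.
#'   The published taxonomy does not quantify "delay"; delayed exemplar
#'   traces show multi-hundred-ms latencies, and 200 ms is the default
#'   here.
#' @param doublet_isi_ms Maximum initial interspike interval for the
#'   initial-doublet type, ms (published value: 40 ms).
#' @param burst_rate_hz Minimum instantaneous rate within the initial
#'   burst, Hz (published value: 25 Hz).
#' @param cv_regular Maximum coefficient of variation of late ISIs for a
#'   train to count as regular (the taxonomy says only "not a regular
#'   frequency"; 0.5 is the default here).
#' @param span_fraction Fraction of the step the train must span for
#'   "firing throughout".
#' @param late_window_ms Length of the final window over which ISI
#'   regularity is assessed, ms.
#' @return A list of thresholds for [classify_firing()].
#' @export
firing_type_thresholds <- function(delay_ms = 200, doublet_isi_ms = 40,
                                   burst_rate_hz = 25, cv_regular = 0.5,
                                   span_fraction = 0.75,
                                   late_window_ms = 500) {
  list(delay_ms = delay_ms, doublet_isi_ms = doublet_isi_ms,
       burst_rate_hz = burst_rate_hz, cv_regular = cv_regular,
       span_fraction = span_fraction, late_window_ms = late_window_ms)
}

isi_cv <- function(isis) {
  if (length(isis) < 2) return(NA_real_)
  sd(isis) / mean(isis)
}

#' Classify a spike train into one of the four firing types
#'
#' Applies the published taxonomy with an explicit precedence order:
#' (1) delayed if the first-spike latency is at least `delay_ms`;
#' (2) initial burst if the train opens with three or more spikes at
#' instantaneous rate above `burst_rate_hz` and the remainder of the step
#' is silent or irregular; (3) initial doublet if the initial ISI is under
#' `doublet_isi_ms` and firing continues regularly through the step at a
#' lower steady rate; (4) tonic if firing spans the step regularly;
#' (5) unclassified otherwise. Exactly one label is always assigned, and
#' the label is invariant to shifting all spike times by the step onset.
#'
#' @param spike_times Spike times, ms (same clock as `step_onset`).
#' @param step_onset Step onset, ms.
#' @param step_duration Step duration, ms (1000 ms convention).
#' @param thresholds A [firing_type_thresholds()] list.
#' @return A list with `firing_type`, `first_spike_latency_ms`,
#'   `initial_isi_ms` (present iff >= 2 spikes), `initial_rate_hz`,
#'   `steady_rate_hz`, and `isi_cv_late`.
#' @export
classify_firing <- function(spike_times, step_onset = 0,
                            step_duration = 1000,
                            thresholds = firing_type_thresholds()) {
  th <- thresholds
  t <- sort(spike_times) - step_onset
  t <- t[t >= 0 & t < step_duration]
  n <- length(t)
  res <- list(firing_type = "unclassified",
              first_spike_latency_ms = NA_real_,
              initial_isi_ms = NA_real_, initial_rate_hz = NA_real_,
              steady_rate_hz = 0, isi_cv_late = NA_real_)
  if (n == 0) return(res)
  res$first_spike_latency_ms <- t[1]
  isis <- diff(t)
  if (n >= 2) {
    res$initial_isi_ms <- isis[1]
    res$initial_rate_hz <- 1000 / isis[1]
  }
  # leading high-rate group: run of initial ISIs under the burst/doublet ISI
  burst_isi <- 1000 / th$burst_rate_hz
  m <- 0L
  while (m < length(isis) && isis[m + 1L] < min(th$doublet_isi_ms, burst_isi)) {
    m <- m + 1L
  }
  group_size <- m + 1L
  group_end <- t[group_size]
  post <- t[t > group_end]
  # regularity over the final window
  late <- t[t >= step_duration - th$late_window_ms]
  cv_late <- isi_cv(diff(late))
  res$isi_cv_late <- cv_late
  post_isis <- diff(post)
  res$steady_rate_hz <- if (length(post) > 0) {
    length(post) / ((step_duration - group_end) / 1000)
  } else if (group_size == n && m == 0L) n / (step_duration / 1000) else 0
  spans <- n >= 2 && t[n] >= th$span_fraction * step_duration
  overall_cv <- isi_cv(isis)
  regular_cv <- if (!is.na(cv_late)) cv_late else overall_cv
  post_regular <- length(post) > 0 &&
    (length(post_isis) < 2 || isi_cv(post_isis) <= th$cv_regular) &&
    t[n] >= th$span_fraction * step_duration

  if (t[1] >= th$delay_ms) {
    res$firing_type <- "delayed"
  } else if (group_size >= 3 &&
             (length(post) == 0 ||
              !(length(post) >= 3 && isi_cv(post_isis) <= th$cv_regular))) {
    res$firing_type <- "initial_burst"
  } else if (!is.na(res$initial_isi_ms) &&
             res$initial_isi_ms < th$doublet_isi_ms &&
             group_size >= 2 && post_regular &&
             res$steady_rate_hz < res$initial_rate_hz) {
    res$firing_type <- "initial_doublet"
  } else if (spans && !is.na(regular_cv) && regular_cv <= th$cv_regular) {
    res$firing_type <- "tonic"
  } else if (spans && n >= 2 && is.na(regular_cv)) {
    # too few late ISIs to assess; fall back to the overall CV
    res$firing_type <- if (!is.na(overall_cv) &&
                           overall_cv <= th$cv_regular) "tonic" else "unclassified"
  }
  res
}
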