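moving_average <- function(x, k) {
  if (k <= 1) return(x)
  k <- as.integer(k)
  if (k %% 2 == 0) k <- k + 1L
  stats::filter(x, rep(1 / k, k), sides = 2) |>
    as.numeric() |>
    (\(v) { # fall back to raw values at the edges
      v[is.na(v)] <- x[is.na(v)]
      v
    })()
}

#' Detect action potentials in a current-clamp sweep
#'
#' One event is returned per suprathreshold excursion. The voltage
#' threshold of each event is the membrane potential at the first sample
#' where dV/dt exceeds `dvdt_threshold` before the peak (the operational
#' reading of "first deflection of the AP"; the conventional range is
#' 10-20 mV/ms).
#'
#' @param sweep A current-clamp `sweep`.
#' @param dvdt_threshold Threshold-detection slope, mV/ms (default 10).
#' @param min_peak_mv Minimum peak voltage for a candidate excursion, mV.
#'   Set below 0 mV so that QC-failing spikes (peak < 0 mV) are still
#'   detected and can trigger the downstream QC exclusion.
#' @param smooth_ms Moving-average window applied before differentiation,
#'   ms.
#' @param lookback_ms How far before a peak to search for the threshold
#'   crossing, ms.
#' @return A `data.frame` with one row per spike: `threshold_time_ms`,
#'   `threshold_voltage_mv`, `peak_time_ms`, `peak_voltage_mv`, sorted by
#'   time.
#' @export
detect_spikes <- function(sweep, dvdt_threshold = 10, min_peak_mv = -20,
                          smooth_ms = 0.3, lookback_ms = 10) {
  if (!identical(sweep$clamp_mode, "current")) {
    stop("detect_spikes requires a current-clamp sweep")
  }
  t_ms <- sweep$time_ms
  v <- sweep$response
  dt <- t_ms[2] - t_ms[1]
  vs <- moving_average(v, round(smooth_ms / dt))
  n <- length(v)
  dvdt <- c(0, diff(vs)) / dt
  # candidate peaks: local maxima of the smoothed trace above min_peak_mv
  is_peak <- c(FALSE, vs[2:(n - 1)] >= vs[1:(n - 2)] &
                 vs[2:(n - 1)] > vs[3:n], FALSE) & vs >= min_peak_mv
  idx <- which(is_peak)
  if (length(idx) == 0) {
    return(data.frame(threshold_time_ms = numeric(0),
                      threshold_voltage_mv = numeric(0),
                      peak_time_ms = numeric(0),
                      peak_voltage_mv = numeric(0)))
  }
  # merge candidates within 2 ms, keep the highest
  ord <- order(-vs[idx])
  taken <- rep(FALSE, length(idx))
  for (j in ord) {
    if (any(taken & abs(t_ms[idx] - t_ms[idx[j]]) < 2)) next
    taken[j] <- TRUE
  }
  idx <- sort(idx[taken])
  look <- round(lookback_ms / dt)
  rows <- lapply(idx, function(p) {
    lo <- max(1, p - look)
    seg <- dvdt[lo:p]
    fast <- which(seg >= dvdt_threshold)
    if (length(fast) == 0) return(NULL) # slow crest, not a spike
    th <- lo + min(fast) - 1L
    # refine peak on the raw trace near the smoothed peak
    w <- max(1, p - round(0.25 / dt)):min(n, p + round(0.25 / dt))
    praw <- w[which.max(v[w])]
    data.frame(threshold_time_ms = t_ms[th],
               threshold_voltage_mv = vs[th],
               peak_time_ms = t_ms[praw],
               peak_voltage_mv = v[praw])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(threshold_time_ms = numeric(0),
                      threshold_voltage_mv = numeric(0),
                      peak_time_ms = numeric(0),
                      peak_voltage_mv = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$threshold_time_ms), , drop = FALSE]
}

sweep_is <- function(sweep, kind) identical(sweep$stimulus$kind, kind)
step_amplitude <- function(sweep) sweep$stimulus$amplitude_pa

step_sweeps <- function(recording, pred) {
  Filter(function(s) sweep_is(s, "step") && pred(step_amplitude(s)),
         recording$sweeps)
}

# mean response over the last `frac` of the step epoch
steady_state <- function(sweep, frac = 0.2) {
  e <- sweep$epoch_ms
  lo <- e[2] - frac * (e[2] - e[1])
  mean(sweep$response[sweep$time_ms >= lo & sweep$time_ms < e[2]])
}

pre_step_baseline <- function(sweep, window_ms = 50) {
  e <- sweep$epoch_ms
  mean(sweep$response[sweep$time_ms >= e[1] - window_ms &
                        sweep$time_ms < e[1]])
}

#' Passive membrane properties
#'
#' Resting potential is the mean voltage over the resting epoch; input
#' resistance is the least-squares slope of steady-state voltage deflection
#' against injected current over the hyperpolarizing steps; the time
#' constant is the time to reach 63% of the maximal deflection on the
#' subthreshold depolarizing step; capacitance is computed as
#' `Cm = tau / Rin` in consistent units (pF = ms / MOhm x 1000).
#'
#' @param recording A `neuron_recording`.
#' @return A list with `em_mv`, `rin_mohm`, `tau_ms`, `cm_pf` (missing
#'   values as `NA` when the needed sweeps are absent).
#' @export
measure_passive <- function(recording) {
  em <- NA_real_
  rest <- Filter(function(s) sweep_is(s, "rest"), recording$sweeps)
  if (length(rest) > 0) em <- mean(rest[[1]]$response)

  hyper <- step_sweeps(recording, function(a) a < 0)
  rin <- NA_real_
  if (length(hyper) >= 1) {
    if (length(hyper) < 2) {
      warning("input resistance estimated from a single hyperpolarizing step")
    }
    di <- vapply(hyper, step_amplitude, numeric(1))
    dv <- vapply(hyper, function(s) steady_state(s) - pre_step_baseline(s),
                 numeric(1))
    rin <- if (length(hyper) == 1) dv / di * 1000 else
      unname(coef(lm(dv ~ di))[2]) * 1000
  }

  tau <- NA_real_
  sub <- recording$sweeps$subthreshold
  if (!is.null(sub)) {
    base <- pre_step_baseline(sub)
    vss <- steady_state(sub)
    target <- base + 0.63 * (vss - base)
    e <- sub$epoch_ms
    on <- sub$time_ms >= e[1] & sub$time_ms < e[2]
    tt <- sub$time_ms[on]
    vv <- sub$response[on]
    hit <- if (vss > base) which(vv >= target) else which(vv <= target)
    if (length(hit) > 0) tau <- tt[hit[1]] - e[1]
  }
  cm <- if (!is.na(tau) && !is.na(rin)) tau / rin * 1000 else NA_real_
  list(em_mv = em, rin_mohm = rin, tau_ms = tau, cm_pf = cm)
}

#' Rheobase from the depolarizing step family
#'
#' @param recording A `neuron_recording` whose protocol includes the
#'   depolarizing step family on a 2 pA grid.
#' @param ... Passed to [detect_spikes()].
#' @return Smallest step amplitude (pA) whose sweep contains at least one
#'   spike.
#' @export
find_rheobase <- function(recording, ...) {
  fam <- step_sweeps(recording, function(a) a > 0)
  fam <- Filter(function(s) !sweep_is(s, "rest"), fam)
  if (length(fam) == 0) stop("no depolarizing step sweeps in recording")
  amps <- vapply(fam, step_amplitude, numeric(1))
  ord <- order(amps)
  fam <- fam[ord]; amps <- amps[ord]
  spiking <- vapply(fam, function(s) nrow(detect_spikes(s, ...)) > 0,
                    logical(1))
  if (!any(spiking)) stop("no rheobase: no spikes at any tested step")
  first <- which(spiking)[1]
  if (first == 1) warning("cell spiked at the lowest tested amplitude; ",
                          "rheobase may be below the tested grid")
  unname(amps[first])
}

#' Action-potential waveform metrics at rheobase
#'
#' Metrics are taken from the first AP of the rheobase step, or from the
#' last AP of the initial doublet/burst when `firing_type_hint` is given
#' (the AHP of those cells follows the final spike of the initial group).
#' The half width is measured at the voltage midway between threshold and
#' peak; the fast-AHP trough is the minimum within `fahp_window_ms` after
#' the downward threshold re-crossing; the slow-AHP trough is the minimum
#' in the 10-300 ms window after a 2 ms moving average, truncated before
#' the next spike. The normalized fAHP amplitude is
#' `(threshold - trough) / (peak - threshold)`.
#'
#' @param sweep The rheobase-step sweep.
#' @param events Spike events from [detect_spikes()] on that sweep.
#' @param firing_type_hint Optional firing-type label.
#' @param fahp_window_ms,sahp_window_ms Search windows, ms.
#' @return A list with `ap_threshold_mv`, `ap_halfwidth_ms`,
#'   `fahp_amplitude_norm`, `fahp_duration_ms`, `sahp_duration_ms`.
#' @export
ap_waveform_metrics <- function(sweep, events, firing_type_hint = NULL,
                                fahp_window_ms = 10,
                                sahp_window_ms = c(10, 300)) {
  if (nrow(events) < 1) stop("no spike events supplied")
  pick <- 1L
  if (!is.null(firing_type_hint) &&
      firing_type_hint %in% c("initial_doublet", "initial_burst") &&
      nrow(events) >= 2) {
    isis <- diff(events$threshold_time_ms)
    m <- 0L
    while (m < length(isis) && isis[m + 1L] < 40) m <- m + 1L
    pick <- m + 1L
  }
  ev <- events[pick, ]
  t_ms <- sweep$time_ms; v <- sweep$response
  dt <- t_ms[2] - t_ms[1]
  thr <- ev$threshold_voltage_mv
  pk <- ev$peak_voltage_mv
  p_idx <- which.min(abs(t_ms - ev$peak_time_ms))

  # half width at the level midway from threshold to peak, with linear
  # interpolation of the two crossings
  level <- (thr + pk) / 2
  th_idx <- which.min(abs(t_ms - ev$threshold_time_ms))
  up <- NA_real_; down <- NA_real_
  for (i in th_idx:p_idx) {
    if (v[i] < level && v[i + 1] >= level) {
      up <- t_ms[i] + dt * (level - v[i]) / (v[i + 1] - v[i]); break
    }
  }
  i <- p_idx
  while (i < length(v) - 1) {
    if (v[i] >= level && v[i + 1] < level) {
      down <- t_ms[i] + dt * (v[i] - level) / (v[i] - v[i + 1]); break
    }
    i <- i + 1
  }
  halfwidth <- down - up

  # fast AHP: minimum within the window after the downward threshold
  # re-crossing
  recross <- NA_integer_
  i <- p_idx
  while (i < length(v)) {
    if (v[i] <= thr) { recross <- i; break }
    i <- i + 1
  }
  fahp_amp <- NA_real_; fahp_dur <- NA_real_; sahp_dur <- NA_real_
  if (!is.na(recross)) {
    win <- t_ms >= t_ms[recross] & t_ms <= t_ms[recross] + fahp_window_ms
    tr_idx <- which(win)[which.min(v[win])]
    trough <- v[tr_idx]
    fahp_dur <- t_ms[tr_idx] - ev$threshold_time_ms
    fahp_amp <- (thr - trough) / (pk - thr)
  }

  # slow AHP: smoothed minimum in the late window, truncated before the
  # next spike
  next_thr <- if (pick < nrow(events)) {
    events$threshold_time_ms[pick + 1L]
  } else Inf
  lo <- ev$threshold_time_ms + sahp_window_ms[1]
  hi <- min(ev$threshold_time_ms + sahp_window_ms[2], next_thr - 5,
            max(t_ms))
  if (hi > lo) {
    vs <- moving_average(v, round(2 / dt))
    win <- which(t_ms >= lo & t_ms <= hi)
    s_idx <- win[which.min(vs[win])]
    sahp_dur <- t_ms[s_idx] - ev$threshold_time_ms
  }
  list(ap_threshold_mv = thr, ap_halfwidth_ms = halfwidth,
       fahp_amplitude_norm = fahp_amp, fahp_duration_ms = fahp_dur,
       sahp_duration_ms = sahp_dur)
}

#' Firing output: F/I slope and firing rates
#'
#' The F/I slope is the least-squares slope of the spike count over the
#' 1-s step (Hz) against injected current over the frequency-current
#' family; the rate at 1.5x rheobase and the resting rate are counts per
#' duration (the resting rate is extrapolated from the resting epoch).
#'
#' @param recording A `neuron_recording`.
#' @param fi_amplitudes Amplitudes of the F/I family, pA.
#' @param ... Passed to [detect_spikes()].
#' @return A list with `fi_slope_hz_per_pa`, `rate_at_1p5x_hz`,
#'   `resting_rate_hz` and the per-sweep `fi_counts`.
#' @export
measure_firing_output <- function(recording, fi_amplitudes = seq(1, 49, 3),
                                  ...) {
  fi <- recording$sweeps[sprintf("fi_%g", fi_amplitudes)]
  fi <- fi[!vapply(fi, is.null, logical(1))]
  fi_slope <- NA_real_; counts <- NULL
  if (length(fi) >= 2) {
    amps <- vapply(fi, step_amplitude, numeric(1))
    counts <- vapply(fi, function(s) {
      ev <- detect_spikes(s, ...)
      e <- s$epoch_ms
      dur_s <- (e[2] - e[1]) / 1000
      sum(ev$threshold_time_ms >= e[1] & ev$threshold_time_ms < e[2]) / dur_s
    }, numeric(1))
    fi_slope <- unname(coef(lm(counts ~ amps))[2])
  }
  rate15 <- NA_real_
  supra <- recording$sweeps$suprathreshold
  if (!is.null(supra)) {
    ev <- detect_spikes(supra, ...)
    e <- supra$epoch_ms
    rate15 <- sum(ev$threshold_time_ms >= e[1] & ev$threshold_time_ms < e[2]) /
      ((e[2] - e[1]) / 1000)
  }
  resting <- NA_real_
  rest <- recording$sweeps$rest
  if (!is.null(rest)) {
    ev <- detect_spikes(rest, ...)
    resting <- nrow(ev) / (diff(range(rest$time_ms)) / 1000)
  }
  list(fi_slope_hz_per_pa = fi_slope, rate_at_1p5x_hz = rate15,
       resting_rate_hz = resting,
       fi_counts = if (is.null(counts)) NULL else
         data.frame(i_pa = vapply(fi, step_amplitude, numeric(1)),
                    rate_hz = counts))
}

#' Persistent-inward-current onset from a slow voltage ramp
#'
#' Fits a leak line to the early (subthreshold) segment of the I-V
#' relation, then reports the command voltage at which the leak-subtracted
#' current first falls below `-max(k * sigma, floor_pa)` and stays below
#' for at least `sustain_ms`.
#'
#' @param ramp_sweep A voltage-clamp ramp `sweep` (28 mV/s convention; a
#'   different slope in the metadata produces a warning, not an error).
#' @param leak_fraction Fraction of the ramp used for the leak fit.
#' @param k Noise multiplier for the deflection criterion.
#' @param sustain_ms Minimum sustained deflection, ms.
#' @param floor_pa Absolute floor of the deflection criterion, pA (keeps
#'   the criterion meaningful on noise-free traces).
#' @return Onset voltage, mV, or `NA` when no sustained negative
#'   deflection is found ("no PIC detected").
#' @export
detect_pic_onset <- function(ramp_sweep, leak_fraction = 0.3, k = 3,
                             sustain_ms = 20, floor_pa = 1) {
  if (!identical(ramp_sweep$clamp_mode, "voltage")) {
    stop("detect_pic_onset requires a voltage-clamp ramp sweep")
  }
  if (sweep_is(ramp_sweep, "ramp") &&
      !is.null(ramp_sweep$stimulus$rate_mv_per_s) &&
      abs(ramp_sweep$stimulus$rate_mv_per_s - 28) > 1e-6) {
    warning("ramp slope differs from the 28 mV/s convention; proceeding")
  }
  v <- ramp_sweep$command
  i <- ramp_sweep$response
  t_ms <- ramp_sweep$time_ms
  dt <- t_ms[2] - t_ms[1]
  n <- length(v)
  fitreg <- seq_len(max(10, floor(leak_fraction * n)))
  fit <- lm(i[fitreg] ~ v[fitreg])
  resid_all <- i - (coef(fit)[1] + coef(fit)[2] * v)
  sigma <- sd(resid_all[fitreg])
  crit <- -max(k * sigma, floor_pa)
  below <- resid_all < crit
  need <- max(1L, round(sustain_ms / dt))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= need)
  if (length(ok) == 0) return(NA_real_)
  v[starts[ok[1]]]
}

#' Extract the 12-property feature vector from a recording
#'
#' Composes the passive, rheobase, waveform, firing-output and PIC
#' measurements, and applies the QC exclusion rules: a neuron fails QC when
#' its resting potential is more depolarized than -40 mV or any detected
#' AP peak does not reach 0 mV. Missing protocol elements yield explicit
#' `NA` markers (never zeros) and are listed in the `log` attribute.
#'
#' @param recording A `neuron_recording`.
#' @param firing_type_hint Optional label steering which AP the AHP metrics
#'   are taken from; when `NULL` and the suprathreshold sweep is present,
#'   the hint is derived with [classify_firing()].
#' @param ... Passed to [detect_spikes()].
#' @return A one-row `data.frame` with the 12 feature columns, the optional
#'   extras `rate_at_1p5x_hz` and `resting_rate_hz`, `firing_type`, and
#'   `qc_pass`; per-field provenance notes in `attr(, "log")`.
#' @export
extract_features <- function(recording, firing_type_hint = NULL, ...) {
  if (!inherits(recording, "neuron_recording")) {
    stop("`recording` must be a neuron_recording")
  }
  if (length(recording$sweeps) == 0) stop("empty recording: no sweeps")
  log <- character(0)
  note <- function(msg) log <<- c(log, msg)

  pass <- measure_passive(recording)
  if (is.na(pass$tau_ms)) note("no subthreshold depolarizing sweep: tau/cm missing")

  rheo <- tryCatch(find_rheobase(recording, ...), error = function(e) {
    note(conditionMessage(e)); NA_real_
  })

  wf <- list(ap_threshold_mv = NA_real_, ap_halfwidth_ms = NA_real_,
             fahp_amplitude_norm = NA_real_, fahp_duration_ms = NA_real_,
             sahp_duration_ms = NA_real_)
  peaks <- numeric(0)
  ft <- NA_character_
  supra <- recording$sweeps$suprathreshold
  if (!is.null(supra)) {
    ev_supra <- detect_spikes(supra, ...)
    peaks <- c(peaks, ev_supra$peak_voltage_mv)
    if (is.null(firing_type_hint)) {
      e <- supra$epoch_ms
      ft <- classify_firing(ev_supra$threshold_time_ms, e[1],
                            e[2] - e[1])$firing_type
    } else ft <- firing_type_hint
  }
  if (!is.na(rheo)) {
    rs <- recording$sweeps[[sprintf("grid_%g", rheo)]]
    if (is.null(rs)) rs <- step_sweeps(recording, function(a) a == rheo)[[1]]
    ev <- detect_spikes(rs, ...)
    peaks <- c(peaks, ev$peak_voltage_mv)
    if (nrow(ev) > 0) {
      wf <- ap_waveform_metrics(rs, ev, firing_type_hint = ft)
    }
  } else note("no rheobase: waveform metrics missing")

  fo <- measure_firing_output(recording, ...)
  if (is.na(fo$fi_slope_hz_per_pa)) note("F/I family missing: fi_slope missing")

  pic <- NA_real_
  ramp <- recording$sweeps$ramp
  if (!is.null(ramp)) {
    pic <- detect_pic_onset(ramp)
    if (is.na(pic)) note("no PIC detected on ramp")
  } else note("no ramp sweep: pic_on missing")

  qc <- TRUE
  if (!is.na(pass$em_mv) && pass$em_mv > -40) {
    qc <- FALSE; note("QC fail: resting potential more depolarized than -40 mV")
  }
  if (length(peaks) > 0 && any(peaks < 0)) {
    qc <- FALSE; note("QC fail: AP peak did not reach 0 mV")
  }

  out <- data.frame(
    neuron_id = recording$neuron_id,
    em_mv = pass$em_mv, rin_mohm = pass$rin_mohm, tau_ms = pass$tau_ms,
    cm_pf = pass$cm_pf, rheobase_pa = rheo,
    ap_threshold_mv = wf$ap_threshold_mv,
    ap_halfwidth_ms = wf$ap_halfwidth_ms,
    fahp_duration_ms = wf$fahp_duration_ms,
    sahp_duration_ms = wf$sahp_duration_ms,
    fahp_amplitude_norm = wf$fahp_amplitude_norm,
    pic_on_mv = pic, fi_slope_hz_per_pa = fo$fi_slope_hz_per_pa,
    rate_at_1p5x_hz = fo$rate_at_1p5x_hz,
    resting_rate_hz = fo$resting_rate_hz,
    firing_type = ft, qc_pass = qc,
    stringsAsFactors = FALSE
  )
  attr(out, "log") <- log
  out
}
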