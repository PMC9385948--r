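#' Stimulus protocol specification
#'
#' Describes the sweep families of a full characterization protocol:
#' a resting epoch, hyperpolarizing current steps, a subthreshold
#' depolarizing step, a 2 pA-grid depolarizing family for rheobase, a 1-s
#' suprathreshold step at 1.5x rheobase, the frequency-current family
#' (1-49 pA in 3 pA increments), and a slow (28 mV/s) voltage-clamp ramp.
#'
#' @param sampling_rate_hz Sampling rate, Hz (acquisition convention:
#'   20 kHz).
#' @param rest_duration_ms Length of the resting recording, ms. The resting
#'   firing rate is extrapolated from this epoch.
#' @param step_onset_ms,step_duration_ms,step_post_ms Current-step timing,
#'   ms; epochs are half-open `[onset, offset)`.
#' @param hyper_steps_pa Hyperpolarizing step amplitudes, pA.
#' @param rheobase_grid_pa Depolarizing step amplitudes for the rheobase
#'   search, pA; `NULL` builds a 2 pA grid bracketing the archetype's
#'   rheobase at synthesis time.
#' @param subthreshold_step_pa Amplitude of the subthreshold depolarizing
#'   step used for the time constant; `NULL` picks 4 pA below rheobase.
#' @param fi_steps_pa Frequency-current family amplitudes, pA.
#' @param supra_factor Multiple of rheobase for the suprathreshold
#'   classification step.
#' @param ramp_rate_mv_per_s,ramp_from_mv,ramp_to_mv Voltage-clamp ramp.
#' @param holding_mv Holding potential for step protocols, mV.
#' @param include Character vector naming which sweep families to build.
#' @return A list of class `"protocol_spec"`.
#' @export
protocol_spec <- function(sampling_rate_hz = 20000, rest_duration_ms = 5000,
                          step_onset_ms = 100, step_duration_ms = 1000,
                          step_post_ms = 100,
                          hyper_steps_pa = c(-20, -15, -10, -5),
                          rheobase_grid_pa = NULL,
                          subthreshold_step_pa = NULL,
                          fi_steps_pa = seq(1, 49, by = 3),
                          supra_factor = 1.5,
                          ramp_rate_mv_per_s = 28, ramp_from_mv = -70,
                          ramp_to_mv = -30, holding_mv = -70,
                          include = c("rest", "hyper", "sub", "grid",
                                      "supra", "fi", "ramp")) {
  include <- match.arg(include, several.ok = TRUE)
  structure(
    list(sampling_rate_hz = sampling_rate_hz,
         rest_duration_ms = rest_duration_ms,
         step_onset_ms = step_onset_ms, step_duration_ms = step_duration_ms,
         step_post_ms = step_post_ms, hyper_steps_pa = hyper_steps_pa,
         rheobase_grid_pa = rheobase_grid_pa,
         subthreshold_step_pa = subthreshold_step_pa,
         fi_steps_pa = fi_steps_pa, supra_factor = supra_factor,
         ramp_rate_mv_per_s = ramp_rate_mv_per_s,
         ramp_from_mv = ramp_from_mv, ramp_to_mv = ramp_to_mv,
         holding_mv = holding_mv, include = include),
    class = "protocol_spec"
  )
}

new_sweep <- function(clamp_mode, time_ms, command, response, epoch_ms,
                      stimulus) {
  structure(
    list(clamp_mode = clamp_mode, time_ms = time_ms, command = command,
         response = response, epoch_ms = epoch_ms, stimulus = stimulus),
    class = "sweep"
  )
}

# Spike times (ms, relative to step onset) placed by the archetype rules
# for a step of amplitude `i_pa`. Empty when i_pa is below rheobase.
archetype_spike_times <- function(params, i_pa, duration_ms) {
  if (i_pa < params$rheobase) return(numeric(0))
  lat <- params$first_spike_latency
  extra <- i_pa - params$rheobase
  margin <- 10
  regular_from <- function(t0, rate_hz) {
    if (rate_hz <= 0) return(numeric(0))
    isi <- 1000 / rate_hz
    tt <- seq(t0 + isi, duration_ms - margin, by = isi)
    tt[tt > t0]
  }
  switch(params$firing_type,
    tonic = {
      rate <- params$steady_rate + params$fi_gain * extra
      n <- max(1L, as.integer(round(rate * (duration_ms - lat) / 1000)))
      if (n == 1L) lat else
        lat + (0:(n - 1L)) * (duration_ms - lat - margin) / (n - 1L)
    },
    initial_doublet = {
      t2 <- lat + params$initial_isi
      rate <- params$steady_rate + params$fi_gain * extra
      c(lat, t2, regular_from(t2, rate))
    },
    initial_burst = {
      lat + (0:(params$n_initial_spikes - 1L)) * params$initial_isi
    },
    delayed = {
      rate <- params$steady_rate + params$fi_gain * extra
      c(lat, regular_from(lat, rate))
    }
  )
}

# Additive spike-deviation template evaluated at offsets `s` (ms) from the
# threshold-crossing time. Amplitudes are expressed relative to the
# designed rheobase-step plateau, so absolute voltages on the rheobase
# sweep equal the archetype's threshold/peak/trough values exactly.
# `include_sahp` lets the caller attach a single cumulative slow AHP to
# the last spike of an initial doublet/burst instead of stacking one per
# spike (which would depress the baseline under the measured spike).
spike_deviation <- function(s, params, pre_slope = 5, tau_rec = 3,
                            include_sahp = TRUE) {
  vhold <- -70
  b <- vhold + params$rheobase * params$input_resistance / 1000
  thr <- params$ap_threshold
  pk <- params$ap_peak
  trough <- thr - params$fahp_depth
  w <- params$ap_halfwidth
  t_f <- params$fahp_latency
  t_pre <- (thr - b) / pre_slope
  d <- numeric(length(s))
  i <- s >= -t_pre & s < 0
  d[i] <- (thr - b) * (1 + s[i] / t_pre)
  i <- s >= 0 & s < w
  d[i] <- (thr - b) + (pk - thr) * s[i] / w
  i <- s >= w & s < 2 * w
  d[i] <- (pk - b) - (pk - thr) * (s[i] - w) / w
  i <- s >= 2 * w & s < t_f
  d[i] <- (thr - b) + (trough - thr) * (s[i] - 2 * w) / (t_f - 2 * w)
  i <- s >= t_f
  d[i] <- (trough - b) * exp(-(s[i] - t_f) / tau_rec)
  # slow AHP: alpha function with its minimum at sahp_latency
  if (include_sahp) {
    i <- s > 0
    d[i] <- d[i] - params$sahp_depth *
      (s[i] / params$sahp_latency) * exp(1 - s[i] / params$sahp_latency)
  }
  d
}

# RC step response around a holding baseline (current clamp, mV).
passive_step <- function(t_ms, onset, offset, i_pa, rin, tau, base) {
  dv <- i_pa * rin / 1000
  v <- rep(base, length(t_ms))
  on <- t_ms >= onset & t_ms < offset
  v[on] <- base + dv * (1 - exp(-(t_ms[on] - onset) / tau))
  off <- t_ms >= offset
  v_off <- dv * (1 - exp(-(offset - onset) / tau))
  v[off] <- base + v_off * exp(-(t_ms[off] - offset) / tau)
  v
}

make_cc_step_sweep <- function(params, protocol, i_pa, with_spikes = TRUE,
                               noise_sd = params$noise_sd) {
  dt <- 1000 / protocol$sampling_rate_hz
  onset <- protocol$step_onset_ms
  offset <- onset + protocol$step_duration_ms
  total <- offset + protocol$step_post_ms
  t_ms <- seq(0, total, by = dt)
  base <- protocol$holding_mv
  v <- passive_step(t_ms, onset, offset, i_pa, params$input_resistance,
                    params$time_constant, base)
  spikes <- numeric(0)
  if (with_spikes && i_pa > 0) {
    spikes <- archetype_spike_times(params, i_pa, protocol$step_duration_ms)
    # one cumulative slow AHP follows an initial doublet/burst
    group <- switch(params$firing_type,
                    initial_doublet = 2L,
                    initial_burst = params$n_initial_spikes, 1L)
    for (j in seq_along(spikes)) {
      s <- t_ms - (onset + spikes[j])
      win <- s >= -20 & s <= 400
      v[win] <- v[win] +
        spike_deviation(s[win], params, include_sahp = j >= group)
    }
  }
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
  cmd <- ifelse(t_ms >= onset & t_ms < offset, i_pa, 0)
  sw <- new_sweep("current", t_ms, cmd, v, c(onset, offset),
                  list(kind = "step", amplitude_pa = i_pa))
  attr(sw, "spike_times_ms") <- onset + spikes
  sw
}

make_rest_sweep <- function(params, protocol) {
  dt <- 1000 / protocol$sampling_rate_hz
  t_ms <- seq(0, protocol$rest_duration_ms, by = dt)
  v <- rep(params$resting_potential, length(t_ms))
  if (params$noise_sd > 0) v <- v + rnorm(length(v), 0, params$noise_sd)
  new_sweep("current", t_ms, rep(0, length(t_ms)), v,
            c(0, protocol$rest_duration_ms), list(kind = "rest"))
}

make_ramp_sweep <- function(params, protocol, g_pic = 3) {
  dt <- 1000 / protocol$sampling_rate_hz
  span <- protocol$ramp_to_mv - protocol$ramp_from_mv
  total <- span / protocol$ramp_rate_mv_per_s * 1000
  t_ms <- seq(0, total, by = dt)
  v <- protocol$ramp_from_mv + protocol$ramp_rate_mv_per_s * t_ms / 1000
  i <- (v - params$resting_potential) / params$input_resistance * 1000
  over <- v > params$pic_onset
  i[over] <- i[over] - g_pic * (v[over] - params$pic_onset)
  if (params$noise_sd > 0) i <- i + rnorm(length(i), 0, params$noise_sd)
  new_sweep("voltage", t_ms, v, i, c(0, total),
            list(kind = "ramp", rate_mv_per_s = protocol$ramp_rate_mv_per_s,
                 from_mv = protocol$ramp_from_mv,
                 to_mv = protocol$ramp_to_mv))
}

#' Synthesize a whole-cell recording from an archetype
#'
#' Builds template-based current- and voltage-clamp sweeps: RC passive
#' responses plus stereotyped action-potential waveforms placed at
#' archetype-rule spike times, with additive Gaussian noise, and a
#' voltage-clamp ramp whose leak-linear current shows an inward deflection
#' beginning at the archetype's PIC onset. The ground-truth parameter
#' record is attached so extraction error is measurable.
#'
#' @param params An [archetype_params()] object.
#' @param protocol A [protocol_spec()]; must include the sweep families
#'   needed by the downstream feature extractors.
#' @param seed Integer seed for the additive noise.
#' @param neuron_id Identifier stored in the recording.
#' @return An object of class `"neuron_recording"`: a list with `neuron_id`,
#'   `sampling_rate_hz`, `holding_mv`, `sweeps` (named list), and
#'   `ground_truth` (true parameter values plus the true feature vector the
#'   extractors should recover).
#' @export
synthesize_recording <- function(params, protocol = protocol_spec(),
                                 seed = 1L, neuron_id = "synthetic") {
  if (!inherits(params, "archetype_params")) stop("`params` must be archetype_params")
  if (!inherits(protocol, "protocol_spec")) stop("`protocol` must be a protocol_spec")
  inc <- protocol$include
  grid <- protocol$rheobase_grid_pa
  if (is.null(grid)) grid <- seq(2, params$rheobase + 6, by = 2)
  sub_pa <- protocol$subthreshold_step_pa
  if (is.null(sub_pa)) sub_pa <- max(2, params$rheobase - 4)
  supra_pa <- round(protocol$supra_factor * params$rheobase)
  sweeps <- list()
  withr::with_seed(seed, {
    if ("rest" %in% inc) sweeps$rest <- make_rest_sweep(params, protocol)
    if ("hyper" %in% inc) {
      for (i_pa in protocol$hyper_steps_pa) {
        sweeps[[sprintf("hyper_%g", i_pa)]] <-
          make_cc_step_sweep(params, protocol, i_pa, with_spikes = FALSE)
      }
    }
    if ("sub" %in% inc) {
      sweeps$subthreshold <-
        make_cc_step_sweep(params, protocol, sub_pa, with_spikes = sub_pa >= params$rheobase)
    }
    if ("grid" %in% inc) {
      for (i_pa in grid) {
        sweeps[[sprintf("grid_%g", i_pa)]] <-
          make_cc_step_sweep(params, protocol, i_pa)
      }
    }
    if ("supra" %in% inc) {
      sweeps$suprathreshold <- make_cc_step_sweep(params, protocol, supra_pa)
    }
    if ("fi" %in% inc) {
      for (i_pa in protocol$fi_steps_pa) {
        sweeps[[sprintf("fi_%g", i_pa)]] <-
          make_cc_step_sweep(params, protocol, i_pa)
      }
    }
    if ("ramp" %in% inc) sweeps$ramp <- make_ramp_sweep(params, protocol)
  })
  fi_counts <- vapply(protocol$fi_steps_pa, function(i_pa) {
    length(archetype_spike_times(params, i_pa, protocol$step_duration_ms))
  }, numeric(1))
  fi_slope <- if (length(protocol$fi_steps_pa) >= 2) {
    unname(coef(lm(fi_counts ~ protocol$fi_steps_pa))[2])
  } else NA_real_
  supra_spikes <- archetype_spike_times(params, supra_pa,
                                        protocol$step_duration_ms)
  truth <- list(
    params = unclass(params),
    features = c(
      em_mv = params$resting_potential,
      rin_mohm = params$input_resistance,
      tau_ms = params$time_constant,
      cm_pf = params$time_constant / params$input_resistance * 1000,
      rheobase_pa = params$rheobase,
      ap_threshold_mv = params$ap_threshold,
      ap_halfwidth_ms = params$ap_halfwidth,
      fahp_duration_ms = params$fahp_latency,
      sahp_duration_ms = params$sahp_latency,
      fahp_amplitude_norm = params$fahp_depth /
        (params$ap_peak - params$ap_threshold),
      pic_on_mv = params$pic_onset,
      fi_slope_hz_per_pa = fi_slope
    ),
    firing_type = params$firing_type,
    fi_counts = data.frame(i_pa = protocol$fi_steps_pa, count = fi_counts),
    supra_spike_times_ms = protocol$step_onset_ms + supra_spikes,
    supra_amplitude_pa = supra_pa
  )
  structure(
    list(neuron_id = neuron_id,
         sampling_rate_hz = protocol$sampling_rate_hz,
         holding_mv = protocol$holding_mv,
         protocol = protocol, sweeps = sweeps, ground_truth = truth),
    class = "neuron_recording"
  )
}

#' @export
print.neuron_recording <- function(x, ...) {
  cat(sprintf("<neuron_recording> %s: %d sweeps @ %g kHz\n", x$neuron_id,
              length(x$sweeps), x$sampling_rate_hz / 1000))
  invisible(x)
}
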