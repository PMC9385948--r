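#' Firing-archetype parameters
#'
#' An archetype is a parametric description of one of the four firing
#' phenotypes seen in adult spinal Shox2/Chx10 neurons, with enough passive
#' and active-waveform parameters to synthesize a full recording
#' ([synthesize_recording()]) whose extracted features have known ground
#' truth.
#'
#' @param firing_type One of `"tonic"`, `"initial_doublet"`,
#'   `"initial_burst"`, `"delayed"`.
#' @param resting_potential Resting membrane potential, mV (<= -40 for a
#'   QC-passing archetype).
#' @param input_resistance Input resistance, MOhm (> 0).
#' @param time_constant Membrane time constant, ms (> 0).
#' @param rheobase Minimal spiking current, pA (placed on the 2 pA grid).
#' @param ap_threshold AP voltage threshold, mV.
#' @param ap_peak AP peak voltage, mV (>= 0 for a QC-passing archetype).
#' @param ap_halfwidth AP width at the voltage midway between threshold and
#'   peak, ms.
#' @param fahp_depth Fast-AHP trough depth below threshold, mV. Must place
#'   the trough below the rheobase-step plateau so the trough is a genuine
#'   local minimum.
#' @param fahp_latency Time from AP threshold to the fast-AHP trough, ms.
#' @param sahp_depth Slow-AHP trough depth below the inter-spike baseline,
#'   mV.
#' @param sahp_latency Time from AP threshold to the slow-AHP trough, ms.
#' @param steady_rate Steady firing rate, Hz (for the doublet archetype,
#'   the post-doublet steady frequency; default 3.9 Hz).
#' @param fi_gain Increment of firing rate per pA above rheobase, Hz/pA.
#' @param initial_isi First interspike interval for doublet/burst
#'   archetypes, ms (< 40).
#' @param n_initial_spikes Number of spikes in the initial burst.
#' @param first_spike_latency Latency from step onset to the first spike,
#'   ms.
#' @param pic_onset Voltage at which the persistent inward current begins
#'   on the voltage ramp, mV.
#' @param noise_sd Additive Gaussian noise SD (mV in current clamp, pA in
#'   voltage clamp).
#' @return An object of class `"archetype_params"`.
#' @export
archetype_params <- function(firing_type, resting_potential, input_resistance,
                             time_constant, rheobase, ap_threshold, ap_peak,
                             ap_halfwidth, fahp_depth, fahp_latency,
                             sahp_depth, sahp_latency, steady_rate,
                             fi_gain = 0.2, initial_isi = NA_real_,
                             n_initial_spikes = 1L,
                             first_spike_latency = 130, pic_onset = -48,
                             noise_sd = 0.3) {
  firing_type <- match.arg(firing_type, FIRING_TYPES)
  stopifnot(resting_potential <= -40, input_resistance > 0, time_constant > 0,
            ap_peak > ap_threshold, fahp_depth > 0, fahp_latency > ap_halfwidth * 2,
            sahp_latency > fahp_latency, noise_sd >= 0)
  if (firing_type %in% c("initial_doublet", "initial_burst") &&
      (is.na(initial_isi) || initial_isi >= 40)) {
    stop("doublet/burst archetypes need initial_isi < 40 ms")
  }
  structure(
    list(firing_type = firing_type, resting_potential = resting_potential,
         input_resistance = input_resistance, time_constant = time_constant,
         rheobase = rheobase, ap_threshold = ap_threshold, ap_peak = ap_peak,
         ap_halfwidth = ap_halfwidth, fahp_depth = fahp_depth,
         fahp_latency = fahp_latency, sahp_depth = sahp_depth,
         sahp_latency = sahp_latency, steady_rate = steady_rate,
         fi_gain = fi_gain, initial_isi = initial_isi,
         n_initial_spikes = as.integer(n_initial_spikes),
         first_spike_latency = first_spike_latency, pic_onset = pic_onset,
         noise_sd = noise_sd),
    class = "archetype_params"
  )
}

#' Catalog of the four firing archetypes
#'
#' Returns one parameter set per firing phenotype: tonic (regular firing
#' throughout the 1-s step), initial doublet (first ISI < 40 ms, then slower
#' regular firing at a steady frequency of 3.9 Hz), initial burst (>= 3
#' initial spikes above 25 Hz, then silence), and delayed (first spike
#' hundreds of ms into the step). Parameters are chosen so that the firing
#' classifier ([classify_firing()]) labels each archetype correctly and all
#' pass the recording QC rules. First-spike latencies sit at >= ~5 membrane
#' time constants so spike templates ride a settled RC baseline, which makes
#' the ground truth exact for extraction testing.
#'
#' @return A named list of four [archetype_params()] objects.
#' @export
archetype_catalog <- function() {
  list(
    tonic = archetype_params(
      firing_type = "tonic", resting_potential = -49, input_resistance = 700,
      time_constant = 25, rheobase = 22, ap_threshold = -36, ap_peak = 20,
      ap_halfwidth = 1.0, fahp_depth = 22, fahp_latency = 4, sahp_depth = 2,
      sahp_latency = 60, steady_rate = 3.0, fi_gain = 0.6,
      first_spike_latency = 130, pic_onset = -48, noise_sd = 0.3),
    initial_doublet = archetype_params(
      firing_type = "initial_doublet", resting_potential = -50,
      input_resistance = 800, time_constant = 28, rheobase = 18,
      ap_threshold = -36, ap_peak = 18, ap_halfwidth = 1.2, fahp_depth = 23,
      fahp_latency = 5, sahp_depth = 2.5, sahp_latency = 60,
      steady_rate = 3.9, fi_gain = 0.1, initial_isi = 25,
      n_initial_spikes = 2L, first_spike_latency = 130, pic_onset = -50,
      noise_sd = 0.3),
    initial_burst = archetype_params(
      firing_type = "initial_burst", resting_potential = -48,
      input_resistance = 650, time_constant = 26, rheobase = 24,
      ap_threshold = -37, ap_peak = 22, ap_halfwidth = 1.2, fahp_depth = 21,
      fahp_latency = 5, sahp_depth = 3, sahp_latency = 100, steady_rate = 0,
      fi_gain = 0, initial_isi = 25, n_initial_spikes = 4L,
      first_spike_latency = 130, pic_onset = -52, noise_sd = 0.3),
    delayed = archetype_params(
      firing_type = "delayed", resting_potential = -50,
      input_resistance = 450, time_constant = 20, rheobase = 28,
      ap_threshold = -33.5, ap_peak = 21, ap_halfwidth = 1.4,
      fahp_depth = 27, fahp_latency = 5.5, sahp_depth = 2,
      sahp_latency = 70, steady_rate = 2.5, fi_gain = 0.15,
      first_spike_latency = 400, pic_onset = -44, noise_sd = 0.3)
  )
}

#' @export
print.archetype_params <- function(x, ...) {
  cat(sprintf("<archetype_params> %s: Rin %g MOhm, tau %g ms, rheobase %g pA, thr %g mV\n",
              x$firing_type, x$input_resistance, x$time_constant,
              x$rheobase, x$ap_threshold))
  invisible(x)
}
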