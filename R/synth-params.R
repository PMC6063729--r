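# Archetype parameter sets for the synthetic-recording generator. The two
# archetypes encode the qualitative contrasts the analysis is built to
# detect: principal cells have sub-millisecond PSPs, small non-overshooting
# APs and onset-only firing; non-principal cells have slow summing PSPs,
# large overshooting APs and sustained/chopper firing.

# Evaluate a block with a temporary RNG seed, restoring the caller's RNG
# state afterwards, so every generator is a pure function of (params, seed).
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Construct an archetype parameter set
#'
#' Bundles every free parameter of the synthetic generator. The defaults of
#' [principal_archetype()] and [nonprincipal_archetype()] are the study
#' conditions used throughout the tests; amplitudes, rates and latencies the
#' source measurements do not pin down are documented choices (see the
#' methods vignette).
#'
#' @param class_label `"principal"` or `"non_principal"`.
#' @param epsp_half_width,ipsp_half_width PSP full width at half maximum (ms).
#' @param epsp_rate_spont,ipsp_rate_spont spontaneous event rates (events/s).
#' @param epsp_amp,ipsp_amp mean PSP peak amplitudes (mV, positive numbers;
#'   IPSPs are applied with negative sign).
#' @param epsp_amp_sd,ipsp_amp_sd amplitude jitter SD (mV).
#' @param ap_amp_mean action-potential amplitude above baseline (mV).
#' @param ap_threshold absolute voltage threshold for spontaneous spike
#'   initiation (mV).
#' @param resting_vm resting membrane potential (mV, junction-corrected).
#' @param firing_mode `"onset"`, `"chopper"`, or `"sustained_irregular"`.
#' @param chopper_isi_mean,chopper_isi_cv gamma-renewal interspike-interval
#'   mean (ms) and coefficient of variation (in \[0, 1)).
#' @param ipsp_latency_at_ref IPSP onset latency (ms) at the reference sound
#'   level `ref_level_db`.
#' @param ipsp_latency_slope latency decrease per dB above reference (ms/dB).
#' @param ref_level_db reference sound level (dB SPL).
#' @param noise_sd Gaussian recording-noise SD (mV).
#' @param membrane_tau membrane time constant (ms).
#' @param sag_fraction fractional relaxation of the peak current-step
#'   deflection toward steady state (I_h sag).
#' @param r_in input resistance (MOhm).
#' @param evoked_onset_rate,evoked_sustained_rate ipsilaterally evoked EPSP
#'   event rates (events/s) at the onset burst and during the sustained
#'   response.
#' @param contra_onset_rate,contra_sustained_rate contralaterally evoked
#'   IPSP event rates (events/s), onset burst and sustained.
#' @param adapt_tau decay time constant of the onset burst rate (ms).
#' @param evoked_amp mean evoked PSP amplitude (mV).
#' @param onset_latency excitatory response latency (ms).
#' @param ild_midpoint,ild_width true ILD logistic midpoint (dB) and width
#'   (dB) used for binaural spike suppression.
#' @param spont_spike_rate spontaneous firing rate for sustained archetypes
#'   (spikes/s; onset cells spike spontaneously only by summation).
#' @return an object of class `lso_archetype` (a validated list).
#' @export
archetype_params <- function(class_label,
                             epsp_half_width, ipsp_half_width,
                             epsp_rate_spont, ipsp_rate_spont,
                             epsp_amp, ipsp_amp,
                             epsp_amp_sd = 0.3 * epsp_amp,
                             ipsp_amp_sd = 0.3 * ipsp_amp,
                             ap_amp_mean, ap_threshold, resting_vm,
                             firing_mode,
                             chopper_isi_mean = 5, chopper_isi_cv = 0.2,
                             ipsp_latency_at_ref = 6,
                             ipsp_latency_slope = 0.12,
                             ref_level_db = 50,
                             noise_sd = 0.3, membrane_tau = 1,
                             sag_fraction = 0.15, r_in = 60,
                             evoked_onset_rate = 9000,
                             evoked_sustained_rate = 1200,
                             contra_onset_rate = 4000,
                             contra_sustained_rate = 150,
                             adapt_tau = 4, evoked_amp = 0.9,
                             onset_latency = 3,
                             ild_midpoint = -10, ild_width = 3,
                             spont_spike_rate = 0) {
  class_label <- match.arg(class_label, c("principal", "non_principal"))
  firing_mode <- match.arg(firing_mode,
                           c("onset", "chopper", "sustained_irregular"))
  if (epsp_half_width <= 0 || ipsp_half_width <= 0)
    stop("PSP half-widths must be positive")
  if (chopper_isi_cv < 0 || chopper_isi_cv >= 1)
    stop("chopper_isi_cv must lie in [0, 1)")
  if (ap_amp_mean <= 0) stop("ap_amp_mean must be positive")
  structure(as.list(environment()), class = "lso_archetype")
}

#' Default principal-cell archetype
#'
#' Fast sub-millisecond EPSPs, small (~28 mV) non-overshooting action
#' potentials, onset-only firing, strong onset adaptation of the evoked
#' drive, fast membrane.
#'
#' @param ... overrides passed to [archetype_params()].
#' @return an `lso_archetype`.
#' @export
principal_archetype <- function(...) {
  defaults <- list(
    class_label = "principal",
    epsp_half_width = 0.6, ipsp_half_width = 1.2,
    epsp_rate_spont = 200, ipsp_rate_spont = 40,
    epsp_amp = 3.5, ipsp_amp = 2.0,
    ap_amp_mean = 28, ap_threshold = -45, resting_vm = -60,
    firing_mode = "onset",
    membrane_tau = 1, r_in = 45, sag_fraction = 0.15,
    evoked_onset_rate = 9000, evoked_sustained_rate = 1200,
    contra_onset_rate = 4000, contra_sustained_rate = 150,
    adapt_tau = 4, evoked_amp = 0.9,
    ipsp_latency_at_ref = 6, ipsp_latency_slope = 0.12)
  do.call(archetype_params, utils::modifyList(defaults, list(...)))
}

#' Default non-principal-cell archetype
#'
#' Slow summing EPSPs (half widths of several ms), large (~66 mV)
#' overshooting action potentials, sustained chopper firing, weak onset
#' adaptation, slower membrane and higher input resistance.
#'
#' @param ... overrides passed to [archetype_params()].
#' @return an `lso_archetype`.
#' @export
nonprincipal_archetype <- function(...) {
  defaults <- list(
    class_label = "non_principal",
    epsp_half_width = 4, ipsp_half_width = 6,
    epsp_rate_spont = 150, ipsp_rate_spont = 40,
    epsp_amp = 3.0, ipsp_amp = 2.5,
    ap_amp_mean = 66, ap_threshold = -50, resting_vm = -60,
    firing_mode = "chopper",
    chopper_isi_mean = 5, chopper_isi_cv = 0.2,
    membrane_tau = 6, r_in = 90, sag_fraction = 0.1,
    evoked_onset_rate = 400, evoked_sustained_rate = 250,
    contra_onset_rate = 400, contra_sustained_rate = 250,
    adapt_tau = 8, evoked_amp = 1.2,
    ipsp_latency_at_ref = 7, ipsp_latency_slope = 0.08)
  do.call(archetype_params, utils::modifyList(defaults, list(...)))
}
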