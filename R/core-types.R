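#' Construct a membrane-potential sweep
#'
#' A `Sweep` is one uniformly sampled membrane-potential trace (mV) with its
#' stimulus metadata. Time 0 is stimulus (or current-step) onset by
#' convention; `t0_offset` gives the time of the first sample relative to
#' that onset, so a sweep that starts 10 ms before the tone has
#' `t0_offset = -10`.
#'
#' @param samples numeric vector of membrane potential (mV); must be finite.
#' @param sampling_rate sampling rate in Hz, within 1-200 kHz.
#' @param t0_offset time of first sample relative to stimulus onset (ms).
#' @param stimulus a [tone_stimulus()], a [current_step()], or the string
#'   `"spontaneous"`.
#' @param series_resistance electrode series resistance (MOhm), optional.
#' @param junction_corrected has the liquid-junction correction been applied?
#' @return an object of class `lso_sweep`.
#' @seealso [correct_junction_potential()], [baseline_median()]
#' @export
sweep_trace <- function(samples, sampling_rate, t0_offset = 0,
                        stimulus = "spontaneous",
                        series_resistance = NA_real_,
                        junction_corrected = FALSE) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("sweep samples must be finite")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate < 1e3 || sampling_rate > 200e3) {
    stop("sampling_rate must be a single value in [1, 200] kHz")
  }
  ok_stim <- identical(stimulus, "spontaneous") ||
    inherits(stimulus, "lso_tone") || inherits(stimulus, "lso_step")
  if (!ok_stim) stop("stimulus must be 'spontaneous', a tone_stimulus or a current_step")
  structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         t0_offset = as.numeric(t0_offset), stimulus = stimulus,
         series_resistance = as.numeric(series_resistance),
         junction_corrected = isTRUE(junction_corrected)),
    class = "lso_sweep")
}

#' Time axis of a sweep
#'
#' @param sweep an `lso_sweep`.
#' @return numeric vector of sample times (ms relative to stimulus onset).
#' @export
sweep_times <- function(sweep) {
  stopifnot(inherits(sweep, "lso_sweep"))
  sweep$t0_offset + (seq_along(sweep$samples) - 1) / sweep$sampling_rate * 1000
}

#' @export
print.lso_sweep <- function(x, ...) {
  dur <- length(x$samples) / x$sampling_rate * 1000
  stim <- if (is.character(x$stimulus)) x$stimulus else class(x$stimulus)[1]
  cat(sprintf("<lso_sweep> %.1f ms @ %.0f kHz, stimulus: %s%s\n",
              dur, x$sampling_rate / 1000, stim,
              if (x$junction_corrected) " (junction-corrected)" else ""))
  invisible(x)
}

#' Construct a tone stimulus descriptor
#'
#' Describes a monaural or binaural pure-tone presentation. The interaural
#' level difference follows the convention
#' `ILD = level_contra - level_ipsi`, so negative ILDs mean the
#' (excitatory) ipsilateral ear is louder.
#'
#' @param ear one of `"ipsi"`, `"contra"`, `"binaural"`.
#' @param frequency tone frequency (Hz).
#' @param level_ipsi,level_contra sound levels (dB SPL); the level of an
#'   unused ear must be `NA`.
#' @param duration tone duration (ms), positive.
#' @param onset stimulus onset time (ms); 0 by convention.
#' @param n_reps number of repetitions collected with this stimulus.
#' @return an object of class `lso_tone`.
#' @export
tone_stimulus <- function(ear, frequency, level_ipsi = NA_real_,
                          level_contra = NA_real_, duration = 50,
                          onset = 0, n_reps = 1L) {
  ear <- match.arg(ear, c("ipsi", "contra", "binaural"))
  if (duration <= 0) stop("tone duration must be positive")
  if (ear %in% c("ipsi", "binaural") && !is.finite(level_ipsi))
    stop("level_ipsi required for ipsi/binaural stimulus")
  if (ear %in% c("contra", "binaural") && !is.finite(level_contra))
    stop("level_contra required for contra/binaural stimulus")
  if (ear == "ipsi") level_contra <- NA_real_
  if (ear == "contra") level_ipsi <- NA_real_
  structure(
    list(ear = ear, frequency = as.numeric(frequency),
         level_ipsi = as.numeric(level_ipsi),
         level_contra = as.numeric(level_contra),
         duration = as.numeric(duration), onset = as.numeric(onset),
         n_reps = as.integer(n_reps)),
    class = "lso_tone")
}

#' Interaural level difference of a tone stimulus
#'
#' `ILD = level_contra - level_ipsi` (negative = ipsilateral louder).
#'
#' @param stim an `lso_tone` with both levels present.
#' @return ILD in dB.
#' @export
ild_of <- function(stim) {
  stopifnot(inherits(stim, "lso_tone"))
  if (!is.finite(stim$level_contra) || !is.finite(stim$level_ipsi))
    stop("ILD requires a binaural stimulus")
  stim$level_contra - stim$level_ipsi
}

#' Construct a current-step descriptor
#'
#' @param amplitude injected current (pA); negative = hyperpolarizing.
#' @param duration step duration (ms), positive.
#' @param onset step onset (ms); 0 by convention.
#' @return an object of class `lso_step`.
#' @export
current_step <- function(amplitude, duration = 100, onset = 0) {
  if (duration <= 0) stop("step duration must be positive")
  structure(list(amplitude = as.numeric(amplitude),
                 duration = as.numeric(duration), onset = as.numeric(onset)),
            class = "lso_step")
}

#' Construct a cell record
#'
#' One recorded neuron: its sweeps grouped by protocol plus anatomy fields.
#' Protocol names are free-form keys (the generator uses `"spontaneous"`,
#' `"ipsi_tone"`, `"contra_tone"`, `"ild"`, `"current_step"`).
#'
#' @param cell_id character identifier.
#' @param sweeps named list of protocols; each protocol is a list of
#'   `lso_sweep` objects sharing one sampling rate.
#' @param anatomical_class one of `"principal"`, `"class5"`, `"marginal"`,
#'   `"multiplanar"`, `"unknown"`.
#' @param CF,BF characteristic / best frequency (Hz), optional.
#' @param normalized_position lateromedial soma position in \[0, 1\]
#'   (0 = lateral edge, 1 = medial edge), optional.
#' @param coverage_percent somatic synaptic coverage (%), optional.
#' @return an object of class `lso_cell`.
#' @export
cell_record <- function(cell_id, sweeps = list(),
                        anatomical_class = "unknown",
                        CF = NA_real_, BF = NA_real_,
                        normalized_position = NA_real_,
                        coverage_percent = NA_real_) {
  anatomical_class <- match.arg(
    anatomical_class, c("principal", "class5", "marginal", "multiplanar", "unknown"))
  if (is.finite(normalized_position) &&
      (normalized_position < 0 || normalized_position > 1))
    stop("normalized_position must lie in [0, 1]")
  if (is.finite(coverage_percent) &&
      (coverage_percent < 0 || coverage_percent > 100))
    stop("coverage_percent must lie in [0, 100]")
  if (length(sweeps)) {
    if (is.null(names(sweeps)) || any(names(sweeps) == ""))
      stop("sweeps must be a named list of protocols")
    for (proto in names(sweeps)) {
      fs <- vapply(sweeps[[proto]], function(s) s$sampling_rate, numeric(1))
      if (length(fs) && length(unique(fs)) != 1L)
        stop(sprintf("protocol '%s': all sweeps must share one sampling rate", proto))
    }
  }
  structure(
    list(cell_id = as.character(cell_id), anatomical_class = anatomical_class,
         CF = as.numeric(CF), BF = as.numeric(BF),
         normalized_position = as.numeric(normalized_position),
         coverage_percent = as.numeric(coverage_percent), sweeps = sweeps),
    class = "lso_cell")
}

#' @export
print.lso_cell <- function(x, ...) {
  cat(sprintf("<lso_cell> %s (%s), %d protocol(s): %s\n",
              x$cell_id, x$anatomical_class, length(x$sweeps),
              paste(sprintf("%s[%d]", names(x$sweeps),
                            lengths(x$sweeps)), collapse = ", ")))
  invisible(x)
}
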