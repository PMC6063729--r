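#' Preprocess a spontaneous-activity sweep for spectral analysis
#'
#' The pipeline that precedes the amplitude spectrum: subtract the median Vm
#' of the first 10 ms, high-pass filter (zero-phase FIR, 10 Hz cutoff), and
#' wavelet-denoise (symlet-8, level 5, heuristic-SURE soft thresholding, no
#' rescaling).
#'
#' @param sweep a spontaneous `lso_sweep` of at least 0.5 s.
#' @return numeric trace, same length as the input samples.
#' @export
preprocess_spontaneous <- function(sweep) {
  stopifnot(inherits(sweep, "lso_sweep"))
  dur_s <- length(sweep$samples) / sweep$sampling_rate
  if (dur_s < 0.5) stop("insufficient spontaneous sample: need >= 0.5 s")
  x <- sweep$samples
  t <- sweep_times(sweep)
  base <- stats::median(x[t - t[1] < 10])
  x <- x - base
  h <- design_highpass(sweep$sampling_rate)
  x <- filtfilt_fir(x, h)
  wavelet_denoise(x, level = 5L)
}

#' Single-sided amplitude spectrum of a trace
#'
#' Computes the DFT magnitude, optionally smooths it with a running median
#' over logarithmically spaced frequencies (1/24 octave by default; raw
#' multi-second DFTs are too noisy for a stable half-maximum crossing), and
#' normalizes to the maximum. The smoothing method is recorded in the
#' result.
#'
#' @param trace numeric signal (typically from [preprocess_spontaneous()]).
#' @param sampling_rate Hz.
#' @param smooth `"median_log"` (default) or `"none"`.
#' @param octave_fraction width of the median window in octaves (default 1/24).
#' @param f_min lowest frequency retained (default 10 Hz, the high-pass cutoff).
#' @return an object of class `lso_spectrum` with fields `frequencies`,
#'   `normalized_amplitude`, `smooth`, and (after [upper_cutoff()])
#'   `upper_cutoff`.
#' @export
amplitude_spectrum <- function(trace, sampling_rate,
                               smooth = c("median_log", "none"),
                               octave_fraction = 1 / 24, f_min = 10) {
  smooth <- match.arg(smooth)
  n <- length(trace)
  if (n < 2) stop("trace too short for a spectrum")
  if (stats::sd(trace) == 0) stop("flat spectrum: trace is constant")
  mag <- Mod(stats::fft(trace))[seq_len(n %/% 2 + 1)]
  freq <- (seq_len(n %/% 2 + 1) - 1) * sampling_rate / n
  if (smooth == "none") {
    amp <- mag / max(mag)
    out <- list(frequencies = freq, normalized_amplitude = amp,
                smooth = smooth, upper_cutoff = NA_real_)
    class(out) <- "lso_spectrum"
    return(out)
  }
  nyq <- sampling_rate / 2
  if (f_min >= nyq) stop("f_min must be below Nyquist")
  n_grid <- ceiling(log2(nyq / f_min) / octave_fraction)
  grid <- f_min * 2^(octave_fraction * (0:n_grid))
  grid <- grid[grid <= nyq]
  half <- 2^(octave_fraction / 2)
  # each window holds at least min_bins raw bins: a fractional-octave window
  # near the low edge of a multi-second DFT spans only 1-2 Rayleigh-
  # distributed bins, whose maxima would otherwise set the normalization
  min_bins <- 41L
  nb <- length(freq)
  sm <- vapply(grid, function(f0) {
    i1 <- findInterval(f0 / half, freq) + 1L
    i2 <- findInterval(f0 * half - 1e-12, freq)
    if (i2 - i1 + 1L < min_bins) {
      ic <- which.min(abs(freq - f0))
      i1 <- max(1L, ic - min_bins %/% 2L)
      i2 <- min(nb, i1 + min_bins - 1L)
      i1 <- max(1L, i2 - min_bins + 1L)
    }
    stats::median(mag[i1:i2])
  }, numeric(1))
  sm <- stats::runmed(sm, 5, endrule = "median")  # settle residual wiggles
  if (max(sm) == 0) stop("flat spectrum: no power above f_min")
  out <- list(frequencies = grid, normalized_amplitude = sm / max(sm),
              smooth = smooth, upper_cutoff = NA_real_)
  class(out) <- "lso_spectrum"
  out
}

#' @export
print.lso_spectrum <- function(x, ...) {
  cat(sprintf("<lso_spectrum> %d bins (%.1f-%.0f Hz), smoothing: %s, cutoff: %s\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              x$smooth,
              if (is.finite(x$upper_cutoff)) sprintf("%.1f Hz", x$upper_cutoff)
              else "not computed"))
  invisible(x)
}

#' Upper cutoff frequency of a normalized amplitude spectrum
#'
#' The frequency at which the high-frequency flank of the normalized
#' spectrum first falls to `fraction` of its maximum (0.5, i.e. -6 dB, by
#' default), linearly interpolated between bins. The search starts at the
#' global maximum above 10 Hz; ties in the maximum are broken toward the
#' lowest frequency.
#'
#' @param spectrum an `lso_spectrum`.
#' @param fraction crossing level (default 0.5).
#' @return the cutoff in Hz; also stored in the returned spectrum by
#'   [spectral_cutoff()].
#' @export
upper_cutoff <- function(spectrum, fraction = 0.5) {
  stopifnot(inherits(spectrum, "lso_spectrum"))
  f <- spectrum$frequencies
  a <- spectrum$normalized_amplitude
  keep <- f >= 10
  f <- f[keep]; a <- a[keep]
  if (!length(f)) stop("no spectral bins at or above 10 Hz")
  peak <- which(a == max(a))[1]
  above <- a[peak:length(a)]
  fa <- f[peak:length(f)]
  idx <- which(above < fraction)
  if (!length(idx)) stop("cutoff not reached below Nyquist")
  i <- idx[1]
  if (i == 1L) return(fa[1])
  # linear interpolation between the last bin >= fraction and the crossing bin
  f1 <- fa[i - 1]; f2 <- fa[i]; a1 <- above[i - 1]; a2 <- above[i]
  f1 + (a1 - fraction) / (a1 - a2) * (f2 - f1)
}

#' Spectral upper cutoff of spontaneous activity, full pipeline
#'
#' Convenience wrapper: [preprocess_spontaneous()] then
#' [amplitude_spectrum()] then [upper_cutoff()].
#'
#' @param sweep a spontaneous `lso_sweep`.
#' @param fraction crossing level (default 0.5).
#' @param ... passed to [amplitude_spectrum()].
#' @return an `lso_spectrum` with `upper_cutoff` populated.
#' @export
spectral_cutoff <- function(sweep, fraction = 0.5, ...) {
  tr <- preprocess_spontaneous(sweep)
  sp <- amplitude_spectrum(tr, sweep$sampling_rate, ...)
  sp$upper_cutoff <- upper_cutoff(sp, fraction = fraction)
  sp
}

#' Detect action potentials in a sweep
#'
#' Spikes are local maxima preceded by a depolarization slope exceeding
#' `slope_threshold`, standing at least `min_prominence` above the local
#' baseline, separated by at least `refractory_ms`. The slope is measured
#' over a short span (0.3 ms) of a lightly smoothed trace so that the
#' detector works for both small (~15 mV) and large (~80 mV) action
#' potentials without firing on sampling noise; the prominence criterion
#' rejects fast sub-millisecond EPSPs whose slopes alone can exceed the
#' threshold.
#'
#' @param sweep an `lso_sweep`.
#' @param slope_threshold minimum dV/dt (mV/ms), default 10.
#' @param refractory_ms minimum spike separation (ms), default 1.
#' @param min_prominence minimum peak height above the local (2 ms) median
#'   baseline (mV), default 8.
#' @return data.frame with columns `time` (ms re stimulus onset) and
#'   `peak_vm` (mV); zero rows when no spikes are found.
#' @export
detect_spikes <- function(sweep, slope_threshold = 10, refractory_ms = 1,
                          min_prominence = 8) {
  stopifnot(inherits(sweep, "lso_sweep"))
  v <- sweep$samples
  fs <- sweep$sampling_rate
  n <- length(v)
  empty <- data.frame(time = numeric(0), peak_vm = numeric(0))
  k_sm <- max(1L, round(0.2e-3 * fs))          # 0.2 ms boxcar
  if (n < 4L * k_sm) return(empty)
  vs <- as.numeric(stats::filter(v, rep(1 / k_sm, k_sm), sides = 2))
  vs[is.na(vs)] <- v[is.na(vs)]
  k_sl <- max(1L, round(0.3e-3 * fs))          # slope over 0.3 ms
  slope <- c(rep(0, k_sl), (vs[(k_sl + 1):n] - vs[1:(n - k_sl)])) /
    (k_sl / fs * 1000)
  cand <- which(slope > slope_threshold)
  if (!length(cand)) return(empty)
  t <- sweep_times(sweep)
  refr_n <- round(refractory_ms / 1000 * fs)
  search_n <- max(1L, round(1.5e-3 * fs))      # peak search span after crossing
  base_n <- max(1L, round(2e-3 * fs))          # local baseline span
  times <- numeric(0); peaks <- numeric(0)
  last_peak_i <- -Inf
  # walk through contiguous runs of suprathreshold slope
  runs <- split(cand, cumsum(c(1L, diff(cand) > 1L)))
  for (run in runs) {
    i0 <- run[1]
    j <- i0:min(n, i0 + search_n)
    pk <- j[which.max(v[j])]
    if (pk - last_peak_i < refr_n) next
    b0 <- max(1L, i0 - base_n)
    local_base <- stats::median(v[b0:i0])
    if (v[pk] - local_base < min_prominence) next
    times <- c(times, t[pk]); peaks <- c(peaks, v[pk])
    last_peak_i <- pk
  }
  data.frame(time = times, peak_vm = peaks)
}

#' Action-potential amplitude from ipsilateral-tone sweeps
#'
#' For every detected spike across all sweeps, the amplitude is the Vm at
#' the spike peak minus the median Vm during the first 2 ms of the same
#' sweep (pre-stimulus baseline of that file); the mean over all spikes and
#' all presented sound levels is returned, pooling as in the population
#' scatter analyses.
#'
#' @param sweeps list of `lso_sweep`s (ipsi-tone repetitions).
#' @param ... passed to [detect_spikes()].
#' @return mean AP amplitude (mV).
#' @export
ap_amplitude <- function(sweeps, ...) {
  amps <- unlist(lapply(sweeps, function(s) {
    sp <- detect_spikes(s, ...)
    if (!nrow(sp)) return(numeric(0))
    t0 <- s$t0_offset
    base <- baseline_median(s, c(t0, t0 + 2))
    sp$peak_vm - base
  }))
  if (!length(amps)) stop("no APs detected in the provided sweeps")
  mean(amps)
}

#' Pointwise median evoked response
#'
#' The median Vm across repetitions at every sample; robust to occasional
#' spiking repetitions.
#'
#' @param sweeps list of at least 3 `lso_sweep`s of identical length for one
#'   stimulus condition.
#' @return an `lso_sweep` carrying the median trace (metadata from the first
#'   repetition).
#' @export
median_evoked <- function(sweeps) {
  if (length(sweeps) < 3) stop("median_evoked needs >= 3 repetitions")
  ns <- lengths(lapply(sweeps, function(s) s$samples))
  if (length(unique(ns)) != 1L) stop("ragged sweep lengths")
  m <- apply(do.call(cbind, lapply(sweeps, function(s) s$samples)), 1,
             stats::median)
  out <- sweeps[[1]]
  out$samples <- m
  out
}

#' Peak-to-sustained ratio of the evoked subthreshold response
#'
#' Repetitions containing a detected spike in either analysis window are
#' discarded; on the pointwise median of the remaining repetitions, the peak
#' is the maximum absolute deviation from the pre-stimulus baseline within
#' the onset window and the sustained level is the mean absolute deviation
#' within the sustained window. The sustained window defaults to 40-50 ms
#' for stimuli of at least 50 ms and 20-25 ms otherwise.
#'
#' @param sweeps list of `lso_sweep`s for one tone condition.
#' @param onset onset window (ms), default `c(5, 15)`.
#' @param sustained sustained window (ms) or `NULL` to auto-select from the
#'   stimulus duration.
#' @param ... passed to [detect_spikes()].
#' @return list with `ratio`, `peak_mV`, `sustained_mV`, `n_used`.
#' @export
peak_to_sustained <- function(sweeps, onset = c(5, 15), sustained = NULL, ...) {
  stopifnot(length(sweeps) >= 1)
  stim <- sweeps[[1]]$stimulus
  if (is.null(sustained)) {
    dur <- if (inherits(stim, "lso_tone")) stim$duration else 50
    sustained <- if (dur >= 50) c(40, 50) else c(20, 25)
  }
  keep <- vapply(sweeps, function(s) {
    sp <- detect_spikes(s, ...)
    !any((sp$time >= onset[1] & sp$time < onset[2]) |
           (sp$time >= sustained[1] & sp$time < sustained[2]))
  }, logical(1))
  if (sum(keep) < 3)
    stop("insufficient spike-free repetitions (need >= 3, have ",
         sum(keep), ")")
  med <- median_evoked(sweeps[keep])
  t <- sweep_times(med)
  base <- stats::median(med$samples[t < 0])
  if (!any(t < 0)) base <- stats::median(med$samples[t - t[1] < 2])
  dev <- abs(med$samples - base)
  pk <- max(dev[t >= onset[1] & t < onset[2]])
  sus <- mean(dev[t >= sustained[1] & t < sustained[2]])
  if (sus < 0.1) stop("sustained response below noise floor (< 0.1 mV)")
  list(ratio = pk / sus, peak_mV = pk, sustained_mV = sus, n_used = sum(keep))
}

#' Input resistance from a hyperpolarizing current step
#'
#' Steady-state resistance uses the median Vm during the last 10% of the
#' step; peak resistance uses the minimal Vm during the step. The baseline
#' is the median Vm over the 10 ms before step onset.
#'
#' @param step_sweep an `lso_sweep` recorded with a hyperpolarizing
#'   [current_step()] stimulus.
#' @param step the `lso_step`; defaults to the sweep's stimulus.
#' @return list with `r_steady` and `r_peak` (MOhm, positive).
#' @export
input_resistance <- function(step_sweep, step = NULL) {
  stopifnot(inherits(step_sweep, "lso_sweep"))
  if (is.null(step)) step <- step_sweep$stimulus
  if (!inherits(step, "lso_step")) stop("sweep has no current-step stimulus")
  if (step$amplitude >= 0) stop("hyperpolarizing steps only")
  t <- sweep_times(step_sweep)
  v <- step_sweep$samples
  base_sel <- t >= step$onset - 10 & t < step$onset
  if (!any(base_sel)) stop("no pre-step baseline samples")
  base <- stats::median(v[base_sel])
  in_step <- t >= step$onset & t < step$onset + step$duration
  last10 <- t >= step$onset + 0.9 * step$duration & t < step$onset + step$duration
  v_steady <- stats::median(v[last10])
  v_peak <- min(v[in_step])
  i_nA <- step$amplitude / 1000                 # pA -> nA; mV/nA = MOhm
  list(r_steady = (v_steady - base) / i_nA, r_peak = (v_peak - base) / i_nA)
}
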