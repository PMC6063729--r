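# Zero-phase FIR high-pass filtering. A 10 Hz cutoff with a <=5 Hz
# transition band at 50-100 kHz sampling requires tens of thousands of taps,
# so the filter is applied by FFT convolution (forward and time-reversed
# passes) rather than a direct recursion.

#' Design the spontaneous-activity high-pass FIR filter
#'
#' Windowed (Hamming) linear-phase FIR high-pass. The order is chosen so the
#' transition band is at most `transition_hz` wide at the given sampling
#' rate.
#'
#' @param sampling_rate Hz.
#' @param cutoff_hz high-pass cutoff (default 10 Hz).
#' @param transition_hz maximum transition-band width (default 5 Hz).
#' @return numeric vector of filter coefficients (odd length, symmetric).
#' @keywords internal
#' @export
design_highpass <- function(sampling_rate, cutoff_hz = 10, transition_hz = 5) {
  # Hamming-window design: transition width ~ 3.3 / N (normalized).
  n_taps <- ceiling(3.3 * sampling_rate / transition_hz)
  if (n_taps %% 2L == 1L) n_taps <- n_taps + 1L  # even order -> odd length
  signal::fir1(n_taps, cutoff_hz / (sampling_rate / 2), type = "high")
}

# Linear convolution via FFT, returning the "same"-length central part, with
# reflective padding of the signal so filter edge transients do not wrap.
fft_conv_same <- function(x, h) {
  n <- length(x); L <- length(h)
  pad <- min(L, n)
  xe <- c(rev(x[seq_len(pad)]), x, rev(x[n - seq_len(pad) + 1L]))
  m <- length(xe) + L - 1L
  nfft <- 2^ceiling(log2(m))
  X <- stats::fft(c(xe, numeric(nfft - length(xe))))
  H <- stats::fft(c(h, numeric(nfft - L)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  # centre of the linear convolution aligned with xe, then drop the padding
  delay <- (L - 1L) %/% 2L
  y[pad + delay + seq_len(n)]
}

#' Zero-phase high-pass filter a trace
#'
#' Applies the FIR filter forward and backward (time-reversed second pass)
#' so the net phase is zero; edges are reflection-padded.
#'
#' @param x numeric signal.
#' @param h FIR coefficients from [design_highpass()].
#' @return filtered signal, same length.
#' @keywords internal
#' @export
filtfilt_fir <- function(x, h) {
  y <- fft_conv_same(x, h)
  rev(fft_conv_same(rev(y), h))
}
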