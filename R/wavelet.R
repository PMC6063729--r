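# Orthogonal periodized discrete wavelet transform with the 16-tap
# symlet-8 filter, plus SURE-based soft-threshold denoising. Implemented
# in-package: the transform is small and the denoising conventions
# (per-level heuristic-SURE thresholds, soft shrinkage, no noise rescaling)
# must match the published analysis exactly.

# Symlet-8 scaling (low-pass decomposition) filter, standard published taps.
SYM8_LO <- c(
  -3.3824159510061256e-03, -5.4213233179114812e-04, 3.1695087811492981e-02,
   7.6074873249176054e-03, -1.4329423835080971e-01, -6.1273359067658524e-02,
   4.8135965125837221e-01,  7.7718575170052351e-01, 3.6444189483533140e-01,
  -5.1945838107709037e-02, -2.7219029917056003e-02, 4.9137179673607506e-02,
   3.8087520138906151e-03, -1.4952258337048231e-02, -3.0292051472136680e-04,
   1.8899503327594609e-03)

# Quadrature-mirror high-pass filter.
sym8_hi <- function() {
  L <- length(SYM8_LO)
  rev(SYM8_LO) * (-1)^(seq_len(L) - 1)
}

# One level of the periodized analysis transform. For an orthonormal filter
# pair the analysis matrix (even shifts of lo and hi, wrapped) is orthogonal,
# so the synthesis step below is its transpose and reconstruction is exact.
dwt_step <- function(x, lo, hi) {
  n <- length(x)
  if (n %% 2L == 1L) {
    x <- c(x, x[n])  # replicate last sample to make the length even
    n <- n + 1L
  }
  L <- length(lo)
  half <- n %/% 2L
  idx <- outer(2L * (seq_len(half) - 1L), seq_len(L) - 1L, "+") %% n + 1L
  xm <- matrix(x[idx], nrow = half, ncol = L)
  list(approx = drop(xm %*% lo), detail = drop(xm %*% hi), n_in = n)
}

idwt_step <- function(approx, detail, lo, hi, n_out) {
  half <- length(approx)
  n <- 2L * half
  L <- length(lo)
  x <- numeric(n)
  base <- 2L * (seq_len(half) - 1L)
  for (m in seq_len(L)) {
    pos <- (base + (m - 1L)) %% n + 1L
    contrib <- approx * lo[m] + detail * hi[m]
    # accumulate with wrap; positions can repeat across k only when n < L
    x[pos] <- x[pos] + contrib
  }
  x[seq_len(n_out)]
}

#' Multi-level periodized sym8 wavelet decomposition
#'
#' @param x numeric signal.
#' @param level number of decomposition levels (default 5).
#' @return list with `approx` (coarsest approximation), `details` (list,
#'   finest level first) and bookkeeping lengths for exact reconstruction.
#' @keywords internal
#' @export
wavelet_decompose <- function(x, level = 5L) {
  lo <- SYM8_LO; hi <- sym8_hi()
  if (length(x) < 2^level)
    stop("signal too short for ", level, "-level decomposition")
  details <- vector("list", level)
  n_ins <- integer(level)
  a <- x
  for (j in seq_len(level)) {
    st <- dwt_step(a, lo, hi)
    details[[j]] <- st$detail
    n_ins[j] <- length(a)
    a <- st$approx
  }
  list(approx = a, details = details, n_ins = n_ins, level = level)
}

#' Reconstruct a signal from a sym8 wavelet decomposition
#'
#' @param dec result of [wavelet_decompose()].
#' @return numeric signal of the original length.
#' @keywords internal
#' @export
wavelet_reconstruct <- function(dec) {
  lo <- SYM8_LO; hi <- sym8_hi()
  a <- dec$approx
  for (j in rev(seq_len(dec$level))) {
    a <- idwt_step(a, dec$details[[j]], lo, hi, dec$n_ins[j])
  }
  a
}

# Per-level threshold selection. With no rescaling the noise SD is taken as
# 1, i.e. thresholds act on the raw coefficient scale (the convention used
# in the source analysis). `sqtwolog` is the universal threshold; `rigrsure`
# minimizes Stein's unbiased risk estimate; `heursure` picks between them
# based on a sparsity heuristic.
sure_threshold <- function(d) {
  n <- length(d)
  s2 <- sort(d^2)
  risks <- (n - 2 * seq_len(n) + cumsum(s2) + (n - seq_len(n)) * s2) / n
  sqrt(s2[which.min(risks)])
}

heursure_threshold <- function(d) {
  n <- length(d)
  univ <- sqrt(2 * log(n))
  eta <- (sum(d^2) - n) / n
  crit <- (log2(n))^1.5 / sqrt(n)
  if (eta < crit) univ else min(sure_threshold(d), univ)
}

soft_threshold <- function(d, thr) sign(d) * pmax(abs(d) - thr, 0)

#' Wavelet-denoise a trace (sym8, level 5, heuristic-SURE soft thresholding)
#'
#' Decomposes the signal with the periodized symlet-8 transform, soft-
#' thresholds each detail level with a heuristic-SURE threshold computed on
#' the raw coefficient scale (no noise rescaling), and reconstructs. The
#' approximation coefficients are left untouched.
#'
#' @param x numeric signal (mV).
#' @param level decomposition depth (default 5).
#' @return denoised signal, same length as `x`.
#' @export
wavelet_denoise <- function(x, level = 5L) {
  dec <- wavelet_decompose(x, level = level)
  dec$details <- lapply(dec$details, function(d) {
    soft_threshold(d, heursure_threshold(d))
  })
  wavelet_reconstruct(dec)
}
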