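#' Extract spike trains from a set of sweeps
#'
#' Runs [detect_spikes()] on every repetition and collects the spike times
#' (ms re stimulus onset) into an `lso_trains` object.
#'
#' @param sweeps list of `lso_sweep`s sharing one stimulus.
#' @param ... passed to [detect_spikes()].
#' @return an `lso_trains`: list with `trains` (list of numeric vectors) and
#'   `stimulus`.
#' @export
extract_trains <- function(sweeps, ...) {
  stopifnot(length(sweeps) >= 1)
  trains <- lapply(sweeps, function(s) sort(detect_spikes(s, ...)$time))
  structure(list(trains = trains, stimulus = sweeps[[1]]$stimulus),
            class = "lso_trains")
}

#' Construct a spike-train set directly from spike times
#'
#' @param trains list of numeric vectors of spike times (ms re onset).
#' @param stimulus optional stimulus descriptor.
#' @return an `lso_trains`.
#' @export
spike_trains <- function(trains, stimulus = NULL) {
  structure(list(trains = lapply(trains, sort), stimulus = stimulus),
            class = "lso_trains")
}

#' @export
print.lso_trains <- function(x, ...) {
  cat(sprintf("<lso_trains> %d repetition(s), %d spike(s) total\n",
              length(x$trains), sum(lengths(x$trains))))
  invisible(x)
}

#' Mean firing rate in a time window
#'
#' Mean spike count per repetition within the half-open window, divided by
#' the window duration.
#'
#' @param trains an `lso_trains`.
#' @param window numeric length-2 (ms), `a < b`.
#' @return rate in spikes/s.
#' @export
window_rate <- function(trains, window) {
  stopifnot(inherits(trains, "lso_trains"), length(window) == 2L,
            window[2] > window[1])
  counts <- vapply(trains$trains,
                   function(tt) sum(tt >= window[1] & tt < window[2]),
                   numeric(1))
  mean(counts) / ((window[2] - window[1]) / 1000)
}

#' Fraction of spikes in the onset window
#'
#' Spikes in `onset` divided by all spikes in `[0, stimulus duration)`.
#'
#' @param trains an `lso_trains` with a tone stimulus (or provide
#'   `duration`).
#' @param onset onset window (ms), default `c(0, 10)`.
#' @param duration stimulus duration (ms); defaults to the stimulus field.
#' @return fraction in \[0, 1\].
#' @export
onset_fraction <- function(trains, onset = c(0, 10), duration = NULL) {
  stopifnot(inherits(trains, "lso_trains"))
  if (is.null(duration)) {
    if (!inherits(trains$stimulus, "lso_tone"))
      stop("duration required when the train set has no tone stimulus")
    duration <- trains$stimulus$duration
  }
  all_t <- unlist(trains$trains)
  all_t <- all_t[all_t >= 0 & all_t < duration]
  if (!length(all_t)) stop("zero spikes in [0, duration)")
  sum(all_t >= onset[1] & all_t < onset[2]) / length(all_t)
}

#' Interspike-interval regularity analysis
#'
#' For every consecutive spike pair within a repetition, the interval is
#' assigned to the time bin containing its first spike. Per bin, the mean,
#' SD and CV of the pooled intervals are computed; a bin is marked included
#' only when at least `min_rep_fraction` (default 20%) of repetitions
#' contribute at least one interval to it.
#'
#' @param trains an `lso_trains`.
#' @param bin_width bin width (ms), default 1.
#' @param t_range analysis range (ms); defaults to `[0, stimulus duration)`.
#' @param min_rep_fraction inclusion criterion, default 0.2.
#' @return an `lso_regularity`: data.frame with columns `bin_center`,
#'   `mean_isi`, `sd_isi`, `cv`, `rep_fraction`, `included`.
#' @export
regularity_curve <- function(trains, bin_width = 1, t_range = NULL,
                             min_rep_fraction = 0.2) {
  stopifnot(inherits(trains, "lso_trains"))
  n_rep <- length(trains$trains)
  if (n_rep < 10)
    warning("regularity analysis with fewer than 10 repetitions")
  if (is.null(t_range)) {
    dur <- if (inherits(trains$stimulus, "lso_tone"))
      trains$stimulus$duration else
        max(c(0, unlist(trains$trains)), na.rm = TRUE)
    t_range <- c(0, dur)
  }
  edges <- seq(t_range[1], t_range[2], by = bin_width)
  if (utils::tail(edges, 1) < t_range[2])
    edges <- c(edges, utils::tail(edges, 1) + bin_width)
  n_bin <- length(edges) - 1L
  isi_first <- numeric(0); isi_val <- numeric(0); isi_rep <- integer(0)
  for (r in seq_len(n_rep)) {
    tt <- trains$trains[[r]]
    if (length(tt) < 2) next
    first <- tt[-length(tt)]
    isi <- diff(tt)
    keep <- first >= t_range[1] & first < t_range[2]
    isi_first <- c(isi_first, first[keep])
    isi_val <- c(isi_val, isi[keep])
    isi_rep <- c(isi_rep, rep(r, sum(keep)))
  }
  if (!length(isi_val)) stop("no intervals: fewer than 2 spikes per repetition")
  bin <- findInterval(isi_first, edges, rightmost.closed = FALSE)
  res <- data.frame(bin_center = edges[-length(edges)] + bin_width / 2,
                    mean_isi = NA_real_, sd_isi = NA_real_, cv = NA_real_,
                    rep_fraction = 0, included = FALSE)
  for (b in seq_len(n_bin)) {
    sel <- bin == b
    if (!any(sel)) next
    v <- isi_val[sel]
    res$rep_fraction[b] <- length(unique(isi_rep[sel])) / n_rep
    res$mean_isi[b] <- mean(v)
    res$sd_isi[b] <- if (length(v) > 1) stats::sd(v) else 0
    res$cv[b] <- res$sd_isi[b] / res$mean_isi[b]
  }
  res$included <- res$rep_fraction >= min_rep_fraction
  class(res) <- c("lso_regularity", "data.frame")
  res
}

#' Best frequency from per-frequency response counts
#'
#' The frequency eliciting the largest spike (or EPSP) count; ties are
#' broken toward the lower frequency.
#'
#' @param frequencies numeric, at least 2 distinct frequencies (Hz).
#' @param counts non-negative counts, same length.
#' @return BF in Hz.
#' @export
bf_from_counts <- function(frequencies, counts) {
  if (length(frequencies) < 2) stop("need counts at >= 2 frequencies")
  if (length(frequencies) != length(counts)) stop("length mismatch")
  if (all(counts == 0)) stop("all counts are zero")
  o <- order(frequencies)
  frequencies <- frequencies[o]; counts <- counts[o]
  frequencies[which.max(counts)]   # which.max returns the first (lowest) max
}
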