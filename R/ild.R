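#' Build an ILD tuning curve from a binaural protocol
#'
#' Computes the windowed firing rate at every ILD of a binaural sweep-set
#' collection (fixed ipsilateral level, varying contralateral level).
#' Window conventions: onset = 0-10 ms, sustained = 10-25 ms post stimulus
#' onset.
#'
#' @param sweep_sets list over ILD conditions; each element a list of
#'   `lso_sweep`s sharing one binaural stimulus.
#' @param window `"onset"`, `"sustained"`, or a numeric length-2 window (ms).
#' @param ... passed to [detect_spikes()] via [extract_trains()].
#' @return an `lso_ildcurve`: list with `ild` (dB, ascending), `rate`
#'   (spikes/s), `normalized_rate`, `window`, `n_reps`, `low_n` flag and
#'   `fit` (populated by [fit_ild_sigmoid()]).
#' @export
build_ild_curve <- function(sweep_sets, window = "onset", ...) {
  if (length(sweep_sets) < 3) stop("need >= 3 ILD values")
  win <- if (is.character(window)) {
    switch(match.arg(window, c("onset", "sustained")),
           onset = c(0, 10), sustained = c(10, 25))
  } else window
  stims <- lapply(sweep_sets, function(ss) ss[[1]]$stimulus)
  ipsi <- vapply(stims, function(s) s$level_ipsi, numeric(1))
  if (length(unique(ipsi)) != 1L)
    stop("ipsi level must be fixed across the ILD series")
  ild <- vapply(stims, ild_of, numeric(1))
  rate <- vapply(sweep_sets, function(ss) {
    window_rate(extract_trains(ss, ...), win)
  }, numeric(1))
  o <- order(ild)
  n_reps <- min(lengths(sweep_sets))
  out <- list(ild = ild[o], rate = rate[o],
              normalized_rate = if (max(rate) > 0) rate[o] / max(rate)
                                else rate[o],
              window = win,
              window_label = if (is.character(window)) window else "custom",
              n_reps = n_reps, low_n = n_reps < 3, fit = NULL)
  class(out) <- "lso_ildcurve"
  out
}

#' @export
print.lso_ildcurve <- function(x, ...) {
  cat(sprintf("<lso_ildcurve> %s window [%g, %g) ms, %d ILDs (%g to %g dB)%s\n",
              x$window_label, x$window[1], x$window[2], length(x$ild),
              min(x$ild), max(x$ild),
              if (!is.null(x$fit) && isTRUE(x$fit$converged))
                sprintf(", midpoint %.1f dB", x$fit$midpoint) else ""))
  invisible(x)
}

#' Fit a descending four-parameter logistic to an ILD curve
#'
#' Least-squares fit of
#' `rate(ild) = floor + (ceiling - floor) / (1 + exp((ild - midpoint)/width))`
#' (rate falls as ILD increases toward contra-louder, the LSO IE geometry).
#' Initialization is deterministic from data quantiles. The slope range is
#' reported as the ILDs where the fit crosses `floor + 0.2*span` and
#' `floor + 0.8*span` (20-80% by default; set `range_fractions` for 10-90%).
#'
#' @param curve an `lso_ildcurve` with >= 4 distinct ILDs and non-constant
#'   rates.
#' @param range_fractions length-2 fractions for the slope range, default
#'   `c(0.2, 0.8)`.
#' @return an `lso_sigmoid`: list with `floor`, `ceiling`, `midpoint`,
#'   `width`, `slope_at_midpoint` (spikes/s per dB), `range_20_80`,
#'   `converged`, `rmse`. On non-convergence `converged = FALSE` and
#'   `midpoint = NA`.
#' @export
fit_ild_sigmoid <- function(curve, range_fractions = c(0.2, 0.8)) {
  stopifnot(inherits(curve, "lso_ildcurve"))
  x <- curve$ild; y <- curve$rate
  if (length(unique(x)) < 4) stop("need >= 4 distinct ILDs")
  if (stats::sd(y) == 0) stop("rates are all equal: nothing to fit")
  fl0 <- min(y); ce0 <- max(y)
  # deterministic init: midpoint where the rate first drops below half-span
  half <- fl0 + (ce0 - fl0) / 2
  below <- which(y <= half)
  mid0 <- if (length(below)) x[below[1]] else stats::median(x)
  wid0 <- max(diff(range(x)) / 8, 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ fl + (ce - fl) / (1 + exp((x - mid) / wid)),
      start = list(fl = fl0, ce = ce0, mid = mid0, wid = wid0),
      lower = c(0, 0, min(x) - 50, 0.1),
      upper = c(max(y), 2 * max(y), max(x) + 50, 100),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(floor = NA_real_, ceiling = NA_real_, midpoint = NA_real_,
                width = NA_real_, slope_at_midpoint = NA_real_,
                range_20_80 = c(NA_real_, NA_real_),
                converged = FALSE, rmse = NA_real_)
    class(out) <- "lso_sigmoid"
    return(out)
  }
  cf <- stats::coef(fit)
  span <- cf[["ce"]] - cf[["fl"]]
  # logistic inverse: crossing of floor + q*span at mid + wid*log((1-q)/q)
  rng <- sort(cf[["mid"]] +
                cf[["wid"]] * log((1 - range_fractions) / range_fractions))
  converged <- span > 0 && isTRUE(fit$convInfo$isConv)
  out <- list(floor = cf[["fl"]], ceiling = cf[["ce"]],
              midpoint = if (converged) cf[["mid"]] else NA_real_,
              width = cf[["wid"]],
              slope_at_midpoint = -span / (4 * cf[["wid"]]),
              range_20_80 = rng, converged = converged,
              rmse = sqrt(mean(stats::resid(fit)^2)))
  class(out) <- "lso_sigmoid"
  out
}

#' @export
print.lso_sigmoid <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<lso_sigmoid> not converged\n")
  } else {
    cat(sprintf(
      "<lso_sigmoid> floor %.1f, ceiling %.1f spikes/s, midpoint %.1f dB, slope range [%.1f, %.1f] dB\n",
      x$floor, x$ceiling, x$midpoint, x$range_20_80[1], x$range_20_80[2]))
  }
  invisible(x)
}
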