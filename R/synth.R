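# Synthetic-recording generator. Every generator is a pure function of
# (params, seed): the caller's RNG state is saved and restored, and the
# same seed reproduces traces bit for bit.

#' Postsynaptic-potential kernel
#'
#' Difference-of-exponentials kernel (rise constant fixed at 1/5 of the
#' decay constant) whose full width at half maximum equals `half_width`;
#' the sampled peak equals `amplitude` exactly (negative for IPSPs).
#'
#' @param kind `"epsp"` or `"ipsp"`.
#' @param amplitude peak magnitude (mV, positive; sign applied by `kind`).
#' @param half_width FWHM (ms), at least 3 sample intervals.
#' @param sampling_rate Hz.
#' @return numeric kernel sampled at `sampling_rate`, starting at onset.
#' @export
psp_kernel <- function(kind = c("epsp", "ipsp"), amplitude, half_width,
                       sampling_rate) {
  kind <- match.arg(kind)
  if (amplitude <= 0) stop("amplitude must be positive (sign applied by kind)")
  if (half_width <= 0) stop("half_width must be positive")
  if (half_width < 3 / sampling_rate * 1000)
    stop("undersampled kernel: half_width shorter than 3 sample intervals")
  rho <- 0.2                                   # tau_rise / tau_decay
  g <- function(t) exp(-t) - exp(-t / rho)     # unit decay constant
  tp <- rho / (1 - rho) * log(1 / rho)
  gp <- g(tp)
  f_half <- function(t) g(t) - gp / 2
  t1 <- stats::uniroot(f_half, c(1e-9, tp), tol = 1e-12)$root
  t2 <- stats::uniroot(f_half, c(tp, 50), tol = 1e-12)$root
  tau_d <- half_width / (t2 - t1)              # FWHM scales linearly
  t_end <- (tp + log(500)) * tau_d
  tt <- seq(0, t_end, by = 1000 / sampling_rate)
  k <- g(tt / tau_d)
  k <- k / max(k) * amplitude
  if (kind == "ipsp") -k else k
}

# Stereotyped 1 ms action-potential waveform with unit peak.
spike_template <- function(sampling_rate) {
  tt <- seq(0, 1, by = 1000 / sampling_rate)
  shape <- exp(-((tt - 0.25) / 0.12)^2)
  list(shape = shape, peak_offset_ms = 0.25)
}

# Homogeneous Poisson event times (ms) on [t0, t1); rate in events/s.
poisson_times <- function(rate, t0, t1) {
  n <- stats::rpois(1, rate * (t1 - t0) / 1000)
  sort(stats::runif(n, t0, t1))
}

# Inhomogeneous Poisson by thinning: onset burst decaying to a sustained
# rate, r(t) = onset*exp(-(t-t0)/adapt_tau) + sustained (events/s).
burst_times <- function(onset_rate, sustained_rate, adapt_tau, t0, t1) {
  m <- onset_rate + sustained_rate
  if (m <= 0) return(numeric(0))
  cand <- poisson_times(m, t0, t1)
  if (!length(cand)) return(cand)
  r <- onset_rate * exp(-(cand - t0) / adapt_tau) + sustained_rate
  sort(cand[stats::runif(length(cand)) < r / m])
}

# Add kernel instances at event times (ms on the sweep's time axis).
add_events <- function(trace, t_axis, times, amps, kernel) {
  n <- length(trace); lk <- length(kernel)
  dt <- t_axis[2] - t_axis[1]
  for (i in seq_along(times)) {
    i0 <- round((times[i] - t_axis[1]) / dt) + 1L
    if (i0 > n) next
    j <- i0:min(n, i0 + lk - 1L)
    trace[j] <- trace[j] + amps[i] * kernel[seq_along(j)]
  }
  trace
}

# Paste spike templates into a trace; the peak reaches baseline + ap_amp.
insert_spikes <- function(trace, t_axis, spike_times, ap_amp, baseline,
                          sampling_rate) {
  tpl <- spike_template(sampling_rate)
  dt <- t_axis[2] - t_axis[1]
  n <- length(trace); lk <- length(tpl$shape)
  for (ts in spike_times) {
    i0 <- round((ts - tpl$peak_offset_ms - t_axis[1]) / dt) + 1L
    j0 <- max(1L, i0)
    j <- j0:min(n, i0 + lk - 1L)
    if (!length(j) || j[1] > n) next
    shp <- tpl$shape[j - i0 + 1L]
    keep <- shp > 1e-4                    # leave the trace outside the bump
    trace[j[keep]] <- pmax(trace[j[keep]], baseline + ap_amp * shp[keep])
  }
  trace
}

truncnorm1 <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a spontaneous-activity sweep
#'
#' Resting potential plus homogeneous-Poisson EPSP/IPSP trains convolved
#' with [psp_kernel()] plus Gaussian noise; an action potential is pasted in
#' whenever the summed synaptic depolarization crosses `ap_threshold`
#' (rare for the principal archetype, whose EPSPs are subthreshold).
#'
#' @param params an `lso_archetype`.
#' @param duration_s duration in seconds, within \[0.5, 10\].
#' @param sampling_rate Hz (default 50 kHz).
#' @param seed integer seed.
#' @return list with `sweep` (an `lso_sweep`) and `truth` (event table,
#'   spike times, class label).
#' @export
gen_spontaneous <- function(params, duration_s = 2.5, sampling_rate = 50e3,
                            seed = 1) {
  stopifnot(inherits(params, "lso_archetype"))
  if (duration_s < 0.5 || duration_s > 10)
    stop("duration_s must lie in [0.5, 10]")
  with_seed(seed, {
    dur_ms <- duration_s * 1000
    t_axis <- seq(0, dur_ms - 1000 / sampling_rate, by = 1000 / sampling_rate)
    v <- rep(params$resting_vm, length(t_axis))
    ek <- psp_kernel("epsp", 1, params$epsp_half_width, sampling_rate)
    ik <- psp_kernel("ipsp", 1, params$ipsp_half_width, sampling_rate)
    te <- poisson_times(params$epsp_rate_spont, 0, dur_ms)
    ti <- poisson_times(params$ipsp_rate_spont, 0, dur_ms)
    ae <- truncnorm1(length(te), params$epsp_amp, params$epsp_amp_sd, 0.2)
    ai <- truncnorm1(length(ti), params$ipsp_amp, params$ipsp_amp_sd, 0.2)
    v <- add_events(v, t_axis, te, ae, ek)
    v <- add_events(v, t_axis, ti, ai, ik)
    # threshold crossings of the summed synaptic drive
    above <- v >= params$ap_threshold
    cross <- which(above & !c(FALSE, above[-length(above)]))
    sp <- numeric(0)
    for (i in cross) {
      tc <- t_axis[i]
      if (length(sp) && tc - sp[length(sp)] < 1) next
      sp <- c(sp, tc)
    }
    if (length(sp))
      v <- insert_spikes(v, t_axis, sp, params$ap_amp_mean,
                         params$resting_vm, sampling_rate)
    v <- v + stats::rnorm(length(v), 0, params$noise_sd)
    events <- rbind(
      data.frame(time = te, kind = rep("epsp", length(te))),
      data.frame(time = ti, kind = rep("ipsp", length(ti))),
      data.frame(time = sp, kind = rep("ap", length(sp))))
    list(sweep = sweep_trace(v, sampling_rate, t0_offset = 0,
                             stimulus = "spontaneous",
                             junction_corrected = TRUE),
         truth = list(events = events[order(events$time), ],
                      spike_times = sp, class_label = params$class_label))
  })
}

# True per-repetition spike probability / thinning factor at a given ILD.
ild_logistic <- function(params, ild) {
  1 / (1 + exp((ild - params$ild_midpoint) / params$ild_width))
}

#' Generate tone-evoked sweeps
#'
#' The ipsilateral ear drives an adapting EPSP barrage starting at
#' `onset_latency`; the contralateral ear drives an IPSP barrage whose onset
#' latency decreases linearly with contralateral level (latency-intensity
#' trading). Onset archetypes fire a single spike near onset with ~0.3 ms
#' latency jitter; chopper archetypes fire a gamma-renewal train for the
#' stimulus duration. For binaural stimuli, spiking is suppressed with the
#' archetype's true ILD logistic (per-spike thinning for sustained trains,
#' a per-repetition Bernoulli draw for onset spikes), and both synaptic
#' drives are superposed.
#'
#' @param params an `lso_archetype`.
#' @param stimulus an `lso_tone`; `stimulus$n_reps` repetitions are drawn.
#' @param seed integer seed.
#' @param sampling_rate Hz.
#' @return list with `sweeps` (list of `lso_sweep`) and `truth` (per-rep
#'   spike times, IPSP onset latency, true ILD sigmoid, class label).
#' @export
gen_tone_response <- function(params, stimulus, seed = 1,
                              sampling_rate = 50e3) {
  stopifnot(inherits(params, "lso_archetype"), inherits(stimulus, "lso_tone"))
  with_seed(seed, {
    dur <- stimulus$duration
    pre <- 10; post <- dur + 30
    t_axis <- seq(-pre, post - 1000 / sampling_rate,
                  by = 1000 / sampling_rate)
    n <- length(t_axis)
    ek <- psp_kernel("epsp", 1, params$epsp_half_width, sampling_rate)
    ik <- psp_kernel("ipsp", 1, params$ipsp_half_width, sampling_rate)
    has_ipsi <- is.finite(stimulus$level_ipsi)
    has_contra <- is.finite(stimulus$level_contra)
    p_spike <- if (has_ipsi && has_contra) {
      0.97 * ild_logistic(params, ild_of(stimulus))
    } else if (has_ipsi) 0.97 else 0
    ipsp_lat <- if (has_contra) {
      max(1, params$ipsp_latency_at_ref -
            params$ipsp_latency_slope *
            (stimulus$level_contra - params$ref_level_db))
    } else NA_real_
    sweeps <- vector("list", stimulus$n_reps)
    spikes <- vector("list", stimulus$n_reps)
    for (r in seq_len(stimulus$n_reps)) {
      v <- rep(params$resting_vm, n)
      if (has_ipsi) {
        lf <- min(stimulus$level_ipsi, 90) / 70
        te <- burst_times(params$evoked_onset_rate * lf,
                          params$evoked_sustained_rate * lf,
                          params$adapt_tau, params$onset_latency, dur + 2)
        ae <- truncnorm1(length(te), params$evoked_amp,
                         0.3 * params$evoked_amp, 0.2)
        # binaural: contralateral (shunting) inhibition scales down the
        # depolarizing drive in proportion to the suppression strength
        if (has_contra) ae <- ae * (0.5 + 0.5 * p_spike / 0.97)
        v <- add_events(v, t_axis, te, ae, ek)
      }
      if (has_contra) {
        lf <- min(stimulus$level_contra, 90) / 70
        ti <- burst_times(params$contra_onset_rate * lf,
                          params$contra_sustained_rate * lf,
                          params$adapt_tau, ipsp_lat, dur + 4)
        ai <- truncnorm1(length(ti), params$evoked_amp,
                         0.3 * params$evoked_amp, 0.2)
        v <- add_events(v, t_axis, ti, ai, ik)
      }
      sp <- numeric(0)
      if (has_ipsi && p_spike > 0) {
        if (params$firing_mode == "onset") {
          if (stats::runif(1) < p_spike) {
            sp <- params$onset_latency + 1 + stats::rnorm(1, 0, 0.3)
            sp <- min(max(sp, params$onset_latency + 0.4), 9.5)
          }
        } else {
          cv <- if (params$firing_mode == "chopper") params$chopper_isi_cv
                else 0.8
          shape <- 1 / cv^2
          tcur <- params$onset_latency + 1.5 + abs(stats::rnorm(1, 0, 0.3))
          while (tcur < dur) {
            sp <- c(sp, tcur)
            tcur <- tcur +
              stats::rgamma(1, shape = shape,
                            scale = params$chopper_isi_mean / shape)
          }
          if (length(sp) && p_spike < 0.97)   # binaural thinning
            sp <- sp[stats::runif(length(sp)) < p_spike / 0.97]
        }
      }
      if (length(sp))
        v <- insert_spikes(v, t_axis, sp, params$ap_amp_mean,
                           params$resting_vm, sampling_rate)
      v <- v + stats::rnorm(n, 0, params$noise_sd)
      sweeps[[r]] <- sweep_trace(v, sampling_rate, t0_offset = -pre,
                                 stimulus = stimulus,
                                 junction_corrected = TRUE)
      spikes[[r]] <- sp
    }
    list(sweeps = sweeps,
         truth = list(spike_times = spikes, ipsp_latency = ipsp_lat,
                      p_spike = p_spike, class_label = params$class_label,
                      ild_sigmoid = list(midpoint = params$ild_midpoint,
                                         width = params$ild_width)))
  })
}

#' Generate a binaural ILD protocol
#'
#' One binaural sweep set per contralateral level, with the ipsilateral
#' level fixed. Spiking is suppressed with increasing contralateral level
#' following the archetype's true ILD logistic, which is returned in the
#' ground truth. Each level uses a sub-seed derived from `seed` and the
#' level's position in the list, so shifting all contralateral levels by a
#' constant reproduces the same spike draws at the shifted ILDs.
#'
#' @param params an `lso_archetype`.
#' @param frequency tone frequency (Hz).
#' @param ipsi_level fixed ipsilateral level (dB SPL).
#' @param contra_levels at least 3 contralateral levels (dB SPL).
#' @param n_reps repetitions per level.
#' @param seed integer seed.
#' @param duration tone duration (ms).
#' @param sampling_rate Hz.
#' @return list with `sweep_sets` (list over levels, each a list of sweeps),
#'   `stimuli`, and `truth` (true sigmoid + per-level spike times).
#' @export
gen_ild_series <- function(params, frequency, ipsi_level, contra_levels,
                           n_reps = 30, seed = 1, duration = 50,
                           sampling_rate = 50e3) {
  if (length(contra_levels) < 3) stop("need >= 3 contralateral levels")
  sets <- vector("list", length(contra_levels))
  stimuli <- vector("list", length(contra_levels))
  spikes <- vector("list", length(contra_levels))
  for (i in seq_along(contra_levels)) {
    stim <- tone_stimulus("binaural", frequency, level_ipsi = ipsi_level,
                          level_contra = contra_levels[i],
                          duration = duration, n_reps = n_reps)
    res <- gen_tone_response(params, stim, seed = (seed + 7919L * i) %% .Machine$integer.max,
                             sampling_rate = sampling_rate)
    sets[[i]] <- res$sweeps
    stimuli[[i]] <- stim
    spikes[[i]] <- res$truth$spike_times
  }
  list(sweep_sets = sets, stimuli = stimuli,
       truth = list(ild_sigmoid = list(midpoint = params$ild_midpoint,
                                       width = params$ild_width),
                    spike_times = spikes,
                    ild = contra_levels - ipsi_level,
                    class_label = params$class_label))
}

#' Generate a current-step response
#'
#' Single-compartment linear response: deflection
#' `I*R*(1 - exp(-t/tau))` with, for hyperpolarizing steps, a delayed slow
#' relaxation of the peak toward steady state by `sag_fraction` (I_h sag;
#' the relaxation starts 5 tau after onset with time constant 20 tau, so
#' the peak/steady deflection ratio is 1/(1-sag)). Onset archetypes fire a
#' single spike at depolarizing onset (and an offset spike after release
#' from strong hyperpolarization); chopper archetypes fire a gamma-renewal
#' train for the step duration.
#'
#' @param params an `lso_archetype`.
#' @param step an `lso_step` with `|amplitude| <= 3000` pA.
#' @param seed integer seed.
#' @param sampling_rate Hz.
#' @return an `lso_sweep` with the step as its stimulus.
#' @export
gen_current_step <- function(params, step, seed = 1, sampling_rate = 50e3) {
  stopifnot(inherits(params, "lso_archetype"), inherits(step, "lso_step"))
  if (abs(step$amplitude) > 3000) stop("|amplitude| must be <= 3000 pA")
  with_seed(seed, {
    pre <- 10; post <- step$duration + 30
    t_axis <- seq(-pre, post - 1000 / sampling_rate,
                  by = 1000 / sampling_rate)
    tau <- params$membrane_tau
    i_nA <- step$amplitude / 1000
    defl_full <- i_nA * params$r_in              # mV at full charging
    sag <- if (step$amplitude < 0) params$sag_fraction else 0
    tr <- pmax(t_axis, 0)
    rise <- (1 - exp(-tr / tau))
    sag_term <- sag * (1 - exp(-pmax(tr - 5 * tau, 0) / (20 * tau)))
    d <- defl_full * (rise - sag_term)
    in_step <- t_axis >= 0 & t_axis < step$duration
    d[t_axis < 0] <- 0
    # exponential return to rest after step offset
    i_off <- which(t_axis >= step$duration)
    if (length(i_off)) {
      d_end <- d[i_off[1] - 1]
      d[i_off] <- d_end * exp(-(t_axis[i_off] - step$duration) / tau)
    }
    v <- params$resting_vm + d
    sp <- numeric(0)
    if (step$amplitude >= 300) {
      if (params$firing_mode == "onset") {
        sp <- 1.2 + stats::rnorm(1, 0, 0.2)
      } else {
        cv <- if (params$firing_mode == "chopper") params$chopper_isi_cv else 0.8
        shape <- 1 / cv^2
        tcur <- 2 + abs(stats::rnorm(1, 0, 0.3))
        while (tcur < step$duration) {
          sp <- c(sp, tcur)
          tcur <- tcur + stats::rgamma(1, shape = shape,
                                       scale = params$chopper_isi_mean / shape)
        }
      }
    } else if (step$amplitude <= -500 && params$firing_mode == "onset") {
      sp <- step$duration + 1.5 + stats::rnorm(1, 0, 0.2)  # offset spike
    }
    if (length(sp))
      v <- insert_spikes(v, t_axis, sp, params$ap_amp_mean,
                         params$resting_vm, sampling_rate)
    v <- v + stats::rnorm(length(v), 0, params$noise_sd)
    sweep_trace(v, sampling_rate, t0_offset = -pre, stimulus = step,
                junction_corrected = TRUE)
  })
}

#' Generate a synthetic cohort of labeled cells
#'
#' Per-cell parameters are drawn from two documented distributions
#' (principal: EPSP half-widths 0.4-0.9 ms, AP amplitude ~ Normal(28, 8) mV
#' truncated above 10; non-principal: half-widths 2-6 ms, AP amplitude ~
#' Normal(66, 10) mV truncated above 10). Each cell receives spontaneous,
#' ipsi-tone, contra-tone, ILD and current-step protocols (selectable via
#' `protocols`), a tonotopically consistent CF, a normalized lateromedial
#' position, and a synaptic-coverage value typical of its class.
#'
#' @param n_principal,n_nonprincipal cell counts (>= 1... 0 allowed for one
#'   group to build degenerate test cases).
#' @param seed integer seed.
#' @param spont_duration_s spontaneous sample length per cell (s).
#' @param n_reps tone repetitions per condition.
#' @param protocols character subset of
#'   `c("spontaneous","ipsi_tone","contra_tone","ild","current_step")`.
#' @param sampling_rate Hz.
#' @return list of `list(cell = lso_cell, truth = list(...))`, principal
#'   cells first.
#' @export
gen_cohort <- function(n_principal = 12, n_nonprincipal = 12, seed = 1,
                       spont_duration_s = 2.5, n_reps = 30,
                       protocols = c("spontaneous", "ipsi_tone",
                                     "contra_tone", "ild", "current_step"),
                       sampling_rate = 50e3) {
  n_total <- n_principal + n_nonprincipal
  if (n_total < 1) stop("need at least one cell")
  protocols <- match.arg(protocols, several.ok = TRUE,
                         choices = c("spontaneous", "ipsi_tone",
                                     "contra_tone", "ild", "current_step"))
  draws <- with_seed(seed, {
    lapply(seq_len(n_total), function(i) {
      principal <- i <= n_principal
      hw <- if (principal) stats::runif(1, 0.4, 0.9) else stats::runif(1, 2, 6)
      ap <- if (principal) truncnorm1(1, 28, 8, 10) else truncnorm1(1, 66, 10, 10)
      pos <- stats::runif(1)
      list(
        principal = principal,
        pos = pos,
        cf = 2000 * 2^(2.2 * pos + stats::rnorm(1, 0, 0.15)),
        coverage = if (principal) min(95, max(40, stats::rnorm(1, 70, 8)))
                   else min(50, max(2, stats::rnorm(1, 25, 8))),
        sub_seed = sample.int(.Machine$integer.max %/% 2L, 1),
        params = if (principal) {
          principal_archetype(epsp_half_width = hw, ipsp_half_width = 2 * hw,
                              ap_amp_mean = ap,
                              membrane_tau = 1.5 * hw,
                              r_in = stats::runif(1, 35, 60),
                              ild_midpoint = stats::rnorm(1, -10, 4))
        } else {
          nonprincipal_archetype(epsp_half_width = hw,
                                 ipsp_half_width = 1.5 * hw,
                                 ap_amp_mean = ap,
                                 membrane_tau = 1.5 * hw,
                                 r_in = stats::runif(1, 70, 120),
                                 chopper_isi_mean = stats::runif(1, 4, 7),
                                 chopper_isi_cv = stats::runif(1, 0.15, 0.35),
                                 ild_midpoint = stats::rnorm(1, -8, 4))
        })
    })
  })
  out <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    d <- draws[[i]]
    p <- d$params
    s0 <- d$sub_seed
    sweeps <- list()
    truth <- list(class_label = p$class_label, params = p,
                  normalized_position = d$pos, CF = d$cf,
                  coverage_percent = d$coverage)
    if ("spontaneous" %in% protocols) {
      g <- gen_spontaneous(p, spont_duration_s, sampling_rate, seed = s0 + 1)
      sweeps$spontaneous <- list(g$sweep)
      truth$spontaneous <- g$truth
    }
    if ("ipsi_tone" %in% protocols) {
      stim <- tone_stimulus("ipsi", d$cf, level_ipsi = 70, duration = 50,
                            n_reps = n_reps)
      g <- gen_tone_response(p, stim, seed = s0 + 2,
                             sampling_rate = sampling_rate)
      sweeps$ipsi_tone <- g$sweeps
      truth$ipsi_tone <- g$truth
    }
    if ("contra_tone" %in% protocols) {
      stim <- tone_stimulus("contra", d$cf, level_contra = 70, duration = 50,
                            n_reps = n_reps)
      g <- gen_tone_response(p, stim, seed = s0 + 3,
                             sampling_rate = sampling_rate)
      sweeps$contra_tone <- g$sweeps
      truth$contra_tone <- g$truth
    }
    if ("ild" %in% protocols) {
      g <- gen_ild_series(p, d$cf, ipsi_level = 70,
                          contra_levels = seq(40, 100, by = 10),
                          n_reps = n_reps, seed = s0 + 4,
                          sampling_rate = sampling_rate)
      sweeps$ild <- do.call(c, g$sweep_sets)
      truth$ild <- g$truth
    }
    if ("current_step" %in% protocols) {
      amps <- c(-1000, -500, 500, 1000)
      sweeps$current_step <- lapply(seq_along(amps), function(k) {
        gen_current_step(p, current_step(amps[k]), seed = s0 + 4 + k,
                         sampling_rate = sampling_rate)
      })
    }
    cls <- if (d$principal) "principal" else
      with_seed(s0 + 99, sample(c("class5", "marginal", "multiplanar"), 1))
    out[[i]] <- list(
      cell = cell_record(sprintf("cell%02d", i), sweeps = sweeps,
                         anatomical_class = cls,
                         CF = d$cf, normalized_position = d$pos,
                         coverage_percent = d$coverage),
      truth = truth)
  }
  out
}
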