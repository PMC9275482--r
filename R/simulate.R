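#' Pharmacodynamic simulation parameters
#'
#' Parameters of the synthetic-recording generator: a sigmoid (Hill)
#' concentration-effect relationship driving a first-order onset/washout
#' effect state, on top of a stable baseline rhythm with bounded drift and
#' per-bin measurement noise. For mixtures, `e_max`, `ec50` and `hill` are
#' vectors named by compound and `interaction_mode` sets how the single
#' -compound equilibrium effects combine.
#'
#' Noise and drift are deliberately bounded (clamped at 2.5 and 2 standard
#' deviations respectively): control preparations in this bioassay hold
#' their rhythm within a few percent over a 22-min registration, and the
#' generator encodes that boundedness rather than unbounded Gaussian tails.
#'
#' @param f0 baseline contraction frequency, contractions/min. The assay
#'   literature does not fix an absolute adult baseline; the default 48 is a
#'   documented placeholder in the physiological range and is configurable.
#' @param e_max maximal percent change per compound (negative for
#'   inhibitors, >= -100).
#' @param ec50 half-effect concentration per compound, mol/L.
#' @param hill Hill coefficient per compound, > 0.
#' @param k_on onset rate constant, 1/min (effect deepening).
#' @param k_off washout rate constant, 1/min (recovery).
#' @param pulse_decay clearance rate of a bolus from the chamber, 1/min.
#' @param noise_sd_freq per-bin frequency noise SD, contractions/min.
#' @param baseline_drift_sd SD of the total baseline drift over the full
#'   recording, percent.
#' @param interaction_mode how two compounds combine at equilibrium:
#'   `"independent"` (Bliss-style product of survivals), `"additive"`
#'   (sum of effects, floored at -100) or `"antagonistic"` (`lambda` times
#'   the additive effect).
#' @param lambda attenuation factor in `[0, 1]` for `"antagonistic"` mode.
#' @return object of class `pd_params`.
#' @export
pd_params <- function(f0 = 48, e_max = -100, ec50 = 1.685e-5, hill = 2,
                      k_on = 0.667, k_off = 0.26, pulse_decay = 0.3,
                      noise_sd_freq = 0.25, baseline_drift_sd = 0.5,
                      interaction_mode = c("independent", "additive",
                                           "antagonistic"),
                      lambda = 1) {
  interaction_mode <- match.arg(interaction_mode)
  n <- max(length(e_max), length(ec50), length(hill))
  e_max <- rep_len(e_max, n); ec50 <- rep_len(ec50, n); hill <- rep_len(hill, n)
  stopifnot(f0 > 0, all(e_max >= -100), all(e_max <= 0), all(ec50 > 0),
            all(hill > 0), k_on > 0, k_off > 0, pulse_decay > 0,
            noise_sd_freq >= 0, baseline_drift_sd >= 0,
            lambda >= 0, lambda <= 1)
  structure(list(f0 = f0, e_max = e_max, ec50 = ec50, hill = hill,
                 k_on = k_on, k_off = k_off, pulse_decay = pulse_decay,
                 noise_sd_freq = noise_sd_freq,
                 baseline_drift_sd = baseline_drift_sd,
                 interaction_mode = interaction_mode, lambda = lambda),
            class = "pd_params")
}

#' Chamber concentration time course under a protocol
#'
#' Perfusion segments impose a step concentration (medium exchange treated
#' as instantaneous; mixing dead time is absorbed into the onset rate).
#' A pulse adds an instantaneous bolus of height
#' `concentration * bolus_volume_fraction` that is then cleared
#' exponentially at rate `pulse_decay`.
#'
#' @param protocol a [protocol_spec()].
#' @param params a [pd_params()] (supplies `pulse_decay`).
#' @param dt output grid spacing, minutes.
#' @return data.frame with column `time` and one concentration column per
#'   non-vehicle solution (mol/L).
#' @export
concentration_trajectory <- function(protocol, params = pd_params(), dt = 0.1) {
  validate_protocol(protocol)
  stopifnot(dt > 0)
  tt <- seq(0, protocol$total_duration, by = dt)
  seg <- protocol$segments
  pul <- protocol$pulses
  ids <- unique(c(seg$solution_id[seg$concentration > 0], pul$solution_id))
  out <- data.frame(time = tt)
  for (id in ids) out[[id]] <- 0
  for (i in seq_len(nrow(seg))) {
    if (seg$concentration[i] <= 0) next
    inside <- tt >= seg$t_start[i] & tt < seg$t_end[i]
    out[[seg$solution_id[i]]][inside] <-
      out[[seg$solution_id[i]]][inside] + seg$concentration[i]
  }
  for (i in seq_len(nrow(pul))) {
    amp <- pul$concentration[i] * pul$bolus_volume_fraction[i]
    after <- tt >= pul$t_apply[i]
    out[[pul$solution_id[i]]][after] <- out[[pul$solution_id[i]]][after] +
      amp * exp(-params$pulse_decay * (tt[after] - pul$t_apply[i]))
  }
  out
}

#' Equilibrium percent-change effect at given concentrations
#'
#' Single compound: the Hill relation
#' `E(C) = e_max * C^h / (C^h + ec50^h)`. Two compounds combine according
#' to `interaction_mode`: independent
#' `100 * ((1 + e1/100) * (1 + e2/100) - 1)`, additive `e1 + e2` floored at
#' -100, antagonistic `lambda * additive`. Monotone non-increasing in each
#' concentration for inhibitors.
#'
#' @param conc concentration(s), mol/L: a scalar/vector (one value per
#'   compound) or a matrix with one row per time point and one column per
#'   compound.
#' @param params a [pd_params()].
#' @return percent change (scalar or vector over rows of `conc`).
#' @export
equilibrium_effect <- function(conc, params) {
  stopifnot(inherits(params, "pd_params"))
  if (is.data.frame(conc)) conc <- as.matrix(conc)
  if (!is.matrix(conc)) conc <- matrix(conc, nrow = 1L)
  if (any(conc < 0)) stop("negative concentration", call. = FALSE)
  k <- ncol(conc)
  if (k > length(params$e_max))
    stop(sprintf("params describe %d compound(s) but %d concentration column(s) given",
                 length(params$e_max), k), call. = FALSE)
  e <- matrix(0, nrow(conc), k)
  for (j in seq_len(k)) {
    ch <- conc[, j]^params$hill[j]
    e[, j] <- ifelse(conc[, j] > 0,
                     params$e_max[j] * ch / (ch + params$ec50[j]^params$hill[j]),
                     0)
  }
  out <- if (k == 1L) e[, 1L] else switch(params$interaction_mode,
    independent = 100 * (apply(1 + e / 100, 1L, prod) - 1),
    additive = pmax(rowSums(e), -100),
    antagonistic = params$lambda * pmax(rowSums(e), -100))
  drop(out)
}

#' Simulate a contraction-frequency recording
#'
#' The effect state follows first-order kinetics towards the equilibrium
#' effect of the current chamber concentration: deepening at rate `k_on`
#' when the target lies below the current state, recovering at rate `k_off`
#' otherwise. Integration uses the exponential (exact-step) update on a fine
#' internal grid. Observed per-bin frequency is
#' `f0 * (1 + E/100) + drift + noise`, truncated at zero; drift is a linear
#' ramp with random total amplitude and noise is independent per bin (both
#' clamped, see [pd_params()]). Identical seeds give identical output.
#'
#' @param protocol a [protocol_spec()].
#' @param params a [pd_params()]. For mixture protocols built with
#'   [protocol_variant_a()] and a 2-compound `params`, the per-compound
#'   concentrations stored in the protocol are used.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param dt output bin width, minutes (bin timestamps are right edges:
#'   the sample at time t summarises `(t - dt, t]`).
#' @param dt_int internal integration step, minutes.
#' @param preparation_id label for the simulated preparation.
#' @return a [recording()] with attribute `"true_effect"`: a data.frame of
#'   the noiseless per-bin effect state (percent).
#' @export
simulate_frequency_series <- function(protocol, params = pd_params(),
                                      seed = NULL, dt = 1, dt_int = 0.02,
                                      preparation_id = "sim01") {
  validate_protocol(protocol)
  stopifnot(inherits(params, "pd_params"), dt > 0, dt_int > 0)
  if (!is.null(seed)) set.seed(seed)

  traj <- concentration_trajectory(protocol, params, dt = dt_int)
  conc <- as.matrix(traj[, -1L, drop = FALSE])
  conc <- expand_mixture_conc(conc, protocol, params)
  e_eq <- if (ncol(conc) == 0L) rep(0, nrow(traj)) else
    as.numeric(equilibrium_effect(conc, params))

  n <- nrow(traj)
  e <- numeric(n)
  for (i in 2:n) {
    target <- e_eq[i]
    k <- if (target <= e[i - 1L]) params$k_on else params$k_off
    e[i] <- target + (e[i - 1L] - target) * exp(-k * dt_int)
  }

  t_out <- seq(dt, protocol$total_duration, by = dt)
  bin_idx <- findInterval(traj$time, c(-Inf, t_out)) # 1..length(t_out)+
  e_bin <- vapply(seq_along(t_out), function(b) {
    sel <- bin_idx == b
    if (!any(sel)) e[findInterval(t_out[b], traj$time)] else mean(e[sel])
  }, numeric(1))

  f <- params$f0 * (1 + e_bin / 100)
  drift_amp <- clamp(stats::rnorm(1L, 0, params$baseline_drift_sd),
                     2 * params$baseline_drift_sd)
  f <- f + params$f0 * (drift_amp * t_out / protocol$total_duration) / 100
  f <- f + clamp(stats::rnorm(length(f), 0, params$noise_sd_freq),
                 2.5 * params$noise_sd_freq)
  f <- pmax(f, 0)

  compound_ids <- active_compounds(protocol)
  variant <- if (nrow(protocol$pulses)) "B_pulse" else
    if (length(compound_ids)) "A_continuous" else "control"
  rec <- recording(t_out, f, preparation_id = preparation_id,
                   compound_ids = if (length(compound_ids)) compound_ids else "saline",
                   concentrations = compound_concentrations(protocol),
                   variant = variant, protocol = protocol)
  attr(rec, "true_effect") <- data.frame(time = t_out, effect = e_bin)
  rec
}

# a variant-A mixture segment stores one concentration for the combined
# solution; expand it to per-compound columns using the `mixture` attribute
expand_mixture_conc <- function(conc, protocol, params) {
  mix <- attr(protocol, "mixture")
  if (is.null(mix) || ncol(conc) != 1L) return(conc)
  step <- conc[, 1L] / max(conc[, 1L], .Machine$double.xmin)
  out <- vapply(mix, function(ci) step * ci, numeric(nrow(conc)))
  colnames(out) <- names(mix)
  out
}

active_compounds <- function(protocol) {
  mix <- attr(protocol, "mixture")
  if (!is.null(mix)) return(names(mix))
  unique(c(protocol$segments$solution_id[protocol$segments$concentration > 0],
           protocol$pulses$solution_id))
}

compound_concentrations <- function(protocol) {
  mix <- attr(protocol, "mixture")
  if (!is.null(mix)) return(unname(mix))
  seg <- protocol$segments
  ids <- active_compounds(protocol)
  if (!length(ids)) return(0)
  vapply(ids, function(id) {
    c_seg <- seg$concentration[seg$solution_id == id]
    c_pul <- protocol$pulses$concentration[protocol$pulses$solution_id == id]
    max(c(c_seg, c_pul, 0))
  }, numeric(1), USE.NAMES = FALSE)
}

clamp <- function(x, bound) pmin(pmax(x, -bound), bound)

#' Densitometric trace container
#'
#' A uniformly sampled arbitrary-unit optical-density signal, as produced by
#' the microdensitometric acquisition (or its simulator). Beat times in
#' `ground_truth_beats` are populated only by [simulate_trace()].
#'
#' @param values numeric signal samples.
#' @param sample_rate samples per second, > 0.
#' @param ground_truth_beats optional numeric, beat times in seconds.
#' @return object of class `od_trace` with fields `sample_rate`, `values`,
#'   `duration` (seconds) and `ground_truth_beats`.
#' @export
od_trace <- function(values, sample_rate, ground_truth_beats = NULL) {
  stopifnot(sample_rate > 0, is.numeric(values), length(values) >= 1L)
  structure(list(sample_rate = sample_rate, values = as.numeric(values),
                 duration = length(values) / sample_rate,
                 ground_truth_beats = ground_truth_beats),
            class = "od_trace")
}

#' @export
print.od_trace <- function(x, ...) {
  cat(sprintf("<od_trace> %.1f s @ %g Hz (%d samples)%s\n", x$duration,
              x$sample_rate, length(x$values),
              if (is.null(x$ground_truth_beats)) "" else
                sprintf(", %d ground-truth beats", length(x$ground_truth_beats))))
  invisible(x)
}

#' Simulate a raw densitometric trace
#'
#' Beats are generated by an integrate-and-fire scheme on the instantaneous
#' contraction rate implied by the effect kinetics (the phase integral
#' reaching 1 emits a beat, with linear interpolation of the firing time).
#' Each beat is stamped onto the baseline as a stereotyped raised-cosine
#' pulse; additive Gaussian noise models the optical measurement.
#'
#' @inheritParams simulate_frequency_series
#' @param sample_rate samples per second; must be at least `20 * f0 / 60`.
#' @param pulse_width width of the raised-cosine beat waveform, seconds.
#'   Must be shorter than the shortest inter-beat interval or beats would
#'   fuse (an error).
#' @param pulse_amp waveform amplitude, arbitrary units.
#' @param noise_sd additive signal noise SD, arbitrary units.
#' @return an [od_trace()] with `ground_truth_beats` populated.
#' @export
simulate_trace <- function(protocol, params = pd_params(), seed = NULL,
                           sample_rate = 40, pulse_width = 0.25,
                           pulse_amp = 1, noise_sd = 0, dt_int = 0.02) {
  validate_protocol(protocol)
  stopifnot(inherits(params, "pd_params"))
  if (sample_rate < 20 * params$f0 / 60)
    stop(sprintf("sample_rate %g too low for f0 = %g contractions/min (need >= %g)",
                 sample_rate, params$f0, 20 * params$f0 / 60), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  # noiseless effect state on the fine grid (minutes)
  traj <- concentration_trajectory(protocol, params, dt = dt_int)
  conc <- expand_mixture_conc(as.matrix(traj[, -1L, drop = FALSE]), protocol,
                              params)
  e_eq <- if (ncol(conc) == 0L) rep(0, nrow(traj)) else
    as.numeric(equilibrium_effect(conc, params))
  e <- numeric(nrow(traj))
  for (i in 2:length(e)) {
    k <- if (e_eq[i] <= e[i - 1L]) params$k_on else params$k_off
    e[i] <- e_eq[i] + (e[i - 1L] - e_eq[i]) * exp(-k * dt_int)
  }

  dur_s <- protocol$total_duration * 60
  ns <- round(dur_s * sample_rate)
  ts <- (seq_len(ns) - 1L) / sample_rate          # seconds
  rate <- params$f0 * (1 + approx_effect(e, traj$time, ts / 60) / 100) / 60

  # integrate-and-fire: cumulative phase, beat whenever it crosses integers
  phase <- cumsum(rate) / sample_rate
  nb <- floor(phase[ns] + 1e-9)
  beats <- numeric(0)
  if (nb >= 1L) {
    ks <- seq_len(nb)
    idx <- findInterval(ks, phase)          # last sample with phase <= k
    ph_aug <- c(0, phase)
    ts_aug <- c(ts[1L] - 1 / sample_rate, ts)
    ph0 <- ph_aug[idx + 1L]
    t0 <- ts_aug[idx + 1L]
    den <- ph_aug[pmin(idx + 2L, ns + 1L)] - ph0
    den[den <= 0] <- 1                      # exact crossing at a sample
    beats <- t0 + pmin((ks - ph0) / den, 1) / sample_rate
  }
  ibi <- diff(beats)
  if (length(ibi) && min(ibi) <= pulse_width)
    stop(sprintf("pulse_width %g s >= shortest inter-beat interval %g s; beats would fuse",
                 pulse_width, min(ibi)), call. = FALSE)

  values <- numeric(ns)
  half <- pulse_width / 2
  for (b in beats) {
    i0 <- max(1L, ceiling((b - half) * sample_rate) + 1L)
    i1 <- min(ns, floor((b + half) * sample_rate) + 1L)
    if (i1 < i0) next
    tt <- ts[i0:i1]
    values[i0:i1] <- values[i0:i1] +
      pulse_amp * 0.5 * (1 + cos(pi * (tt - b) / half))
  }
  if (noise_sd > 0) values <- values + stats::rnorm(ns, 0, noise_sd)
  od_trace(values, sample_rate, ground_truth_beats = beats)
}

approx_effect <- function(e, t_min, at_min) {
  stats::approx(t_min, e, xout = pmin(pmax(at_min, min(t_min)), max(t_min)),
                rule = 2)$y
}
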