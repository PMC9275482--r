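#' Percent change from the first-minute baseline
#'
#' Normalises a recording to the percent change
#' `y(t) = 100 * (f(t) - f_base) / f_base`, where `f_base` is the mean
#' frequency over the baseline window (by default the first minute of the
#' registration, the assay's reference convention). A sample stamped at
#' time t is taken to summarise the interval ending at t, so the closed
#' window `[0, 1]` captures "the frequency in the first minute".
#'
#' @param rec a [recording()].
#' @param baseline_window numeric length-2, minutes; closed interval over
#'   which the baseline mean is taken. Must contain at least one sample and
#'   the mean must be positive.
#' @return object of class `percent_change_series`: list with `times`,
#'   `pct_change`, `baseline_value`, `baseline_window` and the originating
#'   `meta`.
#' @export
percent_change <- function(rec, baseline_window = c(0, 1)) {
  stopifnot(inherits(rec, "recording"), length(baseline_window) == 2L)
  sel <- rec$times >= baseline_window[1L] - 1e-9 &
         rec$times <= baseline_window[2L] + 1e-9
  if (!any(sel))
    stop(sprintf("baseline window [%g, %g] contains no samples",
                 baseline_window[1L], baseline_window[2L]), call. = FALSE)
  base <- mean(rec$frequencies[sel])
  if (base <= 0)
    stop("baseline mean frequency is zero; cannot normalise", call. = FALSE)
  structure(list(times = rec$times,
                 pct_change = 100 * (rec$frequencies - base) / base,
                 baseline_value = base, baseline_window = baseline_window,
                 meta = rec$meta),
            class = "percent_change_series")
}

#' @export
print.percent_change_series <- function(x, ...) {
  cat(sprintf("<percent_change_series> %d points, baseline %.2f contractions/min over [%g, %g] min\n",
              length(x$times), x$baseline_value, x$baseline_window[1L],
              x$baseline_window[2L]))
  invisible(x)
}

#' Slope coefficient of the percent-change trajectory
#'
#' The assay's dynamics statistic: for every consecutive pair of samples
#' the difference quotient `a = (y2 - y1) / (x2 - x1)` in percent per
#' minute. Non-uniform spacing (mixed 1.0- and 0.5-min steps) is handled
#' exactly; each value is stamped with the right endpoint `x2` of its
#' interval, matching how slope tables are indexed by minute.
#'
#' @param pcs a [percent_change()] (or any list with `times` and
#'   `pct_change`).
#' @return data.frame with columns `time` (right endpoint, minutes) and `a`
#'   (percent/min), one row per interval.
#' @export
slope_coefficient <- function(pcs) {
  times <- pcs$times
  y <- pcs$pct_change
  if (length(times) < 2L) stop("need at least 2 points", call. = FALSE)
  dx <- diff(times)
  if (any(dx == 0)) stop("duplicate time points", call. = FALSE)
  data.frame(time = times[-1L], a = diff(y) / dx)
}

#' Per-recording pharmacodynamic summary
#'
#' Computes the maximal effect and per-minute effect readouts of one
#' percent-change trajectory relative to the protocol's exposure window:
#' `e_max` is the signed extreme of the percent change between exposure
#' onset and exposure end (the point of maximal drug effect), `t_max` its
#' time, and `e_at` the percent change at each requested report minute
#' (nearest sample within half the local bin width). The `arrested` flag is
#' set when the frequency reaches zero anywhere inside the exposure window;
#' `non_monotone_onset` flags onset trajectories that overshoot and recede
#' by more than 5% of `|e_max|` before `t_max`.
#'
#' @param pcs a [percent_change()].
#' @param protocol a [protocol_spec()] identifying the exposure window.
#' @param report_minutes minutes at which point effects are reported
#'   (default the 9th and 13th minute).
#' @return object of class `pd_summary`.
#' @export
effect_summary <- function(pcs, protocol, report_minutes = c(9, 13)) {
  stopifnot(inherits(pcs, "percent_change_series"))
  win <- exposure_window(protocol)
  if (is.null(win)) win <- c(onset = 0, end = protocol$total_duration)
  sel <- pcs$times >= win[1L] - 1e-9 & pcs$times <= win[2L] + 1e-9
  if (!any(sel)) stop("no samples inside the exposure window", call. = FALSE)
  y <- pcs$pct_change[sel]
  tt <- pcs$times[sel]
  i_max <- which.max(abs(y))
  e_max <- y[i_max]
  t_max <- tt[i_max]

  bin <- stats::median(diff(pcs$times))
  e_at <- vapply(report_minutes, function(m) {
    if (m < min(pcs$times) - bin / 2 || m > max(pcs$times) + bin / 2)
      stop(sprintf("report minute %g outside the recording", m), call. = FALSE)
    i <- which.min(abs(pcs$times - m))
    if (abs(pcs$times[i] - m) > bin / 2 + 1e-9)
      stop(sprintf("no sample within %g min of report minute %g", bin / 2, m),
           call. = FALSE)
    pcs$pct_change[i]
  }, numeric(1))
  names(e_at) <- as.character(report_minutes)

  freq_in_win <- pcs$baseline_value * (1 + y / 100)
  onset_y <- y[seq_len(i_max)]
  non_mono <- if (i_max > 2L)
    any(abs(diff(cummax(abs(onset_y)))) > 0 &
        (cummax(abs(onset_y)) - abs(onset_y))[-1L] > 0.05 * abs(e_max))
    else FALSE

  structure(list(e_max = e_max, t_max = t_max, e_at = e_at,
                 exposure_window = win,
                 arrested = any(freq_in_win <= 1e-9),
                 non_monotone_onset = non_mono,
                 meta = pcs$meta),
            class = "pd_summary")
}

#' @export
print.pd_summary <- function(x, ...) {
  cat(sprintf("<pd_summary> e_max %.1f%% at %.2f min%s\n", x$e_max, x$t_max,
              if (x$arrested) " [arrested]" else ""))
  for (m in names(x$e_at))
    cat(sprintf("  E(min %s) = %.1f%%\n", m, x$e_at[[m]]))
  invisible(x)
}

#' Time to half-maximal effect (t50)
#'
#' Time from exposure onset to the first crossing of half the maximal
#' effect by the onset trajectory. Two estimators are provided:
#' `"interp"` (default) locates the first piecewise-linear crossing of
#' `e_max / 2` on the raw samples, an assumption-free estimate; `"fit"`
#' least-squares fits the mono-exponential onset
#' `E(t) = e_max * (1 - exp(-k (t - onset)))` to the samples between onset
#' and the time of maximal effect and reports `ln(2) / k`, mirroring
#' nonlinear-regression practice.
#'
#' @param pcs a [percent_change()].
#' @param protocol a [protocol_spec()].
#' @param method `"interp"` or `"fit"`.
#' @return list with `estimate` (minutes from exposure onset), `method`,
#'   `origin` (the onset time used, so alternative clock conventions remain
#'   recoverable) and, for `"fit"`, the fitted rate `k`.
#' @export
t50 <- function(pcs, protocol, method = c("interp", "fit")) {
  method <- match.arg(method)
  smry <- effect_summary(pcs, protocol, report_minutes = numeric(0))
  onset <- unname(smry$exposure_window[1L])
  if (abs(smry$e_max) <= 0) stop("no effect: |e_max| = 0", call. = FALSE)
  sel <- pcs$times >= onset - 1e-9 & pcs$times <= smry$t_max + 1e-9
  tt <- c(onset, pcs$times[sel])
  yy <- c(0, pcs$pct_change[sel])     # effect is 0 at exposure onset
  if (method == "interp") {
    est <- first_crossing(tt, yy, smry$e_max / 2) - onset
    list(estimate = est, method = method, origin = onset)
  } else {
    k <- fit_onset_rate(tt - onset, yy, smry$e_max)
    list(estimate = log(2) / k, method = method, origin = onset, k = k)
  }
}

#' Half-recovery time (RT50)
#'
#' Time from the end of exposure until the percent change has recovered
#' halfway back to the 0% baseline, i.e. first crossing of `e_max / 2` by
#' the recovery trajectory. This "half of the maximal change recovered"
#' reading is used because it is defined for effects of any size (a
#' frequency-reaches-50%-of-baseline reading would be undefined for
#' sub-50% inhibitions). If the recovery never reaches the half level
#' before the recording ends the estimate is `NA` and `censored = TRUE`.
#'
#' @inheritParams t50
#' @return list with `estimate` (minutes from exposure end), `method`,
#'   `origin` (exposure end), `censored`, and `k` for the `"fit"` method.
#' @export
rt50 <- function(pcs, protocol, method = c("interp", "fit")) {
  method <- match.arg(method)
  smry <- effect_summary(pcs, protocol, report_minutes = numeric(0))
  end <- unname(smry$exposure_window[2L])
  if (end >= max(pcs$times) + 1e-9)
    stop("exposure does not end within the recording", call. = FALSE)
  if (abs(smry$e_max) <= 0) stop("no effect: |e_max| = 0", call. = FALSE)
  origin <- max(end, smry$t_max)
  sel <- pcs$times >= origin - 1e-9
  tt <- pcs$times[sel]
  yy <- pcs$pct_change[sel]
  # start the recovery curve from the effect level at exposure end
  y0 <- stats::approx(pcs$times, pcs$pct_change, xout = origin, rule = 2)$y
  tt <- c(origin, tt); yy <- c(y0, yy)
  half <- smry$e_max / 2
  if (method == "interp") {
    cross <- first_crossing(tt, yy, half, direction = "toward_zero")
    list(estimate = if (is.na(cross)) NA_real_ else cross - origin,
         method = method, origin = origin, censored = is.na(cross))
  } else {
    k <- fit_decay_rate(tt - origin, yy, y0)
    list(estimate = log(2) / k, method = method, origin = origin,
         censored = FALSE, k = k)
  }
}

# first time at which the piecewise-linear interpolant of (tt, yy) crosses
# `level`; direction "toward_level" for onset (|y| growing past |level|),
# "toward_zero" for recovery (|y| shrinking past |level|)
first_crossing <- function(tt, yy, level,
                           direction = c("toward_level", "toward_zero")) {
  direction <- match.arg(direction)
  s <- if (level < 0) -1 else 1
  y <- yy * s; lv <- level * s   # work on magnitudes along the effect sign
  reached <- if (direction == "toward_level") y >= lv - 1e-12 else y <= lv + 1e-12
  hit <- which(reached)
  if (!length(hit)) return(NA_real_)
  i1 <- hit[1L]
  if (i1 == 1L) return(tt[1L])
  y1 <- y[i1 - 1L]; y2 <- y[i1]
  if (abs(y2 - y1) < 1e-15) return(tt[i1])
  tt[i1 - 1L] + (lv - y1) / (y2 - y1) * (tt[i1] - tt[i1 - 1L])
}

fit_onset_rate <- function(t_rel, y, e_max) {
  minimise_rate(function(k) sum((y - e_max * (1 - exp(-k * t_rel)))^2))
}

fit_decay_rate <- function(t_rel, y, y0) {
  minimise_rate(function(k) sum((y - y0 * exp(-k * t_rel))^2))
}

# the SSE in k is flat for large k, which defeats plain golden-section
# search; bracket the minimum on a log-spaced grid first, then refine
minimise_rate <- function(sse, lo = 1e-4, hi = 1e3) {
  grid <- exp(seq(log(lo), log(hi), length.out = 80L))
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  stats::optimize(sse, interval = c(grid[max(1L, i - 1L)],
                                    grid[min(length(grid), i + 1L)]))$minimum
}
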