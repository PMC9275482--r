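#' Fit a Hill / four-parameter logistic dose-response curve
#'
#' Least-squares fit of the inhibition curve
#' `E(C) = e_top + (e_bottom - e_top) / (1 + (ic50 / C)^h)` on the
#' log-dose axis: no effect (`e_top`, fixed at 0 by default) at zero dose,
#' `e_bottom` at saturation. The fit is deterministic: a multi-start grid
#' over Hill slopes `{0.5, 1, 2, 4}` and candidate IC50s at every observed
#' dose seeds box-constrained quasi-Newton refinement, and the best
#' candidate by residual sum of squares wins.
#'
#' @param doses molar concentrations, >= 3 distinct positive values.
#' @param effects percent-change effects at each dose (negative for
#'   inhibition), same length.
#' @param e_top effect at zero dose; fixed value (default 0).
#' @param e_bottom saturating effect: `NULL` (default) to estimate it
#'   within `[-100, 0]`, or a fixed value.
#' @param hill_starts Hill-slope grid for the multi-start.
#' @return object of class `dose_response_fit` with elements `ic50`,
#'   `hill`, `e_top`, `e_bottom`, `sse`, `fitted`, `doses`, `effects`,
#'   `extrapolated` (IC50 outside the spanned dose range by more than
#'   100x) and `degenerate` (flat data, no IC50).
#' @export
fit_dose_response <- function(doses, effects, e_top = 0, e_bottom = NULL,
                              hill_starts = c(0.5, 1, 2, 4)) {
  doses <- as.numeric(doses); effects <- as.numeric(effects)
  stopifnot(length(doses) == length(effects))
  if (any(doses <= 0)) stop("doses must be positive", call. = FALSE)
  if (length(unique(doses)) < 3L)
    stop("need at least 3 distinct doses", call. = FALSE)

  if (max(effects) - min(effects) < 1e-9) {
    return(structure(list(ic50 = NA_real_, hill = NA_real_, e_top = e_top,
                          e_bottom = NA_real_, sse = 0,
                          fitted = rep(mean(effects), length(doses)),
                          doses = doses, effects = effects,
                          extrapolated = FALSE, degenerate = TRUE),
                     class = "dose_response_fit"))
  }

  hill_curve <- function(C, ic50, h, bot)
    e_top + (bot - e_top) / (1 + (ic50 / C)^h)
  free_bottom <- is.null(e_bottom)
  obj <- function(par) {
    ic50 <- 10^par[1L]; h <- exp(par[2L])
    bot <- if (free_bottom) par[3L] else e_bottom
    sum((effects - hill_curve(doses, ic50, h, bot))^2)
  }
  lg_rng <- range(log10(doses))
  lower <- c(lg_rng[1L] - 2, log(0.05), if (free_bottom) -100)
  upper <- c(lg_rng[2L] + 2, log(20), if (free_bottom) 0)
  bot0 <- if (free_bottom) max(min(min(effects), -1e-6), -100)

  best <- NULL
  for (h0 in hill_starts) for (d0 in sort(unique(doses))) {
    par0 <- c(log10(d0), log(h0), if (free_bottom) bot0)
    fit <- tryCatch(
      stats::optim(par0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  if (is.null(best))
    stop("dose-response fit failed to converge from every start", call. = FALSE)

  ic50 <- 10^best$par[1L]; h <- exp(best$par[2L])
  bot <- if (free_bottom) best$par[3L] else e_bottom
  structure(list(ic50 = ic50, hill = h, e_top = e_top, e_bottom = bot,
                 sse = best$value, fitted = hill_curve(doses, ic50, h, bot),
                 doses = doses, effects = effects,
                 extrapolated = ic50 < min(doses) * 1e-2 ||
                                ic50 > max(doses) * 1e2,
                 degenerate = FALSE),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<dose_response_fit> degenerate (flat effects); no IC50\n")
    return(invisible(x))
  }
  cat(sprintf("<dose_response_fit> IC50 = %.4g M, hill = %.3g, span %g -> %.4g%%, SSE = %.4g%s\n",
              x$ic50, x$hill, x$e_top, x$e_bottom, x$sse,
              if (x$extrapolated) " [extrapolated]" else ""))
  invisible(x)
}

#' Invert a fitted dose-response curve
#'
#' Closed-form inversion of the fitted Hill curve: the dose at which the
#' fitted effect equals `effect_level` (a value strictly between `e_top`
#' and `e_bottom`). [ec()] is a convenience wrapper returning the dose
#' producing a given percentage of the full span, e.g. `ec(fit, 75)` for
#' the EC75 (75% of maximal inhibition).
#'
#' @param fit a [fit_dose_response()] result.
#' @param effect_level target effect on the percent-change scale.
#' @return dose in mol/L.
#' @export
inverse_dose <- function(fit, effect_level) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (fit$degenerate) stop("degenerate fit has no invertible curve", call. = FALSE)
  lo <- min(fit$e_top, fit$e_bottom); hi <- max(fit$e_top, fit$e_bottom)
  if (effect_level <= lo || effect_level >= hi)
    stop(sprintf("effect_level %g is not strictly between e_top (%g) and e_bottom (%g)",
                 effect_level, fit$e_top, fit$e_bottom), call. = FALSE)
  frac <- (effect_level - fit$e_top) / (fit$e_bottom - fit$e_top)
  fit$ic50 / (1 / frac - 1)^(1 / fit$hill)
}

#' @rdname inverse_dose
#' @param percent percentage of the full effect span (0-100, exclusive).
#' @export
ec <- function(fit, percent) {
  stopifnot(percent > 0, percent < 100)
  inverse_dose(fit, fit$e_top + percent / 100 * (fit$e_bottom - fit$e_top))
}
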