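#' Toxic index of a binary mixture
#'
#' The toxic index compares the mixture effect with the sum of the
#' single-compound effects:
#' `TI = E_mix / (E_a + E_b)`.
#' TI = 1 indicates additivity, TI < 1 antagonism (the mixture does less
#' than the sum of its parts), TI > 1 synergism. The index is computed on
#' signed percent changes; all three effects must share a sign (the
#' framework assumes same-direction, here cardioinhibitory, effects), so
#' the sign cancels and TI > 0.
#'
#' @param e_mix mixture effect, percent change.
#' @param e_a,e_b single-compound effects, percent change.
#' @return TI, dimensionless.
#' @export
toxic_index <- function(e_mix, e_a, e_b) {
  check_same_sign(e_mix, e_a, e_b)
  if (abs(e_a + e_b) < 1e-12)
    stop("toxic index undefined: e_a + e_b = 0", call. = FALSE)
  e_mix / (e_a + e_b)
}

#' Toxic units of a binary mixture
#'
#' The mixture effect expressed in units of each single-compound effect:
#' `TU = E_mix / E_a + E_mix / E_b`.
#' For an exactly additive mixture (`E_mix = E_a + E_b`) this equals the
#' additive reference `(E_a + E_b)/E_a + (E_a + E_b)/E_b`, which is >= 4
#' for same-sign effects; values below the reference indicate antagonism.
#'
#' @inheritParams toxic_index
#' @return TU, dimensionless.
#' @export
toxic_units <- function(e_mix, e_a, e_b) {
  check_same_sign(e_mix, e_a, e_b)
  if (abs(e_a) < 1e-12 || abs(e_b) < 1e-12)
    stop("toxic units undefined: a single-compound effect is zero; ",
         "use the toxic index instead", call. = FALSE)
  e_mix / e_a + e_mix / e_b
}

#' @rdname toxic_units
#' @export
tu_additive_ref <- function(e_a, e_b) {
  if (abs(e_a) < 1e-12 || abs(e_b) < 1e-12)
    stop("additive reference undefined for a zero effect", call. = FALSE)
  (e_a + e_b) / e_a + (e_a + e_b) / e_b
}

check_same_sign <- function(e_mix, e_a, e_b) {
  v <- c(e_mix, e_a, e_b)
  stopifnot(all(is.finite(v)))
  if (any(v > 0) && any(v < 0))
    stop("mixed-sign effects: TI/TU assume all effects act in the same ",
         "direction", call. = FALSE)
  invisible(TRUE)
}

#' Classify a mixture interaction
#'
#' TI rule: additive when `|TI - 1| <= delta`, antagonism when
#' `TI < 1 - delta`, synergism when `TI > 1 + delta`. TU rule: compare TU
#' with the additive reference `tu_additive_ref(e_a, e_b)` using the same
#' relative tolerance: additive within `delta * ref`, antagonism below,
#' synergism above. `delta` is a reporting convention (default 0.05), not a
#' statistical test.
#'
#' @param ti toxic index.
#' @param tu toxic units (optional; `NA` to skip the TU label).
#' @param tu_ref additive-reference TU (from [tu_additive_ref()]).
#' @param delta classification tolerance, dimensionless, >= 0.
#' @return named character vector with elements `label_ti` and `label_tu`.
#' @export
classify_interaction <- function(ti, tu = NA_real_, tu_ref = NA_real_,
                                 delta = 0.05) {
  stopifnot(delta >= 0)
  lab <- function(x, ref, tol) {
    if (is.na(x) || is.na(ref)) return(NA_character_)
    if (abs(x - ref) <= tol) "additive"
    else if (x < ref) "antagonism"
    else "synergism"
  }
  c(label_ti = lab(ti, 1, delta),
    label_tu = lab(tu, tu_ref, delta * abs(tu_ref)))
}

#' End-to-end mixture interaction analysis
#'
#' Runs the full interaction computation on grouped recordings: for each
#' evaluation minute, the effect of each arm is the group mean of the
#' percent change at that minute across the arm's recordings; the arm
#' effects then feed the toxic index, the toxic units, the additive
#' reference and the classification. Arms are independent preparations, so
#' no per-preparation pairing is attempted.
#'
#' @param arms named list with components `a`, `b` and `mix`, each a list
#'   of [recording()]s (single-compound A, single-compound B, and either
#'   the continuously perfused mixture or the drug-plus-pulse arm).
#' @param protocol a [protocol_spec()] identifying the exposure window
#'   (used for percent-change bookkeeping; the evaluation minutes drive the
#'   index itself).
#' @param evaluation_minutes minutes at which the indices are evaluated
#'   (continuous-perfusion default 13; pulse designs typically use 9 and
#'   13).
#' @param baseline_window passed to [percent_change()].
#' @param delta classification tolerance, see [classify_interaction()].
#' @return data.frame of class `interaction_result` with one row per
#'   evaluation minute: `minute`, `e_mix`, `e_a`, `e_b`, `ti`, `tu`,
#'   `tu_additive_ref`, `label_ti`, `label_tu`, `n_a`, `n_b`, `n_mix`,
#'   `delta`.
#' @export
interaction_pipeline <- function(arms, protocol, evaluation_minutes = 13,
                                 baseline_window = c(0, 1), delta = 0.05) {
  need <- c("a", "b", "mix")
  missing_arm <- setdiff(need, names(arms))
  if (length(missing_arm))
    stop("missing arm(s): ", paste(missing_arm, collapse = ", "), call. = FALSE)
  for (nm in need) {
    if (inherits(arms[[nm]], "recording")) arms[[nm]] <- list(arms[[nm]])
    if (!length(arms[[nm]]))
      stop("arm `", nm, "` has no recordings", call. = FALSE)
  }

  arm_effect <- function(recs, minute) {
    mean(vapply(recs, function(r) {
      pcs <- percent_change(r, baseline_window)
      smry <- effect_summary(pcs, r$meta$protocol %||% protocol,
                             report_minutes = minute)
      smry$e_at[[1L]]
    }, numeric(1)))
  }

  rows <- lapply(evaluation_minutes, function(m) {
    e_a <- arm_effect(arms$a, m)
    e_b <- arm_effect(arms$b, m)
    e_mix <- arm_effect(arms$mix, m)
    ti <- toxic_index(e_mix, e_a, e_b)
    tu <- toxic_units(e_mix, e_a, e_b)
    ref <- tu_additive_ref(e_a, e_b)
    labs <- classify_interaction(ti, tu, ref, delta)
    data.frame(minute = m, e_mix = e_mix, e_a = e_a, e_b = e_b, ti = ti,
               tu = tu, tu_additive_ref = ref,
               label_ti = labs[["label_ti"]], label_tu = labs[["label_tu"]],
               n_a = length(arms$a), n_b = length(arms$b),
               n_mix = length(arms$mix), delta = delta,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("interaction_result", class(out))
  out
}

#' @export
print.interaction_result <- function(x, ...) {
  cat("<interaction_result>\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  min %g: TI %.2f (%s), TU %.2f vs additive ref %.2f (%s)\n",
                x$minute[i], x$ti[i], x$label_ti[i], x$tu[i],
                x$tu_additive_ref[i], x$label_tu[i]))
  invisible(x)
}
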