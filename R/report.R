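#' Run configuration
#'
#' Plumbing options shared by the analysis stages.
#'
#' @param baseline_window numeric length-2, minutes.
#' @param binning minutes per frequency bin (> 0).
#' @param smoothing moving-mean width in samples applied to frequency
#'   series before metrics, 0 for none.
#' @param t50_method,rt50_method `"interp"` or `"fit"`.
#' @param delta classification tolerance for interaction labels (>= 0).
#' @param rng_seed integer seed for all stochastic stages.
#' @return object of class `run_config`.
#' @export
run_config <- function(baseline_window = c(0, 1), binning = 1, smoothing = 0,
                       t50_method = "interp", rt50_method = "interp",
                       delta = 0.05, rng_seed = 1L) {
  stopifnot(length(baseline_window) == 2L,
            baseline_window[2L] > baseline_window[1L],
            binning > 0, smoothing >= 0, delta >= 0)
  structure(list(baseline_window = baseline_window, binning = binning,
                 smoothing = smoothing, t50_method = t50_method,
                 rt50_method = rt50_method, delta = delta,
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

#' Summarise one recording into a report row
#'
#' @param rec a [recording()].
#' @param protocol a [protocol_spec()]; defaults to the recording's own.
#' @param config a [run_config()].
#' @param report_minutes minutes at which point effects are reported.
#' @return one-row data.frame with identification, `e_max`, `t_max`, `t50`,
#'   `rt50` (NA when censored), per-minute effects and flags.
#' @export
summarise_recording <- function(rec, protocol = NULL, config = run_config(),
                                report_minutes = c(9, 13)) {
  protocol <- protocol %||% rec$meta$protocol
  if (is.null(protocol)) stop("no protocol available for ",
                              rec$meta$preparation_id, call. = FALSE)
  pcs <- percent_change(rec, config$baseline_window)
  smry <- effect_summary(pcs, protocol, report_minutes)
  t5 <- tryCatch(t50(pcs, protocol, config$t50_method)$estimate,
                 error = function(e) NA_real_)
  r5 <- tryCatch(rt50(pcs, protocol, config$rt50_method)$estimate,
                 error = function(e) NA_real_)
  row <- data.frame(
    preparation_id = rec$meta$preparation_id,
    compound = paste(rec$meta$compound_ids, collapse = "+"),
    concentration = max(rec$meta$concentrations),
    variant = rec$meta$variant,
    e_max = smry$e_max, t_max = smry$t_max, t50 = t5, rt50 = r5,
    arrested = smry$arrested, stringsAsFactors = FALSE)
  for (m in names(smry$e_at)) row[[paste0("e_at_", m)]] <- smry$e_at[[m]]
  row
}

#' Write the machine- and human-readable analysis report
#'
#' Writes `path` (a CSV table, one row per recording plus optional
#' interaction rows appended as a second block) and `<path>.txt`, a short
#' human-readable report echoing configuration, seed and package version.
#' All numbers are formatted with 6 significant digits; identical inputs
#' and configuration produce byte-identical CSV output.
#'
#' @param results data.frame of per-recording summaries (e.g. rows from
#'   [summarise_recording()]).
#' @param path output CSV path.
#' @param interactions optional [interaction_pipeline()] result.
#' @param config a [run_config()] echoed into the text report.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, interactions = NULL,
                         config = run_config()) {
  if (is.null(results) || !is.data.frame(results) || nrow(results) == 0L)
    stop("empty results: nothing to report", call. = FALSE)
  fmt <- function(df) {
    for (cl in names(df)) if (is.numeric(df[[cl]]))
      df[[cl]] <- formatC(df[[cl]], digits = 6, format = "g")
    df
  }
  con <- file(path, open = "wt")
  ok <- FALSE
  on.exit({ close(con); if (!ok) unlink(path) })
  utils::write.csv(fmt(results), con, row.names = FALSE, quote = FALSE)
  if (!is.null(interactions) && nrow(interactions)) {
    writeLines("", con)
    utils::write.csv(fmt(as.data.frame(interactions)), con,
                     row.names = FALSE, quote = FALSE)
  }
  ok <- TRUE

  txt <- c("cardiopd analysis report",
           sprintf("package version: %s",
                   as.character(utils::packageVersion("cardiopd"))),
           sprintf("rng seed: %d", config$rng_seed),
           sprintf("baseline window: [%g, %g] min", config$baseline_window[1L],
                   config$baseline_window[2L]),
           sprintf("binning: %g min; t50: %s; rt50: %s; delta: %g",
                   config$binning, config$t50_method, config$rt50_method,
                   config$delta),
           sprintf("recordings summarised: %d", nrow(results)),
           if (!is.null(interactions))
             sprintf("interaction rows: %d", nrow(interactions)))
  writeLines(txt, paste0(path, ".txt"))
  invisible(path)
}
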