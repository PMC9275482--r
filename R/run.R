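#' Run a complete simulated experiment
#'
#' Orchestrates simulate -> per-recording metrics -> dose-response ->
#' interaction as one reproducible run. The experiment is described by a
#' list of arms; every stochastic stage derives its seed deterministically
#' from the master seed, so a rerun with the same configuration reproduces
#' all machine-readable outputs byte for byte.
#'
#' @param arms named list; each element is a list with components
#'   `protocol` (a [protocol_spec()]), `params` (a [pd_params()]) and `n`
#'   (number of preparations).
#' @param out_dir output directory (created if needed).
#' @param config a [run_config()]; `config$rng_seed` is the master seed.
#' @param interactions optional list of named lists `list(a=, b=, mix=,
#'   minutes=)` mapping arm names to interaction contrasts.
#' @param dose_response optional list of named lists `list(arms =
#'   c(...), doses = c(...), e_bottom = ...)`: arms measured at increasing
#'   doses of one compound; the final-exposure-minute group-mean effect per
#'   arm is fitted against `doses`.
#' @param report_minutes per-recording report minutes.
#' @return invisibly, a list with `summaries`, `interactions`, `fits` and
#'   `manifest` (also written to `out_dir`).
#' @export
run_experiment <- function(arms, out_dir, config = run_config(),
                           interactions = NULL, dose_response = NULL,
                           report_minutes = c(9, 13)) {
  if (!length(arms)) stop("nothing to run: no arms configured", call. = FALSE)
  if (is.null(names(arms)) || any(!nzchar(names(arms))))
    stop("arms must be named", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  recs <- list()
  counter <- 0L
  for (nm in names(arms)) {
    arm <- arms[[nm]]
    n <- arm$n %||% 1L
    recs[[nm]] <- lapply(seq_len(n), function(i) {
      simulate_frequency_series(
        arm$protocol, arm$params, seed = derive_seed(config$rng_seed,
                                                     counter + i),
        dt = config$binning,
        preparation_id = sprintf("%s_%02d", nm, i))
    })
    counter <- counter + n
  }

  all_recs <- unlist(recs, recursive = FALSE)
  write_recording(all_recs, file.path(out_dir, "recordings.csv"))
  summaries <- do.call(rbind, lapply(all_recs, summarise_recording,
                                     config = config,
                                     report_minutes = report_minutes))

  inter_rows <- NULL
  if (!is.null(interactions)) {
    inter_rows <- do.call(rbind, lapply(interactions, function(ctr) {
      res <- interaction_pipeline(
        list(a = recs[[ctr$a]], b = recs[[ctr$b]], mix = recs[[ctr$mix]]),
        arms[[ctr$mix]]$protocol,
        evaluation_minutes = ctr$minutes %||% 13,
        baseline_window = config$baseline_window, delta = config$delta)
      cbind(contrast = sprintf("%s|%s|%s", ctr$a, ctr$b, ctr$mix), res,
            stringsAsFactors = FALSE)
    }))
    utils::write.csv(inter_rows, file.path(out_dir, "interactions.csv"),
                     row.names = FALSE)
  }

  fits <- NULL
  if (!is.null(dose_response)) {
    fits <- lapply(dose_response, function(dr) {
      eff <- vapply(dr$arms, function(nm) {
        win <- exposure_window(arms[[nm]]$protocol)
        last_min <- floor(win[2L] - 1e-9)   # last full minute of exposure
        mean(vapply(recs[[nm]], function(r) {
          pcs <- percent_change(r, config$baseline_window)
          effect_summary(pcs, arms[[nm]]$protocol,
                         report_minutes = last_min)$e_at[[1L]]
        }, numeric(1)))
      }, numeric(1))
      fit <- fit_dose_response(dr$doses, eff,
                               e_bottom = dr$e_bottom %||% NULL)
      list(fit = fit, effects = eff)
    })
    fit_df <- do.call(rbind, lapply(names(fits), function(nm) {
      f <- fits[[nm]]$fit
      data.frame(compound = nm, ic50 = f$ic50, hill = f$hill,
                 e_bottom = f$e_bottom, sse = f$sse,
                 degenerate = f$degenerate, stringsAsFactors = FALSE)
    }))
    utils::write.csv(fit_df, file.path(out_dir, "dose_response.csv"),
                     row.names = FALSE)
  }

  write_report(summaries, file.path(out_dir, "summaries.csv"),
               interactions = inter_rows, config = config)

  manifest <- list(
    package_version = as.character(utils::packageVersion("cardiopd")),
    seed = config$rng_seed,
    config = unclass(config),
    arms = lapply(arms, function(a) list(n = a$n %||% 1L)),
    file_md5 = as.list(tools::md5sum(list.files(out_dir, pattern = "\\.csv$",
                                                full.names = TRUE))))
  names(manifest$file_md5) <- basename(names(manifest$file_md5))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(summaries = summaries, interactions = inter_rows,
                 fits = fits, manifest = manifest))
}

# deterministic per-stage seeds below 2^31, spread by a large prime
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 104729 + index * 7919) %% 2147483647)
}

#' Write the worked-example fixture set
#'
#' Generates the small plain-text fixtures used in documentation and tests:
#' plateau recordings encoding the reference group-mean effects of the
#' continuous-perfusion interaction example (verapamil -77.9%, alpha-
#' solanine -25.3%, alpha-chaconine -28.3%, and the two mixtures -66.7% and
#' -72.3% at minute 13), two analytic-ramp recordings for t50/RT50 checks,
#' and one seeded noisy simulated batch. All files are deterministic.
#'
#' @param out_dir output directory (created if needed).
#' @param seed seed for the noisy batch.
#' @return character vector of file paths, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  proto <- protocol_variant_a("compound", 1e-5)
  written <- character(0)

  plateaus <- c(ver = -77.9, sol = -25.3, chac = -28.3,
                ver_sol = -66.7, ver_chac = -72.3)
  for (nm in names(plateaus)) {
    rec <- plateau_recording(plateaus[[nm]], preparation_id = nm,
                             protocol = proto)
    f <- file.path(out_dir, paste0("plateau_", nm, ".csv"))
    write_recording(rec, f)
    written <- c(written, f)
  }

  tt <- seq(0.5, 22, by = 0.5)
  ramp_t50 <- 100 * pmax(pmin((tt - 4) / 2, 1), 0)      # 0 -> -100 over 4..6
  rec_down <- recording(tt, 50 * (1 - ramp_t50 / 100) + 1e-9,
                        preparation_id = "ramp_t50", protocol = proto)
  ramp_rt <- pmax(pmin((tt - 13.5) / 2, 1), 0)          # recover 13.5..15.5
  y <- -100 * pmax(pmin((tt - 4) / 2, 1), 0) * (1 - ramp_rt)
  rec_rt <- recording(tt, 50 * (1 + y / 100) + 1e-9,
                      preparation_id = "ramp_rt50", protocol = proto)
  for (r in list(rec_down, rec_rt)) {
    f <- file.path(out_dir, paste0(r$meta$preparation_id, ".csv"))
    write_recording(r, f)
    written <- c(written, f)
  }

  noisy <- lapply(1:5, function(i)
    simulate_frequency_series(protocol_variant_a("verapamil", 3e-5),
                              pd_params(ec50 = 1.685e-5),
                              seed = derive_seed(seed, i),
                              preparation_id = sprintf("noisy_%02d", i)))
  f <- file.path(out_dir, "noisy_batch.csv")
  write_recording(noisy, f)
  written <- c(written, f)
  invisible(written)
}

#' Plateau recording encoding a fixed percent-change effect
#'
#' Builds an idealised recording whose percent change ramps from 0 at the
#' exposure onset to `effect` percent, holds that plateau through minute 13
#' (so minute-13 readouts equal `effect` exactly), and recovers linearly
#' after the exposure ends. Used for worked examples and desk checks.
#'
#' @param effect plateau percent change (negative for inhibition).
#' @param f0 baseline frequency, contractions/min.
#' @param protocol a [protocol_spec()]; default variant-A timing.
#' @param dt sample spacing, minutes.
#' @param preparation_id label.
#' @return a [recording()].
#' @export
plateau_recording <- function(effect, f0 = 50,
                              protocol = protocol_variant_a("compound", 1e-5),
                              dt = 0.5, preparation_id = "plateau") {
  win <- exposure_window(protocol)
  tt <- seq(dt, protocol$total_duration, by = dt)
  onset_ramp <- pmax(pmin((tt - win[1L]) / 2, 1), 0)    # 2-min onset ramp
  recovery <- pmax(pmin((tt - win[2L]) / 2, 1), 0)      # 2-min recovery ramp
  y <- effect * onset_ramp * (1 - recovery)
  recording(tt, f0 * (1 + y / 100), preparation_id = preparation_id,
            compound_ids = active_compounds(protocol),
            concentrations = compound_concentrations(protocol),
            variant = "A_continuous", protocol = protocol)
}
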