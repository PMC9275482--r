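#' Heart-contraction frequency recording
#'
#' The pipeline's atomic input: a time-stamped contraction-frequency series
#' for one heart preparation, with compound/protocol metadata. Times are in
#' minutes from the start of registration and must be strictly increasing
#' (they need not be uniformly spaced; 1.0- and 0.5-min grids are both
#' common). Frequencies are contractions per minute and must be >= 0.
#'
#' @param times numeric, minutes, strictly increasing, length >= 2.
#' @param frequencies numeric, contractions/min, same length as `times`.
#' @param preparation_id character label for the preparation.
#' @param compound_ids character vector of compound labels ("saline" for a
#'   control).
#' @param concentrations molar concentrations matching `compound_ids`.
#' @param variant one of `"A_continuous"`, `"B_pulse"`, `"control"`.
#' @param protocol optional [protocol_spec()] describing the perfusion
#'   timeline.
#' @return object of class `recording`.
#' @export
recording <- function(times, frequencies, preparation_id = "prep01",
                      compound_ids = "saline", concentrations = 0,
                      variant = c("control", "A_continuous", "B_pulse"),
                      protocol = NULL) {
  variant <- match.arg(variant)
  times <- as.numeric(times)
  frequencies <- as.numeric(frequencies)
  if (length(times) != length(frequencies))
    stop("times and frequencies differ in length", call. = FALSE)
  # a single point is tolerated (a one-bin frequency summary produces one);
  # analysis functions that need more enforce their own minima
  if (length(times) < 1L)
    stop("a recording needs at least 1 point", call. = FALSE)
  if (anyNA(times) || anyNA(frequencies))
    stop("recording contains missing values", call. = FALSE)
  d <- diff(times)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1L]
    stop(sprintf("times must be strictly increasing; violation at t=%g (row %d)",
                 times[i + 1L], i + 1L), call. = FALSE)
  }
  if (any(frequencies < 0))
    stop(sprintf("negative frequency %g at t=%g",
                 frequencies[which(frequencies < 0)[1L]],
                 times[which(frequencies < 0)[1L]]), call. = FALSE)
  if (!is.null(protocol)) validate_protocol(protocol)
  structure(list(times = times, frequencies = frequencies,
                 meta = list(preparation_id = preparation_id,
                             compound_ids = as.character(compound_ids),
                             concentrations = as.numeric(concentrations),
                             variant = variant, protocol = protocol)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<recording> %s: %d points, %.2f-%.2f min, %s (%s)\n",
              m$preparation_id, length(x$times), min(x$times), max(x$times),
              paste(m$compound_ids, collapse = "+"), m$variant))
  invisible(x)
}

#' @export
as.data.frame.recording <- function(x, ...) {
  data.frame(preparation_id = x$meta$preparation_id, time_min = x$times,
             freq = x$frequencies, stringsAsFactors = FALSE)
}

#' Read contraction-frequency recordings from delimited text
#'
#' Two layouts are accepted. *Tidy/long* (canonical): columns `time_min`,
#' `freq` and optionally `preparation_id`; each preparation becomes one
#' [recording()]. *Wide*: a `time_min` column followed by one column per
#' preparation. The delimiter (comma or tab) is autodetected. A frequency
#' column named `freq_hz` is converted to contractions/min on read.
#' Metadata may be embedded in `#`-prefixed header lines of the form
#' `# key: value`; recognised keys are `compound_ids` (comma-separated),
#' `concentrations` (comma-separated, mol/L) and `variant`.
#'
#' @param path file path.
#' @param format `"tidy"` (long) or `"wide"`.
#' @param protocol optional [protocol_spec()] attached to every recording.
#' @return list of [recording()] objects.
#' @export
read_recording <- function(path, format = c("tidy", "wide"), protocol = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("recording file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  hdr <- grep("^#", raw, value = TRUE)
  meta <- parse_meta_header(hdr)
  body <- raw[!grepl("^#", raw) & nzchar(trimws(raw))]
  if (length(body) < 2L) stop("recording file has no data rows: ", path, call. = FALSE)
  sep <- if (grepl("\t", body[1L])) "\t" else ","
  df <- utils::read.table(text = body, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"time_min" %in% names(df))
    stop("recording file must declare a `time_min` column (minutes): ", path,
         call. = FALSE)

  hz <- "freq_hz" %in% names(df)
  if (hz) names(df)[names(df) == "freq_hz"] <- "freq"

  mk <- function(times, freqs, id) {
    o <- order(times)
    dup <- duplicated(times)
    if (any(dup))
      stop(sprintf("duplicate time point t=%g in %s (%s)", times[dup][1L],
                   path, id), call. = FALSE)
    recording(times[o], if (hz) freqs[o] * 60 else freqs[o],
              preparation_id = id,
              compound_ids = meta$compound_ids %||% "saline",
              concentrations = meta$concentrations %||%
                rep(0, length(meta$compound_ids %||% "saline")),
              variant = meta$variant %||% "control",
              protocol = protocol)
  }

  if (format == "tidy") {
    if (!"freq" %in% names(df))
      stop("tidy recording file needs columns time_min and freq (or freq_hz): ",
           path, call. = FALSE)
    ids <- if ("preparation_id" %in% names(df)) df$preparation_id else "prep01"
    sp <- split(df, if (length(ids) == 1L) rep(ids, nrow(df)) else ids)
    lapply(sp, function(g) mk(g$time_min, g$freq, g$preparation_id[1L] %||% "prep01"))
  } else {
    prep_cols <- setdiff(names(df), "time_min")
    if (!length(prep_cols))
      stop("wide recording file has no preparation columns: ", path, call. = FALSE)
    stats::setNames(lapply(prep_cols, function(cl) mk(df$time_min, df[[cl]], cl)),
                    prep_cols)
  }
}

parse_meta_header <- function(lines) {
  out <- list()
  m <- regmatches(lines, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", lines))
  for (f in m) {
    if (length(f) != 3L) next
    key <- f[2L]; val <- trimws(f[3L])
    out[[key]] <- switch(key,
      compound_ids = trimws(strsplit(val, ",")[[1L]]),
      concentrations = as.numeric(trimws(strsplit(val, ",")[[1L]])),
      val)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write recordings to tidy delimited text
#'
#' Writes one or more recordings as a tidy CSV (`preparation_id`,
#' `time_min`, `freq`) with a `#` metadata header taken from the first
#' recording, so that [read_recording()] round-trips times, frequencies and
#' metadata at full precision.
#'
#' @param recs a [recording()] or list of recordings.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recs, path) {
  if (inherits(recs, "recording")) recs <- list(recs)
  stopifnot(length(recs) > 0L, all(vapply(recs, inherits, TRUE, "recording")))
  m <- recs[[1L]]$meta
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(sprintf("# compound_ids: %s", paste(m$compound_ids, collapse = ",")),
               sprintf("# concentrations: %s",
                       paste(fmt_num(m$concentrations), collapse = ",")),
               sprintf("# variant: %s", m$variant),
               "preparation_id,time_min,freq"), con)
  for (r in recs) {
    writeLines(sprintf("%s,%s,%s", r$meta$preparation_id, fmt_num(r$times),
                       fmt_num(r$frequencies)), con)
  }
  invisible(path)
}
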