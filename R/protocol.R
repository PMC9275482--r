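#' Perfusion protocol specification
#'
#' A `protocol_spec` describes the perfusion timeline of one bioassay run:
#' an ordered set of contiguous segments, each perfusing one solution at a
#' fixed concentration, plus optional bolus ("pulse") applications injected
#' into the perfusion line. Time is measured in minutes from the start of
#' signal registration (the preincubation period is not part of the axis);
#' segments are half-open intervals `[t_start, t_end)`.
#'
#' @param segments data.frame with columns `t_start`, `t_end` (minutes),
#'   `solution_id` (character label; use `"saline"` for vehicle) and
#'   `concentration` (mol/L, 0 for vehicle). Segments must be ordered,
#'   contiguous and cover `[0, total_duration]`.
#' @param total_duration total registration time in minutes. Defaults to the
#'   end of the last segment.
#' @param pulses optional data.frame with columns `t_apply` (minutes),
#'   `solution_id`, `concentration` (mol/L of the injected bolus) and
#'   `bolus_volume_fraction` (bolus volume / chamber volume, dimensionless).
#' @param flow_rate perfusion flow rate in uL/min (metadata only).
#' @return object of class `protocol_spec`.
#' @examples
#' protocol_variant_a("verapamil", 3e-5)
#' @export
protocol_spec <- function(segments, total_duration = NULL, pulses = NULL,
                          flow_rate = 300) {
  if (!is.data.frame(segments) ||
      !all(c("t_start", "t_end", "solution_id", "concentration") %in%
           names(segments))) {
    stop("`segments` must be a data.frame with columns t_start, t_end, ",
         "solution_id, concentration", call. = FALSE)
  }
  segments <- segments[, c("t_start", "t_end", "solution_id", "concentration")]
  segments$solution_id <- as.character(segments$solution_id)
  if (nrow(segments) < 1L) stop("protocol needs at least one segment", call. = FALSE)
  if (is.null(total_duration)) total_duration <- max(segments$t_end)

  if (is.null(pulses)) {
    pulses <- data.frame(t_apply = numeric(0), solution_id = character(0),
                         concentration = numeric(0),
                         bolus_volume_fraction = numeric(0),
                         stringsAsFactors = FALSE)
  } else {
    need <- c("t_apply", "solution_id", "concentration", "bolus_volume_fraction")
    if (!is.data.frame(pulses) || !all(need %in% names(pulses)))
      stop("`pulses` must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    pulses <- pulses[, need]
    pulses$solution_id <- as.character(pulses$solution_id)
  }

  x <- structure(list(total_duration = total_duration, segments = segments,
                      pulses = pulses, flow_rate = flow_rate),
                 class = "protocol_spec")
  validate_protocol(x)
  x
}

#' @rdname protocol_spec
#' @param x object to validate.
#' @export
validate_protocol <- function(x) {
  stopifnot(inherits(x, "protocol_spec"))
  seg <- x$segments
  if (any(!is.finite(seg$t_start)) || any(!is.finite(seg$t_end)))
    stop("protocol: non-finite segment boundary", call. = FALSE)
  if (any(seg$t_end <= seg$t_start)) {
    i <- which(seg$t_end <= seg$t_start)[1L]
    stop(sprintf("protocol: segment %d has t_end <= t_start (%g <= %g)",
                 i, seg$t_end[i], seg$t_start[i]), call. = FALSE)
  }
  if (is.unsorted(seg$t_start, strictly = TRUE) && nrow(seg) > 1L)
    stop("protocol: segments are not in increasing time order", call. = FALSE)
  if (abs(seg$t_start[1L]) > 1e-9)
    stop("protocol: first segment must start at time 0, got ", seg$t_start[1L],
         call. = FALSE)
  if (nrow(seg) > 1L) {
    gap <- seg$t_start[-1L] - seg$t_end[-nrow(seg)]
    if (any(gap > 1e-9)) {
      i <- which(gap > 1e-9)[1L]
      stop(sprintf("protocol: gap between segment %d (ends %g) and segment %d (starts %g)",
                   i, seg$t_end[i], i + 1L, seg$t_start[i + 1L]), call. = FALSE)
    }
    if (any(gap < -1e-9)) {
      i <- which(gap < -1e-9)[1L]
      stop(sprintf("protocol: segments %d and %d overlap (%g > %g)",
                   i, i + 1L, seg$t_end[i], seg$t_start[i + 1L]), call. = FALSE)
    }
  }
  if (abs(seg$t_end[nrow(seg)] - x$total_duration) > 1e-9)
    stop(sprintf("protocol: segments end at %g but total_duration is %g",
                 seg$t_end[nrow(seg)], x$total_duration), call. = FALSE)
  if (any(seg$concentration < 0))
    stop("protocol: negative segment concentration", call. = FALSE)
  p <- x$pulses
  if (nrow(p)) {
    bad <- p$t_apply < 0 | p$t_apply > x$total_duration
    if (any(bad))
      stop(sprintf("protocol: pulse at t=%g lies outside [0, %g]",
                   p$t_apply[which(bad)[1L]], x$total_duration), call. = FALSE)
    if (any(p$concentration < 0))
      stop("protocol: negative pulse concentration", call. = FALSE)
    if (any(p$bolus_volume_fraction <= 0))
      stop("protocol: bolus_volume_fraction must be > 0", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("<protocol_spec> %g min, %d segment(s), %d pulse(s), flow %g uL/min\n",
              x$total_duration, nrow(x$segments), nrow(x$pulses), x$flow_rate))
  for (i in seq_len(nrow(x$segments)))
    cat(sprintf("  [%5.2f, %5.2f) %s %s\n", x$segments$t_start[i],
                x$segments$t_end[i], x$segments$solution_id[i],
                format_conc(x$segments$concentration[i])))
  for (i in seq_len(nrow(x$pulses)))
    cat(sprintf("  pulse @ %.2f min: %s %s (vol. fraction %g)\n",
                x$pulses$t_apply[i], x$pulses$solution_id[i],
                format_conc(x$pulses$concentration[i]),
                x$pulses$bolus_volume_fraction[i]))
  invisible(x)
}

format_conc <- function(c) ifelse(c > 0, sprintf("%.3g M", c), "(vehicle)")

#' Standard protocol constructors
#'
#' Convenience builders for the three application patterns used in the
#' perfusion bioassay: a saline control, continuous perfusion with a test
#' solution in a mid-recording window (variant A), and continuous drug
#' perfusion with a single bolus application of a second compound
#' (variant B). Defaults: 22-min registration, compound window
#' `[4, 13.5)` min, pulse at 8 min.
#'
#' @param compound,concentration solution label and molar concentration for
#'   the continuously perfused test solution. For variant A `compound` may be
#'   a vector of length 2 (a binary mixture) with matching `concentration`.
#' @param window numeric length-2, perfusion window of the test solution in
#'   minutes.
#' @param duration total registration time (minutes).
#' @param flow_rate perfusion rate, uL/min.
#' @return a [protocol_spec()].
#' @export
protocol_control <- function(duration = 22, flow_rate = 300) {
  protocol_spec(data.frame(t_start = 0, t_end = duration,
                           solution_id = "saline", concentration = 0,
                           stringsAsFactors = FALSE),
                total_duration = duration, flow_rate = flow_rate)
}

#' @rdname protocol_control
#' @export
protocol_variant_a <- function(compound, concentration, window = c(4, 13.5),
                               duration = 22, flow_rate = 300) {
  stopifnot(length(compound) == length(concentration), length(window) == 2L)
  id <- paste(compound, collapse = "+")
  seg <- data.frame(
    t_start = c(0, window[1L], window[2L]),
    t_end   = c(window[1L], window[2L], duration),
    solution_id = c("saline", id, "saline"),
    concentration = c(0, max(concentration), 0),
    stringsAsFactors = FALSE)
  p <- protocol_spec(seg, total_duration = duration, flow_rate = flow_rate)
  # mixtures keep per-compound concentrations as an attribute used by the
  # simulator (a segment row stores a single number)
  attr(p, "mixture") <- if (length(compound) > 1L)
    stats::setNames(concentration, compound) else NULL
  p
}

#' @rdname protocol_control
#' @param pulse_compound,pulse_concentration bolus solution label and molar
#'   concentration (variant B).
#' @param t_pulse application time of the bolus, minutes.
#' @param bolus_volume_fraction bolus volume / chamber volume.
#' @export
protocol_variant_b <- function(compound, concentration, window = c(4, 13.5),
                               pulse_compound, pulse_concentration,
                               t_pulse = 8, bolus_volume_fraction = 0.1,
                               duration = 22, flow_rate = 300) {
  seg <- data.frame(
    t_start = c(0, window[1L], window[2L]),
    t_end   = c(window[1L], window[2L], duration),
    solution_id = c("saline", compound, "saline"),
    concentration = c(0, concentration, 0),
    stringsAsFactors = FALSE)
  pulses <- data.frame(t_apply = t_pulse, solution_id = pulse_compound,
                       concentration = pulse_concentration,
                       bolus_volume_fraction = bolus_volume_fraction,
                       stringsAsFactors = FALSE)
  protocol_spec(seg, total_duration = duration, pulses = pulses,
                flow_rate = flow_rate)
}

#' Exposure window of a protocol
#'
#' The exposure window is the time interval during which any test compound
#' is present: from the start of the first non-vehicle segment (or the first
#' pulse, whichever is earlier) to the end of the last non-vehicle segment
#' (or the last pulse time if no such segment exists). It anchors the t50
#' clock (onset) and the RT50 clock (end).
#'
#' @param protocol a [protocol_spec()].
#' @return numeric length-2 `c(onset, end)` in minutes, or `NULL` for a pure
#'   vehicle protocol with no pulses.
#' @export
exposure_window <- function(protocol) {
  validate_protocol(protocol)
  seg <- protocol$segments
  act <- seg[seg$concentration > 0, , drop = FALSE]
  pt <- protocol$pulses$t_apply
  if (nrow(act) == 0L && length(pt) == 0L) return(NULL)
  onset <- suppressWarnings(min(c(act$t_start, pt)))
  end <- if (nrow(act)) max(act$t_end) else max(pt)
  c(onset = onset, end = max(end, onset))
}

#' Read a perfusion protocol from a plain-text file
#'
#' The format is a flat key/value listing, one entry per line, `#` comments
#' allowed:
#' \preformatted{
#' total_duration: 22
#' flow_rate: 300
#' segment: 0 4 saline 0
#' segment: 4 13.5 verapamil 3e-5
#' segment: 13.5 22 saline 0
#' pulse: 8 solanine 1e-5 0.1
#' }
#' `segment:` fields are `t_start t_end solution_id concentration`;
#' `pulse:` fields are `t_apply solution_id concentration
#' bolus_volume_fraction`. Validation is strict: gaps, overlaps and pulses
#' outside the recording are rejected with a located error, never repaired.
#'
#' @param path file path.
#' @return a [protocol_spec()].
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad))
    stop("protocol file: cannot parse line: ", lines[which(bad)[1L]],
         call. = FALSE)
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)

  num <- function(key, default = NULL) {
    i <- which(keys == key)
    if (!length(i)) return(default)
    as.numeric(vals[i[1L]])
  }
  parse_fields <- function(v, n, what, line) {
    f <- strsplit(trimws(v), "\\s+")[[1L]]
    if (length(f) != n)
      stop(sprintf("protocol file: %s needs %d fields, got %d in: %s",
                   what, n, length(f), line), call. = FALSE)
    f
  }
  segs <- which(keys == "segment")
  if (!length(segs)) stop("protocol file: no segment lines", call. = FALSE)
  seg <- do.call(rbind, lapply(segs, function(i) {
    f <- parse_fields(vals[i], 4L, "segment", lines[i])
    data.frame(t_start = as.numeric(f[1L]), t_end = as.numeric(f[2L]),
               solution_id = f[3L], concentration = as.numeric(f[4L]),
               stringsAsFactors = FALSE)
  }))
  pul <- which(keys == "pulse")
  pulses <- if (length(pul)) do.call(rbind, lapply(pul, function(i) {
    f <- parse_fields(vals[i], 4L, "pulse", lines[i])
    data.frame(t_apply = as.numeric(f[1L]), solution_id = f[2L],
               concentration = as.numeric(f[3L]),
               bolus_volume_fraction = as.numeric(f[4L]),
               stringsAsFactors = FALSE)
  })) else NULL
  protocol_spec(seg, total_duration = num("total_duration"),
                pulses = pulses, flow_rate = num("flow_rate", 300))
}

#' Write a protocol to its plain-text representation
#'
#' Inverse of [read_protocol()].
#' @param protocol a [protocol_spec()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  validate_protocol(protocol)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("total_duration: %s", fmt_num(protocol$total_duration)), con)
  writeLines(sprintf("flow_rate: %s", fmt_num(protocol$flow_rate)), con)
  s <- protocol$segments
  for (i in seq_len(nrow(s)))
    writeLines(sprintf("segment: %s %s %s %s", fmt_num(s$t_start[i]),
                       fmt_num(s$t_end[i]), s$solution_id[i],
                       fmt_num(s$concentration[i])), con)
  p <- protocol$pulses
  for (i in seq_len(nrow(p)))
    writeLines(sprintf("pulse: %s %s %s %s", fmt_num(p$t_apply[i]),
                       p$solution_id[i], fmt_num(p$concentration[i]),
                       fmt_num(p$bolus_volume_fraction[i])), con)
  invisible(path)
}

# full-precision, locale-independent numeric formatting shared by writers
fmt_num <- function(x) formatC(x, digits = 15, format = "g")
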