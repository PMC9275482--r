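#' Detect heart beats in a densitometric trace
#'
#' Emulates the cardiomyogram-to-beats conversion step of the acquisition
#' software: beats are local maxima of the (optionally smoothed) signal with
#' topographic prominence at least `min_prominence`, selected greedily in
#' order of decreasing prominence (ties broken by earlier time) under the
#' constraint that accepted beats are at least `refractory` seconds apart.
#' The reported beat time is the parabolic interpolation of the peak apex
#' from the sample and its two neighbours.
#'
#' Prominence of a peak is its height above the higher of the two minima
#' separating it from the nearest higher samples (or the trace edges).
#'
#' @param trace an [od_trace()].
#' @param min_prominence minimum prominence, signal units.
#' @param refractory minimum inter-beat interval, seconds (> 0, < trace
#'   duration).
#' @param smoothing_width moving-mean width in seconds applied before peak
#'   picking; 0 disables smoothing.
#' @return object of class `beat_set`: list with `beat_times` (seconds,
#'   strictly increasing) and `detection_params`.
#' @export
detect_beats <- function(trace, min_prominence = 0.25, refractory = 0.2,
                         smoothing_width = 0) {
  stopifnot(inherits(trace, "od_trace"))
  if (refractory <= 0) stop("refractory must be > 0", call. = FALSE)
  if (refractory >= trace$duration)
    stop(sprintf("refractory (%g s) >= trace duration (%g s)", refractory,
                 trace$duration), call. = FALSE)
  v <- trace$values
  sr <- trace$sample_rate
  if (smoothing_width > 0) {
    w <- max(1L, round(smoothing_width * sr))
    if (w %% 2L == 0L) w <- w + 1L
    v <- as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
    v[is.na(v)] <- trace$values[is.na(v)]   # edges: keep raw samples
  }
  n <- length(v)
  peaks <- which(v[-c(1L, n)] > v[-c(n - 1L, n)] &
                 v[-c(1L, n)] > v[-c(1L, 2L)]) + 1L
  # a trace can begin/end mid-beat: keep one-sided maxima at the edges
  if (n >= 2L && v[1L] > v[2L]) peaks <- c(1L, peaks)
  if (n >= 2L && v[n] > v[n - 1L]) peaks <- c(peaks, n)
  if (!length(peaks))
    return(beat_set(numeric(0), min_prominence, refractory, smoothing_width))

  prom <- peak_prominence(v, peaks)
  keep <- prom >= min_prominence
  peaks <- peaks[keep]; prom <- prom[keep]
  ord <- order(-prom, peaks)
  accepted <- integer(0)
  ref_samples <- refractory * sr
  for (i in ord) {
    p <- peaks[i]
    if (!length(accepted) || all(abs(accepted - p) >= ref_samples))
      accepted <- c(accepted, p)
  }
  accepted <- sort(accepted)
  beat_set(parabolic_apex(v, accepted, sr), min_prominence, refractory,
           smoothing_width)
}

beat_set <- function(beat_times, min_prominence, refractory, smoothing_width) {
  structure(list(beat_times = beat_times,
                 detection_params = list(min_prominence = min_prominence,
                                         refractory = refractory,
                                         smoothing_width = smoothing_width)),
            class = "beat_set")
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("<beat_set> %d beats", length(x$beat_times)))
  if (length(x$beat_times) > 1L)
    cat(sprintf(", mean rate %.1f contractions/min",
                60 * (length(x$beat_times) - 1) / diff(range(x$beat_times))))
  cat("\n")
  invisible(x)
}

# topographic prominence for each candidate peak index: height above the
# higher of the two side minima, each taken down to the nearest higher
# sample or the trace edge; a side with no samples (edge peak) is ignored
peak_prominence <- function(v, peaks) {
  n <- length(v)
  vapply(peaks, function(p) {
    h <- v[p]
    lmin <- Inf
    i <- p - 1L
    while (i >= 1L && v[i] <= h) { lmin <- min(lmin, v[i]); i <- i - 1L }
    rmin <- Inf
    i <- p + 1L
    while (i <= n && v[i] <= h) { rmin <- min(rmin, v[i]); i <- i + 1L }
    base <- if (is.finite(lmin) && is.finite(rmin)) max(lmin, rmin)
            else if (is.finite(lmin)) lmin
            else if (is.finite(rmin)) rmin
            else h
    h - base
  }, numeric(1))
}

parabolic_apex <- function(v, idx, sr) {
  vapply(idx, function(i) {
    if (i <= 1L || i >= length(v)) return((i - 1L) / sr)
    denom <- v[i - 1L] - 2 * v[i] + v[i + 1L]
    delta <- if (denom < 0) 0.5 * (v[i - 1L] - v[i + 1L]) / denom else 0
    (i - 1L + delta) / sr
  }, numeric(1))
}

#' Binned contraction frequency from beat times
#'
#' Counts beats per bin and scales the count to contractions/min
#' (count-based frequency, matching how the bioassay reports per-minute or
#' per-half-minute contraction frequencies). A partial terminal bin is
#' scaled by its actual width; bins of zero width are dropped. An empty
#' beat set yields all-zero frequencies (the representation of cardiac
#' arrest).
#'
#' @param beats a [detect_beats()] or numeric vector of beat times (seconds).
#' @param bin bin width, minutes.
#' @param span numeric length-2 `(t0, t1)` in minutes delimiting the
#'   analysed window; defaults to `(0, last beat rounded up to a full bin)`.
#' @param ... passed to [recording()] (metadata).
#' @return a [recording()] with bin right-edge timestamps (minutes).
#' @export
frequency_from_beats <- function(beats, bin = 1, span = NULL, ...) {
  bt <- if (inherits(beats, "beat_set")) beats$beat_times else as.numeric(beats)
  stopifnot(bin > 0)
  if (is.null(span)) {
    t1 <- if (length(bt)) ceiling(max(bt) / 60 / bin) * bin else bin * 2
    span <- c(0, max(t1, 2 * bin))
  }
  if (span[2L] <= span[1L]) stop("empty span", call. = FALSE)
  edges <- seq(span[1L], span[2L], by = bin)
  if (edges[length(edges)] < span[2L] - 1e-12)
    edges <- c(edges, span[2L])              # partial terminal bin
  widths <- diff(edges)
  keep <- widths > 1e-12
  bt_min <- bt / 60
  counts <- vapply(which(keep), function(i) {
    sum(bt_min > edges[i] & bt_min <= edges[i + 1L]) +
      if (i == 1L) sum(abs(bt_min - edges[1L]) < 1e-12) else 0L
  }, numeric(1))
  recording(edges[-1L][keep], counts / widths[keep], ...)
}
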