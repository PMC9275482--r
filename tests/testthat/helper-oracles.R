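# Independent oracles and shared fixture builders. Oracles deliberately use
# different code paths (explicit loops, O(n^2) scans) than the implementation
# they check.

# slope coefficient recomputed with an explicit loop
oracle_slope <- function(times, y) {
  n <- length(times)
  a <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    a[i] <- (y[i + 1L] - y[i]) / (times[i + 1L] - times[i])
  }
  a
}

# exhaustive beat-detection oracle: enumerate all candidate maxima (strict
# interior maxima plus one-sided edge maxima), compute prominence by brute
# force over the whole trace, then greedily select by decreasing prominence
# (ties by earlier index) under the refractory spacing. Returns sample
# indices (1-based).
oracle_detect_idx <- function(v, sr, min_prominence, refractory) {
  n <- length(v)
  cand <- integer(0)
  for (i in seq_len(n)) {
    left_ok <- i == 1L || v[i] > v[i - 1L]
    right_ok <- i == n || v[i] > v[i + 1L]
    one_sided <- (i == 1L && n >= 2L && v[1L] > v[2L]) ||
                 (i == n && n >= 2L && v[n] > v[n - 1L])
    if ((i > 1L && i < n && left_ok && right_ok) || one_sided)
      cand <- c(cand, i)
  }
  if (!length(cand)) return(integer(0))
  prom <- sapply(cand, function(p) {
    h <- v[p]
    higher <- which(v > h)
    lh <- higher[higher < p]; rh <- higher[higher > p]
    lmin <- if (p > 1L) min(v[max(c(1L, lh + 1L)):(p - 1L)]) else NA_real_
    rmin <- if (p < n) min(v[(p + 1L):min(c(n, rh - 1L))]) else NA_real_
    if (p == 1L) lmin <- NA_real_
    if (p == n) rmin <- NA_real_
    base <- suppressWarnings(max(lmin, rmin, na.rm = TRUE))
    if (!is.finite(base)) base <- h
    h - base
  })
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  ord <- order(-prom, cand)
  acc <- integer(0)
  for (i in ord) {
    if (!length(acc) || all(abs(acc - cand[i]) >= refractory * sr))
      acc <- c(acc, cand[i])
  }
  sort(acc)
}

# noiseless kinetics simulation settings reused across t50/RT50 tests:
# exposure long enough (8 time constants) that the observed maximum is the
# asymptote, plus a recovery tail of 10 half-lives
kinetics_protocol <- function(k_on, k_off) {
  t_on <- 2
  t_off <- t_on + 8 / k_on
  total <- t_off + 10 * log(2) / k_off + 2
  protocol_variant_a("cmpd", 1e-3, window = c(t_on, t_off), duration = total)
}

noiseless_params <- function(...) {
  pd_params(noise_sd_freq = 0, baseline_drift_sd = 0, ...)
}

# match detected events to ground truth within a tolerance (both sorted);
# returns counts used for sensitivity/precision
match_events <- function(detected, truth, tol = 0.25) {
  used <- logical(length(truth))
  tp <- 0L
  for (d in detected) {
    j <- which(!used & abs(truth - d) <= tol)
    if (length(j)) { used[j[1L]] <- TRUE; tp <- tp + 1L }
  }
  list(tp = tp, fp = length(detected) - tp, fn = sum(!used))
}
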