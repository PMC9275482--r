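proto_a <- protocol_variant_a("cmpd", 1e-5)

test_that("percent change normalises against the first-minute baseline", {
  rec <- recording(1:10, rep(50, 10))
  expect_equal(percent_change(rec)$pct_change, rep(0, 10))

  rec2 <- recording(1:10, c(50, rep(25, 9)))
  pcs <- percent_change(rec2)
  expect_equal(pcs$baseline_value, 50)
  expect_equal(pcs$pct_change[-1], rep(-50, 9))

  # 0.5-min sampling: baseline is the mean of both first-minute samples
  rec3 <- recording(seq(0.5, 3, 0.5), c(48, 52, 50, 50, 50, 50))
  expect_equal(percent_change(rec3)$baseline_value, 50)

  expect_error(percent_change(recording(1:5, rep(0, 5))), "zero")
  expect_error(percent_change(rec, baseline_window = c(90, 91)),
               "no samples")
})

test_that("percent change is invariant to frequency rescaling", {
  set.seed(1)
  for (i in 1:20) {
    tt <- sort(runif(30, 0, 22))
    tt[1] <- 0.2                      # keep a baseline sample
    ff <- runif(30, 20, 80)
    scale <- runif(1, 0.1, 10)
    a <- percent_change(recording(tt, ff))$pct_change
    b <- percent_change(recording(tt, ff * scale))$pct_change
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("slope coefficient is the exact difference quotient", {
  pcs <- list(times = c(4, 5), pct_change = c(0, -10))
  expect_equal(slope_coefficient(pcs)$a, -10)
  pcs <- list(times = c(4, 5), pct_change = c(-10, -10))
  expect_equal(slope_coefficient(pcs)$a, 0)
  # half-minute spacing handled exactly
  pcs <- list(times = c(4, 4.5), pct_change = c(0, -15))
  expect_equal(slope_coefficient(pcs)$a, -30)
  expect_error(slope_coefficient(list(times = c(1, 1), pct_change = c(0, 1))),
               "duplicate")
})

test_that("slope coefficient matches the loop oracle to machine precision", {
  set.seed(2)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    tt <- sort(runif(n, 0, 22))
    while (any(diff(tt) == 0)) tt <- sort(runif(n, 0, 22))
    y <- rnorm(n, 0, 40)
    got <- slope_coefficient(list(times = tt, pct_change = y))
    expect_identical(got$a, oracle_slope(tt, y))
    expect_identical(got$time, tt[-1])
  }
})

test_that("effect summary reports e_max, per-minute effects and flags", {
  rec <- plateau_recording(-77.9, protocol = proto_a)
  smry <- effect_summary(percent_change(rec), proto_a)
  expect_equal(smry$e_max, -77.9, tolerance = 1e-9)
  expect_equal(smry$e_at[["13"]], -77.9, tolerance = 1e-9)
  expect_true(abs(smry$e_max) >= max(abs(smry$e_at)))
  expect_false(smry$arrested)

  # all-zero series: e_max = 0 at exposure onset sample
  flat <- recording(seq(0.5, 22, 0.5), rep(50, 44), protocol = proto_a)
  smry0 <- effect_summary(percent_change(flat), proto_a)
  expect_equal(smry0$e_max, 0)
  expect_equal(smry0$t_max, 4, tolerance = 0.5)

  # arrest: zero frequency inside the window sets the flag
  ff <- rep(50, 44); ff[seq(0.5, 22, 0.5) > 6 & seq(0.5, 22, 0.5) < 13] <- 0
  arr <- recording(seq(0.5, 22, 0.5), ff, protocol = proto_a)
  expect_true(effect_summary(percent_change(arr), proto_a)$arrested)

  expect_error(effect_summary(percent_change(rec), proto_a,
                              report_minutes = 40), "outside")
})

test_that("t50: linear ramp and step bounds", {
  tt <- seq(0.5, 22, 0.5)
  # ramp 0 -> -100 over minutes 4 -> 6: t50 = 1.0 after onset
  y <- -100 * pmax(pmin((tt - 4) / 2, 1), 0)
  rec <- recording(tt, 50 * (1 + y / 100), protocol = proto_a)
  est <- t50(percent_change(rec), proto_a)
  expect_equal(est$estimate, 1.0, tolerance = 1e-9)
  expect_equal(unname(est$origin), 4)

  # step to plateau within one bin: t50 <= bin width
  y2 <- ifelse(tt >= 4.5, -80, 0) * (tt <= 13.5)
  rec2 <- recording(tt, 50 * (1 + y2 / 100), protocol = proto_a)
  expect_lte(t50(percent_change(rec2), proto_a)$estimate, 0.5)
})

test_that("rt50: linear recovery and right-censoring", {
  tt <- seq(0.5, 22, 0.5)
  ramp_on <- pmax(pmin((tt - 4) / 2, 1), 0)
  recov <- pmax(pmin((tt - 13.5) / 2, 1), 0)
  y <- -100 * ramp_on * (1 - recov)
  rec <- recording(tt, 50 * (1 + y / 100) + 1e-9, protocol = proto_a)
  est <- rt50(percent_change(rec), proto_a)
  expect_equal(est$estimate, 1.0, tolerance = 1e-9)
  expect_false(est$censored)

  # flat -80 to the end: censored
  y2 <- -80 * pmax(pmin((tt - 4) / 2, 1), 0)
  rec2 <- recording(tt, 50 * (1 + y2 / 100), protocol = proto_a)
  est2 <- rt50(percent_change(rec2), proto_a)
  expect_true(est2$censored)
  expect_true(is.na(est2$estimate))
})

test_that("interp and fit estimators agree on analytic first-order curves", {
  for (k in c(0.26, 0.667, 1.5)) {
    prot <- kinetics_protocol(k, k)
    p <- noiseless_params(e_max = -80, ec50 = 1e-6, hill = 2, k_on = k,
                          k_off = k)
    r <- simulate_frequency_series(prot, p, dt = 0.25)
    pcs <- percent_change(r)
    expect_equal(t50(pcs, prot, "interp")$estimate, log(2) / k,
                 tolerance = 0.26 / (log(2) / k))
    expect_equal(t50(pcs, prot, "fit")$estimate, log(2) / k,
                 tolerance = 0.26 / (log(2) / k))
    expect_equal(rt50(pcs, prot, "interp")$estimate, log(2) / k,
                 tolerance = 0.26 / (log(2) / k))
    expect_equal(rt50(pcs, prot, "fit")$estimate, log(2) / k,
                 tolerance = 0.26 / (log(2) / k))
  }
})
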