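test_that("concentration trajectories follow the step + bolus-decay model", {
  params <- pd_params(pulse_decay = 0.3)
  # control: identically zero (no compound columns at all)
  ctrl <- concentration_trajectory(protocol_control(), params)
  expect_identical(names(ctrl), "time")

  # variant A: step inside the window, zero outside
  va <- protocol_variant_a("ver", 3e-5)
  tr <- concentration_trajectory(va, params, dt = 0.1)
  inside <- tr$time >= 4 & tr$time < 13.5
  expect_true(all(tr$ver[inside] == 3e-5))
  expect_true(all(tr$ver[!inside] == 0))

  # pulse amplitude halves every ln(2)/pulse_decay minutes
  vb <- protocol_variant_b("ver", 0, pulse_compound = "sol",
                           pulse_concentration = 1e-5,
                           bolus_volume_fraction = 0.1, t_pulse = 8)
  tr <- concentration_trajectory(vb, params, dt = 0.25)
  amp0 <- tr$sol[tr$time == 8]
  expect_equal(amp0, 1e-6)
  half_life <- log(2) / params$pulse_decay
  at_half <- approx(tr$time, tr$sol, xout = 8 + half_life)$y
  expect_equal(at_half, amp0 / 2, tolerance = 1e-3)
  expect_true(all(tr$sol >= 0))
})

test_that("equilibrium effect obeys the Hill relation and its limits", {
  p <- pd_params(e_max = -80, ec50 = 1e-6, hill = 1.7)
  expect_equal(equilibrium_effect(0, p), 0)
  expect_equal(equilibrium_effect(1e-6, p), -40)   # C = EC50 -> E_max / 2
  expect_equal(equilibrium_effect(1e3, p), -80, tolerance = 1e-6)
  expect_error(equilibrium_effect(-1, p), "negative")

  # monotone non-increasing in concentration for an inhibitor
  cc <- 10^seq(-9, -3, length.out = 50)
  ee <- equilibrium_effect(matrix(cc, ncol = 1), p)
  expect_true(all(diff(ee) <= 1e-12))
})

test_that("two-compound equilibrium combination rules are exact", {
  mk <- function(mode, lambda = 1)
    pd_params(e_max = c(-50, -30), ec50 = 1e-6, hill = 1,
              interaction_mode = mode, lambda = lambda)
  C <- matrix(c(1e-3, 1e-3), nrow = 1)   # saturating: e1 ~ -50, e2 ~ -30
  expect_equal(equilibrium_effect(C, mk("additive")), -80, tolerance = 1e-3)
  expect_equal(equilibrium_effect(C, mk("independent")),
               100 * ((1 - 0.5) * (1 - 0.3) - 1), tolerance = 1e-3)
  expect_equal(equilibrium_effect(C, mk("antagonistic", 0.65)),
               0.65 * -80, tolerance = 1e-3)
  # additive floor at -100
  deep <- pd_params(e_max = c(-90, -90), ec50 = 1e-6, hill = 1,
                    interaction_mode = "additive")
  expect_equal(equilibrium_effect(C, deep), -100, tolerance = 1e-3)
})

test_that("noiseless saline simulation is constant at f0", {
  r <- simulate_frequency_series(protocol_control(), noiseless_params(),
                                 seed = 1)
  expect_equal(r$frequencies, rep(48, 22))
  expect_identical(r$meta$variant, "control")
})

test_that("saturating dose with e_max = -100 arrests the heart, reversibly", {
  p <- noiseless_params(e_max = -100, ec50 = 1.685e-5, hill = 2, k_on = 5,
                        k_off = 0.5)
  r <- simulate_frequency_series(protocol_variant_a("ver", 5e-3), p, dt = 0.5)
  in_window <- r$times > 6 & r$times < 13
  expect_lt(max(r$frequencies[in_window]), 0.5)   # effective arrest
  # recovery: final-minute frequency back within 3% of baseline
  expect_lt(abs(tail(r$frequencies, 1) - 48) / 48, 0.03)
})

test_that("simulated onset t50 equals ln(2)/k within one bin", {
  k <- 0.667
  prot <- protocol_variant_a("x", 1e-3)
  p <- noiseless_params(e_max = -80, ec50 = 1e-6, hill = 2, k_on = k,
                        k_off = k)
  r <- simulate_frequency_series(prot, p, dt = 0.25)
  est <- t50(percent_change(r), prot, method = "fit")$estimate
  expect_equal(est, log(2) / k, tolerance = 0.25 / (log(2) / k))
})

test_that("frequency series simulation is seed-deterministic", {
  p <- pd_params()
  prot <- protocol_variant_a("ver", 3e-5)
  a <- simulate_frequency_series(prot, p, seed = 11)
  b <- simulate_frequency_series(prot, p, seed = 11)
  cc <- simulate_frequency_series(prot, p, seed = 12)
  expect_identical(a$frequencies, b$frequencies)
  expect_false(identical(a$frequencies, cc$frequencies))
})

test_that("trace simulation: beat counts scale with rate and are seed-stable", {
  p60 <- noiseless_params(f0 = 60)
  tr <- simulate_trace(protocol_control(1), p60, seed = 1)
  expect_length(tr$ground_truth_beats, 60)
  expect_equal(diff(tr$ground_truth_beats), rep(1, 59), tolerance = 1e-9)

  p120 <- noiseless_params(f0 = 120)
  tr2 <- simulate_trace(protocol_control(1), p120, seed = 1)
  expect_lte(abs(length(tr2$ground_truth_beats) -
                 2 * length(tr$ground_truth_beats)), 1)

  n1 <- simulate_trace(protocol_control(1), p60, seed = 5, noise_sd = 0.1)
  n2 <- simulate_trace(protocol_control(1), p60, seed = 5, noise_sd = 0.1)
  expect_identical(n1$values, n2$values)

  expect_error(simulate_trace(protocol_control(1), p60, pulse_width = 1.5),
               "fuse")
  expect_error(simulate_trace(protocol_control(1), p60, sample_rate = 10),
               "sample_rate")
})

test_that("conservation: binned ground-truth beats match the effect profile", {
  p <- noiseless_params(f0 = 60, e_max = -50, ec50 = 1e-6, hill = 2,
                        k_on = 2, k_off = 2)
  prot <- protocol_variant_a("x", 1e-3, window = c(2, 6), duration = 10)
  tr <- simulate_trace(prot, p, seed = 1)
  rec_beats <- frequency_from_beats(tr$ground_truth_beats, bin = 1,
                                    span = c(0, 10))
  rec_series <- simulate_frequency_series(prot, p, dt = 1)
  expect_true(all(abs(rec_beats$frequencies - rec_series$frequencies) <= 1))
})

test_that("control reversibility: effect returns to zero after exposure", {
  p <- noiseless_params(e_max = -60, ec50 = 1e-6, hill = 2, k_off = 0.5)
  r <- simulate_frequency_series(protocol_variant_a("x", 1e-3), p)
  eff <- attr(r, "true_effect")
  expect_lt(abs(tail(eff$effect, 1)), 2)
})
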