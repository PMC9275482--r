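test_that("recordings round-trip through tidy CSV at full precision", {
  tt <- c(0.5, 1, 1.5, 2.25, 3, 4.5)
  ff <- c(50.123456789, 49.5, 48.875, 47 + 1 / 3, 50, 51.25)
  rec <- recording(tt, ff, preparation_id = "p7",
                   compound_ids = c("verapamil", "solanine"),
                   concentrations = c(3e-5, 1e-5), variant = "A_continuous")
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, f)
  back <- read_recording(f)[[1]]
  expect_equal(back$times, tt)
  expect_equal(back$frequencies, ff)
  expect_identical(back$meta$preparation_id, "p7")
  expect_identical(back$meta$compound_ids, c("verapamil", "solanine"))
  expect_equal(back$meta$concentrations, c(3e-5, 1e-5))
  expect_identical(back$meta$variant, "A_continuous")
})

test_that("read_recording parses minimal tidy and wide layouts", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("time_min,freq\n0,50\n1,50", f)
  recs <- read_recording(f)
  expect_length(recs, 1)
  expect_equal(recs[[1]]$frequencies, c(50, 50))

  w <- withr::local_tempfile(fileext = ".csv")
  hdr <- paste(c("time_min", sprintf("prep%02d", 1:15)), collapse = ",")
  rows <- sapply(0:3, function(t) paste(c(t, rep(50, 15)), collapse = ","))
  writeLines(c(hdr, rows), w)
  recs <- read_recording(w, format = "wide")
  expect_length(recs, 15)
  expect_named(recs, sprintf("prep%02d", 1:15))
  expect_equal(recs[["prep09"]]$times, 0:3)
})

test_that("read_recording converts Hz and rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("time_min,freq_hz\n0,1\n1,0.5", f)
  expect_equal(read_recording(f)[[1]]$frequencies, c(60, 30))

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines("time_min,freq\n0,50\n1,50\n1,49", dup)
  expect_error(read_recording(dup), "duplicate time point t=1")

  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines("time_min,freq\n0,50\n1,-2", neg)
  expect_error(read_recording(neg), "negative frequency")
})

test_that("recording constructor enforces its invariants", {
  expect_error(recording(numeric(0), numeric(0)), "at least 1 point")
  expect_error(recording(c(0, 1), c(50, 50, 50)), "differ in length")
  expect_error(recording(c(0, 1, 1), c(50, 50, 50)), "strictly increasing")
  expect_error(recording(c(0, 1), c(50, -1)), "negative frequency")
})

test_that("protocol files round-trip and defaults match the assay design", {
  ctrl <- protocol_control()
  expect_equal(nrow(ctrl$segments), 1)
  expect_equal(ctrl$total_duration, 22)
  expect_null(exposure_window(ctrl))

  va <- protocol_variant_a("verapamil", 3e-5)
  expect_equal(nrow(va$segments), 3)
  expect_equal(unname(exposure_window(va)), c(4, 13.5))

  vb <- protocol_variant_b("verapamil", 3e-5, pulse_compound = "solanine",
                           pulse_concentration = 1e-5)
  expect_equal(nrow(vb$pulses), 1)
  expect_equal(vb$pulses$t_apply, 8)

  f <- withr::local_tempfile(fileext = ".txt")
  write_protocol(vb, f)
  back <- read_protocol(f)
  expect_equal(back$segments, vb$segments)
  expect_equal(back$pulses, vb$pulses)
  expect_equal(back$total_duration, vb$total_duration)
})

test_that("protocol validation rejects malformed timelines with located errors", {
  seg <- function(...) data.frame(..., stringsAsFactors = FALSE)
  # gap between segments
  expect_error(protocol_spec(seg(t_start = c(0, 5), t_end = c(4, 22),
                                 solution_id = c("saline", "x"),
                                 concentration = c(0, 1e-5))),
               "gap between segment 1")
  # overlap
  expect_error(protocol_spec(seg(t_start = c(0, 3), t_end = c(4, 22),
                                 solution_id = c("saline", "x"),
                                 concentration = c(0, 1e-5))),
               "overlap")
  # does not start at zero
  expect_error(protocol_spec(seg(t_start = 1, t_end = 22,
                                 solution_id = "saline", concentration = 0)),
               "start at time 0")
  # pulse outside duration
  expect_error(protocol_spec(seg(t_start = 0, t_end = 22,
                                 solution_id = "saline", concentration = 0),
                             pulses = data.frame(t_apply = 30,
                                                 solution_id = "sol",
                                                 concentration = 1e-5,
                                                 bolus_volume_fraction = 0.1)),
               "outside")
  # negative concentration
  expect_error(protocol_spec(seg(t_start = 0, t_end = 22,
                                 solution_id = "x", concentration = -1)),
               "negative")
})

test_that("write_report writes deterministic tables and refuses empty input", {
  expect_error(write_report(data.frame(), tempfile()), "empty results")
  missing_path <- withr::local_tempfile()
  expect_error(write_report(NULL, missing_path), "empty results")
  expect_false(file.exists(missing_path))

  proto <- protocol_variant_a("verapamil", 3e-5)
  rec <- plateau_recording(-77.9, protocol = proto, preparation_id = "ver")
  row <- summarise_recording(rec, proto)
  expect_equal(nrow(row), 1)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_report(row, f1)
  write_report(row, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(file.exists(paste0(f1, ".txt")))
})
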