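test_that("template has the requested length, apex amplitude and ordered landmarks", {
  tpl <- generate_template(180, 1000)
  expect_length(tpl$values, 180)
  expect_equal(max(tpl$values), 1000)
  expect_equal(which.max(tpl$values),
               tpl$landmarks$center[tpl$landmarks$wave == "R"])
  # exactly one global maximum
  expect_equal(sum(tpl$values == max(tpl$values)), 1)
  # P < Q < R < S < T strictly increasing
  expect_true(all(diff(tpl$landmarks$center) > 0))
  # scales to other resolutions
  tpl90 <- generate_template(90, 500)
  expect_length(tpl90$values, 90)
  expect_equal(max(tpl90$values), 500)
})

test_that("degenerate template parameters are rejected", {
  expect_error(generate_template(180, 0), "positive")
  expect_error(generate_template(180, -5), "positive")
  expect_error(generate_template(10, 1000), ">= 30")
})

test_that("all-zero non-R amplitudes give an isolated R bump with absent landmarks", {
  morph <- default_morphology()
  morph$amplitude[morph$wave != "R"] <- 0
  tpl <- generate_template(180, 1000, morph)
  expect_false(any(tpl$landmarks$present[tpl$landmarks$wave %in% c("P", "Q", "S", "T")]))
  expect_true(tpl$landmarks$present[tpl$landmarks$wave == "R"])
  # away from the R bump the signal is essentially zero
  r_c <- tpl$landmarks$center[tpl$landmarks$wave == "R"]
  far <- abs(seq_len(180) - r_c) > 20
  expect_lt(max(abs(tpl$values[far])), 1e-6 * 1000)
})

test_that("clean recording concatenates cycles with known R-apex positions", {
  tpl <- default_tpl()
  rec <- generate_clean_recording(tpl, n_cycles = 4)
  expect_length(rec$signal, 720)
  r_c <- tpl$landmarks$center[tpl$landmarks$wave == "R"]
  expect_equal(rec$r_indices, r_c + c(0L, 180L, 360L, 540L))
  # single cycle is the template verbatim
  one <- generate_clean_recording(tpl, n_cycles = 1)
  expect_identical(one$signal, tpl$values)
  expect_error(generate_clean_recording(tpl, n_cycles = 0), ">= 1")
})

test_that("rr jitter perturbs cycle lengths around the nominal value", {
  tpl <- default_tpl()
  rec <- generate_clean_recording(tpl, n_cycles = 60, rr_jitter = 0.05,
                                  seed = 7)
  # mean cycle length within 1% of nominal (law of large numbers)
  expect_lt(abs(mean(rec$cycle_lengths) - 180) / 180, 0.01)
  expect_gt(sd(rec$cycle_lengths), 0)
  expect_true(all(abs(rec$cycle_lengths - 180) <= ceiling(180 * 0.05)))
  # jitter requires a seed
  expect_error(generate_clean_recording(tpl, 5, rr_jitter = 0.05), "seed")
})

test_that("multichannel rendering is exact in the noiseless case", {
  tpl <- default_tpl()
  clean <- generate_clean_recording(tpl, n_cycles = 4)
  specs <- replicate(8, channel_spec(), simplify = FALSE)
  mc <- make_multichannel(clean, specs)
  expect_equal(dim(mc$data), c(8L, 720L))
  for (i in 1:8) expect_equal(unname(mc$data[i, ]), clean$signal)
})

test_that("phase offsets delay channels by whole samples with edge replication", {
  x <- as.numeric(1:10)
  specs <- list(channel_spec(), channel_spec(phase_offset = 2),
                channel_spec(phase_offset = -3))
  mc <- make_multichannel(x, specs)
  expect_equal(unname(mc$data[1, ]), x)
  expect_equal(unname(mc$data[2, ]), c(1, 1, 1:8))
  expect_equal(unname(mc$data[3, ]), c(4:10, 10, 10, 10))
  # offset as large as the signal is rejected
  expect_error(make_multichannel(x, list(channel_spec(phase_offset = 10))),
               "phase_offset")
  # adjacent one-sample offsets correspond to 2 degrees at 180 samples/cycle
  expect_equal(degrees_per_sample(180) * 1, 2)
})

test_that("gain scaling multiplies the clean signal", {
  x <- sin(seq(0, 2 * pi, length.out = 100))
  mc <- make_multichannel(x, list(channel_spec(gain_scale = 2.5)))
  expect_equal(unname(mc$data[1, ]), 2.5 * x)
})

test_that("noise is reproducible under a seed and independent across channels", {
  x <- numeric(10000)
  specs <- replicate(2, channel_spec(noise_sigma = 10), simplify = FALSE)
  a <- make_multichannel(x, specs, seed = 99)
  b <- make_multichannel(x, specs, seed = 99)
  expect_identical(a$data, b$data)
  # residuals of the two channels are uncorrelated
  expect_lt(abs(cor(a$data[1, ], a$data[2, ])), 0.1)
  # missing seed with noise present is an error
  expect_error(make_multichannel(x, specs), "seed")
})

test_that("sample noise sd converges to the specified sigma", {
  n <- 50000
  sigma <- 7
  mc <- make_multichannel(numeric(n), list(channel_spec(noise_sigma = sigma)),
                          seed = 5)
  expect_lt(abs(sd(mc$data[1, ]) - sigma), 3 * sigma / sqrt(2 * n))
})

test_that("degrees_per_sample follows the closed form and rejects bad input", {
  expect_equal(degrees_per_sample(180), 2)
  expect_equal(degrees_per_sample(360), 1)
  expect_equal(degrees_per_sample(90), 4)
  expect_error(degrees_per_sample(0), ">= 1")
})

test_that("location presets return the published amplitude scale", {
  expect_equal(location_amplitude("chest"), 1000)
  expect_true(location_amplitude("mastoid") >= 30 &&
              location_amplitude("mastoid") <= 50)
  expect_true(location_amplitude("upper_arm") >= 50 &&
              location_amplitude("upper_arm") <= 70)
})
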