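test_that("peak-to-peak SNR matches a constructed piecewise signal", {
  # 250 Hz: QRS window = r +/- 15 samples, noise window = mid +/- 5 samples
  fs <- 250
  x <- numeric(400)
  x[100] <- 60; x[105] <- -40        # QRS Vpp = 100 inside the 120 ms window
  x[200] <- 8; x[205] <- -2          # noise Vpp = 10 inside the 40 ms window
  rep1 <- ecg_snr(x, fs, r_index = 100, t_end_index = 150, next_p_index = 255)
  expect_equal(rep1$qrs_vpp, 100)
  expect_equal(rep1$noise_vpp, 10)
  expect_equal(rep1$snr_db, 20)
  # windows have the prescribed spans
  expect_equal(diff(rep1$qrs_window), 2 * round(0.5 * 0.120 * fs))
  expect_equal(diff(rep1$noise_window), 2 * round(0.5 * 0.040 * fs))
})

test_that("SNR window extrema agree with an exhaustive scan oracle", {
  set.seed(12)
  fs <- 250
  x <- rnorm(600)
  r <- 300; t_end <- 360; p_next <- 460
  rep1 <- ecg_snr(x, fs, r, t_end, p_next)
  # brute force: scan every sample of each window
  hq <- round(0.5 * 0.120 * fs); hn <- round(0.5 * 0.040 * fs)
  qrs <- x[(r - hq):(r + hq)]
  mid <- round((t_end + p_next) / 2)
  noi <- x[(mid - hn):(mid + hn)]
  expect_equal(rep1$qrs_vpp, max(qrs) - min(qrs))
  expect_equal(rep1$noise_vpp, max(noi) - min(noi))
  expect_equal(rep1$snr_db, 20 * log10(rep1$qrs_vpp / rep1$noise_vpp))
})

test_that("a flat noise window yields an infinite-SNR flag, not an error", {
  tpl <- default_tpl()
  rec <- generate_clean_recording(tpl, n_cycles = 2)
  s <- snr_over_recording(rec$signal, 250, rec$r_indices, tpl)
  expect_true(is.infinite(s$median_snr_db))
  expect_true(s$reports[[1]]$infinite)
})

test_that("SNR is invariant to rescaling the signal", {
  mc <- noisy_recording(n_cycles = 6, snr_db = 12, seed = 21)
  tpl <- default_tpl()
  x <- mc$data[1, ]
  r_idx <- mc$clean$r_indices
  s1 <- snr_over_recording(x, 250, r_idx, tpl)$median_snr_db
  s2 <- snr_over_recording(13.5 * x, 250, r_idx, tpl)$median_snr_db
  expect_equal(s1, s2)
  # out-of-range windows error
  expect_error(ecg_snr(x[1:100], 250, 95, 98, 99), "outside")
  expect_error(ecg_snr(x, 250, 100, 200, 150), "smaller")
})

test_that("R peaks are recovered exactly on a noiseless recording", {
  tpl <- default_tpl()
  rec <- generate_clean_recording(tpl, n_cycles = 10)
  ann <- detect_r_peaks(rec$signal, 250)
  expect_identical(ann$r_indices, as.integer(rec$r_indices))
})

test_that("R peaks on a noisy recording stay within 20 ms of truth with no extras", {
  mc <- noisy_recording(n_cycles = 20, snr_db = 15, seed = 33)
  truth <- mc$clean$r_indices
  ann <- detect_r_peaks(mc$data[1, ], 250)
  expect_equal(length(ann$r_indices), length(truth))
  expect_true(all(abs(ann$r_indices - truth) <= 0.020 * 250))
  # refractory invariant
  expect_true(all(diff(ann$r_indices) >= 0.25 * 250))
})

test_that("degenerate detector inputs behave as documented", {
  expect_warning(ann <- detect_r_peaks(numeric(1000), 250), "no beats")
  expect_length(ann$r_indices, 0)
  expect_error(detect_r_peaks(numeric(100), 250), "2 s")
  expect_error(detect_r_peaks(numeric(1000), 50), ">= 100")
})

test_that("heart-rate series converts RR intervals to bpm", {
  ann <- structure(list(r_indices = as.integer(seq(1, by = 180, length.out = 5)),
                        fs = 250), class = "beat_annotations")
  expect_equal(heart_rate_series(ann), rep(60 * 250 / 180, 4))  # 83.33 bpm
  ann2 <- structure(list(r_indices = as.integer(seq(1, by = 250, length.out = 4)),
                         fs = 250), class = "beat_annotations")
  expect_equal(heart_rate_series(ann2), rep(60, 3))
  bad <- structure(list(r_indices = c(10L, 5L, 20L), fs = 250),
                   class = "beat_annotations")
  expect_error(heart_rate_series(bad), "increasing")
  one <- structure(list(r_indices = 10L, fs = 250), class = "beat_annotations")
  expect_error(heart_rate_series(one), "2 beats")
})

test_that("identical annotations correlate perfectly; disjoint ones error", {
  ann <- structure(list(r_indices = as.integer(cumsum(c(100, 180, 190, 170, 185, 175))),
                        fs = 250), class = "beat_annotations")
  hc <- hr_correlation(ann, ann)
  expect_equal(hc$r, 1)
  expect_equal(hc$n_pairs, length(ann$r_indices))
  far <- structure(list(r_indices = ann$r_indices + 100000L, fs = 250),
                   class = "beat_annotations")
  expect_error(hr_correlation(ann, far), "matched")
})

test_that("two noisy views of one RR process correlate above 0.99", {
  ex <- hr_correlation_experiment(n_beats = 60, rr_jitter = 0.05, seed = 77)
  expect_gte(ex$r, 0.99)
  expect_gte(ex$n_pairs, 55)
})

test_that("CMRR follows its defining gain ratio", {
  expect_equal(cmrr_db(100, 926.5, 1000, 0.086), 100.6, tolerance = 0.1 / 100.6)
  expect_equal(cmrr_db(1, 5, 1, 5), 0)
  expect_equal(cmrr_db(1, 10, 1, 0.01), 60)
  # invariant to common rescaling of the input pair
  expect_equal(cmrr_db(2 * 100, 2 * 926.5, 2 * 1000, 2 * 0.086),
               cmrr_db(100, 926.5, 1000, 0.086))
  expect_error(cmrr_db(0, 1, 1, 1), "positive")
})

test_that("input-referred noise divides the shorted-input Vpp by the gain", {
  const <- matrix(5, nrow = 3, ncol = 100)
  expect_equal(unname(input_referred_noise_vpp(const, 12)), c(0, 0, 0))
  set.seed(8)
  m <- matrix(rnorm(2 * 1000), nrow = 2)
  v1 <- input_referred_noise_vpp(m, 1)
  v2 <- input_referred_noise_vpp(m, 2)
  expect_equal(v1 / 2, v2)
  expect_error(input_referred_noise_vpp(matrix(numeric(0), 0, 0)), "empty")
})

test_that("Vpp calibration reproduces a 1.4 uV 10 s target within 25%", {
  n <- 2500
  sigma <- sigma_for_target_vpp(1.4, n, seed = 10)
  set.seed(11)
  vpps <- replicate(100, {
    x <- rnorm(n, 0, sigma)
    max(x) - min(x)
  })
  expect_lt(abs(mean(vpps) - 1.4) / 1.4, 0.25)
})

test_that("frequency sweep recovers the -3 dB corners of a known band-pass", {
  fl <- 0.15; fh <- 70
  H <- function(f) {
    (f / fl) / sqrt(1 + (f / fl)^2) / sqrt(1 + (f / fh)^2)
  }
  f <- 10^seq(log10(0.01), log10(500), length.out = 120)
  sweep <- list(f = f, vin_vpp = rep(100, length(f)), vout_vpp = 100 * H(f))
  fr <- frequency_response(sweep)
  # analytic -3 dB points located by root finding on the same response
  gmax <- max(20 * log10(H(f)))
  lo <- uniroot(function(x) 20 * log10(H(x)) - (gmax - 3), c(0.01, 1))$root
  hi <- uniroot(function(x) 20 * log10(H(x)) - (gmax - 3), c(10, 500))$root
  expect_lt(abs(fr$f_low_3db - lo) / lo, 0.05)
  expect_lt(abs(fr$f_high_3db - hi) / hi, 0.05)
  expect_false(fr$open_low || fr$open_high)
})

test_that("flat and unity sweeps flag open bands and zero gain", {
  f <- c(1, 2, 5, 10, 20)
  flat <- list(f = f, vin_vpp = rep(2, 5), vout_vpp = rep(4, 5))
  fr <- frequency_response(flat)
  expect_true(fr$open_low && fr$open_high)
  expect_equal(fr$gain_db, 20 * log10(2))
  unity <- list(f = f, vin_vpp = rep(3, 5), vout_vpp = rep(3, 5))
  expect_equal(frequency_response(unity)$gain_db, 0)
  expect_error(frequency_response(list(f = 1:3, vin_vpp = rep(1, 3),
                                       vout_vpp = rep(1, 3))), "5")
})
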