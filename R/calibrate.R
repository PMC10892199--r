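#' Expected peak-to-peak range of Gaussian noise
#'
#' Monte-Carlo estimate of `E[max - min]` of `n` iid standard normal samples.
#' Used to calibrate noise standard deviations against peak-to-peak targets
#' (the Vpp of Gaussian noise grows with the window length, roughly as
#' `2 * sqrt(2 * log(n))` for large `n`).
#'
#' @param n Window length in samples.
#' @param n_draws Number of Monte-Carlo replicates (default 400).
#' @param seed RNG seed.
#' @return Expected range in units of sigma.
#' @export
#' @examples
#' gaussian_vpp_factor(10, seed = 1)   # about 3.1
gaussian_vpp_factor <- function(n, n_draws = 400, seed) {
  if (!is.numeric(n) || n < 2) stop_invalid("`n` must be >= 2")
  with_preserved_seed(seed, {
    mean(vapply(seq_len(n_draws), function(i) {
      x <- rnorm(n)
      max(x) - min(x)
    }, numeric(1)))
  })
}

#' Calibrate channel noise to a target single-channel SNR
#'
#' Chooses the Gaussian noise standard deviation so that a single channel of
#' `template + N(0, sigma^2)` has a peak-to-peak SNR of about
#' `target_snr_db`: with QRS Vpp fixed by the clean template, the expected
#' noise-window Vpp is `sigma * gaussian_vpp_factor(window)`, so
#' `sigma = QRS_vpp / 10^(SNR/20) / factor`. The 40 ms noise window at `fs`
#' determines the extreme-value factor.
#'
#' @param template An [`ecg_template`][generate_template].
#' @param target_snr_db Desired single-channel SNR in dB.
#' @param fs Sampling rate in Hz.
#' @param seed RNG seed for the Monte-Carlo range factor.
#' @return Noise standard deviation in uV.
#' @export
sigma_for_target_snr <- function(template, target_snr_db, fs = 250, seed = 1L) {
  stopifnot(inherits(template, "ecg_template"))
  r_c <- template$landmarks$center[template$landmarks$wave == "R"]
  hq <- round(0.5 * 0.120 * fs)
  lo <- max(1L, r_c - hq)
  hi <- min(template$samples_per_cycle, r_c + hq)
  qrs_vpp <- max(template$values[lo:hi]) - min(template$values[lo:hi])
  n_noise <- 2L * round(0.5 * 0.040 * fs) + 1L
  factor <- gaussian_vpp_factor(n_noise, seed = seed)
  qrs_vpp / 10^(target_snr_db / 20) / factor
}

#' Calibrate channel noise to a target peak-to-peak amplitude
#'
#' Chooses sigma so that the expected Vpp of `n_samples` iid Gaussian noise
#' samples equals `target_vpp`:
#' `sigma = target_vpp / gaussian_vpp_factor(n_samples)`. Used to reproduce
#' bench-style shorted-input noise measurements where only the observed Vpp
#' over a fixed window (e.g. 10 s at 250 Hz) is known.
#'
#' @param target_vpp Target peak-to-peak amplitude (uV).
#' @param n_samples Window length in samples.
#' @param seed RNG seed for the Monte-Carlo range factor.
#' @param factor Optional precomputed [gaussian_vpp_factor()] (saves
#'   recomputation when calibrating several channels over one window).
#' @return Noise standard deviation in uV.
#' @export
sigma_for_target_vpp <- function(target_vpp, n_samples, seed = 1L,
                                 factor = NULL) {
  if (!is.numeric(target_vpp) || target_vpp <= 0) {
    stop_invalid("`target_vpp` must be > 0")
  }
  if (is.null(factor)) factor <- gaussian_vpp_factor(n_samples, seed = seed)
  target_vpp / factor
}
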