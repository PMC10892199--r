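#' Peak-to-peak SNR of one ECG beat
#'
#' SNR in the peak-to-peak sense used for weak-ECG visibility:
#' `20 * log10(QRS_vpp / noise_vpp)`, where `QRS_vpp` is max - min of the
#' signal in a 120 ms window centered on the R apex and `noise_vpp` is
#' max - min in a 40 ms window placed on the isoelectric T-P segment,
#' centered midway between the end of the T wave and the onset of the next
#' beat's P wave. The noise window sits on the T-P segment (rather than
#' inside the R-T interval) so that the T wave itself is never counted as
#' noise.
#'
#' @param signal Numeric uV sequence.
#' @param fs Sampling rate in Hz.
#' @param r_index R-apex sample index (1-based).
#' @param t_end_index Sample index of the end of this beat's T wave.
#' @param next_p_index Sample index of the next beat's P-wave onset
#'   (must exceed `t_end_index`).
#' @return An object of class `snr_report`: list with `snr_db` (Inf when the
#'   noise window is flat, flagged via `infinite`), `qrs_vpp`, `noise_vpp`
#'   (uV), and the `qrs_window` / `noise_window` index pairs.
#' @export
#' @examples
#' tpl <- generate_template(180, 1000)
#' rec <- generate_clean_recording(tpl, n_cycles = 2)
#' r <- rec$r_indices[1]
#' ecg_snr(rec$signal, 250, r, r + 65, rec$r_indices[2] - 40)$snr_db  # Inf
ecg_snr <- function(signal, fs, r_index, t_end_index, next_p_index) {
  signal <- as.numeric(signal)
  n <- length(signal)
  if (!is.numeric(fs) || fs <= 0) stop_invalid("`fs` must be positive")
  if (t_end_index >= next_p_index) {
    stop_invalid("`t_end_index` must be smaller than `next_p_index`")
  }
  hq <- round(0.5 * 0.120 * fs)             # half of the 120 ms QRS span
  hn <- round(0.5 * 0.040 * fs)             # half of the 40 ms noise span
  qrs_window <- c(r_index - hq, r_index + hq)
  mid <- round((t_end_index + next_p_index) / 2)
  noise_window <- c(mid - hn, mid + hn)
  if (qrs_window[1] < 1 || qrs_window[2] > n ||
      noise_window[1] < 1 || noise_window[2] > n) {
    stop_invalid("SNR windows fall outside the signal")
  }
  qrs_seg <- signal[qrs_window[1]:qrs_window[2]]
  noise_seg <- signal[noise_window[1]:noise_window[2]]
  qrs_vpp <- max(qrs_seg) - min(qrs_seg)
  noise_vpp <- max(noise_seg) - min(noise_seg)
  infinite <- noise_vpp == 0
  structure(
    list(
      snr_db = if (infinite) Inf else 20 * log10(qrs_vpp / noise_vpp),
      qrs_vpp = qrs_vpp, noise_vpp = noise_vpp,
      qrs_window = qrs_window, noise_window = noise_window,
      infinite = infinite
    ),
    class = "snr_report"
  )
}

#' @export
print.snr_report <- function(x, ...) {
  cat("<snr_report> SNR ", format(x$snr_db, digits = 4), " dB (QRS Vpp ",
      format(x$qrs_vpp, digits = 4), " uV / noise Vpp ",
      format(x$noise_vpp, digits = 4), " uV)\n", sep = "")
  invisible(x)
}

# Per-beat window offsets (T end, next-P onset) derived from the template
# landmarks, scaled to the local RR interval when beats are jittered.
beat_window_offsets <- function(template) {
  lm <- template$landmarks
  r_c <- lm$center[lm$wave == "R"]
  t_end <- lm$center[lm$wave == "T"] + lm$half_width[lm$wave == "T"]
  p_on <- lm$center[lm$wave == "P"] - lm$half_width[lm$wave == "P"]
  list(t_end_after_r = t_end - r_c, r_minus_p_onset = r_c - p_on)
}

#' Median per-beat SNR over a multi-beat recording
#'
#' Computes [ecg_snr()] for every beat that has a complete following T-P
#' segment (beats 1..n-1 of n) and reports the median, which is robust to a
#' single corrupted beat. T-end and P-onset positions are derived from the
#' template landmarks, scaled to each local RR interval.
#'
#' @param signal Numeric uV sequence.
#' @param fs Sampling rate in Hz.
#' @param r_indices True or detected R apex indices (>= 2).
#' @param template The [`ecg_template`][generate_template] describing the
#'   morphology (provides T-end / P-onset offsets).
#' @return List with `median_snr_db`, `per_beat` (vector of per-beat dB) and
#'   `reports` (list of `snr_report`).
#' @export
snr_over_recording <- function(signal, fs, r_indices, template) {
  if (length(r_indices) < 2) stop_invalid("need at least 2 beats")
  off <- beat_window_offsets(template)
  spc <- template$samples_per_cycle
  reports <- list()
  for (i in seq_len(length(r_indices) - 1)) {
    rr <- r_indices[i + 1] - r_indices[i]
    t_end <- r_indices[i] + round(off$t_end_after_r * rr / spc)
    p_on <- r_indices[i + 1] - round(off$r_minus_p_onset * rr / spc)
    reports[[i]] <- ecg_snr(signal, fs, r_indices[i], t_end, p_on)
  }
  per_beat <- vapply(reports, `[[`, numeric(1), "snr_db")
  list(median_snr_db = median(per_beat), per_beat = per_beat,
       reports = reports)
}

#' Detect R peaks
#'
#' Pan-Tompkins-style detector: the signal is band-passed to the QRS band
#' (5-30 Hz, zero-phase), differentiated and squared, smoothed with a
#' centered 150 ms moving-average window, and local envelope maxima exceeding
#' an adaptive threshold (running signal/noise level estimates) are accepted
#' subject to a 250 ms refractory period. Each accepted envelope peak is then
#' refined to the R apex by searching a +/-60 ms neighbourhood of a lightly
#' low-pass-filtered (40 Hz, zero-phase) copy of the original signal.
#'
#' @param signal Numeric uV sequence, at least 2 s long.
#' @param fs Sampling rate in Hz (>= 100).
#' @return An object of class `beat_annotations`: list with `r_indices`
#'   (strictly increasing, consecutive gaps >= 250 ms) and `fs`. Empty (with
#'   a warning) when no beats are found.
#' @export
#' @examples
#' tpl <- generate_template(180, 1000)
#' rec <- generate_clean_recording(tpl, n_cycles = 10)
#' ann <- detect_r_peaks(rec$signal, 250)
#' all(ann$r_indices == rec$r_indices)  # TRUE (noiseless case)
detect_r_peaks <- function(signal, fs) {
  signal <- as.numeric(signal)
  if (!is.numeric(fs) || fs < 100) stop_invalid("`fs` must be >= 100 Hz")
  if (length(signal) < 2 * fs) stop_invalid("signal must be at least 2 s long")

  empty <- function() {
    warning("no beats found", call. = FALSE)
    structure(list(r_indices = integer(0), fs = fs),
              class = "beat_annotations")
  }
  if (all(signal == signal[1])) return(empty())

  nyq <- fs / 2
  bp <- signal::butter(2, c(5, 30) / nyq, type = "pass")
  x_bp <- zero_phase_filter(bp$b, bp$a, signal)
  d <- c(0, diff(x_bp))
  env <- moving_average_centered(d^2, as.integer(round(0.15 * fs)))
  if (max(env) <= 0) return(empty())

  refractory <- as.integer(round(0.25 * fs))
  n <- length(env)
  # candidate local maxima of the envelope
  cand <- which(diff(sign(diff(env))) < 0) + 1L
  cand <- cand[env[cand] > 0]
  if (length(cand) == 0) return(empty())

  init_span <- seq_len(min(n, as.integer(2.5 * fs)))
  spk <- max(env[init_span])
  npk <- median(env[init_span])
  accepted <- integer(0)
  last <- -Inf
  for (p in cand) {
    thr <- npk + 0.25 * (spk - npk)
    if (env[p] >= thr) {
      if (p - last >= refractory) {
        accepted <- c(accepted, p)
        last <- p
        spk <- 0.125 * env[p] + 0.875 * spk
      } else if (length(accepted) && env[p] > env[accepted[length(accepted)]]) {
        # within refractory: keep the larger envelope peak
        accepted[length(accepted)] <- p
        last <- p
        spk <- 0.125 * env[p] + 0.875 * spk
      }
    } else {
      npk <- 0.125 * env[p] + 0.875 * npk
    }
  }
  if (length(accepted) == 0) return(empty())

  # apex refinement on a low-pass-smoothed copy of the raw signal
  lp <- signal::butter(3, 40 / nyq, type = "low")
  x_lp <- zero_phase_filter(lp$b, lp$a, signal)
  h <- as.integer(round(0.06 * fs))
  r_idx <- vapply(accepted, function(p) {
    lo <- max(1L, p - h)
    hi <- min(length(signal), p + h)
    lo + which.max(x_lp[lo:hi]) - 1L
  }, integer(1))
  r_idx <- sort(unique(r_idx))
  # enforce the refractory period on the refined apices (keep the taller)
  if (length(r_idx) > 1) {
    keep <- r_idx[1]
    for (r in r_idx[-1]) {
      tail_r <- keep[length(keep)]
      if (r - tail_r >= refractory) {
        keep <- c(keep, r)
      } else if (x_lp[r] > x_lp[tail_r]) {
        keep[length(keep)] <- r
      }
    }
    r_idx <- keep
  }
  structure(list(r_indices = as.integer(r_idx), fs = fs),
            class = "beat_annotations")
}

#' @export
print.beat_annotations <- function(x, ...) {
  cat("<beat_annotations> ", length(x$r_indices), " beats @ ", x$fs,
      " Hz\n", sep = "")
  invisible(x)
}

#' Beat-wise instantaneous heart rate
#'
#' Converts RR intervals to beats per minute:
#' `bpm_i = 60 * fs / (r_(i+1) - r_i)`.
#'
#' @param ann A [`beat_annotations`][detect_r_peaks] object (>= 2 beats,
#'   strictly increasing indices).
#' @return Numeric vector of length `n_beats - 1`, in bpm.
#' @export
#' @examples
#' ann <- structure(list(r_indices = seq(1, 1801, by = 180), fs = 250),
#'                  class = "beat_annotations")
#' heart_rate_series(ann)  # constant 83.33 bpm
heart_rate_series <- function(ann) {
  stopifnot(inherits(ann, "beat_annotations"))
  r <- ann$r_indices
  if (length(r) < 2) stop_invalid("need at least 2 beats")
  if (any(diff(r) <= 0)) stop_invalid("R indices must be strictly increasing")
  60 * ann$fs / diff(r)
}

#' Correlation of two beat-wise heart-rate series
#'
#' Matches beats between two annotation sets greedily by nearest R time
#' within `match_tolerance_ms`, computes the heart-rate series over the
#' matched beats of each recording, and returns their Pearson correlation.
#' This mirrors comparing a wearable-array recording against a simultaneous
#' standard-lead reference beat by beat.
#'
#' @param ann_a,ann_b [`beat_annotations`][detect_r_peaks] objects with at
#'   least 3 beats each.
#' @param match_tolerance_ms Maximum |time difference| for a beat match
#'   (default 150 ms, below half the detector's refractory period).
#' @return List with `r` (Pearson correlation), `n_pairs`, `bpm_a`, `bpm_b`,
#'   and `unmatched` (counts dropped from each side).
#' @export
hr_correlation <- function(ann_a, ann_b, match_tolerance_ms = 150) {
  stopifnot(inherits(ann_a, "beat_annotations"),
            inherits(ann_b, "beat_annotations"))
  if (length(ann_a$r_indices) < 3 || length(ann_b$r_indices) < 3) {
    stop_invalid("both annotations need at least 3 beats")
  }
  ta <- ann_a$r_indices / ann_a$fs
  tb <- ann_b$r_indices / ann_b$fs
  tol <- match_tolerance_ms / 1000
  used_b <- rep(FALSE, length(tb))
  ia <- integer(0)
  ib <- integer(0)
  for (i in seq_along(ta)) {
    d <- abs(tb - ta[i])
    d[used_b] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= tol) {
      used_b[j] <- TRUE
      ia <- c(ia, i)
      ib <- c(ib, j)
    }
  }
  if (length(ia) < 3) stop_invalid("fewer than 3 matched beat pairs")
  ord <- order(ia)
  ia <- ia[ord]; ib <- ib[ord]
  bpm_a <- 60 / diff(ta[ia])
  bpm_b <- 60 / diff(tb[ib])
  list(
    r = cor(bpm_a, bpm_b),
    n_pairs = length(ia),
    bpm_a = bpm_a, bpm_b = bpm_b,
    unmatched = c(a = length(ta) - length(ia), b = length(tb) - length(ib))
  )
}

#' Common-mode rejection ratio in dB
#'
#' CMRR is the ratio of the differential-mode gain to the common-mode gain:
#' `20 * log10((diff_out/diff_in) / (cm_out/cm_in))`. A well-matched
#' instrumentation front end reaches 100 dB or more at 50 Hz.
#'
#' @param diff_in_vpp,diff_out_vpp Differential-mode input/output
#'   peak-to-peak amplitudes (same units, > 0).
#' @param cm_in_vpp,cm_out_vpp Common-mode input/output peak-to-peak
#'   amplitudes (> 0).
#' @return CMRR in dB (report to 0.1 dB when quoting bench measurements).
#' @export
#' @examples
#' cmrr_db(100, 926.5, 1000, 0.086)  # 100.6 dB
cmrr_db <- function(diff_in_vpp, diff_out_vpp, cm_in_vpp, cm_out_vpp) {
  vals <- c(diff_in_vpp, diff_out_vpp, cm_in_vpp, cm_out_vpp)
  if (!is.numeric(vals) || any(vals <= 0)) {
    stop_invalid("all four amplitudes must be positive")
  }
  20 * log10((diff_out_vpp / diff_in_vpp) / (cm_out_vpp / cm_in_vpp))
}

#' Input-referred noise from a shorted-input recording
#'
#' With the input terminals short-circuited to ground, the recorded output is
#' pure system noise; dividing its peak-to-peak excursion by the system gain
#' refers it to the input. Reported per channel in uV.
#'
#' @param shorted_recording An [`mc_recording`][make_multichannel] or K x N
#'   numeric matrix of output uV samples.
#' @param system_gain Dimensionless overall gain (> 0).
#' @return Numeric vector of per-channel input-referred Vpp in uV.
#' @export
input_referred_noise_vpp <- function(shorted_recording, system_gain = 1) {
  data <- if (inherits(shorted_recording, "mc_recording")) {
    shorted_recording$data
  } else {
    as.matrix(shorted_recording)
  }
  if (length(data) == 0) stop_invalid("recording is empty")
  if (!is.numeric(system_gain) || system_gain <= 0) {
    stop_invalid("`system_gain` must be > 0")
  }
  apply(data, 1, function(row) (max(row) - min(row)) / system_gain)
}

#' Plateau gain and -3 dB bandwidth from a frequency sweep
#'
#' Given sinusoidal sweep measurements (frequency, input Vpp, output Vpp),
#' returns the plateau gain (maximum of 20*log10(vout/vin)) and the lower and
#' upper -3 dB band edges, interpolated linearly in dB against log10
#' frequency. A side with no crossing is flagged open-ended.
#'
#' @param sweep Data frame (or list) with columns/elements `f` (Hz, strictly
#'   increasing, >= 5 points), `vin_vpp`, `vout_vpp` (same units).
#' @return List with `gain_db`, `f_low_3db`, `f_high_3db` (NA when open),
#'   `open_low`, `open_high`.
#' @export
frequency_response <- function(sweep) {
  f <- sweep$f
  vin <- sweep$vin_vpp
  vout <- sweep$vout_vpp
  if (length(f) < 5) stop_invalid("need at least 5 frequency points")
  if (any(diff(f) <= 0)) stop_invalid("frequencies must be strictly increasing")
  if (any(vin <= 0) || any(vout < 0)) stop_invalid("amplitudes must be positive")
  gain <- 20 * log10(vout / vin)
  imax <- which.max(gain)
  g0 <- gain[imax]
  target <- g0 - 3
  lf <- log10(f)

  cross <- function(idx_range, from_side) {
    # walk away from the plateau until gain drops through target
    for (k in idx_range) {
      g1 <- gain[k]; g2 <- gain[k + from_side]
      if ((g1 - target) * (g2 - target) <= 0 && g1 != g2) {
        w <- (target - g1) / (g2 - g1)
        return(10^(lf[k] + w * (lf[k + from_side] - lf[k])))
      }
    }
    NA_real_
  }
  f_low <- if (imax > 1) cross(seq(imax, 2), -1L) else NA_real_
  f_high <- if (imax < length(f)) cross(seq(imax, length(f) - 1), +1L) else NA_real_
  list(
    gain_db = g0,
    f_low_3db = f_low, f_high_3db = f_high,
    open_low = is.na(f_low), open_high = is.na(f_high)
  )
}
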