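#' Default ECG morphology parameters
#'
#' One cycle of surface ECG is modelled as a sum of five Gaussian bumps, one
#' per wave (P, Q, R, S, T). Centers and widths are expressed as fractions of
#' the cycle so that the same morphology can be rendered at any number of
#' samples per cycle; amplitudes are relative to the R peak. The defaults
#' follow canonical adult durations at a 720 ms cycle (180 samples at 250 Hz):
#' P wave about 80 ms, QRS complex about 90-100 ms, T wave about 160 ms, with
#' relative amplitudes P = 0.15, Q = -0.1, S = -0.2, T = 0.3.
#'
#' @return A data.frame with columns `wave`, `amplitude` (relative to R = 1),
#'   `center` (fraction of cycle) and `width` (Gaussian sigma, fraction of
#'   cycle).
#' @export
#' @examples
#' default_morphology()
default_morphology <- function() {
  data.frame(
    wave      = c("P", "Q", "R", "S", "T"),
    amplitude = c(0.15, -0.10, 1.00, -0.20, 0.30),
    center    = c(30, 53, 60, 67, 105) / 180,
    width     = c(5, 2, 1.5, 2, 10) / 180,
    stringsAsFactors = FALSE
  )
}

#' Generate a single-cycle ECG template
#'
#' Builds one clean cycle of ECG morphology as a sum of per-wave Gaussian
#' bumps, sampled at `samples_per_cycle` points, and rescaled so the R apex
#' equals `r_amplitude` exactly. The returned object records per-wave
#' landmarks (center index, half-width = 2 sigma in samples) used downstream
#' to place SNR measurement windows.
#'
#' @param samples_per_cycle Number of samples in one cycle (>= 30; default
#'   180, i.e. 720 ms at 250 Hz).
#' @param r_amplitude R-peak amplitude in microvolts (> 0). Typical surface
#'   values: 1000 uV on the chest, 30-50 uV at the mastoid, 50-70 uV on the
#'   upper arm (see [location_amplitude()]).
#' @param morphology Per-wave parameters as returned by
#'   [default_morphology()]; waves with `amplitude == 0` are marked absent in
#'   the landmarks.
#' @return An object of class `ecg_template`: a list with `samples_per_cycle`,
#'   `values` (length `samples_per_cycle`, uV) and `landmarks` (data.frame
#'   with `wave`, `center` 1-based sample index, `half_width` samples,
#'   `amplitude` uV, `present`).
#' @export
#' @examples
#' tpl <- generate_template(180, 1000)
#' length(tpl$values)         # 180
#' max(tpl$values)            # 1000 at the R landmark
generate_template <- function(samples_per_cycle = 180L, r_amplitude = 1000,
                              morphology = default_morphology()) {
  if (!is.numeric(samples_per_cycle) || length(samples_per_cycle) != 1 ||
      samples_per_cycle < 30 || samples_per_cycle != round(samples_per_cycle)) {
    stop_invalid("`samples_per_cycle` must be a single integer >= 30")
  }
  if (!is.numeric(r_amplitude) || length(r_amplitude) != 1 || r_amplitude <= 0) {
    stop_invalid("`r_amplitude` must be a single positive value (uV)")
  }
  required <- c("P", "Q", "R", "S", "T")
  if (!all(required %in% morphology$wave)) {
    stop_invalid("`morphology` must contain rows for waves P, Q, R, S, T")
  }
  morphology <- morphology[match(required, morphology$wave), ]
  if (morphology$amplitude[morphology$wave == "R"] <= 0) {
    stop_invalid("the R wave must have positive amplitude")
  }
  if (any(diff(morphology$center) <= 0)) {
    stop_invalid("wave centers must be strictly increasing in order P<Q<R<S<T")
  }

  spc <- as.integer(samples_per_cycle)
  t_frac <- (seq_len(spc) - 1) / spc
  values <- numeric(spc)
  for (i in seq_len(nrow(morphology))) {
    a <- morphology$amplitude[i]
    if (a == 0) next
    c0 <- morphology$center[i]
    w <- morphology$width[i]
    # truncate each wave at +/- 4 sigma so the isoelectric baseline between
    # waves (notably the T-P segment) is exactly flat
    bump <- a * exp(-0.5 * ((t_frac - c0) / w)^2)
    bump[abs(t_frac - c0) > 4 * w] <- 0
    values <- values + bump
  }
  values <- values * (r_amplitude / max(values))

  landmarks <- data.frame(
    wave       = morphology$wave,
    center     = pmin(spc, pmax(1L, as.integer(round(morphology$center * spc)) + 1L)),
    half_width = as.integer(round(2 * morphology$width * spc)),
    amplitude  = morphology$amplitude * r_amplitude,
    present    = morphology$amplitude != 0,
    stringsAsFactors = FALSE
  )
  # anchor the R landmark on the realised apex sample
  landmarks$center[landmarks$wave == "R"] <- which.max(values)

  structure(
    list(samples_per_cycle = spc, values = values, landmarks = landmarks),
    class = "ecg_template"
  )
}

#' @export
print.ecg_template <- function(x, ...) {
  cat("<ecg_template> ", x$samples_per_cycle, " samples/cycle, R peak ",
      format(max(x$values), digits = 5), " uV\n", sep = "")
  print(x$landmarks, row.names = FALSE)
  invisible(x)
}

#' Phase advance represented by one sample offset
#'
#' With `samples_per_cycle` points per ECG cycle, a misalignment of one sample
#' between two channels corresponds to `360 / samples_per_cycle` degrees of
#' cycle phase; at the default 180 samples per cycle a one-point offset is a
#' 2 degree phase difference.
#'
#' @param samples_per_cycle Positive integer.
#' @return Degrees of phase per one-sample offset.
#' @export
#' @examples
#' degrees_per_sample(180)  # 2
degrees_per_sample <- function(samples_per_cycle) {
  if (!is.numeric(samples_per_cycle) || length(samples_per_cycle) != 1 ||
      samples_per_cycle < 1) {
    stop_invalid("`samples_per_cycle` must be a single value >= 1")
  }
  360 / samples_per_cycle
}

#' Typical ECG amplitude by body location
#'
#' Representative R-peak amplitudes of surface ECG at different electrode
#' sites: 1000 uV on the chest, 30-50 uV at the mastoid (behind the ear,
#' 3-5% of chest after neck attenuation), 50-70 uV on the upper arm. Presets
#' return the midpoint of the published range.
#'
#' @param location One of `"chest"`, `"mastoid"`, `"upper_arm"`.
#' @return Amplitude in microvolts.
#' @export
#' @examples
#' location_amplitude("mastoid")  # 40
location_amplitude <- function(location = c("chest", "mastoid", "upper_arm")) {
  location <- match.arg(location)
  switch(location, chest = 1000, mastoid = 40, upper_arm = 60)
}

#' Generate a clean multi-cycle ECG signal
#'
#' Concatenates `n_cycles` renderings of a template. With `rr_jitter = 0`
#' every cycle is the template verbatim; with `rr_jitter > 0` each cycle is
#' linearly resampled to a length drawn uniformly from
#' `samples_per_cycle * (1 +/- rr_jitter)` (seeded), emulating beat-to-beat
#' RR-interval variability. True R-apex indices are returned alongside the
#' signal so detector experiments have ground truth.
#'
#' @param template An [`ecg_template`][generate_template].
#' @param n_cycles Number of cycles (>= 1).
#' @param fs Sampling rate in Hz (default 250).
#' @param rr_jitter Fractional uniform jitter of the cycle length (>= 0).
#' @param seed RNG seed; required when `rr_jitter > 0`.
#' @return An object of class `ecg_clean`: list with `signal` (uV),
#'   `r_indices` (1-based), `cycle_starts`, `cycle_lengths`, `fs`, `template`.
#' @export
#' @examples
#' tpl <- generate_template(180, 1000)
#' rec <- generate_clean_recording(tpl, n_cycles = 4)
#' length(rec$signal)  # 720
#' rec$r_indices       # R landmark + 0, 180, 360, 540
generate_clean_recording <- function(template, n_cycles, fs = 250,
                                     rr_jitter = 0, seed = NULL) {
  stopifnot(inherits(template, "ecg_template"))
  if (!is.numeric(n_cycles) || length(n_cycles) != 1 || n_cycles < 1) {
    stop_invalid("`n_cycles` must be a single integer >= 1")
  }
  if (!is.numeric(fs) || fs <= 0) stop_invalid("`fs` must be positive")
  if (!is.numeric(rr_jitter) || rr_jitter < 0) {
    stop_invalid("`rr_jitter` must be >= 0")
  }
  n_cycles <- as.integer(n_cycles)
  spc <- template$samples_per_cycle

  lengths <- if (rr_jitter > 0) {
    with_preserved_seed(seed, {
      pmax(2L, as.integer(round(spc * (1 + runif(n_cycles, -rr_jitter, rr_jitter)))))
    })
  } else {
    rep.int(spc, n_cycles)
  }

  pieces <- vector("list", n_cycles)
  r_local <- integer(n_cycles)
  for (i in seq_len(n_cycles)) {
    len <- lengths[i]
    if (len == spc) {
      pieces[[i]] <- template$values
    } else {
      pieces[[i]] <- approx(
        x = seq(0, 1, length.out = spc),
        y = template$values,
        xout = seq(0, 1, length.out = len)
      )$y
    }
    r_local[i] <- which.max(pieces[[i]])
  }
  starts <- cumsum(c(0L, lengths[-n_cycles]))
  structure(
    list(
      signal = unlist(pieces, use.names = FALSE),
      r_indices = starts + r_local,
      cycle_starts = starts + 1L,
      cycle_lengths = lengths,
      fs = fs,
      template = template
    ),
    class = "ecg_clean"
  )
}

#' Per-channel acquisition specification
#'
#' Describes how one channel of a multi-electrode array observes the common
#' underlying ECG: additive zero-mean Gaussian noise of standard deviation
#' `noise_sigma` (uV), an integer-sample propagation delay `phase_offset`
#' (positive = delayed; each sample is `degrees_per_sample()` of cycle
#' phase), and a multiplicative `gain_scale`.
#'
#' @param noise_sigma Noise standard deviation in uV (>= 0).
#' @param phase_offset Integer sample delay (may be negative).
#' @param gain_scale Dimensionless positive gain.
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(noise_sigma = 0, phase_offset = 0L, gain_scale = 1) {
  if (!is.numeric(noise_sigma) || length(noise_sigma) != 1 || noise_sigma < 0) {
    stop_invalid("`noise_sigma` must be a single value >= 0")
  }
  if (!is.numeric(phase_offset) || length(phase_offset) != 1 ||
      phase_offset != round(phase_offset)) {
    stop_invalid("`phase_offset` must be a single integer")
  }
  if (!is.numeric(gain_scale) || length(gain_scale) != 1 || gain_scale <= 0) {
    stop_invalid("`gain_scale` must be a single positive value")
  }
  structure(
    list(noise_sigma = noise_sigma, phase_offset = as.integer(phase_offset),
         gain_scale = gain_scale),
    class = "channel_spec"
  )
}

# Integer-sample delay with edge replication (physical propagation delay does
# not wrap within a recording).
shift_replicate <- function(x, k) {
  n <- length(x)
  k <- as.integer(k)
  if (abs(k) >= n) stop_invalid("|phase_offset| must be < signal length")
  if (k == 0) return(x)
  if (k > 0) c(rep.int(x[1], k), x[seq_len(n - k)])
  else c(x[seq.int(1 - k, n)], rep.int(x[n], -k))
}

# Circular integer shift, used for single isolated templates.
shift_circular <- function(x, k) {
  n <- length(x)
  k <- ((as.integer(k)) %% n + n) %% n
  if (k == 0) return(x)
  c(x[seq.int(n - k + 1, n)], x[seq_len(n - k)])
}

#' Render a multi-channel recording from one clean signal
#'
#' Each channel observes the same underlying ECG (the proximity assumption of
#' closely spaced electrodes): row i is
#' `gain_scale_i * shift(clean, phase_offset_i) + N(0, noise_sigma_i^2)`,
#' with noise drawn independently per channel from the seeded generator and
#' the shift implemented as an integer-sample delay with edge replication.
#'
#' @param clean Either an [`ecg_clean`][generate_clean_recording] object or a
#'   bare numeric uV vector.
#' @param channel_specs List of K [channel_spec()] objects.
#' @param seed RNG seed; required when any `noise_sigma > 0`.
#' @param fs Sampling rate in Hz; defaults to `clean$fs` or 250.
#' @return An object of class `mc_recording`: list with `fs`, `data` (K x N
#'   uV matrix, rows `ch1..chK`), `channel_specs`, `seed`, and `clean` (the
#'   underlying signal, for ground-truth comparisons).
#' @export
#' @examples
#' tpl <- generate_template(180, 1000)
#' rec <- generate_clean_recording(tpl, n_cycles = 4)
#' specs <- replicate(8, channel_spec(noise_sigma = 50), simplify = FALSE)
#' mc <- make_multichannel(rec, specs, seed = 7)
#' dim(mc$data)  # 8 x 720
make_multichannel <- function(clean, channel_specs, seed = NULL, fs = NULL) {
  sig <- if (inherits(clean, "ecg_clean")) clean$signal else as.numeric(clean)
  if (is.null(fs)) fs <- if (inherits(clean, "ecg_clean")) clean$fs else 250
  if (length(sig) < 1) stop_invalid("`clean` must be non-empty")
  if (!is.list(channel_specs) || length(channel_specs) < 1) {
    stop_invalid("`channel_specs` must be a non-empty list of channel_spec")
  }
  channel_specs <- lapply(channel_specs, function(cs) {
    if (!inherits(cs, "channel_spec")) {
      stop_invalid("every element of `channel_specs` must be a channel_spec")
    }
    cs
  })
  k <- length(channel_specs)
  n <- length(sig)
  any_noise <- any(vapply(channel_specs, function(cs) cs$noise_sigma > 0, logical(1)))

  build_rows <- function() {
    out <- matrix(0, nrow = k, ncol = n)
    for (i in seq_len(k)) {
      cs <- channel_specs[[i]]
      row <- cs$gain_scale * shift_replicate(sig, cs$phase_offset)
      if (cs$noise_sigma > 0) row <- row + rnorm(n, 0, cs$noise_sigma)
      out[i, ] <- row
    }
    out
  }
  data <- if (any_noise) with_preserved_seed(seed, build_rows()) else build_rows()
  rownames(data) <- paste0("ch", seq_len(k))

  structure(
    list(fs = fs, data = data, channel_specs = channel_specs,
         seed = if (any_noise) as.integer(seed) else NA_integer_,
         clean = clean),
    class = "mc_recording"
  )
}

#' @export
print.mc_recording <- function(x, ...) {
  cat("<mc_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz\n", sep = "")
  sig <- vapply(x$channel_specs, `[[`, numeric(1), "noise_sigma")
  off <- vapply(x$channel_specs, `[[`, integer(1), "phase_offset")
  cat("  noise sigma (uV): ", paste(format(sig, digits = 3), collapse = ", "),
      "\n  phase offsets (samples): ", paste(off, collapse = ", "), "\n", sep = "")
  invisible(x)
}
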