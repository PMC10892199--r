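#' Design a second-order powerline notch filter
#'
#' Standard digital biquad notch (constant-0 dB-gain audio-EQ form): a pair
#' of unit-circle zeros at the notch frequency and poles pulled inside by the
#' quality factor Q (3 dB bandwidth = f0/Q).
#'
#' @param f0 Notch frequency in Hz (0 < f0 < fs/2).
#' @param fs Sampling rate in Hz.
#' @param q Quality factor (> 0); default 30 gives a 1.7 Hz band at 50 Hz.
#' @return List with transfer-function coefficients `b`, `a` (length 3,
#'   `a[1] = 1`).
#' @export
design_notch <- function(f0, fs, q = 30) {
  if (!is.numeric(f0) || f0 <= 0 || f0 >= fs / 2) {
    stop_invalid("notch frequency must satisfy 0 < f0 < fs/2")
  }
  if (!is.numeric(q) || q <= 0) stop_invalid("`q` must be > 0")
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Steady-state initial filter state for a step of unit amplitude (the
# transposed-direct-form-II analogue of scipy.signal.lfilter_zi): solving
# (I - A^T) zi = B for the companion-form state matrix keeps the filter in
# steady state when the first input sample is repeated, which eliminates
# start-up transients in zero-phase filtering.
lfilter_zi <- function(b, a) {
  n <- max(length(b), length(a))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  if (a[1] != 1) {
    b <- b / a[1]
    a <- a / a[1]
  }
  if (n == 1) return(numeric(0))
  A <- matrix(0, n - 1, n - 1)
  A[1, ] <- -a[-1]
  if (n > 2) A[cbind(2:(n - 1), 1:(n - 2))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - t(A), B)
}

# Effective impulse-response length of an IIR stage: the number of samples
# for the slowest pole to decay to 1e-4 of its initial amplitude.
effective_ir_length <- function(b, a) {
  n <- max(length(b), length(a))
  if (n < 2) return(1L)
  a <- c(a, rep(0, n - length(a)))
  r <- max(Mod(polyroot(rev(a / a[1]))))
  if (r >= 1) return(.Machine$integer.max)  # unstable stage; caller errors
  max(n - 1L, as.integer(ceiling(-log(1e-4) / -log(r))))
}

# One zero-phase (bidirectional) pass of a single IIR stage, with
# odd-reflection padding (point symmetry about each endpoint, which
# preserves the signal's slope across the boundary) and steady-state
# initial conditions at both ends.
# The pad length is three times the stage order or the stage's effective
# impulse-response length, whichever is longer (capped at signal length - 1),
# so that edge transients of slow stages such as a 0.1 Hz high-pass decay
# inside the pad. The backward pass is applied first, then the forward pass;
# for LTI stages the order of directions does not affect the
# (squared-magnitude, zero-phase) response.
zero_phase_filter <- function(b, a, x) {
  n <- max(length(b), length(a))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  if (length(x) <= 3L * (n - 1L)) {
    stop_invalid("signal too short for zero-phase filtering: need more than ",
                 3L * (n - 1L), " samples")
  }
  padlen <- min(length(x) - 1L, max(3L * (n - 1L), effective_ir_length(b, a)))
  m <- length(x)
  ext <- if (padlen > 0) {
    c(2 * x[1] - x[seq.int(padlen + 1L, 2L)],
      x,
      2 * x[m] - x[seq.int(m - 1L, m - padlen)])
  } else {
    x
  }
  zi <- lfilter_zi(b, a)
  # backward pass
  rev_ext <- rev(ext)
  y1 <- iir_df2t(b, a, rev_ext, zi * rev_ext[1])$y
  # forward pass
  y1 <- rev(y1)
  y2 <- iir_df2t(b, a, y1, zi * y1[1])$y
  y2[seq.int(padlen + 1L, padlen + m)]
}

#' Specify the real-time noise-removal filter chain
#'
#' The processing chain applied to each displayed channel: powerline notches
#' (defaults 50 and 100 Hz), a low-pass limiting the ECG band (default
#' 100 Hz), and a high-pass removing baseline wander (default 0.1 Hz). Every
#' stage is applied bidirectionally (once in each time direction), giving the
#' squared magnitude response with zero net phase shift. Filter families and
#' orders are package defaults: 2nd-order biquad notches (Q = 30), 4th-order
#' Butterworth low-pass, 2nd-order Butterworth high-pass. At fs = 250 Hz the
#' 100 Hz low-pass sits close to Nyquist (125 Hz), so it overlaps the 100 Hz
#' notch; both are kept, mirroring the deployed processing list.
#'
#' @param fs Sampling rate in Hz.
#' @param notch_freqs Notch frequencies in Hz (may be empty).
#' @param notch_q Notch quality factor.
#' @param lowpass_hz Low-pass corner in Hz, or `NULL` to omit the stage.
#' @param highpass_hz High-pass corner in Hz, or `NULL` to omit the stage.
#' @param lp_order,hp_order Butterworth orders.
#' @return An object of class `filter_chain`: list of stages, each with `b`,
#'   `a`, and a `label`.
#' @export
#' @examples
#' spec <- filter_chain(fs = 250)
#' length(spec$stages)  # 4
filter_chain <- function(fs = 250, notch_freqs = c(50, 100), notch_q = 30,
                         lowpass_hz = 100, highpass_hz = 0.1,
                         lp_order = 4, hp_order = 2) {
  if (!is.numeric(fs) || fs <= 0) stop_invalid("`fs` must be positive")
  nyq <- fs / 2
  corners <- c(notch_freqs, lowpass_hz, highpass_hz)
  if (any(corners >= nyq) || any(corners <= 0)) {
    stop_invalid("all corner/notch frequencies must lie in (0, fs/2)")
  }
  stages <- list()
  for (f0 in notch_freqs) {
    st <- design_notch(f0, fs, notch_q)
    st$label <- sprintf("notch %g Hz (Q=%g)", f0, notch_q)
    stages[[length(stages) + 1L]] <- st
  }
  if (!is.null(lowpass_hz)) {
    bt <- signal::butter(lp_order, lowpass_hz / nyq, type = "low")
    stages[[length(stages) + 1L]] <-
      list(b = bt$b, a = bt$a, label = sprintf("low-pass %g Hz", lowpass_hz))
  }
  if (!is.null(highpass_hz)) {
    bt <- signal::butter(hp_order, highpass_hz / nyq, type = "high")
    stages[[length(stages) + 1L]] <-
      list(b = bt$b, a = bt$a, label = sprintf("high-pass %g Hz", highpass_hz))
  }
  structure(list(fs = fs, stages = stages), class = "filter_chain")
}

#' @export
print.filter_chain <- function(x, ...) {
  cat("<filter_chain> fs = ", x$fs, " Hz, zero-phase stages:\n", sep = "")
  for (st in x$stages) cat("  - ", st$label, "\n", sep = "")
  invisible(x)
}

#' Apply the zero-phase filter chain to a signal
#'
#' Each stage of the chain is applied once backward and once forward in time,
#' so the chain contributes zero net phase at every frequency (the effective
#' magnitude response is the product of squared stage magnitudes). Edge
#' transients are controlled by even-reflection padding of three times each
#' stage's order together with steady-state initial conditions, so a constant
#' input yields exactly the steady-state output (zero, for a chain containing
#' a high-pass).
#'
#' @param x Numeric signal (uV).
#' @param spec A [filter_chain()] object.
#' @return Filtered signal, same length as `x`.
#' @export
#' @examples
#' spec <- filter_chain(fs = 250)
#' t <- seq(0, 4, by = 1 / 250)
#' y <- apply_zero_phase_chain(sin(2 * pi * 10 * t), spec)
apply_zero_phase_chain <- function(x, spec) {
  stopifnot(inherits(spec, "filter_chain"))
  x <- as.numeric(x)
  max_order <- max(vapply(spec$stages, function(st) {
    max(length(st$b), length(st$a)) - 1L
  }, integer(1)))
  if (length(x) <= 3L * max_order) {
    stop_invalid("signal too short: need more than ", 3L * max_order,
                 " samples for this chain")
  }
  for (st in spec$stages) x <- zero_phase_filter(st$b, st$a, x)
  x
}

#' Phase of the analog front-end first-order high-pass
#'
#' The acquisition front end places a first-order RC high-pass (characteristic
#' frequency `fc`, default design 0.15 Hz) before each input channel to block
#' baseline drift. Its transfer function H(s) = s / (s + 2 pi fc) contributes
#' a phase lead of `atan(fc / f)` at frequency `f`; this function returns that
#' phase in degrees. With 1%-tolerance RC components the corner varies only a
#' few percent, keeping inter-channel phase mismatch well below the 2 degree
#' alignment budget of the averaging method (see
#' [frontend_phase_mismatch_deg()]).
#'
#' @param fc Characteristic (corner) frequency in Hz (> 0).
#' @param f Evaluation frequency in Hz (> 0).
#' @return Phase in degrees (45 at `f = fc`, approaching 0 as `f` grows).
#' @export
#' @examples
#' frontend_hp_phase_deg(0.15, 0.15)  # 45
frontend_hp_phase_deg <- function(fc, f) {
  if (!is.numeric(fc) || any(fc <= 0)) stop_invalid("`fc` must be > 0")
  if (!is.numeric(f) || any(f <= 0)) stop_invalid("`f` must be > 0")
  atan(fc / f) * 180 / pi
}

#' Worst-case inter-channel front-end phase mismatch
#'
#' The corner of the RC high-pass is fc = 1/(2 pi R C); with component
#' tolerance `tol` on both R and C the corner spans
#' `fc / (1+tol)^2` to `fc / (1-tol)^2`. The worst-case phase difference
#' between two channels at frequency `f` is the spread of
#' [frontend_hp_phase_deg()] over that corner range.
#'
#' @param fc Nominal corner frequency in Hz.
#' @param f Evaluation frequency in Hz.
#' @param tol Fractional component tolerance (default 0.01 = 1%).
#' @return Maximum phase difference in degrees between any two in-tolerance
#'   channels at `f`.
#' @export
#' @examples
#' frontend_phase_mismatch_deg(0.15, 1)  # far below 2 degrees
frontend_phase_mismatch_deg <- function(fc, f, tol = 0.01) {
  if (!is.numeric(tol) || tol < 0 || tol >= 1) {
    stop_invalid("`tol` must be in [0, 1)")
  }
  hi <- fc / (1 - tol)^2
  lo <- fc / (1 + tol)^2
  frontend_hp_phase_deg(hi, f) - frontend_hp_phase_deg(lo, f)
}
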