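#' Average channels of a multi-channel recording
#'
#' The core superposition estimator: the element-wise arithmetic mean of K
#' simultaneously recorded channels. When each channel carries the same ECG
#' plus independent zero-mean noise, the mean preserves the ECG while its
#' noise standard deviation falls by 1/sqrt(K) (see
#' [predicted_noise_sd_ratio()]). No re-alignment is performed: the method
#' relies on physical electrode proximity keeping the channels in phase, and
#' any compensation is the caller's responsibility.
#'
#' @param rec An [`mc_recording`][make_multichannel] or a bare K x N numeric
#'   matrix.
#' @param channel_subset Optional integer vector of row indices to average
#'   (default: all channels).
#' @return An object of class `averaged_signal`: list with `values` (uV,
#'   length N), `k_channels`, and `source_meta` (the channel specs of the
#'   averaged rows, when available).
#' @export
#' @examples
#' m <- matrix(rnorm(800), nrow = 8)
#' avg <- average_channels(m)
#' avg$k_channels  # 8
average_channels <- function(rec, channel_subset = NULL) {
  data <- if (inherits(rec, "mc_recording")) rec$data else as.matrix(rec)
  if (!is.numeric(data) || nrow(data) < 1 || ncol(data) < 1) {
    stop_invalid("`rec` must contain a non-empty numeric channel matrix")
  }
  if (is.null(channel_subset)) channel_subset <- seq_len(nrow(data))
  channel_subset <- as.integer(channel_subset)
  if (length(channel_subset) < 1) {
    stop_invalid("`channel_subset` must be non-empty")
  }
  if (any(channel_subset < 1 | channel_subset > nrow(data))) {
    stop_invalid("`channel_subset` indices out of range")
  }
  sel <- data[channel_subset, , drop = FALSE]
  meta <- if (inherits(rec, "mc_recording")) rec$channel_specs[channel_subset] else NULL
  structure(
    list(values = colMeans(sel), k_channels = length(channel_subset),
         source_meta = meta),
    class = "averaged_signal"
  )
}

#' @export
print.averaged_signal <- function(x, ...) {
  cat("<averaged_signal> mean of ", x$k_channels, " channels, ",
      length(x$values), " samples\n", sep = "")
  invisible(x)
}

#' Theoretical noise reduction of K-channel averaging
#'
#' For K channels with identical signal and independent noise of common
#' standard deviation sigma, the averaged signal has noise standard deviation
#' sigma/sqrt(K); this returns the ratio 1/sqrt(K).
#'
#' @param k Number of channels (>= 1).
#' @return Dimensionless ratio sigma_avg / sigma_single = 1/sqrt(k).
#' @export
#' @examples
#' predicted_noise_sd_ratio(8)  # 0.3536
predicted_noise_sd_ratio <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop_invalid("`k` must be a single integer >= 1")
  }
  1 / sqrt(k)
}

#' Theoretical SNR gain of K-channel averaging in dB
#'
#' Averaging K aligned channels leaves the signal amplitude unchanged and
#' divides the noise standard deviation by sqrt(K), so the amplitude-ratio
#' SNR improves by `20*log10(sqrt(k)) = 10*log10(k)` dB - about 9.03 dB for
#' eight channels.
#'
#' @param k Number of channels (>= 1).
#' @return SNR improvement in dB.
#' @export
#' @examples
#' predicted_snr_gain_db(8)  # 9.0309
predicted_snr_gain_db <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop_invalid("`k` must be a single integer >= 1")
  }
  10 * log10(k)
}
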