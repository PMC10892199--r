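#' Write a multi-channel recording to CSV
#'
#' Column layout: `t_seconds`, then one column per channel named `ch1..chK`,
#' values in microvolts.
#'
#' @param rec An [`mc_recording`][make_multichannel] or K x N numeric matrix.
#' @param path Output file path.
#' @param fs Sampling rate in Hz (taken from `rec` when available).
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path, fs = NULL) {
  data <- if (inherits(rec, "mc_recording")) rec$data else as.matrix(rec)
  if (is.null(fs)) fs <- if (inherits(rec, "mc_recording")) rec$fs else 250
  n <- ncol(data)
  df <- data.frame(t_seconds = (seq_len(n) - 1) / fs)
  for (i in seq_len(nrow(data))) df[[paste0("ch", i)]] <- data[i, ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a multi-channel recording from CSV
#'
#' Expects the layout written by [write_recording_csv()]: a `t_seconds`
#' column followed by `ch1..chK`. The sampling rate is recovered from the
#' time column.
#'
#' @param path CSV file path.
#' @return An [`mc_recording`][make_multichannel] with unit channel specs.
#' @export
read_recording_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  ch_cols <- grep("^ch[0-9]+$", names(df), value = TRUE)
  if (length(ch_cols) == 0) stop_invalid("no ch1..chK columns found in ", path)
  ch_cols <- ch_cols[order(as.integer(sub("^ch", "", ch_cols)))]
  fs <- if ("t_seconds" %in% names(df) && nrow(df) > 1) {
    1 / median(diff(df$t_seconds))
  } else {
    250
  }
  data <- t(as.matrix(df[ch_cols]))
  rownames(data) <- ch_cols
  structure(
    list(fs = fs, data = data,
         channel_specs = replicate(nrow(data), channel_spec(), simplify = FALSE),
         seed = NA_integer_, clean = NULL),
    class = "mc_recording"
  )
}

#' Read a simulation configuration file
#'
#' YAML configuration for the synthetic generator. Recognised keys:
#' `samples_per_cycle`, `fs`, `n_cycles`, `r_amplitude_uv` (or
#' `location_preset` in chest/mastoid/upper_arm), `rr_jitter`, `seed`, and
#' `channels`: a list of `{noise_sigma_uv, phase_offset_samples, gain_scale}`.
#' Missing keys fall back to the generator defaults.
#'
#' @param path YAML file path.
#' @return Validated list with elements `template_args`, `recording_args`,
#'   `channel_specs`, `seed`.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  spc <- cfg$samples_per_cycle %||% 180L
  amp <- if (!is.null(cfg$r_amplitude_uv)) {
    cfg$r_amplitude_uv
  } else if (!is.null(cfg$location_preset)) {
    location_amplitude(cfg$location_preset)
  } else {
    1000
  }
  channels <- cfg$channels
  specs <- if (is.null(channels)) {
    replicate(8, channel_spec(), simplify = FALSE)
  } else {
    lapply(channels, function(ch) {
      channel_spec(
        noise_sigma = ch$noise_sigma_uv %||% 0,
        phase_offset = ch$phase_offset_samples %||% 0L,
        gain_scale = ch$gain_scale %||% 1
      )
    })
  }
  list(
    template_args = list(samples_per_cycle = spc, r_amplitude = amp),
    recording_args = list(
      n_cycles = cfg$n_cycles %||% 4L,
      fs = cfg$fs %||% 250,
      rr_jitter = cfg$rr_jitter %||% 0
    ),
    channel_specs = specs,
    seed = cfg$seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
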