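#' Construct a 26-byte acquisition packet frame
#'
#' The acquisition board emits one packet per sampling instant: a header
#' byte, eight 24-bit signed ADC codes (channels 1..8), and a tail byte —
#' 26 bytes in total, sent every 4 ms at 250 Hz. Header/tail values are not
#' fixed by the wire format here and default to the common sync pair
#' 0xAA/0x55.
#'
#' @param samples Integer vector of 8 ADC codes, each in
#'   `[-2^23, 2^23 - 1]`.
#' @param header,tail Single byte values (0-255).
#' @return An object of class `packet_frame`.
#' @export
#' @examples
#' pf <- packet_frame(rep(0L, 8))
#' length(encode_packet(pf))  # 26
packet_frame <- function(samples, header = 0xAA, tail = 0x55) {
  samples <- as.numeric(samples)
  if (length(samples) != 8) stop_invalid("a frame carries exactly 8 samples")
  if (any(samples != round(samples))) stop_invalid("samples must be integers")
  if (any(samples < -2^23 | samples > 2^23 - 1)) {
    stop_invalid("samples must lie in [-2^23, 2^23 - 1]")
  }
  for (b in c(header, tail)) {
    if (!is.numeric(b) || length(b) != 1 || b < 0 || b > 255 || b != round(b)) {
      stop_invalid("header and tail must be single byte values (0-255)")
    }
  }
  structure(list(header = as.integer(header), samples = samples,
                 tail = as.integer(tail)),
            class = "packet_frame")
}

#' @export
print.packet_frame <- function(x, ...) {
  cat("<packet_frame> header 0x", toupper(as.character(as.hexmode(x$header))),
      ", tail 0x", toupper(as.character(as.hexmode(x$tail))),
      ", samples: ", paste(format(x$samples, scientific = FALSE),
                           collapse = " "), "\n", sep = "")
  invisible(x)
}

# 24-bit two's-complement <-> byte-triplet helpers (big-endian by default).
int24_to_bytes <- function(v, big_endian = TRUE) {
  u <- ifelse(v < 0, v + 2^24, v)
  b1 <- u %/% 65536
  b2 <- (u %/% 256) %% 256
  b3 <- u %% 256
  m <- if (big_endian) rbind(b1, b2, b3) else rbind(b3, b2, b1)
  as.raw(as.vector(m))
}

bytes_to_int24 <- function(raw3, big_endian = TRUE) {
  b <- as.integer(raw3)
  m <- matrix(b, nrow = 3)
  u <- if (big_endian) m[1, ] * 65536 + m[2, ] * 256 + m[3, ]
       else m[3, ] * 65536 + m[2, ] * 256 + m[1, ]
  ifelse(u >= 2^23, u - 2^24, u)
}

#' Serialize a packet frame to its 26-byte wire form
#'
#' Byte layout: header, then the eight samples as 3-byte two's-complement
#' groups in channel order 1..8 (big-endian within each sample by default),
#' then the tail byte.
#'
#' @param frame A [packet_frame()].
#' @param big_endian Byte order within each 24-bit sample.
#' @return A raw vector of length 26.
#' @export
encode_packet <- function(frame, big_endian = TRUE) {
  stopifnot(inherits(frame, "packet_frame"))
  c(as.raw(frame$header),
    int24_to_bytes(frame$samples, big_endian),
    as.raw(frame$tail))
}

#' Decode one 26-byte packet
#'
#' @param bytes Raw vector of length 26.
#' @param header,tail Expected framing bytes; mismatch is an error.
#' @param big_endian Byte order within each 24-bit sample.
#' @return A [packet_frame()].
#' @export
decode_packet <- function(bytes, header = 0xAA, tail = 0x55,
                          big_endian = TRUE) {
  bytes <- as.raw(bytes)
  if (length(bytes) != 26) stop_invalid("a packet is exactly 26 bytes")
  if (as.integer(bytes[1]) != header || as.integer(bytes[26]) != tail) {
    stop_invalid("framing bytes do not match the expected header/tail")
  }
  packet_frame(bytes_to_int24(bytes[2:25], big_endian),
               header = header, tail = tail)
}

#' Decode a byte stream into packet frames, resynchronizing on corruption
#'
#' Scans the stream for header...tail framing at 26-byte cadence. A position
#' whose header or tail byte does not match is skipped by one byte and the
#' scan retries (resynchronization); skipped bytes are counted. Appending
#' bytes to a stream never changes frames already emitted from its prefix.
#'
#' @param bytes Raw vector (possibly empty).
#' @param header,tail Framing byte values.
#' @param big_endian Byte order within each 24-bit sample.
#' @return List with `frames` (list of [packet_frame()]), and `diagnostics`
#'   (`n_frames`, `dropped_bytes`, `resyncs` = number of contiguous skipped
#'   runs, `trailing_bytes` = unconsumed tail shorter than one packet).
#' @export
decode_stream <- function(bytes, header = 0xAA, tail = 0x55,
                          big_endian = TRUE) {
  bytes <- as.raw(bytes)
  n <- length(bytes)
  frames <- list()
  dropped <- 0L
  resyncs <- 0L
  in_skip <- FALSE
  pos <- 1L
  while (pos + 25L <= n) {
    if (as.integer(bytes[pos]) == header &&
        as.integer(bytes[pos + 25L]) == tail) {
      frames[[length(frames) + 1L]] <-
        packet_frame(bytes_to_int24(bytes[(pos + 1L):(pos + 24L)], big_endian),
                     header = header, tail = tail)
      pos <- pos + 26L
      in_skip <- FALSE
    } else {
      dropped <- dropped + 1L
      if (!in_skip) {
        resyncs <- resyncs + 1L
        in_skip <- TRUE
      }
      pos <- pos + 1L
    }
  }
  list(
    frames = frames,
    diagnostics = list(
      n_frames = length(frames),
      dropped_bytes = dropped,
      resyncs = resyncs,
      trailing_bytes = n - pos + 1L
    )
  )
}

#' ADC conversion configuration
#'
#' Front-end settings of the 24-bit delta-sigma ADC: reference voltage,
#' programmable-gain-amplifier (PGA) gain, and sampling rate. The deployed
#' system uses gain 12 at 250 Hz.
#'
#' @param vref Reference voltage in volts (default 4.5, the chip-standard
#'   internal reference).
#' @param pga_gain One of 1, 2, 4, 6, 8, 12, 24.
#' @param fs One of 250, 500, 1000, 2000, 4000 Hz.
#' @return An object of class `adc_config`.
#' @export
adc_config <- function(vref = 4.5, pga_gain = 12, fs = 250) {
  if (!is.numeric(vref) || vref <= 0) stop_invalid("`vref` must be > 0")
  if (!pga_gain %in% c(1, 2, 4, 6, 8, 12, 24)) {
    stop_invalid("`pga_gain` must be one of 1, 2, 4, 6, 8, 12, 24")
  }
  if (!fs %in% c(250, 500, 1000, 2000, 4000)) {
    stop_invalid("`fs` must be one of 250, 500, 1000, 2000, 4000")
  }
  structure(list(vref = vref, pga_gain = pga_gain, fs = fs),
            class = "adc_config")
}

#' Convert ADC codes to input-referred microvolts
#'
#' One LSB referred to the input is `(2 * vref / pga_gain) / 2^24` volts
#' (bipolar full scale divided by the 24-bit code range, divided by the PGA
#' gain), so `uV = code * (2 * vref / pga_gain) / 2^24 * 1e6`.
#'
#' @param code Integer ADC code(s) in `[-2^23, 2^23 - 1]`.
#' @param cfg An [adc_config()].
#' @return Microvolts (same length as `code`).
#' @export
#' @examples
#' code_to_microvolts(1, adc_config())  # 0.0447 uV per LSB at gain 12
code_to_microvolts <- function(code, cfg = adc_config()) {
  stopifnot(inherits(cfg, "adc_config"))
  code <- as.numeric(code)
  if (any(code != round(code)) || any(code < -2^23 | code > 2^23 - 1)) {
    stop_invalid("codes must be integers in [-2^23, 2^23 - 1]")
  }
  code * (2 * cfg$vref / cfg$pga_gain) / 2^24 * 1e6
}

#' Convert microvolts to the nearest ADC code
#'
#' Inverse of [code_to_microvolts()], rounding to the nearest code; errors if
#' the voltage exceeds the input range.
#'
#' @param uv Microvolts.
#' @param cfg An [adc_config()].
#' @return Integer codes.
#' @export
microvolts_to_code <- function(uv, cfg = adc_config()) {
  stopifnot(inherits(cfg, "adc_config"))
  lsb <- (2 * cfg$vref / cfg$pga_gain) / 2^24 * 1e6
  code <- round(as.numeric(uv) / lsb)
  if (any(code < -2^23 | code > 2^23 - 1)) {
    stop_invalid("voltage exceeds the ADC input range at this gain")
  }
  code
}

#' Serial-link throughput of the packet stream
#'
#' Consistency check for real-time transmission: at `packets_per_s` frames of
#' `packet_bytes` bytes with `bits_per_byte` line bits per byte (10 for
#' 8-N-1 framing), the required bit rate must stay below the configured baud
#' rate. Defaults give 26 x 250 x 10 = 65,000 bps against 115,200 baud.
#'
#' @param packet_bytes Bytes per packet (default 26).
#' @param packets_per_s Packets per second (default 250).
#' @param bits_per_byte Line bits per byte (default 10, 8-N-1).
#' @return Required throughput in bits per second.
#' @export
serial_throughput_bps <- function(packet_bytes = 26, packets_per_s = 250,
                                  bits_per_byte = 10) {
  packet_bytes * packets_per_s * bits_per_byte
}

#' Write / read raw packet streams
#'
#' Thin binary I/O for packet streams: `write_packet_stream()` concatenates
#' encoded frames to a file, `read_packet_stream()` reads the raw bytes back
#' (decode with [decode_stream()]).
#'
#' @param frames List of [packet_frame()] objects.
#' @param path File path.
#' @param big_endian Byte order within each 24-bit sample.
#' @return `write_packet_stream()` returns `path` invisibly;
#'   `read_packet_stream()` returns a raw vector.
#' @export
write_packet_stream <- function(frames, path, big_endian = TRUE) {
  bytes <- do.call(c, c(lapply(frames, encode_packet, big_endian = big_endian),
                        list(raw(0))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(bytes, con)
  invisible(path)
}

#' @rdname write_packet_stream
#' @export
read_packet_stream <- function(path) {
  readBin(path, what = "raw", n = file.size(path))
}
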