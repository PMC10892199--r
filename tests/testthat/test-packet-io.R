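test_that("frames serialize to exactly 26 bytes with the documented layout", {
  pf <- packet_frame(rep(0, 8))
  enc <- encode_packet(pf)
  expect_length(enc, 26)
  expect_equal(as.integer(enc[1]), 0xAA)
  expect_equal(as.integer(enc[26]), 0x55)
  expect_true(all(enc[2:25] == as.raw(0)))
  # -1 encodes as FF FF FF in two's complement
  neg <- encode_packet(packet_frame(c(-1, rep(0, 7))))
  expect_equal(as.integer(neg[2:4]), c(0xFF, 0xFF, 0xFF))
  expect_error(packet_frame(c(2^23, rep(0, 7))), "2\\^23")
  expect_error(packet_frame(rep(0, 7)), "8 samples")
})

test_that("encode/decode round-trips random and boundary frames", {
  frames <- random_frames(1000, seed = 4)
  for (pf in frames[1:50]) {
    expect_equal(decode_packet(encode_packet(pf))$samples, pf$samples)
  }
  # full set via stream decode
  bytes <- do.call(c, lapply(frames, encode_packet))
  dec <- decode_stream(bytes)
  expect_equal(dec$diagnostics$n_frames, 1000)
  expect_equal(dec$diagnostics$dropped_bytes, 0)
  recovered <- t(vapply(dec$frames, `[[`, numeric(8), "samples"))
  original <- t(vapply(frames, `[[`, numeric(8), "samples"))
  expect_equal(recovered, original)
  # boundary codes
  edge <- packet_frame(c(-2^23, 2^23 - 1, -2^23 + 1, 2^23 - 2, 0, 1, -1, 2))
  expect_equal(decode_packet(encode_packet(edge))$samples, edge$samples)
  # little-endian option round-trips too
  expect_equal(decode_packet(encode_packet(edge, big_endian = FALSE),
                             big_endian = FALSE)$samples, edge$samples)
})

test_that("stream decoding resynchronizes past corrupt bytes", {
  frames <- random_frames(100, seed = 6)
  good <- do.call(c, lapply(frames, encode_packet))
  garbage <- as.raw(c(0x01, 0x02, 0x03))
  dec <- decode_stream(c(garbage, good))
  expect_equal(dec$diagnostics$n_frames, 100)
  expect_equal(dec$diagnostics$dropped_bytes, 3)
  expect_equal(dec$diagnostics$resyncs, 1)
  # empty input
  empty <- decode_stream(raw(0))
  expect_equal(empty$diagnostics$n_frames, 0)
})

test_that("stream decoding is prefix-stable", {
  frames <- random_frames(20, seed = 9)
  bytes <- do.call(c, lapply(frames, encode_packet))
  prefix <- decode_stream(bytes[1:(26 * 12)])
  full <- decode_stream(c(bytes, as.raw(c(7, 7))))
  for (i in seq_len(12)) {
    expect_equal(full$frames[[i]]$samples, prefix$frames[[i]]$samples)
  }
})

test_that("packet streams survive a file round trip", {
  frames <- random_frames(25, seed = 13)
  path <- tempfile(fileext = ".bin")
  on.exit(unlink(path))
  write_packet_stream(frames, path)
  dec <- decode_stream(read_packet_stream(path))
  expect_equal(dec$diagnostics$n_frames, 25)
  expect_equal(dec$frames[[25]]$samples, frames[[25]]$samples)
})

test_that("ADC code conversion uses the input-referred LSB", {
  cfg <- adc_config()          # vref 4.5, gain 12
  expect_equal(code_to_microvolts(0, cfg), 0)
  expect_equal(code_to_microvolts(1, cfg), 0.0447, tolerance = 1e-5 / 0.0447)
  expect_equal(code_to_microvolts(1, cfg), 2 * 4.5 / 12 / 2^24 * 1e6)
  # round trip within one LSB
  set.seed(2)
  codes <- sample.int(2^24, 200) - 2^23 - 1
  uv <- code_to_microvolts(codes, cfg)
  expect_true(all(abs(microvolts_to_code(uv, cfg) - codes) <= 1))
  expect_error(code_to_microvolts(2^23, cfg), "2\\^23")
  expect_error(adc_config(pga_gain = 5), "pga_gain")
  expect_error(adc_config(fs = 300), "fs")
})

test_that("the serial link sustains the packet stream in real time", {
  bps <- serial_throughput_bps()
  expect_equal(bps, 65000)
  expect_lt(bps, 115200)
})
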