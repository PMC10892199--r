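# Shared fixtures, built in code: a default chest-scale template and helpers
# to render noisy recordings at a known calibration SNR.

default_tpl <- function(spc = 180L, amp = 1000) generate_template(spc, amp)

noisy_recording <- function(n_cycles = 10, snr_db = 12, k = 1,
                            offsets = rep(0L, k), seed = 42L,
                            rr_jitter = 0, fs = 250) {
  tpl <- default_tpl()
  sigma <- sigma_for_target_snr(tpl, snr_db, fs = fs, seed = seed)
  clean <- generate_clean_recording(tpl, n_cycles = n_cycles, fs = fs,
                                    rr_jitter = rr_jitter,
                                    seed = if (rr_jitter > 0) seed + 1L else NULL)
  specs <- lapply(offsets, function(o) {
    channel_spec(noise_sigma = sigma, phase_offset = o)
  })
  make_multichannel(clean, specs, seed = seed + 2L)
}

random_frames <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    packet_frame(sample.int(2^24, 8, replace = TRUE) - 2^23 - 1)
  })
}
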