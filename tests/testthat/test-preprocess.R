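# steady-state phase/gain of a sinusoid via least squares on the middle
# of the record (edge transients excluded)
fit_sinusoid <- function(x, f, fs) {
  n <- length(x)
  mid <- (n %/% 4):(3 * n %/% 4)
  t <- (mid - 1) / fs
  co <- stats::coef(stats::lm(x[mid] ~ sin(2 * pi * f * t) + cos(2 * pi * f * t) - 1))
  list(amplitude = sqrt(sum(co^2)), phase_deg = atan2(co[2], co[1]) * 180 / pi)
}

test_that("bandpass filtering is zero-phase at 10 Hz", {
  fs <- 1024
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  rec <- make_test_recording(matrix(sin(2 * pi * 10 * t), 1), fs = fs)
  out <- filter_zero_phase(rec, "bandpass", 1, 48)
  fit <- fit_sinusoid(out$data[1, ], 10, fs)
  expect_lt(abs(fit$phase_deg), 0.1)
  expect_equal(fit$amplitude, 1, tolerance = 0.02)
})

test_that("bandstop filtering attenuates 50 Hz by at least 20 dB", {
  fs <- 1024
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  rec <- make_test_recording(matrix(sin(2 * pi * 50 * t), 1), fs = fs)
  out <- filter_zero_phase(rec, "bandstop", 48, 52)
  fit <- fit_sinusoid(out$data[1, ], 50, fs)
  expect_lt(20 * log10(fit$amplitude), -20)
})

test_that("bandpass filtering removes a DC offset", {
  fs <- 1024
  rec <- make_test_recording(matrix(rep(100, 8 * fs), 1), fs = fs)
  out <- filter_zero_phase(rec, "bandpass", 1, 48)
  mid <- (2 * fs):(6 * fs)
  expect_lt(mean(abs(out$data[1, mid])), 1)
  expect_error(filter_zero_phase(rec, "bandpass", 1, 600), "Nyquist|corners")
})

test_that("harmonization aligns both systems on the shared channels", {
  cfg <- small_sim_config(p_bad_channel_dry = 0, p_bad_channel_gel = 0)
  dry <- simulate_subject(cfg, 1, "dry", "CHECK")$recordings$CHECK
  gel <- simulate_subject(cfg, 1, "gel", "CHECK")$recordings$CHECK
  pair <- harmonize_and_rereference(dry, gel)
  expect_identical(pair$dry$channel_labels, pair$gel$channel_labels)
  expect_length(pair$dry$channel_labels, 29)
  # re-referencing twice equals once (idempotence)
  pair2 <- harmonize_and_rereference(pair$dry, pair$gel)
  expect_equal(pair2$gel$data, pair$gel$data, tolerance = 1e-12)
})

test_that("re-referencing to an all-zero M2 channel is the identity", {
  gel <- simulate_subject(small_sim_config(), 1, "gel", "CHECK")$recordings$CHECK
  m2 <- match("M2", gel$channel_labels)
  gel$data[m2, ] <- 0
  before <- gel$data[-m2, ]
  pair <- harmonize_and_rereference(
    simulate_subject(small_sim_config(), 1, "dry", "CHECK")$recordings$CHECK, gel)
  shared <- pair$gel$channel_labels
  expect_equal(pair$gel$data,
               before[match(shared, setdiff(gel$channel_labels, "M2")), ],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("component decomposition reconstructs the data", {
  rec <- simulate_subject(small_sim_config(), 2, "dry", "EOEC")$recordings$EOEC
  rec <- filter_zero_phase(rec, "bandpass", 1, 48)
  dec <- decompose_components(rec)
  recon <- dec$mixing %*% dec$sources
  expect_lt(max(abs(recon - rec$data)), 1e-6)
  # removing nothing is the identity; removing everything zeroes the data
  same <- remove_components(rec, dec, integer(0))
  expect_lt(max(abs(same$data - rec$data)), 1e-6)
  none <- remove_components(rec, dec, seq_len(ncol(dec$mixing)))
  expect_lt(max(abs(none$data)), 1e-9)
  expect_error(remove_components(rec, dec, 999), "range")
})

test_that("the seeded blink component is identified and its removal lowers frontal variance", {
  cfg <- small_sim_config(blink_rate = 30, blink_amplitude = 150, seed = 9)
  sub <- simulate_subject(cfg, 1, "dry", "EOEC")
  rec <- filter_zero_phase(sub$recordings$EOEC, "bandpass", 1, 48)
  dec <- decompose_components(rec)
  blink <- identify_blink_component(dec)
  expect_false(is.na(blink))
  # selected component tracks the ground-truth blink onsets
  onsets <- sub$ground_truth$blink_onsets$EOEC
  src <- dec$sources[blink, ]
  src <- src * sign(sum(src^3))
  at_blinks <- src[onsets + round(0.15 * rec$sample_rate)]
  expect_gt(mean(at_blinks), 2 * stats::sd(src))
  # removal strictly decreases frontal-channel variance
  cleaned <- remove_components(rec, dec, blink)
  frontal <- match(c("Fp1", "Fp2"), rec$channel_labels)
  expect_lt(stats::var(cleaned$data[frontal[1], ]),
            stats::var(rec$data[frontal[1], ]))
})

test_that("no blink component is reported without blinks or frontality", {
  cfg <- small_sim_config(blink_rate = 0)
  rec <- filter_zero_phase(
    simulate_subject(cfg, 1, "dry", "EOEC")$recordings$EOEC, "bandpass", 1, 48)
  dec <- decompose_components(rec)
  expect_true(is.na(identify_blink_component(dec)))
  # a blink-like source with zero frontal energy is never selected
  labels <- shared_channels()
  frontal <- labels %in% c("Fp1", "Fp2", "F7", "F3", "F4", "F8")
  fs <- 256
  src <- numeric(60 * fs)
  for (on in seq(2, 58, by = 2) * fs) {
    src[on:(on + fs / 4)] <- 10
  }
  mixing <- matrix(as.numeric(!frontal), ncol = 1)
  dec0 <- structure(list(mixing = mixing, sources = matrix(src, 1),
                         center = numeric(29), channel_labels = labels,
                         sample_rate = fs),
                    class = "eeg_decomposition")
  expect_true(is.na(identify_blink_component(dec0)))
})
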