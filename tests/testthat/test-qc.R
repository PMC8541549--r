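test_that("global amplitude bounds catch flat and saturated channels", {
  fs <- 256
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  rec <- make_test_recording(list(rep(0, length(t)),
                                  100 * sin(2 * pi * 10 * t),
                                  10 * sin(2 * pi * 10 * t)), fs = fs)
  qc <- flag_bad_channels_global(rec)
  expect_identical(qc$channel_flags$kept, c(FALSE, FALSE, TRUE))
  expect_identical(qc$channel_flags$criterion[1:2],
                   c("flat-line", "high-amplitude"))
  # mean |A sin| = 2A/pi: 100 uV -> 63.7 (out), 10 uV -> 6.37 (in)
  expect_equal(mean(abs(rec$data[2, ])), 200 / pi, tolerance = 1e-3)
  expect_error(flag_bad_channels_global(
    new_recording(matrix(numeric(0), 1, 0), fs, "Cz")), "empty")
})

test_that("identical channels are never rejected by the mean + 2 SD rules", {
  fs <- 256
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  rec <- make_test_recording(matrix(rep(10 * sin(2 * pi * 10 * t), 29),
                                    29, byrow = TRUE), fs = fs)
  qc <- flag_bad_channels_task(rec, window_len = 0.5)
  expect_true(all(qc$channel_flags$kept))
})

test_that("a single high-amplitude channel is caught by the across-channel threshold", {
  fs <- 256
  set.seed(11)
  rows <- lapply(1:29, function(i) rnorm(8 * fs, sd = 5))
  rows[[29]] <- rnorm(8 * fs, sd = 50)   # 10x amplitude, still below 50 uV mean
  rec <- make_test_recording(rows, fs = fs)
  qc <- flag_bad_channels_task(rec, window_len = 0.5)
  expect_identical(which(!qc$channel_flags$kept), 29L)
  expect_identical(qc$channel_flags$criterion[29], "amplitude-outlier")
})

test_that("band-power outliers need at least two bands to be rejected", {
  fs <- 256
  n <- 8 * fs
  set.seed(12)
  bf_delta <- signal::butter(4, c(1, 4) / (fs / 2), type = "pass")
  bf_dt <- signal::butter(4, c(1, 8) / (fs / 2), type = "pass")
  narrow <- function(bf) {
    x <- signal::filtfilt(bf, rnorm(4 * n))[n:(2 * n - 1)]
    5 * x / sd(x)
  }
  rows <- lapply(1:29, function(i) rnorm(n, sd = 5))
  rows[[28]] <- narrow(bf_delta)   # all power in delta: 1 band only
  rows[[29]] <- narrow(bf_dt)      # power in delta + theta: 2 bands
  rec <- make_test_recording(rows, fs = fs)
  qc <- flag_bad_channels_task(rec, window_len = 0.5)
  expect_true(qc$channel_flags$kept[28])
  expect_false(qc$channel_flags$kept[29])
  expect_identical(qc$channel_flags$criterion[29], "band-power-outlier")
})

test_that("bad trials are flagged per channel against that channel's own units", {
  fs <- 256
  wl <- 128
  set.seed(13)
  arr <- array(rnorm(20 * 3 * wl, sd = 5), dim = c(20, 3, wl))
  arr[7, 2, ] <- arr[7, 2, ] * 10   # burst in one trial of one channel
  attr(arr, "sample_rate") <- fs
  dimnames(arr) <- list(NULL, c("Fz", "Cz", "Pz"), NULL)
  qc <- flag_bad_units(arr, band_set(c("delta", "theta", "alpha", "beta")), 2)
  expect_true(any(qc$unit_flags$unit == 7 & qc$unit_flags$channel == "Cz"))
  expect_false(any(qc$unit_flags$channel == "Fz" & qc$unit_flags$unit == 7))
  # identical units are never flagged
  same <- array(rep(sin(seq_len(wl) / 5), each = 20 * 3), dim = c(20, 3, wl))
  attr(same, "sample_rate") <- fs
  expect_identical(nrow(flag_bad_units(same)$unit_flags), 0L)
  expect_error(flag_bad_units(arr[1:2, , ]), "3 units")
})

test_that("a gamma-band spike window is flagged under the gamma-only criterion", {
  fs <- 256
  set.seed(14)
  arr <- array(rnorm(12 * 2 * fs, sd = 3), dim = c(12, 2, fs))
  t <- seq_len(fs) / fs
  arr[5, 1, ] <- arr[5, 1, ] + 20 * sin(2 * pi * 40 * t)
  attr(arr, "sample_rate") <- fs
  dimnames(arr) <- list(NULL, c("Fz", "Cz"), NULL)
  qc <- flag_bad_units(arr, band_set("gamma"), 1)
  expect_true(any(qc$unit_flags$unit == 5 & qc$unit_flags$channel == "Fz"))
})

test_that("channel reliability counts clean 1 s windows", {
  fs <- 256
  x <- rep(0, 10 * fs)
  rec0 <- make_test_recording(matrix(x, 1), fs = fs)
  expect_equal(unname(channel_reliability(rec0)), 100)
  x[3 * fs + 10] <- 500      # one 500 uV step in window 4 of 10
  rec1 <- make_test_recording(matrix(x, 1), fs = fs)
  expect_equal(unname(channel_reliability(rec1)), 90)
  set.seed(15)
  noisy <- make_test_recording(matrix(rnorm(10 * fs), 1), fs = fs)
  expect_equal(unname(channel_reliability(noisy, p2p_threshold = 0)), 0)
  expect_error(channel_reliability(make_test_recording(matrix(0, 1, 10), fs = fs)),
               "shorter")
})

test_that("rejection percentages follow channel-seconds arithmetic", {
  labels <- shared_channels()
  none <- new_qc_report(data.frame(label = labels, kept = TRUE,
                                   criterion = NA_character_),
                        duration_s = 100)
  s0 <- rejection_summary(none)
  expect_equal(s0$subject_pct, 0)
  expect_true(all(s0$per_channel$pct_rejected == 0))
  one <- new_qc_report(data.frame(label = labels, kept = labels != "T7",
                                  criterion = ifelse(labels == "T7", "flat-line", NA)),
                       duration_s = 100)
  s1 <- rejection_summary(one)
  expect_equal(s1$subject_pct, 100 / 29, tolerance = 1e-12)
  expect_equal(s1$per_channel$pct_rejected[labels == "T7"], 100)
  # unit flags on kept channels add unit-seconds
  units <- new_qc_report(
    data.frame(label = labels, kept = TRUE, criterion = NA_character_),
    unit_flags = data.frame(unit = 1:2, channel = c("Cz", "Cz"),
                            criterion = "amplitude"),
    duration_s = 50, unit_seconds = 0.5, n_units = 100)
  s2 <- rejection_summary(list(one, units))
  expected <- 100 * (100 + 2 * 0.5) / (29 * 150)
  expect_equal(s2$subject_pct, expected, tolerance = 1e-12)
})

test_that("simulated dry cohorts lose more data than gel cohorts", {
  cfg <- small_sim_config(n_subjects = 4, p_bad_channel_dry = 0.3,
                          p_bad_channel_gel = 0.02, seed = 21)
  pct <- sapply(c("dry", "gel"), function(sys) {
    mean(vapply(seq_len(cfg$n_subjects), function(s) {
      rec <- simulate_subject(cfg, s, sys, "CHECK")$recordings$CHECK
      rec <- filter_zero_phase(rec, "bandpass", 1, 48)
      rejection_summary(flag_bad_channels_task(rec, 0.5))$subject_pct
    }, 0))
  })
  expect_gt(pct["dry"], pct["gel"])
})

test_that("adding a flat corrupted channel never un-rejects an existing one", {
  # thresholds are recomputed with the new channel included, so this
  # checks that the recomputation does not unmask a clear outlier
  fs <- 128
  set.seed(31)
  violations <- 0
  for (i in 1:100) {
    rows <- lapply(1:12, function(j) rnorm(2 * fs, sd = 5))
    k <- sample(1:12, 1)
    rows[[k]] <- rows[[k]] * runif(1, 8, 12)
    rec_a <- make_test_recording(rows, fs = fs)
    before <- flag_bad_channels_task(rec_a, 0.5)$channel_flags
    rows[[13]] <- rnorm(2 * fs, sd = 0.05)   # flat-line corruption
    rec_b <- make_test_recording(rows, fs = fs)
    after <- flag_bad_channels_task(rec_b, 0.5)$channel_flags
    rejected_before <- before$label[!before$kept]
    rejected_after <- after$label[!after$kept]
    violations <- violations +
      as.integer(!all(rejected_before %in% rejected_after))
  }
  expect_equal(violations, 0)
})

test_that("criterion decisions match a naive reference implementation", {
  fs <- 128
  set.seed(32)
  for (i in 1:50) {
    n_ch <- sample(5:10, 1)
    rows <- lapply(seq_len(n_ch), function(j) rnorm(fs, sd = runif(1, 1, 30)))
    rec <- make_test_recording(rows, fs = fs,
                               labels = paste0("C", seq_len(n_ch)))
    qc <- flag_bad_channels_global(rec)
    # naive transcription of the amplitude rule
    for (j in seq_len(n_ch)) {
      m <- mean(abs(rows[[j]]))
      expect_identical(qc$channel_flags$kept[j], m >= 1 & m <= 50)
    }
    # naive mean + 2 SD amplitude outlier rule
    qct <- flag_bad_channels_task(rec, window_len = 0.25)
    amps <- vapply(rows, function(x) mean(abs(x)), 0)
    thr <- mean(amps) + 2 * sd(amps)
    for (j in seq_len(n_ch)) {
      if (amps[j] >= 1 && amps[j] <= 50) {
        naive_amp_out <- amps[j] > thr
        if (naive_amp_out) {
          expect_identical(qct$channel_flags$criterion[j], "amplitude-outlier")
        } else {
          expect_true(qct$channel_flags$kept[j] ||
                        qct$channel_flags$criterion[j] == "band-power-outlier")
        }
      }
    }
  }
})
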