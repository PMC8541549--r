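test_that("identical (seed, subject, system) reproduces bit-identical recordings", {
  cfg <- small_sim_config()
  a <- simulate_subject(cfg, 1, "dry")
  b <- simulate_subject(cfg, 1, "dry")
  for (task in names(a$recordings)) {
    expect_identical(a$recordings[[task]]$data, b$recordings[[task]]$data)
    expect_identical(a$recordings[[task]]$events, b$recordings[[task]]$events)
  }
  expect_identical(a$ground_truth, b$ground_truth)
  # different system: same latent scales, different data
  g <- simulate_subject(cfg, 1, "gel")
  expect_identical(a$ground_truth$scales, g$ground_truth$scales)
  expect_false(identical(a$recordings$CHECK$data[1:29, 1:100],
                         g$recordings$CHECK$data[1:29, 1:100]))
})

test_that("noise-free epoch-averaged VEP equals the injected template", {
  cfg <- noise_free_config()
  sub <- simulate_subject(cfg, 1, "dry", tasks = "CHECK")
  rec <- sub$recordings$CHECK
  ep <- extract_epochs(rec, -0.1, 0.4, c(-0.1, 0), event_label = "reversal")
  erp <- average_erp(ep)
  # injected template: fixed Gaussian field centered on Oz times the
  # N75/P100 bumps at their configured latencies
  pos <- montage_positions(rec$channel_labels)
  oz <- montage_positions("Oz")
  field <- exp(-((pos$x - oz$x)^2 + (pos$y - oz$y)^2) / (2 * 0.45^2))
  tt <- attr(erp, "times")
  bump <- -cfg$vep_amplitude["N75"] * exp(-(tt - 0.121)^2 / (2 * 0.012^2)) +
    cfg$vep_amplitude["P100"] * exp(-(tt - 0.152)^2 / (2 * 0.015^2))
  expected <- field %o% bump
  expect_lt(max(abs(erp - expected)), 1e-9)
})

test_that("noise-free ASSR concentrates spectral power at 40 Hz", {
  cfg <- noise_free_config(assr_amplitude = 1)
  sub <- simulate_subject(cfg, 1, "dry", tasks = "ASSR")
  rec <- sub$recordings$ASSR
  on <- rec$events$onset_sample[1]
  fs <- rec$sample_rate
  seg <- rec$data[, (on + fs + 1):(on + 12 * fs), drop = FALSE]
  psd <- welch_psd(seg, fs, 4, 0.75, rec$channel_labels)
  cz <- match("Cz", rec$channel_labels)
  p40 <- psd$power[cz, psd$freqs == 40]
  p43 <- psd$power[cz, psd$freqs == 43]
  expect_gt(p40, p43)
  expect_gt(p40, 100 * p43)
})

test_that("recovered 40 Hz power grows monotonically with injected amplitude", {
  # background low enough that the smallest injection is identifiable
  p40s <- vapply(c(0.1, 0.3, 1.0), function(A) {
    cfg <- small_sim_config(assr_amplitude = A, pink_noise_sd = 2,
                            white_noise_sd = 0.5, seed = 5)
    sub <- simulate_subject(cfg, 1, "dry", tasks = "ASSR")
    rec <- sub$recordings$ASSR
    fs <- rec$sample_rate
    segs <- lapply(rec$events$onset_sample, function(on) {
      rec$data[, (on + fs + 1):(on + 12 * fs), drop = FALSE]
    })
    psd <- welch_psd(segs, fs, 4, 0.75, rec$channel_labels)
    mean(psd$power[match(c("Fz", "Cz"), rec$channel_labels), psd$freqs == 40])
  }, 0)
  expect_true(all(diff(p40s) > 0))
})

test_that("eyes-closed alpha gain is detectable across a cohort", {
  cfg <- sim_config(n_subjects = 15, sample_rate = 128, eoec_n_cycles = 4,
                    alpha_ec_gain = 4, seed = 3)
  post <- c("Pz", "POz", "O1", "O2", "Oz", "P3", "P4")
  ec_power <- eo_power <- numeric(cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    rec <- simulate_subject(cfg, s, "gel", tasks = "EOEC")$recordings$EOEC
    fs <- rec$sample_rate
    chans <- match(intersect(post, rec$channel_labels), rec$channel_labels)
    pow <- function(lab, skip) {
      ons <- rec$events$onset_sample[rec$events$label == lab]
      segs <- lapply(ons, function(on) {
        rec$data[chans, (on + skip * fs + 1):(on + (skip + 3) * fs), drop = FALSE]
      })
      psd <- welch_psd(segs, fs, 1, 0.5)
      mean(band_power(psd, band_set("alpha")))
    }
    eo_power[s] <- pow("EO", 1)
    ec_power[s] <- pow("EC", 0)
  }
  wt <- wilcox.test(ec_power, eo_power, paired = TRUE, alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("cohorts pair sessions and report forced corruptions", {
  cfg <- small_sim_config(n_subjects = 2, p_bad_channel_dry = 1,
                          p_bad_channel_gel = 1)
  coh <- simulate_cohort(cfg, tasks = "CHECK")
  expect_length(coh$sessions, 2)
  for (s in 1:2) {
    expect_s3_class(coh$sessions[[s]]$dry$CHECK, "eeg_recording")
    expect_s3_class(coh$sessions[[s]]$gel$CHECK, "eeg_recording")
    expect_gte(nrow(coh$ground_truth[[s]]$dry$bad_channels), 1)
    expect_gte(nrow(coh$ground_truth[[s]]$gel$bad_channels), 1)
    expect_true(all(coh$ground_truth[[s]]$dry$bad_channels$label %in%
                      make_montage("dry")$label))
  }
  expect_error(simulate_cohort(small_sim_config(n_subjects = 1)))
})

test_that("config invariants are enforced", {
  expect_error(small_sim_config(pink_noise_sd = -1))
  expect_error(small_sim_config(p_bad_channel_dry = 1.5))
  expect_error(small_sim_config(sample_rate = 64))
  expect_error(simulate_subject(small_sim_config(), 99, "dry"))
})

test_that("cohort files are written with events, montage and ground truth", {
  cfg <- small_sim_config(n_subjects = 2, sample_rate = 256,
                          check_n_reversals = 10)
  out <- tempfile("cohort")
  coh <- simulate_cohort(cfg, tasks = "CHECK", out_dir = out,
                         format = "delimited")
  files <- list.files(out)
  expect_true("sub01_dry_CHECK.txt" %in% files)
  expect_true("sub02_gel_CHECK_events.tsv" %in% files)
  expect_true("sub01_gel_CHECK_montage.tsv" %in% files)
  expect_true("ground_truth.json" %in% files)
  back <- load_session(file.path(out, "sub01_dry_CHECK.txt"),
                       file.path(out, "sub01_dry_CHECK_events.tsv"))
  expect_identical(back$data, coh$sessions[[1]]$dry$CHECK$data)
})
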