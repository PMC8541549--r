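make_event_recording <- function(signal_rows, fs, onsets, label = "stim") {
  make_test_recording(signal_rows, fs = fs,
                      events = data.frame(onset_sample = as.integer(onsets),
                                          label = label))
}

test_that("epoch geometry and baseline correction follow the half-open contract", {
  fs <- 1024
  x <- rep(5, 10 * fs)   # constant channel
  rec <- make_event_recording(matrix(x, 1), fs, c(2, 4, 6) * fs)
  ep <- extract_epochs(rec, -0.1, 0.4, c(-0.1, 0), event_label = "stim")
  expect_identical(dim(ep$data), c(3L, 1L, 512L))   # 0.5 s at 1024 Hz
  expect_lt(max(abs(ep$data)), 1e-12)               # constant -> all zero
  expect_equal(ep$times[1], round(-0.1 * fs) / fs, tolerance = 1e-12)
})

test_that("full event counts yield full trial counts, edge events are dropped", {
  fs <- 256
  n_ev <- 300
  onsets <- round((10 + 0.45 * (0:(n_ev - 1))) * fs)
  rec <- make_event_recording(matrix(rnorm((150) * fs), 1), fs, onsets)
  ep <- extract_epochs(rec, -0.1, 0.4, c(-0.1, 0))
  expect_identical(dim(ep$data)[1], 300L)
  # event at the very end loses its epoch
  rec2 <- make_event_recording(matrix(rnorm(5 * fs), 1), fs,
                               c(2 * fs, round(4.9 * fs)))
  expect_warning(ep2 <- extract_epochs(rec2, -0.1, 0.4, c(-0.1, 0)), "edge")
  expect_identical(dim(ep2$data)[1], 1L)
})

test_that("averaging identical trials reproduces the trial; invalid channels go missing", {
  fs <- 256
  tmpl <- sin(seq(0, 4 * pi, length.out = 2 * fs))
  x <- c(rep(0, fs), rep(tmpl, 3), rep(0, fs))
  rec <- make_event_recording(rbind(x, x), fs, fs + (0:2) * 2 * fs)
  ep <- extract_epochs(rec, 0, 0.5, NULL)
  erp <- average_erp(ep)
  expect_equal(erp[1, ], ep$data[1, 1, ], tolerance = 1e-12)
  ep$valid[, 2] <- FALSE
  erp2 <- average_erp(ep)
  expect_true(all(is.na(erp2[2, ])))
  expect_false(anyNA(erp2[1, ]))
  ep$valid[, ] <- FALSE
  expect_error(average_erp(ep), "invalid")
})

test_that("averaging suppresses noise at the expected root-n rate", {
  fs <- 256
  set.seed(41)
  tmpl <- 5 * exp(-(seq(0, 0.5 - 1 / fs, by = 1 / fs) - 0.15)^2 / (2 * 0.02^2))
  n_tr <- 300
  total <- (n_tr + 2) * fs %/% 2
  x <- rnorm(total, sd = 3)
  onsets <- fs %/% 2 + (0:(n_tr - 1)) * fs %/% 2
  for (on in onsets) {
    idx <- on + seq_along(tmpl)
    x[idx] <- x[idx] + tmpl
  }
  rec <- make_event_recording(matrix(x, 1), fs, onsets)
  ep <- extract_epochs(rec, 0, 0.5, NULL)
  erp <- average_erp(ep)
  err_avg <- max(abs(erp[1, ] - tmpl))
  err_single <- max(abs(ep$data[1, 1, ] - tmpl))
  # root-n shrinkage up to a generous constant
  expect_lt(err_avg, err_single / sqrt(n_tr) * 6)
})

test_that("GFP equals the brute-force pairwise form", {
  # worked value: U = [2, 0, -2] -> sqrt(8/3)
  erp <- matrix(c(2, 0, -2), 3, 1)
  attr(erp, "times") <- 0
  g <- gfp_timecourse(erp)
  expect_equal(g$gfp, sqrt(8 / 3), tolerance = 1e-12)
  expect_equal(g$gfp, gfp_pairwise_oracle(c(2, 0, -2)), tolerance = 1e-12)
  set.seed(42)
  for (i in 1:100) {
    u <- rnorm(29, sd = runif(1, 0.1, 20))
    m <- matrix(u, 29, 1)
    attr(m, "times") <- 0
    expect_equal(gfp_timecourse(m)$gfp, gfp_pairwise_oracle(u),
                 tolerance = 1e-10)
  }
})

test_that("GFP is homogeneous and vanishes for uniform maps", {
  m <- matrix(rep(3.3, 5), 5, 1); attr(m, "times") <- 0
  expect_equal(gfp_timecourse(m)$gfp, 0)
  set.seed(43)
  u <- rnorm(10)
  m1 <- matrix(u, 10, 1); attr(m1, "times") <- 0
  m2 <- matrix(-2.5 * u, 10, 1); attr(m2, "times") <- 0
  expect_equal(gfp_timecourse(m2)$gfp, 2.5 * gfp_timecourse(m1)$gfp,
               tolerance = 1e-12)
  expect_error(gfp_timecourse(matrix(1, 1, 4)), "2 non-missing")
})

test_that("GFP comparison is rank-invariant and symmetric", {
  set.seed(44)
  a <- abs(rnorm(200)) + seq(0, 1, length.out = 200)
  ga <- structure(list(times = NULL, gfp = a, n_channels = 29),
                  class = "gfp_series")
  gb <- structure(list(times = NULL, gfp = a^3, n_channels = 29),
                  class = "gfp_series")
  same <- compare_gfp(ga, ga)
  expect_equal(same$rho, 1)
  expect_equal(same$rmsd, 0)
  mono <- compare_gfp(ga, gb)
  expect_equal(mono$rho, 1, tolerance = 1e-12)
  expect_gt(mono$rmsd, 0)
  expect_equal(compare_gfp(ga, gb)$rmsd, compare_gfp(gb, ga)$rmsd)
  expect_equal(compare_gfp(ga, gb)$rho, compare_gfp(gb, ga)$rho)
  flat <- structure(list(times = NULL, gfp = rep(1, 200), n_channels = 29),
                    class = "gfp_series")
  expect_warning(r <- compare_gfp(ga, flat), "undefined")
  expect_true(is.na(r$rho))
  expect_error(compare_gfp(ga, structure(list(gfp = a[1:10]), class = "gfp_series")))
})

test_that("GFP peaks are located inside their search windows, earliest on ties", {
  times <- seq(-0.1, 0.4, by = 1 / 1024)
  gfp1 <- exp(-(times - 0.15)^2 / (2 * 0.02^2))
  g1 <- structure(list(times = times, gfp = gfp1, n_channels = 29),
                  class = "gfp_series")
  pk <- find_gfp_peaks(g1, list(P = c(0.1, 0.2)))
  expect_equal(pk$latency, 0.15, tolerance = 1.5 / 1024)
  two <- exp(-(times - 0.12)^2 / (2 * 0.01^2)) +
    0.8 * exp(-(times - 0.16)^2 / (2 * 0.01^2))
  g2 <- structure(list(times = times, gfp = two, n_channels = 29),
                  class = "gfp_series")
  pks <- find_gfp_peaks(g2, list(N75 = c(0.09, 0.14), P100 = c(0.14, 0.19)))
  expect_identical(pks$component, c("N75", "P100"))
  expect_lt(pks$latency[1], pks$latency[2])
  # tie-break to the earliest sample
  gt <- structure(list(times = times, gfp = rep(1, length(times)),
                       n_channels = 29), class = "gfp_series")
  expect_equal(find_gfp_peaks(gt, list(A = c(0.1, 0.2)))$latency,
               times[times >= 0.1][1])
})

test_that("baseline correction commutes with averaging", {
  fs <- 256
  set.seed(45)
  x <- matrix(rnorm(3 * 20 * fs), 3)
  rec <- make_event_recording(x, fs, (2:15) * fs)
  ep_bc <- extract_epochs(rec, -0.1, 0.4, c(-0.1, 0))
  erp_bc <- average_erp(ep_bc)
  ep_raw <- extract_epochs(rec, -0.1, 0.4, NULL)
  erp_raw <- average_erp(ep_raw)
  bidx <- ep_raw$times >= -0.1 & ep_raw$times < 0
  erp_then_bc <- erp_raw - rowMeans(erp_raw[, bidx])
  expect_equal(erp_bc, erp_then_bc, tolerance = 1e-10, ignore_attr = TRUE)
})
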