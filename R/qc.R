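# Multi-criteria rejection cascade: channels (global and per task), then
# trials/windows, plus the dry-cap channel-reliability metric and the
# rejected-data accounting in channel-seconds.
#
# All mean + 2 SD thresholds are single-pass, include the candidate in
# the statistics, use the sample SD (n - 1), and reject on strict ">"
# (so identical channels are never rejected: SD = 0).

#' Canonical EEG frequency bands
#'
#' delta 1-4, theta 4-8, alpha 8-14, beta 14-30, gamma 30-48 Hz.
#'
#' @param names subset of band names to return, in order.
#' @return named list of `c(low, high)` intervals in Hz.
#' @export
band_set <- function(names = c("delta", "theta", "alpha", "beta", "gamma")) {
  all <- list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 14),
              beta = c(14, 30), gamma = c(30, 48))
  stopifnot(all(names %in% names(all)))
  all[names]
}

#' Construct a QC report
#'
#' Container for the rejection cascade's decisions: per-channel flags
#' with the first-triggering criterion, flagged (trial/window, channel)
#' pairs, and the bookkeeping needed to express rejections in
#' channel-seconds.
#'
#' @param channel_flags data frame with `label`, `kept` (logical),
#'   `criterion` (`NA` for kept channels).
#' @param unit_flags data frame of flagged units (`unit`, `channel`,
#'   `criterion`), or `NULL` for none.
#' @param duration_s accounted duration per channel, seconds.
#' @param unit_seconds duration of one trial/window, seconds.
#' @param n_units number of units per channel.
#' @param task task code, if any.
#' @return object of class `qc_report`.
#' @export
new_qc_report <- function(channel_flags, unit_flags = NULL, duration_s = 0,
                          unit_seconds = 0, n_units = 0, task = NA_character_) {
  if (is.null(unit_flags)) {
    unit_flags <- data.frame(unit = integer(0), channel = character(0),
                             criterion = character(0), stringsAsFactors = FALSE)
  }
  structure(list(channel_flags = channel_flags, unit_flags = unit_flags,
                 duration_s = duration_s, unit_seconds = unit_seconds,
                 n_units = n_units, task = task),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> task %s: %d/%d channels rejected, %d unit flags\n",
              x$task, sum(!x$channel_flags$kept), nrow(x$channel_flags),
              nrow(x$unit_flags)))
  invisible(x)
}

# Hann-tapered per-band average power of one channel over nonoverlapping
# windows of `wl` samples.
.window_band_power <- function(x, fs, wl, bands) {
  n_win <- length(x) %/% wl
  if (n_win < 1) stop("window length exceeds the available data")
  w <- 0.5 * (1 - cos(2 * pi * (0:(wl - 1)) / wl))
  scale <- 2 / (fs * sum(w^2))
  freqs <- (0:(wl %/% 2)) * fs / wl
  acc <- matrix(0, n_win, length(freqs))
  for (k in seq_len(n_win)) {
    seg <- x[((k - 1) * wl + 1):(k * wl)]
    sp <- Mod(stats::fft(seg * w)[1:(wl %/% 2 + 1)])^2 * scale
    acc[k, ] <- sp
  }
  pmean <- colMeans(acc)
  vapply(bands, function(b) mean(pmean[freqs >= b[1] & freqs < b[2]]), 0)
}

#' Flag globally bad channels by average amplitude
#'
#' A channel is rejected when its mean absolute amplitude is below 1
#' microvolt (flat line) or above 50 microvolts.
#'
#' @param rec a filtered `eeg_recording`.
#' @param flat_thresh,amp_thresh the two amplitude bounds, microvolts.
#' @return a `qc_report`.
#' @export
flag_bad_channels_global <- function(rec, flat_thresh = 1, amp_thresh = 50) {
  if (ncol(rec$data) == 0) stop("empty recording")
  amp <- rowMeans(abs(rec$data))
  crit <- ifelse(amp < flat_thresh, "flat-line",
                 ifelse(amp > amp_thresh, "high-amplitude", NA))
  flags <- data.frame(label = rec$channel_labels, kept = is.na(crit),
                      criterion = crit, stringsAsFactors = FALSE)
  new_qc_report(flags, duration_s = duration_s(rec), task = rec$task)
}

#' Flag bad channels within one task segment
#'
#' Three criteria, first trigger recorded: (1) task-mean absolute
#' amplitude below 1 or above 50 microvolts; (2) task-mean absolute
#' amplitude above mean + 2 SD over all channels; (3) Hann-windowed
#' average band power above mean + 2 SD over all channels in at least
#' `min_bands` of the five canonical bands. The window length is
#' task-specific (VEP 0.5 s, AEP 0.8 s, 40 Hz-ASSR 11 s, EOEC 3 s).
#'
#' @param rec the task segment as an `eeg_recording` (extracted with its
#'   surrounding padding).
#' @param window_len Hann window length for criterion 3, seconds.
#' @param bands band list from [band_set()].
#' @param min_bands how many bands must exceed their threshold.
#' @param flat_thresh,amp_thresh absolute amplitude bounds, microvolts.
#' @return a `qc_report`.
#' @export
flag_bad_channels_task <- function(rec, window_len, bands = band_set(),
                                   min_bands = 2,
                                   flat_thresh = 1, amp_thresh = 50) {
  wl <- round(window_len * rec$sample_rate)
  if (wl > ncol(rec$data)) stop("window length exceeds the task duration")
  amp <- rowMeans(abs(rec$data))
  crit <- rep(NA_character_, nrow(rec$data))
  crit[amp < flat_thresh | amp > amp_thresh] <- "amplitude-bounds"
  thr_amp <- mean(amp) + 2 * stats::sd(amp)
  crit[is.na(crit) & amp > thr_amp] <- "amplitude-outlier"
  bp <- t(vapply(seq_len(nrow(rec$data)),
                 function(i) .window_band_power(rec$data[i, ], rec$sample_rate,
                                                wl, bands),
                 numeric(length(bands))))
  n_exceed <- rep(0L, nrow(rec$data))
  for (b in seq_along(bands)) {
    thr <- mean(bp[, b]) + 2 * stats::sd(bp[, b])
    n_exceed <- n_exceed + (bp[, b] > thr)
  }
  crit[is.na(crit) & n_exceed >= min_bands] <- "band-power-outlier"
  flags <- data.frame(label = rec$channel_labels, kept = is.na(crit),
                      criterion = crit, stringsAsFactors = FALSE)
  new_qc_report(flags, duration_s = duration_s(rec), task = rec$task)
}

#' Flag bad trials or windows per channel
#'
#' Thresholds are computed per channel across that channel's own units
#' (mean + 2 SD over all trials, or over all windows): a unit is flagged
#' when (1) its mean absolute amplitude exceeds the amplitude threshold,
#' or (2) its Hann-tapered band power exceeds the per-band threshold in
#' at least `min_bands` bands. Band subsets follow the task (VEP/AEP:
#' delta-beta, 2 bands; ASSR windows: gamma only, 1 band; EOEC windows:
#' all five, 2 bands).
#'
#' @param epochs an `epoch_set` (see [extract_epochs()]) or a plain
#'   trials x channels x samples array with attribute `sample_rate`.
#' @param bands band list from [band_set()].
#' @param min_bands bands needed to trigger the power criterion.
#' @return a `qc_report` whose `unit_flags` rows are the flagged
#'   (unit, channel) pairs.
#' @export
flag_bad_units <- function(epochs, bands = band_set(c("delta", "theta",
                                                      "alpha", "beta")),
                           min_bands = 2) {
  if (inherits(epochs, "epoch_set")) {
    arr <- epochs$data; fs <- epochs$sample_rate
    labels <- epochs$channel_labels
  } else {
    arr <- epochs; fs <- attr(epochs, "sample_rate")
    labels <- dimnames(arr)[[2]]
    if (is.null(labels)) labels <- paste0("ch", seq_len(dim(arr)[2]))
  }
  n_units <- dim(arr)[1]; n_ch <- dim(arr)[2]; wl <- dim(arr)[3]
  if (n_units < 3) stop("need at least 3 units per channel for a stable SD")
  w <- 0.5 * (1 - cos(2 * pi * (0:(wl - 1)) / wl))
  scale <- 2 / (fs * sum(w^2))
  freqs <- (0:(wl %/% 2)) * fs / wl
  bidx <- lapply(bands, function(b) which(freqs >= b[1] & freqs < b[2]))
  flags <- list()
  for (c_i in seq_len(n_ch)) {
    xs <- arr[, c_i, , drop = TRUE]
    if (is.null(dim(xs))) xs <- matrix(xs, nrow = n_units)
    amp <- rowMeans(abs(xs))
    thr_amp <- mean(amp) + 2 * stats::sd(amp)
    bp <- matrix(0, n_units, length(bands))
    for (u in seq_len(n_units)) {
      sp <- Mod(stats::fft(xs[u, ] * w)[1:(wl %/% 2 + 1)])^2 * scale
      bp[u, ] <- vapply(bidx, function(ii) mean(sp[ii]), 0)
    }
    n_exceed <- rep(0L, n_units)
    for (b in seq_along(bands)) {
      thr <- mean(bp[, b]) + 2 * stats::sd(bp[, b])
      n_exceed <- n_exceed + (bp[, b] > thr)
    }
    bad_amp <- amp > thr_amp
    bad_pow <- n_exceed >= min_bands
    for (u in which(bad_amp | bad_pow)) {
      flags[[length(flags) + 1]] <- data.frame(
        unit = u, channel = labels[c_i],
        criterion = if (bad_amp[u]) "amplitude" else "band-power",
        stringsAsFactors = FALSE)
    }
  }
  unit_flags <- if (length(flags)) do.call(rbind, flags) else NULL
  channel_flags <- data.frame(label = labels, kept = TRUE,
                              criterion = NA_character_,
                              stringsAsFactors = FALSE)
  new_qc_report(channel_flags, unit_flags,
                duration_s = n_units * wl / fs,
                unit_seconds = wl / fs, n_units = n_units)
}

#' Per-channel signal reliability
#'
#' Percentage of nonoverlapping sliding windows in which the channel's
#' peak-to-peak amplitude stays at or below the threshold (default
#' 400 microvolts in a 1 s window); the acquisition aim for the dry cap
#' is at least 80 % per channel.
#'
#' @param rec a continuous `eeg_recording`.
#' @param p2p_threshold peak-to-peak bound, microvolts.
#' @param window window length, seconds.
#' @return named numeric vector, percent reliable per channel.
#' @export
channel_reliability <- function(rec, p2p_threshold = 400, window = 1) {
  wl <- round(window * rec$sample_rate)
  n_win <- ncol(rec$data) %/% wl
  if (n_win < 1) stop("recording shorter than one window")
  ok <- matrix(FALSE, nrow(rec$data), n_win)
  for (k in seq_len(n_win)) {
    seg <- rec$data[, ((k - 1) * wl + 1):(k * wl), drop = FALSE]
    p2p <- apply(seg, 1, function(v) max(v) - min(v))
    ok[, k] <- p2p <= p2p_threshold
  }
  stats::setNames(100 * rowMeans(ok), rec$channel_labels)
}

#' Aggregate rejection percentages in channel-seconds
#'
#' A fully rejected channel contributes its whole task duration; a
#' flagged unit contributes its unit length on its channel. Percentages
#' are rejected channel-seconds over total channel-seconds, per channel
#' and for the whole subject.
#'
#' @param reports a list of `qc_report`s (or a single one). Reports for
#'   the same channels are pooled across tasks.
#' @return list with `per_channel` (data frame `label`,
#'   `pct_rejected`) and `subject_pct` (scalar percentage).
#' @export
rejection_summary <- function(reports) {
  if (inherits(reports, "qc_report")) reports <- list(reports)
  if (!length(reports)) stop("need at least one report")
  labels <- unique(unlist(lapply(reports, function(r) r$channel_flags$label)))
  rej <- stats::setNames(numeric(length(labels)), labels)
  tot <- stats::setNames(numeric(length(labels)), labels)
  for (r in reports) {
    cf <- r$channel_flags
    tot[cf$label] <- tot[cf$label] + r$duration_s
    rejected <- cf$label[!cf$kept]
    rej[rejected] <- rej[rejected] + r$duration_s
    if (nrow(r$unit_flags)) {
      kept <- cf$label[cf$kept]
      uf <- r$unit_flags[r$unit_flags$channel %in% kept, , drop = FALSE]
      if (nrow(uf)) {
        cnt <- table(uf$channel)
        rej[names(cnt)] <- rej[names(cnt)] + as.numeric(cnt) * r$unit_seconds
      }
    }
  }
  per_channel <- data.frame(label = labels,
                            pct_rejected = 100 * rej / pmax(tot, 1e-12),
                            stringsAsFactors = FALSE)
  list(per_channel = per_channel,
       subject_pct = 100 * sum(rej) / max(sum(tot), 1e-12))
}
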