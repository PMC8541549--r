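# Time-domain analysis: epoching with per-trial baseline correction, ERP
# averaging over valid (trial, channel) entries, global field power and
# its between-system comparison (Spearman COR, RMSD), and GFP component
# peak extraction.

#' Extract stimulus-locked epochs
#'
#' Epochs are half-open sample intervals of length
#' `round((tmax - tmin) * fs)` starting at
#' `onset + round(tmin * fs)`. Baseline correction subtracts, per trial
#' and channel, the mean over the baseline window (default [-0.1, 0) s).
#' Events too close to the recording edge are dropped with a warning.
#'
#' @param rec an `eeg_recording` (for evoked analyses: 1-30 Hz filtered).
#' @param tmin,tmax epoch limits relative to the event, seconds.
#' @param baseline `c(start, stop)` of the baseline window in seconds, or
#'   `NULL` to skip baseline correction.
#' @param event_label only events with this label are used (`NULL`: all).
#' @return an `epoch_set`: list with `data`
#'   (trials x channels x samples), `times` (s, relative to the event),
#'   `valid` (trials x channels logical), `sample_rate`,
#'   `channel_labels`.
#' @export
extract_epochs <- function(rec, tmin = -0.1, tmax = 0.4,
                           baseline = c(-0.1, 0), event_label = NULL) {
  fs <- rec$sample_rate
  ev <- rec$events
  if (!is.null(event_label)) ev <- ev[ev$label %in% event_label, , drop = FALSE]
  if (!nrow(ev)) stop("no matching events")
  n_epoch <- round((tmax - tmin) * fs)
  offset <- round(tmin * fs)
  starts <- ev$onset_sample + offset
  ok <- starts >= 0 & (starts + n_epoch) <= ncol(rec$data)
  if (any(!ok)) {
    warning(sum(!ok), " event(s) too close to the recording edge; dropped")
  }
  starts <- starts[ok]
  if (!length(starts)) stop("no complete epochs")
  n_ch <- nrow(rec$data)
  arr <- array(0, dim = c(length(starts), n_ch, n_epoch))
  for (k in seq_along(starts)) {
    arr[k, , ] <- rec$data[, (starts[k] + 1):(starts[k] + n_epoch)]
  }
  times <- (offset + 0:(n_epoch - 1)) / fs
  if (!is.null(baseline)) {
    bidx <- which(times >= baseline[1] & times < baseline[2])
    if (!length(bidx)) stop("baseline window outside the epoch")
    bmean <- apply(arr[, , bidx, drop = FALSE], c(1, 2), mean)
    arr <- arr - as.vector(bmean)   # recycles over the 3rd dimension
  }
  structure(list(data = arr, times = times,
                 valid = matrix(TRUE, length(starts), n_ch),
                 sample_rate = fs, channel_labels = rec$channel_labels),
            class = "epoch_set")
}

#' Mark flagged (trial, channel) entries of an epoch set invalid
#'
#' @param epochs an `epoch_set`.
#' @param qc a `qc_report` from [flag_bad_units()] on the same epochs.
#' @return the epoch set with its validity mask updated.
#' @export
apply_unit_flags <- function(epochs, qc) {
  uf <- qc$unit_flags
  for (k in seq_len(nrow(uf))) {
    c_i <- match(uf$channel[k], epochs$channel_labels)
    if (!is.na(c_i)) epochs$valid[uf$unit[k], c_i] <- FALSE
  }
  epochs
}

#' Average epochs into an ERP
#'
#' Per channel, the mean over its valid trials; channels without any
#' valid trial become rows of `NA`.
#'
#' @param epochs an `epoch_set`.
#' @return matrix channels x samples (microvolts) with `times` and
#'   `sample_rate` attributes.
#' @export
average_erp <- function(epochs) {
  n_ch <- dim(epochs$data)[2]
  if (!any(epochs$valid)) stop("all trials are invalid")
  out <- matrix(NA_real_, n_ch, dim(epochs$data)[3])
  for (c_i in seq_len(n_ch)) {
    tr <- which(epochs$valid[, c_i])
    if (length(tr)) {
      xs <- matrix(epochs$data[tr, c_i, ], nrow = length(tr))
      out[c_i, ] <- colMeans(xs)
    }
  }
  rownames(out) <- epochs$channel_labels
  attr(out, "times") <- epochs$times
  attr(out, "sample_rate") <- epochs$sample_rate
  out
}

#' Global field power over time
#'
#' The spatial standard deviation of the instantaneous potential over the
#' `n` non-missing channels, equal to the normalized pairwise form
#' `sqrt(sum_ij (U_i - U_j)^2 / (2 n^2))` (population variance, 1/n).
#'
#' @param erp channels x samples matrix (from [average_erp()]).
#' @return list of class `gfp_series` with `times`, `gfp`
#'   (microvolts, one value per sample) and `n_channels`.
#' @export
gfp_timecourse <- function(erp) {
  keep <- !apply(erp, 1, anyNA)
  if (sum(keep) < 2) stop("need at least 2 non-missing channels")
  x <- erp[keep, , drop = FALSE]
  mu <- colMeans(x)
  gfp <- sqrt(colMeans(sweep(x, 2, mu)^2))
  structure(list(times = attr(erp, "times"), gfp = gfp,
                 n_channels = sum(keep)),
            class = "gfp_series")
}

#' Compare two GFP time courses
#'
#' Spearman rank correlation (COR; average ranks on ties) and root mean
#' square deviation (RMSD, microvolts) between two series on identical
#' time axes. A constant series leaves the correlation undefined, which
#' is reported as `NA` with a warning.
#'
#' @param gfp_a,gfp_b `gfp_series` objects with identical time axes.
#' @return list with `rho` and `rmsd`.
#' @export
compare_gfp <- function(gfp_a, gfp_b) {
  if (length(gfp_a$gfp) != length(gfp_b$gfp)) stop("length mismatch")
  if (!is.null(gfp_a$times) && !is.null(gfp_b$times) &&
      max(abs(gfp_a$times - gfp_b$times)) > 1e-9) {
    stop("time axes differ")
  }
  a <- gfp_a$gfp; b <- gfp_b$gfp
  rho <- if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant GFP series: Spearman correlation undefined")
    NA_real_
  } else {
    stats::cor(a, b, method = "spearman")
  }
  list(rho = rho, rmsd = sqrt(mean((a - b)^2)))
}

#' Default GFP component search windows
#'
#' Windows (seconds, post-stimulus) for the two main components of the
#' pattern-reversal VEP (N75, P100) and the auditory N1/P1, wide enough
#' to absorb the constant stimulus-presentation delay of the setup
#' (about 50 ms for the visual, 100 ms for the auditory pathway).
#'
#' @param task `"CHECK"` (VEP) or `"ASSR"` (AEP).
#' @return named list of `c(start, stop)` windows.
#' @export
gfp_component_windows <- function(task = c("CHECK", "ASSR")) {
  task <- match.arg(task)
  switch(task,
         CHECK = list(N75 = c(0.09, 0.14), P100 = c(0.13, 0.19)),
         ASSR = list(N1 = c(0.25, 0.36), P1 = c(0.36, 0.46)))
}

#' Locate GFP component peaks
#'
#' Per component window, the maximum of the GFP series; ties break to the
#' earliest time point.
#'
#' @param gfp a `gfp_series`.
#' @param search_windows named list of `c(start, stop)` windows in
#'   seconds, e.g. [gfp_component_windows()].
#' @return data frame with columns `component`, `amplitude`
#'   (microvolts), `latency` (s).
#' @export
find_gfp_peaks <- function(gfp, search_windows) {
  rows <- lapply(names(search_windows), function(nm) {
    w <- search_windows[[nm]]
    idx <- which(gfp$times >= w[1] & gfp$times <= w[2])
    if (!length(idx)) stop("empty search window for component ", nm)
    k <- idx[which.max(gfp$gfp[idx])]
    data.frame(component = nm, amplitude = gfp$gfp[k],
               latency = gfp$times[k], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
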