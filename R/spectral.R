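# Frequency-domain analysis: Welch PSD with Hann tapering and one-sided
# density scaling, per-channel Z-standardization across frequency, band
# power, and the 40 Hz auditory steady-state response metrics (power at
# the 40 Hz bin and its SNR against the 35-39 / 41-45 Hz flanks).

#' Welch power spectral density
#'
#' Hann-tapered, overlap-averaged periodograms, averaged with equal
#' weights over all windows of all supplied segments. One-sided density
#' scaling in microvolts^2/Hz; the native frequency resolution is
#' `1/window_len`. With the ASSR settings (4 s window, 75 % overlap) the
#' grid contains every bin of the 0.5 Hz-spaced 35-45 Hz analysis strip
#' read by [assr_metrics()]: the 40 Hz signal bin plus 20 noise bins.
#'
#' @param segments a channels x samples matrix, or a list of such
#'   matrices (e.g. surviving trials). All segments must share the
#'   channel count.
#' @param sample_rate Hz.
#' @param window_len Hann window length, seconds.
#' @param overlap window overlap as a fraction in [0, 1).
#' @param channel_labels optional labels for the rows.
#' @return object of class `psd_result`: `freqs` (Hz), `power`
#'   (channels x freqs), `window_len`, `overlap`, `sample_rate`,
#'   `n_windows`, and (after [standardize_psd()]) `z` and `z_range`.
#' @export
welch_psd <- function(segments, sample_rate, window_len, overlap = 0.5,
                      channel_labels = NULL) {
  if (is.matrix(segments)) segments <- list(segments)
  if (!length(segments)) stop("no surviving segments")
  wl <- round(window_len * sample_rate)
  hop <- max(1L, round(wl * (1 - overlap)))
  n_ch <- nrow(segments[[1]])
  w <- 0.5 * (1 - cos(2 * pi * (0:(wl - 1)) / wl))
  scale <- 2 / (sample_rate * sum(w^2))
  nf <- wl %/% 2 + 1
  freqs <- (0:(wl %/% 2)) * sample_rate / wl
  acc <- matrix(0, n_ch, nf)
  n_win <- 0L
  for (seg in segments) {
    if (nrow(seg) != n_ch) stop("segments disagree in channel count")
    if (ncol(seg) < wl) next
    starts <- seq(1, ncol(seg) - wl + 1, by = hop)
    for (s0 in starts) {
      x <- seg[, s0:(s0 + wl - 1), drop = FALSE] * rep(w, each = n_ch)
      sp <- Mod(t(stats::mvfft(t(x))))^2
      sp <- sp[, 1:nf, drop = FALSE] * scale
      sp[, 1] <- sp[, 1] / 2                       # DC not doubled
      if (wl %% 2 == 0) sp[, nf] <- sp[, nf] / 2   # Nyquist not doubled
      acc <- acc + sp
      n_win <- n_win + 1L
    }
  }
  if (n_win == 0L) stop("no segment is at least one window long")
  power <- acc / n_win
  rownames(power) <- channel_labels
  structure(list(freqs = freqs, power = power, window_len = window_len,
                 overlap = overlap, sample_rate = sample_rate,
                 n_windows = n_win, z = NULL, z_range = NULL,
                 channel_labels = channel_labels),
            class = "psd_result")
}

#' Z-standardize a PSD across frequency
#'
#' Per channel, `z(f) = (P(f) - mean) / SD` with mean and sample SD taken
#' over the bins inside `range` only. The result is invariant to
#' per-channel affine transforms `a * P + b` (a > 0) of the spectrum.
#'
#' @param psd a `psd_result`.
#' @param range `c(low, high)` Hz; bins with `low <= f <= high` enter the
#'   standardization (ASSR: 35-45 Hz; eyes-open/closed: 1-48 Hz).
#' @return the `psd_result` with `z` (channels x in-range bins) and
#'   `z_freqs` filled in.
#' @export
standardize_psd <- function(psd, range) {
  idx <- which(psd$freqs >= range[1] & psd$freqs <= range[2])
  if (!length(idx)) stop("standardization range outside the frequency grid")
  p <- psd$power[, idx, drop = FALSE]
  mu <- rowMeans(p)
  sdv <- apply(p, 1, stats::sd)
  finite <- is.finite(sdv)
  if (any(sdv[finite] < 1e-300)) stop("constant spectrum: Z-score undefined")
  psd$z <- sweep(sweep(p, 1, mu), 1, sdv, "/")
  rownames(psd$z) <- rownames(psd$power)
  psd$z_freqs <- psd$freqs[idx]
  psd$z_range <- range
  psd
}

#' Mean band power per channel
#'
#' Mean of the PSD bins whose center lies in `[low, high)` of each band;
#' the last band is closed at its upper edge.
#'
#' @param psd a `psd_result`.
#' @param bands band list from [band_set()].
#' @param use `"absolute"` (microvolts^2/Hz) or `"z"` (requires
#'   [standardize_psd()] first).
#' @return matrix channels x bands.
#' @export
band_power <- function(psd, bands = band_set(), use = c("absolute", "z")) {
  use <- match.arg(use)
  if (use == "z") {
    if (is.null(psd$z)) stop("standardize_psd() must be applied before use = 'z'")
    p <- psd$z; f <- psd$z_freqs
  } else {
    p <- psd$power; f <- psd$freqs
  }
  out <- matrix(NA_real_, nrow(p), length(bands),
                dimnames = list(rownames(p), names(bands)))
  for (b in seq_along(bands)) {
    lim <- bands[[b]]
    sel <- if (b == length(bands)) f >= lim[1] & f <= lim[2] else
      f >= lim[1] & f < lim[2]
    if (!any(sel)) stop("band ", names(bands)[b], " is empty on this grid")
    out[, b] <- rowMeans(p[, sel, drop = FALSE])
  }
  out
}

#' 40 Hz steady-state response power and SNR
#'
#' `p40` is the PSD value at the 40.0 Hz bin; the SNR divides it by the
#' sample SD of the PSD over the noise bins of the 35-45 Hz analysis
#' strip. That strip is sampled on a 0.5 Hz grid (21 bins), and the
#' noise set is every bin except the 40 Hz signal bin (20 bins). Both
#' metrics are computed from the absolute spectrum and, when present,
#' from the standardized one. The SNR is invariant to a global rescaling
#' of the spectrum.
#'
#' @param psd a `psd_result` on a grid containing the 40 Hz bin (use the
#'   4 s / 75 % overlap settings).
#' @param signal_freq signal bin frequency (default 40 Hz).
#' @param noise_freqs noise bin frequencies (default the 0.5 Hz grid over
#'   35-45 Hz without the signal bin).
#' @return list with `per_channel` (data frame: `channel`, `p40`, `snr`,
#'   and `p40_z`, `snr_z` when a standardized twin exists) and the
#'   channel means `p40_mean`, `snr_mean`, `p40_z_mean`, `snr_z_mean`.
#' @export
assr_metrics <- function(psd, signal_freq = 40,
                         noise_freqs = setdiff(seq(35, 45, 0.5), 40)) {
  k <- which(abs(psd$freqs - signal_freq) < 1e-9)
  if (length(k) != 1) stop("frequency grid lacks the ", signal_freq, " Hz bin")
  nidx <- match(noise_freqs, psd$freqs)
  if (anyNA(nidx)) stop("frequency grid lacks some noise bins")
  one <- function(p, ks, ns) {
    p40 <- p[, ks]
    nsd <- apply(p[, ns, drop = FALSE], 1, stats::sd)
    snr <- ifelse(nsd > 0, p40 / nsd, NA_real_)
    if (any(nsd == 0)) warning("noise-band SD is zero for some channel; SNR reported as NA")
    list(p40 = p40, snr = snr)
  }
  ab <- one(psd$power, k, nidx)
  labels <- rownames(psd$power)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(psd$power)))
  per <- data.frame(channel = labels, p40 = ab$p40, snr = ab$snr,
                    stringsAsFactors = FALSE)
  out <- list(per_channel = per,
              p40_mean = mean(ab$p40, na.rm = TRUE),
              snr_mean = mean(ab$snr, na.rm = TRUE))
  if (!is.null(psd$z)) {
    kz <- which(abs(psd$z_freqs - signal_freq) < 1e-9)
    nz <- match(noise_freqs, psd$z_freqs)
    if (length(kz) == 1 && !anyNA(nz)) {
      zb <- one(psd$z, kz, nz)
      out$per_channel$p40_z <- zb$p40
      out$per_channel$snr_z <- zb$snr
      out$p40_z_mean <- mean(zb$p40, na.rm = TRUE)
      out$snr_z_mean <- mean(zb$snr, na.rm = TRUE)
    }
  }
  out
}
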