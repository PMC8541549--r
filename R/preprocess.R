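# Preprocessing: zero-phase Butterworth filtering, channel harmonization
# with mastoid re-referencing, and blink-component identification/removal
# on top of any linear decomposition that reconstructs the data.

#' Zero-phase Butterworth filter
#'
#' Designs a Butterworth filter of the stated base order and applies it
#' forward and backward (`signal::filtfilt`), which cancels the phase
#' response and squares the magnitude response. The default analysis
#' filters are a 2nd-order 1-48 Hz bandpass followed by a 2nd-order
#' 48-52 Hz bandstop for line-noise removal.
#'
#' @param rec an `eeg_recording`.
#' @param kind `"bandpass"` or `"bandstop"`.
#' @param low,high corner frequencies, Hz (`0 < low < high < fs/2`).
#' @param order base filter order before the forward-backward pass.
#' @return the filtered recording (same shape, same metadata).
#' @export
filter_zero_phase <- function(rec, kind = c("bandpass", "bandstop"),
                              low, high, order = 2) {
  kind <- match.arg(kind)
  fs <- rec$sample_rate
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("filter corners must satisfy 0 < low < high < sample_rate/2")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2),
                       type = if (kind == "bandpass") "pass" else "stop")
  for (i in seq_len(nrow(rec$data))) {
    rec$data[i, ] <- signal::filtfilt(bf, rec$data[i, ])
  }
  rec
}

#' Harmonize a dry/gel recording pair to the shared channels
#'
#' Restricts both recordings to their common scalp channels (the expected
#' 29-channel intersection of the two caps; anything else triggers a
#' warning and proceeds with the actual intersection, in shared-montage
#' order) and sets the reference equal: the gel recording is re-referenced
#' to the right mastoid (M2) by subtracting its recorded M2 channel, which
#' is the reference the dry cap already uses. Re-referencing is idempotent
#' because the subtracted M2 channel becomes zero.
#'
#' @param dry,gel `eeg_recording`s of the same subject and task.
#' @return list with elements `dry` and `gel`, both with identical channel
#'   ordering and an M2 reference.
#' @export
harmonize_and_rereference <- function(dry, gel) {
  if ("M2" %in% gel$channel_labels) {
    m2 <- gel$data[match("M2", gel$channel_labels), ]
    gel$data <- sweep(gel$data, 2, m2)
    keep <- gel$channel_labels != "M2"
    gel$data <- gel$data[keep, , drop = FALSE]
    gel$channel_labels <- gel$channel_labels[keep]
    gel$reference_label <- "M2"
  } else if (!identical(gel$reference_label, "M2")) {
    stop("gel recording lacks an M2 channel and is not M2-referenced")
  }
  shared <- intersect(dry$channel_labels, gel$channel_labels)
  if (length(shared) != length(shared_channels())) {
    warning(sprintf("shared channel set has %d channels (expected %d); proceeding with the intersection",
                    length(shared), length(shared_channels())))
  }
  ord <- intersect(c(shared_channels(),
                     setdiff(shared, shared_channels())), shared)
  list(dry = select_channels(dry, ord), gel = select_channels(gel, ord))
}

#' Linear component decomposition of a recording
#'
#' Exact linear decomposition `data = mixing %*% sources`. The spatial
#' common mode (per-sample median over channels, dominated by
#' reference-electrode noise in referenced recordings; the median is
#' robust against focal sources such as blinks) is split off as the
#' first component; the spatially differential remainder is decomposed
#' by SVD into principal components with unit-variance source rows. Any decomposition with the reconstruction property (e.g. an ICA
#' computed elsewhere) can be passed to [identify_blink_component()] and
#' [remove_components()]; this is the package's default.
#'
#' @param rec an `eeg_recording` (assumed high-pass filtered).
#' @param n_components number of SVD components to keep after the
#'   common-mode component (default: all).
#' @return list of class `eeg_decomposition` with `mixing`
#'   (channels x components), `sources` (components x samples),
#'   `channel_labels`, `sample_rate`.
#' @export
decompose_components <- function(rec, n_components = NULL) {
  x <- rec$data
  common <- apply(x, 2, stats::median)
  x0 <- sweep(x, 2, common)
  sv <- svd(x0)
  k <- if (is.null(n_components)) length(sv$d) else min(n_components, length(sv$d))
  m <- ncol(x0)
  # unit-variance sources: sources[i,] = sqrt(m) * v[,i]'
  s_common <- stats::sd(common)
  if (s_common < 1e-300) s_common <- 1
  mixing <- cbind(rep(s_common, nrow(x)),
                  sv$u[, 1:k, drop = FALSE] %*% diag(sv$d[1:k] / sqrt(m), k))
  sources <- rbind(common / s_common, sqrt(m) * t(sv$v[, 1:k, drop = FALSE]))
  structure(list(mixing = mixing, sources = sources,
                 channel_labels = rec$channel_labels,
                 sample_rate = rec$sample_rate),
            class = "eeg_decomposition")
}

# deflection peaks of a source: local maxima of the dominantly-oriented
# signal above `thresh` robust SDs, separated by >= min_sep seconds
.source_peaks <- function(s, fs, thresh = 4, min_sep = 0.3) {
  v <- s * sign(sum(s^3) + .Machine$double.eps)
  scale <- stats::mad(v)
  if (scale < 1e-12) return(integer(0))
  z <- (v - stats::median(v)) / scale
  cand <- which(z > thresh)
  if (!length(cand)) return(integer(0))
  keep <- integer(0)
  gap <- round(min_sep * fs)
  # greedy: take the largest candidate, suppress its neighborhood
  ord <- cand[order(z[cand], decreasing = TRUE)]
  taken <- logical(length(s))
  for (i in ord) {
    if (!taken[i]) {
      keep <- c(keep, i)
      lo <- max(1, i - gap); hi <- min(length(s), i + gap)
      taken[lo:hi] <- TRUE
    }
  }
  sort(keep)
}

#' Identify the eye-blink component of a decomposition
#'
#' Scores every component against three criteria: (1) frontality - the
#' fraction of mixing-vector energy on the frontal channels (Fp1, Fp2,
#' F7, F3, F4, F8) must be at least `frontality_min`; (2) blink-likeness -
#' the source must contain at least `min_peaks` stereotyped large
#' monophasic deflections; (3) task-independence - the deflection rate
#' must be roughly uniform over the session (coefficient of variation of
#' per-third peak counts at most `cv_max`). Among components passing all
#' three, the one with the highest frontality is returned.
#'
#' @param decomp an `eeg_decomposition`.
#' @param frontality_min minimum frontal energy fraction (default 0.6).
#' @param cv_max maximum CV of peak counts across session thirds
#'   (default 0.5).
#' @param min_peaks minimum number of deflections (default 3).
#' @return the selected component index, or `NA_integer_` if no component
#'   passes all three criteria.
#' @export
identify_blink_component <- function(decomp, frontality_min = 0.6,
                                     cv_max = 0.5, min_peaks = 3) {
  k <- ncol(decomp$mixing)
  if (k == 0) stop("empty decomposition")
  frontal <- decomp$channel_labels %in% .frontal_channels
  n <- ncol(decomp$sources)
  fs <- decomp$sample_rate
  best <- NA_integer_; best_frontality <- -Inf
  for (j in seq_len(k)) {
    m <- decomp$mixing[, j]
    frontality <- sum(m[frontal]^2) / sum(m^2)
    if (!is.finite(frontality) || frontality < frontality_min) next
    peaks <- .source_peaks(decomp$sources[j, ], fs)
    if (length(peaks) < min_peaks) next
    thirds <- cut(peaks, breaks = c(0, n / 3, 2 * n / 3, n), labels = FALSE)
    counts <- tabulate(thirds, 3)
    cv <- stats::sd(counts) / mean(counts)
    if (!is.finite(cv) || cv > cv_max) next
    if (frontality > best_frontality) {
      best <- j; best_frontality <- frontality
    }
  }
  best
}

#' Reconstruct a recording with selected components removed
#'
#' Zeroes the listed source rows and reconstructs `mixing %*% sources`.
#' Removing no components reproduces the input to reconstruction
#' tolerance; removing all components yields an all-zero recording.
#'
#' @param rec the `eeg_recording` the decomposition was computed from.
#' @param decomp an `eeg_decomposition` of `rec`.
#' @param indices integer vector of component indices to remove (may be
#'   empty).
#' @return the cleaned recording.
#' @export
remove_components <- function(rec, decomp, indices) {
  k <- ncol(decomp$mixing)
  indices <- indices[!is.na(indices)]
  if (length(indices) && (any(indices < 1) || any(indices > k))) {
    stop("component index out of range")
  }
  keep <- setdiff(seq_len(k), indices)
  recon <- decomp$mixing[, keep, drop = FALSE] %*%
    decomp$sources[keep, , drop = FALSE]
  rec$data <- recon
  rownames(rec$data) <- rec$channel_labels
  rec
}
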