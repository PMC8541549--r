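# Minimal European Data Format (EDF) support: 16-bit integer samples with
# per-channel physical scaling. Covers continuous recordings written by
# this package; annotations (EDF+) are not used — events travel in the
# TSV sidecar.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

# numeric header field: the widest %g representation that fits `width`
# ASCII characters; returns the string, whose parsed value must be used
# for any scaling arithmetic
.edf_num_str <- function(x, width = 8) {
  for (dd in 7:1) {
    s <- sprintf("%.*g", dd, x)
    if (nchar(s) <= width) return(s)
  }
  stop("cannot represent ", x, " in ", width, " characters")
}

.edf_num <- function(x, width) .edf_pad(.edf_num_str(x, width), width)

#' Write a recording as a 16-bit EDF file
#'
#' Each channel is scaled to the signed 16-bit range from its own physical
#' min/max, so the round-trip error is bounded by half a quantization step
#' of the channel range. When the sample count is a multiple of the sample
#' rate, 1 s data records are used; otherwise a single record holds the
#' whole signal.
#'
#' @param rec an `eeg_recording` (data in microvolts).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  x <- rec$data
  ns <- ncol(x)
  nch <- nrow(x)
  if (ns == 0) stop("cannot write an empty recording (0 samples)")
  fs <- rec$sample_rate
  if (ns %% fs == 0 && fs == round(fs)) {
    spr <- as.integer(fs); n_rec <- ns %/% spr; rec_dur <- 1
  } else {
    spr <- ns; n_rec <- 1L; rec_dur <- ns / fs
  }
  pmin <- apply(x, 1, min); pmax <- apply(x, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  # widen to the header-representable values so reader and writer use
  # the identical scaling
  pmin <- vapply(pmin, function(v) as.numeric(.edf_num_str(v - abs(v) * 1e-6 - 1e-9)), 0)
  pmax <- vapply(pmax, function(v) as.numeric(.edf_num_str(v + abs(v) * 1e-6 + 1e-9)), 0)
  dmin <- -32768; dmax <- 32767
  gain <- (pmax - pmin) / (dmax - dmin)
  dig <- round(sweep(sweep(x, 1, pmin), 1, gain, "/")) + dmin
  dig[dig < dmin] <- dmin; dig[dig > dmax] <- dmax
  storage.mode(dig) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(sprintf("subject %s", rec$subject_id), 80),
    .edf_pad(sprintf("system %s task %s", rec$system, rec$task), 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (nch + 1), 8),
    .edf_pad(sprintf("FS=%.10g", fs), 44),   # reserved: exact sample rate
    .edf_pad(n_rec, 8),
    .edf_num(rec_dur, 8),
    .edf_pad(nch, 4))
  sig_hdr <- paste0(
    paste(vapply(rec$channel_labels, .edf_pad, "", width = 16), collapse = ""),
    paste(rep(.edf_pad("EEG", 80), nch), collapse = ""),
    paste(rep(.edf_pad("uV", 8), nch), collapse = ""),
    paste(vapply(pmin, .edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax, .edf_num, "", width = 8), collapse = ""),
    paste(rep(.edf_pad(dmin, 8), nch), collapse = ""),
    paste(rep(.edf_pad(dmax, 8), nch), collapse = ""),
    paste(rep(.edf_pad("", 80), nch), collapse = ""),
    paste(rep(.edf_pad(spr, 8), nch), collapse = ""),
    paste(rep(.edf_pad("", 32), nch), collapse = ""))
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])),
             con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a 16-bit EDF file into a recording
#'
#' Physical units are converted to microvolts: channels whose dimension
#' field reads `mV` are scaled by 1000, `V` by 1e6; `uV` (and unknown
#' units) are taken as already in microvolts.
#'
#' @param path EDF file path.
#' @param events optional event data frame to attach.
#' @return an `eeg_recording`.
#' @export
read_edf <- function(path, events = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) rawToChar(readBin(con, "raw", n))
  rd(8); pat <- rd(80); recinfo <- rd(80); rd(8); rd(8)
  rd(8); reserved <- trimws(rd(44))
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(nch), function(i) trimws(rd(w)), "")
  labels <- fld(16); fld(80); dims <- fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80); spr <- as.integer(fld(8)); fld(32)
  if (length(unique(spr)) != 1) stop("heterogeneous samples-per-record unsupported")
  spr1 <- spr[1]
  gain <- (pmax - pmin) / (dmax - dmin)
  data <- matrix(0, nch, n_rec * spr1)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = nch * spr1, size = 2,
                   signed = TRUE, endian = "little")
    block <- matrix(raw, nrow = spr1, ncol = nch)
    data[, ((r - 1) * spr1 + 1):(r * spr1)] <- t(block)
  }
  data <- sweep(sweep(data, 1, dmin), 1, gain, "*") + pmin
  unit_scale <- ifelse(toupper(dims) == "MV", 1000,
                       ifelse(toupper(dims) == "V", 1e6, 1))
  data <- data * unit_scale
  fs <- if (grepl("^FS=", reserved)) as.numeric(sub("^FS=", "", reserved)) else
    spr1 / rec_dur
  system <- if (grepl("system (\\w+)", recinfo)) sub(".*system (\\w+).*", "\\1", recinfo) else NA
  task <- if (grepl("task (\\w+)", recinfo)) sub(".*task (\\w+).*", "\\1", recinfo) else NA
  subj <- suppressWarnings(as.integer(sub(".*subject (\\S+).*", "\\1", pat)))
  new_recording(data, fs, labels, events = events, system = system,
                subject_id = subj, task = task)
}
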