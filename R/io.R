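# Data model and standard-format IO.
#
# A recording holds a channels x samples matrix in microvolts, the sample
# rate, an ordered label vector, an event table and session metadata.
# Sample indices are 0-based; time t = onset_sample / sample_rate; epoch
# extraction uses half-open sample intervals [start, stop).

#' Construct an EEG recording
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param sample_rate sampling frequency in Hz.
#' @param channel_labels channel labels, one per row of `data`.
#' @param events data frame with columns `onset_sample` (0-based) and
#'   `label`, or `NULL` for none.
#' @param system `"dry"` or `"gel"` (or `NA` when not applicable).
#' @param subject_id subject identifier.
#' @param task task code (`"CHECK"`, `"ASSR"`, `"EOEC"`, or other).
#' @param reference_label label of the reference electrode (default `"M2"`).
#' @return an object of class `eeg_recording`.
#' @export
new_recording <- function(data, sample_rate, channel_labels,
                          events = NULL, system = NA_character_,
                          subject_id = NA_integer_, task = NA_character_,
                          reference_label = "M2") {
  data <- as.matrix(data)
  channel_labels <- canonical_label(channel_labels)
  if (nrow(data) != length(channel_labels)) {
    stop("number of data rows must equal number of channel labels")
  }
  if (anyDuplicated(channel_labels)) stop("duplicate channel labels")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    stop("sample_rate must be a positive scalar")
  }
  events <- validate_events(events, ncol(data))
  rownames(data) <- channel_labels
  structure(list(data = data, sample_rate = sample_rate,
                 channel_labels = channel_labels, events = events,
                 system = system, subject_id = subject_id, task = task,
                 reference_label = reference_label),
            class = "eeg_recording")
}

validate_events <- function(events, n_samples) {
  if (is.null(events) || nrow(events) == 0) {
    return(data.frame(onset_sample = integer(0), label = character(0),
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(c("onset_sample", "label") %in% names(events)))
  if (any(events$onset_sample < 0 | events$onset_sample >= n_samples)) {
    stop("event onsets must lie within [0, n_samples)")
  }
  if (any(!nzchar(events$label))) stop("event labels must be nonempty")
  if (is.unsorted(events$onset_sample)) {
    warning("event onsets were not sorted; sorting by onset")
    events <- events[order(events$onset_sample), , drop = FALSE]
  }
  rownames(events) <- NULL
  events[, c("onset_sample", "label")]
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s/%s subject %s: %d ch x %d samples @ %g Hz, %d events\n",
              x$system, x$task, x$subject_id, nrow(x$data), ncol(x$data),
              x$sample_rate, nrow(x$events)))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)
duration_s <- function(rec) ncol(rec$data) / rec$sample_rate

#' Keep a subset of channels of a recording
#'
#' @param rec an `eeg_recording`.
#' @param labels channel labels to keep, in the requested order.
#' @return the recording restricted (and reordered) to `labels`.
#' @export
select_channels <- function(rec, labels) {
  labels <- canonical_label(labels)
  idx <- match(labels, rec$channel_labels)
  if (anyNA(idx)) {
    stop("channel(s) not present: ", paste(labels[is.na(idx)], collapse = ", "))
  }
  rec$data <- rec$data[idx, , drop = FALSE]
  rec$channel_labels <- labels
  rec
}

# ---- events ----------------------------------------------------------------

#' Write an event table as tab-separated text
#'
#' Columns written: `onset_sample`, `onset_s`, `label`.
#' @param events event data frame (`onset_sample`, `label`).
#' @param sample_rate Hz, used to derive `onset_s`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, sample_rate, path) {
  out <- data.frame(onset_sample = events$onset_sample,
                    onset_s = events$onset_sample / sample_rate,
                    label = events$label)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event table written by [write_events()]
#'
#' Unsorted onsets are sorted with a warning.
#' @param path input path.
#' @return data frame with columns `onset_sample`, `label`.
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("onset_sample", "label") %in% names(ev)))
  if (is.unsorted(ev$onset_sample)) {
    warning("event onsets were not sorted; sorting by onset")
    ev <- ev[order(ev$onset_sample), , drop = FALSE]
  }
  rownames(ev) <- NULL
  ev[, c("onset_sample", "label")]
}

# ---- delimited matrix format ----------------------------------------------

# One row per channel, first field the channel label; '#'-prefixed header
# lines carry sample_rate and session metadata. Lossless (full double
# precision via %.17g).

write_delimited_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(sample_rate = rec$sample_rate, system = rec$system,
            subject_id = rec$subject_id, task = rec$task,
            reference_label = rec$reference_label)
  writeLines(sprintf("# %s=%s", names(meta), as.character(meta)), con)
  for (i in seq_len(nrow(rec$data))) {
    writeLines(paste(c(rec$channel_labels[i],
                       sprintf("%.17g", rec$data[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

read_delimited_recording <- function(path, events = NULL) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta_raw <- sub("^#\\s*", "", lines[hdr])
  meta <- stats::setNames(sub("^[^=]*=", "", meta_raw),
                          sub("=.*$", "", meta_raw))
  body <- strsplit(lines[!hdr], "\t", fixed = TRUE)
  labels <- vapply(body, `[`, character(1), 1)
  data <- do.call(rbind, lapply(body, function(v) as.numeric(v[-1])))
  new_recording(data, as.numeric(meta[["sample_rate"]]), labels,
                events = events,
                system = meta[["system"]],
                subject_id = suppressWarnings(as.integer(meta[["subject_id"]])),
                task = meta[["task"]],
                reference_label = meta[["reference_label"]])
}

# ---- session-level IO ------------------------------------------------------

#' Write a recording plus sidecars to a directory
#'
#' Writes the signal in the requested format (EDF, 16-bit, or the lossless
#' delimited text format), the events as tab-separated text, and the
#' montage positions of the recorded channels.
#'
#' @param rec an `eeg_recording` with at least one sample.
#' @param out_dir output directory (created if needed).
#' @param format `"edf"` or `"delimited"`.
#' @param stem file-name stem; default
#'   `sub<subject>_<system>_<task>`.
#' @return named character vector of file paths (`signal`, `events`,
#'   `montage`).
#' @export
write_session <- function(rec, out_dir, format = c("edf", "delimited"),
                          stem = NULL) {
  format <- match.arg(format)
  if (ncol(rec$data) == 0) stop("cannot write an empty recording (0 samples)")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(stem)) {
    stem <- sprintf("sub%02d_%s_%s", rec$subject_id, rec$system, rec$task)
  }
  sig_path <- file.path(out_dir, paste0(stem, if (format == "edf") ".edf" else ".txt"))
  if (format == "edf") {
    write_edf(rec, sig_path)
  } else {
    write_delimited_recording(rec, sig_path)
  }
  ev_path <- file.path(out_dir, paste0(stem, "_events.tsv"))
  write_events(rec$events, rec$sample_rate, ev_path)
  mon_path <- file.path(out_dir, paste0(stem, "_montage.tsv"))
  pos <- .montage_table[match(rec$channel_labels, .montage_table$label), ]
  ok <- !is.na(pos$label)
  write_montage(pos[ok, ], mon_path)
  c(signal = sig_path, events = ev_path, montage = mon_path)
}

#' Load a recording written by [write_session()]
#'
#' Units are converted to microvolts (an EDF channel declared in `mV` is
#' scaled by 1000, in `V` by 1e6). Channel labels must be present in the
#' montage file; a mismatch is an error rather than a guess.
#'
#' @param signal_path EDF or delimited signal file.
#' @param events_path events TSV (optional; `NULL` for none).
#' @param montage_path montage TSV used to validate channel labels
#'   (optional).
#' @param expected_sample_rate if given, the header sample rate must match.
#' @return an `eeg_recording`.
#' @export
load_session <- function(signal_path, events_path = NULL, montage_path = NULL,
                         expected_sample_rate = NULL) {
  if (!file.exists(signal_path)) stop("signal file not found: ", signal_path)
  events <- if (!is.null(events_path)) read_events(events_path) else NULL
  rec <- if (grepl("\\.edf$", signal_path, ignore.case = TRUE)) {
    read_edf(signal_path, events = events)
  } else {
    read_delimited_recording(signal_path, events = events)
  }
  if (!is.null(expected_sample_rate) &&
      abs(rec$sample_rate - expected_sample_rate) > 1e-9) {
    stop(sprintf("sample-rate mismatch: header %g Hz, expected %g Hz",
                 rec$sample_rate, expected_sample_rate))
  }
  if (!is.null(montage_path)) {
    mon <- read_montage(montage_path)
    missing <- setdiff(rec$channel_labels, mon$label)
    if (length(missing)) {
      stop("channel(s) absent from montage: ", paste(missing, collapse = ", "))
    }
  }
  rec
}

# ---- tabular export --------------------------------------------------------

#' Export a tabular result as tab-separated text
#'
#' Accepts any data frame (QC summaries, peak tables, band-power tables).
#' Numeric columns are serialized with 15 significant digits so a
#' round-trip parse recovers them to well below 1e-9.
#'
#' @param result a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_table <- function(result, path) {
  if (!is.data.frame(result)) stop("unknown result type: expected a data frame")
  out <- result
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.15g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
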