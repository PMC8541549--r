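# Electrode geometry: a 10-10 montage flattened onto the unit head disc.
# Positions are derived from idealized spherical coordinates (azimuth from
# the front midline, positive to the right; inclination from the vertex) and
# projected radially with the mastoid ring (inclination 115 deg) at r = 1.

.montage_table <- local({
  tab <- rbind(
    c("Fp1", -18,  90), c("Fp2",  18,  90),
    c("F7",  -54,  90), c("F8",   54,  90),
    c("T7",  -90,  90), c("T8",   90,  90),
    c("P7", -126,  90), c("P8",  126,  90),
    c("O1", -162,  90), c("O2",  162,  90), c("Oz", 180, 90),
    c("Fz",    0,  45), c("Cz",    0,   0), c("Pz", 180, 45),
    c("C3",  -90,  45), c("C4",   90,  45),
    c("F3",  -39,  60), c("F4",   39,  60),
    c("P3", -141,  60), c("P4",  141,  60),
    c("FC5", -66,  69), c("FC6",  66,  69),
    c("CP5", -114, 69), c("CP6", 114,  69),
    c("FC1", -23,  31), c("FC2",  23,  31),
    c("CP1", -157, 31), c("CP2", 157,  31),
    c("CPz", 180, 22.5),
    c("POz", 180, 67.5), c("AFz",   0, 67.5),
    c("FT9", -72, 113),  c("FT10", 72, 113),
    c("M1", -100, 115),  c("M2",  100, 115))
  az <- as.numeric(tab[, 2]) * pi / 180
  r <- as.numeric(tab[, 3]) / 115
  data.frame(label = tab[, 1],
             x = r * sin(az),
             y = r * cos(az),
             stringsAsFactors = FALSE)
})

# The 29 scalp channels recorded by both systems.
.shared_channels <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                      "FC5", "FC1", "FC2", "FC6",
                      "T7", "C3", "Cz", "C4", "T8",
                      "CP5", "CP1", "CPz", "CP2", "CP6",
                      "P7", "P3", "Pz", "P4", "P8",
                      "O1", "O2", "Oz")

.frontal_channels <- c("Fp1", "Fp2", "F7", "F3", "F4", "F8")

#' Canonicalize 10-10 channel labels
#'
#' Labels are upper-cased, a trailing/inner `z` is lower-cased (`FZ` ->
#' `Fz`, `CPZ` -> `CPz`), and the frontopolar `p` after a leading `F` is
#' lower-cased (`FP1` -> `Fp1`), following 10-10 naming conventions.
#'
#' @param labels character vector of channel labels.
#' @return character vector of canonical labels.
#' @export
canonical_label <- function(labels) {
  out <- toupper(trimws(labels))
  out <- gsub("Z", "z", out, fixed = TRUE)
  out <- sub("^FP", "Fp", out)
  out
}

#' Build the analysis montage for one EEG system
#'
#' Both systems share 29 scalp channels; the gel cap additionally records
#' M1 and POz, the dry cap additionally records AFz, FT9 and FT10.
#' Positions are 2D projections into the unit head disc (front = +y,
#' right = +x).
#'
#' @param system `"dry"` or `"gel"`.
#' @return a data frame of class `eeg_montage` with columns `label`, `x`,
#'   `y`; every position satisfies `sqrt(x^2 + y^2) <= 1`.
#' @examples
#' length(intersect(make_montage("dry")$label, make_montage("gel")$label))
#' @export
make_montage <- function(system = c("dry", "gel")) {
  system <- match.arg(system)
  extra <- switch(system,
                  gel = c("M1", "POz"),
                  dry = c("AFz", "FT9", "FT10"))
  labels <- c(.shared_channels, extra)
  m <- .montage_table[match(labels, .montage_table$label), , drop = FALSE]
  rownames(m) <- NULL
  structure(m, class = c("eeg_montage", "data.frame"), system = system)
}

#' Look up head-disc positions for channel labels
#'
#' @param labels channel labels (canonicalized before lookup).
#' @return data frame with columns `label`, `x`, `y`.
#' @export
montage_positions <- function(labels) {
  labels <- canonical_label(labels)
  idx <- match(labels, .montage_table$label)
  if (anyNA(idx)) {
    stop("unknown channel label(s): ",
         paste(labels[is.na(idx)], collapse = ", "))
  }
  out <- .montage_table[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shared channels of the dry and gel montages
#'
#' @return character vector of the 29 channel labels present in both caps.
#' @export
shared_channels <- function() .shared_channels

#' Write a montage as tab-separated text
#'
#' @param montage an `eeg_montage` (or any data frame with `label`, `x`, `y`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(montage, path) {
  utils::write.table(montage[, c("label", "x", "y")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a montage from tab-separated text
#'
#' @param path file written by [write_montage()].
#' @return an `eeg_montage` data frame.
#' @export
read_montage <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("label", "x", "y") %in% names(m)))
  m$label <- canonical_label(m$label)
  if (anyDuplicated(m$label)) stop("duplicate channel labels in montage")
  if (any(sqrt(m$x^2 + m$y^2) > 1 + 1e-9)) {
    stop("montage positions must lie inside the unit head disc")
  }
  structure(m, class = c("eeg_montage", "data.frame"))
}
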