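# Minimal classic-EDF (16-bit) writer and reader. Covers fixed-rate,
# equally-sampled multichannel records -- enough to round-trip generated
# recordings through the standard on-disk format. EDF+ annotation channels are
# not produced; seizure intervals travel in the plain-text sidecar handled by
# write_annotations()/read_annotations().

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Classic EDF: 16-bit integers, one-second data records, identical sampling
#' rate on every signal. The last record is zero-padded when the record length
#' is not a whole number of seconds. Seizure annotations are not embedded; use
#' [write_annotations()] for the sidecar.
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  abort_if(rec$fs != round(rec$fs), "EDF writer requires an integer sampling rate")
  n <- nrow(rec$signal)
  fs <- as.integer(rec$fs)
  ns <- ncol(rec$signal)
  n_rec <- as.integer(ceiling(ns / fs))
  pmax_ <- max(1e-6, max(abs(rec$signal)))
  pmin_ <- -pmax_
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(rec$patient_id, 80),
    edf_pad("synthetic EEG", 80),
    edf_pad("01.01.20", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * (n + 1L), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(1L, 8),
    edf_pad(n, 4),
    paste(edf_pad(rec$channel_names, 16), collapse = ""),
    paste(rep(edf_pad("", 80), n), collapse = ""),
    paste(rep(edf_pad("uV", 8), n), collapse = ""),
    paste(rep(edf_pad(sprintf("%.2f", pmin_), 8), n), collapse = ""),
    paste(rep(edf_pad(sprintf("%.2f", pmax_), 8), n), collapse = ""),
    paste(rep(edf_pad(dmin, 8), n), collapse = ""),
    paste(rep(edf_pad(dmax, 8), n), collapse = ""),
    paste(rep(edf_pad("", 80), n), collapse = ""),
    paste(rep(edf_pad(fs, 8), n), collapse = ""),
    paste(rep(edf_pad("", 32), n), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  padded <- cbind(rec$signal, matrix(0, n, n_rec * fs - ns))
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    dig <- round((t(padded[, cols, drop = FALSE]) - pmin_) * scale) + dmin
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Parses a classic EDF file with a common sampling rate across signals.
#' Seizure intervals are attached from an annotation table when supplied.
#'
#' @param path EDF file path.
#' @param annotations Optional data.frame from [read_annotations()]; rows whose
#'   `record_id` matches the EDF patient field are attached.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path, annotations = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                              # version
  pid <- rd(80)
  rd(80); rd(8); rd(8)
  rd(8)                              # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n <- as.integer(rd(4))
  labels <- vapply(seq_len(n), function(i) rd(16), "")
  for (i in seq_len(n)) rd(80)       # transducer
  for (i in seq_len(n)) rd(8)        # phys dim
  pmin_ <- vapply(seq_len(n), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(n), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(n), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(n), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(n)) rd(80)       # prefilter
  spr <- vapply(seq_len(n), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(n)) rd(32)
  abort_if(length(unique(spr)) != 1L, "EDF reader requires a common sampling rate")
  fs <- spr[1L] / rec_dur
  X <- matrix(0, n, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    dig <- readBin(con, "integer", n = n * spr[1L], size = 2L,
                   endian = "little", signed = TRUE)
    D <- matrix(dig, nrow = spr[1L], ncol = n)
    cols <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    X[, cols] <- t((D - rep(dmin, each = spr[1L])) *
                     rep((pmax_ - pmin_) / (dmax - dmin), each = spr[1L]) +
                     rep(pmin_, each = spr[1L]))
  }
  rownames(X) <- labels
  ivs <- list()
  if (!is.null(annotations)) {
    sel <- annotations$record_id == pid
    ivs <- lapply(which(sel), function(i)
      c(annotations$onset_s[i], annotations$offset_s[i]))
  }
  new_eeg_recording(X, fs, labels, ivs, pid)
}

#' Plain-text seizure annotations
#'
#' One line per seizure: `record_id<TAB>onset_s<TAB>offset_s`.
#'
#' @param recs A list of `eeg_recording`s (or a single one) to write.
#' @param path File path.
#' @return `read_annotations()` returns a data.frame with columns `record_id`,
#'   `onset_s`, `offset_s`.
#' @export
write_annotations <- function(recs, path) {
  if (inherits(recs, "eeg_recording")) recs <- list(recs)
  rows <- do.call(rbind, lapply(recs, function(r) {
    if (!length(r$seizure_intervals)) return(NULL)
    data.frame(record_id = r$patient_id,
               onset_s = vapply(r$seizure_intervals, `[`, 0, 1L),
               offset_s = vapply(r$seizure_intervals, `[`, 0, 2L))
  }))
  if (is.null(rows))
    rows <- data.frame(record_id = character(), onset_s = numeric(),
                       offset_s = numeric())
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(record_id = character(), onset_s = numeric(),
                      offset_s = numeric()))
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- c("record_id", "onset_s", "offset_s")
  df
}
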