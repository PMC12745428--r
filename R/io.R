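#' Write / read a recording as labeled CSV
#'
#' Plain-text matrix interchange: one column per channel (header row =
#' channel labels), one row per sample. Cue events travel in an optional
#' side-car CSV with columns `sample_index`, `task`.
#'
#' @param rec an [EEGRecording-class].
#' @param path output CSV path.
#' @param events_path optional side-car events CSV path.
#' @return `path`, invisibly.
#' @export
writeRecordingCSV <- function(rec, path, events_path = NULL) {
  df <- as.data.frame(t(rec@data))
  names(df) <- rec@labels
  write.csv(df, path, row.names = FALSE)
  if (!is.null(events_path) && nrow(rec@events)) {
    ev <- data.frame(sample_index = rec@events$sample,
                     task = rec@events$task)
    write.csv(ev, events_path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeRecordingCSV
#' @param fs sampling rate of the stored recording (Hz); CSV carries no
#'   rate metadata.
#' @export
readRecordingCSV <- function(path, fs, events_path = NULL) {
  df <- read.csv(path, check.names = FALSE)
  ev <- data.frame(sample = integer(), task = character())
  if (!is.null(events_path) && file.exists(events_path)) {
    raw <- read.csv(events_path)
    ev <- data.frame(sample = as.integer(raw$sample_index),
                     task = as.character(raw$task))
  }
  EEGRecording(t(as.matrix(df)), fs = fs, labels = names(df), events = ev)
}

## fixed-width ASCII field helper for the EDF header
edfField <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  sprintf("%-*s", width, s)
}

#' Write / read 16-bit EDF
#'
#' Minimal European Data Format codec: standard 256-byte header plus
#' per-signal header blocks, int16 little-endian data records of one
#' second each. Physical scaling is per channel (symmetric range covering
#' the data); the recording length is padded with zeros to a whole number
#' of records, so a read-back may be up to one record longer than the
#' original. Events are not embedded (use the CSV side-car of
#' [writeRecordingCSV()]).
#'
#' @param rec an [EEGRecording-class] with an integer sampling rate.
#' @param path output `.edf` path.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(rec, path) {
  fs <- samplingRate(rec)
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF export requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(rec@data)
  n_samp <- ncol(rec@data)
  n_rec <- as.integer(ceiling(n_samp / fs))
  dat <- rec@data
  if (n_rec * fs > n_samp)
    dat <- cbind(dat, matrix(0, ns, n_rec * fs - n_samp))
  pmax_ <- pmax(apply(abs(dat), 1, max), 1e-6)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edfField("0", 8), edfField("X X X X", 80), edfField("Startdate X", 80),
    edfField("01.01.00", 8), edfField("00.00.00", 8),
    edfField(256 * (1 + ns), 8), edfField("", 44),
    edfField(n_rec, 8), edfField(1, 8), edfField(ns, 4))
  writeChar(hdr, con, nchars = nchar(hdr), eos = NULL)
  sig <- function(vals, width)
    paste(vapply(vals, edfField, "", width = width), collapse = "")
  block <- paste0(
    sig(rec@labels, 16), sig(rep("", ns), 80), sig(rep("uV", ns), 8),
    sig(sprintf("%.6g", -pmax_), 8), sig(sprintf("%.6g", pmax_), 8),
    sig(rep(-32767L, ns), 8), sig(rep(32767L, ns), 8),
    sig(rep("", ns), 80), sig(rep(fs, ns), 8), sig(rep("", ns), 32))
  writeChar(block, con, nchars = nchar(block), eos = NULL)
  for (r in seq_len(n_rec)) {
    idx <- (r - 1L) * fs + seq_len(fs)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round(dat[ch, idx] / pmax_[ch] * 32767))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname writeEDF
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)          # transducer
  for (i in seq_len(ns)) rd(8)           # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)          # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)          # reserved
  fs <- spr[1] / dur
  out <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L,
                     endian = "little")
      phys <- pmin_[ch] + (dig - dmin[ch]) *
        (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
      out[ch, (r - 1L) * spr[ch] + seq_len(spr[ch])] <- phys
    }
  }
  EEGRecording(out, fs = fs, labels = labels)
}

#' Write / read a connectivity matrix CSV
#'
#' 19 x 19 (or N x N) matrix with header and row labels in montage order.
#'
#' @param m a [ConnectivityMatrix-class].
#' @param path CSV path.
#' @return `path` (write) or a [ConnectivityMatrix-class] (read),
#'   invisibly for the writer.
#' @export
writeConnectivityCSV <- function(m, path) {
  df <- as.data.frame(m@values)
  write.csv(cbind(node = m@labels, df), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeConnectivityCSV
#' @param band band name to attach on read.
#' @export
readConnectivityCSV <- function(path, band) {
  df <- read.csv(path, check.names = FALSE)
  labels <- df$node
  v <- as.matrix(df[, -1, drop = FALSE])
  dimnames(v) <- list(labels, labels)
  ConnectivityMatrix(v, band = band, labels = labels)
}

#' Export a binary graph
#'
#' @param g a [BinaryGraph-class].
#' @param path output path.
#' @param format `"graphml"` or `"edgelist"` (tab-separated `node_i`,
#'   `node_j`).
#' @return `path`, invisibly.
#' @export
exportGraph <- function(g, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(asIgraph(g), path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(asIgraph(g))
    utils::write.table(data.frame(node_i = el[, 1], node_j = el[, 2]), path,
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
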