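# Minimal European Data Format (EDF) writer/reader for continuous
# recordings, with a sidecar tab-separated event file. Covers the plain EDF
# profile this pipeline needs: one data-record duration of 1 s, int16
# little-endian samples, per-channel physical/digital scaling. Not a general
# EDF+ implementation (no annotations, no discontinuous records).

.pad <- function(x, n) formatC(as.character(x), width = n, flag = "-")

#' Write a recording to EDF plus an event sidecar
#'
#' Samples are quantized to 16 bits over each channel's physical range, so a
#' round trip preserves values to within one quantization step. Events and
#' the exact sample count go to \code{<path>.events.tsv}.
#'
#' @param recording an \code{mmn_recording}.
#' @param path output file path (conventionally .edf).
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(recording, path) {
  data <- recording$data
  nch <- nrow(data); ns <- ncol(data); rate <- recording$rate
  n_rec <- ceiling(ns / rate)
  if (ns < n_rec * rate)                     # zero-pad the final record
    data <- cbind(data, matrix(0, nch, n_rec * rate - ns))
  pmin_ <- apply(data, 1, min); pmax_ <- apply(data, 1, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, n) writeChar(.pad(x, n), con, nchars = n, eos = NULL)
  wr("0", 8); wr("X", 80); wr("synthetic oddball EEG", 80)
  wr("01.01.01", 8); wr("00.00.01", 8)
  wr(256 * (nch + 1), 8); wr("", 44); wr(n_rec, 8); wr(1, 8); wr(nch, 4)
  for (lab in rownames(data)) wr(lab, 16)
  for (i in seq_len(nch)) wr("AgAgCl electrode", 80)
  for (i in seq_len(nch)) wr("uV", 8)
  for (i in seq_len(nch)) wr(format(pmin_[i], digits = 8), 8)
  for (i in seq_len(nch)) wr(format(pmax_[i], digits = 8), 8)
  for (i in seq_len(nch)) wr(dmin, 8)
  for (i in seq_len(nch)) wr(dmax, 8)
  for (i in seq_len(nch)) wr("", 80)
  for (i in seq_len(nch)) wr(rate, 8)
  for (i in seq_len(nch)) wr("", 32)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * rate + 1):(r * rate)
    block <- round((data[, cols, drop = FALSE] - pmin_) * scale + dmin)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  ev_path <- paste0(path, ".events.tsv")
  con2 <- file(ev_path, "w")
  writeLines(sprintf("# n_samples=%d rate=%g reference=%s", ns, rate,
                     recording$reference), con2)
  utils::write.table(recording$events, con2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con2)
  invisible(path)
}

#' Read an EDF recording written by \code{\link{write_edf}}
#'
#' @param path the EDF file; events are read from \code{<path>.events.tsv}
#'   (a missing event file is an error; an event file with zero rows yields
#'   a recording with no events and a warning).
#' @param montage montage to attach (default: the 64-channel template).
#' @return An \code{mmn_recording}.
#' @export
read_edf <- function(path, montage = build_paper_montage()) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("malformed EDF header (version field): ", path)
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  if (is.na(n_rec) || is.na(nch)) stop("malformed EDF header: ", path)
  labs <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)
  for (i in seq_len(nch)) rd(8)           # units
  pmin_ <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(nch)) rd(80)
  spr <- vapply(seq_len(nch), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(nch)) rd(32)
  if (length(unique(spr)) != 1) stop("mixed per-channel rates unsupported")
  rate <- spr[1] / dur
  data <- matrix(0, nch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = nch * spr[1], size = 2,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1])   # samples x channels
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[, cols] <- t((block - rep(dmin, each = spr[1])) /
                        rep((dmax - dmin) / (pmax_ - pmin_), each = spr[1]) +
                        rep(pmin_, each = spr[1]))
  }
  rownames(data) <- labs
  ev_path <- paste0(path, ".events.tsv")
  if (!file.exists(ev_path))
    stop("missing event sidecar file: ", ev_path)
  hdr <- readLines(ev_path, n = 1L)
  ns <- as.integer(sub(".*n_samples=(\\d+).*", "\\1", hdr))
  reference <- sub(".*reference=(\\S+).*", "\\1", hdr)
  if (!is.na(ns) && ns <= ncol(data)) data <- data[, seq_len(ns)]
  events <- utils::read.table(ev_path, sep = "\t", header = TRUE,
                              comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(events) == 0) {
    warning("event file contains no events: ", ev_path)
    events <- data.frame(sample = integer(0), label = character(0),
                         stimulus_id = character(0))
  }
  new_recording(data, rate, events, montage, reference = reference)
}
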