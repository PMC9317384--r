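#' Minimal EDF writer for continuous EEG
#'
#' Writes plain EDF (16-bit integer samples, one data record spanning the
#' whole signal). Physical scaling per channel is chosen from the channel's
#' range, so the quantization error is below 1/65000 of the per-channel
#' amplitude range. Intended companion of \code{\link{read_edf}}; the pair
#' round-trips signals to quantization accuracy. EDF is inherently 16-bit,
#' so exact round-trips are not possible.
#'
#' @param x a \code{vep_continuous} object, or a channels x samples matrix
#'   (then \code{sample_rate} and \code{channels} are required).
#' @param path output path.
#' @param sample_rate,channels metadata when \code{x} is a matrix.
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(x, path, sample_rate = NULL, channels = NULL) {
  if (inherits(x, "vep_continuous")) {
    sample_rate <- x$sample_rate; channels <- x$channels; x <- x$signal
  }
  stopifnot(is.matrix(x), !is.null(sample_rate))
  if (is.null(channels)) channels <- rownames(x)
  ns <- nrow(x); n_samp <- ncol(x)
  pad <- function(s, w) formatC(substr(s, 1, w), width = -w)
  # per-channel range, rounded so its 8-char ASCII form is exact and the
  # header value equals the value used for scaling
  phys_max <- apply(abs(x), 1, max)
  phys_max <- pmax(signif(phys_max * 1.001, 4), 0.01)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  header_bytes <- 256 + 256 * ns
  wr(pad("0", 8)); wr(pad("anonymous", 80)); wr(pad("ocadx export", 80))
  wr(pad("01.01.00", 8)); wr(pad("00.00.00", 8))
  wr(pad(as.character(header_bytes), 8)); wr(pad("", 44))
  wr(pad("1", 8))                                  # one data record
  wr(pad(format(n_samp / sample_rate, digits = 8), 8))
  wr(pad(as.character(ns), 4))
  for (ch in channels) wr(pad(ch, 16))
  for (i in seq_len(ns)) wr(pad("", 80))           # transducer
  for (i in seq_len(ns)) wr(pad("uV", 8))
  for (i in seq_len(ns)) wr(pad(format(-phys_max[i], digits = 4), 8))
  for (i in seq_len(ns)) wr(pad(format(phys_max[i], digits = 4), 8))
  for (i in seq_len(ns)) wr(pad("-32768", 8))
  for (i in seq_len(ns)) wr(pad("32767", 8))
  for (i in seq_len(ns)) wr(pad("", 80))           # prefiltering
  for (i in seq_len(ns)) wr(pad(as.character(n_samp), 8))
  for (i in seq_len(ns)) wr(pad("", 32))
  for (i in seq_len(ns)) {
    # same affine map the reader inverts: [-pm, pm] -> [-32768, 32767]
    dig <- as.integer(round((x[i, ] + phys_max[i]) / (2 * phys_max[i]) *
                              65535 - 32768))
    writeBin(dig, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Minimal EDF reader
#'
#' Reads plain EDF files (as produced by \code{\link{write_edf}}, and any
#' EDF whose channels share one sampling rate).
#'
#' @param path EDF file path.
#' @return list: \code{signal} (channels x samples matrix, physical units),
#'   \code{sample_rate} (Hz), \code{channels} (labels).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)            # phys dim
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("channels with differing sampling rates are not supported")
  sig <- matrix(NA_real_, ns, spr[1] * n_rec)
  for (r in seq_len(n_rec)) for (i in seq_len(ns)) {
    dig <- readBin(con, integer(), n = spr[i], size = 2, endian = "little")
    gain <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
    sig[i, (r - 1) * spr[i] + seq_len(spr[i])] <-
      pmin_[i] + (dig - dmin_[i]) * gain
  }
  rownames(sig) <- labels
  list(signal = sig, sample_rate = spr[1] / rec_dur, channels = labels)
}

#' Write / read a stimulus-onset events table (TSV)
#'
#' Columns: \code{onset} (seconds from record start), \code{eye}
#' (\code{OS}/\code{OD}).
#'
#' @param onsets numeric vector of onset times, seconds.
#' @param eye eye label recycled over onsets.
#' @param path file path.
#' @export
write_events <- function(onsets, eye, path) {
  utils::write.table(data.frame(onset = onsets, eye = eye), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)
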