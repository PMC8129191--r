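# Minimal EDF (European Data Format) support for interoperability.
# EDF stores samples as int16 with a per-channel linear physical scaling, so
# import/export is inherently lossy (~16-bit quantization of the channel
# range); the HDF5 container is the lossless native format.

edf_pad <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write signals to an EDF file
#'
#' @param signals numeric matrix, channels x samples (microvolts).
#' @param fs sampling frequency, Hz.
#' @param path output file.
#' @param labels channel labels (<= 16 ASCII chars each).
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, fs, path, labels = NULL) {
  ns <- nrow(signals)
  n_samp <- ncol(signals)
  labels <- labels %||% paste0("CH", seq_len(ns))
  # one-second data records; pad the tail record with the last value
  rec_dur <- 1
  spr <- as.integer(round(fs * rec_dur))
  n_rec <- as.integer(ceiling(n_samp / spr))
  pad <- n_rec * spr - n_samp
  if (pad > 0) signals <- cbind(signals, signals[, rep(n_samp, pad),
                                                 drop = FALSE])

  pmin <- apply(signals, 1, min)
  pmax <- apply(signals, 1, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(paste(edf_pad(x, width), collapse = ""),
                                     con, nchars = width * length(x),
                                     eos = NULL)
  wr("0", 8)                                   # version
  wr("X X X X", 80)                            # patient id
  wr("Startdate X X X X", 80)                  # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)         # date, time
  wr(as.character(256L * (1L + ns)), 8)        # header bytes
  wr("", 44)
  wr(as.character(n_rec), 8)
  wr(format(rec_dur), 8)
  wr(as.character(ns), 4)
  wr(labels, 16)
  wr(rep("", ns), 80)                          # transducer
  wr(rep("uV", ns), 8)
  wr(formatC(pmin, digits = 6, format = "g"), 8)
  wr(formatC(pmax, digits = 6, format = "g"), 8)
  wr(rep(as.character(dmin), ns), 8)
  wr(rep(as.character(dmax), ns), 8)
  wr(rep("", ns), 80)                          # prefiltering
  wr(rep(as.character(spr), ns), 8)
  wr(rep("", ns), 32)                          # reserved

  # physical values re-read from the header text, so scaling is consistent
  pmin_h <- as.numeric(formatC(pmin, digits = 6, format = "g"))
  pmax_h <- as.numeric(formatC(pmax, digits = 6, format = "g"))
  gain <- (pmax_h - pmin_h) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((signals[ch, cols] - pmin_h[ch]) / gain[ch] + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Continuous-recording EDF only; annotation channels are not parsed.
#'
#' @param path EDF file.
#' @return list with `signals` (channels x samples), `fs`, `labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width, n = 1) {
    trimws(vapply(seq_len(n), function(i)
      readChar(con, width, useBytes = TRUE), ""))
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- rd(16, ns)
  rd(80, ns); rd(8, ns)
  pmin <- as.numeric(rd(8, ns))
  pmax <- as.numeric(rd(8, ns))
  dmin <- as.numeric(rd(8, ns))
  dmax <- as.numeric(rd(8, ns))
  rd(80, ns)
  spr <- as.integer(rd(8, ns))
  rd(32, ns)
  if (length(unique(spr)) != 1)
    stop("channels with differing sampling rates are not supported")
  fs <- spr[1] / rec_dur
  gain <- (pmax - pmin) / (dmax - dmin)
  out <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2,
                     endian = "little")
      out[ch, cols] <- pmin[ch] + (dig - dmin[ch]) * gain[ch]
    }
  }
  list(signals = out, fs = fs, labels = labels)
}
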