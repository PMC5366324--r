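# Minimal EDF (European Data Format) reader/writer: 256-byte fixed header,
# 256 bytes per signal header, 16-bit little-endian integer data records.
# Records are 1 s long; the final record is zero-padded and the true sample
# count is stored in the 44-byte reserved header field ("NSAMP=<n>") so that
# round-trips are length-exact. Amplitudes are physical microvolts.

.pad <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) x <- substr(x, 1, n)
  formatC(x, width = -n, flag = " ")
}

.num8 <- function(x) .pad(formatC(x, format = "g", digits = 7), 8)

#' Write a multi-channel signal to an EDF file
#'
#' @param signal channels x samples numeric matrix (microvolts), with row
#'   names giving the channel labels.
#' @param fs Sampling rate in Hz; also the per-channel samples per 1-s record.
#' @param path Output file path.
#' @param patient,recording Free-text header fields (80 bytes each).
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(signal, fs, path, patient = "X", recording = "X") {
  nch <- nrow(signal)
  nsamp <- ncol(signal)
  spr <- as.integer(fs)
  nrec <- as.integer(ceiling(nsamp / spr))
  # per-channel physical range; EDF stores int16 against a linear scale.
  # Integer ranges keep the 8-byte ASCII header fields exact.
  amax <- ceiling(apply(abs(signal), 1, max))
  amax[amax == 0] <- 1
  phys_min <- -amax
  phys_max <- amax
  dig_min <- -32767L
  dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .pad("0", 8), .pad(patient, 80), .pad(recording, 80),
    .pad("01.01.20", 8), .pad("00.00.00", 8),
    .pad(256 * (1 + nch), 8), .pad(sprintf("NSAMP=%d", nsamp), 44),
    .pad(nrec, 8), .num8(1), .pad(nch, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, .pad, "", n = width), collapse = ""),
              con, eos = NULL)
  field(rownames(signal), 16)
  field(rep("tin electrode", nch), 80)
  field(rep("uV", nch), 8)
  field(vapply(phys_min, .num8, ""), 8)
  field(vapply(phys_max, .num8, ""), 8)
  field(rep(dig_min, nch), 8)
  field(rep(dig_max, nch), 8)
  field(rep("", nch), 80)
  field(rep(spr, nch), 8)
  field(rep("", nch), 32)

  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  padded <- matrix(0, nch, nrec * spr)
  padded[, seq_len(nsamp)] <- signal
  dig <- round((padded - phys_min) / gain) + dig_min
  dig <- pmin(pmax(dig, dig_min), dig_max)
  # record-major: for each 1-s record, all samples of ch1, then ch2, ...
  arr <- array(t(dig), dim = c(spr, nrec, nch))
  out <- as.integer(aperm(arr, c(1, 3, 2)))
  writeBin(out, con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any simple EDF)
#'
#' @param path EDF file path.
#' @return List with \code{signal} (channels x samples matrix, physical
#'   units), \code{fs}, \code{patient} and \code{recording} header strings.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                                   # version
  patient <- trimws(rd(80))
  recording <- trimws(rd(80))
  rd(16)                                  # date + time
  rd(8)                                   # header bytes
  reserved <- trimws(rd(44))
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(nch), function(i) rd(16), ""))
  rd(80 * nch)                            # transducer
  rd(8 * nch)                             # physical dimension
  phys_min <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  rd(80 * nch)                            # prefilter
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8), ""))
  rd(32 * nch)                            # per-signal reserved
  if (length(unique(spr)) != 1)
    stop("mixed per-channel sampling rates are not supported")
  spr <- spr[1]
  fs <- spr / dur

  raw <- readBin(con, "integer", n = nrec * nch * spr, size = 2,
                 endian = "little")
  arr <- array(raw, dim = c(spr, nch, nrec))
  dig <- matrix(aperm(arr, c(1, 3, 2)), nrow = nrec * spr, ncol = nch)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  sig <- t(dig) * gain + (phys_min - dig_min * gain)
  rownames(sig) <- labels
  nsamp <- nrec * spr
  if (grepl("^NSAMP=", reserved)) {
    n_true <- as.integer(sub("^NSAMP=", "", reserved))
    if (!is.na(n_true) && n_true <= nsamp) sig <- sig[, seq_len(n_true), drop = FALSE]
  }
  list(signal = sig, fs = fs, patient = patient, recording = recording)
}
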