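# Minimal EDF (European Data Format) writer/reader: 16-bit samples, physical
# units in microvolts, 1-second data records. Covers what the package needs
# (continuous single/multi-channel exports and re-import); not a general EDF+
# implementation (no annotations, no discontinuous records).

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = -width)
}

num_field <- function(x, width) {
  for (d in (width - 1):1) {
    s <- formatC(signif(x, d), format = "g", digits = d)
    if (nchar(s) <= width) return(formatC(s, width = -width))
  }
  stop("numeric field does not fit the EDF header", call. = FALSE)
}

#' Write signals to an EDF file
#'
#' Signals are scaled to the full 16-bit digital range per channel and stored
#' in 1-second data records; trailing samples are zero-padded to a whole
#' record (the true length is recoverable from the physical data).
#'
#' @param signals Numeric vector or list of equal-length numeric vectors
#'   (channels), physical units microvolts.
#' @param fs Sampling rate in Hz (integer samples per 1-s record).
#' @param path Output file.
#' @param labels Channel labels (<= 16 ASCII chars each).
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, fs, path, labels = NULL) {
  if (is.numeric(signals)) signals <- list(signals)
  ns <- length(signals)
  check_that(ns > 0 && all(vapply(signals, is.numeric, TRUE)),
             "`signals` must be a numeric vector or list of numeric vectors")
  len <- unique(vapply(signals, length, 1L))
  check_that(length(len) == 1, "`signals` must share one length")
  check_that(is_count(fs) && fs > 0, "`fs` must be a positive integer")
  if (is.null(labels)) labels <- sprintf("ch%d", seq_len(ns))
  n_rec <- ceiling(len / fs)

  phys_min <- vapply(signals, function(x) min(x, -1e-6), 0)
  phys_max <- vapply(signals, function(x) max(x, 1e-6), 0)
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("synthetic iEEG", 80),
    pad_field("ieegnet export", 80),
    pad_field("01.01.20", 8), pad_field("00.00.00", 8),
    pad_field(256 * (ns + 1), 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(ns, 4),
    paste(vapply(labels, pad_field, "", width = 16), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(vapply(phys_min, num_field, "", width = 8), collapse = ""),
    paste(vapply(phys_max, num_field, "", width = 8), collapse = ""),
    paste(rep(pad_field(dig_min, 8), ns), collapse = ""),
    paste(rep(pad_field(dig_max, 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(fs, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)

  digital <- lapply(seq_len(ns), function(j) {
    x <- c(signals[[j]], numeric(n_rec * fs - len))
    g <- (dig_max - dig_min) / (phys_max[j] - phys_min[j])
    as.integer(round((x - phys_min[j]) * g + dig_min))
  })
  for (r in seq_len(n_rec)) {
    rng <- ((r - 1) * fs + 1):(r * fs)
    for (j in seq_len(ns))
      writeBin(digital[[j]][rng], con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any basic 16-bit EDF)
#'
#' @param path EDF file path.
#' @return List with `signals` (list of numeric vectors, physical units),
#'   `fs` (per channel), `labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rd(8)
  ns <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); rdv(8)
  phys_min <- as.numeric(rdv(8)); phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8)); dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)

  signals <- lapply(seq_len(ns), function(j) numeric(n_rec * spr[j]))
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[j], size = 2, endian = "little")
      signals[[j]][((r - 1) * spr[j] + 1):(r * spr[j])] <- raw
    }
  }
  for (j in seq_len(ns)) {
    g <- (phys_max[j] - phys_min[j]) / (dig_max[j] - dig_min[j])
    signals[[j]] <- (signals[[j]] - dig_min[j]) * g + phys_min[j]
  }
  list(signals = signals, fs = spr, labels = labels)
}
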