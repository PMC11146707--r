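# Minimal WFDB (PhysioNet waveform-database) support: header (.hea),
# format-16 signal (.dat), and the MIT binary annotation format (.atr)
# restricted to what rhythm-labeled long records need — annotation words
# with 10-bit time deltas, SKIP pseudo-annotations for long gaps, and AUX
# strings carrying rhythm change labels ("(AFIB", "(N", ...) attached to
# '+' (rhythm-change) annotations.

WFDB_RHYTHM_CODE <- 28L   # '+' rhythm change
WFDB_SKIP <- 59L
WFDB_NUM <- 60L
WFDB_SUB <- 61L
WFDB_CHN <- 62L
WFDB_AUX <- 63L

#' Read a WFDB record with rhythm annotations
#'
#' Reads `<record>.hea`, the format-16 signal file it names, and the
#' `<record>.atr` rhythm annotations. Rhythm intervals are reconstructed
#' from rhythm-change annotations: each one opens an interval that is
#' closed by the next rhythm change or by the end of the record.
#'
#' @param record Record path without extension.
#' @return List with `signal` (samples x leads matrix, mV), `fs`,
#'   `intervals` (a [rhythm_intervals()] table), and `annotations`
#'   (data.frame of raw annotation sample/code/aux).
#' @export
read_wfdb_record <- function(record) {
  hea <- paste0(record, ".hea")
  if (!file.exists(hea))
    stop("no record: header file not found: ", hea, call. = FALSE)
  lines <- grep("^#", trimws(readLines(hea)), value = TRUE, invert = TRUE)
  lines <- lines[nzchar(lines)]
  top <- strsplit(lines[1], "\\s+")[[1]]
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(top[3]) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig_lines <- lines[1 + seq_len(nsig)]
  parse_sig <- function(ln) {
    tok <- strsplit(ln, "\\s+")[[1]]
    fmt <- sub("x.*$", "", tok[2])
    if (fmt != "16")
      stop("unsupported WFDB signal format: ", tok[2],
           " (only format 16 is supported)", call. = FALSE)
    gainspec <- if (length(tok) >= 3) tok[3] else "200"
    gain <- as.numeric(sub("\\(.*$", "", sub("/.*$", "", gainspec)))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gainspec))
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gainspec))
    else if (length(tok) >= 5 && !is.na(suppressWarnings(
      as.numeric(tok[5])))) as.numeric(tok[5]) else 0
    list(file = tok[1], gain = gain, baseline = baseline)
  }
  sigs <- lapply(sig_lines, parse_sig)
  dat <- file.path(dirname(record), sigs[[1]]$file)
  if (!file.exists(dat))
    stop("no record: signal file not found: ", dat, call. = FALSE)
  raw <- readBin(dat, "integer", n = file.size(dat) / 2, size = 2,
                 signed = TRUE, endian = "little")
  n <- length(raw) %/% nsig
  m <- matrix(raw[seq_len(n * nsig)], ncol = nsig, byrow = TRUE)
  for (j in seq_len(nsig))
    m[, j] <- (m[, j] - sigs[[j]]$baseline) / sigs[[j]]$gain
  if (!is.na(nsamp) && nsamp < n) m <- m[seq_len(nsamp), , drop = FALSE]
  atr <- paste0(record, ".atr")
  if (!file.exists(atr))
    stop("no rhythm labels: annotation file not found: ", atr,
         call. = FALSE)
  ann <- read_wfdb_annotations(atr)
  rhy <- ann[ann$code == WFDB_RHYTHM_CODE & nzchar(ann$aux), , drop = FALSE]
  intervals <- if (nrow(rhy)) {
    rhythm_intervals(start = rhy$sample,
                     end = c(rhy$sample[-1], nrow(m)),
                     rhythm = sub("^\\(", "", rhy$aux))
  } else rhythm_intervals(numeric(0), numeric(0), character(0))
  list(signal = m, fs = fs, intervals = intervals, annotations = ann)
}

read_wfdb_annotations <- function(file) {
  bytes <- readBin(file, "raw", n = file.size(file))
  nw <- length(bytes) %/% 2
  words <- matrix(as.integer(bytes[seq_len(2 * nw)]), nrow = 2)
  vals <- words[1, ] + 256L * words[2, ]     # little-endian 16-bit
  samples <- integer(0); codes <- integer(0); auxs <- character(0)
  t <- 0; skip <- 0; i <- 1L
  while (i <= nw) {
    w <- vals[i]
    a <- w %/% 1024L
    f <- w %% 1024L
    if (w == 0L) break
    if (a == WFDB_SKIP) {
      hi <- vals[i + 1L]; lo <- vals[i + 2L]
      skip <- skip + hi * 65536 + lo
      i <- i + 3L
    } else if (a == WFDB_AUX) {
      nbytes <- f
      aux_raw <- bytes[(2L * i + 1L):(2L * i + nbytes)]
      auxs[length(auxs)] <- rawToChar(aux_raw[aux_raw != as.raw(0)])
      i <- i + 1L + ceiling(nbytes / 2)
    } else if (a %in% c(WFDB_NUM, WFDB_SUB, WFDB_CHN)) {
      i <- i + 1L
    } else {
      t <- t + skip + f
      skip <- 0
      samples <- c(samples, t)
      codes <- c(codes, a)
      auxs <- c(auxs, "")
      i <- i + 1L
    }
  }
  data.frame(sample = samples, code = codes, aux = auxs,
             stringsAsFactors = FALSE)
}

#' Write a WFDB record with rhythm annotations
#'
#' Writes a header, a format-16 signal file, and a `.atr` annotation file
#' holding one rhythm-change annotation per row of `rhythms`. Intended for
#' building small fixtures and for round-tripping [read_wfdb_record()].
#'
#' @param record Record path without extension.
#' @param signal Numeric vector or samples x leads matrix, in mV.
#' @param fs Sampling rate, Hz.
#' @param rhythms data.frame with columns `sample` (0-based onset) and
#'   `rhythm` (label, e.g. `"AFIB"`); may be empty.
#' @param gain ADC units per mV (default 200).
#' @return Invisibly, the record path.
#' @export
write_wfdb_record <- function(record, signal, fs, rhythms = NULL,
                              gain = 200) {
  if (!is.matrix(signal)) signal <- matrix(signal, ncol = 1)
  nsig <- ncol(signal); n <- nrow(signal)
  base <- basename(record)
  adc <- round(signal * gain)
  adc <- pmin(pmax(adc, -32768), 32767)
  hdr <- c(sprintf("%s %d %g %d", base, nsig, fs, n),
           sprintf("%s.dat 16 %g(0)/mV 16 0 %d 0 0 lead%d",
                   base, gain, as.integer(adc[1, seq_len(nsig)]),
                   seq_len(nsig)))
  writeLines(hdr, paste0(record, ".hea"))
  writeBin(as.integer(t(adc)), paste0(record, ".dat"), size = 2,
           endian = "little")
  con <- file(paste0(record, ".atr"), "wb")
  on.exit(close(con))
  wword <- function(w) writeBin(as.integer(c(w %% 256, w %/% 256)),
                                con, size = 1)
  t_prev <- 0
  if (!is.null(rhythms) && nrow(rhythms)) {
    rhythms <- rhythms[order(rhythms$sample), , drop = FALSE]
    for (r in seq_len(nrow(rhythms))) {
      delta <- rhythms$sample[r] - t_prev
      if (delta > 1023) {
        wword(WFDB_SKIP * 1024L)
        wword(delta %/% 65536)
        wword(delta %% 65536)
        delta <- 0
      }
      wword(WFDB_RHYTHM_CODE * 1024L + delta)
      aux <- paste0("(", rhythms$rhythm[r])
      ab <- charToRaw(aux)
      wword(WFDB_AUX * 1024L + length(ab))
      if (length(ab) %% 2) ab <- c(ab, as.raw(0))
      writeBin(ab, con)
      t_prev <- rhythms$sample[r]
    }
  }
  wword(0L)
  invisible(record)
}
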