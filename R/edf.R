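# Minimal EDF (European Data Format) I/O: continuous recordings, identical
# sampling rate on every channel, 1-second data records, 16-bit samples.
# Annotations travel in a CSV sidecar (onset_s, duration_s, label) rather
# than as an EDF+ annotations signal.

padField <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width)
}

#' Write a recording to EDF
#'
#' Writes a continuous EDF file (1-second records, 16-bit samples, per
#' channel physical scaling from the data range). The recording is truncated
#' to a whole number of seconds. Condition and artifact annotations are not
#' stored in the EDF itself; use [writeAnnotations()] for the sidecar.
#'
#' @param rec a [Recording-class]
#' @param file output path
#' @return the path, invisibly
#' @export
writeEdf <- function(rec, file) {
  fs <- rec@samplingRate
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  ns <- nrow(rec@samples)
  nrec <- floor(ncol(rec@samples) / fs)
  if (nrec < 1) stop("recording shorter than one EDF record (1 s)")
  X <- rec@samples[, seq_len(nrec * fs), drop = FALSE]

  # rounded to the 2-decimal precision of the header field so that the
  # scaling used for quantisation matches what a reader recovers
  physMax <- round(pmax(apply(abs(X), 1, max), 0.01), 2) + 0.01
  digMax <- 32767
  D <- round(X / physMax * digMax)
  storage.mode(D) <- "integer"

  con <- file(file, "wb")
  on.exit(close(con))
  hdr <- paste0(
    padField("0", 8),
    padField(rec@participant, 80),
    padField("eegperm export", 80),
    padField("01.01.00", 8), padField("00.00.00", 8),
    padField(256 * (1 + ns), 8),
    padField("", 44),
    padField(nrec, 8),
    padField(1, 8),
    padField(ns, 4))
  writeChar(hdr, con, eos = NULL)
  sig <- paste0(
    paste(padField(rownames(X), 16), collapse = ""),
    paste(rep(padField("", 80), ns), collapse = ""),
    paste(rep(padField("uV", 8), ns), collapse = ""),
    paste(padField(sprintf("%.2f", -physMax), 8), collapse = ""),
    paste(padField(sprintf("%.2f", physMax), 8), collapse = ""),
    paste(rep(padField(-digMax, 8), ns), collapse = ""),
    paste(rep(padField(digMax, 8), ns), collapse = ""),
    paste(rep(padField("", 80), ns), collapse = ""),
    paste(rep(padField(fs, 8), ns), collapse = ""),
    paste(rep(padField("", 32), ns), collapse = ""))
  writeChar(sig, con, eos = NULL)
  for (r in seq_len(nrec)) {
    idx <- (r - 1) * fs + seq_len(fs)
    writeBin(as.integer(t(D[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(file)
}

#' Read an EDF file into a Recording
#'
#' Supports the subset written by [writeEdf()]: continuous recordings with
#' the same number of samples per record on every signal.
#'
#' @param file path to an EDF file
#' @return a [Recording-class] (reference flag `"original"`, no annotations)
#' @export
readEdf <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8) # version
  participant <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  nrec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80) # transducer
  for (i in seq_len(ns)) rd(8)  # dimension
  physMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  physMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  digMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  digMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80) # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("only recordings with a common sampling rate are supported")
  fs <- spr[1] / recDur
  X <- matrix(0, ns, nrec * spr[1], dimnames = list(labels, NULL))
  for (r in seq_len(nrec)) {
    raw <- readBin(con, integer(), n = ns * spr[1], size = 2,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    for (i in seq_len(ns)) {
      scale <- (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
      X[i, (r - 1) * spr[1] + seq_len(spr[1])] <-
        physMin[i] + (block[, i] - digMin[i]) * scale
    }
  }
  recording(X, fs, participant = participant)
}

#' Write / read the annotations sidecar
#'
#' Condition blocks are written as `condition:state/memory/phase` labels,
#' artifacts as `artifact`; bad channels as `bad_channel:<label>` rows with
#' zero duration.
#'
#' @param rec a [Recording-class]
#' @param file sidecar CSV path (`onset_s`, `duration_s`, `label`)
#' @return `readAnnotations` returns the raw sidecar `data.frame`;
#'   `applyAnnotations` returns the recording with annotations attached.
#' @export
writeAnnotations <- function(rec, file) {
  ca <- rec@conditionAnnotations
  rows <- data.frame(onset_s = numeric(), duration_s = numeric(),
                     label = character())
  if (nrow(ca))
    rows <- rbind(rows, data.frame(
      onset_s = ca$onset_s, duration_s = ca$duration_s,
      label = paste0("condition:", ca$state, "/", ca$memory, "/",
                     ca$phase)))
  aa <- rec@artifactAnnotations
  if (nrow(aa))
    rows <- rbind(rows, data.frame(onset_s = aa$onset_s,
                                   duration_s = aa$duration_s,
                                   label = "artifact"))
  if (length(rec@badChannels))
    rows <- rbind(rows, data.frame(onset_s = 0, duration_s = 0,
                                   label = paste0("bad_channel:",
                                                  rec@badChannels)))
  write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeAnnotations
#' @export
readAnnotations <- function(file) read.csv(file, stringsAsFactors = FALSE)

#' @rdname writeAnnotations
#' @export
applyAnnotations <- function(rec, file) {
  ann <- readAnnotations(file)
  cond <- ann[startsWith(ann$label, "condition:"), , drop = FALSE]
  if (nrow(cond)) {
    parts <- do.call(rbind, strsplit(sub("^condition:", "", cond$label),
                                     "/", fixed = TRUE))
    rec@conditionAnnotations <- data.frame(
      onset_s = cond$onset_s, duration_s = cond$duration_s,
      state = parts[, 1], memory = parts[, 2], phase = parts[, 3])
  }
  art <- ann[ann$label == "artifact", , drop = FALSE]
  rec@artifactAnnotations <- data.frame(onset_s = art$onset_s,
                                        duration_s = art$duration_s)
  bad <- ann[startsWith(ann$label, "bad_channel:"), , drop = FALSE]
  rec@badChannels <- sub("^bad_channel:", "", bad$label)
  validObject(rec)
  rec
}
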