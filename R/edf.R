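# Minimal EDF+C writer/reader for 59-channel recordings.
# 16-bit samples, 1 s data records, annotations stored as EDF+ TALs in a
# dedicated "EDF Annotations" signal.

.edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

.edfNum <- function(x, width)
  .edfPad(trimws(formatC(x, format = "g", digits = 8)), width)

# TAL byte stream for one record: timestamp TAL plus the events whose onset
# falls inside [recStart, recStart + 1).
.talBytes <- function(recStart, events) {
  out <- c(charToRaw(sprintf("+%g\x14\x14", recStart)), as.raw(0L))
  for (i in seq_len(nrow(events)))
    out <- c(out,
             charToRaw(sprintf("+%g\x15%g\x14%s\x14", events$onset[i],
                               events$duration[i], events$label[i])),
             as.raw(0L))
  out
}

#' Write a recording to an EDF+ file
#'
#' Signals are quantised to 16 bits over each channel's physical range;
#' annotations are encoded as EDF+ time-stamped annotation lists. The
#' recording is padded with zeros to a whole number of 1 s data records.
#'
#' @param rec an [EEGRecording-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  rate <- rec@rate
  if (abs(rate - round(rate)) > 1e-9)
    stop("EDF export requires an integer sampling rate")
  rate <- as.integer(round(rate))
  nch <- nrow(rec@signals)
  n <- ncol(rec@signals)
  nrec <- as.integer(ceiling(n / rate))
  sig <- rec@signals
  if (nrec * rate > n)
    sig <- cbind(sig, matrix(0, nch, nrec * rate - n))

  # physical limits rounded to 2 decimals so that the 8-byte header fields
  # carry exactly the values used for quantisation
  pmin <- floor(apply(sig, 1, min) * 100) / 100
  pmax <- ceiling(apply(sig, 1, max) * 100) / 100
  flat <- pmax - pmin < 1e-2
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767
  dig <- round((sig - pmin) / (pmax - pmin) * (dmax - dmin) + dmin)
  storage.mode(dig) <- "integer"

  ann <- rec@annotations
  recIdx <- if (nrow(ann)) pmin(floor(ann$onset), nrec - 1L) else integer()
  talSize <- max(c(64L, vapply(seq_len(nrec) - 1L, function(r) {
    length(.talBytes(r, ann[recIdx == r, , drop = FALSE]))
  }, integer(1))))
  talSize <- as.integer(2L * ceiling(talSize / 2L))  # whole int16 samples

  ns <- nch + 1L
  hdrBytes <- 256L * (ns + 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(.edfPad("0", 8))
  wr(.edfPad(paste("X X X", rec@subject), 80))
  wr(.edfPad("Startdate 01-JAN-2000 X X X", 80))
  wr(.edfPad("01.01.00", 8)); wr(.edfPad("00.00.00", 8))
  wr(.edfNum(hdrBytes, 8)); wr(.edfPad("EDF+C", 44))
  wr(.edfNum(nrec, 8)); wr(.edfNum(1, 8)); wr(.edfNum(ns, 4))
  labels <- c(channelNames(rec), "EDF Annotations")
  for (l in labels) wr(.edfPad(l, 16))
  for (i in seq_len(ns)) wr(.edfPad("", 80))
  for (i in seq_len(ns)) wr(.edfPad(if (i <= nch) "uV" else "", 8))
  for (v in c(pmin, -1)) wr(.edfNum(v, 8))
  for (v in c(pmax, 1)) wr(.edfNum(v, 8))
  for (i in seq_len(ns)) wr(.edfNum(dmin, 8))
  for (i in seq_len(ns)) wr(.edfNum(dmax, 8))
  for (i in seq_len(ns)) wr(.edfPad("", 80))
  for (i in seq_len(ns)) wr(.edfNum(c(rep(rate, nch), talSize / 2L)[i], 8))
  for (i in seq_len(ns)) wr(.edfPad("", 32))

  for (r in seq_len(nrec) - 1L) {
    cols <- (r * rate + 1L):((r + 1L) * rate)
    writeBin(as.vector(t(dig[, cols, drop = FALSE])), con,
             size = 2L, endian = "little")
    tal <- .talBytes(r, ann[recIdx == r, , drop = FALSE])
    writeBin(c(tal, raw(talSize - length(tal))), con)
  }
  invisible(path)
}

#' Read an EDF+ file written for the 59-channel montage
#'
#' Parses the EDF header, reconstructs physical signal values and decodes
#' EDF+ annotation lists. Files whose data channels do not match the
#' 59-electrode montage are rejected.
#'
#' @param path EDF file path.
#' @return An [EEGRecording-class].
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nb) readChar(con, nb, useBytes = TRUE)
  rd(8)                       # version
  patient <- trimws(rd(80))
  rd(80); rd(8); rd(8); rd(8); rd(44)
  nrec <- as.integer(trimws(rd(8)))
  recDur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  fld <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- fld(16); fld(80); fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)

  isAnn <- labels == "EDF Annotations"
  montage <- standardMontage()
  dataIdx <- which(!isAnn)
  if (!identical(labels[dataIdx], montage@labels))
    stop("EDF format error: expected the 59-channel montage, got ",
         length(dataIdx), " data channels")
  rate <- spr[dataIdx[1]] / recDur
  nch <- length(dataIdx)
  sig <- matrix(0, nch, nrec * spr[dataIdx[1]])
  talRaw <- raw()
  for (r in seq_len(nrec) - 1L) {
    for (i in seq_len(ns)) {
      if (isAnn[i]) {
        talRaw <- c(talRaw, readBin(con, "raw", n = 2L * spr[i]))
      } else {
        v <- readBin(con, "integer", n = spr[i], size = 2L,
                     endian = "little")
        j <- match(i, dataIdx)
        sig[j, (r * spr[i] + 1L):((r + 1L) * spr[i])] <-
          (v - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) + pmin[i]
      }
    }
  }
  ann <- .parseTALs(talRaw)
  subject <- sub("^X X X ?", "", patient)
  new("EEGRecording", signals = sig, rate = rate, montage = montage,
      annotations = ann, subject = subject)
}

# Decode concatenated TAL byte stream into an annotation data.frame,
# dropping the per-record timekeeping TALs (empty label). TALs are
# terminated by a NUL byte; fields inside a TAL are \x14-separated and the
# onset/duration pair is \x15-separated.
.parseTALs <- function(bytes) {
  zero <- bytes == as.raw(0L)
  grp <- cumsum(c(TRUE, zero[-length(zero)]))
  segs <- split(bytes[!zero], grp[!zero])
  out <- list()
  for (seg in segs) {
    parts <- strsplit(rawToChar(seg), "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2L || !nzchar(parts[2])) next
    od <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
    out[[length(out) + 1L]] <- data.frame(
      onset = as.numeric(od[1]),
      duration = if (length(od) > 1L) as.numeric(od[2]) else 0,
      label = parts[2])
  }
  if (!length(out))
    return(data.frame(onset = numeric(), duration = numeric(),
                      label = character()))
  res <- do.call(rbind, out)
  res[order(res$onset), , drop = FALSE]
}
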