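# EDF+ reading and writing. Implemented against the EDF/EDF+ specification:
# 256-byte fixed header, 256 bytes per signal header, data records of 16-bit
# little-endian integers, events coded as time-stamped annotation lists
# (TALs) in an "EDF Annotations" signal. Physical values are microvolts.

.edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: '", x, "'")
  formatC(x, width = width, flag = "-")
}

.edfNum <- function(x, width) {
  s <- formatC(x, width = 1, format = "g", digits = 7)
  if (nchar(s) > width) s <- substr(s, 1, width)
  .edfPad(s, width)
}

#' Write a recording as EDF+
#'
#' Samples are quantized to 16 bits over a symmetric physical range chosen
#' from the data (so quantization error is at most physicalRange/2^16), and
#' events are stored as EDF+ annotations whose labels are the condition
#' names. Data records are 1 s long; the final record is zero-padded when
#' the recording length is not a whole number of seconds.
#'
#' @param recording an [EEGRecording-class].
#' @param path output file path.
#' @param physMax symmetric physical range bound in microvolts; by default
#'   the smallest multiple of 100 covering the data.
#' @return \code{path}, invisibly.
#' @seealso [readEDF()]
#' @export
writeEDF <- function(recording, path, physMax = NULL) {
  stopifnot(is(recording, "EEGRecording"))
  validObject(recording)
  X <- recording@data
  rate <- recording@rate
  if (rate != round(rate)) stop("writeEDF requires an integer sampling rate")
  nCh <- nrow(X)
  if (is.null(physMax)) physMax <- max(100, ceiling(max(abs(X)) / 100) * 100)
  nRec <- as.integer(ceiling(ncol(X) / rate))
  padded <- cbind(X, matrix(0, nCh, nRec * rate - ncol(X)))
  # affine map [-physMax, physMax] -> [-32768, 32767], the inverse of the
  # reader's physMin + (v - digMin) * range ratio
  dig <- matrix(as.integer(round((padded + physMax) / (2 * physMax) * 65535
                                 - 32768)), nCh)
  dig[dig > 32767L] <- 32767L
  dig[dig < -32768L] <- -32768L

  # annotation payload per record (as raw, since TAL separators include a
  # nul byte): a record-start TAL plus the events onsetting in that second
  SEP <- as.raw(20)   # 0x14, annotation separator
  DUR <- as.raw(21)   # 0x15, duration marker
  NUL <- as.raw(0)
  onsetSec <- (recording@events@onsets - 1) / rate
  labs <- as.character(recording@events@labels)
  annByRec <- lapply(seq_len(nRec) - 1, function(r) {
    tal <- c(charToRaw(sprintf("+%g", r)), SEP, SEP, NUL)
    inRec <- which(onsetSec >= r & onsetSec < r + 1)
    evs <- lapply(inRec, function(i)
      c(charToRaw(sprintf("+%.6f", onsetSec[i])), DUR, charToRaw("0"),
        SEP, charToRaw(labs[i]), SEP, NUL))
    c(tal, unlist(evs))
  })
  annBytes <- max(vapply(annByRec, length, integer(1))) + 2
  annSamples <- as.integer(ceiling(annBytes / 2))

  ns <- nCh + 1L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(.edfPad("0", 8))
  wr(.edfPad("X X X X", 80))
  wr(.edfPad("Startdate 01-JAN-2000 X X X", 80))
  wr(.edfPad("01.01.00", 8))
  wr(.edfPad("00.00.00", 8))
  wr(.edfNum(256 * (ns + 1), 8))
  wr(.edfPad("EDF+C", 44))
  wr(.edfNum(nRec, 8))
  wr(.edfNum(1, 8))
  wr(.edfNum(ns, 4))
  labels <- c(recording@montage@channelNames, "EDF Annotations")
  for (l in labels) wr(.edfPad(l, 16))
  for (l in labels) wr(.edfPad("", 80))                       # transducer
  wr(paste(vapply(seq_len(ns), function(i)
    .edfPad(if (i <= nCh) "uV" else "", 8), character(1)), collapse = ""))
  for (i in seq_len(ns)) wr(.edfNum(if (i <= nCh) -physMax else -1, 8))
  for (i in seq_len(ns)) wr(.edfNum(if (i <= nCh) physMax else 1, 8))
  for (i in seq_len(ns)) wr(.edfNum(-32768, 8))
  for (i in seq_len(ns)) wr(.edfNum(32767, 8))
  for (i in seq_len(ns)) wr(.edfPad("", 80))                  # prefiltering
  for (i in seq_len(ns)) wr(.edfNum(if (i <= nCh) rate else annSamples, 8))
  for (i in seq_len(ns)) wr(.edfPad("", 32))                  # reserved

  for (r in seq_len(nRec)) {
    idx <- ((r - 1) * rate + 1):(r * rate)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
    raw <- annByRec[[r]]
    raw <- c(raw, raw(annSamples * 2 - length(raw)))
    writeBin(raw, con)
  }
  invisible(path)
}

.readEdfField <- function(con, width, n = 1) {
  vapply(seq_len(n), function(i) {
    s <- readChar(con, width, useBytes = TRUE)
    if (nchar(s, type = "bytes") < width) stop("truncated EDF header")
    trimws(s)
  }, character(1))
}

.edfHeaderNum <- function(x, field) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v)))
    stop("malformed EDF header: field '", field, "' is not numeric ('",
         paste(x[is.na(v)], collapse = "', '"), "')")
  v
}

#' Read an EDF/EDF+ file
#'
#' Reconstructs an [EEGRecording-class] from an EDF+ file written by
#' [writeEDF()] (or any EDF+ file whose events are annotation-coded with
#' labels neutral/happy/angry/emotional). A montage can be supplied; by
#' default channel positions are looked up in [standardMontage()].
#'
#' @param path EDF file path.
#' @param montage optional [Montage-class] matching the file's channels.
#' @return an [EEGRecording-class].
#' @export
readEDF <- function(path, montage = NULL) {
  fsize <- file.info(path)$size
  if (is.na(fsize) || fsize < 256) stop("not an EDF file (shorter than one header)")
  con <- file(path, "rb")
  on.exit(close(con))
  .readEdfField(con, 8)                       # version
  .readEdfField(con, 80); .readEdfField(con, 80)
  .readEdfField(con, 8); .readEdfField(con, 8)
  headerBytes <- .edfHeaderNum(.readEdfField(con, 8), "header bytes")
  .readEdfField(con, 44)
  nRec <- .edfHeaderNum(.readEdfField(con, 8), "number of data records")
  recDur <- .edfHeaderNum(.readEdfField(con, 8), "record duration")
  ns <- as.integer(.edfHeaderNum(.readEdfField(con, 4), "number of signals"))
  if (ns < 1) stop("malformed EDF header: number of signals < 1")
  if (headerBytes != 256 * (ns + 1))
    stop("malformed EDF header: header bytes inconsistent with signal count")
  labels <- .readEdfField(con, 16, ns)
  .readEdfField(con, 80, ns)
  .readEdfField(con, 8, ns)
  physMin <- .edfHeaderNum(.readEdfField(con, 8, ns), "physical minimum")
  physMax <- .edfHeaderNum(.readEdfField(con, 8, ns), "physical maximum")
  digMin <- .edfHeaderNum(.readEdfField(con, 8, ns), "digital minimum")
  digMax <- .edfHeaderNum(.readEdfField(con, 8, ns), "digital maximum")
  .readEdfField(con, 80, ns)
  spr <- as.integer(.edfHeaderNum(.readEdfField(con, 8, ns), "samples per record"))
  .readEdfField(con, 32, ns)

  isAnn <- labels == "EDF Annotations"
  recBytes <- 2 * sum(spr)
  expect <- headerBytes + nRec * recBytes
  if (fsize < expect)
    stop("truncated EDF file: expected ", expect, " bytes, found ", fsize)
  eeg <- which(!isAnn)
  rate <- spr[eeg[1]] / recDur
  if (any(spr[eeg] != spr[eeg[1]]))
    stop("unsupported EDF: differing per-signal sampling rates")

  data <- matrix(0, length(eeg), nRec * spr[eeg[1]])
  annText <- character(0)
  for (r in seq_len(nRec)) {
    for (s in seq_len(ns)) {
      if (isAnn[s]) {
        raw <- readBin(con, "raw", n = 2 * spr[s])
        annText <- c(annText, rawToChar(raw[raw != as.raw(0)], multiple = FALSE))
      } else {
        v <- readBin(con, "integer", n = spr[s], size = 2, endian = "little")
        j <- match(s, eeg)
        scale <- (physMax[s] - physMin[s]) / (digMax[s] - digMin[s])
        data[j, ((r - 1) * spr[s] + 1):(r * spr[s])] <-
          physMin[s] + (v - digMin[s]) * scale
      }
    }
  }
  rownames(data) <- labels[eeg]

  # parse TALs: "+onset(\x15dur)?\x14label\x14"; drop record-start stamps
  tals <- regmatches(paste(annText, collapse = ""),
    gregexpr("[+-][0-9.]+(\x15[0-9.]*)?\x14[^\x14]+\x14",
             paste(annText, collapse = "")))[[1]]
  onsets <- integer(0); labs <- character(0)
  for (tal in tals) {
    parts <- strsplit(tal, "\x14")[[1]]
    lab <- parts[2]
    t0 <- as.numeric(strsplit(parts[1], "\x15")[[1]][1])
    onsets <- c(onsets, as.integer(round(t0 * rate)) + 1L)
    labs <- c(labs, lab)
  }
  ord <- order(onsets)
  lv <- intersect(c("neutral", "happy", "angry", "emotional"), labs)
  if (!length(lv)) lv <- unique(labs)
  events <- new("EventSequence", onsets = onsets[ord],
                labels = factor(labs[ord], levels = lv),
                interOnsetMs = if (length(onsets) > 1)
                  min(diff(sort(onsets))) / rate * 1000 else 2200)
  if (is.null(montage)) {
    std <- standardMontage()
    if (all(rownames(data) %in% std@channelNames)) {
      mast <- intersect(std@mastoidLabels, rownames(data))
      if (length(mast) < 2) mast <- rownames(data)[1:2]
      montage <- subsetMontage(std, rownames(data), mast)
    } else {
      stop("channels not in the standard montage; supply `montage`")
    }
  }
  new("EEGRecording", data = data, rate = rate, montage = montage,
      events = events)
}
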