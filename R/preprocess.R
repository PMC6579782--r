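# Preprocessing chain: mastoid re-referencing, zero-phase filtering,
# epoching with baseline correction, peak-to-peak artifact rejection and
# inverse-distance bad-channel interpolation.

#' Re-reference to the mastoid average
#'
#' Subtracts the per-sample mean of the left and right mastoid channels
#' from every channel (the offline reference used after online FCz
#' referencing).
#'
#' @param rec an [EEGRecording-class] whose montage names both mastoids.
#' @return the re-referenced [EEGRecording-class].
#' @export
rereferenceToMastoids <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  mast <- rec@montage@mastoidLabels
  missing <- setdiff(mast, rownames(rec@data))
  if (length(missing))
    stop("mastoid channel(s) ", paste(missing, collapse = ", "),
         " not found; available: ", paste(rownames(rec@data), collapse = ", "))
  ref <- colMeans(rec@data[mast, , drop = FALSE])
  rec@data <- sweep(rec@data, 2, ref)
  rec
}

#' Zero-phase filter a recording
#'
#' Applies, in order, a 4th-order Butterworth high-pass, a 4th-order
#' Butterworth low-pass and a 2nd-order IIR notch (Q = 30), each
#' forward-backward (zero phase) as cascaded second-order sections. Any
#' stage can be skipped by passing \code{NULL}. Defaults follow the
#' 0.1-30 Hz analysis band with 50 Hz mains suppression.
#'
#' @param rec an [EEGRecording-class].
#' @param hpHz,lpHz,notchHz cutoff / notch frequencies in Hz (all below the
#'   Nyquist frequency; \code{hpHz < lpHz}).
#' @param notchQ notch quality factor.
#' @return the filtered [EEGRecording-class].
#' @export
filterRecording <- function(rec, hpHz = 0.1, lpHz = 30, notchHz = 50,
                            notchQ = 30) {
  stopifnot(is(rec, "EEGRecording"))
  nyq <- rec@rate / 2
  for (f in c(hpHz, lpHz, notchHz))
    if (!is.null(f) && f >= nyq)
      stop("cutoff ", f, " Hz is at or above the Nyquist frequency (", nyq, " Hz)")
  if (!is.null(hpHz) && !is.null(lpHz) && hpHz >= lpHz)
    stop("high-pass cutoff must be below the low-pass cutoff")
  sos <- c(
    if (!is.null(hpHz)) zpk2sos(butterZpk(4, hpHz, rec@rate, "high")),
    if (!is.null(lpHz)) zpk2sos(butterZpk(4, lpHz, rec@rate, "low")),
    if (!is.null(notchHz)) notchSos(notchHz, rec@rate, notchQ))
  if (is.null(sos) || !length(sos)) return(rec)
  out <- t(sosFiltfiltMat(sos, t(rec@data)))
  rownames(out) <- rownames(rec@data)
  rec@data <- out
  rec
}

#' Cut stimulus-locked epochs
#'
#' Segments the recording into half-open windows
#' \code{[windowMs[1], windowMs[2])} around each event onset and subtracts
#' the per-trial, per-channel mean of the baseline interval. At 500 Hz the
#' default [-200, 1000) ms window yields exactly 600 samples. Events whose
#' window would fall outside the recording are dropped with a warning.
#'
#' @param rec an [EEGRecording-class] with events.
#' @param windowMs half-open epoch window in ms relative to onset.
#' @param baselineMs half-open baseline interval (must lie in the window);
#'   \code{NULL} disables baseline correction.
#' @return an [EpochSet-class].
#' @export
epochRecording <- function(rec, windowMs = c(-200, 1000),
                           baselineMs = c(-200, 0)) {
  stopifnot(is(rec, "EEGRecording"))
  if (!length(rec@events@onsets)) stop("recording has no events")
  if (!is.null(baselineMs) &&
      (baselineMs[1] < windowMs[1] || baselineMs[2] > windowMs[2]))
    stop("baseline interval must lie within the epoch window")
  rate <- rec@rate
  s0 <- round(windowMs[1] / 1000 * rate)
  s1 <- round(windowMs[2] / 1000 * rate) - 1   # half-open upper edge
  rel <- s0:s1
  nS <- ncol(rec@data)
  keep <- rec@events@onsets + s0 >= 1 & rec@events@onsets + s1 <= nS
  if (!any(keep)) stop("no usable events: all epoch windows fall outside the recording")
  if (any(!keep))
    warning(sum(!keep), " event(s) dropped: epoch window outside the recording")
  onsets <- rec@events@onsets[keep]
  labels <- droplevels(rec@events@labels[keep])
  nT <- length(onsets)
  nCh <- nrow(rec@data)
  dat <- array(0, c(nT, nCh, length(rel)))
  for (k in seq_len(nT)) dat[k, , ] <- rec@data[, onsets[k] + rel]
  timesMs <- rel / rate * 1000
  if (!is.null(baselineMs)) {
    bl <- which(timesMs >= baselineMs[1] & timesMs < baselineMs[2])
    base <- apply(dat[, , bl, drop = FALSE], c(1, 2), mean)
    dat <- dat - as.vector(base)   # recycles over the time dimension
  } else {
    baselineMs <- c(NA_real_, NA_real_)
  }
  new("EpochSet", data = dat, timesMs = timesMs, labels = labels,
      rate = rate, montage = rec@montage, baselineWindowMs = baselineMs,
      nDropped = sum(!keep))
}

#' Reject high-amplitude epochs
#'
#' Drops every trial whose peak-to-peak amplitude (max minus min) on any
#' scalp channel exceeds the threshold; mastoid channels are ignored. The
#' per-trial decisions are attached as attribute \code{"rejectionLog"}
#' (data.frame: trial, condition, worst channel, peak-to-peak, decision)
#' and the surviving count per condition is reported as a message.
#'
#' @param epochs an [EpochSet-class].
#' @param peakToPeakUv rejection threshold in microvolts (> 0); 150 by
#'   default.
#' @return the pruned [EpochSet-class] with the rejection log attached.
#' @export
rejectArtifactEpochs <- function(epochs, peakToPeakUv = 150) {
  stopifnot(is(epochs, "EpochSet"))
  if (!(peakToPeakUv > 0)) stop("threshold must be > 0")
  scalp <- match(scalpChannels(epochs@montage), epochs@montage@channelNames)
  nT <- dim(epochs@data)[1]
  p2pCh <- apply(epochs@data[, scalp, , drop = FALSE], c(1, 2), max) -
           apply(epochs@data[, scalp, , drop = FALSE], c(1, 2), min)
  worst <- max.col(p2pCh)
  p2p <- p2pCh[cbind(seq_len(nT), worst)]
  keep <- p2p <= peakToPeakUv
  log <- data.frame(trial = seq_len(nT),
                    condition = as.character(epochs@labels),
                    channel = scalpChannels(epochs@montage)[worst],
                    peakToPeakUv = p2p,
                    decision = ifelse(keep, "keep", "reject"))
  if (!any(keep))
    stop("all ", nT, " trials exceed ", peakToPeakUv,
         " uV peak-to-peak; review the rejection threshold")
  surv <- table(droplevels(epochs@labels[keep]))
  message("artifact rejection: kept ", sum(keep), "/", nT, " trials (",
          paste(sprintf("%s=%d", names(surv), surv), collapse = ", "), ")")
  epochs@data <- epochs@data[keep, , , drop = FALSE]
  epochs@labels <- droplevels(epochs@labels[keep])
  attr(epochs, "rejectionLog") <- log
  epochs
}

#' Interpolate a bad channel
#'
#' Replaces the bad channel, in every trial and timepoint, by the
#' inverse-great-circle-distance weighted average of the remaining scalp
#' channels (weights proportional to 1/distance, normalized to sum to 1).
#'
#' @param epochs an [EpochSet-class].
#' @param bad name of the channel to rebuild.
#' @return the [EpochSet-class] with the channel replaced.
#' @export
interpolateChannel <- function(epochs, bad) {
  stopifnot(is(epochs, "EpochSet"))
  chans <- epochs@montage@channelNames
  ib <- match(bad, chans)
  if (is.na(ib)) stop("channel '", bad, "' not in montage")
  good <- setdiff(scalpChannels(epochs@montage), bad)
  if (length(good) < 2) stop("need at least 2 good scalp channels")
  ig <- match(good, chans)
  P <- epochs@montage@positions
  cosang <- pmin(1, pmax(-1, P[ig, , drop = FALSE] %*% P[ib, ]))
  d <- acos(cosang)
  w <- as.numeric(1 / d)
  w <- w / sum(w)
  for (k in seq_len(dim(epochs@data)[1]))
    epochs@data[k, ib, ] <- crossprod(epochs@data[k, ig, , drop = TRUE], w)
  attr(epochs, "interpolationWeights") <- stats::setNames(w, good)
  epochs
}
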