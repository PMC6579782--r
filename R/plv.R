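# Phase-locking-value connectivity: band-passed analytic-signal phase,
# across-trial PLV per timepoint, time-averaged over the post-stimulus
# window (Lachaux-style event-related formulation).

#' Instantaneous phase of epoched data
#'
#' Band-pass filters every trial and channel (zero-phase, 4th-order
#' Butterworth sections) and takes the angle of the analytic signal.
#' The epoch must contain at least one full cycle of the band's low edge,
#' otherwise the phase estimate is meaningless and an error is raised.
#'
#' @param epochs an [EpochSet-class].
#' @param bandHz length-2 band (Hz), inside (0, Nyquist).
#' @return a [PhaseTensor-class] with values in (-pi, pi].
#' @export
instantaneousPhase <- function(epochs, bandHz = c(1, 30)) {
  stopifnot(is(epochs, "EpochSet"))
  nyq <- epochs@rate / 2
  if (length(bandHz) != 2 || bandHz[1] <= 0 || bandHz[2] <= bandHz[1] ||
      bandHz[2] >= nyq)
    stop("invalid band: need 0 < low < high < Nyquist (", nyq, " Hz)")
  d <- dim(epochs@data)
  epochSec <- d[3] / epochs@rate
  if (epochSec < 1 / bandHz[1])
    stop("epoch (", signif(epochSec, 3), " s) shorter than one cycle of the ",
         bandHz[1], " Hz band edge")
  # time x (trial*channel) matrix, filter all series at once
  X <- matrix(aperm(epochs@data, c(3, 1, 2)), d[3], d[1] * d[2])
  X <- sosFiltfiltMat(zpk2sos(butterZpk(4, bandHz[1], epochs@rate, "high")), X)
  X <- sosFiltfiltMat(zpk2sos(butterZpk(4, bandHz[2], epochs@rate, "low")), X)
  ph <- Arg(analyticSignalMat(X))
  ph <- aperm(array(ph, c(d[3], d[1], d[2])), c(2, 3, 1))
  new("PhaseTensor", phase = ph, bandHz = bandHz, timesMs = epochs@timesMs,
      labels = epochs@labels, channelNames = epochs@montage@channelNames,
      rate = epochs@rate)
}

.windowIndex <- function(timesMs, windowMs) {
  it <- which(timesMs >= windowMs[1] & timesMs <= windowMs[2])
  if (!length(it)) stop("averaging window contains no samples")
  it
}

#' Phase-locking value of one channel pair
#'
#' PLV(t) = |K^-1 sum_k exp(i (phi_a,k(t) - phi_b,k(t)))| over the K trials,
#' averaged over the post-stimulus window. 0 means no locking, 1 perfect
#' locking.
#'
#' @param phases a [PhaseTensor-class].
#' @param chA,chB channel names.
#' @param windowMs averaging interval in ms (default 0-1000, post-stimulus
#'   only so the baseline does not dilute condition effects).
#' @param trials optional trial subset (indices); default all trials.
#' @return PLV in [0, 1].
#' @export
plvPair <- function(phases, chA, chB, windowMs = c(0, 1000), trials = NULL) {
  stopifnot(is(phases, "PhaseTensor"))
  ia <- match(chA, phases@channelNames)
  ib <- match(chB, phases@channelNames)
  if (is.na(ia) || is.na(ib)) stop("unknown channel name")
  if (is.null(trials)) trials <- seq_len(dim(phases@phase)[1])
  if (length(trials) < 2)
    stop("PLV is degenerate with a single trial (always 1); need >= 2 trials")
  it <- .windowIndex(phases@timesMs, windowMs)
  dphi <- phases@phase[trials, ia, it, drop = TRUE] -
          phases@phase[trials, ib, it, drop = TRUE]
  plvT <- Mod(colMeans(exp(1i * dphi)))
  mean(plvT)
}

#' Phase-locking-value matrix
#'
#' Computes the across-trial PLV for every unordered channel pair over the
#' averaging window; the matrix is symmetric with unit diagonal.
#'
#' @param phases a [PhaseTensor-class].
#' @param windowMs averaging interval in ms.
#' @param trials optional trial subset (indices).
#' @param subject,group,condition metadata labels stored in the result.
#' @return a [PLVMatrix-class].
#' @export
plvMatrix <- function(phases, windowMs = c(0, 1000), trials = NULL,
                      subject = "", group = "", condition = "") {
  stopifnot(is(phases, "PhaseTensor"))
  if (is.null(trials)) trials <- seq_len(dim(phases@phase)[1])
  if (length(trials) < 2) stop("need >= 2 trials for a PLV matrix")
  it <- .windowIndex(phases@timesMs, windowMs)
  nCh <- length(phases@channelNames)
  E <- exp(1i * phases@phase[trials, , it, drop = FALSE])
  K <- length(trials)
  acc <- matrix(0, nCh, nCh)
  for (j in seq_along(it)) {
    Et <- E[, , j, drop = TRUE]
    if (is.null(dim(Et))) Et <- matrix(Et, K, nCh)
    G <- crossprod(Conj(Et), Et) / K        # G[a,b] = mean_k e^{i(phi_b-phi_a)}
    acc <- acc + Mod(G)
  }
  P <- acc / length(it)
  P <- (P + t(P)) / 2
  diag(P) <- 1
  dimnames(P) <- list(phases@channelNames, phases@channelNames)
  new("PLVMatrix", plv = P, windowMs = as.numeric(windowMs),
      nTrials = as.integer(K), subject = subject, group = group,
      condition = condition)
}

#' Long-format PLV table
#'
#' @param x a [PLVMatrix-class].
#' @return data.frame (ch_a, ch_b, plv) over unordered pairs, for
#'   downstream statistics and TSV export.
#' @export
plvLongTable <- function(x) {
  stopifnot(is(x, "PLVMatrix"))
  ch <- rownames(x@plv)
  ut <- which(upper.tri(x@plv), arr.ind = TRUE)
  data.frame(subject = x@subject, group = x@group, condition = x@condition,
             ch_a = ch[ut[, 1]], ch_b = ch[ut[, 2]], plv = x@plv[ut])
}
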