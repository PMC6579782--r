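# Condition-average ERPs, mass-univariate paired sign-flip permutation
# statistics with Benjamini-Yekutieli FDR control, and component
# measurement (N1 / P3a / LPP mean amplitudes).

#' Pool the deviant conditions into "emotional"
#'
#' Relabels happy and angry trials as a single emotional condition (the
#' pleasant and unpleasant deviants are analyzed jointly).
#'
#' @param epochs an [EpochSet-class] (or [PhaseTensor-class]).
#' @return the object with labels \code{neutral} / \code{emotional}.
#' @export
poolEmotional <- function(epochs) {
  pool <- function(f) {
    x <- as.character(f)
    x[x %in% c("happy", "angry")] <- "emotional"
    factor(x, levels = intersect(c("neutral", "emotional"), unique(x)))
  }
  if (is(epochs, "EpochSet")) epochs@labels <- pool(epochs@labels)
  else if (is(epochs, "PhaseTensor")) epochs@labels <- pool(epochs@labels)
  else stop("poolEmotional expects an EpochSet or PhaseTensor")
  epochs
}

#' Condition-average ERP
#'
#' @param epochs an [EpochSet-class].
#' @param condition a condition label present in the epochs.
#' @return an [ERPWaveform-class]: the per-channel, per-timepoint
#'   arithmetic mean over trials of that condition.
#' @export
conditionAverage <- function(epochs, condition) {
  stopifnot(is(epochs, "EpochSet"))
  sel <- which(epochs@labels == condition)
  if (!length(sel))
    stop("unknown or empty condition '", condition, "'; available: ",
         paste(levels(droplevels(epochs@labels)), collapse = ", "))
  m <- apply(epochs@data[sel, , , drop = FALSE], c(2, 3), mean)
  rownames(m) <- epochs@montage@channelNames
  new("ERPWaveform", mean = m, nTrials = length(sel),
      condition = as.character(condition), timesMs = epochs@timesMs,
      channelNames = epochs@montage@channelNames)
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up adjustment with the harmonic-sum correction factor
#' c(m) = sum_{i=1..m} 1/i, valid under arbitrary dependence of the tests.
#'
#' @param pRaw vector of raw p-values in [0, 1].
#' @return adjusted p-values (elementwise >= the input, capped at 1).
#' @export
byAdjust <- function(pRaw) {
  if (any(is.na(pRaw)) || any(pRaw < 0 | pRaw > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pRaw, method = "BY")
}

# subjects x cells matrix from a subjects x channels x time array (or an
# already-flat matrix / list of ERPWaveforms)
.asSubjectMatrix <- function(x) {
  if (is.list(x) && all(vapply(x, is, logical(1), "ERPWaveform"))) {
    x <- do.call(rbind, lapply(x, function(w) as.vector(w@mean)))
  }
  if (is.array(x) && length(dim(x)) == 3) {
    d <- dim(x)
    dim(x) <- c(d[1], d[2] * d[3])
    attr(x, "cellDim") <- d[2:3]
  } else {
    x <- as.matrix(x)
    attr(x, "cellDim") <- c(ncol(x), 1L)
  }
  x
}

#' Mass-univariate paired permutation test
#'
#' At every (channel, timepoint) cell, computes the paired t statistic
#' between conditions across subjects and derives its p-value from the
#' sign-flip permutation null: all 2^n flips are enumerated when n <= 12,
#' otherwise \code{nPerm} random flips are drawn with the add-one
#' correction p = (b + 1) / (m + 1). The p-value map is then adjusted over
#' all cells with the Benjamini-Yekutieli procedure, which keeps the false
#' discovery rate below \code{q} under arbitrary dependence.
#'
#' @param valuesA,valuesB per-subject ERPs in matching subject order: a
#'   subjects x channels x time array, a subjects x cells matrix, or a list
#'   of [ERPWaveform-class] objects.
#' @param nPerm number of random sign flips when exact enumeration is not
#'   feasible (1000 by default).
#' @param q FDR level for the significance mask.
#' @param seed RNG seed for the random flips.
#' @param channelNames,timesMs optional dimension labels for the result.
#' @return a [MassUnivariateResult-class].
#' @export
massUnivariatePairedT <- function(valuesA, valuesB, nPerm = 1000, q = 0.05,
                                  seed = 1, channelNames = NULL,
                                  timesMs = NULL) {
  A <- .asSubjectMatrix(valuesA)
  B <- .asSubjectMatrix(valuesB)
  if (!all(dim(A) == dim(B)))
    stop("valuesA and valuesB must have identical shape (paired subjects)")
  n <- nrow(A)
  if (n < 2) stop("need at least 2 paired subjects")
  cellDim <- attr(A, "cellDim")
  D <- A - B
  ss <- colSums(D^2)                       # invariant under sign flips
  tFromMean <- function(M) {
    v <- (ss[col(M)] - n * M^2) / (n - 1)
    dim(v) <- dim(M)
    tt <- M / sqrt(v / n)
    tt[!is.finite(tt)] <- 0                # zero-variance cells
    tt
  }
  tObs <- drop(tFromMean(matrix(colMeans(D), 1)))
  exact <- n <= 12
  S <- if (exact) {
    as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    withSeed(seed, matrix(sample(c(1, -1), nPerm * n, replace = TRUE), nPerm, n))
  }
  Tperm <- tFromMean(S %*% D / n)
  exceed <- colSums(abs(Tperm) >= abs(rep(tObs, each = nrow(S))) - 1e-12)
  pRaw <- if (exact) exceed / nrow(S) else (exceed + 1) / (nrow(S) + 1)
  pAdj <- byAdjust(pRaw)
  shape <- function(v) matrix(v, cellDim[1], cellDim[2])
  if (is.null(channelNames)) channelNames <- as.character(seq_len(cellDim[1]))
  if (is.null(timesMs)) timesMs <- as.numeric(seq_len(cellDim[2]))
  new("MassUnivariateResult", t = shape(tObs), pRaw = shape(pRaw),
      pAdj = shape(pAdj), sigMask = shape(pAdj < q), q = q,
      nPerm = as.integer(nrow(S)), exact = exact,
      channelNames = channelNames, timesMs = timesMs)
}

#' Component measurement specification
#'
#' Default windows and channel sets: N1 100-200 ms frontal, P3a 250-400 ms
#' frontal (the paradigm literature does not fix this window; it is a
#' configurable default), LPP 400-1000 ms parietal-occipital.
#'
#' @param component \code{N1}, \code{P3a} or \code{LPP}.
#' @param windowMs half-open measurement interval in ms (defaults per
#'   component).
#' @param channels channel subset (defaults per component).
#' @return a list with \code{component}, \code{windowMs}, \code{channels}.
#' @export
componentSpec <- function(component = c("N1", "P3a", "LPP"), windowMs = NULL,
                          channels = NULL) {
  component <- match.arg(component)
  if (is.null(windowMs))
    windowMs <- switch(component, N1 = c(100, 200), P3a = c(250, 400),
                       LPP = c(400, 1000))
  if (is.null(channels))
    channels <- switch(component,
                       N1 = c("F3", "Fz", "F4"),
                       P3a = c("F3", "Fz", "F4"),
                       LPP = c("P3", "Pz", "P4", "O1", "Oz", "O2"))
  list(component = component, windowMs = windowMs, channels = channels)
}

#' Measure a component's mean amplitude
#'
#' Mean amplitude of the waveform over the component's time window and
#' channel set.
#'
#' @param erp an [ERPWaveform-class].
#' @param spec a [componentSpec()] list.
#' @return mean amplitude in microvolts (scalar).
#' @export
measureComponent <- function(erp, spec) {
  stopifnot(is(erp, "ERPWaveform"))
  ich <- match(spec$channels, erp@channelNames)
  if (any(is.na(ich)))
    stop("channels not in waveform: ",
         paste(spec$channels[is.na(ich)], collapse = ", "))
  it <- which(erp@timesMs >= spec$windowMs[1] & erp@timesMs < spec$windowMs[2])
  step <- if (length(erp@timesMs) > 1) erp@timesMs[2] - erp@timesMs[1] else 0
  if (!length(it) || spec$windowMs[1] < min(erp@timesMs) ||
      spec$windowMs[2] > max(erp@timesMs) + step + 1e-9)
    stop("measurement window outside the epoch")
  mean(erp@mean[ich, it])
}

#' Export a mass-univariate result as a long-format table
#'
#' @param res a [MassUnivariateResult-class].
#' @return data.frame with channel, time_ms, t, p_raw, p_adj, sig.
#' @export
massUnivariateTable <- function(res) {
  stopifnot(is(res, "MassUnivariateResult"))
  data.frame(channel = rep(res@channelNames, length(res@timesMs)),
             time_ms = rep(res@timesMs, each = length(res@channelNames)),
             t = as.vector(res@t), p_raw = as.vector(res@pRaw),
             p_adj = as.vector(res@pAdj), sig = as.vector(res@sigMask))
}
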