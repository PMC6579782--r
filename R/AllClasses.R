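#' @import methods
NULL

#' Electrode montage
#'
#' Describes a set of EEG channels by name and by position on the unit
#' sphere (head-centred coordinates, nose along +x, left ear along +y,
#' vertex along +z), together with the pair of mastoid reference channels.
#'
#' @slot channelNames character vector of unique 10-20 style labels.
#' @slot positions numeric matrix (channels x 3) of unit-norm xyz positions;
#'   rownames equal \code{channelNames}.
#' @slot mastoidLabels character vector of length 2 naming the left and right
#'   mastoid channels; both must be montage channels.
#' @seealso [standardMontage()], [subsetMontage()]
#' @export
setClass("Montage",
  representation(channelNames = "character",
                 positions = "matrix",
                 mastoidLabels = "character"),
  validity = function(object) {
    msg <- character(0)
    if (anyDuplicated(object@channelNames))
      msg <- c(msg, "channel names must be unique")
    if (nrow(object@positions) != length(object@channelNames))
      msg <- c(msg, "positions must have one row per channel")
    else {
      nrm <- sqrt(rowSums(object@positions^2))
      if (any(abs(nrm - 1) > 1e-6))
        msg <- c(msg, "positions must have unit norm (within 1e-6)")
    }
    if (length(object@mastoidLabels) != 2)
      msg <- c(msg, "exactly two mastoid labels required")
    if (!all(object@mastoidLabels %in% object@channelNames))
      msg <- c(msg, "mastoid labels must be montage channels")
    if (length(msg)) msg else TRUE
  })

#' Oddball event sequence
#'
#' Stimulus onsets (1-based sample indices) and condition labels for one
#' auditory oddball block. Events are spaced by \code{interOnsetMs}
#' (stimulus duration plus interstimulus interval).
#'
#' @slot onsets integer vector of strictly increasing 1-based sample indices.
#' @slot labels factor with levels \code{neutral}, \code{happy}, \code{angry}.
#' @slot interOnsetMs numeric scalar, onset-to-onset spacing in milliseconds.
#' @seealso [generateOddballSequence()]
#' @export
setClass("EventSequence",
  representation(onsets = "integer",
                 labels = "factor",
                 interOnsetMs = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@onsets) != length(object@labels))
      msg <- c(msg, "onsets and labels must have equal length")
    if (length(object@onsets) > 1 && any(diff(object@onsets) <= 0))
      msg <- c(msg, "onsets must be strictly increasing")
    if (!all(levels(object@labels) %in% c("neutral", "happy", "angry", "emotional")))
      msg <- c(msg, "labels must be neutral/happy/angry (or pooled emotional)")
    if (length(object@interOnsetMs) != 1 || object@interOnsetMs <= 0)
      msg <- c(msg, "interOnsetMs must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

#' Synthetic subject specification
#'
#' Parameters controlling one simulated subject: group membership, ERP
#' component amplitudes per condition, inter-channel phase-coupling entries,
#' oscillation frequency and amplitude, background-noise scale and RNG seed.
#'
#' @slot group one of \code{HC}, \code{MCS}, \code{UWS}.
#' @slot erpAmplitudes numeric matrix, rows \code{N1}, \code{P3a}, \code{LPP},
#'   columns \code{neutral}, \code{happy}, \code{angry}; values in microvolts.
#' @slot coupling data.frame with columns \code{chA}, \code{chB},
#'   \code{condition} (a stimulus label or \code{emotional} for the pooled
#'   deviants) and \code{kappa} (von Mises concentration, >= 0).
#' @slot couplingFreqHz oscillation frequency of the coupled component (Hz).
#' @slot oscAmplitudeUv amplitude of the coupled oscillation (microvolts).
#' @slot noiseScale RMS of the 1/f background noise (microvolts).
#' @slot seed integer RNG seed; fixed seed gives bit-identical output.
#' @seealso [subjectSpec()], [groupSpecTemplates()], [synthesizeSubject()]
#' @export
setClass("SubjectSpec",
  representation(group = "character",
                 erpAmplitudes = "matrix",
                 coupling = "data.frame",
                 couplingFreqHz = "numeric",
                 oscAmplitudeUv = "numeric",
                 noiseScale = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (!object@group %in% c("HC", "MCS", "UWS"))
      msg <- c(msg, "group must be HC, MCS or UWS")
    if (!all(c("N1", "P3a", "LPP") %in% rownames(object@erpAmplitudes)) ||
        !all(c("neutral", "happy", "angry") %in% colnames(object@erpAmplitudes)))
      msg <- c(msg, "erpAmplitudes needs rows N1/P3a/LPP and columns neutral/happy/angry")
    if (any(!is.finite(object@erpAmplitudes)))
      msg <- c(msg, "erpAmplitudes must be finite")
    if (nrow(object@coupling) &&
        (!all(c("chA", "chB", "condition", "kappa") %in% names(object@coupling)) ||
         any(object@coupling$kappa < 0)))
      msg <- c(msg, "coupling needs columns chA/chB/condition/kappa with kappa >= 0")
    if (object@noiseScale < 0) msg <- c(msg, "noiseScale must be >= 0")
    if (object@oscAmplitudeUv < 0) msg <- c(msg, "oscAmplitudeUv must be >= 0")
    if (object@couplingFreqHz <= 0) msg <- c(msg, "couplingFreqHz must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Continuous EEG recording
#'
#' @slot data numeric matrix (channels x samples) in microvolts; rownames
#'   equal the montage channel names.
#' @slot rate sampling rate in Hz.
#' @slot montage a [Montage-class] object.
#' @slot events an [EventSequence-class]; all onsets lie inside the recording.
#' @export
setClass("EEGRecording",
  representation(data = "matrix",
                 rate = "numeric",
                 montage = "Montage",
                 events = "EventSequence"),
  validity = function(object) {
    msg <- character(0)
    if (nrow(object@data) != length(object@montage@channelNames))
      msg <- c(msg, "data must have one row per montage channel")
    if (length(object@rate) != 1 || object@rate <= 0)
      msg <- c(msg, "rate must be a positive scalar")
    if (length(object@events@onsets) &&
        max(object@events@onsets) > ncol(object@data))
      msg <- c(msg, "all event onsets must fall inside the recording")
    if (length(msg)) msg else TRUE
  })

#' Epoched EEG data
#'
#' Stimulus-locked trials cut from a continuous recording, with per-trial
#' condition labels and the baseline convention used for correction.
#'
#' @slot data numeric array (trials x channels x time) in microvolts.
#' @slot timesMs per-sample latency in ms relative to stimulus onset
#'   (half-open window, e.g. -200 to 998 ms at 500 Hz).
#' @slot labels factor, condition per trial.
#' @slot rate sampling rate in Hz.
#' @slot montage the recording [Montage-class].
#' @slot baselineWindowMs half-open interval used for baseline correction.
#' @slot nDropped number of events dropped because their window fell outside
#'   the recording.
#' @export
setClass("EpochSet",
  representation(data = "array",
                 timesMs = "numeric",
                 labels = "factor",
                 rate = "numeric",
                 montage = "Montage",
                 baselineWindowMs = "numeric",
                 nDropped = "integer"),
  validity = function(object) {
    msg <- character(0)
    d <- dim(object@data)
    if (length(d) != 3)
      msg <- c(msg, "data must be a trials x channels x time array")
    else {
      if (d[1] != length(object@labels))
        msg <- c(msg, "labels length must equal trial count")
      if (d[2] != length(object@montage@channelNames))
        msg <- c(msg, "channel dimension must match montage")
      if (d[3] != length(object@timesMs))
        msg <- c(msg, "time dimension must match timesMs")
    }
    if (length(msg)) msg else TRUE
  })

#' Instantaneous-phase tensor
#'
#' Per-trial, per-channel, per-timepoint instantaneous phase (radians in
#' (-pi, pi]) obtained from the band-passed analytic signal.
#'
#' @slot phase numeric array (trials x channels x time), radians.
#' @slot bandHz numeric length-2, the band-pass used before the Hilbert step.
#' @slot timesMs latencies as in the source [EpochSet-class].
#' @slot labels per-trial condition labels.
#' @slot channelNames channel labels.
#' @slot rate sampling rate in Hz.
#' @export
setClass("PhaseTensor",
  representation(phase = "array",
                 bandHz = "numeric",
                 timesMs = "numeric",
                 labels = "factor",
                 channelNames = "character",
                 rate = "numeric"),
  validity = function(object) {
    msg <- character(0)
    d <- dim(object@phase)
    if (length(d) != 3) msg <- c(msg, "phase must be a 3-d array")
    else {
      if (d[2] != length(object@channelNames))
        msg <- c(msg, "channel dimension must match channelNames")
      if (d[1] != length(object@labels))
        msg <- c(msg, "labels length must equal trial count")
    }
    if (any(object@phase > pi + 1e-9 | object@phase <= -pi - 1e-9))
      msg <- c(msg, "phase values must lie in (-pi, pi]")
    if (length(msg)) msg else TRUE
  })

#' Phase-locking-value matrix
#'
#' Symmetric channels x channels matrix of time-averaged across-trial
#' phase-locking values for one subject and condition. The diagonal is 1.
#'
#' @slot plv numeric symmetric matrix with unit diagonal, entries in [0, 1].
#' @slot windowMs the post-stimulus averaging interval.
#' @slot nTrials number of trials entering the estimate.
#' @slot subject,group,condition metadata labels.
#' @export
setClass("PLVMatrix",
  representation(plv = "matrix",
                 windowMs = "numeric",
                 nTrials = "integer",
                 subject = "character",
                 group = "character",
                 condition = "character"),
  validity = function(object) {
    msg <- character(0)
    p <- object@plv
    if (nrow(p) != ncol(p)) msg <- c(msg, "plv must be square")
    else {
      if (max(abs(p - t(p))) > 1e-9) msg <- c(msg, "plv must be symmetric")
      if (max(abs(diag(p) - 1)) > 1e-9) msg <- c(msg, "plv diagonal must be 1")
      if (any(p < -1e-9 | p > 1 + 1e-9)) msg <- c(msg, "plv entries must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
  })

#' Condition-average ERP waveform
#'
#' @slot mean numeric matrix (channels x time), the arithmetic trial average
#'   in microvolts.
#' @slot nTrials number of trials averaged.
#' @slot condition condition label.
#' @slot timesMs per-sample latencies (ms).
#' @slot channelNames channel labels.
#' @export
setClass("ERPWaveform",
  representation(mean = "matrix",
                 nTrials = "integer",
                 condition = "character",
                 timesMs = "numeric",
                 channelNames = "character"),
  validity = function(object) {
    msg <- character(0)
    if (any(!is.finite(object@mean))) msg <- c(msg, "mean must be finite")
    if (nrow(object@mean) != length(object@channelNames))
      msg <- c(msg, "mean rows must match channelNames")
    if (ncol(object@mean) != length(object@timesMs))
      msg <- c(msg, "mean columns must match timesMs")
    if (length(msg)) msg else TRUE
  })

#' Mass-univariate test result
#'
#' Per-(channel, timepoint) paired t statistics with sign-flip permutation
#' p-values and Benjamini-Yekutieli adjusted p-values.
#'
#' @slot t,pRaw,pAdj numeric matrices (channels x time).
#' @slot sigMask logical matrix, \code{pAdj < q}.
#' @slot q FDR level used for the mask.
#' @slot nPerm number of permutations (or \code{2^n} when enumerated exactly).
#' @slot exact TRUE when all sign flips were enumerated.
#' @slot channelNames,timesMs dimension labels.
#' @export
setClass("MassUnivariateResult",
  representation(t = "matrix", pRaw = "matrix", pAdj = "matrix",
                 sigMask = "matrix", q = "numeric", nPerm = "integer",
                 exact = "logical", channelNames = "character",
                 timesMs = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (any(object@pRaw < 0 | object@pRaw > 1) ||
        any(object@pAdj < 0 | object@pAdj > 1))
      msg <- c(msg, "p values must lie in [0, 1]")
    if (any(object@pAdj + 1e-12 < object@pRaw))
      msg <- c(msg, "adjusted p must be >= raw p")
    if (length(msg)) msg else TRUE
  })

#' Weighted undirected graph
#'
#' @slot weights symmetric non-negative matrix with zero diagonal; for PLV
#'   networks entries lie in [0, 1].
#' @slot nodeNames node (channel) labels.
#' @seealso [asWeightedGraph()]
#' @export
setClass("WeightedGraph",
  representation(weights = "matrix", nodeNames = "character"),
  validity = function(object) {
    msg <- character(0)
    w <- object@weights
    if (nrow(w) != ncol(w)) msg <- c(msg, "weights must be square")
    else {
      if (max(abs(w - t(w))) > 1e-12) msg <- c(msg, "weights must be symmetric (1e-12)")
      if (any(diag(w) != 0)) msg <- c(msg, "no self-loops: diagonal must be zero")
      if (any(w < 0)) msg <- c(msg, "weights must be non-negative")
      if (length(object@nodeNames) != nrow(w))
        msg <- c(msg, "nodeNames must match matrix dimension")
    }
    if (length(msg)) msg else TRUE
  })

#' Mixed repeated-measures ANOVA result
#'
#' @slot effects data.frame with one row per effect (group, stimulation,
#'   group x stimulation): F, dfNum, dfDen, p, pGG.
#' @slot epsilonGG Greenhouse-Geisser epsilon (1 exactly for a 2-level
#'   within factor).
#' @slot mauchlyW,mauchlyP Mauchly sphericity statistic and p-value
#'   (NA, "not applicable", for a 2-level within factor).
#' @slot degenerate TRUE when an error stratum had (near-)zero variance and
#'   the corresponding F is unreliable.
#' @export
setClass("RmAnovaResult",
  representation(effects = "data.frame", epsilonGG = "numeric",
                 mauchlyW = "numeric", mauchlyP = "numeric",
                 degenerate = "logical"))

#' Edge-wise network comparison result
#'
#' @slot table data.frame with one row per electrode pair: \code{chA},
#'   \code{chB}, \code{t}, \code{p}, \code{direction} (increase/decrease),
#'   \code{sigUncorrected} (p < alpha) and \code{sigBonferroni}
#'   (p < alpha / m).
#' @slot alpha nominal level (default 0.05).
#' @slot m number of edges in the Bonferroni family.
#' @slot paired TRUE for a paired contrast.
#' @export
setClass("EdgeComparisonResult",
  representation(table = "data.frame", alpha = "numeric",
                 m = "integer", paired = "logical"),
  validity = function(object) {
    tb <- object@table
    msg <- character(0)
    if (any(tb$sigBonferroni & !tb$sigUncorrected))
      msg <- c(msg, "Bonferroni mask must be a subset of the uncorrected mask")
    if (length(msg)) msg else TRUE
  })
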