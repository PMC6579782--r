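#' Channel names of an object
#'
#' @param x a Montage, EEGRecording, EpochSet, PhaseTensor, PLVMatrix or
#'   WeightedGraph.
#' @return character vector of channel / node labels.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname channelNames
#' @export
setMethod("channelNames", "Montage", function(x) x@channelNames)
#' @rdname channelNames
#' @export
setMethod("channelNames", "EEGRecording", function(x) x@montage@channelNames)
#' @rdname channelNames
#' @export
setMethod("channelNames", "EpochSet", function(x) x@montage@channelNames)
#' @rdname channelNames
#' @export
setMethod("channelNames", "PhaseTensor", function(x) x@channelNames)
#' @rdname channelNames
#' @export
setMethod("channelNames", "PLVMatrix", function(x) rownames(x@plv))
#' @rdname channelNames
#' @export
setMethod("channelNames", "WeightedGraph", function(x) x@nodeNames)

#' Sampling rate in Hz
#' @param x an EEGRecording, EpochSet or PhaseTensor.
#' @return sampling rate (Hz).
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@rate)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@rate)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "PhaseTensor", function(x) x@rate)

#' Number of trials
#' @param x an EpochSet, PhaseTensor, PLVMatrix or ERPWaveform.
#' @return trial count.
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname nTrials
#' @export
setMethod("nTrials", "EpochSet", function(x) dim(x@data)[1])
#' @rdname nTrials
#' @export
setMethod("nTrials", "PhaseTensor", function(x) dim(x@phase)[1])
#' @rdname nTrials
#' @export
setMethod("nTrials", "PLVMatrix", function(x) x@nTrials)
#' @rdname nTrials
#' @export
setMethod("nTrials", "ERPWaveform", function(x) x@nTrials)

#' Per-trial condition labels
#' @param x an EpochSet or PhaseTensor.
#' @return factor of condition labels, one per trial.
#' @export
setGeneric("conditionLabels", function(x) standardGeneric("conditionLabels"))
#' @rdname conditionLabels
#' @export
setMethod("conditionLabels", "EpochSet", function(x) x@labels)
#' @rdname conditionLabels
#' @export
setMethod("conditionLabels", "PhaseTensor", function(x) x@labels)

#' PLV matrix values
#' @param x a PLVMatrix.
#' @return the symmetric numeric channels x channels matrix.
#' @export
plvValues <- function(x) {
  stopifnot(is(x, "PLVMatrix"))
  x@plv
}

#' Edge weight matrix of a WeightedGraph
#' @param x a WeightedGraph.
#' @return the symmetric weight matrix (zero diagonal).
#' @export
edgeWeights <- function(x) {
  stopifnot(is(x, "WeightedGraph"))
  x@weights
}

setMethod("show", "Montage", function(object) {
  cat("Montage:", length(object@channelNames), "channels (",
      paste(utils::head(object@channelNames, 6), collapse = ", "),
      if (length(object@channelNames) > 6) ", ..." else "",
      "), mastoids:", paste(object@mastoidLabels, collapse = "/"), "\n")
})

setMethod("show", "EventSequence", function(object) {
  cat("EventSequence:", length(object@onsets), "events (",
      paste(sprintf("%s=%d", names(table(object@labels)), table(object@labels)),
            collapse = ", "),
      "), onset-to-onset", object@interOnsetMs, "ms\n")
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(object@data), ncol(object@data), object@rate,
              ncol(object@data) / object@rate, length(object@events@onsets)))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], object@rate))
  cat("  window:", sprintf("[%g, %g) ms", min(object@timesMs),
      max(object@timesMs) + 1000 / object@rate),
      " conditions:", paste(sprintf("%s=%d", names(table(droplevels(object@labels))),
                                    table(droplevels(object@labels))), collapse = ", "), "\n")
})

setMethod("show", "PhaseTensor", function(object) {
  d <- dim(object@phase)
  cat(sprintf("PhaseTensor: %d trials x %d channels x %d samples, band %g-%g Hz\n",
              d[1], d[2], d[3], object@bandHz[1], object@bandHz[2]))
})

setMethod("show", "PLVMatrix", function(object) {
  cat(sprintf("PLVMatrix: %d channels, %d trials, window [%g, %g] ms (%s/%s/%s)\n",
              nrow(object@plv), object@nTrials, object@windowMs[1],
              object@windowMs[2], object@subject, object@group, object@condition))
})

setMethod("show", "ERPWaveform", function(object) {
  cat(sprintf("ERPWaveform '%s': %d channels x %d samples, %d trials\n",
              object@condition, nrow(object@mean), ncol(object@mean),
              object@nTrials))
})

setMethod("show", "MassUnivariateResult", function(object) {
  cat(sprintf("MassUnivariateResult: %d channels x %d timepoints, %s%d permutations\n",
              nrow(object@t), ncol(object@t),
              if (object@exact) "exact, " else "", object@nPerm))
  cat(sprintf("  significant cells at q=%g (BY): %d\n", object@q,
              sum(object@sigMask)))
})

setMethod("show", "WeightedGraph", function(object) {
  cat(sprintf("WeightedGraph: %d nodes, %d edges (w > 0)\n",
              nrow(object@weights), sum(object@weights[upper.tri(object@weights)] > 0)))
})

setMethod("show", "RmAnovaResult", function(object) {
  cat("Mixed repeated-measures ANOVA\n")
  print(object@effects, row.names = FALSE)
  cat(sprintf("  GG epsilon: %g; Mauchly W: %s (p %s)\n", object@epsilonGG,
              format(object@mauchlyW), format(object@mauchlyP)))
  if (object@degenerate)
    cat("  WARNING: an error stratum had (near-)zero variance; F unreliable\n")
})

setMethod("show", "EdgeComparisonResult", function(object) {
  cat(sprintf("EdgeComparisonResult: %d edges (%s), %d uncorrected / %d Bonferroni significant at alpha=%g\n",
              object@m, if (object@paired) "paired" else "two-sample",
              sum(object@table$sigUncorrected), sum(object@table$sigBonferroni),
              object@alpha))
})
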