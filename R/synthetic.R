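# Synthetic emotional-oddball EEG: event sequences, ERP templates,
# von Mises phase-coupled oscillations and 1/f background noise.

# Run expr under a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic per-subject seed from a master seed and subject index, so
# adding subjects never perturbs existing ones. Kept below 2^31.
deriveSeed <- function(masterSeed, index) {
  h <- (as.numeric(masterSeed) %% 2147483647) + 1
  for (k in c(index, 104729L)) {
    h <- (h * 48271 + as.numeric(k) * 16807 + 11) %% 2147483647
  }
  as.integer(h)
}

#' Generate an oddball stimulus sequence
#'
#' Builds one auditory oddball block: \code{nStandard} neutral standards and
#' \code{nHappy} + \code{nAngry} emotional deviants in randomly permuted
#' order, under the constraint that no two deviants occupy adjacent
#' positions (the strictest reading of deviants never appearing in quick
#' succession). Deviants are placed into distinct gaps between standards.
#'
#' @param nStandard,nHappy,nAngry event counts (the standard block is
#'   86/12/12, 110 stimuli in total).
#' @param seed integer seed; output is reproducible bit-for-bit.
#' @param interOnsetMs onset-to-onset spacing in ms (700 ms stimulus +
#'   1500 ms interstimulus interval = 2200 ms).
#' @param rate sampling rate (Hz) used to convert onsets to sample indices.
#' @param prerollMs silence before the first onset (must cover the epoch
#'   baseline).
#' @return an [EventSequence-class] with exactly
#'   \code{nStandard + nHappy + nAngry} events.
#' @examples
#' ev <- generateOddballSequence(86, 12, 12, seed = 1)
#' table(ev@labels)
#' @export
generateOddballSequence <- function(nStandard, nHappy, nAngry, seed,
                                    interOnsetMs = 2200, rate = 500,
                                    prerollMs = 1000) {
  stopifnot(nStandard >= 0, nHappy >= 0, nAngry >= 0)
  nDev <- nHappy + nAngry
  if (nStandard < nDev - 1)
    stop("infeasible design: need nStandard >= nHappy + nAngry - 1 (",
         nStandard, " standards cannot separate ", nDev, " deviants)")
  n <- nStandard + nDev
  if (n == 0) stop("at least one event required")
  labels <- withSeed(seed, {
    devLabels <- sample(c(rep("happy", nHappy), rep("angry", nAngry)))
    # choose nDev of the nStandard+1 gaps around the standards
    gaps <- sort(sample.int(nStandard + 1, nDev))
    out <- character(0)
    d <- 1
    for (g in seq_len(nStandard + 1)) {
      if (d <= nDev && gaps[d] == g) {
        out <- c(out, devLabels[d])
        d <- d + 1
      }
      if (g <= nStandard) out <- c(out, "neutral")
    }
    out
  })
  step <- round(interOnsetMs / 1000 * rate)
  onsets <- as.integer(round(prerollMs / 1000 * rate) + (seq_len(n) - 1) * step + 1)
  new("EventSequence", onsets = onsets,
      labels = factor(labels, levels = c("neutral", "happy", "angry")),
      interOnsetMs = interOnsetMs)
}

#' Expected PLV of a von Mises phase-jitter model
#'
#' For phase differences drawn from a von Mises distribution with
#' concentration \code{kappa}, the population mean resultant length is the
#' Bessel-function ratio I1(kappa)/I0(kappa): the PLV reached in the limit
#' of infinitely many trials.
#'
#' @param kappa non-negative concentration parameter (vectorized).
#' @return expected PLV in [0, 1).
#' @examples
#' expectedPLVFromKappa(c(0, 1, 2, 4))
#' @export
expectedPLVFromKappa <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be >= 0")
  # exponentially scaled Bessel ratio; asymptotic series where besselI
  # leaves its supported range
  r <- suppressWarnings(besselI(kappa, 1, expon.scaled = TRUE) /
                        besselI(kappa, 0, expon.scaled = TRUE))
  big <- kappa > 1e4 | !is.finite(r)
  if (any(big)) {
    k <- kappa[big]
    r[big] <- 1 - 1 / (2 * k) - 1 / (8 * k^2) - 1 / (8 * k^3)
  }
  r[kappa == 0] <- 0
  r
}

#' Construct a SubjectSpec
#'
#' @param group \code{HC}, \code{MCS} or \code{UWS}.
#' @param erpAmplitudes 3 x 3 matrix (rows N1/P3a/LPP, columns
#'   neutral/happy/angry) of component amplitudes in microvolts
#'   (N1 amplitudes are negative).
#' @param coupling data.frame with columns \code{chA}, \code{chB},
#'   \code{condition}, \code{kappa}; \code{condition} may be a stimulus
#'   label or \code{"emotional"} (applies to happy and angry events).
#' @param couplingFreqHz shared-oscillation frequency (default 10 Hz,
#'   within the 0.1-30 Hz analysis band).
#' @param oscAmplitudeUv oscillation amplitude in microvolts.
#' @param noiseScale 1/f background noise RMS in microvolts.
#' @param seed integer RNG seed.
#' @return a [SubjectSpec-class].
#' @export
subjectSpec <- function(group, erpAmplitudes, coupling = emptyCoupling(),
                        couplingFreqHz = 10, oscAmplitudeUv = 8,
                        noiseScale = 10, seed = 1L) {
  new("SubjectSpec", group = group, erpAmplitudes = erpAmplitudes,
      coupling = coupling, couplingFreqHz = couplingFreqHz,
      oscAmplitudeUv = oscAmplitudeUv, noiseScale = noiseScale,
      seed = as.integer(seed))
}

#' @rdname subjectSpec
#' @export
emptyCoupling <- function() {
  data.frame(chA = character(0), chB = character(0),
             condition = character(0), kappa = numeric(0))
}

#' Build an ERP amplitude matrix
#'
#' @param n1,p3a,lpp length-3 amplitude vectors (microvolts) for the
#'   neutral, happy and angry conditions.
#' @return 3 x 3 matrix suitable for [subjectSpec()].
#' @export
erpAmplitudeMatrix <- function(n1, p3a, lpp) {
  m <- rbind(N1 = n1, P3a = p3a, LPP = lpp)
  colnames(m) <- c("neutral", "happy", "angry")
  m
}

#' Default group profiles for the three-group synthetic dataset
#'
#' Templates emulating the qualitative group signatures expected under the
#' emotional oddball paradigm: healthy controls show an emotion-enhanced
#' late positive potential over parietal-occipital sites plus strong
#' emotional-condition phase coupling along fronto-/parieto-occipital pairs;
#' minimally conscious patients show an emotion-sensitive frontal P3a and
#' weak temporal coupling; unresponsive-wakefulness patients show only an
#' enhanced N1 with marginal, diffuse coupling. Amplitudes are in
#' microvolts; coupling strengths are von Mises concentrations.
#'
#' @return named list of [SubjectSpec-class] templates (\code{HC},
#'   \code{MCS}, \code{UWS}); per-subject seeds are assigned by
#'   [generateGroupDataset()].
#' @export
groupSpecTemplates <- function() {
  hcCoupling <- data.frame(
    chA = c("F3", "F4", "Fz", "P3", "P4", "Pz", "P3", "O1"),
    chB = c("O1", "O2", "Oz", "O1", "O2", "Oz", "P4", "O2"),
    condition = "emotional", kappa = 3)
  mcsCoupling <- data.frame(
    chA = c("T7", "T8", "T7"), chB = c("P7", "P8", "T8"),
    condition = "emotional", kappa = 1)
  uwsCoupling <- data.frame(
    chA = c("T7", "T7"), chB = c("T8", "P7"),
    condition = "emotional", kappa = 0.2)
  list(
    HC = subjectSpec("HC",
      erpAmplitudeMatrix(n1 = c(-3, -4, -4), p3a = c(1.5, 2.5, 2.5),
                         lpp = c(0.5, 6, 6)),
      coupling = hcCoupling),
    MCS = subjectSpec("MCS",
      erpAmplitudeMatrix(n1 = c(-2, -2.5, -2.5), p3a = c(1, 4, 4),
                         lpp = c(0, 0, 0)),
      coupling = mcsCoupling),
    UWS = subjectSpec("UWS",
      erpAmplitudeMatrix(n1 = c(-1.5, -3, -3), p3a = c(0.5, 0.8, 0.8),
                         lpp = c(0, 0, 0)),
      coupling = uwsCoupling))
}

# Unit-peak component templates over the post-stimulus second.
# N1: negative-going Gaussian centred at 150 ms (sign carried by the
# amplitude); P3a: Gaussian at 300 ms; LPP: sustained plateau 400-1000 ms
# with raised-cosine ramps.
erpTemplate <- function(component, rate) {
  tMs <- (seq_len(round(rate)) - 1) / rate * 1000
  switch(component,
    N1 = exp(-(tMs - 150)^2 / (2 * 20^2)),
    P3a = exp(-(tMs - 300)^2 / (2 * 45^2)),
    LPP = {
      y <- numeric(length(tMs))
      up <- tMs >= 400 & tMs < 480
      y[up] <- 0.5 - 0.5 * cos(pi * (tMs[up] - 400) / 80)
      y[tMs >= 480 & tMs <= 920] <- 1
      dn <- tMs > 920 & tMs <= 1000
      y[dn] <- 0.5 + 0.5 * cos(pi * (tMs[dn] - 920) / 80)
      y
    },
    stop("unknown component: ", component))
}

# Fixed scalp topographies (channel weights in [0, 1]) for each component.
erpTopography <- function(component, channels) {
  frontal <- c(Fp1 = 0.5, Fp2 = 0.5, F7 = 0.4, F3 = 0.8, Fz = 1, F4 = 0.8,
               F8 = 0.4, C3 = 0.3, Cz = 0.4, C4 = 0.3)
  parOcc <- c(P7 = 0.65, P3 = 0.85, Pz = 1, P4 = 0.85, P8 = 0.65,
              O1 = 0.85, Oz = 0.9, O2 = 0.85, C3 = 0.6, Cz = 0.7, C4 = 0.6)
  w <- switch(component, N1 = frontal, P3a = frontal, LPP = parOcc,
              stop("unknown component: ", component))
  out <- stats::setNames(numeric(length(channels)), channels)
  common <- intersect(channels, names(w))
  out[common] <- w[common]
  out
}

matchesCondition <- function(eventLabels, condition) {
  if (condition == "emotional") eventLabels %in% c("happy", "angry")
  else eventLabels == condition
}

#' Synthesize one subject's recording
#'
#' Output is the sum of 1/f background noise, per-event ERP templates (N1,
#' P3a, LPP) scaled by the condition-specific amplitudes of \code{spec}, and
#' a band-limited oscillation at \code{couplingFreqHz} shared between each
#' coupled channel pair during epochs of the stated condition, with a von
#' Mises phase offset of concentration kappa applied to the second channel.
#' Deterministic given \code{spec@seed}.
#'
#' @param spec a [SubjectSpec-class].
#' @param montage a [Montage-class].
#' @param events an [EventSequence-class] (must fit the synthesized length).
#' @param rate sampling rate in Hz (500 Hz by convention).
#' @return an [EEGRecording-class]; the duration is the smallest whole
#'   number of seconds covering the last event plus 1.2 s.
#' @export
synthesizeSubject <- function(spec, montage, events, rate = 500) {
  stopifnot(is(spec, "SubjectSpec"), is(montage, "Montage"),
            is(events, "EventSequence"))
  validObject(spec)
  chans <- montage@channelNames
  if (nrow(spec@coupling)) {
    unknown <- setdiff(unique(c(spec@coupling$chA, spec@coupling$chB)), chans)
    if (length(unknown))
      stop("coupling references unknown channel(s): ",
           paste(unknown, collapse = ", "))
  }
  nSamp <- as.integer(ceiling((max(events@onsets) + 1.2 * rate) / rate) * rate)
  nCh <- length(chans)
  postLen <- round(rate)                    # 0..1000 ms post-stimulus
  epochIdx <- -round(0.2 * rate):(postLen - 1)

  data <- withSeed(spec@seed, {
    X <- if (spec@noiseScale > 0) {
      t(pinkNoiseMat(nSamp, nCh)) * spec@noiseScale
    } else matrix(0, nCh, nSamp)
    # ERP templates per event
    for (comp in c("N1", "P3a", "LPP")) {
      tpl <- erpTemplate(comp, rate)
      topo <- erpTopography(comp, chans)
      act <- which(topo > 0)
      if (!length(act)) next
      for (k in seq_along(events@onsets)) {
        amp <- spec@erpAmplitudes[comp, as.character(events@labels[k])]
        if (amp == 0) next
        idx <- events@onsets[k] + seq_len(postLen) - 1
        X[act, idx] <- X[act, idx] + outer(topo[act] * amp, tpl)
      }
    }
    # shared narrow-band oscillation with per-trial von Mises phase offsets
    if (nrow(spec@coupling) && spec@oscAmplitudeUv > 0) {
      taperLen <- round(0.05 * rate)
      taper <- rep(1, length(epochIdx))
      ramp <- 0.5 - 0.5 * cos(pi * (seq_len(taperLen) - 1) / (taperLen - 1))
      taper[seq_len(taperLen)] <- ramp
      taper[length(taper) + 1 - seq_len(taperLen)] <- ramp
      for (r in seq_len(nrow(spec@coupling))) {
        cp <- spec@coupling[r, ]
        sel <- which(matchesCondition(as.character(events@labels), cp$condition))
        if (!length(sel)) next
        psi <- stats::runif(length(sel), -pi, pi)     # common phase per trial
        delta <- rVonMises(length(sel), cp$kappa)     # jitter on channel B
        ia <- match(cp$chA, chans); ib <- match(cp$chB, chans)
        for (j in seq_along(sel)) {
          idx <- events@onsets[sel[j]] + epochIdx
          tt <- (idx - 1) / rate
          carrier <- 2 * pi * spec@couplingFreqHz * tt
          X[ia, idx] <- X[ia, idx] +
            spec@oscAmplitudeUv * taper * cos(carrier + psi[j])
          X[ib, idx] <- X[ib, idx] +
            spec@oscAmplitudeUv * taper * cos(carrier + psi[j] + delta[j])
        }
      }
    }
    X
  })
  rownames(data) <- chans
  new("EEGRecording", data = data, rate = rate, montage = montage,
      events = events)
}

#' Generate a three-group synthetic dataset
#'
#' Draws \code{nPerGroup} subjects per group from the supplied templates.
#' Each subject receives a deterministic seed derived from the master seed
#' and subject index and an independently randomized oddball sequence, so
#' the dataset is reproducible bit-for-bit and adding subjects never changes
#' existing ones.
#'
#' @param groupSpecs named list of [SubjectSpec-class] templates (default
#'   [groupSpecTemplates()]).
#' @param nPerGroup subjects per group (15 per group, matching the typical
#'   cohort size in this field).
#' @param seed master integer seed.
#' @param montage a [Montage-class] (default [standardMontage()]).
#' @param rate sampling rate in Hz.
#' @param design event counts \code{c(nStandard, nHappy, nAngry)} per block.
#' @return list with \code{recordings} (list of [EEGRecording-class]) and
#'   \code{metadata} (data.frame: subject, group, seed).
#' @export
generateGroupDataset <- function(groupSpecs = groupSpecTemplates(),
                                 nPerGroup = 15, seed = 1,
                                 montage = standardMontage(), rate = 500,
                                 design = c(86, 12, 12)) {
  stopifnot(nPerGroup >= 1, length(design) == 3)
  recordings <- list()
  meta <- list()
  idx <- 0L
  for (g in names(groupSpecs)) {
    template <- groupSpecs[[g]]
    for (i in seq_len(nPerGroup)) {
      idx <- idx + 1L
      sseed <- deriveSeed(seed, idx)
      ev <- generateOddballSequence(design[1], design[2], design[3],
                                    seed = deriveSeed(sseed, 1L), rate = rate)
      spec <- template
      spec@seed <- sseed
      id <- sprintf("%s%02d", g, i)
      recordings[[id]] <- synthesizeSubject(spec, montage, ev, rate)
      meta[[id]] <- data.frame(subject = id, group = g, seed = sseed)
    }
  }
  list(recordings = recordings, metadata = do.call(rbind, c(meta, make.row.names = FALSE)))
}
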