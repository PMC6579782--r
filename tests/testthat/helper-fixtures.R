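# Shared fixtures, generated in code.

smallMontage <- function(chans = c("F3", "Fz", "O1", "Oz", "M1", "M2")) {
  subsetMontage(standardMontage(), chans)
}

# a tiny recording with known content: per-channel signals supplied as a
# function of time (seconds)
toyRecording <- function(nSec = 10, rate = 100,
                         chans = c("F3", "Fz", "O1", "Oz", "M1", "M2"),
                         signal = function(ch, t) 0 * t,
                         events = NULL) {
  m <- smallMontage(chans)
  t <- (seq_len(nSec * rate) - 1) / rate
  dat <- t(vapply(chans, function(ch) signal(ch, t), numeric(length(t))))
  rownames(dat) <- chans
  if (is.null(events)) {
    ons <- unique(as.integer(round(seq(rate, max(rate + 1, nSec * rate - rate),
                                       length.out = 4))))
    labs <- rep(c("neutral", "happy", "neutral", "angry"),
                length.out = length(ons))
    events <- new("EventSequence", onsets = ons,
                  labels = factor(labs, levels = c("neutral", "happy", "angry")),
                  interOnsetMs = 2200)
  }
  new("EEGRecording", data = dat, rate = rate, montage = m, events = events)
}

# zero-amplitude ERP matrix
zeroAmps <- function() erpAmplitudeMatrix(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))

# symmetric random weight matrix in (0, 1]
randomWeights <- function(n, seed) {
  set.seed(seed)
  w <- matrix(stats::runif(n * n, 0.05, 1), n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

# independent Floyd-Warshall all-pairs distances with lengths 1/w
floydWarshall <- function(w) {
  n <- nrow(w)
  D <- 1 / w
  D[w == 0] <- Inf
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# brute-force Onnela clustering by triple loop
onnelaBruteForce <- function(w) {
  n <- nrow(w)
  W <- (w / max(w))^(1 / 3)
  k <- rowSums(w > 0)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n))
      if (j != i && h != i && h != j) s <- s + W[i, j] * W[i, h] * W[j, h]
    ci[i] <- if (k[i] >= 2) s / (k[i] * (k[i] - 1)) else 0
  }
  mean(ci)
}

# hand-rolled balanced split-plot sums-of-squares oracle (one between
# factor, one within factor), returning F for group/condition/interaction
splitPlotOracle <- function(Y, group) {
  n <- nrow(Y); k <- ncol(Y)
  gl <- unique(group); a <- length(gl); ng <- n / a
  gm <- mean(Y)
  sMean <- rowMeans(Y)
  gMean <- tapply(sMean, group, mean)[gl]
  cMean <- colMeans(Y)
  cellM <- sapply(seq_len(k), function(j) tapply(Y[, j], group, mean)[gl])
  ssb <- k * sum((sMean - gm)^2)
  ssg <- ng * k * sum((gMean - gm)^2)
  sse1 <- ssb - ssg
  ssc <- n * sum((cMean - gm)^2)
  ssi <- ng * sum((cellM - outer(gMean, rep(1, k)) -
                     outer(rep(1, a), cMean) + gm)^2)
  sse2 <- sum((Y - gm)^2) - ssb - ssc - ssi
  dfe1 <- a * (ng - 1); dfe2 <- a * (ng - 1) * (k - 1)
  list(F = c(group = (ssg / (a - 1)) / (sse1 / dfe1),
             condition = (ssc / (k - 1)) / (sse2 / dfe2),
             interaction = (ssi / ((a - 1) * (k - 1))) / (sse2 / dfe2)),
       dfDen = c(dfe1, dfe2, dfe2))
}

# property table builder
propertyTable <- function(Y, group, conditions = c("neutral", "emotional")) {
  subj <- sprintf("S%02d", seq_len(nrow(Y)))
  do.call(rbind, lapply(seq_along(conditions), function(j)
    data.frame(subject = subj, group = group, condition = conditions[j],
               value = Y[, j])))
}

# PLVMatrix from an upper-triangle vector
plvFromUpper <- function(x, chans) {
  n <- length(chans)
  p <- diag(1, n)
  p[upper.tri(p)] <- x
  p <- p + t(p) - diag(diag(p))
  diag(p) <- 1
  rownames(p) <- colnames(p) <- chans
  new("PLVMatrix", plv = p, windowMs = c(0, 1000), nTrials = 10L,
      subject = "s", group = "g", condition = "c")
}
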