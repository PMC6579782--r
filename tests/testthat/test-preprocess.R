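test_that("mastoid re-referencing subtracts the mastoid mean", {
  # zero mastoids: identity
  rec <- toyRecording(signal = function(ch, t)
    if (ch %in% c("M1", "M2")) 0 * t else sin(2 * pi * 3 * t))
  expect_equal(rereferenceToMastoids(rec)@data, rec@data)
  # constant +10 on both mastoids: every channel shifted by -10
  rec2 <- toyRecording(signal = function(ch, t)
    if (ch %in% c("M1", "M2")) 0 * t + 10 else 0 * t)
  out <- rereferenceToMastoids(rec2)
  expect_equal(unique(as.vector(out@data[c("F3", "Fz", "O1", "Oz"), ])), -10)
  # random recording: brute-force per-sample loop oracle
  set.seed(8)
  rec3 <- toyRecording(nSec = 2, signal = function(ch, t) rnorm(length(t)))
  out3 <- rereferenceToMastoids(rec3)
  oracle <- rec3@data
  for (s in seq_len(ncol(oracle)))
    oracle[, s] <- oracle[, s] - mean(rec3@data[c("M1", "M2"), s])
  expect_equal(out3@data, oracle, tolerance = 1e-12)
  # idempotent once mastoids are zeroed
  expect_equal(rereferenceToMastoids(out3)@data, out3@data, tolerance = 1e-12)
  # missing mastoid errors and lists channels
  bad <- subsetMontage(standardMontage(), c("F3", "Fz", "O1", "M1", "M2"))
  bad@mastoidLabels <- c("M1", "TP10")
  expect_error(rereferenceToMastoids(
    new("EEGRecording", data = rec@data[c(1, 2, 3, 5, 6), ], rate = rec@rate,
        montage = bad, events = rec@events)), "available")
})

test_that("filtering attenuates stopband, passes passband, removes DC", {
  rate <- 500
  rec50 <- toyRecording(nSec = 10, rate = rate,
                        signal = function(ch, t) sin(2 * pi * 50 * t))
  out <- filterRecording(rec50)
  expect_lt(sqrt(mean(out@data[1, ]^2)) / sqrt(mean(rec50@data[1, ]^2)), 0.05)
  rec10 <- toyRecording(nSec = 10, rate = rate,
                        signal = function(ch, t) sin(2 * pi * 10 * t))
  out10 <- filterRecording(rec10)
  expect_equal(sd(out10@data[1, ]) / sd(rec10@data[1, ]), 1, tolerance = 0.05)
  recDC <- toyRecording(nSec = 10, rate = rate, signal = function(ch, t) 0 * t + 7)
  expect_lt(max(abs(filterRecording(recDC)@data)), 1e-3)
  expect_error(filterRecording(rec10, lpHz = 300), "Nyquist")
})

test_that("filtering is linear", {
  rate <- 500
  set.seed(9)
  x <- rnorm(5 * rate); y <- rnorm(5 * rate)
  mk <- function(v) {
    r <- toyRecording(nSec = 5, rate = rate, chans = c("Fz", "Oz", "M1", "M2"),
                      signal = function(ch, t) 0 * t)
    r@data[1, ] <- v
    r
  }
  f <- function(v) filterRecording(mk(v))@data[1, ]
  lhs <- f(2 * x + 3 * y)
  rhs <- 2 * f(x) + 3 * f(y)
  expect_lt(max(abs(lhs - rhs)) / sd(lhs), 1e-6)
})

test_that("epoching follows the half-open window convention", {
  rate <- 500
  ev <- new("EventSequence", onsets = c(10L, 600L, 1500L),
            labels = factor(c("neutral", "happy", "neutral"),
                            levels = c("neutral", "happy", "angry")),
            interOnsetMs = 2200)
  rec <- toyRecording(nSec = 6, rate = rate, signal = function(ch, t) sin(t),
                      events = ev)
  expect_warning(ep <- epochRecording(rec), "dropped")
  expect_equal(dim(ep@data), c(2, 6, 600))   # event at sample 10 dropped
  expect_equal(ep@nDropped, 1L)
  expect_equal(range(ep@timesMs), c(-200, 998))
  # baseline mean is zero for every trial and channel
  bl <- ep@timesMs >= -200 & ep@timesMs < 0
  expect_lt(max(abs(apply(ep@data[, , bl], c(1, 2), mean))), 1e-9)
  # trial content matches direct slicing (before baseline, trial 2)
  ep2 <- suppressWarnings(epochRecording(rec, baselineMs = NULL))
  expect_equal(ep2@data[1, 3, ], rec@data[3, (600 - 100):(600 + 499)])
  expect_error(epochRecording(rec, windowMs = c(-200, 1000),
                              baselineMs = c(-300, 0)), "baseline")
})

test_that("artifact rejection drops exactly the spiked trials", {
  rec <- toyRecording(nSec = 12, rate = 100,
                      signal = function(ch, t) sin(2 * pi * 2 * t))
  ep <- epochRecording(rec, baselineMs = NULL)
  expect_identical(nTrials(suppressMessages(
    rejectArtifactEpochs(ep, Inf))), nTrials(ep))
  ep2 <- ep
  ep2@data[2, 2, 30] <- ep2@data[2, 2, 30] + 500   # 500 uV spike, trial 2
  out <- suppressMessages(rejectArtifactEpochs(ep2, 200))
  expect_equal(nTrials(out), nTrials(ep) - 1)
  log <- attr(out, "rejectionLog")
  expect_identical(which(log$decision == "reject"), 2L)
  # surviving count equals a brute-force scan
  scalp <- match(scalpChannels(ep2@montage), channelNames(ep2))
  brute <- sum(vapply(seq_len(nTrials(ep2)), function(k) {
    m <- ep2@data[k, scalp, ]
    max(apply(m, 1, max) - apply(m, 1, min)) <= 200
  }, logical(1)))
  expect_equal(nTrials(out), brute)
  expect_error(suppressMessages(rejectArtifactEpochs(ep2, 1e-6)), "threshold")
})

test_that("epoch bookkeeping: kept + dropped + rejected = total events", {
  rate <- 100
  ev <- new("EventSequence", onsets = c(5L, 150L, 400L, 700L, 1190L),
            labels = factor(rep("neutral", 5), levels = "neutral"),
            interOnsetMs = 2200)
  rec <- toyRecording(nSec = 12, rate = rate,
                      signal = function(ch, t) sin(2 * pi * 2 * t), events = ev)
  rec@data[1, 155] <- 900    # spike inside epoch of event 2
  expect_warning(ep <- epochRecording(rec), "dropped")
  kept <- suppressMessages(rejectArtifactEpochs(ep, 200))
  rejected <- nTrials(ep) - nTrials(kept)
  expect_equal(nTrials(kept) + rejected + ep@nDropped, length(ev@onsets))
})

test_that("bad-channel interpolation is an inverse-distance weighted mean", {
  rec <- toyRecording(nSec = 4, rate = 100,
                      signal = function(ch, t) sin(2 * pi * 2 * t))
  ep <- epochRecording(rec, baselineMs = NULL)
  # identical signal on all good channels: interpolation reproduces it
  out <- interpolateChannel(ep, "F3")
  expect_equal(out@data[1, 1, ], ep@data[1, 2, ], tolerance = 1e-10)
  w <- attr(out, "interpolationWeights")
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w >= 0))
  # brute-force weighted sum on a random epoch set
  set.seed(10)
  ep@data[] <- rnorm(length(ep@data))
  out2 <- interpolateChannel(ep, "Oz")
  iOz <- match("Oz", channelNames(ep))
  good <- setdiff(scalpChannels(ep@montage), "Oz")
  P <- ep@montage@positions
  d <- acos(pmin(1, pmax(-1, P[good, ] %*% P["Oz", ])))
  wts <- as.numeric(1 / d); wts <- wts / sum(wts)
  oracle <- 0
  for (j in seq_along(good))
    oracle <- oracle + wts[j] * ep@data[2, match(good[j], channelNames(ep)), ]
  expect_equal(out2@data[2, iOz, ], oracle, tolerance = 1e-12)
  expect_error(interpolateChannel(ep, "XX"), "not in montage")
})
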