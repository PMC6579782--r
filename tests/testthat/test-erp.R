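test_that("condition averages equal the brute-force trial mean", {
  rec <- toyRecording(nSec = 12, rate = 100,
                      signal = function(ch, t) 0 * t)
  ep <- epochRecording(rec, baselineMs = NULL)
  set.seed(11)
  ep@data[] <- rnorm(length(ep@data))
  avg <- conditionAverage(ep, "neutral")
  sel <- which(ep@labels == "neutral")
  oracle <- matrix(0, dim(ep@data)[2], dim(ep@data)[3])
  for (k in sel) oracle <- oracle + ep@data[k, , ]
  oracle <- oracle / length(sel)
  expect_equal(unname(avg@mean), oracle, tolerance = 1e-12)
  expect_equal(avg@nTrials, length(sel))
  # single trial equals that trial; x and -x average to zero
  one <- ep
  one@data <- ep@data[1, , , drop = FALSE]
  one@labels <- droplevels(ep@labels[1])
  expect_equal(unname(conditionAverage(one, "neutral")@mean), ep@data[1, , ])
  two <- ep
  two@data <- ep@data[1:2, , , drop = FALSE]
  two@data[2, , ] <- -two@data[1, , ]
  two@labels <- factor(c("neutral", "neutral"))
  expect_equal(max(abs(conditionAverage(two, "neutral")@mean)), 0)
  expect_error(conditionAverage(ep, "nosuch"), "condition")
})

test_that("pooling deviants relabels happy/angry as emotional", {
  rec <- toyRecording(nSec = 12, rate = 100, signal = function(ch, t) 0 * t)
  ep <- poolEmotional(epochRecording(rec, baselineMs = NULL))
  expect_setequal(levels(ep@labels), c("neutral", "emotional"))
  expect_equal(sum(ep@labels == "emotional"), 2)
})

test_that("BY adjustment matches the published step-up rule", {
  # single p with c(1) = 1
  expect_equal(byAdjust(0.03), 0.03)
  # brute-force implementation of the step-up procedure as oracle
  byOracle <- function(p) {
    m <- length(p)
    cm <- sum(1 / seq_len(m))
    o <- order(p)
    adj <- p[o] * cm * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
  }
  set.seed(12)
  for (rep in 1:5) {
    p <- runif(50)^2
    expect_equal(byAdjust(p), byOracle(p), tolerance = 1e-12)
  }
  p <- rep(0.01, 7)   # ties
  expect_equal(byAdjust(p), byOracle(p), tolerance = 1e-12)
  # properties: >= input, <= 1, more conservative than BH
  p <- runif(200)
  expect_true(all(byAdjust(p) >= p - 1e-15))
  expect_true(all(byAdjust(p) <= 1))
  expect_true(all(byAdjust(p) >= p.adjust(p, "BH") - 1e-15))
  expect_error(byAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("paired permutation t matches the closed form and null identity", {
  # values_a == values_b: all t zero, nothing significant
  set.seed(13)
  a <- matrix(rnorm(5 * 20), 5)
  r0 <- massUnivariatePairedT(a, a)
  expect_true(all(r0@t == 0))
  expect_equal(sum(r0@sigMask), 0)
  # single-cell closed form with d = (1, 1, 2)
  r1 <- massUnivariatePairedT(matrix(c(1, 2, 3), 3), matrix(c(0, 1, 1), 3))
  d <- c(1, 1, 2)
  expect_equal(as.numeric(r1@t), mean(d) / (sd(d) / sqrt(3)))
  expect_true(r1@exact)
  expect_equal(r1@nPerm, 2L^3)
  # exact enumeration p at one cell: fraction of the 2^n sign patterns
  # whose |t| >= |t_obs| (brute force over all 8 patterns)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), 3)))
  tAll <- apply(signs, 1, function(s) {
    ds <- s * d
    mean(ds) / (sd(ds) / sqrt(3))
  })
  expect_equal(as.numeric(r1@pRaw),
               mean(abs(tAll) >= abs(mean(d) / (sd(d) / sqrt(3))) - 1e-12))
  expect_error(massUnivariatePairedT(a[1, , drop = FALSE], a[1, , drop = FALSE]),
               "2 paired subjects")
  expect_error(massUnivariatePairedT(a, a[, 1:3]), "identical shape")
})

test_that("permutation p-values are reproducible and well calibrated", {
  set.seed(14)
  a <- matrix(rnorm(20 * 50), 20)
  b <- matrix(rnorm(20 * 50), 20)
  r1 <- massUnivariatePairedT(a, b, nPerm = 500, seed = 7)
  r2 <- massUnivariatePairedT(a, b, nPerm = 500, seed = 7)
  expect_identical(r1@pRaw, r2@pRaw)
  expect_false(r1@exact)
  # super-uniformity under the null: empirical CDF below the diagonal
  # within sampling tolerance (KS-style check on pooled null p-values)
  set.seed(15)
  ps <- c()
  for (i in 1:20) {
    x <- matrix(rnorm(10 * 25), 10)
    y <- matrix(rnorm(10 * 25), 10)
    ps <- c(ps, as.numeric(massUnivariatePairedT(x, y, nPerm = 200,
                                                 seed = i)@pRaw))
  }
  grid <- seq(0.05, 0.95, by = 0.05)
  emp <- vapply(grid, function(g) mean(ps <= g), numeric(1))
  expect_true(all(emp <= grid + 3 * sqrt(grid * (1 - grid) / length(ps)) + 0.02))
})

test_that("component measurement equals the brute-force window mean", {
  rec <- toyRecording(nSec = 12, rate = 100, signal = function(ch, t) 0 * t)
  ep <- epochRecording(rec, baselineMs = NULL)
  set.seed(16)
  ep@data[] <- rnorm(length(ep@data))
  avg <- conditionAverage(ep, "neutral")
  sp <- componentSpec("N1", channels = c("F3", "Fz"))
  v <- measureComponent(avg, sp)
  acc <- c()
  for (ch in sp$channels)
    for (j in which(avg@timesMs >= 100 & avg@timesMs < 200))
      acc <- c(acc, avg@mean[match(ch, avg@channelNames), j])
  expect_equal(v, mean(acc), tolerance = 1e-12)
  # flat zero waveform measures 0
  z <- avg; z@mean[] <- 0
  expect_equal(measureComponent(z, componentSpec("LPP", channels = c("O1", "Oz"))), 0)
  expect_error(measureComponent(avg, componentSpec("LPP", windowMs = c(400, 5000),
                                                   channels = c("O1", "Oz"))),
               "window")
})

test_that("HC-profile significant cells concentrate in the LPP window", {
  # noiseless LPP injection: emotional vs neutral differs only over
  # 400-1000 ms on parietal-occipital channels
  m <- smallMontage(c("Fz", "Pz", "Oz", "M1", "M2"))
  amps <- erpAmplitudeMatrix(c(0, 0, 0), c(0, 0, 0), c(0.5, 5, 5))
  ev <- generateOddballSequence(6, 2, 2, seed = 8)
  erpN <- list(); erpE <- list()
  for (s in 1:12) {
    spec <- subjectSpec("HC", amps, noiseScale = 2, seed = 30 + s)
    ep <- poolEmotional(epochRecording(
      synthesizeSubject(spec, m, ev, rate = 250)))
    erpN[[s]] <- conditionAverage(ep, "neutral")
    erpE[[s]] <- conditionAverage(ep, "emotional")
  }
  A <- aperm(simplify2array(lapply(erpE, function(w) w@mean)), c(3, 1, 2))
  B <- aperm(simplify2array(lapply(erpN, function(w) w@mean)), c(3, 1, 2))
  res <- massUnivariatePairedT(A, B, q = 0.05, seed = 1,
                               channelNames = channelNames(m),
                               timesMs = erpN[[1]]@timesMs)
  sig <- res@sigMask
  inWin <- res@timesMs >= 400 & res@timesMs < 1000
  po <- res@channelNames %in% c("Pz", "Oz")
  expect_gt(sum(sig[po, inWin]), 0)                  # non-empty overlap
  # the mask concentrates in the injected window x channels (the FDR level
  # tolerates a small fraction of stray discoveries)
  expect_gt(sum(sig[po, inWin]) / sum(sig), 0.9)
})
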