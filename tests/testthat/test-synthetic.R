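test_that("oddball sequences have exact counts and no adjacent deviants", {
  ev <- generateOddballSequence(86, 12, 12, seed = 1)
  expect_length(ev@onsets, 110)
  expect_equal(unname(table(ev@labels)[c("neutral", "happy", "angry")]),
               c(86L, 12L, 12L), ignore_attr = TRUE)
  expect_true(all(diff(ev@onsets) > 0))
  for (s in c(2, 17, 123)) {
    ev <- generateOddballSequence(86, 12, 12, seed = s)
    dev <- as.character(ev@labels) != "neutral"
    expect_equal(sum(dev[-1] & dev[-length(dev)]), 0)
  }
})

test_that("degenerate and infeasible designs are handled", {
  ev <- generateOddballSequence(1, 0, 0, seed = 0)
  expect_length(ev@onsets, 1)
  expect_equal(as.character(ev@labels), "neutral")
  expect_error(generateOddballSequence(3, 3, 2, seed = 1), "infeasible")
})

test_that("sequence generation is deterministic under a fixed seed", {
  a <- generateOddballSequence(20, 4, 4, seed = 99)
  b <- generateOddballSequence(20, 4, 4, seed = 99)
  expect_identical(a@labels, b@labels)
  expect_identical(a@onsets, b@onsets)
})

test_that("expectedPLVFromKappa matches Monte Carlo and is monotone", {
  expect_equal(expectedPLVFromKappa(0), 0)
  expect_gt(expectedPLVFromKappa(1e6), 0.999)
  expect_lt(expectedPLVFromKappa(1e6), 1)
  # Monte-Carlo mean resultant length at kappa = 2
  set.seed(42)
  th <- erpnet:::rVonMises(1e6, 2)
  mc <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  se <- 1 / sqrt(1e6)   # conservative bound on the MC standard error
  expect_lt(abs(expectedPLVFromKappa(2) - mc), 3 * se + 1e-3)
  # monotone non-decreasing over a kappa grid, range [0, 1)
  grid <- expectedPLVFromKappa(c(0, 0.5, 1, 2, 4, 8, 32, 1e5))
  expect_true(all(diff(grid) >= 0))
  expect_true(all(grid >= 0 & grid < 1))
  expect_error(expectedPLVFromKappa(-1), "kappa")
})

test_that("noiseless ERP injection reproduces the template exactly", {
  m <- smallMontage()
  amps <- erpAmplitudeMatrix(c(-5, -5, -5), c(0, 0, 0), c(0, 0, 0))
  spec <- subjectSpec("UWS", amps, noiseScale = 0, seed = 3)
  ev <- generateOddballSequence(4, 1, 0, seed = 2)
  rec <- synthesizeSubject(spec, m, ev, rate = 500)
  ep <- epochRecording(rec, baselineMs = NULL)
  avg <- conditionAverage(ep, "neutral")
  tpl <- erpnet:::erpTemplate("N1", 500)
  w <- erpnet:::erpTopography("N1", channelNames(m))
  post <- avg@timesMs >= 0
  expect_equal(avg@mean["Fz", post], -5 * w["Fz"] * tpl,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(avg@mean["F3", post], -5 * w["F3"] * tpl,
               tolerance = 1e-12, ignore_attr = TRUE)
  # no LPP leakage onto frontal sites pre-peak, none at all on O1 (zero LPP)
  expect_equal(max(abs(avg@mean["O1", ])), 0)
})

test_that("strong coupling yields near-perfect phase locking", {
  m <- smallMontage()
  spec <- subjectSpec("HC", zeroAmps(),
                      coupling = data.frame(chA = "F3", chB = "O1",
                                            condition = "emotional",
                                            kappa = 1e6),
                      noiseScale = 0, seed = 11)
  ev <- generateOddballSequence(10, 5, 5, seed = 4)
  rec <- synthesizeSubject(spec, m, ev, rate = 500)
  ph <- instantaneousPhase(epochRecording(rec, baselineMs = NULL), c(8, 12))
  ph <- poolEmotional(ph)
  idx <- which(conditionLabels(ph) == "emotional")
  expect_gt(plvPair(ph, "F3", "O1", trials = idx), 0.99)
})

test_that("unknown coupling channels are rejected", {
  spec <- subjectSpec("HC", zeroAmps(),
                      coupling = data.frame(chA = "F3", chB = "XX",
                                            condition = "neutral", kappa = 1),
                      noiseScale = 0, seed = 1)
  ev <- generateOddballSequence(3, 0, 0, seed = 1)
  expect_error(synthesizeSubject(spec, smallMontage(), ev), "unknown channel")
})

test_that("group dataset generation is deterministic and stable", {
  specs <- groupSpecTemplates()
  # shrink for speed: 4-channel montage, 6-event blocks
  m <- smallMontage(c("F3", "O1", "M1", "M2"))
  for (g in names(specs)) specs[[g]]@coupling <- emptyCoupling()
  d1 <- generateGroupDataset(specs, nPerGroup = 2, seed = 7, montage = m,
                             design = c(5, 1, 1))
  d2 <- generateGroupDataset(specs, nPerGroup = 2, seed = 7, montage = m,
                             design = c(5, 1, 1))
  expect_identical(d1$recordings[["HC01"]]@data, d2$recordings[["HC01"]]@data)
  expect_identical(d1$metadata, d2$metadata)
  expect_equal(nrow(d1$metadata), 6)
  expect_equal(unname(table(d1$metadata$group)), c(2L, 2L, 2L),
               ignore_attr = TRUE)
  # adding subjects does not perturb existing ones
  d3 <- generateGroupDataset(specs, nPerGroup = 3, seed = 7, montage = m,
                             design = c(5, 1, 1))
  expect_identical(d3$recordings[["HC01"]]@data, d1$recordings[["HC01"]]@data)
})

test_that("montage invariants hold and subsetting checks mastoids", {
  m <- standardMontage()
  expect_true(validObject(m))
  expect_equal(max(abs(sqrt(rowSums(m@positions^2)) - 1)), 0, tolerance = 1e-9)
  expect_setequal(m@mastoidLabels, c("M1", "M2"))
  expect_length(scalpChannels(m), 20)
  expect_error(subsetMontage(m, c("Fz", "Cz")), "mastoid")
  f <- tempfile(fileext = ".json")
  writeMontageJSON(m, f)
  m2 <- readMontageJSON(f)
  expect_equal(m2@positions, m@positions, tolerance = 1e-12)
  expect_identical(m2@channelNames, m@channelNames)
})
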