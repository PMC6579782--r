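test_that("mixed RM-ANOVA matches the split-plot sums-of-squares oracle", {
  set.seed(23)
  for (rep in 1:5) {
    n <- 5
    group <- rep(c("HC", "MCS", "UWS"), each = n)
    Y <- matrix(rnorm(15 * 2), 15, 2,
                dimnames = list(NULL, c("neutral", "emotional")))
    Y[group == "HC", 2] <- Y[group == "HC", 2] + rnorm(1)
    tb <- propertyTable(Y, group)
    res <- mixedRmAnova(tb)
    o <- splitPlotOracle(Y[order(sprintf("S%02d", 1:15)), ],
                         group[order(sprintf("S%02d", 1:15))])
    expect_equal(res@effects$F, unname(o$F), tolerance = 1e-8)
    expect_equal(res@effects$dfDen, unname(o$dfDen))
    pOracle <- pf(o$F, c(2, 1, 2), o$dfDen, lower.tail = FALSE)
    expect_equal(res@effects$p, unname(pOracle), tolerance = 1e-8)
  }
})

test_that("two-level condition factor forces epsilon 1 and Mauchly NA", {
  set.seed(24)
  Y <- matrix(rnorm(24), 12, 2, dimnames = list(NULL, c("neutral", "emotional")))
  res <- mixedRmAnova(propertyTable(Y, rep(c("HC", "MCS", "UWS"), each = 4)))
  expect_identical(res@epsilonGG, 1)
  expect_true(is.na(res@mauchlyP))
  expect_equal(res@effects$pGG, res@effects$p)
  mt <- mauchlyTest(Y)
  expect_equal(mt$W, 1)
  expect_true(is.na(mt$p))
  expect_equal(ggEpsilon(Y), 1)
})

test_that("degenerate tables are flagged, identical conditions give F = 0", {
  group <- rep(c("HC", "MCS", "UWS"), each = 3)
  base <- rnorm(9)
  Y <- cbind(neutral = base, emotional = base)   # no condition difference
  res <- mixedRmAnova(propertyTable(Y, group))
  expect_equal(res@effects$F[res@effects$effect == "stimulation"], 0,
               tolerance = 1e-10)
  # constant group offsets with zero within-subject noise: degenerate strata
  Y2 <- cbind(neutral = rep(c(0, 1, 2), each = 3),
              emotional = rep(c(0, 1, 2), each = 3))
  res2 <- mixedRmAnova(propertyTable(Y2, group))
  expect_true(res2@degenerate)
  expect_equal(res2@effects$F[res2@effects$effect == "group:stimulation"], 0,
               tolerance = 1e-10)
  # missing cells refuse to run
  tb <- propertyTable(cbind(neutral = rnorm(9), emotional = rnorm(9)), group)
  expect_error(mixedRmAnova(tb[-1, ]), "exactly one row per condition")
})

test_that("Mauchly and GG epsilon agree with independent formulations", {
  set.seed(25)
  # spherical covariance, k = 3: W near 1, large p, epsilon near 1
  X <- matrix(rnorm(50 * 3), 50)
  mt <- mauchlyTest(X)
  expect_gt(mt$W, 0.8)
  expect_gt(mt$p, 0.05)
  expect_gt(ggEpsilon(X), 0.85)
  # arbitrary k = 3 data: W equals stats::mauchly.test on the mlm
  S <- matrix(c(1, .4, .2, .4, 1.5, .1, .2, .1, .7), 3)
  X2 <- matrix(rnorm(40 * 3), 40) %*% chol(S)
  mt2 <- mauchlyTest(X2)
  ref <- stats::mauchly.test(stats::lm(X2 ~ 1), X = ~1)
  expect_equal(mt2$W, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mt2$p, ref$p.value, tolerance = 1e-10)
  # spherical k = 4 simulation: epsilon near 1
  X4 <- matrix(rnorm(60 * 4), 60)
  expect_gt(ggEpsilon(X4), 0.85)
  # maximally non-spherical k = 3: one dominant contrast eigenvalue
  # pushes epsilon to its lower bound 1/2
  M <- erpnet:::.orthContrasts(3)
  scores <- cbind(rnorm(30), 1e-6 * rnorm(30))   # contrast-space scores
  Xd <- scores %*% t(M)
  lam <- eigen(stats::cov(Xd %*% M), symmetric = TRUE)$values
  direct <- sum(lam)^2 / (2 * sum(lam^2))
  expect_equal(ggEpsilon(Xd), max(0.5, min(1, direct)), tolerance = 1e-10)
  expect_lt(ggEpsilon(Xd), 0.51)
  expect_error(mauchlyTest(X[1:3, ]), "n > k")
})

test_that("Bonferroni post hocs multiply p by the comparison count", {
  set.seed(26)
  group <- rep(c("HC", "MCS", "UWS"), each = 6)
  Y <- cbind(neutral = rnorm(18), emotional = rnorm(18))
  Y[group == "HC", ] <- Y[group == "HC", ] + 2
  ph <- bonferroniPosthoc(propertyTable(Y, group))
  expect_equal(nrow(ph), 3)
  expect_equal(ph$pAdj, pmin(1, ph$p * 3))
  expect_true(all(ph$pAdj >= ph$p))
  # null calibration: no adjusted p < 0.05 in >= 95% of null simulations
  hits <- vapply(1:60, function(s) {
    set.seed(300 + s)
    Yn <- cbind(neutral = rnorm(30), emotional = rnorm(30))
    any(bonferroniPosthoc(propertyTable(Yn, rep(c("HC", "MCS", "UWS"),
                                                each = 10)))$pAdj < 0.05)
  }, logical(1))
  expect_lte(mean(hits), 0.05 + 2 * sqrt(0.05 * 0.95 / 60))
})

test_that("simple effects flag only the group with an injected shift", {
  set.seed(27)
  group <- rep(c("HC", "MCS", "UWS"), each = 15)
  noise <- rnorm(45)
  Y <- cbind(neutral = noise, emotional = noise + rnorm(45, sd = 1))
  Y[group == "HC", "emotional"] <- Y[group == "HC", "emotional"] + 2  # 2 SD
  se <- simpleEffects(propertyTable(Y, group))
  expect_equal(se$group, c("HC", "MCS", "UWS"))
  expect_lt(se$pAdj[se$group == "HC"], 0.05)
  expect_true(all(se$pAdj >= se$p))
  # single-group table returns that group only
  se1 <- simpleEffects(propertyTable(Y[group == "HC", ],
                                     rep("HC", 15)))
  expect_equal(nrow(se1), 1)
  # condition-label swap flips the sign of the effect
  Ys <- Y[, c("emotional", "neutral")]
  colnames(Ys) <- c("neutral", "emotional")
  seS <- simpleEffects(propertyTable(Ys, group))
  expect_equal(seS$meanDiff, -se$meanDiff, tolerance = 1e-12)
})

test_that("condition-label swap leaves ANOVA F values unchanged", {
  set.seed(28)
  group <- rep(c("HC", "MCS", "UWS"), each = 5)
  Y <- cbind(neutral = rnorm(15), emotional = rnorm(15, 0.5))
  r1 <- mixedRmAnova(propertyTable(Y, group))
  Ys <- Y[, 2:1]; colnames(Ys) <- c("neutral", "emotional")
  r2 <- mixedRmAnova(propertyTable(Ys, group))
  expect_equal(r1@effects$F, r2@effects$F, tolerance = 1e-10)
})

test_that("edge-wise contrasts detect a constructed shifted edge", {
  chans <- c("F3", "Fz", "O1", "Oz", "Pz")
  mEdges <- choose(5, 2)
  set.seed(29)
  mk <- function(shift) plvFromUpper(0.3 + rnorm(mEdges, 0, 0.02) + shift, chans)
  shift <- c(0.3, rep(0, mEdges - 1))
  a <- lapply(1:15, function(i) mk(shift))
  b <- lapply(1:15, function(i) mk(0))
  ec <- edgewiseContrast(a, b, paired = TRUE)
  expect_equal(ec@m, mEdges)
  expect_true(ec@table$sigBonferroni[1])
  expect_identical(ec@table$direction[1], "increase")
  expect_equal(sum(ec@table$sigBonferroni), 1)
  # identical inputs: empty masks
  ec0 <- edgewiseContrast(a, a, paired = TRUE)
  expect_equal(sum(ec0@table$sigUncorrected), 0)
  # Bonferroni mask is a subset of the uncorrected mask
  expect_true(all(!ec@table$sigBonferroni | ec@table$sigUncorrected))
  # unpaired route runs and finds the same edge
  ec2 <- edgewiseContrast(a, b, paired = FALSE)
  expect_true(ec2@table$sigBonferroni[1])
  expect_error(edgewiseContrast(a[1:3], b, paired = TRUE), "equal-length")
})

test_that("demographics utility returns t and chi-square rows", {
  set.seed(30)
  out <- compareDemographics(continuousA = rnorm(8, 59, 15),
                             continuousB = rnorm(7, 53, 13),
                             countsA = c(5, 3), countsB = c(4, 3))
  expect_equal(out$variable, c("continuous", "categorical"))
  expect_true(all(out$p >= 0 & out$p <= 1))
})
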