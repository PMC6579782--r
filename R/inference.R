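# Group-level statistics: 3 x 2 mixed repeated-measures ANOVA (between:
# group HC/MCS/UWS, within: stimulation condition neutral/emotional) with
# Mauchly sphericity and Greenhouse-Geisser correction, Bonferroni post
# hocs, simple effects, and edge-wise PLV contrasts.

.checkPropertyTable <- function(table) {
  need <- c("subject", "group", "condition", "value")
  if (!all(need %in% names(table)))
    stop("property table needs columns ", paste(need, collapse = ", "))
  tab <- base::table(table$subject, table$condition)
  if (any(tab != 1))
    stop("each subject needs exactly one row per condition (no imputation)")
  g <- unique(table[, c("subject", "group")])
  if (anyDuplicated(g$subject))
    stop("each subject must belong to exactly one group")
  invisible(table)
}

# wide subjects x conditions matrix plus the group factor, subject-sorted
.wideTable <- function(table) {
  conds <- levels(factor(table$condition))
  subs <- sort(unique(table$subject))
  Y <- sapply(conds, function(cc)
    table$value[match(paste(subs, cc),
                      paste(table$subject, table$condition))])
  Y <- matrix(Y, length(subs), length(conds),
              dimnames = list(subs, conds))
  grp <- factor(table$group[match(subs, table$subject)])
  list(Y = Y, group = grp, conditions = conds)
}

# orthonormal within-subject contrast matrix (k x (k-1))
.orthContrasts <- function(k) {
  M <- stats::contr.helmert(k)
  qr.Q(qr(M))[, seq_len(k - 1), drop = FALSE]
}

#' Mauchly's sphericity test
#'
#' W from the covariance of the orthonormalized within-subject contrasts
#' with the standard chi-square approximation. For k = 2 there is a single
#' contrast, sphericity holds trivially and the test is not applicable
#' (W = 1, p = NA).
#'
#' @param withinData numeric matrix, subjects x k conditions (n > k).
#' @return list with W, chi2, df, p.
#' @export
mauchlyTest <- function(withinData) {
  X <- as.matrix(withinData)
  n <- nrow(X); k <- ncol(X)
  if (k < 2) stop("need at least 2 conditions")
  if (n <= k) stop("need more subjects than conditions (n > k)")
  if (k == 2)
    return(list(W = 1, chi2 = NA_real_, df = 0L, p = NA_real_))
  M <- .orthContrasts(k)
  S <- stats::cov(X %*% M)
  d <- k - 1
  W <- det(S) / (sum(diag(S)) / d)^d
  f <- 1 - (2 * d^2 + d + 2) / (6 * d * (n - 1))
  chi2 <- -(n - 1) * f * log(W)
  df <- as.integer(d * (d + 1) / 2 - 1)
  list(W = W, chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Greenhouse-Geisser epsilon
#'
#' Computed from the eigenvalues of the orthonormal-contrast covariance,
#' clipped to its theoretical range [1/(k-1), 1]. Equals 1 exactly for a
#' 2-level within factor.
#'
#' @param withinData numeric matrix, subjects x k conditions (n > k).
#' @return epsilon in [1/(k-1), 1].
#' @export
ggEpsilon <- function(withinData) {
  X <- as.matrix(withinData)
  n <- nrow(X); k <- ncol(X)
  if (k < 2) stop("need at least 2 conditions")
  if (n <= k) stop("need more subjects than conditions (n > k)")
  if (k == 2) return(1)
  S <- stats::cov(X %*% .orthContrasts(k))
  lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  eps <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  min(1, max(1 / (k - 1), eps))
}

#' Mixed repeated-measures ANOVA
#'
#' Classical mixed-design (split-plot) ANOVA with group as the
#' between-subject factor and condition as the within-subject factor:
#' the group effect is tested against subject-within-group error, the
#' condition and interaction effects against the condition x
#' subject-within-group error (Type III sums of squares, as in common
#' statistical practice for this design). Greenhouse-Geisser-adjusted
#' p-values are reported alongside; with a 2-level condition factor
#' epsilon is exactly 1 and Mauchly's test is not applicable.
#'
#' @param table data.frame with columns subject, group, condition, value;
#'   every subject complete, >= 2 subjects per group.
#' @return an [RmAnovaResult-class].
#' @export
mixedRmAnova <- function(table) {
  .checkPropertyTable(table)
  w <- .wideTable(table)
  if (any(base::table(w$group) < 2)) stop("need >= 2 subjects per group")
  k <- length(w$conditions)
  df <- data.frame(group = w$group)
  mlm <- stats::lm(w$Y ~ group, data = df,
                   contrasts = list(group = "contr.sum"))
  idata <- data.frame(condition = factor(w$conditions, levels = w$conditions))
  av <- car::Anova(mlm, idata = idata, idesign = ~condition, type = 3)
  su <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- su$univariate.tests
  rn <- rownames(ut)
  pick <- function(nm) which(rn == nm)
  rows <- c(pick("group"), pick("condition"), pick("group:condition"))
  SS <- ut[rows, "Sum Sq"]; ESS <- ut[rows, "Error SS"]
  dfNum <- ut[rows, "num Df"]; dfDen <- ut[rows, "den Df"]
  scale <- sum(abs(SS)) + sum(abs(ESS)) + 1e-300
  Fv <- numeric(3); pv <- numeric(3)
  for (i in 1:3) {
    if (SS[i] <= 1e-12 * scale) {            # no effect variance: F = 0
      Fv[i] <- 0; pv[i] <- 1
    } else if (ESS[i] <= 1e-12 * scale) {    # zero error stratum: flagged
      Fv[i] <- Inf; pv[i] <- 0
    } else {
      Fv[i] <- (SS[i] / dfNum[i]) / (ESS[i] / dfDen[i])
      pv[i] <- stats::pf(Fv[i], dfNum[i], dfDen[i], lower.tail = FALSE)
    }
  }
  eff <- data.frame(
    effect = c("group", "stimulation", "group:stimulation"),
    F = Fv, dfNum = dfNum, dfDen = dfDen, p = pv)
  eps <- ggEpsilon(w$Y)
  mt <- mauchlyTest(w$Y)
  if (k == 2) {
    eff$pGG <- eff$p                     # epsilon = 1 exactly
  } else {
    eff$pGG <- eff$p
    within <- eff$effect != "group"
    eff$pGG[within] <- stats::pf(eff$F[within], eff$dfNum[within] * eps,
                                 eff$dfDen[within] * eps, lower.tail = FALSE)
  }
  degenerate <- any(ESS <= 1e-12 * scale)
  new("RmAnovaResult", effects = eff, epsilonGG = eps,
      mauchlyW = mt$W, mauchlyP = mt$p, degenerate = degenerate)
}

#' Bonferroni post hoc group comparisons
#'
#' All pairwise between-group contrasts on the per-subject condition means,
#' two-sample pooled-variance t tests with p multiplied by the number of
#' comparisons (capped at 1). Intended to follow a significant omnibus
#' group effect; this is pipeline policy, not enforced here.
#'
#' @param table property table (see [mixedRmAnova()]).
#' @return data.frame: groupA, groupB, meanDiff, t, df, p, pAdj.
#' @export
bonferroniPosthoc <- function(table) {
  .checkPropertyTable(table)
  w <- .wideTable(table)
  means <- rowMeans(w$Y)
  gl <- levels(w$group)
  if (length(gl) < 2) stop("need at least 2 groups")
  pairs <- utils::combn(gl, 2)
  out <- apply(pairs, 2, function(pr) {
    a <- means[w$group == pr[1]]; b <- means[w$group == pr[2]]
    tt <- stats::t.test(a, b, var.equal = TRUE)
    data.frame(groupA = pr[1], groupB = pr[2],
               meanDiff = mean(a) - mean(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, out)
  out$pAdj <- pmin(1, out$p * ncol(pairs))
  out
}

#' Simple effects of condition within each group
#'
#' Per-group paired t test of emotional vs neutral with Bonferroni
#' adjustment over the groups. Groups with fewer than 2 subjects are
#' skipped with a warning.
#'
#' @param table property table with conditions neutral and emotional.
#' @return data.frame: group, n, meanDiff (emotional - neutral), t, df, p,
#'   pAdj.
#' @export
simpleEffects <- function(table) {
  .checkPropertyTable(table)
  w <- .wideTable(table)
  if (!all(c("neutral", "emotional") %in% w$conditions))
    stop("simple effects expect conditions 'neutral' and 'emotional'")
  gl <- levels(w$group)
  rows <- list()
  for (g in gl) {
    sel <- w$group == g
    if (sum(sel) < 2) {
      warning("group ", g, " has fewer than 2 subjects; skipped")
      next
    }
    d <- w$Y[sel, "emotional"] - w$Y[sel, "neutral"]
    tt <- stats::t.test(d)
    rows[[g]] <- data.frame(group = g, n = sum(sel), meanDiff = mean(d),
                            t = unname(tt$statistic),
                            df = unname(tt$parameter), p = tt$p.value)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$pAdj <- pmin(1, out$p * length(gl))
  out
}

.plvUpper <- function(mats) {
  ch <- rownames(mats[[1]]@plv)
  for (m in mats)
    if (!identical(rownames(m@plv), ch))
      stop("PLV matrices have mismatched channels")
  ut <- which(upper.tri(mats[[1]]@plv), arr.ind = TRUE)
  V <- t(vapply(mats, function(m) m@plv[upper.tri(m@plv)],
                numeric(nrow(ut))))
  list(V = V, chA = ch[ut[, 1]], chB = ch[ut[, 2]])
}

#' Edge-wise PLV contrast
#'
#' Per-edge paired (or two-sample pooled-variance) t test between two sets
#' of PLV matrices, with significance masks at p < alpha uncorrected and
#' p < alpha / m Bonferroni (m = number of electrode pairs). The direction
#' is the sign of the mean difference a - b (increase when positive).
#'
#' @param a,b lists of [PLVMatrix-class] (paired: equal length, matching
#'   subject order).
#' @param paired paired subjects (TRUE) or independent samples (FALSE).
#' @param alpha nominal significance level.
#' @return an [EdgeComparisonResult-class].
#' @export
edgewiseContrast <- function(a, b, paired = TRUE, alpha = 0.05) {
  if (!length(a) || !length(b)) stop("both PLV sets must be non-empty")
  if (paired && length(a) != length(b))
    stop("paired contrast requires equal-length, subject-matched sets")
  ua <- .plvUpper(a); ub <- .plvUpper(b)
  if (!identical(ua$chA, ub$chA)) stop("channel sets differ between a and b")
  m <- ncol(ua$V)
  if (paired) {
    n <- nrow(ua$V)
    if (n < 2) stop("paired contrast needs >= 2 subjects")
    D <- ua$V - ub$V
    mu <- colMeans(D)
    sdv <- apply(D, 2, stats::sd)
    t <- mu / (sdv / sqrt(n))
    df <- n - 1
  } else {
    n1 <- nrow(ua$V); n2 <- nrow(ub$V)
    if (n1 < 2 || n2 < 2) stop("two-sample contrast needs >= 2 subjects per set")
    mu <- colMeans(ua$V) - colMeans(ub$V)
    v1 <- apply(ua$V, 2, stats::var); v2 <- apply(ub$V, 2, stats::var)
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    t <- mu / sqrt(sp * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  t[!is.finite(t)] <- 0
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  tb <- data.frame(chA = ua$chA, chB = ua$chB, t = t, p = p,
                   direction = ifelse(mu >= 0, "increase", "decrease"),
                   sigUncorrected = p < alpha,
                   sigBonferroni = p < alpha / m)
  new("EdgeComparisonResult", table = tb, alpha = alpha, m = as.integer(m),
      paired = paired)
}

#' Demographics comparison utility
#'
#' Thin helper mirroring the usual patient-table statistics: Welch t test
#' for continuous variables and a chi-square test for categorical counts
#' between two groups.
#'
#' @param continuousA,continuousB numeric vectors (e.g. ages) for the two
#'   groups, or NULL.
#' @param countsA,countsB integer count vectors over the same categories
#'   (e.g. male/female), or NULL.
#' @return data.frame of variable, statistic, p.
#' @export
compareDemographics <- function(continuousA = NULL, continuousB = NULL,
                                countsA = NULL, countsB = NULL) {
  rows <- list()
  if (!is.null(continuousA)) {
    tt <- stats::t.test(continuousA, continuousB)
    rows$cont <- data.frame(variable = "continuous",
                            statistic = unname(tt$statistic), p = tt$p.value)
  }
  if (!is.null(countsA)) {
    ct <- suppressWarnings(stats::chisq.test(rbind(countsA, countsB)))
    rows$cat <- data.frame(variable = "categorical",
                           statistic = unname(ct$statistic), p = ct$p.value)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
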