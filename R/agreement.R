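# Method-agreement statistics: ICC(2,1), Bland-Altman, Lin's concordance
# with the precision/accuracy split, the staged concordance workflow, the
# power-based minimum sample size, and lone-outlier discrepancy counts.

#' Two-way random-effects absolute-agreement ICC, single rater
#'
#' ICC(2,1) from the standard two-way ANOVA mean squares
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with an F-distribution 95% confidence interval (McGraw & Wong).  Absolute
#' agreement is the appropriate form when the question is whether raters'
#' measured angles are interchangeable, not merely correlated; it equals 1
#' exactly if and only if all raters report identical values.
#'
#' @param values n x k numeric matrix, cases in rows, raters in columns; no
#'   missing cells.
#' @param conf confidence level, default 0.95.
#' @return A list with `icc`, `ciLow`, `ciHigh`, `n`, `k`.
#' @examples
#' m <- matrix(rnorm(24), 6, 4) + 1:6
#' iccAbsoluteAgreement(m)
#' @export
iccAbsoluteAgreement <- function(values, conf = 0.95) {
  x <- as.matrix(values)
  if (anyNA(x)) stop("ICC input must have no missing cells", call. = FALSE)
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2L || k < 2L) stop("ICC needs at least 2 cases and 2 raters", call. = FALSE)
  if (all(x == x[, 1L])) {
    # raters agree exactly: agreement is perfect by definition; short-circuit
    # before the sums of squares so round-off cannot blur the exact 1
    if (stats::var(x[, 1L]) == 0)
      stop("between-case variance is zero; ICC is undefined", call. = FALSE)
    return(list(icc = 1, ciLow = 1, ciHigh = 1, n = n, k = k))
  }
  grand <- mean(x)
  rowm <- rowMeans(x)
  colm <- colMeans(x)
  SSR <- k * sum((rowm - grand)^2)
  SSC <- n * sum((colm - grand)^2)
  SST <- sum((x - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- max(SSE / ((n - 1) * (k - 1)), 0)  # guard tiny negative round-off
  if (MSR <= 0)
    stop("between-case variance is zero; ICC is undefined", call. = FALSE)
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))

  if (MSE == 0 && MSC == 0) {
    # raters identical: agreement is exact and so is the interval
    return(list(icc = 1, ciLow = 1, ciHigh = 1, n = n, k = k))
  }
  alpha <- 1 - conf
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  ciLow <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  ciHigh <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  list(icc = icc, ciLow = ciLow, ciHigh = ciHigh, n = n, k = k)
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' @param a,b paired numeric samples of equal length >= 3.
#' @return A list with `bias` (mean of `a - b`), `loaLow`, `loaHigh`
#'   (bias -/+ 1.96 x sample SD of the differences).
#' @export
blandAltman <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples differ in length", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loaLow = bias - 1.96 * s, loaHigh = bias + 1.96 * s)
}

#' Lin's concordance correlation coefficient with precision/accuracy split
#'
#' Lin's estimator with population (1/n) moments,
#' \deqn{\rho_c = \frac{2 s_{ab}}{s_a^2 + s_b^2 + (\bar a - \bar b)^2},}
#' factored as `ccc = r * c_b` into the Pearson precision component and the
#' bias-correction accuracy factor `c_b`.  The total discordance splits as
#' `1 - ccc = (1 - r) + r (1 - c_b)`, giving the lack-of-precision and
#' lack-of-accuracy percentages
#' `lopPct = 100 (1 - r) / (1 - ccc)` and
#' `loaPct = 100 r (1 - c_b) / (1 - ccc)`, which sum to 100 whenever
#' `ccc < 1`; for perfectly concordant samples both are reported as 0.
#'
#' @param a,b paired numeric samples, equal length >= 3, neither constant.
#' @return A list with `ccc`, `cB`, `lopPct`, `loaPct`.
#' @examples
#' linCCC(c(1, 2, 3), c(2, 3, 4))  # ccc = 4/7, all discordance from accuracy
#' @export
linCCC <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples differ in length", call. = FALSE)
  n <- length(a)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  ma <- mean(a)
  mb <- mean(b)
  sa2 <- mean((a - ma)^2)
  sb2 <- mean((b - mb)^2)
  if (sa2 == 0 || sb2 == 0)
    stop("constant sample: correlation undefined", call. = FALSE)
  sab <- mean((a - ma) * (b - mb))
  ccc <- 2 * sab / (sa2 + sb2 + (ma - mb)^2)
  r <- sab / sqrt(sa2 * sb2)
  cB <- ccc / r
  if (abs(1 - ccc) < 1e-15) {
    return(list(ccc = 1, cB = 1, lopPct = 0, loaPct = 0))
  }
  lop <- 100 * (1 - r) / (1 - ccc)
  loa <- 100 * r * (1 - cB) / (1 - ccc)
  list(ccc = ccc, cB = cB, lopPct = lop, loaPct = loa)
}

#' Staged concordance workflow between two measurement methods
#'
#' Reproduces the staged decision rule used to compare inclination methods:
#' \enumerate{
#'   \item Pearson correlation; if `r <= rGate` (default 0.7) the comparison
#'     stops with verdict `correlation-failed`.
#'   \item Bland-Altman; if `|bias| <= biasThreshold` (default 3 deg) and the
#'     limit-of-agreement half-width `1.96 sd(d) <= ciThreshold` (default
#'     5 deg), the methods are `concordant` and Lin's coefficient is *not*
#'     computed (its fields stay `NA`).
#'   \item Otherwise the Lin decomposition attributes the discordance:
#'     `discordant-precision-dominant` when `lopPct > 50`, else
#'     `discordant-accuracy-dominant`.
#' }
#'
#' @param a,b paired samples (e.g. rater-averaged inclinations of two
#'   methods), degrees.
#' @param rGate Pearson gate.
#' @param biasThreshold maximum acceptable mean bias, degrees.
#' @param ciThreshold maximum acceptable limit-of-agreement half-width,
#'   degrees.
#' @return An [AgreementReport-class].
#' @export
concordanceWorkflow <- function(a, b, rGate = 0.7, biasThreshold = 3,
                                ciThreshold = 5) {
  if (length(a) != length(b)) stop("paired samples differ in length", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 pairs", call. = FALSE)
  r <- stats::cor(a, b)
  if (!is.finite(r) || r <= rGate) {
    return(new("AgreementReport", r = r, biasDeg = NA_real_,
               loaLowDeg = NA_real_, loaHighDeg = NA_real_, ccc = NA_real_,
               cB = NA_real_, lopPct = NA_real_, loaPct = NA_real_,
               verdict = "correlation-failed"))
  }
  ba <- blandAltman(a, b)
  halfWidth <- (ba$loaHigh - ba$loaLow) / 2
  if (abs(ba$bias) <= biasThreshold && halfWidth <= ciThreshold) {
    return(new("AgreementReport", r = r, biasDeg = ba$bias,
               loaLowDeg = ba$loaLow, loaHighDeg = ba$loaHigh, ccc = NA_real_,
               cB = NA_real_, lopPct = NA_real_, loaPct = NA_real_,
               verdict = "concordant"))
  }
  lin <- linCCC(a, b)
  verdict <- if (lin$lopPct > 50) "discordant-precision-dominant"
             else "discordant-accuracy-dominant"
  new("AgreementReport", r = r, biasDeg = ba$bias, loaLowDeg = ba$loaLow,
      loaHighDeg = ba$loaHigh, ccc = lin$ccc, cB = lin$cB,
      lopPct = lin$lopPct, loaPct = lin$loaPct, verdict = verdict)
}

#' Minimum sample size, two-sample normal approximation
#'
#' \deqn{n = \lceil 2 (z_{1-\alpha/2} + z_{1-\beta})^2 (sd/\delta)^2 \rceil}
#' With the design parameters of the reference protocol (detectable
#' positioning error 5 mm, SD 10 mm, alpha 0.05, beta 0.20) this gives 63
#' cases per group.
#'
#' @param delta smallest effect of interest (same units as `sd`).
#' @param sd outcome standard deviation.
#' @param alpha two-sided type-I error rate.
#' @param beta type-II error rate (power = 1 - beta).
#' @return Integer minimum group size.
#' @examples
#' minSampleSize(5, 10)  # 63
#' @export
minSampleSize <- function(delta, sd, alpha = 0.05, beta = 0.20) {
  stopifnot(length(delta) == 1L, is.finite(delta), delta > 0,
            length(sd) == 1L, is.finite(sd), sd > 0,
            alpha > 0, alpha < 1, beta > 0, beta < 1)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(1 - beta)
  as.integer(ceiling(2 * z^2 * (sd / delta)^2))
}

#' Lone-outlier discrepancy counts between the three methods
#'
#' For each case, a method is flagged as the lone outlier when it differs by
#' at least `outlierThreshold` from *both* other methods while those two
#' agree within `agreeThreshold` of each other.  Also reports the pairwise
#' rates of cases with an absolute difference of at least
#' `outlierThreshold`, and the per-case maximum pairwise difference.
#'
#' @param yAxis,gtLine,bflf per-case (rater-averaged) inclinations, degrees.
#' @param outlierThreshold discrepancy threshold, degrees (default 5).
#' @param agreeThreshold agreement threshold for the two "other" methods,
#'   degrees (default 5).
#' @return A list with `flags` (data.frame of per-case logicals per method),
#'   `counts` (named integer), `pairwiseRatePct` (named percentages for
#'   `y_vs_gt`, `y_vs_bflf`, `gt_vs_bflf`), and `maxPairwiseDiff`.
#' @examples
#' discrepancyOutliers(c(0, 1), c(0, 1), c(9, 1.5))$counts  # bflf flagged once
#' @export
discrepancyOutliers <- function(yAxis, gtLine, bflf, outlierThreshold = 5,
                                agreeThreshold = 5) {
  n <- length(yAxis)
  if (length(gtLine) != n || length(bflf) != n)
    stop("per-method vectors differ in length", call. = FALSE)
  dYG <- abs(yAxis - gtLine)
  dYB <- abs(yAxis - bflf)
  dGB <- abs(gtLine - bflf)
  flagY <- dYG >= outlierThreshold & dYB >= outlierThreshold & dGB < agreeThreshold
  flagG <- dYG >= outlierThreshold & dGB >= outlierThreshold & dYB < agreeThreshold
  flagB <- dYB >= outlierThreshold & dGB >= outlierThreshold & dYG < agreeThreshold
  list(
    flags = data.frame(case = seq_len(n), y_axis = flagY, gt_line = flagG,
                       bflf = flagB),
    counts = c(y_axis = sum(flagY), gt_line = sum(flagG), bflf = sum(flagB)),
    pairwiseRatePct = c(y_vs_gt = 100 * mean(dYG >= outlierThreshold),
                        y_vs_bflf = 100 * mean(dYB >= outlierThreshold),
                        gt_vs_bflf = 100 * mean(dGB >= outlierThreshold)),
    maxPairwiseDiff = pmax(dYG, dYB, dGB))
}
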