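# Desk-scale replication of the multi-rater study design: generate a cohort,
# measure every case with four simulated raters and three transverse-axis
# methods, compute per-method summaries, per-method ICC on the pre-averaging
# per-rater values, between-method concordance on the rater-averaged values,
# and the lone-outlier discrepancy counts.

#' Construct a study configuration
#'
#' Defaults mirror the reference design: 82 cases, four raters, ground-truth
#' inclinations uniform on [-15, 21] degrees, a 10% worst-case medial-border
#' mixture (offset SDs 2 / 10 mm), the default rater noise model, correlation
#' gate 0.7, bias threshold 3 degrees, limit half-width threshold 5 degrees
#' and a 5-degree discrepancy threshold.
#'
#' @param nCases number of cases.
#' @param seed RNG seed for the whole study.
#' @param inclinationRange numeric(2) degrees.
#' @param offsetSdNormal,offsetSdWorst,worstCaseProb trigonum offset mixture.
#' @param noise a [RaterNoiseModel-class].
#' @param params template [ScapulaParams-class].
#' @param rGate,biasThreshold,ciThreshold,outlierThreshold thresholds of the
#'   concordance workflow and the outlier count.
#' @param outDir optional output directory; when set, [runStudy()] writes
#'   `measurements.csv`, `rater_averaged.csv`, `truth.csv` and
#'   `summary.json` there.
#' @return A validated [StudyConfig-class].
#' @export
studyConfig <- function(nCases = 82L, seed = 7L,
                        inclinationRange = c(-15, 21),
                        offsetSdNormal = 2, offsetSdWorst = 10,
                        worstCaseProb = 0.1,
                        noise = raterNoiseModel(),
                        params = scapulaParams(),
                        rGate = 0.7, biasThreshold = 3, ciThreshold = 5,
                        outlierThreshold = 5, outDir = character(0)) {
  new("StudyConfig", nCases = as.integer(nCases), seed = as.integer(seed),
      inclinationRange = as.numeric(inclinationRange),
      offsetSdNormal = offsetSdNormal, offsetSdWorst = offsetSdWorst,
      worstCaseProb = worstCaseProb, noise = noise, params = params,
      rGate = rGate, biasThreshold = biasThreshold,
      ciThreshold = ciThreshold, outlierThreshold = outlierThreshold,
      outDir = as.character(outDir))
}

# measure one case for all raters; shared mesh-level geometry computed once.
# The Y-axis method is fully automated: it reads only the mesh and the shared
# (true) glenoid center, so its value is identical across raters.
.measureStudyCase <- function(cs, raterLms) {
  mesh <- cs@mesh
  trueLm <- cs@trueLandmarks
  pl <- frontalPlane(mesh)
  sph <- fitSphere(mesh@vertices[mesh@labels == "glenoid", , drop = FALSE])
  bnd <- spineBodyBoundary(mesh)
  bndLine <- fitLine(bnd)
  bndCtr <- colMeans(bnd)

  glAxisAt <- function(ctr) {
    d <- sph@center - ctr
    new("Axis3", point = ctr, direction = .unit(d))
  }
  yAxisAt <- function(ctr) {
    d <- bndLine@direction
    if (sum(d * (ctr - bndCtr)) < 0) d <- -d
    new("Axis3", point = ctr, direction = d)
  }
  angleOf <- function(transverse, ctr, infAngle) {
    fr <- .frameFromPlane(pl, transverse@direction, infAngle, ctr)
    .inclinationAngle(transverse@direction, glAxisAt(ctr)@direction, fr)
  }

  trueCtr <- glenoidCenter(trueLm)
  yVal <- angleOf(yAxisAt(trueCtr), trueCtr, trueLm@inferiorAngle)

  perRater <- lapply(raterLms, function(lm) {
    ctr <- glenoidCenter(lm)
    c(y_axis = yVal,
      gt_line = angleOf(gtLine(ctr, lm@trigonum), ctr, lm@inferiorAngle),
      bflf = angleOf(bflfAxis(lm, ctr), ctr, lm@inferiorAngle))
  })
  do.call(rbind, perRater)  # raters x methods
}

#' Run a simulated multi-rater study
#'
#' Generates the cohort, measures every case with every rater and method,
#' then reproduces the reporting structure of the reference design: ICC per
#' method on the per-rater (pre-averaging) values; rater-averaged values for
#' all between-method comparisons (summary table, staged concordance per
#' method pair, lone-outlier counts).  Per-case measurement failures are
#' caught, counted and excluded; the pipeline continues.  Deterministic
#' given `config@seed`.
#'
#' @param config a [StudyConfig-class].
#' @return A [StudyResult-class].
#' @examples
#' \donttest{
#' res <- runStudy(studyConfig(nCases = 12, seed = 1))
#' res@summaryTable
#' }
#' @export
runStudy <- function(config) {
  stopifnot(is(config, "StudyConfig"))
  cohort <- generateCohort(config@nCases,
                           inclinationRange = config@inclinationRange,
                           offsetSdNormal = config@offsetSdNormal,
                           offsetSdWorst = config@offsetSdWorst,
                           worstCaseProb = config@worstCaseProb,
                           noise = config@noise, seed = config@seed,
                           params = config@params)
  nR <- config@noise@nRaters
  rows <- list()
  failures <- integer(0)
  perCase <- vector("list", config@nCases)
  for (i in seq_len(config@nCases)) {
    m <- tryCatch(.measureStudyCase(cohort$cases[[i]], cohort$raterLandmarks[[i]]),
                  error = function(e) {
                    warning("case ", i, " failed: ", conditionMessage(e),
                            call. = FALSE)
                    NULL
                  })
    if (is.null(m)) {
      failures <- c(failures, i)
      next
    }
    perCase[[i]] <- m
    for (r in seq_len(nR)) {
      rows[[length(rows) + 1L]] <- data.frame(
        case = i, rater = r, method = .METHODS,
        inclination_deg = as.numeric(m[r, .METHODS]))
    }
  }
  ok <- setdiff(seq_len(config@nCases), failures)
  if (length(ok) < 2L) stop("fewer than 2 cases measured successfully", call. = FALSE)
  measurements <- do.call(rbind, rows)

  avg <- t(vapply(perCase[ok], colMeans, numeric(3L)))
  raterAveraged <- data.frame(case = ok,
                              truth = cohort$truth$true_inclination_deg[ok],
                              y_axis = avg[, "y_axis"],
                              gt_line = avg[, "gt_line"],
                              bflf = avg[, "bflf"])

  summaryTable <- data.frame(
    statistic = c("Mean (deg)", "Minimum (deg)", "Maximum (deg)", "SD (deg)"),
    y_axis = c(mean(avg[, 1L]), min(avg[, 1L]), max(avg[, 1L]), stats::sd(avg[, 1L])),
    gt_line = c(mean(avg[, 2L]), min(avg[, 2L]), max(avg[, 2L]), stats::sd(avg[, 2L])),
    bflf = c(mean(avg[, 3L]), min(avg[, 3L]), max(avg[, 3L]), stats::sd(avg[, 3L])))

  icc <- lapply(stats::setNames(.METHODS, .METHODS), function(m) {
    mat <- t(vapply(perCase[ok], function(x) x[, m], numeric(nR)))
    iccAbsoluteAgreement(mat)
  })

  wf <- function(a, b) concordanceWorkflow(a, b, rGate = config@rGate,
                                           biasThreshold = config@biasThreshold,
                                           ciThreshold = config@ciThreshold)
  agreements <- list(
    y_axis_vs_gt_line = wf(raterAveraged$y_axis, raterAveraged$gt_line),
    bflf_vs_gt_line = wf(raterAveraged$bflf, raterAveraged$gt_line),
    y_axis_vs_bflf = wf(raterAveraged$y_axis, raterAveraged$bflf))

  outliers <- discrepancyOutliers(raterAveraged$y_axis, raterAveraged$gt_line,
                                  raterAveraged$bflf,
                                  outlierThreshold = config@outlierThreshold,
                                  agreeThreshold = config@outlierThreshold)

  result <- new("StudyResult", measurements = measurements,
                raterAveraged = raterAveraged, summaryTable = summaryTable,
                icc = icc, agreements = agreements, outliers = outliers,
                failures = failures, config = config)
  if (length(config@outDir)) .writeStudyOutputs(result, config@outDir)
  result
}

.writeStudyOutputs <- function(result, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  utils::write.csv(result@measurements, file.path(outDir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(result@raterAveraged, file.path(outDir, "rater_averaged.csv"),
                   row.names = FALSE)
  agr <- lapply(result@agreements, function(a) list(
    r = a@r, bias_deg = a@biasDeg, loa_low_deg = a@loaLowDeg,
    loa_high_deg = a@loaHighDeg, ccc = a@ccc, c_b = a@cB,
    lop_pct = a@lopPct, loa_pct = a@loaPct, verdict = a@verdict))
  jsonlite::write_json(
    list(summary = result@summaryTable, icc = result@icc, agreements = agr,
         outlier_counts = as.list(result@outliers$counts),
         pairwise_rate_pct = as.list(result@outliers$pairwiseRatePct),
         failed_cases = result@failures),
    file.path(outDir, "summary.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  invisible(outDir)
}

#' Human-readable study summary
#'
#' Formats the three reporting tables (per-method inclination summary,
#' per-method ICC with confidence intervals, per-pair concordance) plus the
#' lone-outlier paragraph values.  Angles are rounded to 0.1 degree,
#' coefficients to 0.01 and percentages to integers in the printed report
#' only; the tables in the returned list keep full precision.
#'
#' @param result a [StudyResult-class].
#' @param print print the formatted report (default TRUE).
#' @return Invisibly, a list with `inclination`, `icc` and `concordance`
#'   data.frames and the `outliers` list.
#' @export
summarizeStudy <- function(result, print = TRUE) {
  stopifnot(is(result, "StudyResult"))
  methodLabels <- c(y_axis = "Y-axis", gt_line = "Glenoid-Trigonum line",
                    bflf = "Best-fit line fossa")
  inclTab <- result@summaryTable
  iccTab <- data.frame(
    method = methodLabels[.METHODS],
    icc = vapply(result@icc[.METHODS], `[[`, 0, "icc"),
    ci_low = vapply(result@icc[.METHODS], `[[`, 0, "ciLow"),
    ci_high = vapply(result@icc[.METHODS], `[[`, 0, "ciHigh"),
    row.names = NULL)
  concTab <- do.call(rbind, lapply(names(result@agreements), function(nm) {
    a <- result@agreements[[nm]]
    data.frame(pair = nm, r = a@r, bias_deg = a@biasDeg,
               loa_low = a@loaLowDeg, loa_high = a@loaHighDeg,
               ccc = a@ccc, lop_pct = a@lopPct, loa_pct = a@loaPct,
               verdict = a@verdict)
  }))
  if (print) {
    rnd <- function(x, d) ifelse(is.na(x), NA, round(x, d))
    cat("Inclination by transverse-axis method (rater-averaged):\n")
    tab <- inclTab
    tab[, -1L] <- round(tab[, -1L], 1)
    print(tab, row.names = FALSE)
    cat("\nInterobserver ICC (per-rater values):\n")
    tab <- iccTab
    tab[, -1L] <- round(tab[, -1L], 2)
    print(tab, row.names = FALSE)
    cat("\nBetween-method concordance (rater-averaged values):\n")
    tab <- concTab
    tab$r <- rnd(tab$r, 2); tab$ccc <- rnd(tab$ccc, 2)
    tab$bias_deg <- rnd(tab$bias_deg, 1)
    tab$loa_low <- rnd(tab$loa_low, 1); tab$loa_high <- rnd(tab$loa_high, 1)
    tab$lop_pct <- rnd(tab$lop_pct, 0); tab$loa_pct <- rnd(tab$loa_pct, 0)
    print(tab, row.names = FALSE)
    cnt <- result@outliers$counts
    cat(sprintf(
      "\nLone-outlier cases (>= %g deg from both other methods): Y-axis %d, GT-line %d, BFLF %d\n",
      result@config@outlierThreshold, cnt[["y_axis"]], cnt[["gt_line"]],
      cnt[["bflf"]]))
    pr <- result@outliers$pairwiseRatePct
    cat(sprintf(
      "Pairwise discrepancy rates >= %g deg: Y vs GT %.0f%%, Y vs BFLF %.0f%%, GT vs BFLF %.0f%%\n",
      result@config@outlierThreshold, pr[["y_vs_gt"]], pr[["y_vs_bflf"]],
      pr[["gt_vs_bflf"]]))
  }
  invisible(list(inclination = inclTab, icc = iccTab, concordance = concTab,
                 outliers = result@outliers))
}
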