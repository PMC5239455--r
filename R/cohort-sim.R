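# Synthetic patient cohort generator.
#
# Each patient gets receptor abundances drawn from truncated normals, a
# HER2-HER3 dimer level from the mass-action network, a FRET efficiency that
# is a stated monotone (linear in the standardized log dimer level) map plus
# Gaussian measurement noise, clinico-pathological covariates drawn from
# marginals matching a breast-cancer TMA cohort, and a survival outcome from
# a proportional-hazards generative model:
#   event time  ~ Exp(baselineHazard * exp(beta * z)),  z = standardized
#                 log HER2-HER3 dimer level
#   censor time ~ Exp(censoringRate), administratively capped at followupCap.

#' Configuration of the synthetic cohort generator
#'
#' @param nPatients number of patients (>= 2; the reference imaging cohort
#'   is 131).
#' @param abundanceMeans named mean total abundance per receptor (defaults:
#'   abundant HER1 relative to HER2/HER3/HER4, the network regime in which
#'   dimer level decouples from expression).
#' @param abundanceCvs coefficient(s) of variation for abundances.
#' @param rates a [RateConstants-class] (default [detailedModelRates()]).
#' @param fretMean,fretPerSd,fretNoiseSd parameters of the FRET map:
#'   `fret_eff = fretMean + fretPerSd * z + N(0, fretNoiseSd)` in percent,
#'   with z the standardized log dimer level. Defaults put the cohort mean
#'   at 7.7% with values spanning roughly 0-20%.
#' @param baselineHazard baseline distant-metastasis hazard (events/year).
#' @param logHrPerDimerSd log hazard ratio per 1 SD of log dimer level.
#' @param censoringRate independent exponential censoring rate (events/year).
#' @param followupCap administrative censoring horizon (years). Defaults are
#'   set so the median event-or-censoring follow-up is about 7.6 years.
#' @param her2IhcCutpoints three strictly increasing thresholds on total
#'   HER2 mapping to IHC scores 0/1/2/3; scores 2-3 are "pos".
#' @param covariateMarginals named list of marginal probabilities for the
#'   categorical covariates (see defaults in the function signature).
#' @param seed integer seed.
#' @return a list of class `CohortSimConfig`.
#' @export
cohortSimConfig <- function(nPatients = 131L,
                            abundanceMeans = c(E1 = 100, E2 = 1, E3 = 1,
                                               E4 = 1),
                            abundanceCvs = 0.3,
                            rates = detailedModelRates(),
                            fretMean = 7.7, fretPerSd = 3.2,
                            fretNoiseSd = 1.5,
                            baselineHazard = 0.035,
                            logHrPerDimerSd = log(2),
                            censoringRate = 0.05,
                            followupCap = 15,
                            her2IhcCutpoints = c(0.9, 1.28, 1.6),
                            covariateMarginals = list(
                              erPos = 0.84, prPos = 0.59, sizeGt20 = 0.60,
                              grade = c(0.115, 0.345, 0.50, 0.04),
                              her3Loc = c(C = 0.50, `C+M` = 0.26,
                                          `M/M+C` = 0.20, `NA` = 0.04),
                              nodes = c(`0` = 0.39, `1-3` = 0.44,
                                        `>3` = 0.16, `NA` = 0.01),
                              her2NA = 0.11),
                            seed = 1L) {
  if (nPatients < 2) stop("nPatients must be at least 2")
  stopifnot(all(abundanceMeans > 0), all(abundanceCvs >= 0))
  if (baselineHazard <= 0 || censoringRate <= 0 || followupCap <= 0)
    stop("all rates must be positive")
  if (fretNoiseSd < 0) stop("fretNoiseSd must be non-negative")
  if (any(diff(her2IhcCutpoints) <= 0))
    stop("her2IhcCutpoints must be strictly increasing")
  structure(list(
    nPatients = as.integer(nPatients), abundanceMeans = abundanceMeans,
    abundanceCvs = abundanceCvs, rates = rates, fretMean = fretMean,
    fretPerSd = fretPerSd, fretNoiseSd = fretNoiseSd,
    baselineHazard = baselineHazard, logHrPerDimerSd = logHrPerDimerSd,
    censoringRate = censoringRate, followupCap = followupCap,
    her2IhcCutpoints = her2IhcCutpoints,
    covariateMarginals = covariateMarginals, seed = as.integer(seed)
  ), class = "CohortSimConfig")
}

#' Simulate a patient cohort
#'
#' Generates one row per patient with FRET efficiency, clinico-pathological
#' covariates, and a survival outcome. The dimer-to-hazard link works
#' through the latent standardized log HER2-HER3 dimer level `z_dimer`
#' (kept in the output so effect recovery can be checked against the truth);
#' `fret_eff` is a noisy monotone readout of the same latent level. HER2 IHC
#' status is cut from total HER2 abundance; all other covariates are drawn
#' independently from their stated marginals.
#'
#' @param config a [cohortSimConfig()].
#' @return a `data.frame` of class `CohortTable`; columns `patient_id`,
#'   `fret_eff` (percent), `her2_ihc` (factor neg/pos, NA), `her3_loc`
#'   (factor C, C+M, M/M+C, NA), `er`, `pr` (factor neg/pos), `size_gt20`,
#'   `grade3` (logical, NA possible), `nodes_grp` (factor 0, 1-3, >3, NA),
#'   `time_years`, `event` (0/1), plus latent truth columns `z_dimer`,
#'   `e23`, `total_her2`.
#' @export
simulateCohort <- function(config = cohortSimConfig()) {
  stopifnot(inherits(config, "CohortSimConfig"))
  if (config$baselineHazard <= 0 || config$censoringRate <= 0 ||
      config$followupCap <= 0)
    stop("all rates must be positive")
  set.seed(config$seed)
  n <- config$nPatients
  kd <- kdMatrix(config$rates)
  r <- nrow(kd)
  means <- rep_len(config$abundanceMeans, r)
  cvs <- rep_len(config$abundanceCvs, r)
  totals <- sapply(seq_len(r), function(i) {
    if (cvs[i] == 0) rep(means[i], n) else rtruncnorm(n, means[i],
                                                      cvs[i] * means[i])
  })
  free <- solveFreeMonomers(totals, kd)
  e23 <- free[, 2] * free[, 3] / kd[2, 3]
  logE <- log(pmax(e23, 1e-300))
  z <- if (stats::sd(logE) > 0) (logE - mean(logE)) / stats::sd(logE)
       else rep(0, n)
  fret <- config$fretMean + config$fretPerSd * z +
    stats::rnorm(n, 0, config$fretNoiseSd)

  cut3 <- config$her2IhcCutpoints
  her2Score <- findInterval(totals[, 2], cut3)          # 0..3
  m <- config$covariateMarginals
  her2 <- factor(ifelse(her2Score >= 2, "pos", "neg"), levels = c("neg", "pos"))
  her2[stats::runif(n) < m$her2NA] <- NA
  drawFac <- function(p) {
    lv <- names(p)
    x <- sample(lv, n, replace = TRUE, prob = p)
    x[x == "NA"] <- NA
    factor(x, levels = setdiff(lv, "NA"))
  }
  her3 <- drawFac(m$her3Loc)
  nodes <- drawFac(m$nodes)
  er <- factor(ifelse(stats::runif(n) < m$erPos, "pos", "neg"),
               levels = c("neg", "pos"))
  pr <- factor(ifelse(stats::runif(n) < m$prPos, "pos", "neg"),
               levels = c("neg", "pos"))
  sizeGt20 <- stats::runif(n) < m$sizeGt20
  gradeDraw <- sample(c("1", "2", "3", "NA"), n, replace = TRUE,
                      prob = m$grade)
  grade3 <- ifelse(gradeDraw == "NA", NA, gradeDraw == "3")

  hazard <- config$baselineHazard * exp(config$logHrPerDimerSd * z)
  tEvent <- stats::rexp(n, hazard)
  tCens <- pmin(stats::rexp(n, config$censoringRate), config$followupCap)
  time <- pmin(tEvent, tCens)
  event <- as.integer(tEvent <= tCens)

  out <- data.frame(
    patient_id = seq_len(n), fret_eff = fret, her2_ihc = her2,
    her3_loc = her3, er = er, pr = pr, size_gt20 = sizeGt20,
    grade3 = grade3, nodes_grp = nodes, time_years = time, event = event,
    z_dimer = z, e23 = e23, total_her2 = totals[, 2]
  )
  class(out) <- c("CohortTable", "data.frame")
  out
}

cohortCsvColumns <- c("patient_id", "fret_eff", "her2_ihc", "her3_loc",
                      "er", "pr", "size_gt20", "grade3", "nodes_grp",
                      "time_years", "event")

#' Read / write a cohort table as CSV
#'
#' The CSV schema is the documented 11-column header (`patient_id, fret_eff,
#' her2_ihc, her3_loc, er, pr, size_gt20, grade3, nodes_grp, time_years,
#' event`); latent truth columns are written only with `all = TRUE`.
#'
#' @param table a `CohortTable` data.frame.
#' @param path CSV file path.
#' @param all write latent truth columns too.
#' @return `readCohortTable` returns a validated `CohortTable`.
#' @export
writeCohortTable <- function(table, path, all = FALSE) {
  cols <- if (all) names(table) else
    intersect(cohortCsvColumns, names(table))
  utils::write.csv(table[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortTable
#' @export
readCohortTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cohortCsvColumns, names(df))
  if (length(missing))
    stop("cohort CSV ", path, " is missing columns: ",
         paste(missing, collapse = ", "))
  df$her2_ihc <- factor(df$her2_ihc, levels = c("neg", "pos"))
  df$her3_loc <- factor(df$her3_loc, levels = c("C", "C+M", "M/M+C"))
  df$er <- factor(df$er, levels = c("neg", "pos"))
  df$pr <- factor(df$pr, levels = c("neg", "pos"))
  df$nodes_grp <- factor(df$nodes_grp, levels = c("0", "1-3", ">3"))
  df$size_gt20 <- as.logical(df$size_gt20)
  df$grade3 <- as.logical(df$grade3)
  validateCohortTable(df)
  class(df) <- c("CohortTable", "data.frame")
  df
}

validateCohortTable <- function(df) {
  if (any(df$time_years < 0, na.rm = TRUE))
    stop("time_years must be non-negative")
  if (!all(df$event %in% c(0L, 1L)))
    stop("event must be 0/1")
  invisible(df)
}
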