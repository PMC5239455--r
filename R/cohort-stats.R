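#' ROC analysis with Youden-optimal threshold
#'
#' Evaluates every candidate cutpoint (the midpoints between consecutive
#' sorted unique scores) and returns the one maximizing the Youden index
#' J = sensitivity + specificity - 1 (equal weights). Ties are broken toward
#' the lower threshold. A case is called positive when its score is strictly
#' above the threshold. AUC is the Mann-Whitney statistic (ties count 1/2).
#'
#' @param scores numeric scores (e.g. FRET efficiency, percent).
#' @param labels binary outcome labels (0/1 or logical); both classes must
#'   be present.
#' @return list of class `ROCResult`: `thresholds`, `sensitivity`,
#'   `specificity`, `youden`, `youdenThreshold`, `auc`, `J`.
#' @export
youdenThreshold <- function(scores, labels) {
  labels <- as.integer(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary")
  if (length(unique(labels)) < 2L)
    stop("both outcome classes must be present")
  u <- sort(unique(scores))
  if (length(u) < 2L) stop("need at least 2 distinct scores")
  thr <- (u[-length(u)] + u[-1]) / 2
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  sens <- vapply(thr, function(t) mean(pos > t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg <= t), numeric(1))
  J <- sens + spec - 1
  best <- which(J == max(J))[1]          # ties -> lower threshold
  auc <- mean(vapply(pos, function(p)
    mean(p > neg) + 0.5 * mean(p == neg), numeric(1)))
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 youden = J, youdenThreshold = thr[best], auc = auc,
                 J = J[best]),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf("ROCResult: Youden threshold %.4g (J = %.3f), AUC = %.3f\n",
              x$youdenThreshold, x$J, x$auc))
  invisible(x)
}

#' Dichotomize FRET efficiency at a threshold
#'
#' Adds a `fret_high` flag, TRUE for `fret_eff` strictly above the
#' threshold (the boundary value itself is classified low).
#'
#' @param table a `CohortTable` data.frame with a `fret_eff` column.
#' @param threshold finite numeric cutpoint (same units as `fret_eff`).
#' @return the table with a `fret_high` column; counts of high/low in the
#'   `"counts"` attribute.
#' @export
dichotomizeFret <- function(table, threshold) {
  stopifnot(is.finite(threshold))
  table$fret_high <- table$fret_eff > threshold
  attr(table, "counts") <- c(high = sum(table$fret_high, na.rm = TRUE),
                             low = sum(!table$fret_high, na.rm = TRUE))
  table
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator, with administrative censoring applied at
#' `horizon` before estimation. Wraps `survival::survfit`.
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators.
#' @param horizon horizon in the time units of `times` (default `Inf`).
#' @return data.frame with columns `time`, `nRisk`, `nEvent`, `surv`
#'   (right-continuous step values; S(0) = 1 is included as the first row).
#' @export
kmEstimate <- function(times, events, horizon = Inf) {
  if (length(times) == 0L) stop("empty input")
  if (any(times < 0)) stop("times must be non-negative")
  cens <- censorAtHorizon(times, events, horizon)
  fit <- survival::survfit(survival::Surv(cens$time, cens$event) ~ 1)
  data.frame(time = c(0, fit$time), nRisk = c(length(times), fit$n.risk),
             nEvent = c(0, fit$n.event), surv = c(1, fit$surv))
}

#' Evaluate a Kaplan-Meier step function at given times
#'
#' @param km data.frame from [kmEstimate()].
#' @param t times at which to evaluate S(t).
#' @return numeric survival probabilities.
#' @export
kmSurvAt <- function(km, t) {
  vapply(t, function(tt) {
    i <- findInterval(tt, km$time)
    if (i < 1) 1 else km$surv[i]
  }, numeric(1))
}

censorAtHorizon <- function(times, events, horizon) {
  over <- times > horizon
  list(time = pmin(times, horizon),
       event = ifelse(over, 0L, as.integer(events)))
}

#' Cox proportional-hazards fit
#'
#' Fits a Cox model of `Surv(time_years, event)` on the given covariates
#' after administrative censoring at `horizon`, using the Efron tie
#' approximation, on complete cases for the listed covariates. Wald 95%
#' confidence intervals and p-values are reported per coefficient.
#' Monotone-likelihood / separation (diverging coefficient or enormous
#' standard error) is flagged as unreliable rather than hidden.
#'
#' @param table a `CohortTable` data.frame (columns `time_years`, `event`).
#' @param covariates character vector of covariate column names.
#' @param horizon censoring horizon in years (default `Inf`).
#' @return data.frame of class `CoxResult` with one row per coefficient:
#'   `term`, `logHR`, `HR`, `lower95`, `upper95`, `p`, `unreliable`;
#'   attributes `nUsed`, `nEvents`, `horizon`, `type`.
#' @export
coxFit <- function(table, covariates, horizon = Inf) {
  stopifnot(all(c("time_years", "event") %in% names(table)),
            all(covariates %in% names(table)))
  cc <- stats::complete.cases(table[, covariates, drop = FALSE]) &
    !is.na(table$time_years) & !is.na(table$event)
  dat <- table[cc, , drop = FALSE]
  cens <- censorAtHorizon(dat$time_years, dat$event, horizon)
  dat$.time <- cens$time; dat$.event <- cens$event
  if (sum(dat$.event) == 0L) stop("no events before the horizon")
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(covariates, collapse = " + ")))
  diverged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("coefficient may be infinite|Ran out of iterations",
                conditionMessage(w))) {
        diverged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  s <- summary(fit)
  co <- s$coefficients
  res <- data.frame(
    term = rownames(co),
    logHR = co[, "coef"],
    HR = exp(co[, "coef"]),
    lower95 = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
    upper95 = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
    p = co[, "Pr(>|z|)"],
    unreliable = diverged |
      abs(co[, "coef"]) > 15 | co[, "se(coef)"] > 100,
    row.names = NULL
  )
  attr(res, "nUsed") <- sum(cc)
  attr(res, "nEvents") <- sum(dat$.event)
  attr(res, "horizon") <- horizon
  attr(res, "type") <- if (length(covariates) > 1L) "multivariate"
                       else "univariate"
  class(res) <- c("CoxResult", "data.frame")
  res
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by direct hypergeometric enumeration: with margins
#' fixed, every table at least as improbable as the observed one (null
#' probability not exceeding the observed table's) contributes to p.
#'
#' @param m 2x2 matrix of non-negative integer counts with positive margins.
#' @return the two-sided p-value.
#' @export
fisherExact <- function(m) {
  m <- as.matrix(m)
  if (!identical(dim(m), c(2L, 2L))) stop("m must be a 2x2 table")
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("all margins must be positive")
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); N <- sum(m)
  a <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(a, c1, N - c1, r1)
  pObs <- stats::dhyper(m[1, 1], c1, N - c1, r1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

#' Configuration for the full cohort analysis
#'
#' @param horizons survival horizons (years) for the KM and Cox models.
#' @param rocHorizon horizon defining the ROC outcome label: event within
#'   `rocHorizon` years. Patients censored before the horizon without an
#'   event carry no label and are excluded from the ROC (they remain in all
#'   survival models).
#' @param threshold `"auto"` (Youden from the ROC) or a fixed numeric
#'   cutpoint on `fret_eff`.
#' @param covariates covariate columns for the multivariate model.
#' @return list of class `CohortAnalysisConfig`.
#' @export
cohortAnalysisConfig <- function(horizons = c(5, 10), rocHorizon = 10,
                                 threshold = "auto",
                                 covariates = c("fret_high", "her2_ihc",
                                                "her3_loc", "er", "pr",
                                                "size_gt20", "grade3",
                                                "nodes_grp")) {
  structure(list(horizons = horizons, rocHorizon = rocHorizon,
                 threshold = threshold, covariates = covariates),
            class = "CohortAnalysisConfig")
}

rocLabels <- function(table, horizon) {
  lab <- rep(NA_integer_, nrow(table))
  lab[table$time_years >= horizon] <- 0L
  lab[table$event == 1L & table$time_years <= horizon] <- 1L
  lab
}

#' Run the full cohort analysis
#'
#' Executes the complete sequence: ROC of FRET efficiency against
#' event-within-horizon outcome with Youden dichotomization (or a fixed
#' threshold), Kaplan-Meier curves by FRET group and by HER2 status at each
#' horizon, univariate Cox models per covariate, the full multivariate Cox
#' model on complete cases at each horizon, and Fisher exact association
#' tests of FRET group against each binary covariate (multi-level
#' covariates use the generalized exact network test).
#'
#' @param table a `CohortTable` data.frame.
#' @param config a [cohortAnalysisConfig()].
#' @return list of class `CohortReport`.
#' @export
runCohortAnalysis <- function(table, config = cohortAnalysisConfig()) {
  stopifnot(inherits(config, "CohortAnalysisConfig"))
  validateCohortTable(table)

  lab <- rocLabels(table, config$rocHorizon)
  roc <- NULL
  if (identical(config$threshold, "auto")) {
    roc <- youdenThreshold(table$fret_eff[!is.na(lab)], lab[!is.na(lab)])
    threshold <- roc$youdenThreshold
  } else {
    threshold <- config$threshold
  }
  table <- dichotomizeFret(table, threshold)

  km <- list()
  for (h in config$horizons) {
    km[[sprintf("fret_%gyr", h)]] <- lapply(
      split(table, table$fret_high),
      function(d) kmEstimate(d$time_years, d$event, h))
    if ("her2_ihc" %in% names(table))
      km[[sprintf("her2_%gyr", h)]] <- lapply(
        split(table, table$her2_ihc),
        function(d) if (nrow(d)) kmEstimate(d$time_years, d$event, h))
  }

  uni <- list(); multi <- list()
  for (h in config$horizons) {
    uni[[sprintf("%gyr", h)]] <- lapply(
      stats::setNames(config$covariates, config$covariates),
      function(cv) tryCatch(coxFit(table, cv, h), error = function(e)
        paste("not fitted:", conditionMessage(e))))
    multi[[sprintf("%gyr", h)]] <- tryCatch(
      coxFit(table, config$covariates, h),
      error = function(e) paste("not fitted:", conditionMessage(e)))
  }

  catCovs <- setdiff(config$covariates, "fret_high")
  fisher <- lapply(stats::setNames(catCovs, catCovs), function(cv) {
    tab <- base::table(high = table$fret_high, table[[cv]])
    if (any(dim(tab) < 2) || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      return(NA_real_)
    if (all(dim(tab) == 2L)) fisherExact(tab)
    else stats::fisher.test(tab)$p.value
  })

  completeN <- sum(stats::complete.cases(
    table[, config$covariates, drop = FALSE]))
  res <- list(roc = roc, threshold = threshold,
              counts = attr(table, "counts"), km = km, coxUnivariate = uni,
              coxMultivariate = multi, fisher = fisher,
              nTotal = nrow(table), nComplete = completeN, config = config)
  class(res) <- "CohortReport"
  res
}

#' @export
print.CohortReport <- function(x, ...) {
  cat("CohortReport\n")
  cat(sprintf("  FRET threshold: %.4g (%s); high/low = %d/%d\n",
              x$threshold,
              if (is.null(x$roc)) "fixed" else
                sprintf("Youden, AUC %.3f", x$roc$auc),
              x$counts["high"], x$counts["low"]))
  cat(sprintf("  patients: %d total, %d complete cases\n",
              x$nTotal, x$nComplete))
  for (h in names(x$coxMultivariate)) {
    cat(sprintf("  multivariate Cox, %s horizon:\n", h))
    m <- x$coxMultivariate[[h]]
    if (is.character(m)) { cat("   ", m, "\n"); next }
    i <- grep("fret_high", m$term)
    if (length(i))
      cat(sprintf("    FRET high vs low: HR %.2f (%.2f-%.2f), p = %.3g [n = %d]\n",
                  m$HR[i], m$lower95[i], m$upper95[i], m$p[i],
                  attr(m, "nUsed")))
  }
  invisible(x)
}
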