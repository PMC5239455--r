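test_that("Youden threshold separates a separable sample perfectly", {
  roc <- youdenThreshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(roc$youdenThreshold, 0.5)
  expect_equal(roc$J, 1)
  expect_equal(roc$auc, 1)
})

test_that("Youden threshold equals the exhaustive-scan maximizer", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(20:120, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- rnorm(n, mean = labels)          # informative
    if (s %% 3 == 0) scores <- sample(scores)  # sometimes null
    roc <- youdenThreshold(scores, labels)
    oracle <- oracleYouden(scores, labels)
    expect_identical(roc$youdenThreshold, oracle$threshold)
    expect_equal(roc$J, oracle$J, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(10)
  labels <- rbinom(200, 1, 0.5)
  scores <- rnorm(200, labels)
  roc <- youdenThreshold(scores, labels)
  ref <- pROC::auc(pROC::roc(labels, scores, quiet = TRUE))
  expect_equal(roc$auc, as.numeric(ref), tolerance = 1e-10)
})

test_that("permuted labels give a near-diagonal ROC", {
  set.seed(4)
  scores <- rnorm(400)
  labels <- rbinom(400, 1, 0.5)
  roc <- youdenThreshold(scores, labels)
  expect_lt(abs(roc$auc - 0.5), 0.08)
  expect_lt(roc$J, 0.2)
})

test_that("dichotomization is strict '>' at the boundary", {
  tab <- data.frame(fret_eff = c(8.55, 8.56, 8.57))
  d <- dichotomizeFret(tab, 8.56)
  expect_identical(d$fret_high, c(FALSE, FALSE, TRUE))
  expect_identical(unname(attr(d, "counts")), c(1L, 2L))
  low <- dichotomizeFret(data.frame(fret_eff = c(1, 2)), 5)
  expect_identical(unname(attr(low, "counts")["high"]), 0L)
})

test_that("Kaplan-Meier estimates match hand calculation and closed form", {
  km <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(kmSurvAt(km, 1), 2 / 3)
  expect_equal(kmSurvAt(km, 3), 0)
  expect_equal(kmSurvAt(km, 0), 1)

  allCens <- kmEstimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(allCens$surv == 1))

  # no censoring: product-limit reduces to the empirical survival function
  set.seed(2)
  t <- rexp(300, 0.5)
  km2 <- kmEstimate(t, rep(1, 300))
  expect_equal(kmSurvAt(km2, median(t) + 1e-9), mean(t > median(t) + 1e-9),
               tolerance = 1e-12)

  # exponential truth at t = 1/lambda
  set.seed(3)
  t3 <- rexp(10000, 0.4)
  km3 <- kmEstimate(t3, rep(1, 10000))
  expect_lt(abs(kmSurvAt(km3, 2.5) - exp(-1)), 0.02)
  expect_error(kmEstimate(numeric(0), numeric(0)), "empty")
})

test_that("Cox fit matches the grid-search partial-likelihood oracle", {
  d <- data.frame(time_years = c(1, 2, 3, 4, 5, 6),
                  event = c(1, 1, 0, 1, 1, 0),
                  x = c(1, 0, 1, 0, 1, 0))
  cf <- coxFit(d, "x")
  grid <- seq(-3, 3, by = 1e-4)
  pl <- vapply(grid, oraclePartialLik, numeric(1),
               time = d$time_years, event = d$event, x = d$x)
  expect_lt(abs(cf$logHR - grid[which.max(pl)]), 2e-4)
  expect_equal(cf$HR, exp(cf$logHR))
  expect_true(cf$lower95 < cf$HR && cf$HR < cf$upper95)
})

test_that("Cox symmetry: identical event patterns give logHR = 0", {
  d <- data.frame(time_years = rep(c(1, 2, 3, 4), 2),
                  event = rep(c(1, 0, 1, 0), 2),
                  x = rep(c(0, 1), each = 4))
  cf <- coxFit(d, "x")
  expect_lt(abs(cf$logHR), 1e-8)
})

test_that("Cox separation is flagged unreliable, zero events error", {
  sep <- data.frame(time_years = c(1, 2, 3, 10, 11, 12),
                    event = c(1, 1, 1, 0, 0, 0),
                    x = c(1, 1, 1, 0, 0, 0))
  cf <- expect_silent(coxFit(sep, "x"))
  expect_true(cf$unreliable)
  none <- data.frame(time_years = 1:4, event = rep(0, 4), x = c(0, 1, 0, 1))
  expect_error(coxFit(none, "x"), "no events")
})

test_that("horizon censoring is applied before model fitting", {
  d <- data.frame(time_years = c(2, 8, 12, 14), event = c(1, 1, 1, 0),
                  x = c(1, 0, 1, 0))
  cf <- coxFit(d, "x", horizon = 10)
  expect_equal(attr(cf, "nEvents"), 2L)   # the year-12 event is censored
  km <- kmEstimate(d$time_years, d$event, horizon = 10)
  expect_equal(max(km$time), 10)
})

test_that("Fisher exact matches enumeration and reference implementation", {
  expect_equal(fisherExact(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisherExact(matrix(c(2, 0, 0, 2), 2)), 1 / 3,
               tolerance = 1e-12)
  set.seed(9)
  for (i in 1:40) {
    m <- matrix(rpois(4, 4) + 1, 2, 2)   # positive margins, n <= ~40
    p <- fisherExact(m)
    expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-10)
    expect_equal(p, fisherExact(t(m)), tolerance = 1e-12)
  }
  expect_error(fisherExact(matrix(c(0, 0, 1, 2), 2)), "margins")
  expect_error(fisherExact(matrix(1:6, 2, 3)), "2x2")
})

test_that("full cohort analysis reports complete-case bookkeeping", {
  tab <- simulateCohort(cohortSimConfig(nPatients = 200, seed = 17))
  rep <- runCohortAnalysis(tab)
  expect_lt(rep$nComplete, rep$nTotal)   # NA-rich covariates by design
  m <- rep$coxMultivariate[["10yr"]]
  expect_s3_class(m, "CoxResult")
  expect_equal(attr(m, "nUsed"), rep$nComplete)
  expect_true(any(grepl("fret_high", m$term)))
  expect_true(all(c("fret_5yr", "fret_10yr") %in% names(rep$km)))
  expect_true(is.numeric(rep$fisher$her2_ihc))
})

test_that("ROC labelling excludes early-censored patients only from the ROC", {
  tab <- data.frame(fret_eff = c(1, 2, 9, 10, 5, 6),
                    time_years = c(12, 3, 2, 4, 11, 10),
                    event = c(0, 0, 1, 1, 1, 1))
  # patient 2: censored at 3 yr without event -> no 10-yr ROC label;
  # patient 5: event after the horizon -> labelled 0;
  # patient 6: event exactly at the horizon -> labelled 1
  lab <- dimerFLIM:::rocLabels(tab, 10)
  expect_identical(lab, c(0L, NA_integer_, 1L, 1L, 0L, 1L))
  rep <- runCohortAnalysis(cbind(tab,
                                 her2_ihc = factor(rep("neg", nrow(tab)),
                                                   levels = c("neg", "pos"))),
                           cohortAnalysisConfig(horizons = 10,
                                                covariates = "fret_high"))
  expect_true(is.finite(rep$threshold))
})
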