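test_that("mono-exponential MLE recovers noiseless model data exactly", {
  cfg <- decaySimConfig(photonsPerPixel = 1e6)
  h <- simulateDecayHistogram(cfg, list(c(2.0, 1.0)), noise = FALSE)
  fit <- fitMonoexponential(h, DT256)
  expect_lt(abs(lifetimes(fit) - 2.0) / 2.0, 1e-4)
  expect_true(fit@converged)
  expect_equal(ampFractions(fit), 1)
})

test_that("mono MLE equals direct likelihood maximization on noisy data", {
  # independent oracle: 1-D optimize of the multinomial log-likelihood
  for (s in 1:5) {
    set.seed(s)
    h <- rpois(256, 1e4 * oracleBinProbs(2.2))
    fit <- fitMonoexponential(h, DT256)
    nll <- function(tau) -sum(h * log(oracleBinProbs(tau)))
    opt <- optimize(nll, c(0.5, 10), tol = 1e-10)
    expect_lt(abs(lifetimes(fit) - opt$minimum), 1e-6)
  }
})

test_that("degenerate and under-exposed histograms are handled explicitly", {
  h <- integer(256); h[1] <- 500L
  fit <- fitMonoexponential(h, DT256)
  expect_false(fit@converged)
  expect_error(fitMonoexponential(integer(256), DT256), "insufficient photons")
  expect_error(fitMonoexponential(rep(1L, 50), DT256), "insufficient photons")
})

test_that("bi-exponential fit recovers a noiseless mixture", {
  cfg <- decaySimConfig(photonsPerPixel = 1e6)
  h <- simulateDecayHistogram(cfg, list(c(0.8, 0.3), c(2.6, 0.7)),
                              noise = FALSE)
  fit <- fitBiexponential(h, DT256)
  expect_length(lifetimes(fit), 2)
  expect_lt(abs(lifetimes(fit)[1] - 0.8) / 0.8, 0.01)
  expect_lt(abs(lifetimes(fit)[2] - 2.6) / 2.6, 0.01)
  expect_lt(max(abs(ampFractions(fit) - c(0.3, 0.7))), 0.02)
  expect_lt(abs(sum(ampFractions(fit)) - 1), 1e-9)
})

test_that("bi-exponential fit collapses gracefully in nested-model limits", {
  cfg <- decaySimConfig(photonsPerPixel = 1e6)
  mono <- simulateDecayHistogram(cfg, list(c(2.0, 1.0)), noise = FALSE)
  fit <- fitBiexponential(mono, DT256)
  expect_length(lifetimes(fit), 1)
  expect_true(fit@flags %in% c("fallback_mono", "degenerate"))
  expect_lt(abs(lifetimes(fit) - 2.0) / 2.0, 1e-3)
  # near-identical lifetimes are ill-conditioned: collapse, still converged
  close <- simulateDecayHistogram(cfg, list(c(2.0, 0.5), c(2.04, 0.5)),
                                  noise = FALSE)
  fit2 <- fitBiexponential(close, DT256)
  expect_length(lifetimes(fit2), 1)
  expect_true(fit2@converged)
})

test_that("bi-exponential Poisson fits recover the long component", {
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    p <- 0.3 * oracleBinProbs(0.8) + 0.7 * oracleBinProbs(2.6)
    h <- rpois(256, 1e5 * p)
    fit <- fitBiexponential(h, DT256)
    abs(lifetimes(fit)[length(lifetimes(fit))] - 2.6) / 2.6
  }, numeric(1))
  expect_lt(median(errs), 0.03)
})

test_that("lifetime maps honour intensity thresholds and binning", {
  cube <- smallCube(tau = 2.0, photons = 1e4, shape = c(8, 8), seed = 5)
  map <- buildLifetimeMap(cube, flimConfig(minPhotons = 100))
  expect_true(all(validMask(map)))
  expect_true(all(tauMap(map) > 1.9 & tauMap(map) < 2.1))

  # zero-photon border: border invalid, interior valid
  cnt <- counts(cube)
  cnt[1, , ] <- 0L; cnt[, 1, ] <- 0L
  map2 <- buildLifetimeMap(TCSPCCube(cnt, 12.5), flimConfig(minPhotons = 100))
  expect_false(any(validMask(map2)[1, ]))
  expect_true(all(validMask(map2)[2:8, 2:8]))
  expect_true(all(is.na(tauMap(map2)[1, ])))

  # 2x2 binning quadruples photons: pixel-tau dispersion drops ~2x
  cubeLow <- smallCube(tau = 2.0, photons = 1e3, shape = c(16, 16), seed = 6)
  sdU <- sd(tauMap(buildLifetimeMap(cubeLow, flimConfig(minPhotons = 50))))
  sdB <- sd(tauMap(buildLifetimeMap(cubeLow, flimConfig(minPhotons = 50,
                                                        binFactor = 2L))))
  expect_lt(abs(sdU / sdB - 2), 0.2 * 2)
})

test_that("empty maps raise 'no evaluable pixels'", {
  cube <- smallCube(photons = 10, shape = c(4, 4), seed = 2)
  expect_error(buildLifetimeMap(cube, flimConfig(minPhotons = 1e5)),
               "no evaluable pixels")
})

test_that("lifetime filter keeps exactly the in-window pixels", {
  tau <- matrix(c(0.5, 2.0, 6.0, 2.5), 2, 2)
  map <- new("LifetimeMap", tau = tau,
             photons = matrix(100, 2, 2),
             valid = matrix(TRUE, 2, 2), binWidth = DT256)
  f <- lifetimeFilter(map, c(1.0, 4.0))
  expect_identical(validMask(f), matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2))
  # idempotent, and never adds valid pixels
  expect_identical(validMask(lifetimeFilter(f, c(1.0, 4.0))), validMask(f))
  for (s in 1:10) {
    set.seed(s)
    m <- new("LifetimeMap", tau = matrix(runif(16, 0, 8), 4, 4),
             photons = matrix(100, 4, 4), valid = matrix(TRUE, 4, 4),
             binWidth = DT256)
    w <- sort(runif(2, 0, 8))
    f1 <- lifetimeFilter(m, w)
    expect_true(all(validMask(f1) <= validMask(m)))
    expect_identical(validMask(lifetimeFilter(f1, w)), validMask(f1))
  }
  expect_error(lifetimeFilter(map, c(4, 1)))
})

test_that("ROI mean lifetime is the photon-weighted mean of valid pixels", {
  map <- new("LifetimeMap", tau = matrix(c(2.0, 3.0), 1, 2),
             photons = matrix(c(100, 300), 1, 2),
             valid = matrix(TRUE, 1, 2), binWidth = DT256)
  expect_equal(roiMeanLifetime(map), 2.75)
  expect_equal(roiMeanLifetime(map, "uniform"), 2.5)
  one <- new("LifetimeMap", tau = matrix(c(2.2, NA), 1, 2),
             photons = matrix(c(50, 500), 1, 2),
             valid = matrix(c(TRUE, FALSE), 1, 2), binWidth = DT256)
  expect_equal(roiMeanLifetime(one), 2.2)
  none <- lifetimeFilter(map, c(9, 10))
  expect_error(roiMeanLifetime(none), "no valid pixels")
})

test_that("FRET efficiency formula and negative-E flagging", {
  expect_equal(as.numeric(fretEfficiency(2.0, 2.0)), 0)
  expect_equal(as.numeric(fretEfficiency(2.0, 1.8)), 0.10)
  eNeg <- fretEfficiency(2.0, 2.1)
  expect_equal(as.numeric(eNeg), -0.05)
  expect_true(attr(eNeg, "negative"))
  expect_error(fretEfficiency(-1, 2), "positive")
  expect_error(fretEfficiency(2, 0), "positive")
})

test_that("core-level FRET recovers construction and flags exclusions", {
  # null construction: no FRET -> E ~ 0
  cfg0 <- decaySimConfig(fretFraction = 0, photonsPerPixel = 1e4,
                         imageShape = c(16, 16), seed = 7)
  p0 <- simulateCorePair(cfg0)
  fr0 <- coreFret(p0$donor, p0$donorAcceptor)
  expect_lt(abs(fr0@fretEfficiency), 0.01)
  expect_equal(fr0@fretEfficiency, 1 - fr0@tauDA / fr0@tauD)

  # mixed population: mono fit estimates the apparent mixture lifetime
  cfgM <- decaySimConfig(tauDonor = 2.8, tauFret = 1.4, fretFraction = 0.2,
                         photonsPerPixel = 2e4, imageShape = c(16, 16),
                         seed = 8)
  pM <- simulateCorePair(cfgM)
  frM <- coreFret(pM$donor, pM$donorAcceptor)
  eOracle <- 1 - oracleApparentTau(c(2.8, 1.4), c(0.8, 0.2)) / 2.8
  expect_lt(abs(frM@fretEfficiency - eOracle), 0.01)

  # a window that excludes everything names the excluded core
  expect_error(coreFret(p0$donor, p0$donorAcceptor,
                        flimConfig(filterWindow = c(8, 10))),
               "core excluded")
})

test_that("estimated FRET is monotone and unbiased across the observed range", {
  ests <- vapply(c(0, 0.05, 0.10, 0.22), function(E) {
    cfg <- decaySimConfig(tauDonor = 2.8,
                          tauFret = if (E > 0) 2.8 * (1 - E) else 1.4,
                          fretFraction = as.numeric(E > 0),
                          photonsPerPixel = 1e4, imageShape = c(16, 16),
                          seed = 11)
    p <- simulateCorePair(cfg)
    coreFret(p$donor, p$donorAcceptor)@fretEfficiency
  }, numeric(1))
  expect_true(all(diff(ests) > 0))
  expect_lt(max(abs(ests - c(0, 0.05, 0.10, 0.22))), 0.01)
})
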