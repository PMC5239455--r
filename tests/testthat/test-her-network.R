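test_that("two-species equilibrium matches the closed form", {
  eq <- equilibriumState(c(0, 1, 1), isolatedDimerRates(1))
  expect_equal(dimerLevels(eq)[2, 3], (3 - sqrt(5)) / 2, tolerance = 1e-10)
  expect_equal(unname(freeMonomers(eq)[2]), (sqrt(5) - 1) / 2,
               tolerance = 1e-10)
  ode <- steadyStateODE(c(0, 1, 1), isolatedDimerRates(1))
  expect_equal(dimerLevels(ode)[2, 3], (3 - sqrt(5)) / 2, tolerance = 1e-8)
})

test_that("no-binding and frozen-dynamics limits are exact", {
  k <- rateConstants(matrix(Inf, 3, 3))
  eq <- equilibriumState(c(2, 5, 0.1), k)
  expect_equal(unname(freeMonomers(eq)), c(2, 5, 0.1))
  expect_true(all(dimerLevels(eq) == 0))
  ode <- steadyStateODE(c(2, 5, 0.1), k, kon = 0)
  expect_equal(unname(freeMonomers(ode)), c(2, 5, 0.1))
})

test_that("algebraic solver and ODE oracle agree on random instances", {
  set.seed(7)
  for (i in 1:20) {
    detailed <- i > 10
    r <- if (detailed) 4 else 3
    kd <- matrix(Inf, r, r)
    if (detailed) {
      kd[] <- exp(runif(r * r, log(0.2), log(5)))
      kd <- sqrt(kd * t(kd))
    } else {
      for (p in list(c(1, 2), c(1, 3), c(2, 3)))
        kd[p[1], p[2]] <- kd[p[2], p[1]] <- exp(runif(1, log(0.2), log(5)))
    }
    tot <- runif(r, 0.1, 5)
    a <- equilibriumState(tot, rateConstants(kd))
    b <- steadyStateODE(tot, rateConstants(kd))
    expect_lt(max(abs(freeMonomers(a) - freeMonomers(b)) /
                    pmax(freeMonomers(a), 1e-9)), 1e-6)
    expect_lt(max(abs(dimerLevels(a) - dimerLevels(b)) /
                    pmax(dimerLevels(a), 1e-6 * max(tot)^2)), 1e-6)
  }
})

test_that("conservation holds to 1e-8 relative in solved states", {
  set.seed(11)
  for (i in 1:20) {
    tot <- runif(4, 0, 10)   # include exact zeros sometimes
    if (i %% 4 == 0) tot[sample(4, 1)] <- 0
    eq <- equilibriumState(tot, detailedModelRates(exp(runif(1, -2, 2))))
    D <- dimerLevels(eq)
    bound <- rowSums(D) + diag(D)
    expect_lt(max(abs(freeMonomers(eq) + bound - tot) / pmax(tot, 1e-12)),
              1e-8)
  }
})

test_that("equilibrium responds monotonically to Kd and competition", {
  e23 <- function(kd23, tot1) {
    kd <- matrix(Inf, 3, 3)
    kd[1, 2] <- kd[2, 1] <- kd[1, 3] <- kd[3, 1] <- 1
    kd[2, 3] <- kd[3, 2] <- kd23
    dimerLevels(equilibriumState(c(tot1, 1, 1), rateConstants(kd)))[2, 3]
  }
  # weaker HER2-HER3 binding -> strictly less dimer
  kds <- c(0.1, 0.5, 1, 5, 20)
  vals <- vapply(kds, e23, numeric(1), tot1 = 1)
  expect_true(all(diff(vals) < 0))
  # more competitor HER1 -> weakly less dimer
  tots <- c(0, 1, 10, 100)
  vals2 <- vapply(tots, function(t1) e23(1, t1), numeric(1))
  expect_true(all(diff(vals2) <= 1e-12))
})

test_that("equilibrium is scale invariant and permutation symmetric", {
  set.seed(3)
  kd <- matrix(exp(runif(16, -1, 1)), 4, 4); kd <- sqrt(kd * t(kd))
  tot <- runif(4, 0.5, 3)
  eq <- equilibriumState(tot, rateConstants(kd))
  s <- 7.3
  eqS <- equilibriumState(s * tot, rateConstants(s * kd))
  expect_equal(freeMonomers(eqS), s * freeMonomers(eq), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(dimerLevels(eqS), s * dimerLevels(eq), tolerance = 1e-8,
               ignore_attr = TRUE)
  perm <- c(3, 1, 4, 2)
  eqP <- equilibriumState(tot[perm], rateConstants(kd[perm, perm]))
  expect_equal(unname(freeMonomers(eqP)), unname(freeMonomers(eq)[perm]),
               tolerance = 1e-8)
  expect_equal(unname(dimerLevels(eqP)), unname(dimerLevels(eq)[perm, perm]),
               tolerance = 1e-8)
})

test_that("population simulation handles degenerate and isolated regimes", {
  sim0 <- simulatePopulation(50, c(1, 1, 1), cvs = 0, isolatedDimerRates(),
                             seed = 1)
  expect_true(all(is.na(sim0$correlations$pearson)))
  expect_match(attr(sim0, "note"), "degenerate")

  iso <- simulatePopulation(400, c(1, 1, 1), cvs = 0.3,
                            isolatedDimerRates(), seed = 2)
  expect_gt(iso$correlations$pearson[1], 0.55)
  expect_gt(iso$correlations$pearson[2], 0.55)
  expect_equal(iso$nSolved, 400)
  expect_true(all(abs(iso$correlations$pearson) <= 1))
  # reproducibility
  iso2 <- simulatePopulation(400, c(1, 1, 1), cvs = 0.3,
                             isolatedDimerRates(), seed = 2)
  expect_identical(iso$table, iso2$table)
})

test_that("regime report reproduces the qualitative correlation structure", {
  rr <- regimeReport(n = 400, seed = 3)
  get <- function(name) rr[rr$regime == name, ]
  # abundant-competitor regimes decorrelate the dimer from both totals
  expect_lt(abs(get("regimeC")$rPearsonHER2), 0.3)
  expect_lt(abs(get("regimeC")$rPearsonHER3), 0.3)
  # overexpression couples the dimer to the scarce partner only
  expect_gt(get("her2Over")$rPearsonHER3, 0.9)
  expect_lt(abs(get("her2Over")$rPearsonHER2), 0.3)
  expect_gt(get("her3Over")$rPearsonHER2, 0.9)
  # the detailed model decorrelates less sharply than the isolated baseline
  # (the HER1 homodimer buffers free HER1), but competition still weakens
  # the coupling
  expect_lt(get("regimeCDetailed")$rPearsonHER2,
            get("isolated")$rPearsonHER2)
})

test_that("network inputs are validated", {
  expect_error(equilibriumState(c(-1, 1, 1), simpleModelRates()),
               "non-negative")
  expect_error(equilibriumState(c(1, 1), simpleModelRates()), "match")
  expect_error(rateConstants(matrix(c(1, 2, 3, 4), 2, 2)), "symmetric")
  expect_error(rateConstants(matrix(c(1, -2, -2, 1), 2, 2)), "positive")
  expect_error(simulatePopulation(1, c(1, 1, 1), 0.3, simpleModelRates()),
               "n >= 2")
})
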