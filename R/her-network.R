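# Mass-action dimerization equilibrium of the HER/ErbB receptor network.
#
# Receptors E1..Er bind pairwise: Ei + Ej <-> Eij with dissociation constant
# Kd[i,j] (Inf disables the pair). At equilibrium
#     [Eij] Kd[i,j] = free_i free_j          (i != j)
#     [Eii] Kd[i,i] = free_i^2               (statistical-factor convention)
# and conservation per receptor
#     free_i + sum_{j!=i} [Eij] + 2 [Eii] = total_i.
# Substituting the equilibrium relations reduces the system to the free
# monomer concentrations:
#     free_i (1 + sum_{j!=i} free_j/Kd[i,j] + 2 free_i/Kd[i,i]) = total_i.

#' Construct a RateConstants object
#'
#' @param kd symmetric square matrix of dissociation constants (> 0,
#'   `Inf` = pair disabled).
#' @return a [RateConstants-class].
#' @export
rateConstants <- function(kd) {
  kd <- as.matrix(kd)
  if (is.null(rownames(kd)))
    dimnames(kd) <- list(paste0("E", seq_len(nrow(kd))),
                         paste0("E", seq_len(nrow(kd))))
  new("RateConstants", kd = kd)
}

#' Standard HER network rate constant sets
#'
#' `simpleModelRates()` is the reduced 3-receptor model: HER2-HER3
#' dimerization plus competitive binding of both to HER1 (pairs E12, E13,
#' E23; no homodimers). `detailedModelRates()` is the 4-receptor model with
#' all 10 homo- and heterodimer pairs enabled. `isolatedDimerRates()` keeps
#' only the HER2-HER3 pair, the baseline in which dimer level tracks both
#' totals. All enabled pairs share a single normalized Kd by default.
#'
#' @param kd dissociation constant for every enabled pair (normalized
#'   concentration units).
#' @param disable optional list of `c(i, j)` pairs to disable (e.g.
#'   `list(c(3, 3))` to drop the kinase-dead HER3 homodimer).
#' @return a [RateConstants-class].
#' @export
simpleModelRates <- function(kd = 1) {
  m <- matrix(Inf, 3, 3)
  for (p in list(c(1, 2), c(1, 3), c(2, 3)))
    m[p[1], p[2]] <- m[p[2], p[1]] <- kd
  rateConstants(m)
}

#' @rdname simpleModelRates
#' @export
detailedModelRates <- function(kd = 1, disable = NULL) {
  m <- matrix(kd, 4, 4)
  for (p in disable) m[p[1], p[2]] <- m[p[2], p[1]] <- Inf
  rateConstants(m)
}

#' @rdname simpleModelRates
#' @export
isolatedDimerRates <- function(kd = 1) {
  m <- matrix(Inf, 3, 3)
  m[2, 3] <- m[3, 2] <- kd
  rateConstants(m)
}

# Vectorized damped fixed-point + Newton solver for the free-monomer system.
# totals: n x r matrix (rows = instances). Returns n x r matrix of free
# concentrations. invKd has 0 where a pair is disabled.
solveFreeMonomers <- function(totals, kd, tol = 1e-12, maxFix = 400L,
                              maxNewton = 50L) {
  n <- nrow(totals); r <- ncol(totals)
  invK <- 1 / kd
  invK[!is.finite(kd)] <- 0
  diagInv <- diag(invK)
  pos <- totals > 0
  f <- totals / 2
  resid <- function(f) {
    S <- f %*% invK                       # includes f_i/K_ii once
    f * (1 + S + sweep(f, 2, diagInv, `*`)) - totals
  }
  relResid <- function(f) {
    s <- pmax(totals, 1e-300)
    abs(resid(f)) / s
  }
  # damped fixed point: globally convergent for this monotone system
  for (it in seq_len(maxFix)) {
    S <- f %*% invK
    denom <- 1 + S + sweep(f, 2, diagInv, `*`)
    fn <- totals / denom
    f <- sqrt(pmax(f, 1e-300) * fn)
    f[!pos] <- 0
    if (it %% 25L == 0L && max(relResid(f)[pos]) < tol) break
  }
  # Newton polish per instance for quadratic convergence to full precision
  for (i in seq_len(n)) {
    act <- which(pos[i, ])
    if (!length(act)) next
    fi <- f[i, act]
    ti <- totals[i, act]
    K <- invK[act, act, drop = FALSE]
    dK <- diagInv[act]
    for (it in seq_len(maxNewton)) {
      S <- as.vector(K %*% fi)
      R <- fi * (1 + S + dK * fi) - ti
      if (max(abs(R) / ti) < tol) break
      J <- fi * K
      diag(J) <- 1 + S + 2 * dK * fi
      step <- tryCatch(solve(J, R), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      while (any(fi - lam * step <= 0) && lam > 1e-8) lam <- lam / 2
      fi <- fi - lam * step
    }
    f[i, act] <- fi
  }
  rr <- relResid(f)
  if (any(rr[pos] > 1e-8))
    stop(sprintf(
      "equilibrium solver failed to converge (max relative residual %.3g)",
      max(rr[pos])))
  f
}

dimersFromFree <- function(free, kd) {
  invK <- 1 / kd
  invK[!is.finite(kd)] <- 0
  D <- outer(free, free) * invK
  diag(D) <- free^2 * diag(invK)
  dimnames(D) <- dimnames(kd)
  D
}

#' Solve the dimerization network for its equilibrium state
#'
#' Computes free monomer and dimer concentrations satisfying mass-action
#' equilibrium and per-receptor conservation, by reducing the system to the
#' free concentrations and solving with a damped fixed-point iteration
#' followed by Newton refinement. Deterministic; residuals are verified to
#' 1e-8 relative by the result's validity method and the solver errors out
#' (never silently) if it cannot reach that.
#'
#' @param totals numeric vector of total receptor abundances (>= 0).
#' @param rates a [RateConstants-class] of matching dimension.
#' @return an [EquilibriumState-class].
#' @examples
#' k <- isolatedDimerRates(kd = 1)
#' eq <- equilibriumState(c(0, 1, 1), k)
#' dimerLevels(eq)[2, 3]   # (3 - sqrt(5)) / 2
#' @export
equilibriumState <- function(totals, rates) {
  stopifnot(is(rates, "RateConstants"))
  kd <- kdMatrix(rates)
  if (length(totals) != nrow(kd))
    stop("totals length must match the rate constant dimension")
  if (any(totals < 0)) stop("totals must be non-negative")
  f <- solveFreeMonomers(matrix(totals, nrow = 1), kd)[1, ]
  names(f) <- rownames(kd)
  new("EquilibriumState", free = f, dimers = dimersFromFree(f, kd),
      totals = as.numeric(totals), kd = kd)
}

#' Steady state by ODE integration (dynamic formulation)
#'
#' Integrates the mass-action kinetics
#' `d[Eij]/dt = kon * free_i * free_j - koff_ij * [Eij]` (with
#' `kon * free_i^2` for homodimers) from an all-monomer initial condition
#' until the maximum relative derivative falls below 1e-10, with
#' `koff_ij = kon * Kd_ij`. This dynamic route serves as an independent
#' cross-check of [equilibriumState()]: both must agree to high precision.
#'
#' @param totals numeric vector of total receptor abundances (>= 0).
#' @param rates a [RateConstants-class].
#' @param kon association rate constant shared by all enabled pairs.
#' @return an [EquilibriumState-class].
#' @export
steadyStateODE <- function(totals, rates, kon = 1) {
  stopifnot(is(rates, "RateConstants"), kon >= 0)
  kd <- kdMatrix(rates)
  r <- nrow(kd)
  if (length(totals) != r)
    stop("totals length must match the rate constant dimension")
  pairs <- which(upper.tri(kd, diag = TRUE) & is.finite(kd), arr.ind = TRUE)
  if (nrow(pairs) == 0L || kon == 0) {
    D <- matrix(0, r, r, dimnames = dimnames(kd))
    return(new("EquilibriumState", free = stats::setNames(as.numeric(totals),
                                                          rownames(kd)),
               dimers = D, totals = as.numeric(totals), kd = kd))
  }
  koff <- kon * kd[pairs]
  deriv <- function(t, y, parms) {
    bound <- numeric(r)
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      mult <- if (i == j) 2 else 1
      bound[i] <- bound[i] + mult * y[p]
      if (i != j) bound[j] <- bound[j] + y[p]
    }
    free <- totals - bound
    dy <- kon * free[pairs[, 1]] * free[pairs[, 2]] - koff * y
    list(dy)
  }
  y <- numeric(nrow(pairs))
  scale <- max(totals, 1)
  # integrate until the mass-action residual of every enabled pair meets the
  # equilibrium invariant (relative where the species is appreciable)
  eqResid <- function(y) {
    bound <- numeric(r)
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      bound[i] <- bound[i] + (if (i == j) 2 else 1) * y[p]
      if (i != j) bound[j] <- bound[j] + y[p]
    }
    free <- totals - bound
    lhs <- y * kd[pairs]
    rhs <- free[pairs[, 1]] * free[pairs[, 2]]
    max(abs(lhs - rhs) / pmax(lhs, rhs, 1e-5 * scale^2))
  }
  tEnd <- 10 / kon / max(min(kd[pairs]), 1e-6)
  for (chunk in 1:60) {
    sol <- deSolve::ode(y, c(0, tEnd), deriv, NULL, method = "lsoda",
                        rtol = 1e-13, atol = 1e-15 * scale)
    y <- sol[nrow(sol), -1]
    if (eqResid(y) < 5e-9) break
    tEnd <- tEnd * 4
    if (chunk == 60) stop("ODE integration did not reach steady state")
  }
  D <- matrix(0, r, r, dimnames = dimnames(kd))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    D[i, j] <- D[j, i] <- max(y[p], 0)
  }
  bound <- rowSums(D) + diag(D)
  new("EquilibriumState",
      free = stats::setNames(pmax(totals - bound, 0), rownames(kd)),
      dimers = D, totals = as.numeric(totals), kd = kd)
}

# truncated-normal draws by rejection (re-draw on non-positive values)
rtruncnorm <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Simulate a patient population through the dimerization network
#'
#' Draws per-patient receptor abundances from truncated normal distributions
#' (mean and coefficient of variation per receptor; negative draws are
#' rejected and re-drawn), solves the mass-action equilibrium for every
#' patient, and quantifies the Pearson and Spearman correlation of the
#' HER2-HER3 dimer level `[E23]` with total HER2 and total HER3.
#'
#' @param n number of patients (>= 2; 400 is the reference population size).
#' @param means numeric vector of mean abundances per receptor (> 0).
#' @param cvs coefficient(s) of variation, recycled across receptors
#'   (default 0.3). `cv = 0` gives a degenerate population; correlations are
#'   then reported as NA with an explanatory `"note"` attribute.
#' @param rates a [RateConstants-class].
#' @param seed integer seed.
#' @return list of class `PopulationSimResult`: `table` (per-patient totals
#'   and all dimer levels, E23 in column `e23`), `correlations` (data.frame
#'   of Pearson/Spearman r of E23 vs total HER2 / HER3), `nSolved`, `seed`.
#' @export
simulatePopulation <- function(n, means, cvs = 0.3, rates, seed = 1L) {
  stopifnot(is(rates, "RateConstants"), n >= 2, all(means > 0))
  kd <- kdMatrix(rates)
  r <- nrow(kd)
  if (length(means) != r)
    stop("means length must match the rate constant dimension")
  cvs <- rep_len(cvs, r)
  if (any(cvs < 0)) stop("cvs must be non-negative")
  set.seed(as.integer(seed))
  totals <- sapply(seq_len(r), function(i) {
    if (cvs[i] == 0) rep(means[i], n) else rtruncnorm(n, means[i],
                                                      cvs[i] * means[i])
  })
  colnames(totals) <- rownames(kd)
  free <- tryCatch(solveFreeMonomers(totals, kd), error = function(e) NULL)
  nFailed <- 0L
  if (is.null(free)) {
    # retry patient by patient so isolated failures are excluded, not fatal
    rows <- lapply(seq_len(n), function(i)
      tryCatch(solveFreeMonomers(totals[i, , drop = FALSE], kd),
               error = function(e) NULL))
    ok <- !vapply(rows, is.null, logical(1))
    nFailed <- sum(!ok)
    if (!any(ok)) stop("equilibrium solver failed for every patient")
    totals <- totals[ok, , drop = FALSE]
    free <- do.call(rbind, rows[ok])
    n <- nrow(totals)
  }
  invK23 <- if (is.finite(kd[2, 3])) 1 / kd[2, 3] else 0
  e23 <- free[, 2] * free[, 3] * invK23
  tab <- data.frame(patient = seq_len(n), totals, check.names = FALSE)
  tab$e23 <- e23
  corOr <- function(x, y, method) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = method)
  }
  correlations <- data.frame(
    against = c("totalHER2", "totalHER3"),
    pearson = c(corOr(e23, totals[, 2], "pearson"),
                corOr(e23, totals[, 3], "pearson")),
    spearman = c(corOr(e23, totals[, 2], "spearman"),
                 corOr(e23, totals[, 3], "spearman"))
  )
  res <- list(table = tab, correlations = correlations, nSolved = n,
              nFailed = nFailed, seed = as.integer(seed))
  if (any(is.na(correlations$pearson)))
    attr(res, "note") <- "degenerate population: correlation undefined"
  class(res) <- "PopulationSimResult"
  res
}

#' @export
print.PopulationSimResult <- function(x, ...) {
  cat(sprintf("PopulationSimResult: %d patients solved (seed %d)\n",
              x$nSolved, x$seed))
  print(x$correlations, row.names = FALSE)
  if (!is.null(attr(x, "note"))) cat(" note:", attr(x, "note"), "\n")
  invisible(x)
}

#' Reference abundance regimes of the HER network
#'
#' The named regimes contrast how the HER2-HER3 dimer level tracks total
#' HER2/HER3 abundance across expression scenarios: `regimeC`
#' (HER2 ~ HER3 << HER1) and `regimeD` (HER2 << HER3 << HER1) decorrelate
#' the dimer from both totals because the abundant competitor HER1 dominates
#' the binding balance; `her2Over` / `her3Over` restore a strong correlation
#' with the scarce partner only; `isolated` is the no-competition baseline
#' in which the dimer tracks both totals; `regimeCDetailed` is the abundant
#' HER1 scenario in the full 4-receptor model with all dimer pairs enabled.
#'
#' @param kd shared dissociation constant for enabled pairs.
#' @return named list of regimes, each with `means` and `rates`.
#' @export
herRegimes <- function(kd = 1) {
  list(
    regimeC = list(means = c(100, 1, 1), rates = simpleModelRates(kd)),
    regimeD = list(means = c(100, 0.1, 1), rates = simpleModelRates(kd)),
    her2Over = list(means = c(1, 100, 1), rates = simpleModelRates(kd)),
    her3Over = list(means = c(1, 1, 100), rates = simpleModelRates(kd)),
    isolated = list(means = c(1, 1, 1), rates = isolatedDimerRates(kd)),
    regimeCDetailed = list(means = c(100, 1, 1, 1),
                           rates = detailedModelRates(kd))
  )
}

#' Correlation report across abundance regimes
#'
#' Runs [simulatePopulation()] for each regime and tabulates the Pearson and
#' Spearman correlations of the HER2-HER3 dimer level with total HER2 and
#' total HER3.
#'
#' @param regimes named list as returned by [herRegimes()].
#' @param n patients per regime.
#' @param cvs coefficient(s) of variation passed through.
#' @param seed integer seed (one independent substream per regime).
#' @return data.frame with one row per regime.
#' @export
regimeReport <- function(regimes = herRegimes(), n = 400, cvs = 0.3,
                         seed = 1L) {
  rows <- lapply(seq_along(regimes), function(i) {
    rg <- regimes[[i]]
    sim <- simulatePopulation(n, rg$means, cvs, rg$rates,
                              seed = as.integer(seed) + i - 1L)
    data.frame(regime = names(regimes)[i],
               rPearsonHER2 = sim$correlations$pearson[1],
               rPearsonHER3 = sim$correlations$pearson[2],
               rSpearmanHER2 = sim$correlations$spearman[1],
               rSpearmanHER3 = sim$correlations$spearman[2],
               nSolved = sim$nSolved)
  })
  do.call(rbind, rows)
}
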