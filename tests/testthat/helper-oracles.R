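# Shared independent oracles and small fixture builders.

DT256 <- 12.5 / 256

# truncated-exponential bin probabilities, written independently of the
# package internals (direct edge differences)
oracleBinProbs <- function(tau, nBins = 256, T = 12.5) {
  e <- seq(0, T, length.out = nBins + 1)
  (exp(-e[-(nBins + 1)] / tau) - exp(-e[-1] / tau)) / (1 - exp(-T / tau))
}

# model mean (0-based) bin index of a truncated-exponential histogram
oracleMeanIndex <- function(tau, nBins = 256, T = 12.5) {
  sum((seq_len(nBins) - 1) * oracleBinProbs(tau, nBins, T))
}

# apparent mono-exponential lifetime of a lifetime mixture: the tau whose
# model mean arrival time matches the mixture's (the noiseless limit of a
# mono fit on mixed decays)
oracleApparentTau <- function(taus, weights, nBins = 256, T = 12.5) {
  target <- sum(weights * vapply(taus, oracleMeanIndex, numeric(1),
                                 nBins = nBins, T = T))
  uniroot(function(t) oracleMeanIndex(t, nBins, T) - target,
          c(0.05, 50), tol = 1e-12)$root
}

# exhaustive Youden scan, independent of youdenThreshold()
oracleYouden <- function(scores, labels) {
  u <- sort(unique(scores))
  thr <- (u[-length(u)] + u[-1]) / 2
  J <- vapply(thr, function(t)
    mean(scores[labels == 1] > t) + mean(scores[labels == 0] <= t) - 1,
    numeric(1))
  list(threshold = thr[which.max(J)], J = max(J))
}

# Cox partial log-likelihood for a single covariate, Breslow-free (no ties
# in the fixtures that use it)
oraclePartialLik <- function(beta, time, event, x) {
  s <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    s <- s + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  s
}

smallCube <- function(tau = 2.0, photons = 1e4, shape = c(8, 8),
                      nBins = 64, T = 12.5, seed = 1) {
  set.seed(seed)
  p <- oracleBinProbs(tau, nBins, T)
  arr <- array(rpois(prod(shape) * nBins, rep(photons * p, each = prod(shape))),
               dim = c(shape, nBins))
  TCSPCCube(arr, T)
}
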