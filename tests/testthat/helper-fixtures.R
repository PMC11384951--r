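## Shared fixture builders: everything is generated in code at test time.

## a small, fast cohort in which patients actually recover to SOFA <= 1
smallCohort <- function(seed = 1L, nTdm = 15L, nControl = 15L,
                        maxDays = 8L, missingRate = 0,
                        nContinuous = 8L, nDiscrete = 3L, nPathogen = 3L,
                        nInformative = 5L,
                        recoveryRateControl = 0.4, recoveryRateTdm = 0.55,
                        deathHazardScale = 0.002, ...) {
  generateCohort(cohortConfig(
    nTdm = nTdm, nControl = nControl,
    nContinuous = nContinuous, nDiscrete = nDiscrete,
    nPathogen = nPathogen, nInformative = nInformative,
    maxDays = maxDays, recoveryRateControl = recoveryRateControl,
    recoveryRateTdm = recoveryRateTdm, deathHazardScale = deathHazardScale,
    missingRate = missingRate, seed = seed, ...))
}

## planted linear regression data with patient grouping for GA tests
plantedRegression <- function(seed = 1L, nPatients = 60L, daysPer = 5L,
                              nInformative = 5L, nNoise = 20L, betaScale = 2,
                              noiseSd = 0.5) {
  set.seed(seed)
  n <- nPatients * daysPer
  p <- nInformative + nNoise
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  beta <- c(rep(betaScale, nInformative), rep(0, nNoise))
  list(x = x,
       y = as.numeric(x %*% beta) + rnorm(n, sd = noiseSd),
       groups = rep(sprintf("P%03d", seq_len(nPatients)), each = daysPer),
       informative = sprintf("f%02d", seq_len(nInformative)),
       noise = sprintf("f%02d", nInformative + seq_len(nNoise)))
}

## discretize a Gaussian density onto integer-width-independent bins
binnedGaussian <- function(mean, sd, breaks) {
  p <- diff(stats::pnorm(breaks, mean, sd))
  p / sum(p)
}
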