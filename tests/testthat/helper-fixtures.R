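## Shared fixtures, built in code. Small cohorts are cached per-session so
## several test files can reuse the same simulated data without re-running
## the generator.

.fixtureCache <- new.env(parent = emptyenv())

cachedCohort <- function(key, ...) {
  if (!exists(key, .fixtureCache)) {
    assign(key, simulateMethylationCohort(simulationConfig(...)), .fixtureCache)
  }
  get(key, .fixtureCache)
}

## a small, signal-bearing cohort used across modules
smallCohort <- function() {
  cachedCohort("small", nSamples = 120, nProbes = 300, nCausalProbes = 30,
               liabilityVarianceExplained = 0.4, seed = 101)
}

## a null cohort: no causal probes, no batch effects, equal composition
nullCohort <- function() {
  cachedCohort("null", nSamples = 150, nProbes = 300, nCausalProbes = 0,
               liabilityVarianceExplained = 0, batchSD = 0, seed = 202)
}

## shift one cell type's Dirichlet mean by `delta`, rescaling the others,
## keeping the total concentration fixed
shiftAlpha <- function(alpha, type, delta) {
  means <- alpha / sum(alpha)
  means[type] <- means[type] + delta
  means[-match(type, names(means))] <-
    means[-match(type, names(means))] *
    (1 - means[type]) / sum(means[-match(type, names(means))])
  means * sum(alpha)
}

## tiny deterministic beta matrix with dimnames
toyBeta <- function(nProbe = 5, nSample = 4, seed = 7) {
  set.seed(seed)
  matrix(runif(nProbe * nSample, 0.1, 0.9), nProbe, nSample,
         dimnames = list(sprintf("cg%03d", seq_len(nProbe)),
                         sprintf("s%02d", seq_len(nSample))))
}
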