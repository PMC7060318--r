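## A tiny standardized matrix with known algebra.
stdToy <- function(n = 8, m = 6, seed = 3) {
  set.seed(seed)
  b <- matrix(runif(m * n, 0.1, 0.9), m, n,
              dimnames = list(sprintf("cg%02d", 1:m), sprintf("s%02d", 1:n)))
  standardizeProbes(b)
}

test_that("single-probe ORM is the scaled outer product of that probe", {
  w <- c(-1.22474487, 0, 1.22474487)
  W <- matrix(w, 3, 1, dimnames = list(paste0("s", 1:3), "cg1"))
  A <- ormMatrix(computeORM(W))
  expect_equal(A, outer(w, w), tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("ORM diagonal averages one and duplicated probes change nothing", {
  W <- stdToy(10, 8)
  A <- computeORM(W)
  expect_equal(mean(diag(ormMatrix(A))), 1, tolerance = 1e-8)
  Wd <- cbind(stdMatrix(W), stdMatrix(W))
  colnames(Wd) <- paste0("p", seq_len(ncol(Wd)))
  expect_equal(ormMatrix(computeORM(Wd)), ormMatrix(A), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("REML matches a grid-search likelihood oracle on a small problem", {
  set.seed(12)
  n <- 8
  W <- stdToy(n, 6)
  A <- computeORM(W)
  y <- c(1, 0, 1, 1, 0, 0, 1, 0)
  d <- cohortDesign(y, NULL)
  fit <- remlFit(d, A)
  ## the grid likelihood evaluated at the fitted components reproduces the
  ## fitted log-likelihood (same objective, independent code path) ...
  atFit <- remlLogLikGrid(d, A, fit@sigmaO, fit@sigmaE)$logLik
  expect_equal(atFit, fit@logLik, tolerance = 1e-6)
  ## ... and no grid point beats the optimum
  grid <- remlLogLikGrid(d, A, seq(0.001, 0.6, length.out = 40),
                         seq(0.01, 0.6, length.out = 40))
  expect_gte(fit@logLik + 1e-6, max(grid$logLik, na.rm = TRUE))
})

test_that("a phenotype independent of the probes yields rho2 near zero", {
  sim <- nullCohort()
  W <- standardizeProbes(sim$mset)
  fit <- remlFit(sim$design, computeORM(W))
  expect_lt(rho2(fit), 2 * fit@se["rho2"])
  expect_gt(fit@pLRT, 0.01)
})

test_that("rho2 is recovered from a liability cohort at study scale", {
  h2 <- liabilityVarianceForObserved(0.3, 0.5)
  sim <- cachedCohort("recovery", nSamples = 500, nProbes = 2000,
                      nCausalProbes = 100, liabilityVarianceExplained = h2,
                      seed = 102)
  fit <- remlFit(sim$design, computeORM(standardizeProbes(sim$mset)))
  expect_true(fit@converged)
  expect_lt(abs(rho2(fit) - 0.3), 2 * fit@se["rho2"])
})

test_that("log-likelihood is non-decreasing across REML iterations", {
  sim <- smallCohort()
  fit <- remlFit(sim$design, computeORM(standardizeProbes(sim$mset)))
  expect_true(all(diff(fit@trace$logLik) >= -1e-9))
})

test_that("rho2 is invariant to a global rescaling of the probe matrix", {
  sim <- smallCohort()
  W <- standardizeProbes(sim$mset)
  f1 <- remlFit(sim$design, computeORM(stdMatrix(W)))
  ## scaling W scales A; REML rescales sigma_o accordingly, rho2 via A is
  ## scale-free because A is renormalized by construction of WW'/m
  A2 <- new("OmicsRelationshipMatrix", A = ormMatrix(computeORM(W)) * 1,
            m = ncol(stdMatrix(W)))
  f2 <- remlFit(sim$design, A2)
  expect_equal(rho2(f1), rho2(f2), tolerance = 1e-8)
  ## and multiplying every probe value by a constant leaves A unchanged
  expect_equal(ormMatrix(computeORM(3 * stdMatrix(W))) / 9,
               ormMatrix(computeORM(stdMatrix(W))), tolerance = 1e-10)
})

test_that("BLUP effects vanish when the omic variance is zero", {
  W <- stdToy(10, 5)
  d <- cohortDesign(rep(c(0, 1), 5), NULL)
  ve <- new("VarianceEstimate", sigmaO = 0, sigmaE = 0.25, rho2 = 0,
            se = c(sigmaO = 0, sigmaE = 0, rho2 = 0), logLik = 0, pLRT = 1,
            converged = TRUE, iterations = 1L,
            trace = data.frame(iter = 1L, logLik = 0), clamped = TRUE)
  u <- probeEffects(blupProbeEffects(d, W, ve))
  expect_equal(unname(u), rep(0, 5))
})

test_that("single-probe BLUP matches the scalar closed form", {
  set.seed(33)
  n <- 12
  b <- matrix(runif(n, 0.2, 0.8), 1, n,
              dimnames = list("cg1", paste0("s", 1:n)))
  W <- standardizeProbes(b)
  y <- rbinom(n, 1, 0.5); y[1] <- 1; y[2] <- 0
  d <- cohortDesign(y, NULL)
  so <- 0.1; se <- 0.2
  ve <- new("VarianceEstimate", sigmaO = so, sigmaE = se, rho2 = so / (so + se),
            se = c(sigmaO = 0, sigmaE = 0, rho2 = 0), logLik = 0, pLRT = 1,
            converged = TRUE, iterations = 1L,
            trace = data.frame(iter = 1L, logLik = 0), clamped = FALSE)
  u <- probeEffects(blupProbeEffects(d, W, ve))
  ## scalar oracle: V = so*ww' + se*I (m = 1), beta-hat by GLS, u = so w'V^-1 r
  w <- as.vector(stdMatrix(W))
  V <- so * outer(w, w) + diag(se, n)
  Vi <- solve(V)
  X <- matrix(1, n, 1)
  bh <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  uOracle <- so * as.numeric(t(w) %*% Vi %*% (y - X %*% bh))
  expect_equal(unname(u), uOracle, tolerance = 1e-10)
})

test_that("mixed-model equations identity holds on a small fit", {
  ## BLUP residual identity: u-hat = sigma_u^2 W' V^-1 (y - C beta-hat)
  ## implies the fitted random values g = W u-hat satisfy
  ## g = sigma_o A V^-1 (y - C beta-hat)
  W <- stdToy(10, 4, seed = 9)
  y <- rep(c(1, 0), 5)
  d <- cohortDesign(y, NULL)
  so <- 0.15; se <- 0.3
  ve <- new("VarianceEstimate", sigmaO = so, sigmaE = se, rho2 = so / (so + se),
            se = c(sigmaO = 0, sigmaE = 0, rho2 = 0), logLik = 0, pLRT = 1,
            converged = TRUE, iterations = 1L,
            trace = data.frame(iter = 1L, logLik = 0), clamped = FALSE)
  u <- probeEffects(blupProbeEffects(d, W, ve))
  Wm <- stdMatrix(W); m <- ncol(Wm)
  A <- ormMatrix(computeORM(W))
  V <- so * A + diag(se, nrow(Wm))
  Vi <- solve(V)
  X <- matrix(1, nrow(Wm), 1)
  bh <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  g <- as.vector(Wm %*% u)
  gOracle <- as.vector(so * A %*% Vi %*% (y - X %*% bh))
  expect_equal(g, gOracle, tolerance = 1e-10)
})

test_that("unconverged variance estimates are refused for BLUP", {
  W <- stdToy(8, 3)
  d <- cohortDesign(rep(c(0, 1), 4), NULL)
  ve <- new("VarianceEstimate", sigmaO = 0.1, sigmaE = 0.1, rho2 = 0.5,
            se = c(sigmaO = 0, sigmaE = 0, rho2 = 0), logLik = 0, pLRT = 1,
            converged = FALSE, iterations = 100L,
            trace = data.frame(), clamped = FALSE)
  expect_error(blupProbeEffects(d, W, ve), "converge")
})
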