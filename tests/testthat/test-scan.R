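## Small design with covariates for scan tests.
scanFixture <- function(n = 12, m = 5, seed = 14) {
  set.seed(seed)
  b <- matrix(runif(m * n, 0.1, 0.9), m, n,
              dimnames = list(sprintf("cg%02d", 1:m), sprintf("s%02d", 1:n)))
  W <- standardizeProbes(b)
  y <- rbinom(n, 1, 0.5); y[1:2] <- c(0, 1)
  d <- cohortDesign(y, data.frame(sex = rbinom(n, 1, 0.5), age = rnorm(n)))
  list(W = W, d = d)
}

fixedVE <- function(so, se) {
  new("VarianceEstimate", sigmaO = so, sigmaE = se, rho2 = so / (so + se),
      se = c(sigmaO = 0, sigmaE = 0, rho2 = 0), logLik = 0, pLRT = 1,
      converged = TRUE, iterations = 1L,
      trace = data.frame(iter = 1L, logLik = 0), clamped = FALSE)
}

test_that("least-squares scan matches lm() coefficient for coefficient", {
  fx <- scanFixture()
  res <- olsScan(fx$d, fx$W)
  Wm <- stdMatrix(fx$W)
  for (j in seq_len(ncol(Wm))) {
    dat <- data.frame(y = phenotype(fx$d),
                      covariateMatrix(fx$d)[, -1, drop = FALSE],
                      w = Wm[, j])
    fit <- summary(stats::lm(y ~ ., data = dat))$coefficients
    expect_equal(res$bStd[j], fit["w", 1], tolerance = 1e-10)
    expect_equal(res$seStd[j], fit["w", 2], tolerance = 1e-10)
    expect_equal(res$p[j], fit["w", 4], tolerance = 1e-10)
  }
})

test_that("a probe equal to the adjusted phenotype dominates the scan", {
  set.seed(15)
  n <- 60; m <- 20
  b <- matrix(runif(m * n, 0.1, 0.9), m, n,
              dimnames = list(sprintf("cg%02d", 1:m), sprintf("s%02d", 1:n)))
  y <- rbinom(n, 1, 0.5)
  d <- cohortDesign(y, data.frame(sex = rbinom(n, 1, 0.5)))
  r <- stats::resid(stats::lm(y ~ covariateMatrix(d) - 1))
  b[1, ] <- (r - min(r)) / (max(r) - min(r)) * 0.8 + 0.1  # affine copy of r
  W <- standardizeProbes(b)
  res <- olsScan(d, W)
  expect_equal(which.min(res$p), 1L)
  expect_lt(res$p[1], 1e-20)
})

test_that("collinear probes are flagged rather than fitted", {
  fx <- scanFixture()
  Wm <- stdMatrix(fx$W)
  sexStd <- scale(covariateMatrix(fx$d)[, "sex"])[, 1]
  Wm[, 2] <- sexStd / sqrt(mean(sexStd^2))   # exact copy of a covariate
  W2 <- new("StandardizedMethylation", W = Wm,
            probeMeans = fx$W@probeMeans, probeSDs = fx$W@probeSDs,
            nImputed = fx$W@nImputed)
  res <- olsScan(fx$d, W2)
  expect_true(is.na(res$p[2]))
  expect_false(anyNA(res$p[-2]))
})

test_that("mixed-model scan collapses to least squares when variance vanishes", {
  fx <- scanFixture(n = 40, m = 8, seed = 16)
  ols <- olsScan(fx$d, fx$W)
  moa <- moaScan(fx$d, fx$W, varianceEstimate = fixedVE(1e-14, 1))
  expect_equal(moa$bStd, ols$bStd, tolerance = 1e-6)
  ## the GLS standard error assumes the residual variance is known; after
  ## aligning the scale to each probe's residual-variance estimate the two
  ## scans coincide
  n <- length(phenotype(fx$d)); p <- ncol(covariateMatrix(fx$d))
  sigma2 <- (ols$seStd / moa$seStd)^2      # per-probe residual variance
  expect_equal(moa$seStd * sqrt(sigma2), ols$seStd, tolerance = 1e-8)
  expect_gt(min(sigma2), 0.05)             # sane variance scale
})

test_that("mixed-model scan matches a dense GLS oracle probe by probe", {
  fx <- scanFixture(n = 15, m = 4, seed = 18)
  W <- fx$W; d <- fx$d
  ve <- fixedVE(0.12, 0.3)
  res <- moaScan(d, W, varianceEstimate = ve)
  Wm <- stdMatrix(W); n <- nrow(Wm)
  V <- ve@sigmaO * tcrossprod(Wm) / ncol(Wm) + diag(ve@sigmaE, n)
  Vi <- solve(V)
  for (j in seq_len(ncol(Wm))) {
    X <- cbind(covariateMatrix(d), w = Wm[, j])
    XtViX <- t(X) %*% Vi %*% X
    coefs <- solve(XtViX, t(X) %*% Vi %*% phenotype(d))
    se <- sqrt(diag(solve(XtViX)))
    expect_equal(res$bStd[j], unname(coefs["w", 1]), tolerance = 1e-8)
    expect_equal(res$seStd[j], unname(se["w"]), tolerance = 1e-8)
  }
})

test_that("probe partition honours the threshold including its boundaries", {
  init <- data.frame(probe = paste0("cg", 1:100),
                     p = c(rep(0.001, 7), seq(0.02, 1, length.out = 93)))
  part <- partitionProbes(init, 0.01)
  expect_equal(sum(part$group == 1L), 7L)
  expect_equal(sum(part$group == 2L), 93L)
  expect_true(all(partitionProbes(init, 1)$group == 1L))
  expect_true(all(partitionProbes(init, 0)$group == 2L))
})

test_that("the exclusion window is open at 50 kb and local to the chromosome", {
  sim <- smallCohort()
  W <- standardizeProbes(sim$mset)
  ann <- probeAnnotation(sim$mset)
  ## move three probes to engineered positions on chromosome 21/22 labels
  annA <- ann
  iA <- 1L; iB <- 2L; iC <- nrow(ann)
  annA$chrom[c(iA, iB)] <- "21"; annA$chrom[iC] <- "22"
  annA$bp[iA] <- 1000000L
  annA$bp[iB] <- 1049999L          # strictly inside the 50 kb window
  part <- partitionProbes(olsScan(sim$design, W, annA), 0.25)
  scanNear <- momentScan(sim$design, W, annA, partition = part)

  annB <- annA; annB$bp[iB] <- 1050000L   # exactly 50 kb away: included
  scanEdge <- momentScan(sim$design, W, annB, partition = part)

  annC <- annA; annC$bp[iB] <- 1020000L   # still excluded
  scanIn <- momentScan(sim$design, W, annC, partition = part)

  pid <- annA$probe[iA]
  near <- scanNear[scanNear$probe == pid, c("bStd", "seStd")]
  edge <- scanEdge[scanEdge$probe == pid, c("bStd", "seStd")]
  inw <- scanIn[scanIn$probe == pid, c("bStd", "seStd")]
  ## moving an excluded neighbour within the window changes nothing
  expect_equal(near, inw, tolerance = 1e-12, ignore_attr = TRUE)
  ## crossing the boundary re-admits the neighbour to the random effects
  expect_false(isTRUE(all.equal(near$seStd, edge$seStd, tolerance = 1e-9)))
  ## probes on the other chromosome are untouched by any of this
  pidC <- annA$probe[iC]
  expect_equal(scanNear[scanNear$probe == pidC, c("bStd", "seStd", "p")],
               scanEdge[scanEdge$probe == pidC, c("bStd", "seStd", "p")],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the multi-component scan collapses to least squares on pure noise", {
  set.seed(19)
  n <- 80; m <- 30
  b <- matrix(runif(m * n, 0.2, 0.8), m, n,
              dimnames = list(sprintf("cg%02d", 1:m), sprintf("s%02d", 1:n)))
  ann <- data.frame(probe = rownames(b), chrom = "1",
                    bp = seq(1e6, by = 5e6, length.out = m), gene = NA)
  y <- rbinom(n, 1, 0.5)
  d <- cohortDesign(y, NULL)
  W <- standardizeProbes(b)
  ## vanishing random components: the GLS estimator is exactly OLS
  mom <- momentScan(d, W, ann, varComponents = c(1e-14, 1e-14, 1))
  ols <- olsScan(d, W, ann)
  expect_equal(mom$bStd, ols$bStd, tolerance = 1e-6)
  sigma2 <- (ols$seStd / mom$seStd)^2      # known- vs estimated-variance scale
  expect_equal(mom$seStd * sqrt(sigma2), ols$seStd, tolerance = 1e-8)
})

test_that("genomic inflation is one for uniform p and scales with the statistics", {
  m <- 2001
  pu <- (seq_len(m) - 0.5) / m
  expect_equal(genomicInflation(pu), 1, tolerance = 1e-3)
  chi <- qchisq(pu, 1, lower.tail = FALSE)
  pDouble <- pchisq(2 * chi, 1, lower.tail = FALSE)
  expect_equal(genomicInflation(pDouble), 2, tolerance = 1e-3)
  expect_error(genomicInflation(runif(10)), "at least 30")
})
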