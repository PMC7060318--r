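test_that("pooling two cohorts reproduces the worked two-decimal results", {
  ## per-cohort (b, se) pairs as printed for the chr10 probe, MOA then the
  ## multi-component method; inputs are 2-dp rounded, so pooled values carry
  ## a propagated rounding error of up to ~0.01
  moa <- ivwMeta(list(c(-1.55, 0.29), c(-1.17, 0.56)))
  expect_lt(abs(moa$b - (-1.47)), 0.005)
  expect_lt(abs(moa$se - 0.26), 0.005)
  mom <- ivwMeta(list(c(-1.09, 0.29), c(-0.77, 0.53)))
  expect_lt(abs(mom$b - (-1.01)), 0.01)
  expect_lt(abs(mom$se - 0.25), 0.005)
})

test_that("two identical cohorts pool to (b, se/sqrt(2))", {
  res <- ivwMeta(list(c(0.8, 0.2), c(0.8, 0.2)))
  expect_equal(res$b, 0.8)
  expect_equal(res$se, 0.2 / sqrt(2))
  expect_error(ivwMeta(list(c(1, 0), c(1, 0.1))), "positive")
  expect_error(ivwMeta(list(c(1, 0.1))), "at least 2")
})

test_that("pooling is order-invariant and matches a fixed-effect oracle", {
  set.seed(20)
  inputs <- replicate(4, c(rnorm(1), runif(1, 0.1, 0.5)), simplify = FALSE)
  a <- ivwMeta(inputs)
  b <- ivwMeta(rev(inputs))
  expect_equal(a$b, b$b, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-12)
  ## independent oracle: metafor's fixed-effect model
  bs <- vapply(inputs, `[`, 1, 1); ses <- vapply(inputs, `[`, 1, 2)
  or <- metafor::rma(yi = bs, sei = ses, method = "FE")
  expect_equal(a$b, as.numeric(or$beta), tolerance = 1e-8)
  expect_equal(a$se, as.numeric(or$se), tolerance = 1e-8)
})

test_that("table-level meta-analysis restricts to the shared probe set", {
  t1 <- data.frame(probe = c("a", "b", "c"), chrom = "1", bp = 1:3,
                   gene = NA, b = c(1, 2, 3), se = c(0.5, 0.5, 0.5))
  t2 <- data.frame(probe = c("b", "c", "d"), b = c(2.2, 2.8, 9),
                   se = c(0.5, 0.5, 0.5))
  res <- metaAnalyze(list(t1, t2))
  expect_equal(attr(res, "nCommon"), 2L)
  expect_setequal(res$probe, c("b", "c"))
  expect_equal(res$b[res$probe == "b"], (2 + 2.2) / 2)
})

test_that("multiple-testing cutoffs match the printed thresholds", {
  expect_equal(bonferroniThreshold(229071), 2.18e-7, tolerance = 0.005)
  expect_equal(bonferroniThreshold(263264), 1.9e-7, tolerance = 0.005)
  expect_equal(bonferroniThreshold(242205), 2.06e-7, tolerance = 0.005)
  expect_equal(bonferroniThreshold(12), 4.2e-3, tolerance = 0.005)
  expect_error(bonferroniThreshold(0), ">= 1")
})

test_that("the sign-concordance tail is exact", {
  expect_equal(signConcordanceBinomial(17, 21), 3.6e-3, tolerance = 0.02)
  expect_equal(signConcordanceBinomial(10, 10), 0.5^10)
  expect_equal(signConcordanceBinomial(8, 10), 56 / 1024)
  ## complement identity P(X >= k) + P(X <= k - 1) = 1
  for (k in c(0, 3, 11, 21))
    expect_equal(signConcordanceBinomial(k, 21) + pbinom(k - 1, 21, 0.5), 1,
                 tolerance = 1e-12)
  expect_error(signConcordanceBinomial(22, 21), "k <= n")
})

test_that("correlation pruning keeps the lowest-p member of correlated sets", {
  probes <- paste0("cg", 1:5)
  R <- diag(5); dimnames(R) <- list(probes, probes)
  R["cg1", "cg2"] <- R["cg2", "cg1"] <- 1       # duplicates
  R["cg3", "cg4"] <- R["cg4", "cg3"] <- 0.5     # r2 = 0.25
  rec <- data.frame(probe = probes, p = c(1e-6, 1e-8, 1e-4, 1e-3, 0.5))
  kept <- pruneProbesByR2(rec, R, r2Max = 0.1)
  expect_setequal(kept$probe, c("cg2", "cg3", "cg5"))
  ## invariant: no kept pair at or above the ceiling
  combs <- utils::combn(kept$probe, 2)
  expect_true(all(R[t(combs)]^2 < 0.1))
  ## r2Max = 1 keeps everything except exact duplicates
  keptAll <- pruneProbesByR2(rec, R, r2Max = 1)
  expect_setequal(keptAll$probe, c("cg2", "cg3", "cg4", "cg5"))
})

test_that("pruning matches brute-force greedy selection on random problems", {
  set.seed(21)
  for (rep in 1:5) {
    k <- 8
    X <- matrix(rnorm(40 * k), 40, k)
    X[, 2] <- X[, 1] + rnorm(40, 0, 0.1)
    R <- cor(X); probes <- paste0("cg", 1:k)
    dimnames(R) <- list(probes, probes)
    rec <- data.frame(probe = probes, p = runif(k))
    kept <- pruneProbesByR2(rec, R, r2Max = 0.2)
    ## oracle: explicit greedy walk written independently
    ord <- probes[order(rec$p, rec$probe)]
    sel <- character()
    for (pr in ord) if (!length(sel) || all(R[pr, sel]^2 < 0.2))
      sel <- c(sel, pr)
    expect_identical(kept$probe, sel)
  }
})

test_that("the empirical sign null concentrates at the exact binomial tail", {
  set.seed(22)
  m <- 400
  disc <- data.frame(probe = paste0("cg", 1:m), b = rnorm(m),
                     p = runif(m))
  repl <- data.frame(probe = paste0("cg", 1:m), b = rnorm(m))  # coin flips
  sel <- disc$probe[order(disc$p)][1:21]
  obs <- sum(sign(disc$b[match(sel, disc$probe)]) ==
               sign(repl$b[match(sel, repl$probe)]))
  res <- empiricalSignNull(disc, repl, nSelect = 21, reps = 4000, seed = 5,
                           selected = sel)
  expect_equal(res$observedConcordant, obs)
  exact <- signConcordanceBinomial(obs, 21)
  expect_equal(res$empiricalP, exact, tolerance = 0.25)
  ## determinism
  res2 <- empiricalSignNull(disc, repl, nSelect = 21, reps = 4000, seed = 5,
                            selected = sel)
  expect_identical(res2$empiricalP, res$empiricalP)
  ## degenerate: full concordance everywhere gives p = 1
  repl2 <- disc
  resAll <- empiricalSignNull(disc, repl2, nSelect = 10, reps = 100, seed = 1)
  expect_equal(resAll$empiricalP, 1)
  expect_error(empiricalSignNull(disc, repl, nSelect = m + 1), "exceeds")
})

test_that("effect concordance recovers identity, negation and a known rho", {
  rec <- data.frame(probe = paste0("cg", 1:50), b = rnorm(50),
                    p = runif(50, 0, 1e-5))
  expect_equal(effectConcordance(rec, rec)$r, 1, tolerance = 1e-12)
  neg <- rec; neg$b <- -neg$b
  expect_equal(effectConcordance(rec, neg)$r, -1, tolerance = 1e-12)
  set.seed(23)
  z <- MASS::mvrnorm(50, c(0, 0), matrix(c(1, 0.8, 0.8, 1), 2))
  a <- data.frame(probe = rec$probe, b = z[, 1], p = rec$p)
  b <- data.frame(probe = rec$probe, b = z[, 2], p = rec$p)
  expect_equal(effectConcordance(a, b)$r, 0.8, tolerance = 0.2)
  expect_error(effectConcordance(rec[1:2, ], rec), "fewer than 3")
})

test_that("replication power is monotone with the right fixed points", {
  seModel <- function(n) 2 / sqrt(n)
  pw <- replicationPower(0.5, seModel, alpha = 0.05)
  expect_true(all(diff(pw$power) >= 0))
  ## |b|/se(n) = z_alpha exactly gives power 1/2
  nStar <- (qnorm(0.95) * 2 / 0.5)^2
  pwStar <- replicationPower(0.5, seModel, alpha = 0.05, nGrid = nStar)
  expect_equal(pwStar$power, 0.5, tolerance = 1e-10)
  expect_warning(pw0 <- replicationPower(0, seModel, alpha = 0.05), "zero")
  expect_true(all(pw0$power == 0.05))
  expect_true(is.finite(attr(pw, "nRequired")))
})
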