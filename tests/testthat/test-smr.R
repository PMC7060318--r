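test_that("Wald-ratio statistic has its null and worked values", {
  null <- smrTest(0.5, 0.05, 0, 0.03)
  expect_equal(null$bXy, 0)
  expect_equal(null$p, 1)
  ## strong instrument, weak outcome: T ~ 4 * 1e6 / (4 + 1e6)
  r <- smrTest(1000, 1, 2, 1)
  expect_equal(r$chisq, 4e6 / (4 + 1e6), tolerance = 1e-10)
  expect_equal(r$p, pchisq(3.99998, 1, lower.tail = FALSE), tolerance = 1e-4)
  expect_equal(r$bXy, 2 / 1000)
  expect_error(smrTest(0, 1, 1, 1), "zero instrument")
})

test_that("the SMR p-value is monotone in the outcome statistic", {
  zx <- 8
  ps <- vapply(seq(0.1, 6, length.out = 30), function(zy)
    smrTest(zx * 0.1, 0.1, zy * 0.1, 0.1)$p, 1)
  expect_true(all(diff(ps) < 0))
})

test_that("allele harmonization makes results strand-entry invariant", {
  trio <- simulateSummaryTrio(nSnps = 12, seed = 6)
  flipped <- trio$eqtl
  ix <- c(2, 5, 9)
  flipped$A1[ix] <- "G"; flipped$A2[ix] <- "A"
  flipped$b[ix] <- -flipped$b[ix]
  flipped$freq[ix] <- 1 - flipped$freq[ix]
  h1 <- harmonizeSummary(trio$mqtl, trio$eqtl)
  h2 <- harmonizeSummary(trio$mqtl, flipped)
  expect_equal(h2$outcome$b, h1$outcome$b, tolerance = 1e-12)
  p1 <- heidiTest(trio$mqtl, trio$eqtl, trio$panel)$p
  p2 <- heidiTest(trio$mqtl, flipped, trio$panel)$p
  expect_equal(p2, p1, tolerance = 1e-10)
  incompatible <- trio$eqtl
  incompatible$A1[1] <- "T"
  expect_warning(harmonizeSummary(trio$mqtl, incompatible), "incompatible")
})

test_that("instrument selection respects the threshold and tie-breaks", {
  ex <- data.frame(SNP = c("rs1", "rs2", "rs3"), A1 = "A", A2 = "G",
                   freq = 0.5, b = c(0.5, 0.4, 0.1),
                   se = 0.05, p = c(1e-9, 1e-9, 0.5), N = 1000,
                   bp = c(200, 100, 300))
  sel <- selectInstrument(ex)
  expect_equal(sel$status, "ok")
  expect_equal(sel$snp, "rs2")   # p tie broken by smaller bp
  weak <- ex; weak$p <- c(1e-7, 1e-6, 0.5)
  expect_equal(selectInstrument(weak)$status, "no-instrument")
  expect_error(selectInstrument(ex[0, ]), "empty")
})

test_that("the Wald ratio recovers the true effect under a shared causal variant", {
  hits <- 0; reps <- 60
  for (r in seq_len(reps)) {
    trio <- simulateSummaryTrio(nSnps = 20, bZx = 0.5, bXw = -0.4, seed = 3000 + r)
    h <- harmonizeSummary(trio$mqtl, trio$eqtl)
    inst <- selectInstrument(h$exposure)
    i <- match(inst$snp, h$exposure$SNP)
    s <- smrTest(h$exposure$b[i], h$exposure$se[i],
                 h$outcome$b[i], h$outcome$se[i])
    if (abs(s$bXy - (-0.4)) < 2 * s$se) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("identical exposure and outcome show no instrument heterogeneity", {
  trio <- simulateSummaryTrio(nSnps = 20, seed = 8)
  res <- heidiTest(trio$mqtl, trio$mqtl, trio$panel)
  expect_equal(res$status, "ok")
  expect_gt(res$p, 0.99)   # d_i identically zero
})

test_that("perfect proxies of the instrument leave the test unrunnable", {
  trio <- simulateSummaryTrio(nSnps = 6, seed = 9)
  R1 <- matrix(1, 6, 6, dimnames = list(trio$mqtl$SNP, trio$mqtl$SNP))
  res <- heidiTest(trio$mqtl, trio$eqtl, R1)
  expect_equal(res$status, "heidi-not-run")
  expect_true(is.na(res$p))
})

test_that("numerical and Monte-Carlo tails of the quadratic form agree", {
  trio <- simulateSummaryTrio(nSnps = 25, scenario = "linkage_two_causal",
                              seed = 10)
  a <- heidiTest(trio$mqtl, trio$eqtl, trio$panel, method = "imhof")
  b <- heidiTest(trio$mqtl, trio$eqtl, trio$panel, method = "montecarlo",
                 seed = 2)
  expect_equal(a$status, "ok")
  expect_lt(abs(a$p - b$p), 0.1 * max(a$p, 0.05))
})

test_that("linkage of two causal variants is flagged more often than chance", {
  rej <- 0; reps <- 40
  for (r in seq_len(reps)) {
    trio <- simulateSummaryTrio(nSnps = 20, scenario = "linkage_two_causal",
                                secondCausalOffset = 6, seed = 5000 + r)
    h <- heidiTest(trio$mqtl, trio$eqtl, trio$panel)
    if (h$status == "ok" && h$p < 0.05) rej <- rej + 1
  }
  ## one-sided binomial check against a 5% null rate
  expect_lt(pbinom(rej - 1, reps, 0.05, lower.tail = FALSE), 0.01)
})

test_that("gene filtering applies a strict cis-eQTL threshold", {
  sets <- list(g1 = data.frame(p = c(4e-8, 0.5)),
               g2 = data.frame(p = c(5e-8, 0.2)),
               g3 = data.frame(p = 1e-12))
  expect_setequal(filterGenesWithEqtl(sets), c("g1", "g3"))
  expect_identical(filterGenesWithEqtl(list()), character())
})

test_that("probe-gene-trait chaining windows genes and corrects for tests", {
  trio <- simulateSummaryTrio(nSnps = 20, seed = 11)
  eqtlSets <- setNames(rep(list(trio$eqtl), 13), paste0("gene", 1:13))
  geneBp <- setNames(c(rep(1e6, 12), 3.6e6), names(eqtlSets))
  res <- smrChain(trio$mqtl, eqtlSets, trio$gwas, ld = trio$panel,
                  probeBp = 1.03e6, geneBp = geneBp)
  expect_equal(attr(res, "nTests"), 12L)           # the 2.5-Mb-away gene is out
  expect_equal(attr(res, "bonferroni"), 0.05 / 12)
  expect_false(any(grepl("gene13", res$outcome)))
  expect_true("trait" %in% res$outcome)
  mToE <- res[res$exposure == "methylation" & grepl("expression", res$outcome), ]
  expect_true(all(mToE$status %in% c("ok", "heidi-not-run")))
})

test_that("a broken expression-trait link stays null while the upstream link fires", {
  set.seed(30)
  sig <- 0; nullRej <- 0; reps <- 30
  for (r in seq_len(reps)) {
    trio <- simulateSummaryTrio(nSnps = 20, bZx = 0.5, bXw = -0.4, bWy = 0,
                                seed = 7000 + r)
    h1 <- harmonizeSummary(trio$mqtl, trio$eqtl)
    i1 <- match(selectInstrument(h1$exposure)$snp, h1$exposure$SNP)
    s1 <- smrTest(h1$exposure$b[i1], h1$exposure$se[i1],
                  h1$outcome$b[i1], h1$outcome$se[i1])
    if (s1$p < 0.05) sig <- sig + 1
    h2 <- harmonizeSummary(trio$eqtl, trio$gwas)
    inst2 <- selectInstrument(h2$exposure)
    if (inst2$status != "ok") next   # weak eQTL instrument in this draw
    i2 <- match(inst2$snp, h2$exposure$SNP)
    s2 <- smrTest(h2$exposure$b[i2], h2$exposure$se[i2],
                  h2$outcome$b[i2], h2$outcome$se[i2])
    if (s2$p < 0.05) nullRej <- nullRej + 1
  }
  expect_gte(sig / reps, 0.9)               # methylation -> expression fires
  expect_lte(nullRej / reps, 0.2)           # expression -> trait stays near alpha
})
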