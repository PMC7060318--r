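## Fixed-effect inverse-variance meta-analysis across cohorts and the
## replication diagnostics used on cross-cohort summary statistics.

#' Inverse-variance-weighted fixed-effect meta-analysis
#'
#' Pools per-cohort effect estimates with weights 1/se^2, assuming
#' independence among cohorts. The pooled standard error is
#' (sum of weights)^(-1/2) and the p-value is two-sided normal.
#' Heterogeneity is summarized by Cochran's Q (reported, not modelled).
#'
#' @param inputs a list of length-2 numeric vectors c(b, se), or a
#'   data.frame/matrix with columns b and se (one row per cohort).
#' @return list with b, se, z, p, nCohorts, Q, pQ.
#' @examples
#' ivwMeta(list(c(-1.55, 0.29), c(-1.17, 0.56)))
#' @export
ivwMeta <- function(inputs) {
  if (is.data.frame(inputs) || is.matrix(inputs)) {
    b <- inputs[, "b"]; se <- inputs[, "se"]
  } else {
    b <- vapply(inputs, `[`, 1, 1)
    se <- vapply(inputs, `[`, 1, 2)
  }
  if (length(b) < 2) stop("need at least 2 cohorts")
  if (any(se <= 0)) stop("all standard errors must be positive")
  w <- 1 / se^2
  bp <- sum(w * b) / sum(w)
  sep <- 1 / sqrt(sum(w))
  z <- bp / sep
  Q <- sum(w * (b - bp)^2)
  list(b = bp, se = sep, z = z, p = 2 * pnorm(-abs(z)),
       nCohorts = length(b), Q = Q,
       pQ = pchisq(Q, df = length(b) - 1, lower.tail = FALSE))
}

#' Meta-analyse per-probe association tables from several cohorts
#'
#' Restricts to probes present in every cohort (the intersection size is
#' recorded as an attribute), then applies [ivwMeta()] probe-wise.
#'
#' @param tables list of association data.frames (probe, b, se columns; the
#'   first cohort's annotation columns are carried through).
#' @return data.frame probe, chrom, bp, gene, b, se, z, p, nCohorts with
#'   attribute \code{nCommon}.
#' @export
metaAnalyze <- function(tables) {
  if (length(tables) < 2) stop("need at least 2 cohorts")
  common <- Reduce(intersect, lapply(tables, function(t) t$probe[!is.na(t$se)]))
  if (!length(common)) stop("no probes shared across all cohorts")
  B <- vapply(tables, function(t) t$b[match(common, t$probe)], numeric(length(common)))
  SE <- vapply(tables, function(t) t$se[match(common, t$probe)], numeric(length(common)))
  w <- 1 / SE^2
  bp <- rowSums(w * B) / rowSums(w)
  sep <- 1 / sqrt(rowSums(w))
  z <- bp / sep
  first <- tables[[1]][match(common, tables[[1]]$probe), ]
  out <- data.frame(probe = common,
                    chrom = if ("chrom" %in% colnames(first)) first$chrom else NA,
                    bp = if ("bp" %in% colnames(first)) first$bp else NA,
                    gene = if ("gene" %in% colnames(first)) first$gene else NA,
                    b = bp, se = sep, z = z, p = 2 * pnorm(-abs(z)),
                    nCohorts = length(tables), stringsAsFactors = FALSE)
  attr(out, "nCommon") <- length(common)
  out
}

#' Bonferroni-adjusted significance threshold
#'
#' @param mTests number of tests (>= 1).
#' @param alpha family-wise error rate (default 0.05).
#' @return alpha / mTests.
#' @examples
#' bonferroniThreshold(229071)
#' @export
bonferroniThreshold <- function(mTests, alpha = 0.05) {
  if (mTests < 1) stop("mTests must be >= 1")
  alpha / mTests
}

#' One-sided binomial sign-concordance test
#'
#' Exact tail probability P(X >= k) for X ~ Binomial(n, 1/2): the chance of
#' observing at least k of n independent effects with matching direction if
#' direction were random.
#'
#' @param kConcordant number of concordant effects.
#' @param nTotal number of effects compared.
#' @return one-sided p-value.
#' @examples
#' signConcordanceBinomial(17, 21)
#' @export
signConcordanceBinomial <- function(kConcordant, nTotal) {
  if (kConcordant > nTotal || kConcordant < 0) stop("need 0 <= k <= n")
  pbinom(kConcordant - 1, nTotal, 0.5, lower.tail = FALSE)
}

#' Greedy correlation pruning of association records
#'
#' Selects approximately independent probes: candidates are visited in order
#' of ascending p (ties broken by probe id) and kept iff their squared
#' correlation with every already-kept probe is below \code{r2Max}.
#'
#' @param records association data.frame (probe, p columns).
#' @param corMatrix probe correlation matrix with dimnames covering the
#'   records (of probe methylation values, not effects).
#' @param r2Max squared-correlation ceiling (default 0.1).
#' @param pMax optional p-value ceiling applied before pruning.
#' @return the kept subset of \code{records}, in selection order.
#' @export
pruneProbesByR2 <- function(records, corMatrix, r2Max = 0.1, pMax = NULL) {
  records <- records[!is.na(records$p), , drop = FALSE]
  if (!is.null(pMax)) records <- records[records$p < pMax, , drop = FALSE]
  if (!nrow(records)) return(records)
  if (!all(records$probe %in% rownames(corMatrix)))
    stop("correlation matrix is not aligned to the records")
  ord <- order(records$p, records$probe)
  records <- records[ord, , drop = FALSE]
  kept <- integer()
  for (i in seq_len(nrow(records))) {
    pid <- records$probe[i]
    if (!length(kept)) { kept <- i; next }
    r2 <- corMatrix[pid, records$probe[kept]]^2
    if (all(r2 < r2Max)) kept <- c(kept, i)
  }
  records[kept, , drop = FALSE]
}

#' Empirical null for cross-cohort sign concordance
#'
#' Repeatedly draws \code{nSelect} probes uniformly without replacement from
#' the shared probe universe, counts how many have the same effect direction
#' in both cohorts, and reports the +1-corrected empirical p
#' (1 + #\{null >= observed\}) / (reps + 1). The observed concordance is
#' computed over \code{selected} (defaults to the \code{nSelect}
#' smallest-p discovery probes).
#'
#' @param discovery,replication association data.frames sharing a probe
#'   universe (probe, b, p columns).
#' @param nSelect number of probes per draw (default 21).
#' @param reps number of null draws (default 10000).
#' @param seed integer seed.
#' @param selected optional character vector of probe ids defining the
#'   observed set.
#' @return list with observedConcordant, empiricalP, nSelect, reps.
#' @export
empiricalSignNull <- function(discovery, replication, nSelect = 21L,
                              reps = 10000L, seed = 1L, selected = NULL) {
  shared <- intersect(discovery$probe, replication$probe)
  if (nSelect > length(shared))
    stop("nSelect exceeds the shared probe universe")
  bd <- setNames(discovery$b[match(shared, discovery$probe)], shared)
  br <- setNames(replication$b[match(shared, replication$probe)], shared)
  concord <- sign(bd) == sign(br)
  if (is.null(selected)) {
    pd <- discovery$p[match(shared, discovery$probe)]
    selected <- shared[order(pd)][seq_len(nSelect)]
  }
  if (!all(selected %in% shared)) stop("selected probes outside shared universe")
  obs <- sum(concord[selected])
  nullK <- .withSubstream(seed, "empirical_sign_null", {
    vapply(seq_len(reps), function(r)
      sum(concord[sample(shared, nSelect)]), 1)
  })
  list(observedConcordant = obs,
       empiricalP = (1 + sum(nullK >= obs)) / (reps + 1),
       nSelect = nSelect, reps = reps)
}

#' Effect-size concordance between two association tables
#'
#' Pearson correlation of effect sizes over the probes selected in table A
#' (p below \code{pThreshold}) that are also present in table B.
#'
#' @param recordsA,recordsB association data.frames (probe, b, p).
#' @param pThreshold selection threshold applied to table A.
#' @return list with r, p, nShared.
#' @export
effectConcordance <- function(recordsA, recordsB, pThreshold = 1e-4) {
  sel <- recordsA[!is.na(recordsA$p) & recordsA$p < pThreshold, ]
  shared <- intersect(sel$probe, recordsB$probe)
  if (length(shared) < 3) stop("fewer than 3 shared probes after selection")
  ba <- sel$b[match(shared, sel$probe)]
  bb <- recordsB$b[match(shared, recordsB$probe)]
  ct <- cor.test(ba, bb)
  list(r = unname(ct$estimate), p = ct$p.value, nShared = length(shared))
}

#' Replication power across sample sizes
#'
#' One-sided power at significance level \code{alpha} for detecting a
#' discovery effect of size b when the replication standard error scales
#' with n as \code{seModel(n)}:
#' power(n) = Phi(|b| / se(n) - z_alpha).
#'
#' @param bDiscovery discovery effect size.
#' @param seModel function mapping n to a standard error (monotone
#'   decreasing).
#' @param alpha one-sided significance level (default 0.05).
#' @param nGrid sample sizes to evaluate.
#' @param targetPower power target used for the reported minimum n
#'   (default 0.8).
#' @return data.frame n, power with attribute \code{nRequired} (smallest
#'   n in the grid reaching the target, NA when none does).
#' @export
replicationPower <- function(bDiscovery, seModel, alpha = 0.05,
                             nGrid = seq(100, 5000, by = 100),
                             targetPower = 0.8) {
  za <- qnorm(1 - alpha)
  power <- pnorm(abs(bDiscovery) / seModel(nGrid) - za)
  if (bDiscovery == 0) {
    warning("zero discovery effect: power equals alpha at every n")
    power <- rep(alpha, length(nGrid))
  }
  out <- data.frame(n = nGrid, power = power)
  hit <- which(power >= targetPower)
  attr(out, "nRequired") <- if (length(hit)) nGrid[min(hit)] else NA_integer_
  out
}
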