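## Summary-data Mendelian randomization: the Wald-ratio SMR statistic, the
## heterogeneity-in-dependent-instruments (HEIDI) test against linkage of
## two distinct causal variants, and the probe-gene-trait chaining with the
## instrument and gene filters.

#' Harmonize two summary-association sets to common SNPs and alleles
#'
#' Joins by SNP id, checks that each SNP's allele pair matches, and flips the
#' outcome effect sign (and frequency) where the effect allele is swapped.
#'
#' @param exposure,outcome data.frames with columns SNP, A1, A2, b, se, p
#'   (freq and N carried when present).
#' @return list with the aligned \code{exposure} and \code{outcome}
#'   data.frames (identical SNP order, outcome expressed on the exposure's
#'   effect allele).
#' @export
harmonizeSummary <- function(exposure, outcome) {
  shared <- intersect(exposure$SNP, outcome$SNP)
  if (!length(shared)) stop("no shared SNPs to harmonize")
  e <- exposure[match(shared, exposure$SNP), , drop = FALSE]
  o <- outcome[match(shared, outcome$SNP), , drop = FALSE]
  same <- toupper(e$A1) == toupper(o$A1) & toupper(e$A2) == toupper(o$A2)
  flip <- toupper(e$A1) == toupper(o$A2) & toupper(e$A2) == toupper(o$A1)
  bad <- !(same | flip)
  if (any(bad)) {
    warning(sum(bad), " SNP(s) dropped for incompatible alleles")
    e <- e[!bad, , drop = FALSE]; o <- o[!bad, , drop = FALSE]
    flip <- flip[!bad]
  }
  o$b[flip] <- -o$b[flip]
  if ("freq" %in% colnames(o)) o$freq[flip] <- 1 - o$freq[flip]
  o$A1 <- e$A1; o$A2 <- e$A2
  rownames(e) <- rownames(o) <- NULL
  list(exposure = e, outcome = o)
}

#' Select the top cis-QTL as the MR instrument
#'
#' Returns the SNP with the smallest exposure p-value, provided it passes
#' the instrument threshold; otherwise a typed "no-instrument" outcome. Ties
#' in p are broken by smaller base-pair position when a \code{bp} column is
#' present, else by SNP id.
#'
#' @param exposure summary-association data.frame for the cis window.
#' @param pInstrument instrument significance threshold (default 5e-8;
#'   the minimum p must be strictly below it).
#' @return list with status ("ok" or "no-instrument"), snp, p.
#' @export
selectInstrument <- function(exposure, pInstrument = 5e-8) {
  if (!nrow(exposure)) stop("empty cis window")
  ord <- if ("bp" %in% colnames(exposure))
    order(exposure$p, exposure$bp) else order(exposure$p, exposure$SNP)
  top <- exposure[ord[1], ]
  if (is.na(top$p) || top$p >= pInstrument)
    return(list(status = "no-instrument", snp = NA_character_, p = top$p))
  list(status = "ok", snp = top$SNP, p = top$p)
}

#' SMR test at a single instrument
#'
#' The Wald-ratio estimate b_xy = b_zy / b_zx of the exposure's effect on
#' the outcome, with the chi-square statistic
#' T = z_zy^2 z_zx^2 / (z_zy^2 + z_zx^2) referred to chi2(1), and a
#' delta-method standard error.
#'
#' @param bZx,seZx instrument effect and SE on the exposure.
#' @param bZy,seZy instrument effect and SE on the outcome.
#' @return list with bXy, se, chisq, p.
#' @examples
#' smrTest(0.5, 0.05, -0.1, 0.03)
#' @export
smrTest <- function(bZx, seZx, bZy, seZy) {
  if (bZx == 0) stop("zero instrument-exposure effect")
  zx <- bZx / seZx; zy <- bZy / seZy
  bXy <- bZy / bZx
  chisq <- if (zy == 0) 0 else zy^2 * zx^2 / (zy^2 + zx^2)
  seXy <- sqrt(seZy^2 / bZx^2 + bZy^2 * seZx^2 / bZx^4)
  list(bXy = bXy, se = seXy, chisq = chisq,
       p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

## Tail probability P(sum_i lambda_i chi2_1i > q) for a quadratic form in
## standard normals, by Imhof's numerical inversion; Monte-Carlo fallback.
.quadFormTail <- function(q, lambda, method = c("imhof", "montecarlo"),
                          nSim = 2e5, seed = 1L) {
  method <- match.arg(method)
  lambda <- lambda[lambda > 1e-10]
  if (!length(lambda)) return(1)
  if (method == "imhof") {
    theta <- function(u) 0.5 * colSums(atan(outer(lambda, u))) - q * u / 2
    rho <- function(u) exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    f <- function(u) sin(theta(u)) / (u * rho(u))
    val <- tryCatch(
      integrate(f, 0, Inf, rel.tol = 1e-9, subdivisions = 2000L)$value,
      error = function(e) NA_real_)
    if (!is.na(val)) return(min(max(0.5 + val / pi, 1e-12), 1))
    ## fall through to Monte-Carlo on integration failure
  }
  sims <- .withSubstream(seed, "quadform_mc", {
    colSums(lambda * matrix(stats::rchisq(length(lambda) * nSim, 1),
                            length(lambda)))
  })
  max(mean(sims >= q), 1 / nSim)
}

.ldMatrix <- function(ld, snps) {
  ld <- as.matrix(ld)
  if (nrow(ld) == ncol(ld) &&
      !is.null(rownames(ld)) && all(snps %in% rownames(ld)) &&
      max(abs(ld)) <= 1 + 1e-8) {
    return(ld[snps, snps, drop = FALSE])
  }
  ## genotype panel: individuals x SNPs
  if (is.null(colnames(ld)) || !all(snps %in% colnames(ld)))
    stop("LD reference does not cover the required SNPs")
  if (nrow(ld) < 50)
    stop("LD reference panel too small (need >= 50 individuals)")
  stats::cor(ld[, snps, drop = FALSE])
}

#' HEIDI test for heterogeneity in dependent instruments
#'
#' Tests whether the Wald ratios b_xy at cis SNPs correlated with the top
#' instrument are mutually consistent (a single shared causal variant)
#' against the alternative that two distinct causal variants in linkage
#' disequilibrium drive exposure and outcome. SNPs are eligible if their
#' exposure p is below \code{snpPMax} and their squared correlation with the
#' instrument lies within \code{ldPrune}. For each eligible SNP,
#' d_i = b_xy(i) - b_xy(top); the statistic sum z_d^2 is referred to the
#' distribution of a quadratic form in correlated normals with delta-method
#' covariance implied by LD, evaluated by eigenvalue-weighted chi-square
#' inversion (Monte-Carlo fallback).
#'
#' @param exposure,outcome summary-association data.frames over the cis
#'   window (harmonized internally).
#' @param ld LD information: either a correlation matrix with SNP dimnames
#'   or a reference genotype/dosage panel (individuals x SNPs, >= 50 rows).
#' @param snpPMax exposure p ceiling for SNP inclusion (default 1.6e-3,
#'   i.e. |z| > ~3.16).
#' @param ldPrune length-2 numeric, admissible squared correlation with the
#'   instrument (default c(0.05, 0.9)).
#' @param method tail evaluation, "imhof" or "montecarlo".
#' @param seed seed for the Monte-Carlo tail (only).
#' @return list with status ("ok" or "heidi-not-run"), p, nSnps, instrument.
#' @export
heidiTest <- function(exposure, outcome, ld, snpPMax = 1.6e-3,
                      ldPrune = c(0.05, 0.9),
                      method = c("imhof", "montecarlo"), seed = 1L) {
  method <- match.arg(method)
  h <- harmonizeSummary(exposure, outcome)
  e <- h$exposure; o <- h$outcome
  inst <- selectInstrument(e, pInstrument = 1)  # top SNP; caller gates significance
  t <- match(inst$snp, e$SNP)
  R <- .ldMatrix(ld, e$SNP)
  r2t <- R[t, ]^2
  elig <- which(e$p < snpPMax & r2t >= ldPrune[1] & r2t <= ldPrune[2] &
                  seq_len(nrow(e)) != t)
  if (length(elig) < 3)
    return(list(status = "heidi-not-run", p = NA_real_,
                nSnps = length(elig), instrument = inst$snp))
  idx <- c(t, elig)
  bx <- e$b[idx]; sx <- e$se[idx]
  by <- o$b[idx]; sy <- o$se[idx]
  Rs <- R[idx, idx]
  bxy <- by / bx
  k <- length(idx)
  ## delta-method covariance of the Wald ratios (exposure and outcome
  ## studies independent; within-study effects correlated through LD)
  covXY <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    covXY[i, j] <- Rs[i, j] * sy[i] * sy[j] / (bx[i] * bx[j]) +
      by[i] * by[j] * Rs[i, j] * sx[i] * sx[j] / (bx[i]^2 * bx[j]^2)
  }
  ## d_i = bxy_i - bxy_top; index 1 is the instrument
  m <- k - 1
  covD <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    covD[i, j] <- covXY[i + 1, j + 1] - covXY[i + 1, 1] - covXY[j + 1, 1] +
      covXY[1, 1]
  }
  d <- bxy[-1] - bxy[1]
  sdD <- sqrt(diag(covD))
  zD <- d / sdD
  Rd <- covD / outer(sdD, sdD)
  Rd <- (Rd + t(Rd)) / 2
  lam <- eigen(Rd, symmetric = TRUE, only.values = TRUE)$values
  stat <- sum(zD^2)
  p <- .quadFormTail(stat, lam, method = method, seed = seed)
  list(status = "ok", p = p, nSnps = m, instrument = inst$snp, stat = stat)
}

#' Filter genes by cis-eQTL evidence
#'
#' Keeps genes whose best cis-eQTL p-value is strictly below the threshold
#' (a gene at exactly the threshold is dropped).
#'
#' @param eqtlSets named list of per-gene summary-association data.frames.
#' @param p threshold (default 5e-8).
#' @return character vector of gene names.
#' @export
filterGenesWithEqtl <- function(eqtlSets, p = 5e-8) {
  if (!length(eqtlSets)) return(character())
  keep <- vapply(eqtlSets, function(s) min(s$p, na.rm = TRUE) < p, TRUE)
  names(eqtlSets)[keep]
}

#' Chain SMR tests through methylation, expression and trait
#'
#' For one methylation probe and every candidate gene whose transcription
#' start lies within \code{cisBp} of the probe, runs SMR (and HEIDI when LD
#' is supplied) for methylation -> expression, and additionally
#' methylation -> trait and expression -> trait. The Bonferroni threshold
#' reported corrects for the number of genes tested in the
#' methylation -> expression analysis.
#'
#' @param mqtl methylation QTL summary set (cis window of the probe).
#' @param eqtlSets named list of per-gene eQTL summary sets.
#' @param gwas trait GWAS summary set.
#' @param ld LD reference (see [heidiTest()]); NULL skips HEIDI.
#' @param probeBp probe position (bp).
#' @param geneBp named numeric of gene transcription-start positions.
#' @param cisBp window half-width (default 2e6).
#' @param pInstrument instrument threshold (default 5e-8).
#' @return data.frame with one row per test: exposure, outcome, instrument,
#'   bXy, se, pSMR, pHEIDI, nSnpsHEIDI, status; attributes \code{nTests}
#'   and \code{bonferroni}.
#' @export
smrChain <- function(mqtl, eqtlSets, gwas, ld = NULL, probeBp, geneBp,
                     cisBp = 2e6, pInstrument = 5e-8) {
  genes <- names(eqtlSets)
  if (is.null(genes)) stop("eqtlSets must be a named list (gene names)")
  inWindow <- genes[abs(geneBp[genes] - probeBp) <= cisBp]
  runPair <- function(exposure, outcome, exposureId, outcomeId) {
    base <- data.frame(exposure = exposureId, outcome = outcomeId,
                       instrument = NA_character_, bXy = NA_real_,
                       se = NA_real_, pSMR = NA_real_, pHEIDI = NA_real_,
                       nSnpsHEIDI = NA_integer_, status = "no-instrument",
                       stringsAsFactors = FALSE)
    h <- harmonizeSummary(exposure, outcome)
    inst <- selectInstrument(h$exposure, pInstrument)
    if (inst$status != "ok") return(base)
    i <- match(inst$snp, h$exposure$SNP)
    s <- smrTest(h$exposure$b[i], h$exposure$se[i],
                 h$outcome$b[i], h$outcome$se[i])
    base$instrument <- inst$snp
    base$bXy <- s$bXy; base$se <- s$se; base$pSMR <- s$p
    base$status <- "ok"
    if (!is.null(ld)) {
      hd <- heidiTest(h$exposure, h$outcome, ld)
      base$pHEIDI <- hd$p
      base$nSnpsHEIDI <- hd$nSnps
      if (hd$status != "ok") base$status <- "heidi-not-run"
    }
    base
  }
  rows <- list()
  for (g in inWindow) {
    rows[[length(rows) + 1L]] <-
      runPair(mqtl, eqtlSets[[g]], "methylation", paste0("expression:", g))
    rows[[length(rows) + 1L]] <-
      runPair(eqtlSets[[g]], gwas, paste0("expression:", g), "trait")
  }
  rows[[length(rows) + 1L]] <- runPair(mqtl, gwas, "methylation", "trait")
  out <- do.call(rbind, rows)
  nTests <- length(inWindow)
  attr(out, "nTests") <- nTests
  attr(out, "bonferroni") <- if (nTests > 0) 0.05 / nTests else NA_real_
  out
}
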