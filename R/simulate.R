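## Synthetic-cohort generator.
##
## Emulates the structure of a blood 450K case-control methylation study at
## desk scale: probes on 22 autosomes, beta values arising from a cell-type
## mixture of per-type signatures, slide/row/column batch structure,
## measurement noise, and binary disease status generated by a liability
## threshold model with sparse probe effects. All randomness flows from one
## integer seed through named substreams (see substreamSeed).

#' Simulation configuration for a synthetic methylation cohort
#'
#' Defaults describe the study conditions the package's calibration and
#' recovery experiments assume: a single cohort of 500 samples and 2000
#' autosomal probes with roughly balanced cases and controls, a liability
#' model in which 100 causal probes explain 30% of liability variance,
#' realistic whole-blood cell-type composition, and modest slide/row/column
#' batch effects and measurement noise on the logit (M-value) scale.
#'
#' @param nSamples number of samples.
#' @param nProbes number of probes.
#' @param nChromosomes number of autosomes probes are spread over.
#' @param probeSpacingBp mean inter-probe distance (bp); spacing is
#'   exponential, positions 1-based.
#' @param nCausalProbes number of probes with liability effects.
#' @param liabilityVarianceExplained fraction of liability variance explained
#'   jointly by the causal probes, in [0, 1).
#' @param caseFraction fraction of samples that are cases (liability
#'   threshold at this quantile).
#' @param alphaControls,alphaCases Dirichlet concentration parameters for the
#'   cell-type proportions of controls and cases (named, strictly positive).
#'   Defaults reflect typical whole-blood composition with identical
#'   case/control composition; shift \code{alphaCases} to plant a
#'   composition difference.
#' @param celltypeSeparation SD (logit scale) of per-probe cell-type
#'   signature differences.
#' @param celltypeInformativeFraction fraction of probes carrying cell-type
#'   signature differences (the rest are identical across types); 1 spreads
#'   the composition signal over every probe, small values concentrate it on
#'   a subset, as for strongly cell-type-specific CpGs.
#' @param nSlides,nRows,nColumns batch levels (slide, sentrix row, sentrix
#'   column).
#' @param batchSD SD (logit scale) of per-probe batch-level effects.
#' @param noiseSd measurement noise SD on the logit scale.
#' @param covariateLiabilityEffects named numeric, liability effects of the
#'   simulated covariates (sex, standardized age, smoking score).
#' @param seed master integer seed.
#' @return A validated \code{SimulationConfig} list.
#' @examples
#' cfg <- simulationConfig(nSamples = 100, nProbes = 200, seed = 7)
#' @export
simulationConfig <- function(nSamples = 500L,
                             nProbes = 2000L,
                             nChromosomes = 22L,
                             probeSpacingBp = 30000,
                             nCausalProbes = 100L,
                             liabilityVarianceExplained = 0.3,
                             caseFraction = 0.5,
                             alphaControls = c(B = 0.06, CD4T = 0.15, CD8T = 0.08,
                                               NK = 0.06, mono = 0.08, eos = 0.02,
                                               neu = 0.55) * 30,
                             alphaCases = NULL,
                             celltypeSeparation = 0.5,
                             celltypeInformativeFraction = 1,
                             nSlides = 8L, nRows = 6L, nColumns = 2L,
                             batchSD = 0.1,
                             noiseSd = 0.3,
                             covariateLiabilityEffects = c(sex = 0.2, age = 0.3,
                                                           smoking = 0.1),
                             seed = 1L) {
  if (nSamples < 2 || nProbes < 1)
    stop("sample and probe counts must be positive (>= 2 samples)")
  .assertScalarNumber(liabilityVarianceExplained, "liabilityVarianceExplained", 0, 1)
  if (liabilityVarianceExplained >= 1)
    stop("liabilityVarianceExplained must be < 1")
  .assertScalarNumber(caseFraction, "caseFraction", 0, 1)
  if (nCausalProbes > nProbes)
    stop("nCausalProbes must not exceed nProbes")
  if (is.null(alphaCases)) alphaCases <- alphaControls
  if (any(alphaControls <= 0) || any(alphaCases <= 0))
    stop("Dirichlet concentration parameters must be strictly positive")
  .assertScalarNumber(celltypeInformativeFraction, "celltypeInformativeFraction", 0, 1)
  if (!identical(names(alphaControls), names(alphaCases)))
    stop("alphaControls and alphaCases must name the same cell types")
  cfg <- list(nSamples = as.integer(nSamples), nProbes = as.integer(nProbes),
              nChromosomes = as.integer(nChromosomes),
              probeSpacingBp = probeSpacingBp,
              nCausalProbes = as.integer(nCausalProbes),
              liabilityVarianceExplained = liabilityVarianceExplained,
              caseFraction = caseFraction,
              alphaControls = alphaControls, alphaCases = alphaCases,
              celltypeSeparation = celltypeSeparation,
              celltypeInformativeFraction = celltypeInformativeFraction,
              nSlides = as.integer(nSlides), nRows = as.integer(nRows),
              nColumns = as.integer(nColumns), batchSD = batchSD,
              noiseSd = noiseSd,
              covariateLiabilityEffects = covariateLiabilityEffects,
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat(sprintf("SimulationConfig: n = %d, m = %d probes on %d autosomes (seed %d)\n",
              x$nSamples, x$nProbes, x$nChromosomes, x$seed))
  cat(sprintf("  liability: %d causal probes, h2(liability) = %.2f, case fraction %.2f\n",
              x$nCausalProbes, x$liabilityVarianceExplained, x$caseFraction))
  cat(sprintf("  batch SD %.2f, noise SD %.2f (logit scale)\n", x$batchSD, x$noiseSd))
  invisible(x)
}

#' Liability-scale variance needed for a target observed-scale fraction
#'
#' Binary status analysed as 0/1 with a linear mixed model yields a variance
#' fraction on the observed scale. Under the liability threshold model the
#' two scales are linked (for many small effects) by
#' \deqn{\rho^2_{obs} = h^2_{liab} \, z^2 / (p(1-p))}
#' where p is the case fraction and z the standard-normal density at the
#' threshold. This helper inverts the relation so study conditions can be
#' stated on the observed scale.
#'
#' @param rho2Observed target observed-scale variance fraction.
#' @param caseFraction case fraction p.
#' @return The liability-scale variance fraction.
#' @examples
#' liabilityVarianceForObserved(0.3, 0.5)
#' @export
liabilityVarianceForObserved <- function(rho2Observed, caseFraction) {
  z <- dnorm(qnorm(1 - caseFraction))
  rho2Observed * caseFraction * (1 - caseFraction) / z^2
}

.observedFromLiability <- function(h2Liab, caseFraction) {
  z <- dnorm(qnorm(1 - caseFraction))
  h2Liab * z^2 / (caseFraction * (1 - caseFraction))
}

.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  x / rowSums(x)
}

#' Simulate a cell-type reference signature matrix
#'
#' Generates per-probe mean beta values for a panel of leukocyte types. Each
#' probe has a shared baseline on the logit scale plus an independent
#' per-type deviation with SD \code{separation}; \code{separation = 0} gives
#' identical columns.
#'
#' @param nCelltypes number of cell types (>= 2). Seven types are named
#'   B, CD4T, CD8T, NK, mono, eos, neu; other counts get generic names.
#' @param nReferenceProbes number of reference probes.
#' @param separation SD of per-type deviations on the logit scale (>= 0).
#' @param seed integer seed.
#' @param probeIds optional probe ids (length \code{nReferenceProbes}).
#' @param baseline optional numeric vector of per-probe logit-scale baselines.
#' @return A probes x cell-types matrix of beta values in [0,1].
#' @examples
#' ref <- simulateCellTypeReference(7, 50, separation = 2, seed = 1)
#' colnames(ref)
#' @export
simulateCellTypeReference <- function(nCelltypes = 7L, nReferenceProbes = 100L,
                                      separation = 2, seed = 1L,
                                      probeIds = NULL, baseline = NULL) {
  if (nCelltypes < 2) stop("need at least 2 cell types")
  if (separation < 0) stop("'separation' must be non-negative")
  typeNames <- if (nCelltypes == 7L)
    c("B", "CD4T", "CD8T", "NK", "mono", "eos", "neu")
  else paste0("CT", seq_len(nCelltypes))
  .withSubstream(seed, "celltype_reference", {
    if (is.null(baseline)) baseline <- rnorm(nReferenceProbes, 0, 1.5)
    dev <- matrix(rnorm(nReferenceProbes * nCelltypes, 0, 1), nReferenceProbes,
                  nCelltypes) * separation
    ref <- invlogit(baseline + dev)
    dimnames(ref) <- list(
      if (is.null(probeIds)) sprintf("cg%07d", seq_len(nReferenceProbes)) else probeIds,
      typeNames)
    ref
  })
}

.simulateAnnotation <- function(cfg) {
  .withSubstream(cfg$seed, "annotation", {
    chrom <- sort(rep_len(seq_len(cfg$nChromosomes), cfg$nProbes))
    bp <- integer(cfg$nProbes)
    for (c in unique(chrom)) {
      idx <- which(chrom == c)
      bp[idx] <- 1L + as.integer(cumsum(rexp(length(idx), 1 / cfg$probeSpacingBp)))
    }
    data.frame(probe = sprintf("cg%07d", seq_len(cfg$nProbes)),
               chrom = as.character(chrom), bp = bp,
               gene = sprintf("GENE%04d", 1L + (seq_len(cfg$nProbes) - 1L) %/% 5L),
               crossReactive = FALSE, sexChromosome = FALSE,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a methylation case-control cohort with known truth
#'
#' Generates a [MethylationSet-class], a [CohortDesign-class] of basic
#' covariates (intercept, sex, standardized age, smoking score) and a truth
#' record. Per-sample beta values are a cell-type-proportion-weighted mixture
#' of per-type probe signatures; slide/row/column batch effects and
#' measurement noise are added on the logit scale and mapped back through the
#' inverse logit, so all values stay in [0,1]. Case status is drawn from a
#' liability threshold model: liability = causal standardized-probe
#' contributions (scaled to the configured variance fraction) + covariate
#' effects + normal residual, thresholded at the case-fraction quantile.
#'
#' When \code{alphaCases} differs from \code{alphaControls} the cell-type
#' proportions (and hence methylation) of samples classified as cases are
#' re-drawn from the case Dirichlet after status assignment. This plants a
#' composition difference between groups for confounding studies; it also
#' attenuates the causal-probe/liability link for those probes, so
#' composition-shift scenarios are meant for calibration rather than
#' effect-recovery experiments.
#'
#' @param config a [simulationConfig()].
#' @param cohortSeed optional seed for the sample-level draws (cell-type
#'   proportions, covariates, batches, noise, liability residuals). The
#'   probe-level architecture — annotation, cell-type signatures, causal
#'   probe identities and effects — always derives from \code{config$seed},
#'   so two calls with the same config and different \code{cohortSeed}
#'   produce independent cohorts sharing the same causal architecture (a
#'   discovery/replication pair). Defaults to \code{config$seed}.
#' @return A list with elements \code{mset} (MethylationSet; colData carries
#'   status, sex, age, smoking, slide, row, column and the true cell-type
#'   proportions prefixed \code{ctp.}), \code{design} (CohortDesign with
#'   intercept + sex + age + smoking), \code{reference} (the cell-type
#'   signature matrix at all probes), and \code{truth} (causal probe ids and
#'   effects, true cell-type proportions, batch assignments and effects, and
#'   the variance fractions on the liability and observed scales).
#' @examples
#' sim <- simulateMethylationCohort(simulationConfig(nSamples = 60,
#'                                                   nProbes = 120, seed = 3))
#' sim$mset
#' @export
simulateMethylationCohort <- function(config, cohortSeed = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  if (is.null(cohortSeed)) cohortSeed <- cfg$seed
  n <- cfg$nSamples; m <- cfg$nProbes
  ann <- .simulateAnnotation(cfg)
  types <- names(cfg$alphaControls)
  k <- length(types)

  ## per-probe, per-type signatures (beta scale)
  ref <- simulateCellTypeReference(k, m, separation = cfg$celltypeSeparation,
                                   seed = cfg$seed, probeIds = ann$probe)
  colnames(ref) <- types
  if (cfg$celltypeInformativeFraction < 1) {
    ## flatten the signatures of non-informative probes to their row mean
    nInf <- max(2L, round(cfg$celltypeInformativeFraction * m))
    flat <- .withSubstream(cfg$seed, "celltype_informative",
                           sort(sample.int(m, m - nInf)))
    ref[flat, ] <- rowMeans(ref[flat, , drop = FALSE])
  }

  ## covariates
  cov <- .withSubstream(cohortSeed, "covariates", {
    data.frame(sex = rbinom(n, 1, 0.5),
               age = round(rnorm(n, 65, 10), 1),
               smoking = rnorm(n))
  })

  ## initial cell-type proportions (control composition for everyone)
  ctp <- .withSubstream(cohortSeed, "ctp", .rdirichlet(n, cfg$alphaControls))
  colnames(ctp) <- types

  ## batch structure: per-level, per-probe effects on the logit scale
  batch <- .withSubstream(cohortSeed, "batch", {
    assign <- data.frame(
      slide = sample(seq_len(cfg$nSlides), n, replace = TRUE),
      row = sample(seq_len(cfg$nRows), n, replace = TRUE),
      column = sample(seq_len(cfg$nColumns), n, replace = TRUE))
    eff <- list(
      slide = matrix(rnorm(cfg$nSlides * m, 0, cfg$batchSD), cfg$nSlides, m),
      row = matrix(rnorm(cfg$nRows * m, 0, cfg$batchSD), cfg$nRows, m),
      column = matrix(rnorm(cfg$nColumns * m, 0, cfg$batchSD), cfg$nColumns, m))
    list(assign = assign, effects = eff)
  })
  batchTerm <- batch$effects$slide[batch$assign$slide, , drop = FALSE] +
    batch$effects$row[batch$assign$row, , drop = FALSE] +
    batch$effects$column[batch$assign$column, , drop = FALSE]

  noise <- .withSubstream(cohortSeed, "noise",
                          matrix(rnorm(n * m, 0, cfg$noiseSd), n, m))

  buildBeta <- function(ctpMat, rows = seq_len(n)) {
    mix <- ctpMat[rows, , drop = FALSE] %*% t(ref)     # samples x probes
    invlogit(logit(.clipUnit(mix)) + batchTerm[rows, , drop = FALSE] +
               noise[rows, , drop = FALSE])
  }
  beta <- buildBeta(ctp)                               # samples x probes

  ## liability model on standardized probe values
  arch <- .withSubstream(cfg$seed, "architecture", {
    causal <- if (cfg$nCausalProbes > 0)
      sort(sample.int(m, cfg$nCausalProbes)) else integer()
    gamma <- if (length(causal)) rnorm(length(causal)) else numeric()
    list(causal = causal, gamma = gamma)
  })
  truthFx <- c(arch, list(resid = .withSubstream(cohortSeed, "liability", rnorm(n))))
  h2 <- cfg$liabilityVarianceExplained
  covEff <- cfg$covariateLiabilityEffects
  covTerm <- covEff["sex"] * (cov$sex - mean(cov$sex)) +
    covEff["age"] * scale(cov$age)[, 1] +
    covEff["smoking"] * scale(cov$smoking)[, 1]
  varCov <- sum(covEff^2)
  g <- rep(0, n)
  if (length(truthFx$causal) && h2 > 0) {
    Wc <- scale(beta[, truthFx$causal, drop = FALSE])
    Wc[is.na(Wc)] <- 0
    g <- as.vector(Wc %*% truthFx$gamma)
    gsd <- .popSD(g)
    if (gsd > 0) g <- g / gsd * sqrt(h2)
  }
  residScale <- sqrt(max(1 - h2 - varCov, 0.05))
  liability <- g + covTerm + residScale *
    (truthFx$resid / .popSD(truthFx$resid))
  thr <- quantile(liability, 1 - cfg$caseFraction, type = 1)
  status <- as.integer(liability > thr)

  ## composition shift: re-draw case CTPs (and their methylation) if the case
  ## Dirichlet differs from the control one
  if (!isTRUE(all.equal(cfg$alphaCases, cfg$alphaControls))) {
    caseRows <- which(status == 1L)
    if (length(caseRows)) {
      ctpCase <- .withSubstream(cohortSeed, "ctp_cases",
                                .rdirichlet(length(caseRows), cfg$alphaCases))
      colnames(ctpCase) <- types
      ctp[caseRows, ] <- ctpCase
      beta[caseRows, ] <- buildBeta(ctp, caseRows)
    }
  }

  sampleIds <- sprintf("c%d.S%04d", cohortSeed, seq_len(n))
  rownames(ctp) <- sampleIds
  rownames(batch$assign) <- sampleIds
  colData <- cbind(data.frame(status = status), cov, batch$assign,
                   setNames(as.data.frame(ctp), paste0("ctp.", types)))
  rownames(colData) <- sampleIds
  betaPM <- t(beta)
  dimnames(betaPM) <- list(ann$probe, sampleIds)
  mset <- MethylationSet(betaPM, annotation = ann, colData = colData)
  design <- cohortDesign(status,
                         data.frame(sex = cov$sex, age = scale(cov$age)[, 1],
                                    smoking = cov$smoking),
                         sampleIds = sampleIds)
  truth <- list(causalProbes = ann$probe[truthFx$causal],
                liabilityEffects = setNames(truthFx$gamma, ann$probe[truthFx$causal]),
                ctp = ctp, batch = batch,
                rho2Liability = h2,
                rho2Observed = .observedFromLiability(h2, cfg$caseFraction),
                liability = liability, threshold = thr)
  class(truth) <- "TruthRecord"
  list(mset = mset, design = design, reference = ref, truth = truth)
}

#' @export
print.TruthRecord <- function(x, ...) {
  cat(sprintf("TruthRecord: %d causal probes; h2(liability) = %.3f, rho2(observed) = %.3f\n",
              length(x$causalProbes), x$rho2Liability, x$rho2Observed))
  invisible(x)
}

#' Simulate SNP summary-statistic trios for SMR/HEIDI experiments
#'
#' Generates per-SNP effect estimates, standard errors and p-values for a
#' methylation QTL study, an expression QTL study and a trait GWAS over one
#' cis window, together with an LD reference panel and the generating truth.
#' Under \code{"shared_causal"} one variant drives methylation, which drives
#' expression, which drives the trait (marginal effects follow the LD
#' profile, so every SNP's Wald ratio estimates the same effect). Under
#' \code{"linkage_two_causal"} two correlated variants act through distinct
#' paths (one on methylation, one directly on expression), the scenario the
#' heterogeneity test is designed to flag.
#'
#' Default effective sample sizes follow brain QTL and PD GWAS resources of
#' the scale used in blood/brain integration studies (mQTL 1160, eQTL 1194,
#' GWAS 308518).
#'
#' @param nSnps SNPs in the cis window (>= 2).
#' @param ldRho lag-1 autocorrelation of the AR(1) LD structure.
#' @param scenario \code{"shared_causal"} or \code{"linkage_two_causal"}.
#' @param bZx causal-SNP effect on methylation.
#' @param bXw methylation effect on expression.
#' @param bWy expression effect on the trait.
#' @param bZw2 direct effect of the second causal SNP on expression
#'   (linkage scenario only).
#' @param nMqtl,nEqtl,nGwas effective sample sizes of the three studies.
#' @param nRef LD reference panel size (>= 50 enforced downstream).
#' @param causalIndex index of the (first) causal SNP.
#' @param secondCausalOffset index offset of the second causal SNP
#'   (linkage scenario).
#' @param seed integer seed.
#' @return list with \code{mqtl}, \code{eqtl}, \code{gwas} (data.frames in
#'   .ma layout: SNP, A1, A2, freq, b, se, p, N, plus bp), \code{panel}
#'   (reference genotype-dosage matrix), \code{ld} (true LD correlation
#'   matrix) and \code{truth}.
#' @examples
#' trio <- simulateSummaryTrio(nSnps = 10, seed = 5)
#' head(trio$mqtl)
#' @export
simulateSummaryTrio <- function(nSnps = 30L, ldRho = 0.9,
                                scenario = c("shared_causal", "linkage_two_causal"),
                                bZx = 0.5, bXw = -0.4, bWy = 0.15, bZw2 = 0.3,
                                nMqtl = 1160L, nEqtl = 1194L, nGwas = 308518L,
                                nRef = 500L, causalIndex = NULL,
                                secondCausalOffset = 2L, seed = 1L) {
  scenario <- match.arg(scenario)
  if (nSnps < 2) stop("cis window must contain at least 2 SNPs")
  snp <- sprintf("rs%05d", seq_len(nSnps))
  bp <- 1e6 + (seq_len(nSnps) - 1L) * 2000
  R <- ldRho^abs(outer(seq_len(nSnps), seq_len(nSnps), "-"))
  if (is.null(causalIndex)) causalIndex <- ceiling(nSnps / 2)
  c1 <- causalIndex

  if (scenario == "shared_causal") {
    bM <- R[, c1] * bZx
    bE <- R[, c1] * bZx * bXw
    bG <- R[, c1] * bZx * bXw * bWy
    truth <- list(causalSnp = snp[c1], bZx = bZx, bXw = bXw, bWy = bWy, ld = R)
  } else {
    c2 <- min(c1 + secondCausalOffset, nSnps)
    bM <- R[, c1] * bZx
    bE <- R[, c2] * bZw2
    bG <- R[, c2] * bZw2 * bWy
    truth <- list(causalSnp = snp[c(c1, c2)], bZx = bZx, bZw2 = bZw2,
                  bWy = bWy, rCausal = R[c1, c2], ld = R)
  }

  draw <- function(bTrue, nStudy, stream) {
    se <- rep(1 / sqrt(nStudy), nSnps)
    bHat <- .withSubstream(seed, stream,
                           as.vector(MASS::mvrnorm(1, bTrue, R / nStudy)))
    data.frame(SNP = snp, A1 = "A", A2 = "G", freq = 0.5,
               b = bHat, se = se, p = 2 * pnorm(-abs(bHat / se)),
               N = nStudy, bp = bp, stringsAsFactors = FALSE)
  }
  panel <- .withSubstream(seed, "ld_panel",
                          MASS::mvrnorm(nRef, rep(0, nSnps), R))
  colnames(panel) <- snp
  class(truth) <- "SummaryTrioTruth"
  list(mqtl = draw(bM, nMqtl, "mqtl"),
       eqtl = draw(bE, nEqtl, "eqtl"),
       gwas = draw(bG, nGwas, "gwas"),
       panel = panel, ld = R, truth = truth)
}
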