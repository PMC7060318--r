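## Probe- and sample-level quality control, batch residualization and probe
## standardization for beta-value matrices.

#' Probe-level quality control
#'
#' Applies, in order: detection-rate filter (a probe must reach detection
#' p < \code{detectP} in at least \code{detectRateMin} of samples), bead-count
#' filter (a probe fails if more than \code{beadFailMax} of samples have
#' fewer than \code{minBeads} beads), cross-reactive filter, sex-chromosome
#' filter, and a low-variability filter removing probes with beta SD below
#' \code{sdMin}. Filters whose supporting layer (detection p-values, bead
#' counts, annotation flags) is absent are skipped and reported as such.
#'
#' @param M a [MethylationSet-class].
#' @param detectRateMin minimum fraction of samples with detection
#'   p < \code{detectP} (default 0.95).
#' @param detectP detection p-value cutoff (default 0.01).
#' @param minBeads minimum bead count (default 3).
#' @param beadFailMax maximum tolerated fraction of samples below
#'   \code{minBeads} (default 0.05).
#' @param sdMin minimum per-probe beta SD (default 0.02).
#' @param crossReactiveIds optional character vector of additional probe ids
#'   to drop as cross-reactive (e.g. from a published masking list).
#' @return list with \code{mset}, the filtered MethylationSet, and
#'   \code{report}, a data.frame of per-filter removal counts in order of
#'   application (including skipped filters).
#' @examples
#' sim <- simulateMethylationCohort(simulationConfig(nSamples = 20,
#'                                                   nProbes = 50, seed = 1))
#' qcProbes(sim$mset)$report
#' @export
qcProbes <- function(M, detectRateMin = 0.95, detectP = 0.01, minBeads = 3,
                     beadFailMax = 0.05, sdMin = 0.02,
                     crossReactiveIds = NULL) {
  stopifnot(is(M, "MethylationSet"))
  keep <- rep(TRUE, nrow(M))
  names(keep) <- rownames(M)
  report <- data.frame(filter = character(), removed = integer(),
                       applied = logical(), stringsAsFactors = FALSE)
  note <- function(filter, removed, applied = TRUE) {
    report <<- rbind(report, data.frame(filter = filter, removed = removed,
                                        applied = applied))
  }
  assays <- SummarizedExperiment::assayNames(M)
  rd <- SummarizedExperiment::rowData(M)

  if ("detectionP" %in% assays) {
    dp <- SummarizedExperiment::assay(M, "detectionP")
    rate <- rowMeans(dp < detectP, na.rm = TRUE)
    fail <- keep & rate < detectRateMin
    note("detection_rate", sum(fail)); keep[fail] <- FALSE
  } else note("detection_rate", 0L, applied = FALSE)

  if ("beadCount" %in% assays) {
    bc <- SummarizedExperiment::assay(M, "beadCount")
    failFrac <- rowMeans(bc < minBeads, na.rm = TRUE)
    fail <- keep & failFrac > beadFailMax
    note("bead_count", sum(fail)); keep[fail] <- FALSE
  } else note("bead_count", 0L, applied = FALSE)

  crossFlag <- if ("crossReactive" %in% colnames(rd))
    as.logical(rd$crossReactive) else rep(FALSE, nrow(M))
  if (!is.null(crossReactiveIds))
    crossFlag <- crossFlag | rownames(M) %in% crossReactiveIds
  fail <- keep & crossFlag
  note("cross_reactive", sum(fail),
       applied = "crossReactive" %in% colnames(rd) || !is.null(crossReactiveIds))
  keep[fail] <- FALSE

  if ("sexChromosome" %in% colnames(rd)) {
    fail <- keep & (as.logical(rd$sexChromosome) |
                      rd$chrom %in% c("X", "Y", "chrX", "chrY"))
    note("sex_chromosome", sum(fail)); keep[fail] <- FALSE
  } else note("sex_chromosome", 0L, applied = FALSE)

  sds <- apply(betaValues(M), 1, sd, na.rm = TRUE)
  fail <- keep & (is.na(sds) | sds < sdMin)
  note("low_variability", sum(fail)); keep[fail] <- FALSE

  if (!any(keep)) stop("probe QC removed all probes")
  list(mset = M[keep, ], report = report)
}

#' Sample-level quality control
#'
#' Removes samples with a low call rate (fewer than \code{minDetectedProbes}
#' probes detected at p < \code{callrateP}; values in (0,1] are interpreted
#' as a fraction of the probe count, so the classical absolute array
#' threshold generalizes to matrices of any size), samples whose predicted
#' sex (colData \code{predictedSex}) disagrees with reported sex
#' (\code{reportedSex}), and samples whose median methylated signal
#' (\code{medMethSignal}) lies more than \code{signalSD} standard deviations
#' from the cohort mean. Checks whose colData columns are absent are skipped
#' and reported.
#'
#' @param M a [MethylationSet-class].
#' @param minDetectedProbes absolute count, or fraction of probes in (0,1]
#'   (default 0.927, the classical 450000/485512).
#' @param callrateP detection p-value cutoff for the call rate (default 0.001).
#' @param signalSD signal-outlier cutoff in SD units (default 3).
#' @return list with \code{mset} and \code{report} (data.frame sample/reason,
#'   plus attribute \code{skipped} naming skipped checks).
#' @export
qcSamples <- function(M, minDetectedProbes = 0.927, callrateP = 0.001,
                      signalSD = 3) {
  stopifnot(is(M, "MethylationSet"))
  keep <- rep(TRUE, ncol(M))
  names(keep) <- colnames(M)
  reasons <- data.frame(sample = character(), reason = character(),
                        stringsAsFactors = FALSE)
  skipped <- character()
  cd <- SummarizedExperiment::colData(M)

  if ("detectionP" %in% SummarizedExperiment::assayNames(M)) {
    thr <- if (minDetectedProbes <= 1) minDetectedProbes * nrow(M)
           else minDetectedProbes
    dp <- SummarizedExperiment::assay(M, "detectionP")
    nDet <- colSums(dp < callrateP, na.rm = TRUE)
    fail <- which(nDet < thr)
    if (length(fail))
      reasons <- rbind(reasons, data.frame(sample = colnames(M)[fail],
                                           reason = "low_call_rate"))
    keep[fail] <- FALSE
  } else skipped <- c(skipped, "call_rate")

  if (all(c("reportedSex", "predictedSex") %in% colnames(cd))) {
    mism <- which(!is.na(cd$reportedSex) & !is.na(cd$predictedSex) &
                    cd$reportedSex != cd$predictedSex)
    if (length(mism))
      reasons <- rbind(reasons, data.frame(sample = colnames(M)[mism],
                                           reason = "sex_mismatch"))
    keep[mism] <- FALSE
  } else skipped <- c(skipped, "sex_check")

  if ("medMethSignal" %in% colnames(cd)) {
    s <- cd$medMethSignal
    ## robust centre/scale so a gross outlier cannot mask itself
    z <- (s - median(s, na.rm = TRUE)) / stats::mad(s, na.rm = TRUE)
    out <- which(!is.na(z) & abs(z) > signalSD)
    if (length(out))
      reasons <- rbind(reasons, data.frame(sample = colnames(M)[out],
                                           reason = "signal_outlier"))
    keep[out] <- FALSE
  } else skipped <- c(skipped, "signal_outlier")

  if (!any(keep)) stop("sample QC removed all samples")
  attr(reasons, "skipped") <- skipped
  list(mset = M[, keep], report = reasons)
}

#' Residualize probes on known batch factors
#'
#' Regresses each probe's beta values on one-hot indicators of the supplied
#' categorical batch factors (jointly) by least squares, replaces the probe
#' with its residuals and re-centres at the original probe mean. Residualized
#' values may leave [0,1]; downstream analyses use standardized values, so
#' this is recorded rather than clipped.
#'
#' @param M a [MethylationSet-class].
#' @param batchFactors character vector of colData column names, or a
#'   data.frame of per-sample labels. Each factor must have at least two
#'   levels among the samples.
#' @return A MethylationSet with the beta assay residualized.
#' @export
residualizeBatch <- function(M, batchFactors) {
  stopifnot(is(M, "MethylationSet"))
  if (is.character(batchFactors)) {
    cd <- as.data.frame(SummarizedExperiment::colData(M))
    missing <- setdiff(batchFactors, colnames(cd))
    if (length(missing))
      stop("batch factors not in colData: ", paste(missing, collapse = ", "))
    fac <- cd[batchFactors]
  } else fac <- as.data.frame(batchFactors)
  fac[] <- lapply(fac, factor)
  nlev <- vapply(fac, nlevels, 1L)
  if (any(nlev < 2))
    stop("batch factor(s) with a single level: ",
         paste(names(fac)[nlev < 2], collapse = ", "))
  X <- stats::model.matrix(~ ., data = fac)
  beta <- betaValues(M)
  ## residuals of t(beta) (samples x probes) on the one-hot design
  fit <- lm.fit(X, t(beta))
  res <- fit$residuals
  resid <- t(res) + rowMeans(beta, na.rm = TRUE)
  out <- M
  SummarizedExperiment::assay(out, "beta") <- resid
  S4Vectors::metadata(out)$residualized <- TRUE
  out
}

#' Standardize probes to mean 0, population variance 1
#'
#' Columns of the returned matrix W (samples x probes) have mean 0 and
#' variance 1 with the population (1/n) denominator, so that the diagonal of
#' WW'/m averages exactly 1. Missing beta values are imputed to the observed
#' probe mean before scaling, and the number of imputed entries is recorded.
#'
#' @param M a [MethylationSet-class] or a probes x samples numeric matrix.
#' @return A [StandardizedMethylation-class].
#' @examples
#' b <- matrix(c(0.2, 0.4, 0.6), 1, 3,
#'             dimnames = list("cg1", paste0("s", 1:3)))
#' stdMatrix(standardizeProbes(b))
#' @export
standardizeProbes <- function(M) {
  beta <- if (is(M, "MethylationSet")) betaValues(M) else as.matrix(M)
  X <- t(beta)                                   # samples x probes
  nImputed <- colSums(is.na(X))
  mu <- colMeans(X, na.rm = TRUE)
  if (any(nImputed > 0)) {
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  n <- nrow(X)
  ctr <- sweep(X, 2, colMeans(X))
  sds <- sqrt(colMeans(ctr^2))
  if (any(sds == 0))
    stop("constant probe(s) present (run qcProbes first): ",
         paste(head(colnames(X)[sds == 0], 5L), collapse = ", "))
  W <- sweep(ctr, 2, sds, "/")
  new("StandardizedMethylation", W = W, probeMeans = mu, probeSDs = sds,
      nImputed = as.integer(nImputed))
}
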