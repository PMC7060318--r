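#' @import methods
#' @importFrom stats as.formula binomial coef cor cor.test dnorm glm integrate
#'   lm.fit logLik median na.omit optimise pbinom pchisq pnorm qchisq qnorm
#'   quantile rbinom resid rexp rnorm runif sd setNames var vcov
#' @importFrom utils head
NULL

#' MethylationSet: beta-value matrix with probe annotation and sample metadata
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding a
#' probes-by-samples matrix of methylation beta values (assay \code{"beta"}),
#' optional detection p-value and bead-count assays of the same shape, probe
#' genomic annotation in \code{rowData} (\code{chrom}, \code{bp} 1-based,
#' \code{gene}, \code{crossReactive}, \code{sexChromosome}) and per-sample
#' metadata in \code{colData} (case status, reported/predicted sex, signal
#' summaries, batch factors ...).
#'
#' Beta values are intensity ratios in [0,1]; after batch residualization
#' (see [residualizeBatch()]) values may step slightly outside that range,
#' which is recorded in \code{metadata(x)$residualized}.
#'
#' @slot se the underlying SummarizedExperiment is the object itself
#'   (the class \code{contains} SummarizedExperiment).
#' @export
setClass("MethylationSet", contains = "SummarizedExperiment")

setValidity("MethylationSet", function(object) {
  msgs <- character()
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'beta' is required")
  for (nm in intersect(c("detectionP", "beadCount"),
                       SummarizedExperiment::assayNames(object))) {
    if (!identical(dim(SummarizedExperiment::assay(object, nm)), dim(object)))
      msgs <- c(msgs, sprintf("assay '%s' has inconsistent dimensions", nm))
  }
  if (anyDuplicated(rownames(object)))
    msgs <- c(msgs, "probe ids (rownames) must be unique")
  rd <- SummarizedExperiment::rowData(object)
  if ("bp" %in% colnames(rd) && any(rd$bp <= 0, na.rm = TRUE))
    msgs <- c(msgs, "probe positions must be positive (1-based)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MethylationSet
#'
#' @param beta numeric matrix, probes as rows (rownames = probe ids), samples
#'   as columns (colnames = sample ids); values in [0,1], NA allowed.
#' @param annotation optional data.frame of probe annotation with columns
#'   \code{probe}, \code{chrom}, \code{bp} (1-based) and optionally
#'   \code{gene}, \code{crossReactive}, \code{sexChromosome}. Must cover every
#'   probe in \code{beta}.
#' @param colData optional data.frame of per-sample metadata, rows aligned to
#'   the columns of \code{beta}.
#' @param detectionP,beadCount optional matrices matching \code{dim(beta)}.
#' @param allowOutOfRange logical; permit beta values outside [0,1]
#'   (used internally after batch residualization).
#' @return A [MethylationSet-class] object.
#' @examples
#' b <- matrix(runif(12), 3, 4,
#'             dimnames = list(paste0("cg", 1:3), paste0("s", 1:4)))
#' MethylationSet(b)
#' @export
MethylationSet <- function(beta, annotation = NULL, colData = NULL,
                           detectionP = NULL, beadCount = NULL,
                           allowOutOfRange = FALSE) {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta)))
    stop("'beta' must have probe ids as rownames")
  if (is.null(colnames(beta)))
    colnames(beta) <- paste0("sample", seq_len(ncol(beta)))
  if (!allowOutOfRange) {
    bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
    if (nrow(bad)) {
      ex <- head(bad, 5L)
      stop("beta values outside [0,1] at: ",
           paste(sprintf("(%s, %s)", rownames(beta)[ex[, 1]],
                         colnames(beta)[ex[, 2]]), collapse = ", "),
           if (nrow(bad) > 5L) sprintf(" and %d more", nrow(bad) - 5L))
    }
  }
  assays <- list(beta = beta)
  if (!is.null(detectionP)) assays$detectionP <- as.matrix(detectionP)
  if (!is.null(beadCount)) assays$beadCount <- as.matrix(beadCount)
  rd <- S4Vectors::DataFrame(row.names = rownames(beta))
  if (!is.null(annotation)) {
    annotation <- as.data.frame(annotation)
    if (!all(c("probe", "chrom", "bp") %in% colnames(annotation)))
      stop("annotation needs columns 'probe', 'chrom', 'bp'")
    if (anyDuplicated(annotation$probe))
      stop("duplicate probe ids in annotation")
    missing <- setdiff(rownames(beta), annotation$probe)
    if (length(missing))
      stop("annotation missing probes present in the matrix: ",
           paste(head(missing, 5L), collapse = ", "))
    annotation <- annotation[match(rownames(beta), annotation$probe), , drop = FALSE]
    rd <- S4Vectors::DataFrame(annotation[setdiff(colnames(annotation), "probe")],
                               row.names = rownames(beta))
  }
  cd <- S4Vectors::DataFrame(row.names = colnames(beta))
  if (!is.null(colData)) {
    colData <- as.data.frame(colData)
    if (nrow(colData) != ncol(beta))
      stop("colData rows must match the number of samples")
    cd <- S4Vectors::DataFrame(colData, row.names = colnames(beta))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowData = rd, colData = cd,
    metadata = list(residualized = allowOutOfRange))
  new("MethylationSet", se)
}

#' @describeIn MethylationSet beta-value assay (probes x samples).
#' @param x a MethylationSet.
#' @export
betaValues <- function(x) SummarizedExperiment::assay(x, "beta")

#' @describeIn MethylationSet probe annotation as a data.frame with a
#'   \code{probe} column.
#' @export
probeAnnotation <- function(x) {
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  cbind(probe = rownames(x), rd, stringsAsFactors = FALSE)
}

setMethod("show", "MethylationSet", function(object) {
  cat(sprintf("MethylationSet: %d probes x %d samples\n",
              nrow(object), ncol(object)))
  cat("assays:", paste(SummarizedExperiment::assayNames(object), collapse = ", "), "\n")
  rd <- colnames(SummarizedExperiment::rowData(object))
  if (length(rd)) cat("probe annotation:", paste(rd, collapse = ", "), "\n")
  cd <- colnames(SummarizedExperiment::colData(object))
  if (length(cd)) cat("sample data:", paste(cd, collapse = ", "), "\n")
})

#' StandardizedMethylation: column-standardized probe matrix W
#'
#' Holds the n x m matrix W of probe values standardized probe-wise to mean 0
#' and population (1/n) variance 1, together with the location/scale used so
#' effects can be mapped back to the beta scale. Missing values are
#' mean-imputed before scaling and counted per probe.
#'
#' @slot W numeric matrix, samples x probes.
#' @slot probeMeans,probeSDs numeric vectors of the per-probe mean and
#'   population SD applied.
#' @slot nImputed integer vector, number of imputed entries per probe.
#' @export
setClass("StandardizedMethylation",
         representation(W = "matrix", probeMeans = "numeric",
                        probeSDs = "numeric", nImputed = "integer"))

setValidity("StandardizedMethylation", function(object) {
  msgs <- character()
  m <- ncol(object@W)
  if (length(object@probeMeans) != m || length(object@probeSDs) != m)
    msgs <- c(msgs, "probeMeans/probeSDs must have one entry per probe")
  if (is.null(colnames(object@W)))
    msgs <- c(msgs, "W must carry probe ids as colnames")
  cm <- colMeans(object@W)
  cv <- colMeans(object@W^2) - cm^2
  if (any(abs(cm) > 1e-8) || any(abs(cv - 1) > 1e-6))
    msgs <- c(msgs, "columns of W must have mean 0 and population variance 1")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "StandardizedMethylation", function(object) {
  cat(sprintf("StandardizedMethylation: %d samples x %d probes (%d values imputed)\n",
              nrow(object@W), ncol(object@W), sum(object@nImputed)))
})

#' @describeIn StandardizedMethylation the standardized matrix (samples x probes).
#' @param x a StandardizedMethylation.
#' @export
stdMatrix <- function(x) x@W

#' CohortDesign: phenotype and fixed-covariate design
#'
#' @slot y numeric 0/1 phenotype vector (1 = case).
#' @slot C numeric fixed-effects design matrix including the intercept.
#' @slot sampleIds character sample identifiers.
#' @export
setClass("CohortDesign",
         representation(y = "numeric", covariates = "matrix", sampleIds = "character"))

setValidity("CohortDesign", function(object) {
  msgs <- character()
  if (length(object@y) != nrow(object@covariates))
    msgs <- c(msgs, "y and C must have the same number of rows")
  if (!all(object@y %in% c(0, 1)))
    msgs <- c(msgs, "y must be coded 0/1")
  if (qr(object@covariates)$rank < ncol(object@covariates))
    msgs <- c(msgs, "covariate matrix C is rank deficient")
  if (length(object@sampleIds) != length(object@y))
    msgs <- c(msgs, "sampleIds must align with y")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CohortDesign
#'
#' @param y 0/1 phenotype vector.
#' @param covariates data.frame of fixed covariates (numeric or factor); an
#'   intercept column is prepended. Factors are expanded to treatment-coded
#'   indicators.
#' @param sampleIds optional character ids; defaults to covariate rownames or
#'   an integer sequence.
#' @return A [CohortDesign-class].
#' @examples
#' cohortDesign(c(0, 1, 0, 1), data.frame(sex = c(0, 1, 1, 0), age = 60:63))
#' @export
cohortDesign <- function(y, covariates = NULL, sampleIds = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(covariates)) {
    C <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  } else {
    covariates <- as.data.frame(covariates)
    mm <- stats::model.matrix(~ ., data = covariates)
    colnames(mm)[1] <- "intercept"
    C <- mm
    attr(C, "assign") <- NULL
    attr(C, "contrasts") <- NULL
  }
  if (is.null(sampleIds)) {
    sampleIds <- if (!is.null(covariates) && !is.null(rownames(covariates)) &&
                     !identical(rownames(covariates), as.character(seq_len(n))))
      rownames(covariates) else sprintf("sample%03d", seq_len(n))
  }
  new("CohortDesign", y = y, covariates = C, sampleIds = as.character(sampleIds))
}

#' @describeIn cohortDesign phenotype accessor.
#' @param design a CohortDesign.
#' @export
phenotype <- function(design) design@y

#' @describeIn cohortDesign fixed-covariate matrix accessor.
#' @export
covariateMatrix <- function(design) design@covariates

setMethod("show", "CohortDesign", function(object) {
  cat(sprintf("CohortDesign: %d samples (%d cases), %d fixed covariates (%s)\n",
              length(object@y), sum(object@y), ncol(object@covariates),
              paste(colnames(object@covariates), collapse = ", ")))
})

#' OmicsRelationshipMatrix: A = WW'/m over standardized probes
#'
#' The methylation analogue of a genomic relationship matrix. With W
#' standardized using the population (1/n) variance, the diagonal of A
#' averages exactly 1, which fixes the scale of the variance component
#' attached to it.
#'
#' @slot A symmetric n x n numeric matrix.
#' @slot m integer, number of probes used.
#' @export
setClass("OmicsRelationshipMatrix",
         representation(A = "matrix", m = "integer"))

setValidity("OmicsRelationshipMatrix", function(object) {
  msgs <- character()
  A <- object@A
  if (nrow(A) != ncol(A)) msgs <- c(msgs, "A must be square")
  else if (max(abs(A - t(A))) > 1e-8) msgs <- c(msgs, "A must be symmetric")
  if (object@m < 1L) msgs <- c(msgs, "m must be >= 1")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "OmicsRelationshipMatrix", function(object) {
  cat(sprintf("OmicsRelationshipMatrix: %d x %d from m = %d probes; mean diag = %.6f\n",
              nrow(object@A), ncol(object@A), object@m, mean(diag(object@A))))
})

#' @describeIn OmicsRelationshipMatrix the relationship matrix.
#' @param x an OmicsRelationshipMatrix.
#' @export
ormMatrix <- function(x) x@A

#' VarianceEstimate: REML variance components and the probe-captured fraction
#'
#' @slot sigmaO variance attached to the omics relationship matrix
#'   (sigma^2_o = m * sigma^2_u).
#' @slot sigmaE residual variance.
#' @slot rho2 sigmaO / (sigmaO + sigmaE), the proportion of phenotypic
#'   variance captured by all probes on the observed 0/1 scale.
#' @slot se named numeric standard errors for sigmaO, sigmaE and (by the delta
#'   method from the average-information matrix) rho2.
#' @slot logLik restricted log-likelihood at the optimum.
#' @slot pLRT p-value of the 0.5*chi2_0 + 0.5*chi2_1 mixture likelihood-ratio
#'   test of sigmaO = 0 (this package's convention).
#' @slot converged logical.
#' @slot iterations integer.
#' @slot trace data.frame of per-iteration components and log-likelihood.
#' @slot clamped logical, TRUE when a component was clamped at its lower bound.
#' @export
setClass("VarianceEstimate",
         representation(sigmaO = "numeric", sigmaE = "numeric", rho2 = "numeric",
                        se = "numeric", logLik = "numeric", pLRT = "numeric",
                        converged = "logical", iterations = "integer",
                        trace = "data.frame", clamped = "logical"))

setMethod("show", "VarianceEstimate", function(object) {
  cat(sprintf("VarianceEstimate: rho2 = %.4f (se %.4f), sigma_o = %.4f, sigma_e = %.4f\n",
              object@rho2, object@se["rho2"], object@sigmaO, object@sigmaE))
  cat(sprintf("  logLik(REML) = %.6f after %d iterations (%s)%s; LRT p = %.3g\n",
              object@logLik, object@iterations,
              if (object@converged) "converged" else "NOT converged",
              if (object@clamped) ", component clamped" else "", object@pLRT))
})

#' @describeIn VarianceEstimate variance fraction accessor.
#' @param x a VarianceEstimate.
#' @export
rho2 <- function(x) x@rho2

#' @describeIn VarianceEstimate named variance components c(sigmaO, sigmaE).
#' @export
varComponents <- function(x) c(sigmaO = x@sigmaO, sigmaE = x@sigmaE)

#' BLUPEffects: joint shrinkage estimates of all probe effects
#'
#' @slot u named numeric vector of per-probe BLUP solutions (on the
#'   standardized-probe scale).
#' @slot sigmaO,sigmaE the variance components used.
#' @export
setClass("BLUPEffects",
         representation(u = "numeric", sigmaO = "numeric", sigmaE = "numeric"))

setValidity("BLUPEffects", function(object) {
  if (is.null(names(object@u))) return("u must be named by probe id")
  if (any(!is.finite(object@u))) return("u must be finite")
  TRUE
})

setMethod("show", "BLUPEffects", function(object) {
  cat(sprintf("BLUPEffects: %d probes, sd(u) = %.3g\n",
              length(object@u), sd(object@u)))
})

#' @describeIn BLUPEffects probe-effect accessor.
#' @param x a BLUPEffects.
#' @export
probeEffects <- function(x) x@u
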