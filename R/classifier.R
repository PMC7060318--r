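## Methylation profile scoring from BLUP probe effects and out-of-sample
## classifier evaluation (Nagelkerke R^2, likelihood-ratio p, AUC with a
## DeLong confidence interval).

#' Methylation profile scores for a target cohort
#'
#' Scores each target sample as the id-keyed inner product of its
#' standardized probe values with the training BLUP effects; training probes
#' missing from the target are dropped (the overlap fraction is recorded)
#' and scores are z-scaled within the target cohort.
#'
#' @param targetW a [StandardizedMethylation-class] (or standardized
#'   samples x probes matrix with probe colnames) for the target cohort.
#' @param blup a [BLUPEffects-class] from the training cohort.
#' @param minOverlap minimum tolerated fraction of training probes present
#'   in the target (default 0.5).
#' @return [S4Vectors::DataFrame] with columns raw and z (rownames = sample
#'   ids); metadata holds \code{overlap} and \code{nProbesUsed}.
#' @export
profileScores <- function(targetW, blup, minOverlap = 0.5) {
  stopifnot(is(blup, "BLUPEffects"))
  Wm <- if (is(targetW, "StandardizedMethylation")) stdMatrix(targetW)
        else as.matrix(targetW)
  u <- probeEffects(blup)
  common <- intersect(names(u), colnames(Wm))
  overlap <- length(common) / length(u)
  if (overlap < minOverlap)
    stop(sprintf("probe overlap %.2f below the %.2f floor", overlap, minOverlap))
  raw <- as.vector(Wm[, common, drop = FALSE] %*% u[common])
  s <- sd(raw)
  if (s == 0)
    stop("profile scores are constant (zero-SD); cannot z-scale")
  out <- S4Vectors::DataFrame(raw = raw, z = (raw - mean(raw)) / s,
                              row.names = rownames(Wm))
  S4Vectors::metadata(out) <- list(overlap = overlap,
                                   nProbesUsed = length(common))
  out
}

#' Nagelkerke pseudo-R-squared of a score for a binary outcome
#'
#' Max-rescaled Cox-Snell R^2 comparing the logistic model
#' y ~ covariates + score against y ~ covariates, with the p-value from the
#' likelihood-ratio test of the score term.
#'
#' @param y 0/1 outcome.
#' @param score numeric score.
#' @param covariates optional data.frame of adjustment covariates.
#' @return list with R2, p, llNull, llFull, separated (logical flag).
#' @examples
#' set.seed(1)
#' y <- rbinom(100, 1, 0.5)
#' nagelkerkeR2(y, rnorm(100))$R2
#' @export
nagelkerkeR2 <- function(y, score, covariates = NULL) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  n <- length(y)
  dat0 <- data.frame(y = y)
  if (!is.null(covariates)) dat0 <- cbind(dat0, as.data.frame(covariates))
  fit0 <- glm(y ~ ., data = dat0, family = binomial())
  dat1 <- cbind(dat0, score = score)
  fit1 <- suppressWarnings(glm(y ~ ., data = dat1, family = binomial()))
  if (!fit0$converged || !fit1$converged)
    stop("logistic model failed to converge")
  ll0 <- as.numeric(logLik(fit0)); ll1 <- as.numeric(logLik(fit1))
  csR2 <- 1 - exp(2 / n * (ll0 - ll1))
  maxR2 <- 1 - exp(2 / n * ll0)
  lrt <- 2 * (ll1 - ll0)
  list(R2 = max(csR2 / maxR2, 0),
       p = pchisq(max(lrt, 0), df = 1, lower.tail = FALSE),
       llNull = ll0, llFull = ll1, separated = .checkSeparation(fit1))
}

#' AUC with a DeLong 95% confidence interval
#'
#' Area under the receiver-operating-characteristic curve via the rank
#' (Mann-Whitney) formulation with tie correction, and the DeLong variance
#' for the interval.
#'
#' @param y 0/1 outcome (both classes required).
#' @param score numeric classifier score (larger = more case-like).
#' @param conf.level confidence level (default 0.95).
#' @return named numeric c(auc, lower, upper).
#' @examples
#' aucWithCI(c(1, 0, 1, 0), c(3, 2, 1, 0))
#' @export
aucWithCI <- function(y, score, conf.level = 0.95) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  r <- pROC::roc(response = y, predictor = score, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(r, conf.level = conf.level, method = "delong"))
  c(auc = ci[2], lower = ci[1], upper = ci[3])
}

#' Train-on-one-cohort, classify-the-other evaluation
#'
#' Fits the all-probe mixed model on the training cohort, computes BLUP
#' probe effects, scores the target cohort and evaluates the scores by
#' logistic regression on the target phenotype (Nagelkerke R^2,
#' likelihood-ratio p) and by AUC with a DeLong interval.
#'
#' @param trainDesign,trainW training [CohortDesign-class] and
#'   [StandardizedMethylation-class].
#' @param targetDesign,targetW target cohort objects.
#' @param targetCovariates optional data.frame of evaluation covariates for
#'   the target logistic model (e.g. sex, predicted age, smoking, cell-type
#'   proportions).
#' @param minOverlap probe-overlap floor passed to [profileScores()].
#' @return list with varianceEstimate, blup, scores, nagelkerke, auc,
#'   probeOverlap.
#' @export
evaluateClassifier <- function(trainDesign, trainW, targetDesign, targetW,
                               targetCovariates = NULL, minOverlap = 0.5) {
  if (length(intersect(trainDesign@sampleIds, targetDesign@sampleIds)))
    warning("sample ids overlap between training and target cohorts")
  ve <- remlFit(trainDesign, computeORM(trainW))
  blup <- blupProbeEffects(trainDesign, trainW, ve)
  scores <- profileScores(targetW, blup, minOverlap = minOverlap)
  nk <- nagelkerkeR2(targetDesign@y, scores$z, targetCovariates)
  auc <- aucWithCI(targetDesign@y, scores$z)
  list(varianceEstimate = ve, blup = blup, scores = scores,
       nagelkerke = nk, auc = auc,
       probeOverlap = S4Vectors::metadata(scores)$overlap)
}
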