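## Reference-based cell-type deconvolution and cell-type-proportion analyses
## (case-control differences, medication-dose correlations).

#' Estimate blood cell-type proportions by constrained projection
#'
#' Reference-based deconvolution in the Houseman tradition: for each sample,
#' solves min ||R p - beta||^2 subject to p >= 0 over the reference probes
#' (nonnegative least squares), then normalizes p to sum to 1. A
#' \code{granulocyte} column (eosinophils + neutrophils) is appended when
#' both types are present in the reference.
#'
#' @param M a [MethylationSet-class] or probes x samples beta matrix; only
#'   probes present in the reference are used (ids must align).
#' @param reference probes x cell-types matrix of mean beta values (e.g. from
#'   [simulateCellTypeReference()]).
#' @return data.frame of per-sample proportions (one column per cell type,
#'   plus \code{granulocyte} when applicable), rownames = sample ids.
#' @examples
#' ref <- simulateCellTypeReference(7, 60, separation = 2, seed = 1)
#' props <- rbind(c(0.1, 0.15, 0.1, 0.05, 0.08, 0.02, 0.5),
#'                c(0.2, 0.2, 0.1, 0.1, 0.1, 0.05, 0.25))
#' mix <- ref %*% t(props)
#' colnames(mix) <- paste0("s", 1:2)
#' estimateCellProportions(mix, ref)
#' @export
estimateCellProportions <- function(M, reference) {
  beta <- if (is(M, "MethylationSet")) betaValues(M) else as.matrix(M)
  reference <- as.matrix(reference)
  if (ncol(reference) < 2) stop("reference must contain at least 2 cell types")
  if (nrow(reference) < ncol(reference))
    stop("need at least as many reference probes as cell types")
  if (qr(reference)$rank < ncol(reference))
    stop("rank-deficient reference: cell-type signatures are collinear")
  common <- intersect(rownames(reference), rownames(beta))
  if (length(common) < ncol(reference))
    stop("probe ids of the sample matrix do not align with the reference ",
         sprintf("(%d shared probes)", length(common)))
  R <- reference[common, , drop = FALSE]
  B <- beta[common, , drop = FALSE]
  props <- t(apply(B, 2, function(b) {
    ok <- !is.na(b)
    p <- pracma::lsqnonneg(R[ok, , drop = FALSE], b[ok])$x
    s <- sum(p)
    if (s <= 0) rep(NA_real_, ncol(R)) else p / s
  }))
  colnames(props) <- colnames(reference)
  out <- as.data.frame(props)
  if (all(c("eos", "neu") %in% colnames(out)))
    out$granulocyte <- out$eos + out$neu
  rownames(out) <- colnames(beta)
  out
}

.checkSeparation <- function(fit) {
  probs <- fitted(fit)
  isTRUE(any(probs > 1 - 1e-8) || any(probs < 1e-8)) &&
    any(abs(coef(fit)) > 15, na.rm = TRUE)
}

#' Test cell-type proportions for association with case status
#'
#' One logistic model per cell type: status ~ covariates + proportion, with a
#' Wald test on the proportion term. The granulocyte composite is tested like
#' any other column when present.
#'
#' @param y 0/1 case status.
#' @param ctp data.frame of proportions as returned by
#'   [estimateCellProportions()].
#' @param covariates data.frame of adjustment covariates (typically sex and
#'   predicted age), row-aligned with \code{y}.
#' @return data.frame with cellType, estimate (log-odds per unit proportion),
#'   se, z, p. Perfectly separated fits are flagged with p = NA.
#' @export
testCtpAssociation <- function(y, ctp, covariates = NULL) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("no variation in outcome y")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  ctp <- as.data.frame(ctp)
  out <- lapply(colnames(ctp), function(ct) {
    dat <- data.frame(y = y, x = ctp[[ct]])
    if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
    fit <- suppressWarnings(glm(y ~ ., data = dat, family = binomial()))
    cf <- summary(fit)$coefficients
    sep <- .checkSeparation(fit)
    data.frame(cellType = ct, estimate = cf["x", 1], se = cf["x", 2],
               z = cf["x", 3], p = if (sep) NA_real_ else cf["x", 4],
               separated = sep, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Preprocess levodopa-equivalent daily dose records
#'
#' Ranges are replaced by their midpoint, values are natural-log transformed
#' (the dose distribution is right skewed) and z-standardized over the
#' non-missing values.
#'
#' @param records data.frame with either a \code{ledd} column (mg/day) or
#'   \code{leddLow}/\code{leddHigh} range columns (a row may use either);
#'   optional \code{duration} (disease duration, years) is carried through.
#' @return The input with columns \code{ledd} (midpoint-resolved raw dose)
#'   and \code{leddStd} (log-transformed, standardized).
#' @examples
#' preprocessLEDD(data.frame(leddLow = c(530, NA, 200),
#'                           leddHigh = c(1800, NA, 400),
#'                           ledd = c(NA, 700, NA)))
#' @export
preprocessLEDD <- function(records) {
  records <- as.data.frame(records)
  ledd <- if ("ledd" %in% colnames(records)) records$ledd
          else rep(NA_real_, nrow(records))
  if (all(c("leddLow", "leddHigh") %in% colnames(records))) {
    useRange <- is.na(ledd) & !is.na(records$leddLow) & !is.na(records$leddHigh)
    ledd[useRange] <- (records$leddLow[useRange] + records$leddHigh[useRange]) / 2
  }
  if (all(is.na(ledd))) stop("no non-missing LEDD values")
  if (any(ledd <= 0, na.rm = TRUE))
    stop("LEDD must be positive (mg/day)")
  lg <- log(ledd)
  s <- sd(lg, na.rm = TRUE)
  if (is.na(s) || s == 0)
    stop("cannot standardize LEDD: zero variance across samples")
  records$ledd <- ledd
  records$leddStd <- (lg - mean(lg, na.rm = TRUE)) / s
  records
}

#' Correlate cell-type proportions with medication dose
#'
#' Pearson correlation of each tested cell type with (processed) LEDD among
#' cases, optionally residualizing both variables on disease duration first.
#' The Bonferroni threshold 0.05 / (number of tested types) is reported
#' alongside. The default tested set is the seven blood types minus
#' eosinophils.
#'
#' @param ctp data.frame of proportions (cases only).
#' @param ledd numeric processed dose (e.g. \code{leddStd} from
#'   [preprocessLEDD()]), aligned with \code{ctp} rows.
#' @param adjustFor \code{"none"} or \code{"disease_duration"}.
#' @param duration numeric disease duration (years), required when adjusting.
#' @param cellTypes character, the tested set.
#' @return data.frame cellType, r, p, n, plus attributes
#'   \code{bonferroni} and \code{adjusted}.
#' @export
correlateCtpLedd <- function(ctp, ledd,
                             adjustFor = c("none", "disease_duration"),
                             duration = NULL,
                             cellTypes = c("B", "CD4T", "CD8T", "NK",
                                           "mono", "neu")) {
  adjustFor <- match.arg(adjustFor)
  ctp <- as.data.frame(ctp)
  cellTypes <- intersect(cellTypes, colnames(ctp))
  if (!length(cellTypes)) stop("none of the requested cell types are present")
  out <- lapply(cellTypes, function(ct) {
    x <- ctp[[ct]]; z <- ledd
    ok <- !is.na(x) & !is.na(z)
    if (adjustFor == "disease_duration") {
      if (is.null(duration)) stop("duration required for adjustment")
      ok <- ok & !is.na(duration)
      x[ok] <- resid(stats::lm(x[ok] ~ duration[ok]))
      z[ok] <- resid(stats::lm(z[ok] ~ duration[ok]))
    }
    if (sum(ok) < 3) stop("fewer than 3 complete pairs for ", ct)
    ct_test <- cor.test(x[ok], z[ok])
    data.frame(cellType = ct, r = unname(ct_test$estimate),
               p = ct_test$p.value, n = sum(ok), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "bonferroni") <- 0.05 / length(cellTypes)
  attr(res, "adjusted") <- adjustFor
  res
}

#' Compare cell-type differences between dose-extreme cases and controls
#'
#' Runs [testCtpAssociation()] twice: controls versus the most-exposed cases
#' (top \code{quantile} of dose) and controls versus the least-exposed cases
#' (bottom \code{quantile}). Similar estimates in the two strata argue
#' against a medication explanation for case-control composition differences.
#'
#' @param y 0/1 status for all samples.
#' @param ctp proportions for all samples.
#' @param ledd dose values (NA for controls is fine; only case doses are used).
#' @param quantile stratum size as a fraction of cases, in (0, 0.5].
#' @param covariates optional adjustment covariates.
#' @param minStratum minimum cases per stratum (default 10).
#' @return list with elements \code{top} and \code{bottom}, each a
#'   [testCtpAssociation()] table, plus \code{nTop}/\code{nBottom}.
#' @export
compareExposureExtremes <- function(y, ctp, ledd, quantile = 0.10,
                                    covariates = NULL, minStratum = 10L) {
  .assertScalarNumber(quantile, "quantile")
  if (quantile <= 0 || quantile > 0.5)
    stop("'quantile' must lie in (0, 0.5]")
  y <- as.numeric(y)
  cases <- which(y == 1 & !is.na(ledd))
  controls <- which(y == 0)
  if (!length(cases)) stop("empty stratum: no cases with dose data")
  qs <- stats::quantile(ledd[cases], c(quantile, 1 - quantile))
  bottom <- cases[ledd[cases] <= qs[1]]
  top <- cases[ledd[cases] >= qs[2]]
  if (length(bottom) < minStratum || length(top) < minStratum)
    stop(sprintf("stratum too small (top %d, bottom %d; need >= %d)",
                 length(top), length(bottom), minStratum))
  runStratum <- function(strat) {
    idx <- c(controls, strat)
    testCtpAssociation(y[idx], ctp[idx, , drop = FALSE],
                       if (!is.null(covariates))
                         as.data.frame(covariates)[idx, , drop = FALSE])
  }
  list(top = runStratum(top), bottom = runStratum(bottom),
       nTop = length(top), nBottom = length(bottom))
}
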