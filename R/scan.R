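## Per-probe association scans: initial least squares, the mixed-model test
## with the target probe fitted both fixed and random (MOA), and the
## two-random-component variant that excludes probes near the target
## (MOMENT). Effects are reported on the unstandardized beta scale of the
## phenotype regression, with the probe SD recorded so standardized effects
## are recoverable.

.annLookup <- function(ann, probes) {
  if (is.null(ann))
    return(data.frame(probe = probes, chrom = NA_character_, bp = NA_integer_,
                      gene = NA_character_, stringsAsFactors = FALSE))
  ann <- as.data.frame(ann)
  idx <- match(probes, ann$probe)
  if (anyNA(idx)) stop("annotation missing probes: ",
                       paste(head(probes[is.na(idx)], 5L), collapse = ", "))
  data.frame(probe = probes, chrom = as.character(ann$chrom[idx]),
             bp = ann$bp[idx],
             gene = if ("gene" %in% colnames(ann)) ann$gene[idx] else NA,
             stringsAsFactors = FALSE)
}

.assembleRecords <- function(probes, bStd, seStd, z, p, probeSDs, ann, method,
                             df = NA_real_) {
  out <- .annLookup(ann, probes)
  out$b <- bStd / probeSDs
  out$se <- seStd / probeSDs
  out$probeSD <- probeSDs
  out$bStd <- bStd
  out$seStd <- seStd
  out$z <- z
  out$p <- p
  out$method <- method
  out
}

#' Initial least-squares association scan
#'
#' For each probe, ordinary least squares of y on the fixed covariates plus
#' that probe's standardized values, with a Wald t test on the probe term.
#' This is the preliminary regression used to partition probes for the
#' multi-component scan.
#'
#' @param design a [CohortDesign-class].
#' @param W a [StandardizedMethylation-class].
#' @param ann optional probe annotation data.frame
#'   (probe/chrom/bp/gene columns).
#' @return data.frame with one row per probe: probe, chrom, bp, gene,
#'   b and se (unstandardized, per unit beta), probeSD, bStd/seStd
#'   (per-SD-of-probe scale), z, p, method. Probes collinear with the
#'   covariates are flagged with p = NA.
#' @export
olsScan <- function(design, W, ann = NULL) {
  stopifnot(is(design, "CohortDesign"), is(W, "StandardizedMethylation"))
  y <- design@y; C <- design@covariates
  Wm <- stdMatrix(W)
  n <- length(y); p <- ncol(C)
  qrC <- qr(C)
  ry <- qr.resid(qrC, y)
  RW <- qr.resid(qrC, Wm)
  wss <- colSums(RW^2)
  ok <- wss > 1e-10 * n
  b <- rep(NA_real_, ncol(Wm)); seB <- tval <- pval <- b
  b[ok] <- colSums(RW[, ok, drop = FALSE] * ry) / wss[ok]
  rss <- sum(ry^2) - b[ok]^2 * wss[ok]
  df <- n - p - 1
  sigma2 <- rss / df
  seB[ok] <- sqrt(sigma2 / wss[ok])
  tval[ok] <- b[ok] / seB[ok]
  pval[ok] <- 2 * stats::pt(-abs(tval[ok]), df)
  .assembleRecords(colnames(Wm), b, seB, tval, pval, W@probeSDs, ann, "OLS")
}

#' Mixed-model association scan (target probe fixed and random)
#'
#' Variance components are estimated once by REML under the all-probe model
#' (the tested probe remains part of the genome-wide random effect), then
#' every probe is tested by generalized least squares of y on
#' [covariates, probe] with the phenotypic covariance
#' V = A sigma^2_o + I sigma^2_e held fixed — the standard two-step
#' ("population parameters previously determined") strategy.
#'
#' @param design a [CohortDesign-class].
#' @param W a [StandardizedMethylation-class].
#' @param ann optional probe annotation.
#' @param varianceEstimate optional precomputed [remlFit()] result; fitted
#'   from the data when NULL.
#' @return data.frame of association records (see [olsScan()]); z is a Wald
#'   statistic referred to the standard normal.
#' @export
moaScan <- function(design, W, ann = NULL, varianceEstimate = NULL) {
  stopifnot(is(design, "CohortDesign"), is(W, "StandardizedMethylation"))
  Wm <- stdMatrix(W)
  y <- design@y; C <- design@covariates
  n <- length(y)
  if (is.null(varianceEstimate))
    varianceEstimate <- remlFit(design, computeORM(W))
  so <- varianceEstimate@sigmaO; se <- varianceEstimate@sigmaE
  V <- so * tcrossprod(Wm) / ncol(Wm) + diag(se, n)
  L <- chol(V)                     # V = L'L, whiten with backsolve
  yw <- backsolve(L, y, transpose = TRUE)
  Cw <- backsolve(L, C, transpose = TRUE)
  Ww <- backsolve(L, Wm, transpose = TRUE)
  qrC <- qr(Cw)
  ry <- qr.resid(qrC, yw)
  RW <- qr.resid(qrC, Ww)
  wss <- colSums(RW^2)
  ok <- wss > 1e-12 * n
  b <- rep(NA_real_, ncol(Wm)); seB <- z <- pv <- b
  b[ok] <- colSums(RW[, ok, drop = FALSE] * ry) / wss[ok]
  seB[ok] <- 1 / sqrt(wss[ok])    # V treated as known
  z[ok] <- b[ok] / seB[ok]
  pv[ok] <- 2 * pnorm(-abs(z[ok]))
  out <- .assembleRecords(colnames(Wm), b, seB, z, pv, W@probeSDs, ann, "MOA")
  attr(out, "varianceEstimate") <- varianceEstimate
  out
}

#' Partition probes into two groups by preliminary association strength
#'
#' Group 1 holds probes whose initial-scan p-value is below
#' \code{thresholdP}; group 2 the remainder. A threshold of 1 (or more)
#' assigns every probe to group 1, a threshold of 0 assigns every probe to
#' group 2.
#'
#' @param initial association table from [olsScan()].
#' @param thresholdP partition threshold (default 0.01).
#' @return list with \code{group} (named integer vector of 1/2),
#'   \code{thresholdP} and \code{pValues}.
#' @export
partitionProbes <- function(initial, thresholdP = 0.01) {
  p <- initial$p
  group <- ifelse(!is.na(p) & (p < thresholdP | thresholdP >= 1), 1L, 2L)
  names(group) <- initial$probe
  list(group = group, thresholdP = thresholdP,
       pValues = setNames(p, initial$probe))
}

#' Multi-component mixed-model scan excluding the target's neighbourhood
#'
#' The two-random-component model: probes are split by preliminary
#' association strength (see [partitionProbes()]); variance components for
#' the two groups plus the residual are estimated once by REML without any
#' window exclusion; then, for each target probe, all probes on the same
#' chromosome within \code{windowBp} of the target (the target included) are
#' removed from both random components by an exact low-rank downdate of the
#' covariance (Woodbury identity) and the target is tested as a fixed effect
#' by generalized least squares.
#'
#' If group 1 is empty the model collapses to a single random component with
#' a warning.
#'
#' @param design a [CohortDesign-class].
#' @param W a [StandardizedMethylation-class].
#' @param ann probe annotation with chrom and bp (required for the window).
#' @param partition optional [partitionProbes()] result; computed from an
#'   internal [olsScan()] when NULL.
#' @param windowBp exclusion window (default 50000; probes strictly closer
#'   than this are excluded).
#' @param thresholdP partition threshold when \code{partition} is NULL.
#' @param varComponents optional fixed variance components (numeric vector:
#'   one per-probe variance per non-empty group, then the residual), mainly
#'   for limiting-case checks; estimated by REML when NULL.
#' @return data.frame of association records (method \code{"MOMENT"}).
#' @export
momentScan <- function(design, W, ann, partition = NULL, windowBp = 50000,
                       thresholdP = 0.01, varComponents = NULL) {
  stopifnot(is(design, "CohortDesign"), is(W, "StandardizedMethylation"))
  if (is.null(ann)) stop("probe annotation with positions is required")
  Wm <- stdMatrix(W)
  probes <- colnames(Wm)
  loc <- .annLookup(ann, probes)
  if (anyNA(loc$bp)) stop("annotation missing positions for tested probes")
  y <- design@y; C <- design@covariates
  n <- length(y); m <- ncol(Wm)

  if (is.null(partition))
    partition <- partitionProbes(olsScan(design, W, ann), thresholdP)
  group <- partition$group[probes]
  g1 <- which(group == 1L); g2 <- which(group == 2L)
  if (!length(g1)) {
    warning("empty first component; collapsing to a single random component")
  }
  comps <- Filter(function(ix) length(ix) > 0, list(g1 = g1, g2 = g2))
  Klist <- lapply(comps, function(ix) tcrossprod(Wm[, ix, drop = FALSE]))
  if (is.null(varComponents)) {
    fit <- .remlVarComp(y, C, Klist)
    su <- setNames(fit$s[seq_along(comps)], names(comps))  # per-probe variances
    sigE <- fit$s[length(fit$s)]
  } else {
    ## accept a two-group specification even when one group is empty: the
    ## residual is always the last entry
    stopifnot(length(varComponents) >= length(comps) + 1L)
    su <- setNames(varComponents[seq_along(comps)], names(comps))
    sigE <- varComponents[length(varComponents)]
  }

  ## per-probe variance multiplier for downdating
  suProbe <- numeric(m)
  for (nm in names(comps)) suProbe[comps[[nm]]] <- su[nm]

  V <- diag(sigE, n)
  for (j in seq_along(comps)) V <- V + su[j] * Klist[[j]]
  Vinv <- chol2inv(chol(V))
  VinvC <- Vinv %*% C
  Vinvy <- as.vector(Vinv %*% y)
  VinvW <- Vinv %*% Wm
  CtVC <- crossprod(C, VinvC)
  CtVy <- as.vector(crossprod(VinvC, y))
  CtVW <- crossprod(VinvC, Wm)          # p x m
  wVw <- colSums(Wm * VinvW)
  wVy <- as.vector(crossprod(Wm, Vinvy))

  p <- ncol(C)
  bStd <- seStd <- z <- pv <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    S <- which(loc$chrom == loc$chrom[i] & abs(loc$bp - loc$bp[i]) < windowBp)
    S <- S[suProbe[S] > 1e-12]
    if (length(S)) {
      U <- Wm[, S, drop = FALSE]
      VU <- VinvW[, S, drop = FALSE]
      Cap <- diag(1 / suProbe[S], length(S)) - crossprod(U, VU)
      Cs <- tryCatch(solve(Cap), error = function(e) NULL)
      if (is.null(Cs)) next
      CU <- CtVW[, S, drop = FALSE]                    # C' Vinv U
      wU <- crossprod(U, VinvW[, i])                   # U' Vinv w_i (k x 1)
      yU <- wVy[S]                                     # U' Vinv y
      CtViC <- CtVC + CU %*% Cs %*% t(CU)
      CtViw <- CtVW[, i] + as.vector(CU %*% Cs %*% wU)
      CtViy <- CtVy + as.vector(CU %*% Cs %*% yU)
      wtViw <- wVw[i] + drop(crossprod(wU, Cs %*% wU))
      wtViy <- wVy[i] + drop(crossprod(wU, Cs %*% yU))
    } else {
      CtViC <- CtVC; CtViw <- CtVW[, i]; CtViy <- CtVy
      wtViw <- wVw[i]; wtViy <- wVy[i]
    }
    XtX <- rbind(cbind(CtViC, CtViw), c(CtViw, wtViw))
    Xty <- c(CtViy, wtViy)
    sol <- tryCatch(solve(XtX), error = function(e) NULL)
    if (is.null(sol) || sol[p + 1, p + 1] <= 0) next
    coefs <- sol %*% Xty
    bStd[i] <- coefs[p + 1]
    seStd[i] <- sqrt(sol[p + 1, p + 1])
    z[i] <- bStd[i] / seStd[i]
    pv[i] <- 2 * pnorm(-abs(z[i]))
  }
  out <- .assembleRecords(probes, bStd, seStd, z, pv, W@probeSDs, ann, "MOMENT")
  attr(out, "varianceComponents") <- c(su, sigmaE = unname(sigE))
  attr(out, "partition") <- partition
  out
}

#' Genomic inflation factor of an association scan
#'
#' lambda = median of the chi-square (1 df) statistics implied by the
#' p-values, divided by the null median 0.4549364. Values near 1 indicate
#' well-calibrated tests.
#'
#' @param records association data.frame with a \code{p} column, or a
#'   numeric vector of p-values.
#' @param minRecords minimum number of valid p-values (default 30).
#' @return lambda (numeric scalar).
#' @examples
#' genomicInflation(runif(1000))
#' @export
genomicInflation <- function(records, minRecords = 30L) {
  p <- if (is.data.frame(records)) records$p else as.numeric(records)
  p <- p[!is.na(p) & p > 0 & p <= 1]
  if (length(p) < minRecords)
    stop(sprintf("need at least %d valid p-values, got %d", minRecords,
                 length(p)))
  chi <- qchisq(p, df = 1, lower.tail = FALSE)
  unname(median(chi) / qchisq(0.5, df = 1))
}
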