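## Omics relationship matrix, REML variance components (average-information
## updates with an expectation-maximization safeguard), and BLUP probe
## effects.

#' Compute the omics relationship matrix A = WW'/m
#'
#' @param W a [StandardizedMethylation-class] (or an already-standardized
#'   samples x probes matrix).
#' @return An [OmicsRelationshipMatrix-class].
#' @examples
#' sim <- simulateMethylationCohort(simulationConfig(nSamples = 40,
#'                                                   nProbes = 100, seed = 2))
#' A <- computeORM(standardizeProbes(sim$mset))
#' mean(diag(ormMatrix(A)))
#' @export
computeORM <- function(W) {
  Wm <- if (is(W, "StandardizedMethylation")) stdMatrix(W) else as.matrix(W)
  m <- ncol(Wm)
  if (m == 0) stop("cannot build an ORM from zero probes")
  A <- tcrossprod(Wm) / m
  A <- (A + t(A)) / 2
  rownames(A) <- colnames(A) <- rownames(Wm)
  new("OmicsRelationshipMatrix", A = A, m = as.integer(m))
}

## General REML for V = sum_j s_j K_j + s_e I, by average-information updates
## with EM fallback and step halving; log-likelihood is guaranteed
## non-decreasing across accepted steps. Klist may be empty (residual-only
## model, closed form). Returns components, REML log-likelihood (constant
## terms omitted consistently), AI matrix and a per-iteration trace.
.remlVarComp <- function(y, C, Klist, maxit = 100L, tol = 1e-8,
                         startValues = NULL) {
  n <- length(y)
  p <- ncol(C)
  if (n < p + 2) stop("need n >= p + 2 samples for REML")
  K <- length(Klist)
  ## phenotypic variance after fixed effects
  r0 <- stats::lm.fit(C, y)$residuals
  vp <- sum(r0^2) / (n - p)
  lower <- 1e-6 * vp

  llFun <- function(s) {
    V <- diag(s[K + 1], n)
    for (j in seq_len(K)) V <- V + s[j] * Klist[[j]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    VinvC <- Vinv %*% C
    M <- crossprod(C, VinvC)
    chM <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(chM)) return(NULL)
    Minv <- chol2inv(chM)
    Py <- Vinv %*% y - VinvC %*% (Minv %*% crossprod(VinvC, y))
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chM))) +
                    sum(y * Py))
    list(ll = ll, Vinv = Vinv, VinvC = VinvC, Minv = Minv, Py = as.vector(Py))
  }

  if (K == 0L) {
    se <- vp  # REML closed form: RSS / (n - p)
    st <- llFun(se)
    return(list(s = c(sigmaE = se), logLik = st$ll, AI = matrix(2 * se^2 / (n - p)),
                converged = TRUE, iterations = 0L, clamped = FALSE,
                trace = data.frame(iter = 0L, logLik = st$ll)))
  }

  ## per-component lower bounds account for the scale of each K matrix so a
  ## clamped component contributes at most ~1e-6 of the phenotypic variance
  diagScale <- c(vapply(Klist, function(Kj) mean(diag(Kj)), 1), 1)
  lowerVec <- lower / diagScale
  s <- if (!is.null(startValues)) startValues else {
    c(vp / (K + 1) / diagScale[seq_len(K)], vp / (K + 1))
  }
  s <- pmax(s, lowerVec)
  clamped <- FALSE
  trace <- data.frame(iter = integer(), logLik = numeric())
  st <- llFun(s)
  if (is.null(st)) stop("REML: initial covariance not positive definite")
  AI <- NULL
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    Py <- st$Py
    ## gradient and AI pieces; component K+1 is the identity
    q <- vector("list", K + 1L)
    trPK <- numeric(K + 1L)
    for (j in seq_len(K)) {
      q[[j]] <- as.vector(Klist[[j]] %*% Py)
      trPK[j] <- sum(st$Vinv * Klist[[j]]) -
        sum(st$Minv * (crossprod(st$VinvC, Klist[[j]] %*% st$VinvC)))
    }
    q[[K + 1L]] <- Py
    trPK[K + 1L] <- sum(diag(st$Vinv)) - sum(st$Minv * crossprod(st$VinvC))
    yPKPy <- vapply(q, function(qj) sum(Py * qj), 1)
    grad <- -0.5 * (trPK - yPKPy)
    Q <- vapply(q, identity, numeric(n))
    Pq <- vapply(q, function(qj) {
      as.vector(st$Vinv %*% qj - st$VinvC %*% (st$Minv %*% crossprod(st$VinvC, qj)))
    }, numeric(n))
    AI <- 0.5 * crossprod(Q, Pq)
    AI <- (AI + t(AI)) / 2

    ## freeze components sitting on their lower bound whose gradient points
    ## further down (active-set handling of the boundary)
    atBound <- s <= lowerVec * (1 + 1e-8)
    active <- which(!(atBound & grad < 0))
    if (!length(active)) { converged <- TRUE; break }

    step <- rep(0, K + 1L)
    stepA <- tryCatch(solve(AI[active, active, drop = FALSE], grad[active]),
                      error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(stepA)) {
      step[active] <- stepA
      fac <- 1
      for (half in 1:6) {
        sNew <- pmax(s + fac * step, lowerVec)
        stNew <- llFun(sNew)
        if (!is.null(stNew) && stNew$ll >= st$ll - 1e-10) {
          accepted <- TRUE; break
        }
        fac <- fac / 2
      }
    }
    if (!accepted) {
      ## EM-REML fallback step (monotone), frozen components held
      emStep <- (s^2 / n) * (yPKPy - trPK)
      emStep[setdiff(seq_len(K + 1L), active)] <- 0
      sNew <- pmax(s + emStep, lowerVec)
      stNew <- llFun(sNew)
      if (is.null(stNew)) break
    }
    delta <- stNew$ll - st$ll
    s <- sNew; st <- stNew
    trace <- rbind(trace, data.frame(iter = it, logLik = st$ll))
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  if (!converged && it >= maxit)
    warning(sprintf("REML did not converge after %d iterations (trace attached)",
                    maxit))
  clamped <- any(s <= lowerVec * (1 + 1e-9))
  names(s) <- c(if (K > 0) paste0("sigmaK", seq_len(K)), "sigmaE")
  list(s = s, logLik = st$ll, AI = AI, converged = converged,
       iterations = it, clamped = clamped,
       trace = trace, vp = vp, Vinv = st$Vinv, VinvC = st$VinvC,
       Minv = st$Minv, Py = st$Py)
}

#' REML estimation of the variance captured by all probes
#'
#' Fits the single-random-effect mixed model y = C beta + g + e with
#' var(g) = A sigma^2_o, var(e) = I sigma^2_e by restricted maximum
#' likelihood (average-information updates, expectation-maximization
#' fallback, step halving; convergence when the log-likelihood moves by less
#' than \code{tol}). Negative components are clamped at 1e-6 times the
#' phenotypic variance and flagged. The probe-captured fraction
#' rho^2 = sigma^2_o / (sigma^2_o + sigma^2_e) gets a delta-method standard
#' error from the inverse average-information matrix, and a p-value from the
#' 0.5 chi2_0 + 0.5 chi2_1 mixture likelihood-ratio test against
#' sigma^2_o = 0 (this package's convention for testing a boundary
#' parameter).
#'
#' A binary phenotype is analysed as 0/1 on the observed scale; no liability
#' transformation is applied.
#'
#' @param design a [CohortDesign-class].
#' @param orm an [OmicsRelationshipMatrix-class].
#' @param maxit,tol iteration controls.
#' @return A [VarianceEstimate-class].
#' @export
remlFit <- function(design, orm, maxit = 100L, tol = 1e-8) {
  stopifnot(is(design, "CohortDesign"), is(orm, "OmicsRelationshipMatrix"))
  y <- design@y; C <- design@covariates
  if (nrow(ormMatrix(orm)) != length(y))
    stop("ORM dimension does not match the design")
  fit <- .remlVarComp(y, C, list(ormMatrix(orm)), maxit = maxit, tol = tol)
  s <- fit$s
  so <- s[1]; se <- s[2]
  rho <- so / (so + se)
  ## delta method: d rho / d(so, se) = (se, -so) / (so + se)^2
  Sigma <- tryCatch(solve(fit$AI), error = function(e)
    matrix(NA_real_, 2, 2))
  gvec <- c(se, -so) / (so + se)^2
  seRho <- sqrt(max(drop(t(gvec) %*% Sigma %*% gvec), 0))
  ses <- c(sigmaO = sqrt(max(Sigma[1, 1], 0)),
           sigmaE = sqrt(max(Sigma[2, 2], 0)), rho2 = seRho)
  null <- .remlVarComp(y, C, list(), maxit = maxit, tol = tol)
  lrt <- 2 * (fit$logLik - null$logLik)
  pLRT <- if (lrt <= 0) 1 else 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
  new("VarianceEstimate", sigmaO = unname(so), sigmaE = unname(se),
      rho2 = unname(rho), se = ses, logLik = fit$logLik, pLRT = pLRT,
      converged = fit$converged, iterations = as.integer(fit$iterations),
      trace = fit$trace, clamped = fit$clamped)
}

#' Grid evaluation of the REML log-likelihood
#'
#' Direct evaluation of the restricted log-likelihood over a grid of
#' (sigma^2_o, sigma^2_e) values; used as an independent check of the
#' iterative fit on small problems.
#'
#' @param design a [CohortDesign-class].
#' @param orm an [OmicsRelationshipMatrix-class].
#' @param sigmaO,sigmaE numeric grids.
#' @return data.frame sigmaO, sigmaE, logLik.
#' @export
remlLogLikGrid <- function(design, orm, sigmaO, sigmaE) {
  y <- design@y; C <- design@covariates; A <- ormMatrix(orm)
  n <- length(y)
  grid <- expand.grid(sigmaO = sigmaO, sigmaE = sigmaE)
  grid$logLik <- vapply(seq_len(nrow(grid)), function(i) {
    V <- grid$sigmaO[i] * A + diag(grid$sigmaE[i], n)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NA_real_)
    Vinv <- chol2inv(ch)
    VinvC <- Vinv %*% C
    M <- crossprod(C, VinvC)
    chM <- chol(M)
    Py <- Vinv %*% y - VinvC %*% (chol2inv(chM) %*% crossprod(VinvC, y))
    -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chM))) + sum(y * Py))
  }, 1)
  grid
}

#' BLUP solutions for the joint probe effects
#'
#' Computes u-hat = (sigma^2_o / m) W' V^{-1} (y - C beta-hat) with
#' V = A sigma^2_o + I sigma^2_e and beta-hat the generalized-least-squares
#' fixed effects; these are the shrinkage estimates of every probe's effect
#' under the all-probe model, used to score external samples.
#'
#' @param design a [CohortDesign-class].
#' @param W a [StandardizedMethylation-class].
#' @param varianceEstimate a converged [VarianceEstimate-class] from
#'   [remlFit()] on the same data.
#' @return A [BLUPEffects-class].
#' @export
blupProbeEffects <- function(design, W, varianceEstimate) {
  stopifnot(is(W, "StandardizedMethylation"),
            is(varianceEstimate, "VarianceEstimate"))
  if (!varianceEstimate@converged)
    stop("variance estimation did not converge; refusing to compute BLUPs")
  Wm <- stdMatrix(W)
  y <- design@y; C <- design@covariates
  n <- length(y); m <- ncol(Wm)
  so <- varianceEstimate@sigmaO; se <- varianceEstimate@sigmaE
  stopifnot(se > 0)
  V <- (so / m) * tcrossprod(Wm) + diag(se, n)
  ch <- chol(V)
  Vinv <- chol2inv(ch)
  VinvC <- Vinv %*% C
  betaHat <- solve(crossprod(C, VinvC), crossprod(VinvC, y))
  r <- as.vector(Vinv %*% (y - C %*% betaHat))
  u <- (so / m) * as.vector(crossprod(Wm, r))
  names(u) <- colnames(Wm)
  new("BLUPEffects", u = u, sigmaO = so, sigmaE = se)
}
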