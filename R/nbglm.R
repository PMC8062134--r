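#' Negative-binomial log-likelihood
#'
#' Log-likelihood of counts under the gamma-Poisson model with mean `mu`
#' and overdispersion `theta` (`Var(Y) = mu + mu^2 / theta`):
#' \deqn{\ell(\beta,\theta) = -\sum_n \big[(y_n+\theta)\log(\mu_n+\theta)
#'   - y_n\log\mu_n + \log\Gamma(y_n+1) - \theta\log\theta
#'   + \log\Gamma(\theta) - \log\Gamma(\theta+y_n)\big].}
#'
#' @param y non-negative integer counts.
#' @param mu fitted means (recycled).
#' @param theta overdispersion, > 0.
#' @return scalar log-likelihood.
#' @export
nbLogLik <- function(y, mu, theta) {
  logmu <- ifelse(y == 0, 0, log(mu))  # y*log(mu): 0*log(0) := 0
  -sum((y + theta) * log(mu + theta) - y * logmu + lgamma(y + 1) -
         theta * log(theta) + lgamma(theta) - lgamma(theta + y))
}

# one IRLS run for fixed theta; log link. Step-halves whenever a full IRLS
# step fails to improve the likelihood, so convergence is guaranteed to a
# stationary point (at the cost of speed on hard cases).
.irlsNb <- function(y, X, theta, beta = NULL, maxit = 50, tol = 1e-8,
                    etaClamp = 30) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(beta)) {
    beta <- rep(0, p)
    beta[1] <- log(mean(y) + 0.1)  # intercept start at the count mean
  }
  eta <- pmin(pmax(drop(X %*% beta), -etaClamp), etaClamp)
  mu <- exp(eta)
  ll <- nbLogLik(y, mu, theta)
  converged <- FALSE
  flagged <- FALSE
  for (it in seq_len(maxit)) {
    w <- mu * theta / (theta + mu)
    z <- eta + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    betaNew <- fit$coefficients
    if (anyNA(betaNew)) stop("model matrix is rank deficient")
    step <- betaNew - beta
    lam <- 1
    repeat {
      bTry <- beta + lam * step
      etaTry <- drop(X %*% bTry)
      if (max(abs(etaTry)) > etaClamp) {
        etaTry <- pmin(pmax(etaTry, -etaClamp), etaClamp)
        flagged <- TRUE
      }
      llTry <- nbLogLik(y, exp(etaTry), theta)
      if (is.finite(llTry) && llTry >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) { llTry <- ll; bTry <- beta; etaTry <- eta; break }
    }
    improved <- llTry - ll
    beta <- bTry; eta <- etaTry; mu <- exp(eta); ll <- llTry
    if (abs(improved) < tol * (abs(ll) + 1)) { converged <- TRUE; break }
  }
  list(beta = beta, mu = mu, logLik = ll, converged = converged,
       flagged = flagged, iterations = it)
}

# profile-likelihood update of theta given mu
.mlTheta <- function(y, mu, lower = 1e-3, upper = 1e7) {
  f <- function(lt) nbLogLik(y, mu, exp(lt))
  opt <- stats::optimize(f, c(log(lower), log(upper)), maximum = TRUE,
                         tol = 1e-8)
  exp(opt$maximum)
}

#' Fit a negative-binomial GLM with log link
#'
#' Maximizes the likelihood [nbLogLik()] by iteratively reweighted least
#' squares. With `theta` supplied, only the coefficients are estimated;
#' otherwise the fit alternates IRLS for the coefficients with a profile
#' maximum-likelihood update of `theta` until the joint log-likelihood
#' stabilizes. Every IRLS step is guarded by step-halving, trading speed
#' for certain convergence; linear predictors are clamped at +/-30 (means
#' between ~1e-13 and ~1e13) and fits that hit the clamp are flagged.
#'
#' @param y non-negative integer counts.
#' @param X model matrix (first column typically the intercept).
#' @param theta optional fixed overdispersion; if `NULL`, estimated by
#'   maximum likelihood.
#' @param beta optional starting coefficients (warm start).
#' @param maxit maximum IRLS iterations per round (default 50).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @return An object of class `"NBFit"`: list with `beta`, `theta`,
#'   `logLik`, `mu`, `converged`, `flagged`, `thetaEstimated`.
#' @examples
#' set.seed(1)
#' y <- rnbinom(500, size = 2, mu = exp(1))
#' fit <- fitNbGlm(y, cbind(intercept = rep(1, 500)))
#' c(fit$beta, fit$theta)
#' @export
fitNbGlm <- function(y, X, theta = NULL, beta = NULL, maxit = 50,
                     tol = 1e-8) {
  X <- as.matrix(X)
  if (any(y < 0) || any(y != floor(y)))
    stop("y must be non-negative integer counts")
  if (nrow(X) <= ncol(X))
    stop("need more observations than coefficients")
  if (qr(X)$rank < ncol(X)) stop("model matrix is rank deficient")
  estimateTheta <- is.null(theta)
  if (estimateTheta) {
    # moment start for theta
    m <- mean(y); v <- stats::var(y)
    theta <- if (v > m) m^2 / (v - m) else 100
    theta <- min(max(theta, 1e-3), 1e6)
  }
  fit <- .irlsNb(y, X, theta, beta = beta, maxit = maxit, tol = tol)
  if (estimateTheta) {
    for (round in 1:25) {
      thetaNew <- .mlTheta(y, fit$mu)
      fitNew <- .irlsNb(y, X, thetaNew, beta = fit$beta, maxit = maxit,
                        tol = tol)
      done <- abs(fitNew$logLik - fit$logLik) <
        tol * (abs(fitNew$logLik) + 1)
      theta <- thetaNew; fit <- fitNew
      if (done) break
    }
  }
  structure(list(beta = fit$beta, theta = theta, logLik = fit$logLik,
                 mu = fit$mu, converged = fit$converged,
                 flagged = fit$flagged,
                 thetaEstimated = estimateTheta),
            class = "NBFit")
}

#' @export
print.NBFit <- function(x, ...) {
  cat("NBFit: logLik =", format(x$logLik), " theta =", format(x$theta),
      if (x$thetaEstimated) "(ML)" else "(fixed)", "\n")
  print(x$beta)
  invisible(x)
}

#' Likelihood-ratio statistic, LOD score and p-value
#'
#' For nested fits, the likelihood-ratio statistic is
#' `-2 (lReduced - lFull)`; the LOD score divides it by `2 ln 10`, and the
#' p-value assumes a chi-squared distribution with `df` degrees of freedom.
#' A slightly negative statistic within numerical slack is clipped to zero;
#' beyond the slack it is an error (the reduced model should be refit).
#'
#' @param lFull,lReduced log-likelihoods of the full and reduced models.
#' @param df degrees of freedom (default 1).
#' @param slack numerical tolerance for a negative statistic (default 1e-6).
#' @return list with `lrt`, `lod`, `p`.
#' @examples
#' lrtLod(-100, -100 - 4.60517 / 2)  # LOD 1
#' @export
lrtLod <- function(lFull, lReduced, df = 1, slack = 1e-6) {
  lrt <- -2 * (lReduced - lFull)
  if (lrt < -slack)
    stop("negative likelihood-ratio statistic (", format(lrt),
         "): full model fits worse than reduced; refit required")
  lrt <- max(lrt, 0)
  list(lrt = lrt, lod = lrt / (2 * log(10)),
       p = stats::pchisq(lrt, df = df, lower.tail = FALSE))
}
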