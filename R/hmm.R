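## Variational-Bayes Gaussian-emission HMM (vbFRET-style) and a
## maximum-likelihood Baum-Welch baseline.
##
## Conjugate model: Dirichlet priors on the initial distribution and each
## transition-matrix row, Normal-Gamma prior on each state's emission mean
## and precision.  The E-step runs forward-backward under the expected
## natural parameters (exp of expected logs); the M-step applies the
## conjugate hyperparameter updates.  The evidence lower bound is
## ln Z_tilde - KL(q||p) over all parameter blocks and is non-decreasing
## across iterations.

#' Priors for the variational HMM
#'
#' Weakly informative defaults: symmetric Dirichlet concentration 1 on the
#' initial distribution and transition rows; emission-mean prior centred at
#' E = 0.5 with weak coupling (beta0 = 0.25); broad Gamma precision prior
#' (shape 1, rate 0.01, i.e. prior sd ~ 0.1 but nearly flat).
#'
#' @param dirTrans,dirInit Dirichlet concentrations
#' @param m0,beta0 emission mean prior location and precision scaling
#' @param a0,b0 Gamma shape/rate for the emission precision
#' @return list of hyperparameters
#' @export
vbPriors <- function(dirTrans = 1, dirInit = 1, m0 = 0.5, beta0 = 0.25,
    a0 = 1, b0 = 0.01) {
  stopifnot(dirTrans > 0, dirInit > 0, beta0 > 0, a0 > 0, b0 > 0)
  list(dirTrans = dirTrans, dirInit = dirInit, m0 = m0, beta0 = beta0,
    a0 = a0, b0 = b0)
}

.klDirichlet <- function(aq, ap) {
  lgamma(sum(aq)) - sum(lgamma(aq)) - lgamma(sum(ap)) + sum(lgamma(ap)) +
    sum((aq - ap) * (digamma(aq) - digamma(sum(aq))))
}

.klNormalGamma <- function(m, beta, a, b, m0, beta0, a0, b0) {
  Elam <- a / b
  kln <- 0.5 * log(beta / beta0) - 0.5 + 0.5 * beta0 * (1 / beta + Elam * (m - m0)^2)
  klg <- (a - a0) * digamma(a) - lgamma(a) + lgamma(a0) +
    a0 * (log(b) - log(b0)) + a * (b0 - b) / b
  kln + klg
}

## one VBEM run from an initial hard assignment of points to states
.vbemRun <- function(x, K, pr, maxIter, tol, muInit) {
  T <- length(x)
  assign0 <- max.col(-abs(outer(x, muInit, "-")), ties.method = "first")
  gamma <- matrix(0, T, K); gamma[cbind(seq_len(T), assign0)] <- 1
  xiSum <- matrix(0, K, K)
  if (T > 1) {
    tr <- table(factor(assign0[-T], 1:K), factor(assign0[-1], 1:K))
    xiSum <- matrix(as.numeric(tr), K, K)
  }

  mstep <- function(gamma, xiSum) {
    Nk <- colSums(gamma)
    xbar <- as.numeric(crossprod(gamma, x))
    xbar <- ifelse(Nk > 1e-12, xbar / Nk, pr$m0)
    Sk <- colSums(gamma * (outer(x, xbar, "-"))^2)
    Sk <- ifelse(Nk > 1e-12, Sk / Nk, 0)
    beta <- pr$beta0 + Nk
    m <- (pr$beta0 * pr$m0 + Nk * xbar) / beta
    a <- pr$a0 + Nk / 2
    b <- pr$b0 + 0.5 * (Nk * Sk + pr$beta0 * Nk * (xbar - pr$m0)^2 / beta)
    list(w = pr$dirInit + gamma[1, ], W = pr$dirTrans + xiSum,
      m = m, beta = beta, a = a, b = b)
  }

  q <- mstep(gamma, xiSum)
  elbo <- rep(NA_real_, maxIter)
  for (it in seq_len(maxIter)) {
    ElnPi <- digamma(q$w) - digamma(sum(q$w))
    ElnA <- digamma(q$W) - digamma(rowSums(q$W))
    logB <- 0.5 * (rep(digamma(q$a) - log(q$b) - log(2 * pi), each = T) -
      rep(1 / q$beta, each = T) -
      (outer(x, q$m, "-"))^2 * rep(q$a / q$b, each = T))
    dim(logB) <- c(T, K)
    fb <- cpp_forward_backward(ElnPi, matrix(ElnA, K, K), logB)
    kl <- .klDirichlet(q$w, rep(pr$dirInit, K)) +
      sum(vapply(seq_len(K), function(j)
        .klDirichlet(q$W[j, ], rep(pr$dirTrans, K)), numeric(1))) +
      sum(.klNormalGamma(q$m, q$beta, q$a, q$b,
        pr$m0, pr$beta0, pr$a0, pr$b0))
    elbo[it] <- fb$lnZ - kl
    conv <- it > 1 &&
      (elbo[it] - elbo[it - 1]) < tol * (abs(elbo[it]) + 1e-10)
    q <- mstep(fb$gamma, fb$xiSum)
    if (conv) break
  }
  list(q = q, gamma = fb$gamma, elbo = elbo[!is.na(elbo)],
    converged = it < maxIter, iterations = it)
}

.finalizeVB <- function(run, x, K, pr, binWidth = NA_real_) {
  q <- run$q
  ord <- order(q$m)
  mu <- q$m[ord]
  sigma <- sqrt(q$b / q$a)[ord]
  A <- q$W[ord, ord, drop = FALSE]
  A <- A / rowSums(A)
  piProb <- q$w[ord] / sum(q$w)
  logB <- vapply(seq_len(K), function(k) dnorm(x, mu[k], sigma[k], log = TRUE),
    numeric(length(x)))
  dim(logB) <- c(length(x), K)
  path <- cpp_viterbi(log(piProb), log(A), logB)
  new("VBHMMResult", K = as.integer(K), mu = mu, sigma = sigma, A = A,
    piProb = piProb, evidence = tail(run$elbo, 1),
    evidenceTrace = run$elbo, path = as.integer(path),
    responsibilities = run$gamma[, ord, drop = FALSE],
    converged = run$converged, iterations = as.integer(run$iterations),
    posterior = list(w = q$w[ord], W = q$W[ord, ord, drop = FALSE],
      m = mu, beta = q$beta[ord], a = q$a[ord], b = q$b[ord]),
    priors = pr)
}

#' Fit a K-state variational-Bayes HMM to a FRET-efficiency series
#'
#' Best-of-\code{restarts} VBEM runs from perturbed quantile initializations;
#' convergence when the relative ELBO increase falls below \code{tol}.
#'
#' @param E FRET efficiency series (finite values)
#' @param K number of states
#' @param priors from \code{\link{vbPriors}}
#' @param restarts random initializations (default 10)
#' @param seed optional RNG seed (deterministic results for equal seeds)
#' @param maxIter,tol VBEM iteration cap and relative ELBO tolerance
#' @param binWidth optional bin width (ms), carried for rate conversion
#' @return a \code{VBHMMResult}
#' @export
vbemFit <- function(E, K, priors = vbPriors(), restarts = 10, seed = NULL,
    maxIter = 500, tol = 1e-6, binWidth = NA_real_) {
  if (any(!is.finite(E))) stop("E series contains non-finite values")
  stopifnot(K >= 1, length(E) >= 2)
  withSeed(seed, {
    best <- NULL
    qs <- quantile(E, probs = (seq_len(K) - 0.5) / K, names = FALSE)
    spread <- max(sd(E), 0.02)
    for (r in seq_len(restarts)) {
      muInit <- if (r == 1) qs else sort(qs + rnorm(K, 0, 0.3 * spread))
      run <- .vbemRun(E, K, priors, maxIter, tol, muInit)
      if (is.null(best) || tail(run$elbo, 1) > tail(best$elbo, 1)) best <- run
    }
    .finalizeVB(best, E, K, priors, binWidth)
  })
}

#' Select the number of states by maximized evidence
#'
#' Fits K = 1..Kmax and returns the fit with the highest evidence lower
#' bound.
#'
#' @inheritParams vbemFit
#' @param Kmax largest state count to try
#' @return the best \code{VBHMMResult}
#' @export
selectModel <- function(E, Kmax = 4, priors = vbPriors(), restarts = 10,
    seed = NULL, maxIter = 500, tol = 1e-6, binWidth = NA_real_) {
  withSeed(seed, {
    fits <- lapply(seq_len(Kmax), function(K)
      vbemFit(E, K, priors, restarts, seed = NULL, maxIter, tol, binWidth))
    fits[[which.max(vapply(fits, evidence, numeric(1)))]]
  })
}

#' Viterbi path of a fitted model on a series
#'
#' Most probable state sequence under the posterior-mean parameters; ties
#' break toward the lower-mean state.
#'
#' @param result a \code{VBHMMResult}
#' @param E FRET efficiency series
#' @return integer state sequence (1 = lowest mean)
#' @export
viterbiPath <- function(result, E) {
  K <- result@K
  logB <- vapply(seq_len(K), function(k)
    dnorm(E, result@mu[k], result@sigma[k], log = TRUE), numeric(length(E)))
  dim(logB) <- c(length(E), K)
  as.integer(cpp_viterbi(log(result@piProb), log(result@A), logB))
}

#' Maximum-likelihood Baum-Welch baseline
#'
#' Same interface and return type as \code{\link{vbemFit}}, but plain
#' maximum-likelihood EM (no priors); \code{evidence} holds the final log
#' likelihood.  Used as the comparison baseline in the validation harness.
#'
#' @inheritParams vbemFit
#' @param sigmaFloor lower bound on emission sd (guards collapse)
#' @return a \code{VBHMMResult}
#' @export
mlBaselineFit <- function(E, K, restarts = 10, seed = NULL, maxIter = 500,
    tol = 1e-6, sigmaFloor = 1e-3, binWidth = NA_real_) {
  if (any(!is.finite(E))) stop("E series contains non-finite values")
  T <- length(E)
  withSeed(seed, {
    qs <- quantile(E, probs = (seq_len(K) - 0.5) / K, names = FALSE)
    spread <- max(sd(E), 0.02)
    best <- NULL
    for (r in seq_len(restarts)) {
      mu <- if (r == 1) qs else sort(qs + rnorm(K, 0, 0.3 * spread))
      sg <- rep(max(spread / 2, sigmaFloor), K)
      A <- matrix(0.1 / max(K - 1, 1), K, K); diag(A) <- if (K > 1) 0.9 else 1
      piP <- rep(1 / K, K)
      ll <- -Inf; lls <- numeric(0)
      for (it in seq_len(maxIter)) {
        logB <- vapply(seq_len(K), function(k)
          dnorm(E, mu[k], sg[k], log = TRUE), numeric(T))
        dim(logB) <- c(T, K)
        fb <- cpp_forward_backward(log(piP), log(A), logB)
        lls <- c(lls, fb$lnZ)
        if (it > 1 && fb$lnZ - ll < tol * (abs(fb$lnZ) + 1e-10)) { ll <- fb$lnZ; break }
        ll <- fb$lnZ
        g <- fb$gamma
        Nk <- colSums(g)
        mu <- ifelse(Nk > 1e-12, as.numeric(crossprod(g, E)) / Nk, mu)
        sg <- sqrt(pmax(colSums(g * (outer(E, mu, "-"))^2) /
          pmax(Nk, 1e-12), sigmaFloor^2))
        if (K > 1) {
          A <- fb$xiSum / pmax(rowSums(fb$xiSum), 1e-12)
          A <- pmax(A, 1e-12); A <- A / rowSums(A)
        }
        piP <- pmax(g[1, ], 1e-12); piP <- piP / sum(piP)
      }
      if (is.null(best) || ll > best$ll)
        best <- list(mu = mu, sg = sg, A = A, piP = piP, ll = ll,
          lls = lls, it = it, gamma = fb$gamma)
    }
    ord <- order(best$mu)
    mu <- best$mu[ord]; sg <- best$sg[ord]
    A <- best$A[ord, ord, drop = FALSE]; A <- A / rowSums(A)
    piP <- best$piP[ord] / sum(best$piP[ord])
    logB <- vapply(seq_len(K), function(k) dnorm(E, mu[k], sg[k], log = TRUE),
      numeric(T))
    dim(logB) <- c(T, K)
    path <- cpp_viterbi(log(piP), log(A), logB)
    new("VBHMMResult", K = as.integer(K), mu = mu, sigma = sg, A = A,
      piProb = piP, evidence = best$ll, evidenceTrace = best$lls,
      path = as.integer(path),
      responsibilities = best$gamma[, ord, drop = FALSE],
      converged = best$it < maxIter, iterations = as.integer(best$it),
      posterior = list(), priors = list(method = "ml"))
  })
}

#' Collapse sub-resolution states of a fitted HMM path
#'
#' Bin averaging puts bins that straddle a transition at intermediate
#' efficiencies; with bright, clean data the evidence can assign them a
#' dedicated state whose sojourns last ~1 bin.  Such states sit below the
#' temporal resolution of the binned analysis (the same 2-bin limit used by
#' the dwell fits) and are artifacts of binning, not kinetic states.  This
#' reassigns every bin of states whose mean Viterbi dwell is shorter than
#' \code{minDwellBins} to the most likely remaining state under the fitted
#' emission densities.
#'
#' @param result a \code{VBHMMResult}
#' @param E the fitted series
#' @param minDwellBins resolution limit (default 1.5 bins)
#' @return list with \code{path} (collapsed), \code{keptStates} (original
#'   indices), \code{mu} (their means)
#' @export
collapseSubResolutionStates <- function(result, E, minDwellBins = 1.5) {
  path <- statePath(result)
  r <- rle(path)
  meanDwell <- vapply(seq_len(result@K), function(k) {
    d <- r$lengths[r$values == k]
    if (length(d)) mean(d) else Inf
  }, numeric(1))
  present <- seq_len(result@K) %in% r$values
  drop <- which(present & meanDwell < minDwellBins)
  keep <- setdiff(which(present), drop)
  if (!length(keep)) keep <- which.max(meanDwell)
  if (length(drop) && length(keep)) {
    bad <- path %in% drop
    if (any(bad)) {
      ll <- vapply(keep, function(k)
        dnorm(E[bad], result@mu[k], result@sigma[k], log = TRUE),
        numeric(sum(bad)))
      dim(ll) <- c(sum(bad), length(keep))
      path[bad] <- keep[max.col(ll, ties.method = "first")]
    }
  }
  ## renumber to 1..length(keep) in ascending-mean order
  keep <- sort(keep)
  newPath <- match(path, keep)
  list(path = as.integer(newPath), keptStates = keep, mu = result@mu[keep])
}

#' Convert a per-step transition matrix to rates
#'
#' First-order expansion k = p / dt by default; the exact embedding
#' -ln(1 - p)/dt is selectable.  HMM-derived rates are diagnostic; dwell-time
#' fitting is the primary rate path.
#'
#' @param A per-step transition probability matrix
#' @param binWidth time step (ms)
#' @param method "linear" (p/dt) or "log" (-ln(1-p)/dt)
#' @return matrix of rates (s^-1), diagonal NA
#' @export
ratesFromTransitionMatrix <- function(A, binWidth,
    method = c("linear", "log")) {
  method <- match.arg(method)
  dt_s <- binWidth / 1000
  k <- if (method == "linear") A / dt_s else -log(1 - A) / dt_s
  diag(k) <- NA_real_
  k
}
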