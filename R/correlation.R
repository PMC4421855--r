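## FCS autocorrelation and donor-acceptor cross-correlation.

#' Normalized intensity autocorrelation
#'
#' \eqn{G(\tau) = \langle \delta I(t) \delta I(t+\tau)\rangle / \langle I
#' \rangle^2}, with deviations taken from the full-series mean and the sum
#' at lag l divided by the number of contributing pairs (n - l).  A direct
#' estimator on a linear or user-given lag grid, or a multi-tau estimator
#' (octave coarsening, the standard choice for long FCS streams spanning
#' decades of lag time).
#'
#' @param intensity binned intensity series (counts per bin)
#' @param binWidth bin width (ms)
#' @param lagBins integer lags (bins) for the direct estimator; default
#'   1..min(n/4, 4096)
#' @param estimator "multitau" or "direct"
#' @param pointsPerOctave multi-tau lags per octave (default 8)
#' @return a \code{CorrelationCurve} (lags in ms)
#' @export
autocorrelate <- function(intensity, binWidth, lagBins = NULL,
    estimator = c("multitau", "direct"), pointsPerOctave = 8) {
  estimator <- match.arg(estimator)
  x <- as.numeric(intensity)
  n <- length(x)
  gAt <- function(x, l) {
    n <- length(x); m <- mean(x)
    if (m == 0 || l >= n) return(0)
    d <- x - m
    sum(d[1:(n - l)] * d[(l + 1):n]) / (n - l) / m^2
  }
  if (estimator == "direct") {
    if (is.null(lagBins)) lagBins <- seq_len(min(n %/% 4, 4096))
    G <- vapply(lagBins, function(l) gAt(x, l), numeric(1))
    return(correlationCurve(lagBins * binWidth, G, 1L, "auto"))
  }
  ## multi-tau: fine lags at the base resolution, then coarsen by 2 per octave
  lagsMs <- numeric(); G <- numeric()
  xc <- x; wc <- binWidth; base <- 0
  firstLevel <- TRUE
  while (length(xc) >= 4 * pointsPerOctave) {
    ls <- if (firstLevel) seq_len(2 * pointsPerOctave)
      else (pointsPerOctave + 1):(2 * pointsPerOctave)
    ls <- ls[ls < length(xc)]
    lagsMs <- c(lagsMs, ls * wc)
    G <- c(G, vapply(ls, function(l) gAt(xc, l), numeric(1)))
    nc <- length(xc) %/% 2
    xo <- xc[seq_len(2 * nc)]
    xc <- xo[c(TRUE, FALSE)] + xo[c(FALSE, TRUE)]
    wc <- 2 * wc
    firstLevel <- FALSE
  }
  correlationCurve(lagsMs, G, 1L, "auto")
}

#' Fit the 3D-diffusion FCS model
#'
#' Least-squares fit of \eqn{G(\tau) = (1/N) (1+\tau/\tau_D)^{-1}
#' (1+\tau/(\kappa^2\tau_D))^{-1/2}}.  The aspect ratio is fixed by default
#' (fitting kappa on noisy curves is ill-conditioned).
#'
#' @param curve a \code{CorrelationCurve}
#' @param kappa aspect ratio (default 3)
#' @param fitKappa also fit kappa (default FALSE)
#' @param geometry optional \code{ConfocalGeometry}; adds the tau_D -> D
#'   conversion and effective volume to the report
#' @return list with N, tauD_ms, kappa, residualNorm, fit, and (with
#'   geometry) D_um2_s and Veff_fl; the report also notes that Veff follows
#'   from the calibrated geometry, not from an independent volume estimate
#' @export
fitFCS <- function(curve, kappa = 3, fitKappa = FALSE, geometry = NULL) {
  df <- data.frame(tau = lags(curve), G = amplitudes(curve))
  g0 <- max(mean(head(df$G, 3)), 1e-12)
  tD0 <- df$tau[which.min(abs(df$G - g0 / 2))]
  fit <- tryCatch({
    if (fitKappa)
      minpack.lm::nlsLM(G ~ g0f / ((1 + tau / tD) * sqrt(1 + tau / (k2^2 * tD))),
        data = df, start = list(g0f = g0, tD = tD0, k2 = kappa),
        lower = c(0, 1e-6, 1), control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(G ~ g0f / ((1 + tau / tD) * sqrt(1 + tau / (kappa^2 * tD))),
        data = df, start = list(g0f = g0, tD = tD0),
        lower = c(0, 1e-6), control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) stop("FCS fit failed to converge: ",
    conditionMessage(e), " (G0 start ", signif(g0, 3), ", tauD start ",
    signif(tD0, 3), " ms)"))
  cf <- coef(fit)
  out <- list(N = 1 / cf[["g0f"]], tauD_ms = cf[["tD"]],
    kappa = if (fitKappa) cf[["k2"]] else kappa,
    residualNorm = sqrt(sum(residuals(fit)^2)), fit = fit)
  if (!is.null(geometry)) {
    out$D_um2_s <- diffusionCoefficient(geometry, out$tauD_ms)
    out$Veff_fl <- effectiveVolume(geometry)
  }
  out
}

#' Donor-acceptor cross-correlation of normalized intensities
#'
#' Per bin, donor and acceptor intensities are normalized by the
#' donor-excitation total: d = F(Dex,Dem)/(F(Dex,Dem)+F(Dex,Aem)) and
#' a = 1 - d, which removes the common diffusion-brightness envelope.  The
#' normalized cross-covariance \eqn{\langle\delta d(t) \delta a(t+\tau)
#' \rangle / (\bar d \bar a)} is computed per trace (zero-total bins are
#' excluded from the sums) and averaged across traces; lags run from one bin
#' to half the shortest contributing trace.
#'
#' @param traces list of \code{BinnedTrace} (one per molecule)
#' @param minTraceMs minimum trace length used (default 25 ms)
#' @param minTraces traces required for a stable average (default 50)
#' @param strict error (rather than warn) when fewer traces remain
#' @param maxLagMs optional cap on the lag range
#' @return a \code{CorrelationCurve} of type "cross"
#' @export
crossCorrelate <- function(traces, minTraceMs = 25, minTraces = 50,
    strict = FALSE, maxLagMs = NULL) {
  bw <- binWidth(traces[[1]])
  lenMs <- vapply(traces, function(tr) nBins(tr) * binWidth(tr), numeric(1))
  traces <- traces[lenMs >= minTraceMs]
  if (length(traces) < minTraces) {
    msg <- sprintf("only %d trace(s) >= %g ms (requested >= %d)",
      length(traces), minTraceMs, minTraces)
    if (strict || length(traces) == 0) stop(msg) else warning(msg)
  }
  maxLag <- floor(min(vapply(traces, nBins, numeric(1))) / 2)
  if (!is.null(maxLagMs)) maxLag <- min(maxLag, floor(maxLagMs / bw))
  lagBins <- seq_len(maxLag)
  norm <- lapply(traces, function(tr) {
    cts <- counts(tr)
    tot <- cts[, 1] + cts[, 2]
    ok <- tot > 0
    list(d = ifelse(ok, cts[, 1] / tot, NA_real_),
      a = ifelse(ok, cts[, 2] / tot, NA_real_))
  })
  ## deviations from the pooled means: subtracting each short trace's own
  ## sample mean biases the covariance tail downward by O(tau_corr/n) and
  ## distorts the fitted relaxation time
  md <- mean(unlist(lapply(norm, `[[`, "d")), na.rm = TRUE)
  ma <- mean(unlist(lapply(norm, `[[`, "a")), na.rm = TRUE)
  acc <- matrix(NA_real_, length(traces), maxLag)
  for (i in seq_along(norm)) {
    dd <- norm[[i]]$d - md; da <- norm[[i]]$a - ma
    n <- length(dd)
    for (l in lagBins) {
      u <- dd[1:(n - l)] * da[(l + 1):n]
      acc[i, l] <- mean(u, na.rm = TRUE) / (md * ma)
    }
  }
  correlationCurve(lagBins * bw, colMeans(acc, na.rm = TRUE),
    length(traces), "cross")
}

#' Single-exponential fit of a correlation curve
#'
#' Least squares of \eqn{A e^{-t/\tau}} with free-signed amplitude
#' (anticorrelation gives A < 0).  A curve indistinguishable from flat is
#' returned flagged with an NA correlation time instead of a spurious fit.
#'
#' @param curve a \code{CorrelationCurve}
#' @param minSignalLags minimum number of lags with signal above the noise
#'   floor (default 5)
#' @return list with amplitude, tau_ms, apparentRate_s (=1000/tau_ms),
#'   tauStderr_ms, flagged, fit
#' @export
fitSingleExponential <- function(curve, minSignalLags = 5) {
  tau <- lags(curve); G <- amplitudes(curve)
  noise <- sd(tail(G, max(5, length(G) %/% 3)))
  nSig <- sum(abs(G) > 2 * noise)
  if (!is.finite(noise)) noise <- 0
  headAmp <- abs(mean(head(G, 5)))
  if (nSig < minSignalLags || headAmp < 3 * noise / sqrt(5)) {
    return(list(amplitude = mean(head(G, 3)), tau_ms = NA_real_,
      apparentRate_s = NA_real_, tauStderr_ms = NA_real_, flagged = TRUE,
      fit = NULL))
  }
  A0 <- G[1]
  ## crude tau start from the 1/e point of |G|
  tgt <- abs(A0) / exp(1)
  t0 <- tau[which.min(abs(abs(G) - tgt))]
  df <- data.frame(t = tau, G = G)
  fit <- tryCatch(
    minpack.lm::nlsLM(G ~ A * exp(-t / tu), data = df,
      start = list(A = A0, tu = max(t0, tau[1])),
      lower = c(-Inf, 1e-6), control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("exponential fit failed to converge: ",
      conditionMessage(e)))
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit)))[["tu"]], error = function(e) NA_real_)
  list(amplitude = cf[["A"]], tau_ms = cf[["tu"]],
    apparentRate_s = 1000 / cf[["tu"]], tauStderr_ms = se, flagged = FALSE,
    fit = fit)
}

#' Bin a photon stream into a single intensity series for FCS
#'
#' Donor-excitation photons only (both channels) unless \code{category}
#' selects otherwise.
#'
#' @param stream a \code{PhotonStream}
#' @param binWidth bin width (ms; default 0.1, the FCS-mode binning)
#' @param category "DexSum", "DexDem", "DexAem" or "AexAem"
#' @param duration optional span (ms)
#' @return numeric counts per bin
#' @export
fcsBin <- function(stream, binWidth = 0.1, category = "DexSum",
    duration = NULL) {
  tr <- binPhotons(stream, binWidth, duration)
  cts <- counts(tr)
  switch(category,
    DexSum = cts[, 1] + cts[, 2],
    DexDem = cts[, 1], DexAem = cts[, 2], AexAem = cts[, 3],
    stop("unknown category: ", category))
}
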