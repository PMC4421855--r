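test_that("autocorrelation obeys its closed-form limits", {
  ## constant intensity: G identically zero
  expect_true(all(amplitudes(autocorrelate(rep(7, 5000), 0.1)) == 0))
  ## independent Poisson noise: G(tau > 0) within the estimator noise floor
  set.seed(2)
  x <- rpois(2e4, 5)
  G <- amplitudes(autocorrelate(x, 0.1, estimator = "direct",
    lagBins = 1:50))
  expect_lt(max(abs(G)), 4 / (5 * sqrt(2e4 - 50)) * 3)
  ## time-reversal invariance
  set.seed(3)
  y <- rpois(5000, 10) + rep(c(0, 4), each = 10, length.out = 5000)
  c1 <- autocorrelate(y, 0.1, estimator = "direct", lagBins = 1:40)
  c2 <- autocorrelate(rev(y), 0.1, estimator = "direct", lagBins = 1:40)
  expect_equal(amplitudes(c1), amplitudes(c2), tolerance = 1e-12)
})

test_that("the 3D-diffusion FCS model is recovered exactly from itself", {
  tau <- exp(seq(log(0.01), log(500), length.out = 60))
  G <- 1 / ((1 + tau / 5) * sqrt(1 + tau / (9 * 5)))
  fit <- fitFCS(correlationCurve(tau, G), kappa = 3)
  expect_equal(fit$N, 1, tolerance = 1e-6)
  expect_equal(fit$tauD_ms, 5, tolerance = 1e-6)
})

test_that("FCS on simulated diffusion recovers tau_D and the D ratio", {
  g <- calibrateGeometry()
  runFCS <- function(D, dur, seed) {
    cfg <- simConfig(geometry = g, scheme = staticScheme(0.05), D = D,
      peakRate = 100, alternation = FALSE, background = 0, duration = dur,
      boxHalfWidth = 2.5 * wz(g), dt = 10, nMolecules = 20)
    s <- simulateStream(cfg, seed = seed, truth = FALSE)
    fitFCS(autocorrelate(fcsBin(s, 0.1, duration = dur * 1000), 0.1),
      kappa = 3, geometry = g)
  }
  fFree <- runFCS(46.4, 60, 33)
  expect_equal(fFree$tauD_ms, diffusionTime(g, 46.4), tolerance = 0.1)
  expect_equal(fFree$D_um2_s, 46.4, tolerance = 0.1)
  fTeth <- runFCS(3.0, 250, 32)
  expect_equal(fTeth$tauD_ms, 20, tolerance = 0.1)
  ## diffusion-time ratio tracks the 15.5-fold D ratio within 10%
  expect_equal(fTeth$tauD_ms / fFree$tauD_ms, 46.4 / 3.0, tolerance = 0.1)
})

test_that("G amplitude scales as 1/N with the number of diffusers", {
  g <- calibrateGeometry()
  amp <- vapply(c(1, 2, 4), function(n) {
    cfg <- simConfig(geometry = g, scheme = staticScheme(0.05), D = 46.4,
      peakRate = 100, alternation = FALSE, background = 0, duration = 60,
      boxHalfWidth = 1.5 * wz(g), dt = 10, nMolecules = n)
    s <- simulateStream(cfg, seed = 40 + n, truth = FALSE)
    fitFCS(autocorrelate(fcsBin(s, 0.1, duration = 6e4), 0.1), kappa = 3)$N
  }, numeric(1))
  expect_equal(amp[2] / amp[1], 2, tolerance = 0.15)
  expect_equal(amp[3] / amp[1], 4, tolerance = 0.15)
})

test_that("single-exponential fits recover their inputs and flag flat curves", {
  t <- seq(0.5, 25, by = 0.5)
  f <- fitSingleExponential(correlationCurve(t, -0.1 * exp(-t / 5)))
  expect_equal(f$amplitude, -0.1, tolerance = 1e-6)
  expect_equal(f$tau_ms, 5, tolerance = 1e-6)
  expect_false(f$flagged)
  ## noisy Monte-Carlo: 5% noise, 50-curve average, tau within 10%
  set.seed(6)
  Gavg <- rowMeans(vapply(1:50, function(r)
    -0.1 * exp(-t / 5) + rnorm(length(t), 0, 0.005), numeric(length(t))))
  fn <- fitSingleExponential(correlationCurve(t, Gavg))
  expect_equal(fn$tau_ms, 5, tolerance = 0.1)
  ## flat curve: flagged, no spurious time constant
  set.seed(7)
  ff <- fitSingleExponential(correlationCurve(t, rnorm(length(t), 0, 1e-3)))
  expect_true(ff$flagged)
  expect_true(is.na(ff$tau_ms))
})

test_that("donor-acceptor cross-correlation relaxes at k12 + k21", {
  ## static-E traces: amplitude at shot-noise level, flagged
  trS <- simulateBurstSet(60, staticScheme(0.5), minDuration = 30,
    seed = 3)$traces
  fS <- fitSingleExponential(crossCorrelate(trS, minTraces = 50))
  expect_true(fS$flagged)
  expect_lt(abs(fS$amplitude), 0.005)
  ## two-state relaxation identity across the dynamic range (10-15%)
  relax <- function(ksum, bw, minDur, seed) {
    tr <- simulateBurstSet(150, twoStateScheme(ksum / 2, ksum / 2),
      binWidth = bw, minDuration = minDur, meanExcess = minDur / 2,
      seed = seed)$traces
    fitSingleExponential(crossCorrelate(tr, minTraces = 50,
      minTraceMs = 25))$apparentRate_s
  }
  expect_equal(relax(582, 0.5, 30, 291), 582, tolerance = 0.1)   # tau 1.72 ms
  expect_equal(relax(200, 0.5, 80, 100), 200, tolerance = 0.15)
  expect_equal(relax(1500, 0.2, 30, 15), 1500, tolerance = 0.15)
})

test_that("normalization removes a shared brightness envelope", {
  ## same traces with and without a multiplicative envelope applied to all
  ## three channels: the normalized cross-correlation time must not move
  tr <- simulateBurstSet(120, twoStateScheme(291, 291), minDuration = 30,
    meanExcess = 15, envelope = "flat", seed = 5)$traces
  set.seed(6)
  scaled <- lapply(tr, function(x) {
    cts <- counts(x)
    env <- exp(cumsum(rnorm(nrow(cts), 0, 0.15)))
    env <- 0.25 + env / max(env)
    binnedTrace(round(cts[, 1] * env), round(cts[, 2] * env),
      round(cts[, 3] * env), binWidth(x))
  })
  tFlat <- fitSingleExponential(crossCorrelate(tr, minTraces = 50))$tau_ms
  tEnv <- fitSingleExponential(crossCorrelate(scaled, minTraces = 50))$tau_ms
  expect_equal(tEnv, tFlat, tolerance = 0.1)
})

test_that("the trace-count guard warns or errors as configured", {
  tr <- simulateBurstSet(10, twoStateScheme(), minDuration = 30,
    seed = 8)$traces
  expect_warning(crossCorrelate(tr, minTraces = 50), "only 10 trace")
  expect_error(crossCorrelate(tr, minTraces = 50, strict = TRUE),
    "only 10 trace")
  expect_error(suppressWarnings(crossCorrelate(tr, minTraceMs = 1000,
    minTraces = 1)))
})

test_that("a multi-step SSB-like scheme shows the published apparent rate", {
  ## nearest-neighbour stepping at ~200/s: the donor-acceptor relaxation is
  ## dominated by the slow eigenmode, giving an apparent rate compatible
  ## with the 172 +/- 45 /s cross-correlation estimate
  k <- 200
  Q <- matrix(0, 3, 3)
  for (i in 1:2) { Q[i, i + 1] <- k; Q[i + 1, i] <- k }
  tr <- simulateBurstSet(120, kineticScheme(c(0.3, 0.55, 0.8), Q),
    minDuration = 40, meanExcess = 20, seed = 9)$traces
  f <- fitSingleExponential(crossCorrelate(tr, minTraces = 50))
  expect_gt(f$apparentRate_s, 172 - 45)
  expect_lt(f$apparentRate_s, 172 + 45)
})
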