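test_that("stitching groups bursts as the working protocol prescribes", {
  mkES <- function(n, id) {
    e <- mkESTrace(rep(0.6, n), E = rep(0.5, n))
    e@sourceId <- id
    e
  }
  ## single burst: identity, no interior boundaries
  st1 <- stitchTraces(list(mkES(80, "a")))
  expect_identical(length(st1), 1L)
  expect_identical(length(boundaries(st1[[1]])), 0L)
  expect_identical(length(st1[[1]]), 80L)
  ## 40 + 60 + 50 points, target 150: one group, boundaries at 40 and 100
  st2 <- stitchTraces(list(mkES(40, "a"), mkES(60, "b"), mkES(50, "c")),
    targetPoints = 150)
  expect_identical(length(st2), 1L)
  expect_identical(boundaries(st2[[1]]), c(40L, 100L))
  expect_identical(st2[[1]]@sourceIds, c("a", "b", "c"))
  ## 15-ms bursts at 0.5-ms bins (30 points) reach 150 points in groups of
  ## 5, inside the 5-10-trace working range
  st3 <- stitchTraces(lapply(1:20, function(i) mkES(30, paste0("b", i))),
    targetPoints = 150)
  expect_true(all(vapply(st3, function(s) length(s@segLengths), integer(1))
    == 5L))
  ## fixed group size and seeded shuffling
  st4 <- stitchTraces(lapply(1:9, function(i) mkES(30, paste0("b", i))),
    groupSize = 3)
  expect_identical(length(st4), 3L)
  sh1 <- stitchTraces(lapply(1:9, function(i) mkES(30, paste0("b", i))),
    groupSize = 3, shuffleSeed = 5)
  sh2 <- stitchTraces(lapply(1:9, function(i) mkES(30, paste0("b", i))),
    groupSize = 3, shuffleSeed = 5)
  expect_identical(sh1[[1]]@sourceIds, sh2[[1]]@sourceIds)
})

test_that("unstitching removes boundary transitions by construction", {
  st <- new("StitchedTrace", E = rep(0.5, 10), segLengths = c(4L, 6L),
    sourceIds = c("a", "b"), binWidth = 0.5)
  ## constant path across the boundary: no transition anywhere
  p1 <- unstitchAndClean(st, rep(1L, 10))
  dw1 <- extractDwells(p1, 0.5)
  expect_identical(nrow(dw1), 2L)
  expect_true(all(is.na(dw1$toState)))
  ## state change exactly at the boundary: still no recorded transition
  p2 <- unstitchAndClean(st, c(rep(1L, 4), rep(2L, 6)))
  dw2 <- extractDwells(p2, 0.5)
  expect_true(all(is.na(dw2$toState)))
  expect_identical(dw2$fromState, c(1L, 2L))
  expect_error(unstitchAndClean(st, rep(1L, 9)), "length")
})

test_that("stitch/unstitch transition bookkeeping balances exactly", {
  for (s in 1:5) {
    set.seed(s)
    segs <- lapply(1:6, function(i)
      sample(1:2, sample(10:40, 1), TRUE, prob = c(0.7, 0.3)))
    st <- new("StitchedTrace", E = runif(sum(lengths(segs))),
      segLengths = lengths(segs),
      sourceIds = as.character(1:6), binWidth = 0.5)
    path <- unlist(segs)
    full <- sum(diff(path) != 0)
    cleaned <- extractDwells(unstitchAndClean(st, path), 0.5)
    nClean <- sum(!is.na(cleaned$toState))
    bnd <- boundaries(st)
    nBoundaryChanges <- sum(path[bnd] != path[bnd + 1])
    expect_lte(nClean, full)
    expect_identical(full - nClean, nBoundaryChanges)
  }
})

test_that("dwell extraction enumerates runs with censoring flags", {
  dw <- extractDwells(list(c(1L, 1L, 1L, 2L, 2L, 1L)), 0.5)
  expect_identical(nrow(dw), 3L)
  ## interior dwell: state 2, 1.0 ms, uncensored
  expect_identical(dw$fromState[2], 2L)
  expect_equal(dw$duration[2], 1.0)
  expect_false(dw$leftCensored[2] || dw$rightCensored[2])
  expect_true(dw$leftCensored[1] && dw$rightCensored[3])
  ## a transition-free burst yields one fully censored dwell
  dw0 <- extractDwells(list(rep(1L, 30)), 0.5)
  expect_identical(nrow(dw0), 1L)
  expect_true(dw0$leftCensored & dw0$rightCensored)
  expect_error(fitDwellRate(dw0, 1, binWidth = 0.5), "insufficient")
})

test_that("the dwell MLE matches the closed-form oracle on iid data", {
  ## exponential dwells, mean 3.33 ms, fine binning so rounding is
  ## negligible: MLE equals 1/sample-mean, k = 300/s within 2%
  set.seed(4)
  d <- rexp(1e4, 300)
  nb <- pmax(round(d / 5e-5), 1L)
  dw <- data.frame(duration = nb * 0.05, nBins = nb, fromState = 1L,
    toState = 2L, leftCensored = FALSE, rightCensored = FALSE,
    segLength = 1e6L, burst = "x")
  r <- fitDwellRate(dw, 1, binWidth = 0.05, conversion = "rounding")
  expect_equal(r$k, 300, tolerance = 0.02)
  expect_equal(r$k, 1 / mean(d) , tolerance = 0.02)
  expect_equal(r$stderr, r$k / sqrt(r$n))
  ## least-squares histogram cross-check agrees
  rl <- fitDwellRate(dw, 1, binWidth = 0.05, method = "lsq")
  expect_equal(rl$k, 300, tolerance = 0.1)
})

test_that("survival treatment of censored dwells removes the short-segment bias", {
  ## geometric-chain oracle cut into short segments: the naive
  ## censored-excluded estimator overestimates, the survival MLE does not
  set.seed(5)
  p <- 0.13
  paths <- lapply(1:2500, function(r) {
    z <- integer(24); z[1] <- sample(1:2, 1)
    for (t in 2:24) z[t] <- if (runif(1) < p) 3L - z[t - 1] else z[t - 1]
    z
  })
  dw <- extractDwells(paths, 0.5)
  kTrue <- -log(1 - p) / 5e-4
  kSurv <- fitDwellRate(dw, 1, binWidth = 0.5, conversion = "rounding")$k
  kNaive <- fitDwellRate(dw, 1, binWidth = 0.5, conversion = "rounding",
    censoring = "exclude")$k
  expect_equal(kSurv, kTrue, tolerance = 0.06)
  expect_gt(kNaive, 1.3 * kTrue)
})

test_that("transition-density plots cluster at the state-pair coordinates", {
  td0 <- transitionDensity(list(rep(1L, 20)), c(0.25, 0.75))
  expect_identical(td0$nTransitions, 0L)
  expect_true(all(td0$counts == 0L))
  ## two-state paths: exactly two occupied clusters, (0.25,0.75) and
  ## (0.75,0.25), nothing on the diagonal
  bs <- simulateBurstSet(60, twoStateScheme(), seed = 17)
  td <- transitionDensity(bs$trueStates, c(0.25, 0.75))
  occ <- which(td$counts > 0, arr.ind = TRUE)
  cellOf <- function(e1, e2) c(findInterval(e1, td$breaks),
    findInterval(e2, td$breaks))
  expect_identical(nrow(unique(occ)), 2L)
  expect_true(all(apply(occ, 1, function(rc) !identical(rc[1], rc[2]))))
  expect_identical(td$nTransitions,
    sum(vapply(bs$trueStates, function(z) sum(diff(z) != 0), integer(1))))
  ## three-state linear chain: four nearest-neighbour clusters dominate;
  ## apparent 1<->3 events (two sub-bin transitions) stay at the noise level
  k <- 250
  Q <- matrix(0, 3, 3); for (i in 1:2) { Q[i, i + 1] <- k; Q[i + 1, i] <- k }
  bs3 <- simulateBurstSet(120, kineticScheme(c(0.2, 0.5, 0.8), Q),
    minDuration = 20, seed = 19)
  td3 <- transitionDensity(bs3$trueStates, c(0.2, 0.5, 0.8))
  main <- vapply(list(c(0.2, 0.5), c(0.5, 0.2), c(0.5, 0.8), c(0.8, 0.5)),
    function(p) { rc <- cellOf(p[1], p[2]); td3$counts[rc[1], rc[2]] },
    integer(1))
  expect_true(all(main > 50))
  c13 <- cellOf(0.2, 0.8); c31 <- cellOf(0.8, 0.2)
  expect_lt((td3$counts[c13[1], c13[2]] + td3$counts[c31[1], c31[2]]) /
    sum(main), 0.05)
})

test_that("the minimum-length rule keeps bursts of >= factor x dwell", {
  df <- data.frame(duration = c(10, 14, 16, 30))
  expect_equal(minimumLengthFilter(df, meanDwell = 3, factor = 4)$duration,
    c(14, 16, 30))
  esl <- lapply(c(10, 14, 16, 30), function(ms)
    mkESTrace(rep(0.6, ms / 0.5)))
  kept <- minimumLengthFilter(esl, 3, 4)
  expect_identical(length(kept), 3L)
  ## HJ defaults: 3-ms dwell and factor 4 reproduce the 15-ms-class cut
  expect_identical(length(minimumLengthFilter(esl, 3.5, 4)), 3L)
  expect_identical(length(minimumLengthFilter(esl, 10, 4)), 0L)
  expect_error(minimumLengthFilter(esl, 0))
})

test_that("truncation sensitivity reproduces the minimum-trace-length rule", {
  bs <- simulateBurstSet(60, twoStateScheme(), minDuration = 25,
    meanExcess = 10, seed = 5)
  esl <- burstESList(bs)
  sens <- truncationSensitivity(esl, cutLengths = c(12, 24), seed = 7)
  ## full-length cut: every piece is the original series; consistency
  full <- truncationSensitivity(esl, cutLengths = 1000, seed = 7)
  expect_equal(full$relRate, 1, tolerance = 0.06)
  ## >= 4x mean dwell: both directions within 10% of the reference
  expect_lt(abs(sens$relRate12[1] - 1), 0.1)
  expect_lt(abs(sens$relRate21[1] - 1), 0.1)
  ## the naive censored-excluded analysis overestimates at ~1x dwell and
  ## its error shrinks monotonically with trace length
  naive <- truncationSensitivity(esl, cutLengths = c(3, 6, 12, 24),
    seed = 7, censoring = "exclude", conversion = "rounding")
  expect_gt(naive$relRate[1], 1.5)
  expect_true(all(diff(naive$relRate) < 0))
  expect_true(all(naive$relRate > 1))
  ## sub-2-bin cuts are skipped with a warning
  expect_warning(truncationSensitivity(esl, cutLengths = c(0.5, 12),
    seed = 7), "below 2 bins")
})

test_that("symmetric schemes yield statistically equal rates", {
  bs <- simulateBurstSet(150, twoStateScheme(400, 400), seed = 23)
  r <- recoverRates(burstESList(bs), 0.5)
  r12 <- fitDwellRate(r$dwells, 1, binWidth = 0.5)
  r21 <- fitDwellRate(r$dwells, 2, binWidth = 0.5)
  pooledSE <- sqrt(r12$stderr^2 + r21$stderr^2)
  expect_lt(abs(r12$k - r21$k), 2 * pooledSE + 1e-9)
})

test_that("Arrhenius fits recover activation energies", {
  R <- 8.314
  Ts <- c(288, 295, 303, 310)
  k0 <- 200 * exp(-28e3 / R * (1 / Ts - 1 / 295))
  ## two exact points: slope recovered exactly
  f2 <- arrheniusFit(Ts[c(1, 4)], k0[c(1, 4)])
  expect_equal(f2$Ea_kJmol, 28, tolerance = 1e-9)
  ## temperature-independent rates: Ea = 0
  expect_equal(arrheniusFit(Ts, rep(150, 4))$Ea_kJmol, 0, tolerance = 1e-9)
  ## 5% noise, 100 replicates: recovered within the published 7 kJ/mol
  set.seed(2)
  reps <- replicate(100, arrheniusFit(Ts, k0 * exp(rnorm(4, 0, 0.05)))$Ea_kJmol)
  expect_lt(abs(mean(reps) - 28), 7)
  expect_lt(sd(reps), 7)
  ## extrapolation helper: the fitted line predicts its own inputs
  expect_equal(arrheniusFit(Ts, k0)$predictRate(310), k0[4], tolerance = 1e-6)
  expect_error(arrheniusFit(295, 100), ">= 2 temperatures")
})
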