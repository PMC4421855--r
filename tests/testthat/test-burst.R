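test_that("photons are categorized and binned by hand-checkable rules", {
  ## 7 photons in one bin: DexDem x3, DexAem x3, AexAem x1
  s <- photonStream(c(10, 20, 30, 40, 50, 60, 70),
    channel = c("D", "D", "D", "A", "A", "A", "A"),
    excitation = c("D", "D", "D", "D", "D", "D", "A"))
  tr <- binPhotons(s, 1)
  expect_identical(as.integer(counts(tr)[1, ]), c(3L, 3L, 1L))
  ## empty stream: all-zero trace
  tr0 <- binPhotons(photonStream(), 0.5)
  expect_true(all(counts(tr0) == 0L))
  ## bins are half-open [t, t + width): a photon at exactly 1000 us
  ## belongs to the second 1-ms bin
  s2 <- photonStream(c(999, 1000), c("D", "D"), c("D", "D"))
  expect_identical(as.integer(counts(binPhotons(s2, 1))[, 1]), c(1L, 1L))
})

test_that("dual-channel burst search applies both thresholds strictly", {
  mk <- function(dd, da, aa) binnedTrace(dd, da, aa, binWidth = 1)
  ## all below threshold
  expect_identical(nrow(dualChannelBurstSearch(mk(rep(10, 5), rep(10, 5),
    rep(40, 5)), 30)), 0L)
  ## sum channel above but no acceptor-excitation signal: rejected
  expect_identical(nrow(dualChannelBurstSearch(mk(rep(40, 5), rep(40, 5),
    rep(0, 5)), 30)), 0L)
  ## 20-bin trace satisfying both conditions on bins 5..14 (0-based)
  dd <- rep(5, 20); da <- rep(5, 20); aa <- rep(5, 20)
  dd[6:15] <- 30; da[6:15] <- 30; aa[6:15] <- 40
  b <- dualChannelBurstSearch(mk(dd, da, aa), 30)
  expect_identical(nrow(b), 1L)
  expect_identical(b$startBin, 5L)
  expect_identical(b$endBin, 15L)
  expect_equal(b$duration, 10)
  expect_identical(b$nDexDem, 300L)
  ## threshold comparison is strict: a bin exactly at threshold is out
  b2 <- singleChannelBurstSearch(mk(rep(15, 3), rep(15, 3), rep(0, 3)), 30)
  expect_identical(nrow(b2), 0L)
  b3 <- singleChannelBurstSearch(mk(rep(16, 3), rep(15, 3), rep(0, 3)), 30)
  expect_identical(nrow(b3), 1L)
})

test_that("burst search is idempotent and padding-invariant", {
  set.seed(8)
  dd <- rpois(50, 40); da <- rpois(50, 30); aa <- rpois(50, 40)
  tr <- binnedTrace(dd, da, aa, 1)
  b <- dualChannelBurstSearch(tr, 30)
  pad <- binnedTrace(c(rep(0, 7), dd, rep(0, 9)), c(rep(0, 7), da, rep(0, 9)),
    c(rep(0, 7), aa, rep(0, 9)), 1)
  bp <- dualChannelBurstSearch(pad, 30)
  expect_identical(nrow(b), nrow(bp))
  expect_identical(bp$startBin - 7L, b$startBin)
  expect_identical(bp$nDexAem, b$nDexAem)
  ## merging all bursts never double-counts a bin
  expect_true(all(b$endBin[-nrow(b)] <= b$startBin[-1]))
  expect_lte(sum(b$endBin - b$startBin), nBins(tr))
})

test_that("E and S follow the uncorrected ALEX ratios", {
  tr <- binnedTrace(c(75, 0, 50), c(25, 0, 50), c(33, 50, 0), 0.5)
  es <- esValues(computeES(tr))
  expect_equal(es$E[1], 0.25)          # low-E conformer ratio
  expect_equal(es$S[1], 100 / 133)
  expect_true(is.na(es$E[2]))          # donor-dark bin: invalid, not NaN
  expect_false(es$valid[2])
  expect_equal(es$S[2], 0)
  expect_equal(es$E[3], 0.5)           # acceptor-bleached signature
  expect_equal(es$S[3], 1)
})

test_that("E and S are invariant under uniform count rescaling", {
  tr1 <- binnedTrace(c(30, 12), c(10, 44), c(20, 30), 0.5)
  tr7 <- binnedTrace(7 * c(30, 12), 7 * c(10, 44), 7 * c(20, 30), 0.5)
  expect_equal(esValues(computeES(tr1))[c("E", "S")],
    esValues(computeES(tr7))[c("E", "S")])
})

test_that("stoichiometry filter classifies bleach jumps and excursions", {
  set.seed(1)
  clean <- filterByStoichiometry(mkESTrace(rnorm(60, 0.6, 0.02)))
  expect_identical(disposition(clean), "clean")
  expect_true(is.na(clean@truncIndex))
  ## terminal rise persisting to the end: acceptor photobleach, truncated
  stepUp <- filterByStoichiometry(mkESTrace(c(rnorm(39, 0.6, 0.02),
    rnorm(21, 1.0, 0.02))))
  expect_identical(disposition(stepUp), "truncated")
  expect_lt(abs(stepUp@truncIndex - 40), 3)
  ## transient excursion: discarded
  exc <- filterByStoichiometry(mkESTrace(c(rnorm(25, 0.6, 0.02),
    rnorm(10, 0.95, 0.02), rnorm(25, 0.6, 0.02))))
  expect_identical(disposition(exc), "discarded")
  ## burst shorter than the window: clean with a warning flag
  short <- filterByStoichiometry(mkESTrace(rnorm(6, 0.6, 0.02)))
  expect_identical(disposition(short), "clean")
  expect_true(short@shortWarning)
  ## shot-noise S fluctuation at working brightness is not flagged
  bs <- simulateBurstSet(30, twoStateScheme(), seed = 77)
  disp <- vapply(burstESList(bs), function(e)
    disposition(filterByStoichiometry(e)), character(1))
  expect_gt(mean(disp == "clean"), 0.9)
})

test_that("acceptor bleaching in the generator produces truncatable bursts", {
  bs <- simulateBurstSet(30, twoStateScheme(), bleachAcceptor = 40,
    minDuration = 20, seed = 3)
  disp <- vapply(burstESList(bs), function(e)
    disposition(filterByStoichiometry(e)), character(1))
  expect_gt(sum(disp == "truncated"), 3)
})

test_that("long-burst fraction counts strictly beyond the cutoff", {
  expect_equal(longBurstFraction(data.frame(duration = rep(1, 5)), 10), 0)
  expect_equal(longBurstFraction(data.frame(duration = c(5, 12, 15, 3)), 10),
    0.5)
  expect_error(longBurstFraction(data.frame(duration = numeric())),
    "no bursts")
})

test_that("mean burst E converges to the occupancy-weighted state mean", {
  ## k12 = 300, k21 = 600: pi = (2/3, 1/3), E = 2/3*0.25 + 1/3*0.75 = 5/12
  bs <- simulateBurstSet(150, twoStateScheme(300, 600), minDuration = 20,
    seed = 13)
  E <- unlist(lapply(burstESList(bs), function(e) e@E[e@valid]))
  expect_equal(mean(E), 2 / 3 * 0.25 + 1 / 3 * 0.75, tolerance = 0.02)
})
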