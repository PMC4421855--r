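test_that("PSF has the 3D-Gaussian closed form", {
  g <- confocalGeometry(0.5, kappa = 3)
  expect_equal(psfIntensity(c(0, 0, 0), g), 1.0)
  expect_equal(psfIntensity(c(wxy(g) / sqrt(2), 0, 0), g), exp(-1))
  expect_equal(psfIntensity(c(0, 0, wz(g)), g), exp(-2))
  ## effective volume consistent with the radii
  expect_equal(effectiveVolume(g), pi^1.5 * 0.5^2 * 1.5, tolerance = 1e-9)
})

test_that("geometry calibration reproduces the (D, tauD) anchor", {
  g <- calibrateGeometry(D = 3.0, tauD = 20, kappa = 3)
  expect_equal(wxy(g), sqrt(4 * 3 * 0.02), tolerance = 1e-12)
  expect_equal(diffusionTime(g, 3.0), 20, tolerance = 1e-12)
  expect_equal(diffusionCoefficient(g, 20), 3.0, tolerance = 1e-12)
})

test_that("invalid simulation configs are rejected", {
  expect_error(simConfig(D = -1), "'D' must be > 0")
  expect_error(simConfig(dt = 0), "'dt' must be > 0")
  expect_error(simConfig(dt = 100, alexPeriod = 25), "half-period")
})

test_that("Brownian paths have MSD = 2 D t per axis within 5%", {
  D <- 3.0
  cfg <- simConfig(D = D, dt = 10, duration = 0.01, boxHalfWidth = Inf)
  lag <- 250
  msdAt <- function(D, seed0) {
    acc <- 0; cnt <- 0
    for (r in 1:200) {
      p <- simulatePath(simConfig(D = D, dt = 10, duration = 0.01,
        boxHalfWidth = Inf), nSteps = 500, pos0 = c(0, 0, 0),
        seed = seed0 + r)
      d <- p[(lag + 1):501, ] - p[1:(501 - lag), ]
      acc <- acc + sum(d^2); cnt <- cnt + length(d)
    }
    acc / cnt
  }
  m3 <- msdAt(3.0, 1000)
  expect_equal(m3, 2 * 3.0 * lag * 1e-5, tolerance = 0.05)
  ## free 40-bp dsDNA vs tethered: MSD ratio 15.5 +/- 0.5 at any lag
  ## (common random numbers: increments scale exactly with sqrt(D))
  m46 <- msdAt(46.4, 1000)
  expect_lt(abs(m46 / m3 - 46.4 / 3.0), 0.5)
  expect_equal(round(m46 / m3), 15)
})

test_that("CTMC trajectories have exponential dwells and correct occupancy", {
  ## all-zero rates: a single dwell spanning the duration
  tr0 <- simulateStates(kineticScheme(c(0.3, 0.7), matrix(0, 2, 2)), 1,
    seed = 1)
  expect_identical(length(tr0$transitionTimes), 1L)
  ## k12 = k21 = 1500/s: mean dwell 0.667 ms within 3%
  tr <- simulateStates(twoStateScheme(1500, 1500), 10, seed = 2)
  dwells <- diff(tr$transitionTimes)
  expect_gt(length(dwells), 1e4)
  expect_equal(mean(dwells) * 1000, 1 / 1.5, tolerance = 0.03)
  ## occupancy of state 1 equals k21/(k12+k21) within 2%
  tr2 <- simulateStates(twoStateScheme(300, 600), 60, seed = 3)
  tt <- c(tr2$transitionTimes, 60)
  occ1 <- sum(diff(tt)[tr2$states == 1]) / 60
  expect_equal(occ1, 600 / 900, tolerance = 0.02)
})

test_that("photon emission splits FRET channels binomially", {
  g <- calibrateGeometry()
  cfg <- simConfig(geometry = g, scheme = kineticScheme(0.75, matrix(0, 1, 1)),
    peakRate = 400, background = 0, duration = 2, dt = 10)
  path <- matrix(0, 2e5 + 1, 3)           # clamped at the volume centre
  traj <- list(transitionTimes = 0, states = 1L)
  st <- emitPhotons(path, traj, cfg, seed = 4)
  pc <- photonCategories(st)
  nD <- sum(pc != "AexAem")
  frac <- mean(pc[pc != "AexAem"] == "DexAem")
  expect_lt(abs(frac - 0.75), 3 * sqrt(0.75 * 0.25 / nD))
  ## ALEX phase bookkeeping: red-excitation photons are acceptor-channel
  expect_true(all(st@channel[st@excitation == 2L] == 2L))
  ## empty limit
  cfg0 <- simConfig(geometry = g, peakRate = 0, background = 0, duration = 0.01)
  st0 <- emitPhotons(matrix(0, 1001, 3), traj, cfg0, seed = 5)
  expect_identical(length(st0), 0L)
})

test_that("streams are byte-identical under a fixed seed", {
  cfg <- simConfig(duration = 2, background = 0.2)
  s1 <- simulateStream(cfg, seed = 11)
  s2 <- simulateStream(cfg, seed = 11)
  expect_identical(timestamps(s1), timestamps(s2))
  expect_identical(s1@channel, s2@channel)
  expect_identical(s1@truth, s2@truth)
  s3 <- simulateStream(cfg, seed = 12)
  expect_false(identical(timestamps(s1), timestamps(s3)))
})

test_that("binned totals conserve the photon count at any bin width", {
  cfg <- simConfig(duration = 3, D = 10)
  s <- simulateStream(cfg, seed = 21)
  for (bw in c(0.2, 0.5, 1, 2)) {
    tr <- binPhotons(s, bw, duration = 3000)
    expect_identical(sum(counts(tr)), length(s))
  }
})

test_that("stronger bleaching never increases the mean photon yield", {
  g <- calibrateGeometry()
  traj <- list(transitionTimes = 0, states = 1L)
  path <- matrix(0, 5001, 3)
  yield <- function(bleach, seed0) {
    mean(vapply(1:100, function(r) {
      cfg <- simConfig(geometry = g,
        scheme = kineticScheme(0.75, matrix(0, 1, 1)), peakRate = 100,
        background = 0, duration = 0.05, bleachDonor = bleach,
        bleachAcceptor = bleach)
      length(emitPhotons(path, traj, cfg, seed = seed0 + r))
    }, numeric(1)))
  }
  y <- c(yield(0, 100), yield(30, 200), yield(120, 300))
  expect_true(all(diff(y) < 0))
})

test_that("photon files round-trip through both formats", {
  cfg <- simConfig(duration = 1, D = 20)
  s <- simulateStream(cfg, seed = 31)
  expect_gt(length(s), 100)
  f <- withr::local_tempfile(fileext = ".csv")
  writePhotons(s, f)
  s2 <- readPhotons(f)
  expect_identical(timestamps(s), timestamps(s2))
  expect_identical(s@channel, s2@channel)
  expect_identical(s@excitation, s2@excitation)
  expect_identical(s@truth$true_state, s2@truth$true_state)
  ## photon-HDF5-compatible text layout
  d <- withr::local_tempdir()
  writePhotons(s, d, format = "phdf5", metadata = list(alex_period_us = 25))
  s3 <- readPhotons(d)
  expect_identical(timestamps(s), timestamps(s3))
  md <- yaml::read_yaml(file.path(d, "metadata.yaml"))
  expect_equal(md$alex_period_us, 25)
  ## empty stream: header-only file reads back empty
  f0 <- withr::local_tempfile(fileext = ".csv")
  writePhotons(photonStream(), f0)
  expect_identical(length(readPhotons(f0)), 0L)
})

test_that("malformed photon files fail with a line/field diagnostic", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp_us,channel,excitation", "12,D,D", "oops,A,D"), f)
  expect_error(readPhotons(f), "timestamp_us at data line 2")
  writeLines(c("timestamp_us,channel,excitation", "12,X,D"), f)
  expect_error(readPhotons(f), "bad channel at data line 1")
  writeLines(c("timestamp_us,channel", "12,D"), f)
  expect_error(readPhotons(f), "missing column")
})
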