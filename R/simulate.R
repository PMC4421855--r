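## Photon-level simulation of diffusing FRET molecules.

#' 3D-Gaussian excitation profile
#'
#' Relative excitation/detection efficiency of the confocal volume:
#' \eqn{exp(-2(x^2+y^2)/w_{xy}^2 - 2 z^2/w_z^2)}.
#'
#' @param position numeric length-3 (um) or an (n x 3) matrix
#' @param geometry a \code{ConfocalGeometry}
#' @return relative intensity in [0, 1]
#' @export
psfIntensity <- function(position, geometry) {
  p <- if (is.matrix(position)) position else matrix(position, ncol = 3)
  exp(-2 * (p[, 1]^2 + p[, 2]^2) / wxy(geometry)^2 - 2 * p[, 3]^2 / wz(geometry)^2)
}

#' Simulate a Brownian path on a fixed time grid
#'
#' Per-axis increments are Gaussian with variance 2 D dt; positions are
#' wrapped periodically into the simulation box (re-injection preserving a
#' uniform concentration).
#'
#' @param config a \code{SimConfig} (uses D, dt, duration, boxHalfWidth)
#' @param nSteps number of steps; default \code{duration/dt}
#' @param pos0 initial position (um); default uniform in the box
#' @param seed optional RNG seed
#' @return (nSteps+1) x 3 matrix of positions (um), first row = pos0
#' @export
simulatePath <- function(config, nSteps = NULL, pos0 = NULL, seed = NULL) {
  stopifnot(is(config, "SimConfig"))
  dt_s <- config@dt * 1e-6
  if (is.null(nSteps)) nSteps <- ceiling(config@duration / dt_s)
  withSeed(seed, {
    if (is.null(pos0)) pos0 <- runif(3, -config@boxHalfWidth, config@boxHalfWidth)
    cpp_brownian_path(as.integer(nSteps), dt_s, config@D,
      config@boxHalfWidth, pos0)
  })
}

#' Simulate a continuous-time Markov state trajectory
#'
#' Dwell times in state i are exponential with mean 1/sum_j k_ij; the next
#' state is drawn with probability k_ij / sum k_ij.
#'
#' @param scheme a \code{KineticScheme}
#' @param duration total time (s)
#' @param seed optional RNG seed
#' @param state0 initial state (default drawn from the stationary
#'   distribution)
#' @return list with \code{transitionTimes} (s, strictly increasing; first
#'   element 0 = start), \code{states} (state occupied from each time on)
#' @export
simulateStates <- function(scheme, duration, seed = NULL, state0 = NULL) {
  Q <- rateMatrix(scheme)
  n <- nStates(scheme)
  withSeed(seed, {
    if (is.null(state0))
      state0 <- sample.int(n, 1, prob = stationaryDistribution(scheme))
    times <- 0
    states <- state0
    t <- 0; s <- state0
    repeat {
      kexit <- -Q[s, s]
      if (kexit <= 0) break
      t <- t + rexp(1, kexit)
      if (t >= duration) break
      probs <- Q[s, ]; probs[s] <- 0
      s <- sample.int(n, 1, prob = probs)
      times <- c(times, t); states <- c(states, s)
    }
    list(transitionTimes = times, states = states)
  })
}

## State at arbitrary times, from a simulateStates() trajectory.
stateAt <- function(trajectory, t) {
  trajectory$states[findInterval(t, trajectory$transitionTimes)]
}

#' Emit photons from a position path and a state trajectory
#'
#' Reference (vectorized R) emitter used for controlled tests: photons arrive
#' as an inhomogeneous Poisson process with rate \code{peakRate *
#' psfIntensity}, are gated by the ALEX phase of their timestamp, FRET-split
#' by the current state's E, with direct acceptor excitation during
#' acceptor-excitation half-periods and constant per-category background.
#' Bleaching uses the same excitation-weighted first-order model as the
#' integrated simulator.  For long simulations use \code{\link{simulateStream}}.
#'
#' @param path (n x 3) position matrix on the config's dt grid (um)
#' @param trajectory a state trajectory from \code{\link{simulateStates}}
#' @param config a \code{SimConfig}
#' @param seed optional RNG seed
#' @param truth keep ground-truth columns (default TRUE)
#' @return a \code{PhotonStream}
#' @export
emitPhotons <- function(path, trajectory, config, seed = NULL, truth = TRUE) {
  stopifnot(is(config, "SimConfig"))
  dt_s <- config@dt * 1e-6
  nStep <- nrow(path) - 1L
  tGrid <- (seq_len(nStep) - 1) * dt_s
  psf <- psfIntensity(path[seq_len(nStep), , drop = FALSE], config@geometry)
  alexHalf <- if (config@alternation) config@alexPeriod * 1e-6 else Inf
  peak_s <- config@peakRate * 1000      # photons/s
  direct_s <- peak_s * config@directExFraction

  withSeed(seed, {
    ## bleach times from integrated hazards
    dutyD <- if (config@alternation) 0.5 else 1
    tBleachD <- tBleachA <- Inf
    if (config@bleachDonor > 0) {
      H <- cumsum(config@bleachDonor * psf * dutyD * dt_s)
      th <- rexp(1)
      i <- which(H >= th)[1]
      if (!is.na(i)) {
        H0 <- if (i > 1) H[i - 1] else 0
        tBleachD <- tGrid[i] + (th - H0) / (config@bleachDonor * psf[i] * dutyD)
      }
    }
    if (config@bleachAcceptor > 0) {
      H <- cumsum(config@bleachAcceptor * psf * dt_s)
      th <- rexp(1)
      i <- which(H >= th)[1]
      if (!is.na(i)) {
        H0 <- if (i > 1) H[i - 1] else 0
        tBleachA <- tGrid[i] + (th - H0) / (config@bleachAcceptor * psf[i])
      }
    }

    sampleStep <- function(ratePerStep) {
      n <- rpois(nStep, ratePerStep)
      idx <- rep.int(seq_len(nStep), n)
      tGrid[idx] + runif(length(idx)) * dt_s
    }
    inPhase <- function(t, phase) {
      if (!config@alternation) return(phase == 1L)
      (floor(t / alexHalf) %% 2) == (phase - 1L)
    }

    ## donor-excitation candidates
    tD <- sampleStep(peak_s * psf * dt_s)
    tD <- tD[inPhase(tD, 1L) & tD < tBleachD]
    stD <- stateAt(trajectory, tD)
    aliveA <- tD < tBleachA
    isAcc <- aliveA & (runif(length(tD)) < EStates(config@scheme)[stD])
    chD <- ifelse(isAcc, 2L, 1L)

    ## acceptor-excitation photons
    if (config@alternation && direct_s > 0) {
      tA <- sampleStep(direct_s * psf * dt_s)
      tA <- tA[inPhase(tA, 2L) & tA < tBleachA]
    } else tA <- numeric()
    stA <- stateAt(trajectory, tA)

    ## background, drawn in the matching laser phase
    dur <- nStep * dt_s
    bgCat <- lapply(1:3, function(i) {
      nb <- rpois(1, config@background[i] * 1000 * dur)
      tb <- sort(runif(nb, 0, dur))
      if (config@alternation) {
        offs <- if (i < 3) 0 else alexHalf
        tb <- floor(tb / (2 * alexHalf)) * 2 * alexHalf + offs +
          runif(nb) * alexHalf
        tb <- tb[tb < dur]
      } else if (i == 3L) tb <- numeric()   # no red laser
      tb
    })

    tall <- c(tD, tA, bgCat[[1]], bgCat[[2]], bgCat[[3]])
    ch <- c(chD, rep(2L, length(tA)), rep(1L, length(bgCat[[1]])),
      rep(2L, length(bgCat[[2]])), rep(2L, length(bgCat[[3]])))
    ex <- c(rep(1L, length(tD)), rep(2L, length(tA)),
      rep(1L, length(bgCat[[1]])), rep(1L, length(bgCat[[2]])),
      rep(2L, length(bgCat[[3]])))
    st <- c(stD, stA, rep(NA_integer_,
      length(bgCat[[1]]) + length(bgCat[[2]]) + length(bgCat[[3]])))
    da <- c(rep(TRUE, length(tD)), tA < tBleachD, rep(NA, length(st) - length(tD) - length(tA)))
    aa <- c(aliveA, rep(TRUE, length(tA)), rep(NA, length(st) - length(tD) - length(tA)))

    o <- order(tall)
    ts_us <- round(tall[o] * 1e6)   # stored at 1-us resolution
    tr <- if (truth) data.frame(true_state = st[o], donor_alive = da[o],
      acceptor_alive = aa[o]) else data.frame()
    photonStream(ts_us, ch[o], ex[o], tr)
  })
}

#' Integrated photon-stream simulation
#'
#' Runs the full diffusing-molecule simulation (Brownian motion, CTMC state
#' switching, PSF-modulated Poisson emission, ALEX gating, bleaching,
#' background) with a compiled core.  Far from the detection volume the
#' propagation step is lengthened adaptively (photon emission there is
#' negligible and Brownian increments are exact at any step), which makes
#' hour-scale simulated times practical.
#'
#' @param config a \code{SimConfig}; \code{nMolecules > 1} simulates
#'   independent diffusers and merges their photons
#' @param seed optional RNG seed (byte-identical streams for equal seeds)
#' @param truth keep ground-truth columns
#' @param adaptive use far-field step lengthening (default TRUE)
#' @return a \code{PhotonStream}
#' @export
simulateStream <- function(config, seed = NULL, truth = TRUE, adaptive = TRUE) {
  stopifnot(is(config, "SimConfig"))
  withSeed(seed, {
    peak_s <- config@peakRate * 1000
    alexHalf <- if (config@alternation) config@alexPeriod * 1e-6 else -1
    parts <- lapply(seq_len(config@nMolecules), function(m) {
      pos0 <- runif(3, -config@boxHalfWidth, config@boxHalfWidth)
      st0 <- sample.int(nStates(config@scheme), 1,
        prob = stationaryDistribution(config@scheme))
      cpp_simulate_stream(config@duration, config@dt * 1e-6, config@D,
        wxy(config@geometry), wz(config@geometry), config@boxHalfWidth,
        peak_s, peak_s * config@directExFraction, alexHalf,
        EStates(config@scheme), rateMatrix(config@scheme),
        config@bleachDonor, config@bleachAcceptor, pos0, st0 - 1L, adaptive)
    })
    ## background photons (volume-wide, molecule-independent)
    dur <- config@duration
    bg <- local({
      tb <- chb <- exb <- list()
      for (i in 1:3) {
        nb <- rpois(1, config@background[i] * 1000 * dur)
        t0 <- runif(nb, 0, dur)
        if (config@alternation) {
          offs <- if (i < 3) 0 else alexHalf
          t0 <- floor(t0 / (2 * alexHalf)) * 2 * alexHalf + offs +
            runif(nb) * alexHalf
          t0 <- t0[t0 < dur]
        } else if (i == 3L) t0 <- numeric()
        tb[[i]] <- t0
        chb[[i]] <- rep(if (i == 1L) 1L else 2L, length(t0))
        exb[[i]] <- rep(if (i == 3L) 2L else 1L, length(t0))
      }
      list(t = unlist(tb), ch = unlist(chb), ex = unlist(exb))
    })

    tall <- c(unlist(lapply(parts, `[[`, "t")), bg$t)
    ch <- c(unlist(lapply(parts, `[[`, "channel")), bg$ch)
    ex <- c(unlist(lapply(parts, `[[`, "excitation")), bg$ex)
    st <- c(unlist(lapply(parts, `[[`, "state")), rep(NA_integer_, length(bg$t)))
    da <- c(unlist(lapply(parts, `[[`, "donor_alive")), rep(NA_integer_, length(bg$t)))
    aa <- c(unlist(lapply(parts, `[[`, "acceptor_alive")), rep(NA_integer_, length(bg$t)))

    o <- order(tall)
    ts_us <- round(tall[o] * 1e6)
    tr <- if (truth) data.frame(true_state = st[o],
      donor_alive = as.logical(da[o]), acceptor_alive = as.logical(aa[o]))
      else data.frame()
    photonStream(ts_us, as.integer(ch[o]), as.integer(ex[o]), tr)
  })
}
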