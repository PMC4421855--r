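## Synthetic binned FRET traces and burst sets.
##
## These generators work at the level of binned counts/efficiencies (the
## HMM's input), complementing the photon-level simulator: state dynamics
## are a continuous-time Markov chain, each bin's expected efficiency is the
## occupancy-weighted mean of the state efficiencies over the bin (sub-bin
## averaging, as in real binned data), and observation noise is either
## Gaussian or binomial photon-counting noise.

## occupancy-weighted mean E per bin for a CTMC trajectory
.binMeanE <- function(trajectory, EStates, nBins, binWidth_s) {
  edges <- c(trajectory$transitionTimes, Inf)
  Ebar <- numeric(nBins)
  for (seg in seq_along(trajectory$states)) {
    t0 <- edges[seg]; t1 <- min(edges[seg + 1], nBins * binWidth_s)
    if (t0 >= nBins * binWidth_s || t1 <= t0) next
    b0 <- floor(t0 / binWidth_s) + 1; b1 <- ceiling(t1 / binWidth_s)
    for (b in b0:b1) {
      lo <- max(t0, (b - 1) * binWidth_s); hi <- min(t1, b * binWidth_s)
      if (hi > lo) Ebar[b] <- Ebar[b] + (hi - lo) / binWidth_s * EStates[trajectory$states[seg]]
    }
  }
  Ebar
}

## majority state per bin (ground truth for accuracy scoring)
.binMajorityState <- function(trajectory, nBins, binWidth_s) {
  mids <- (seq_len(nBins) - 0.5) * binWidth_s
  stateAt(trajectory, mids)
}

#' Simulate a binned FRET-efficiency trace
#'
#' @param scheme a \code{KineticScheme}
#' @param nPoints number of bins
#' @param binWidth bin width (ms)
#' @param noise "gaussian" (additive, sd = \code{sigma}) or "photon"
#'   (binomial acceptor split of Poisson donor-excitation counts)
#' @param sigma Gaussian noise sd (E units)
#' @param peakRate photons/ms at the detector for noise = "photon"; the
#'   donor-excitation count per bin is Poisson with mean
#'   \code{peakRate * binWidth / 2} (ALEX duty cycle)
#' @param seed optional RNG seed
#' @return list with \code{E} (observed series), \code{Ebar} (noise-free
#'   bin means), \code{trueStates} (majority state per bin), \code{binWidth}
#' @export
simulateETrace <- function(scheme, nPoints, binWidth = 0.5,
    noise = c("gaussian", "photon"), sigma = 0.05, peakRate = 400,
    seed = NULL) {
  noise <- match.arg(noise)
  bw_s <- binWidth / 1000
  withSeed(seed, {
    traj <- simulateStates(scheme, nPoints * bw_s)
    Ebar <- .binMeanE(traj, EStates(scheme), nPoints, bw_s)
    E <- if (noise == "gaussian") Ebar + rnorm(nPoints, 0, sigma)
    else {
      N <- rpois(nPoints, peakRate * binWidth / 2)
      ifelse(N > 0, rbinom(nPoints, N, pmin(pmax(Ebar, 0), 1)) / N, NA_real_)
    }
    list(E = E, Ebar = Ebar, trueStates = .binMajorityState(traj, nPoints, bw_s),
      binWidth = binWidth)
  })
}

#' Simulate a set of single-molecule bursts at the binned level
#'
#' Emulates the analysed output of the liposome-tethered experiment: each
#' burst has a duration drawn as \code{minDuration} plus an exponential
#' excess, two-state (or N-state) CTMC FRET dynamics, Poisson
#' donor-excitation counts per bin with binomial FRET splitting, Poisson
#' direct acceptor-excitation counts, and optional permanent acceptor
#' photobleaching (FRET photons reroute to the donor channel and the
#' acceptor-excitation signal drops to background, producing the terminal S
#' rise the stoichiometry filter truncates).
#'
#' @param nBursts number of bursts
#' @param scheme a \code{KineticScheme}
#' @param binWidth bin width (ms)
#' @param peakRate photons/ms at the centre under donor excitation; the
#'   donor-excitation sum per bin has mean \code{peakRate * binWidth / 2}
#' @param directExFraction acceptor direct-excitation brightness fraction
#' @param minDuration,meanExcess burst duration model (ms): duration =
#'   minDuration + Exp(meanExcess)
#' @param durations explicit durations (ms), overriding the duration model
#' @param bleachAcceptor acceptor bleach rate (s^-1; 0 = off)
#' @param background photons/ms added to each category
#' @param envelope "transit" (default) modulates the brightness by the PSF
#'   of a diffusing position confined above the burst-search detectability
#'   floor, as in a real above-threshold transit; "flat" holds the
#'   brightness at \code{peakRate}
#' @param D diffusion coefficient for the transit envelope (um^2 s^-1)
#' @param psfFloor lowest relative excitation inside a detected burst; the
#'   default 0.3 is the 30-photon / 0.5-ms / 400 photons-per-ms detection
#'   floor of the donor-excitation sum channel
#' @param seed optional RNG seed
#' @return list with \code{traces} (list of \code{BinnedTrace}),
#'   \code{trueStates} (majority state per bin), \code{durations} (ms)
#' @export
simulateBurstSet <- function(nBursts, scheme = twoStateScheme(),
    binWidth = 0.5, peakRate = 400, directExFraction = 0.67,
    minDuration = 15, meanExcess = 10, durations = NULL,
    bleachAcceptor = 0, background = 0.1,
    envelope = c("transit", "flat"), D = 3.0,
    psfFloor = 0.3, geometry = calibrateGeometry(), seed = NULL) {
  envelope <- match.arg(envelope)
  bw_s <- binWidth / 1000
  ## confined-transit brightness: PSF of a Brownian position reflected at
  ## the detectability surface, in scaled coordinates where the PSF is
  ## exp(-|v|^2)
  transitEnvelope <- function(nb) {
    R <- sqrt(-log(psfFloor))
    sdv <- sqrt(2 * D * bw_s) * sqrt(2) / c(wxy(geometry), wxy(geometry),
      wz(geometry))
    v <- runif(3, -1, 1)
    v <- v / sqrt(sum(v^2)) * R * runif(1)^(1 / 3)
    e <- numeric(nb)
    for (b in seq_len(nb)) {
      e[b] <- exp(-sum(v^2))
      vn <- v + rnorm(3) * sdv
      r <- sqrt(sum(vn^2))
      if (r > R) vn <- vn * max(2 * R - r, 0.01) / r    # radial reflection
      v <- vn
    }
    e
  }
  withSeed(seed, {
    if (is.null(durations))
      durations <- minDuration + rexp(nBursts, 1 / meanExcess)
    traces <- vector("list", nBursts)
    truths <- vector("list", nBursts)
    for (i in seq_len(nBursts)) {
      nb <- max(2L, floor(durations[i] / binWidth))
      traj <- simulateStates(scheme, nb * bw_s)
      Ebar <- .binMeanE(traj, EStates(scheme), nb, bw_s)
      env <- if (envelope == "transit") transitEnvelope(nb) else rep(1, nb)
      N <- rpois(nb, peakRate * env * binWidth / 2 + background * binWidth)
      nA <- rbinom(nb, N, pmin(pmax(Ebar, 0), 1))
      aex <- rpois(nb, peakRate * directExFraction * env * binWidth / 2 +
        background * binWidth)
      if (bleachAcceptor > 0) {
        tb <- rexp(1, bleachAcceptor)
        dark <- which((seq_len(nb) - 0.5) * bw_s > tb)
        if (length(dark)) {
          nA[dark] <- 0                                   # FRET -> donor channel
          aex[dark] <- rpois(length(dark), background * binWidth)
        }
      }
      traces[[i]] <- binnedTrace(N - nA, nA, aex, binWidth)
      truths[[i]] <- .binMajorityState(traj, nb, bw_s)
    }
    list(traces = traces, trueStates = truths, durations = durations)
  })
}

#' Write versioned synthetic fixture datasets
#'
#' Emits the small synthetic datasets used by the test-suite and examples:
#' \describe{
#'   \item{free_dsdna / tethered_dsdna}{photon streams of a single-dye
#'     species diffusing at D = 46.4 / 3.0 um^2/s (CSV photon tables)}
#'   \item{hj_2state}{a Holliday-junction-like two-state burst set
#'     (>= 180 bursts of >= 15 ms) as a binned-count table}
#'   \item{ssb_multistep}{a 4-state nearest-neighbour stepping burst set}
#'   \item{bleach}{bursts with elevated acceptor bleaching (terminal S jumps)}
#' }
#' Files are byte-stable under a fixed seed.
#'
#' @param suite one of the names above
#' @param seed RNG seed
#' @param dir output directory
#' @return invisible character vector of files written
#' @export
makeFixtures <- function(suite = c("free_dsdna", "tethered_dsdna",
    "hj_2state", "ssb_multistep", "bleach"), seed = 1,
    dir = tempfile("fixtures")) {
  suite <- match.arg(suite)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geom <- calibrateGeometry()
  writeBurstSet <- function(bs, path) {
    df <- do.call(rbind, lapply(seq_along(bs$traces), function(i) {
      cts <- counts(bs$traces[[i]])
      data.frame(burst = i, bin = seq_len(nrow(cts)), DexDem = cts[, 1],
        DexAem = cts[, 2], AexAem = cts[, 3], true_state = bs$trueStates[[i]])
    }))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    path
  }
  files <- switch(suite,
    free_dsdna = , tethered_dsdna = {
      D <- if (suite == "free_dsdna") 46.4 else 3.0
      cfg <- simConfig(geometry = geom, scheme = staticScheme(0.05), D = D,
        peakRate = 100, alternation = FALSE, background = 0.1,
        duration = 20, boxHalfWidth = 3 * wz(geom))
      f <- file.path(dir, paste0(suite, "_photons.csv"))
      writePhotons(simulateStream(cfg, seed = seed, truth = FALSE), f)
      f
    },
    hj_2state = {
      bs <- simulateBurstSet(190, twoStateScheme(), seed = seed)
      writeBurstSet(bs, file.path(dir, "hj_2state_bursts.csv"))
    },
    ssb_multistep = {
      k <- 200
      Q <- matrix(0, 4, 4)
      for (i in 1:3) { Q[i, i + 1] <- k; Q[i + 1, i] <- k }
      bs <- simulateBurstSet(60, kineticScheme(c(0.2, 0.4, 0.6, 0.8), Q),
        minDuration = 25, seed = seed)
      writeBurstSet(bs, file.path(dir, "ssb_multistep_bursts.csv"))
    },
    bleach = {
      bs <- simulateBurstSet(30, twoStateScheme(), bleachAcceptor = 40,
        minDuration = 20, seed = seed)
      writeBurstSet(bs, file.path(dir, "bleach_bursts.csv"))
    })
  invisible(files)
}

#' Read a burst-set fixture written by \code{\link{makeFixtures}}
#'
#' @param path the CSV file
#' @param binWidth bin width of the stored counts (ms)
#' @return list with \code{traces} and \code{trueStates}, as
#'   \code{\link{simulateBurstSet}}
#' @export
readBurstSet <- function(path, binWidth = 0.5) {
  df <- read.csv(path)
  ids <- unique(df$burst)
  traces <- lapply(ids, function(i) {
    d <- df[df$burst == i, ]
    binnedTrace(d$DexDem, d$DexAem, d$AexAem, binWidth)
  })
  truths <- lapply(ids, function(i) df$true_state[df$burst == i])
  list(traces = traces, trueStates = truths)
}
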