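## End-to-end orchestration: simulate (or read) -> bin -> burst search ->
## E/S -> stoichiometry filter -> minimum-length filter -> stitch -> VB-HMM
## -> unstitch -> dwells -> rates / transition density.

#' Default pipeline configuration
#'
#' Analysis defaults mirror the standard operating point: 0.5-ms bins,
#' 30-photon dual-channel threshold, S-filter window 5 bins / jump 0.2,
#' stitching to ~150 points, VB-HMM with Kmax 4, dwell fits with a 2-bin
#' cutoff and censored dwells excluded, minimum-length factor 4.
#'
#' @param ... named overrides of the defaults (nested lists merged)
#' @return configuration list
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    simulation = list(
      mode = "bursts",            # "bursts", "photons" or "file"
      nBursts = 200, k12 = 300, k21 = 282, EStates = c(0.25, 0.75),
      peakRate = 400, directExFraction = 0.67,
      minDuration = 15, meanExcess = 10, bleachAcceptor = 0,
      file = NULL, D = 3.0, duration = 10),
    analysis = list(
      binWidth = 0.5, threshold = 30, search = "dual",
      sWindow = 5, sJump = 0.2,
      minLengthFactor = 4, firstPassMinMs = 10,
      targetPoints = 150, Kmax = 4, restarts = 5,
      minBins = 2, minDwells = 20),
    seed = 1)
  user <- list(...)
  for (nm in names(user)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(user[[nm]]))
      modifyList(cfg[[nm]], user[[nm]]) else user[[nm]]
  }
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file mirroring \code{\link{pipelineConfig}} fields
#' @return configuration list (defaults merged)
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

## stable short hash of a configuration (DJB2 over its YAML serialization)
configHash <- function(cfg) {
  cfg$seed <- NULL
  s <- utf8ToInt(yaml::as.yaml(cfg[order(names(cfg))]))
  h <- 5381
  for (v in s) h <- (h * 33 + v) %% 2^31
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Generates (or reads) data, detects bursts, computes E/S, applies the
#' stoichiometry and minimum-length filters, stitches, idealizes with the
#' evidence-selected VB-HMM, separates the idealized paths, and fits
#' dwell-time rates.  The state count is chosen by the summed evidence over
#' stitched traces, so one model describes the whole data set.
#'
#' @param config from \code{\link{pipelineConfig}} /
#'   \code{\link{readPipelineConfig}}
#' @param verbose print stage-wise counts
#' @return list with \code{rates} (per transition type), \code{K},
#'   \code{mu}, \code{tdp}, \code{log} (stage counts), \code{fits},
#'   \code{dwells}, \code{configHash}, \code{config}
#' @export
runPipeline <- function(config = pipelineConfig(), verbose = FALSE) {
  sim <- config$simulation; an <- config$analysis
  say <- function(...) if (verbose) message(sprintf(...))
  logCounts <- list()

  ## 1) data acquisition: per-burst binned traces
  esList <- withSeed(config$seed, {
    makeScheme <- function() {
      if (!is.null(sim$Q)) kineticScheme(sim$EStates, sim$Q)
      else kineticScheme(sim$EStates,
        matrix(c(0, sim$k12, sim$k21, 0), 2, 2, byrow = TRUE))
    }
    if (sim$mode == "bursts") {
      scheme <- makeScheme()
      bs <- simulateBurstSet(sim$nBursts, scheme, binWidth = an$binWidth,
        peakRate = sim$peakRate, directExFraction = sim$directExFraction,
        minDuration = sim$minDuration, meanExcess = sim$meanExcess,
        bleachAcceptor = sim$bleachAcceptor)
      lapply(seq_along(bs$traces), function(i) {
        es <- computeES(bs$traces[[i]])
        es@sourceId <- sprintf("burst_%03d", i)
        es
      })
    } else {
      stream <- if (sim$mode == "file") readPhotons(sim$file)
        else {
          geom <- calibrateGeometry()
          simulateStream(simConfig(geometry = geom, scheme = makeScheme(),
            D = sim$D, peakRate = sim$peakRate,
            directExFraction = sim$directExFraction,
            duration = sim$duration))
        }
      trace <- binPhotons(stream, an$binWidth)
      bursts <- if (an$search == "dual")
        dualChannelBurstSearch(trace, an$threshold)
        else singleChannelBurstSearch(trace, an$threshold)
      lapply(seq_len(nrow(bursts)), function(i)
        computeES(trace, bursts[i, ]))
    }
  })
  logCounts$burstsFound <- length(esList)
  say("bursts found: %d", logCounts$burstsFound)
  if (!length(esList)) {
    return(list(rates = NULL, K = NA_integer_, mu = numeric(), tdp = NULL,
      log = logCounts, fits = list(), dwells = NULL,
      configHash = configHash(config), config = config))
  }

  ## 2) stoichiometry filter
  esList <- lapply(esList, filterByStoichiometry,
    jumpThreshold = an$sJump, window = an$sWindow)
  disp <- vapply(esList, disposition, character(1))
  logCounts$discardedByS <- sum(disp == "discarded")
  logCounts$truncatedByS <- sum(disp == "truncated")
  esList <- esList[disp != "discarded"]
  say("after S filter: %d kept (%d truncated, %d discarded)",
    length(esList), logCounts$truncatedByS, logCounts$discardedByS)

  ## 3) two-pass minimum-length rule: first-pass rates on bursts >= 10 ms
  ## give the mean dwell, then keep bursts >= factor * mean dwell
  bw <- an$binWidth
  firstPass <- esList[vapply(esList,
    function(e) length(e@E) * bw >= an$firstPassMinMs, logical(1))]
  analyseSet <- function(set, seedOff = 0) {
    stitched <- stitchTraces(set, targetPoints = an$targetPoints)
    if (!length(stitched)) stop("no stitchable traces")
    evidenceByK <- sapply(seq_len(an$Kmax), function(K) {
      sum(vapply(seq_along(stitched), function(i)
        evidence(vbemFit(stitched[[i]]@E, K, restarts = an$restarts,
          seed = config$seed + seedOff + i, binWidth = bw)), numeric(1)))
    })
    K <- which.max(evidenceByK)
    fits <- lapply(seq_along(stitched), function(i)
      vbemFit(stitched[[i]]@E, K, restarts = an$restarts,
        seed = config$seed + seedOff + i, binWidth = bw))
    ## bins straddling a transition can earn a dedicated sub-resolution
    ## state on bright data; collapse those before dwell analysis
    coll <- lapply(seq_along(stitched), function(i)
      collapseSubResolutionStates(fits[[i]], stitched[[i]]@E))
    ## common state space: the modal collapsed state count across traces;
    ## every trace's states are mapped to the nearest global mean
    nK <- vapply(coll, function(cc) length(cc$keptStates), integer(1))
    Keff <- as.integer(names(which.max(table(nK))))
    muEff <- if (Keff == 1L) mean(vapply(coll[nK == 1L], function(cc) cc$mu,
      numeric(1))) else rowMeans(vapply(coll[nK == Keff], function(cc) cc$mu,
      numeric(Keff)))
    paths <- unlist(lapply(seq_along(stitched), function(i) {
      cc <- coll[[i]]
      mapped <- vapply(cc$mu, function(m) which.min(abs(m - muEff)),
        integer(1))
      unstitchAndClean(stitched[[i]], mapped[cc$path])
    }), recursive = FALSE)
    dwells <- extractDwells(paths, bw)
    list(K = Keff, Kmodel = K, mu = muEff, fits = fits, paths = paths,
      dwells = dwells, evidenceByK = evidenceByK)
  }
  fp <- analyseSet(firstPass, seedOff = 10000)
  fpRates <- tryCatch({
    lapply(seq_len(fp$K), function(s) fitDwellRate(fp$dwells, s,
      binWidth = bw, minBins = an$minBins, minDwells = an$minDwells))
  }, error = function(e) NULL)
  meanDwell <- if (is.null(fpRates)) 3
    else 1000 * mean(vapply(fpRates, function(r) 1 / r$k, numeric(1)))
  logCounts$firstPassMeanDwell_ms <- meanDwell
  say("first-pass mean dwell: %.2f ms", meanDwell)

  ## 4) final pass
  kept <- minimumLengthFilter(esList, meanDwell, an$minLengthFactor)
  logCounts$afterLengthFilter <- length(kept)
  say("after minimum-length filter (%.1f ms): %d bursts",
    an$minLengthFactor * meanDwell, length(kept))
  res <- analyseSet(kept, seedOff = 0)

  mu <- res$mu
  rates <- list()
  for (s in seq_len(res$K)) {
    r <- tryCatch(fitDwellRate(res$dwells, s, binWidth = bw,
      minBins = an$minBins, minDwells = an$minDwells),
      error = function(e) NULL)
    if (!is.null(r)) rates[[sprintf("state%d", s)]] <- r
  }
  logCounts$dwells <- nrow(res$dwells)
  tdp <- transitionDensity(res$paths, mu)

  list(rates = rates, K = res$K, mu = mu, tdp = tdp, log = logCounts,
    fits = res$fits, dwells = res$dwells, evidenceByK = res$evidenceByK,
    configHash = configHash(config), config = config)
}
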