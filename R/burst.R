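## Burst detection, E/S computation, and stoichiometry filtering.

#' Bin a photon stream into the three ALEX intensity series
#'
#' Photons are categorized by (excitation, channel) into F(Dex,Dem),
#' F(Dex,Aem) and F(Aex,Aem) and counted on half-open bins [t, t + width).
#'
#' @param stream a \code{PhotonStream}
#' @param binWidth bin width (ms)
#' @param duration optional trace span (ms); default covers the last photon
#' @return a \code{BinnedTrace}
#' @export
binPhotons <- function(stream, binWidth, duration = NULL) {
  stopifnot(binWidth > 0)
  w_us <- binWidth * 1000
  if (is.null(duration)) {
    n <- if (length(stream) == 0) 1L
      else as.integer(floor(max(stream@timestamps) / w_us)) + 1L
  } else n <- as.integer(ceiling(duration / binWidth))
  idx <- floor(stream@timestamps / w_us) + 1
  keep <- idx >= 1 & idx <= n
  cat3 <- as.integer(photonCategories(stream))
  m <- matrix(0L, n, 3, dimnames = list(NULL, c("DexDem", "DexAem", "AexAem")))
  for (j in 1:3) {
    sel <- keep & cat3 == j
    if (any(sel)) m[, j] <- tabulate(idx[sel], nbins = n)
  }
  new("BinnedTrace", binWidth = binWidth, counts = m, origin = 0)
}

## maximal runs of TRUE in a logical mask -> burst table
.burstsFromMask <- function(trace, mask, sourceId) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  if (!length(sel)) {
    return(data.frame(sourceId = character(), startBin = integer(),
      endBin = integer(), duration = numeric(), nDexDem = integer(),
      nDexAem = integer(), nAexAem = integer(), stringsAsFactors = FALSE))
  }
  s <- starts[sel]; e <- ends[sel] + 1L   # half-open [startBin, endBin)
  cm <- apply(counts(trace), 2, cumsum)
  cm <- rbind(0L, cm)
  data.frame(sourceId = sprintf("%s_b%03d", sourceId, seq_along(s)),
    startBin = s - 1L, endBin = e - 1L,               # 0-based, half-open
    duration = (e - s) * binWidth(trace),
    nDexDem = cm[e, 1] - cm[s, 1], nDexAem = cm[e, 2] - cm[s, 2],
    nAexAem = cm[e, 3] - cm[s, 3], stringsAsFactors = FALSE)
}

#' Dual-channel burst search
#'
#' A burst is a maximal run of consecutive bins satisfying both thresholds
#' simultaneously: F(Dex,Dem) + F(Dex,Aem) > threshold AND F(Aex,Aem) >
#' threshold (strict).  The second condition admits only dually labelled
#' molecules, rejecting donor-only species and acceptor-bleached stretches.
#' Default threshold: 30 photons per bin for 1-ms and 0.5-ms bins; use 20
#' for 0.2-ms bins.
#'
#' @param trace a \code{BinnedTrace}
#' @param threshold photons per bin (strict >)
#' @param sourceId id prefix for burst names
#' @return data.frame with columns sourceId, startBin, endBin (0-based,
#'   half-open), duration (ms), nDexDem, nDexAem, nAexAem
#' @export
dualChannelBurstSearch <- function(trace, threshold = 30, sourceId = "trace") {
  stopifnot(threshold > 0)
  cts <- counts(trace)
  mask <- (cts[, 1] + cts[, 2] > threshold) & (cts[, 3] > threshold)
  .burstsFromMask(trace, mask, sourceId)
}

#' Single-channel burst search
#'
#' As \code{\link{dualChannelBurstSearch}} but thresholding only the
#' donor-excitation sum F(Dex,Dem) + F(Dex,Aem); used for single-dye species
#' and FCS-mode streams.
#'
#' @inheritParams dualChannelBurstSearch
#' @return burst data.frame (see \code{\link{dualChannelBurstSearch}})
#' @export
singleChannelBurstSearch <- function(trace, threshold = 30, sourceId = "trace") {
  stopifnot(threshold > 0)
  cts <- counts(trace)
  .burstsFromMask(trace, cts[, 1] + cts[, 2] > threshold, sourceId)
}

#' Per-bin FRET efficiency and stoichiometry of a burst
#'
#' E = F(Dex,Aem) / (F(Dex,Dem) + F(Dex,Aem)) is the uncorrected proximity
#' ratio; S = (F(Dex,Dem) + F(Dex,Aem)) / (all three).  Zero-denominator
#' bins are flagged invalid (NA), never propagated.
#'
#' @param trace a \code{BinnedTrace}
#' @param burst one row of a burst data.frame (or a list with startBin,
#'   endBin, sourceId); NULL takes the whole trace
#' @return an \code{ESTrace}
#' @export
computeES <- function(trace, burst = NULL) {
  if (is.null(burst))
    burst <- list(startBin = 0L, endBin = nBins(trace),
      sourceId = "trace_full")
  stopifnot(burst$startBin >= 0, burst$endBin <= nBins(trace),
    burst$endBin > burst$startBin)
  idx <- (burst$startBin + 1L):burst$endBin
  cts <- counts(trace)[idx, , drop = FALSE]
  dex <- cts[, 1] + cts[, 2]
  tot <- dex + cts[, 3]
  E <- ifelse(dex > 0, cts[, 2] / dex, NA_real_)
  S <- ifelse(tot > 0, dex / tot, NA_real_)
  new("ESTrace", E = E, S = S, valid = dex > 0, counts = cts,
    binWidth = binWidth(trace), disposition = "clean",
    truncIndex = NA_integer_, sourceId = as.character(burst$sourceId),
    shortWarning = FALSE)
}

#' Stoichiometry-based artifact filter
#'
#' Detects sustained S-level changes with a moving-window mean: at each
#' interior bin the means of the preceding and following \code{window} bins
#' are compared.  A single rise exceeding \code{jumpThreshold} that persists
#' to the end of the burst is the signature of permanent acceptor
#' photobleaching: the trace is kept but truncated at the change point.  Any
#' other sustained S change (transient excursions, drops, multiple events)
#' marks photophysics (blinking, spectral shift) and discards the trace.
#'
#' @param es an \code{ESTrace}
#' @param jumpThreshold minimum sustained |delta S| (default 0.2)
#' @param window moving-window length in bins (default 5)
#' @return the \code{ESTrace} with disposition (and truncIndex) set; bursts
#'   shorter than 2*window are returned clean with \code{shortWarning}
#' @export
filterByStoichiometry <- function(es, jumpThreshold = 0.2, window = 5) {
  n <- length(es@E)
  if (n < 2 * window) {
    es@shortWarning <- TRUE
    es@disposition <- "clean"
    return(es)
  }
  s <- es@S
  pos <- (window + 1L):(n - window + 1L)
  delta <- vapply(pos, function(i) {
    mean(s[(i - window):(i - 1L)], na.rm = TRUE) -
      mean(s[i:(i + window - 1L)], na.rm = TRUE)
  }, numeric(1))
  delta <- -delta                      # positive = S rises at i
  hit <- which(abs(delta) > jumpThreshold & is.finite(delta))
  if (!length(hit)) {
    es@disposition <- "clean"
    return(es)
  }
  ## merge contiguous hit runs (within one window) into events;
  ## event index = bin position of max |delta| within the run
  ev <- split(hit, cumsum(c(1, diff(hit) > window)))
  evIdx <- vapply(ev, function(ii) {
    d <- abs(delta[ii]); pos[ii[which.max(d)]]
  }, numeric(1))
  evSign <- vapply(ev, function(ii) sign(delta[ii[which.max(abs(delta[ii]))]]),
    numeric(1))
  if (length(evIdx) == 1L && evSign[1] > 0) {
    cpt <- as.integer(evIdx[1])
    pre <- mean(s[1:(cpt - 1L)], na.rm = TRUE)
    tailMean <- mean(s[max(cpt, n - window + 1L):n], na.rm = TRUE)
    if (is.finite(tailMean) && tailMean - pre > jumpThreshold) {
      es@disposition <- "truncated"
      es@truncIndex <- cpt
      return(es)
    }
  }
  es@disposition <- "discarded"
  es
}

#' Fraction of bursts longer than a duration cutoff
#'
#' @param bursts burst data.frame (needs a \code{duration} column, ms)
#' @param cutoff duration cutoff (ms, strict >; default 10)
#' @return fraction in [0, 1]
#' @export
longBurstFraction <- function(bursts, cutoff = 10) {
  if (nrow(bursts) == 0) stop("undefined fraction: no bursts")
  mean(bursts$duration > cutoff)
}

#' Simulate burst-duration statistics of a diffusing species
#'
#' Runs the integrated photon simulation in chunks until at least
#' \code{minBursts} bursts are detected, returning their durations.  Bursts
#' touching a chunk edge are dropped (their duration is censored by the
#' chunking).
#'
#' @param config a \code{SimConfig}; its \code{duration} is the chunk length
#' @param threshold photons per bin
#' @param binWidth bin width (ms)
#' @param minBursts stop once this many bursts are collected
#' @param maxChunks safety cap on the number of chunks
#' @param search "single" (donor-sum only) or "dual"
#' @param seed RNG seed; chunk c uses seed + c - 1
#' @return numeric vector of burst durations (ms)
#' @export
simulateBurstDurations <- function(config, threshold = 30, binWidth = 1,
    minBursts = 500, maxChunks = 200, search = c("single", "dual"),
    seed = 1) {
  search <- match.arg(search)
  durations <- numeric()
  for (chunk in seq_len(maxChunks)) {
    stream <- simulateStream(config, seed = seed + chunk - 1, truth = FALSE)
    trace <- binPhotons(stream, binWidth,
      duration = config@duration * 1000)
    b <- if (search == "dual") dualChannelBurstSearch(trace, threshold)
      else singleChannelBurstSearch(trace, threshold)
    if (nrow(b)) {
      edge <- b$startBin == 0 | b$endBin == nBins(trace)
      durations <- c(durations, b$duration[!edge])
    }
    if (length(durations) >= minBursts) break
  }
  durations
}
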