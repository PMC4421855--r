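## Stitch-fit-unstitch kinetics: trace stitching, dwell extraction,
## exponential rate fits, transition-density plots, truncation sensitivity
## and Arrhenius analysis.

#' Usable E series of a filtered burst
#'
#' Valid bins only; truncated bursts are cut before the bleach point;
#' discarded bursts yield NULL.
#'
#' @param es an \code{ESTrace}
#' @return numeric E series or NULL
#' @export
esSeries <- function(es) {
  if (es@disposition == "discarded") return(NULL)
  idx <- if (es@disposition == "truncated") seq_len(es@truncIndex - 1L)
    else seq_along(es@E)
  E <- es@E[idx][es@valid[idx]]
  if (length(E)) E else NULL
}

#' Stitch burst E series for HMM fitting
#'
#' Concatenates bursts (acquisition order preserved) into traces with enough
#' points for a stable HMM fit.  Grouping either fills each stitched trace to
#' \code{targetPoints} (the 100-200-point working range; 5-10 typical bursts
#' per stitch) or uses a fixed \code{groupSize}.
#'
#' @param esList list of filtered \code{ESTrace} objects (discarded bursts
#'   are skipped)
#' @param groupSize fixed number of bursts per stitch (overrides
#'   \code{targetPoints})
#' @param targetPoints close a group once it reaches this many points
#' @param shuffleSeed optional seed to randomize burst order (order
#'   independence checks); default keeps acquisition order
#' @return list of \code{StitchedTrace}
#' @export
stitchTraces <- function(esList, groupSize = NULL, targetPoints = 150,
    shuffleSeed = NULL) {
  if (!length(esList)) return(list())
  series <- lapply(esList, esSeries)
  ids <- vapply(esList, function(e) e@sourceId, character(1))
  keep <- !vapply(series, is.null, logical(1))
  series <- series[keep]; ids <- ids[keep]
  if (!length(series)) return(list())
  bw <- esList[[which(keep)[1]]]@binWidth
  if (!is.null(shuffleSeed)) {
    o <- withSeed(shuffleSeed, sample.int(length(series)))
    series <- series[o]; ids <- ids[o]
  }
  groups <- list(); cur <- integer(); pts <- 0L
  for (i in seq_along(series)) {
    cur <- c(cur, i); pts <- pts + length(series[[i]])
    done <- if (!is.null(groupSize)) length(cur) >= groupSize
      else pts >= targetPoints
    if (done) { groups <- c(groups, list(cur)); cur <- integer(); pts <- 0L }
  }
  if (length(cur)) groups <- c(groups, list(cur))
  lapply(groups, function(g) {
    new("StitchedTrace", E = unlist(series[g], use.names = FALSE),
      segLengths = vapply(series[g], length, integer(1)),
      sourceIds = ids[g], binWidth = bw)
  })
}

#' Separate a stitched idealized path into per-burst paths
#'
#' The fitted state path is split at the stitch boundaries; a state change
#' across a boundary is a stitching artifact and is not counted as a
#' transition (splitting removes it by construction).  Dwells abutting a
#' boundary become the first/last dwell of their segment and are flagged
#' censored downstream.
#'
#' @param stitched a \code{StitchedTrace}
#' @param path integer state path aligned to the stitched series
#' @return named list of per-burst integer paths
#' @export
unstitchAndClean <- function(stitched, path) {
  if (length(path) != length(stitched@E))
    stop("path length does not match stitched trace")
  ends <- cumsum(stitched@segLengths)
  starts <- c(1L, head(ends, -1) + 1L)
  out <- lapply(seq_along(ends), function(i) path[starts[i]:ends[i]])
  names(out) <- stitched@sourceIds
  out
}

#' Extract dwell records from idealized per-burst paths
#'
#' A dwell is a maximal run of one state.  The first and last dwell of each
#' burst are censored (their true extent is cut by the burst edges or by a
#' stitch boundary) and excluded from rate fits.
#'
#' @param paths list of integer state paths (one per burst)
#' @param binWidth bin width (ms)
#' @return data.frame with duration (ms), nBins, fromState, toState,
#'   leftCensored, rightCensored, burst
#' @export
extractDwells <- function(paths, binWidth) {
  if (is.integer(paths) || is.numeric(paths)) paths <- list(paths)
  recs <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    r <- rle(as.integer(p))
    nr <- length(r$lengths)
    data.frame(duration = r$lengths * binWidth, nBins = r$lengths,
      fromState = r$values,
      toState = c(r$values[-1], NA_integer_),
      leftCensored = seq_len(nr) == 1L,
      rightCensored = seq_len(nr) == nr,
      segLength = length(p),
      burst = if (!is.null(names(paths))) names(paths)[i] else as.character(i),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Exponential rate from a dwell-time distribution
#'
#' Maximum-likelihood fit for the requested transition type.  Run lengths of
#' the majority-state idealized path are geometric with p = 1 - exp(-k dt)
#' (a dwell of length tau spans ~round(tau/dt) bins), so the fitted per-bin
#' exit probability converts to a rate as k = -ln(1-p)/dt.
#'
#' Censoring and truncation are handled in the per-bin Bernoulli view of
#' the idealized path.  A dwell whose exit is observed contributes
#' (n - minBins) continuation failures and one exit (dwells shorter than
#' \code{minBins} bins are excluded as resolution-limited and the
#' likelihood conditioned on n >= minBins); the last dwell of every burst
#' or stitched segment has an unobserved exit and contributes its survival,
#' n - 1 failures.  An unobserved dwell entry (first dwell of a segment)
#' needs no correction under memorylessness.  Dropping the edge dwells
#' entirely instead ("exclude") over-represents short dwells inside short
#' segments and overestimates rates - the effect that makes rates from
#' too-short traces unreliable.  The closed-form MLE is
#' p = C / (C + sum(n_exit - minBins) + sum(n_last - 1)).
#'
#' For two-state dwell sets the per-bin exit probabilities of both states
#' are inverted jointly through the discrete-time embedding of the sampled
#' chain (p_i = (k_i/s)(1 - exp(-s dt)), s = k12 + k21), and a first-order
#' missed-event correction is applied: sojourns shorter than about half a
#' bin cannot be registered by a binned idealization, so each exit rate is
#' multiplied by exp(k_other * d) with dead time d = deadTimeBins * dt
#' (the classical single-channel missed-event treatment), solved by fixed
#' point.  \code{conversion = "rounding"} instead uses the plain
#' k = -ln(1-p)/dt majority-rounding model with no missed-event term.
#'
#' Alternatives: \code{censoring = "exclude"} drops censored dwells (the
#' naive estimator); \code{method = "lsq"} fits the log dwell histogram by
#' least squares as a cross-check.
#'
#' @param dwells data.frame from \code{\link{extractDwells}}
#' @param from state index whose dwells are fitted
#' @param to optional destination state (default: any); censored dwells
#'   have no recorded destination and are used for any \code{to}
#' @param binWidth bin width (ms)
#' @param minBins short-dwell cutoff for complete dwells (default 2 bins)
#' @param minDwells minimum number of complete dwells (default 20)
#' @param method "mle" or "lsq"
#' @param censoring "survival" (default) or "exclude"
#' @param conversion "embedding" (two-state embedding + missed-event
#'   correction, the default) or "rounding" (-ln(1-p)/dt)
#' @param deadTimeBins missed-event dead time in bins (default 0.5)
#' @return list with k (s^-1), stderr (k/sqrt(n)), n (complete dwells),
#'   nCensored, method
#' @export
fitDwellRate <- function(dwells, from, to = NULL, binWidth,
    minBins = 2, minDwells = 20, method = c("mle", "lsq"),
    censoring = c("survival", "exclude"),
    conversion = c("embedding", "rounding"), deadTimeBins = 0.5) {
  method <- match.arg(method)
  censoring <- match.arg(censoring)
  conversion <- match.arg(conversion)
  isFrom <- dwells$fromState == from
  exitSeen <- !dwells$rightCensored
  if (censoring == "exclude") exitSeen <- exitSeen & !dwells$leftCensored
  sel <- isFrom & exitSeen & dwells$nBins >= minBins
  if (!is.null(to)) sel <- sel & dwells$toState == to
  n <- sum(sel)
  if (n < minDwells)
    stop(sprintf("insufficient dwells for state %d: %d < %d", from, n, minDwells))
  dt_s <- binWidth / 1000

  exitProb <- function(selC, selS) {
    nb <- dwells$nBins[selC]
    if (method == "lsq") {
      tab <- table(nb)
      if (sum(tab >= 5) >= 3) tab <- tab[tab >= 5]   # log-count bias guard
      x <- as.numeric(names(tab)); y <- log(as.numeric(tab))
      if (length(x) < 3) return(1 / (mean(nb) - minBins + 1))
      return(1 - exp(coef(lm(y ~ x, weights = as.numeric(tab)))[2]))
    }
    nsurv <- if (censoring == "survival") sum(dwells$nBins[selS] - 1) else 0
    length(nb) / (length(nb) + sum(nb - minBins) + nsurv)
  }
  p <- exitProb(sel, isFrom & dwells$rightCensored)

  states <- sort(unique(dwells$fromState))
  if (conversion == "embedding" && length(states) == 2 && from %in% states) {
    other <- setdiff(states, from)
    isO <- dwells$fromState == other
    selO <- isO & exitSeen & dwells$nBins >= minBins
    if (sum(selO) >= minDwells) {
      q <- exitProb(selO, isO & dwells$rightCensored)
      ## point-sampled two-state chain: p_i = (k_i/s)(1 - e^{-s dt})
      tot <- min(p + q, 0.999)
      s <- -log(1 - tot) / dt_s
      kf <- p / (p + q) * s
      ko <- q / (p + q) * s
      d <- deadTimeBins * dt_s
      if (d > 0) {
        kf0 <- kf; ko0 <- ko
        for (it in 1:8) {
          kf1 <- kf0 * exp(ko * d); ko1 <- ko0 * exp(kf * d)
          kf <- kf1; ko <- ko1
        }
      }
      return(list(k = unname(kf), stderr = unname(kf / sqrt(n)), n = n,
        nCensored = sum(isFrom & dwells$rightCensored),
        method = paste0(method, "+embedding")))
    }
  }
  k <- -log(1 - min(p, 0.999)) / dt_s
  list(k = unname(k), stderr = unname(k / sqrt(n)), n = n,
    nCensored = sum(isFrom & dwells$rightCensored), method = method)
}

#' Transition-density histogram
#'
#' 2D histogram over (E before, E after) of every transition in the
#' separated per-burst idealized paths, using the fitted state means.
#'
#' @param paths list of per-burst integer state paths
#' @param EMeans fitted emission mean per state
#' @param nbins histogram bins per axis on [0, 1]
#' @return list with counts (nbins x nbins), breaks, nTransitions
#' @export
transitionDensity <- function(paths, EMeans, nbins = 50) {
  if (is.integer(paths) || is.numeric(paths)) paths <- list(paths)
  breaks <- seq(0, 1, length.out = nbins + 1)
  cts <- matrix(0L, nbins, nbins)
  nTr <- 0L
  for (p in paths) {
    r <- rle(as.integer(p))
    if (length(r$values) < 2) next
    eb <- EMeans[head(r$values, -1)]
    ea <- EMeans[r$values[-1]]
    i <- pmin(pmax(findInterval(eb, breaks, rightmost.closed = TRUE), 1), nbins)
    j <- pmin(pmax(findInterval(ea, breaks, rightmost.closed = TRUE), 1), nbins)
    for (t in seq_along(i)) cts[i[t], j[t]] <- cts[i[t], j[t]] + 1L
    nTr <- nTr + length(i)
  }
  list(counts = cts, breaks = breaks, nTransitions = nTr)
}

#' Keep bursts long enough for quantitative rate analysis
#'
#' Traces shorter than about four mean dwell times yield overestimated
#' rates; the default keeps bursts with duration >= factor * meanDwell.
#'
#' @param esList list of \code{ESTrace} (or a data.frame with a duration
#'   column in ms)
#' @param meanDwell mean dwell time estimate (ms)
#' @param factor multiple of the mean dwell required (default 4)
#' @return the filtered input
#' @export
minimumLengthFilter <- function(esList, meanDwell, factor = 4) {
  stopifnot(meanDwell > 0)
  cut <- factor * meanDwell
  if (is.data.frame(esList)) return(esList[esList$duration >= cut, , drop = FALSE])
  keep <- vapply(esList, function(e) length(e@E) * e@binWidth >= cut,
    logical(1))
  esList[keep]
}

#' Rate sensitivity to trace truncation
#'
#' Re-analyses a burst set after cutting every burst to a fixed length,
#' stitching the cut pieces back to ~stitchTo ms, idealizing with the VB-HMM
#' and refitting dwell rates; reports rates relative to the reference
#' analysis of the full-length (uncut) traces.
#'
#' @param esList list of filtered \code{ESTrace}
#' @param cutLengths trace lengths to test (ms)
#' @param K number of HMM states (default 2)
#' @param stitchTo stitched-trace length (ms, default 100)
#' @param restarts,seed HMM options
#' @param minBins,minDwells dwell-fit options
#' @param ... further options passed to \code{\link{fitDwellRate}} (e.g.
#'   \code{censoring = "exclude"} to reproduce the naive dwell treatment
#'   whose short-trace overestimation motivates the minimum-length rule)
#' @return data.frame with cut_ms, dwellRatio (cut / mean dwell), relRate
#'   (mean over transition types), relRate12, relRate21, nDwells
#' @export
truncationSensitivity <- function(esList, cutLengths, K = 2, stitchTo = 100,
    restarts = 5, seed = NULL, minBins = 2, minDwells = 20, ...) {
  bw <- esList[[1]]@binWidth
  targetPts <- round(stitchTo / bw)

  analyse <- function(seriesList, sseed) {
    stitched <- list()
    ## wrap plain series into stitch groups of targetPts
    cur <- list(); pts <- 0
    for (sser in seriesList) {
      if (is.null(sser) || !length(sser)) next
      cur <- c(cur, list(sser)); pts <- pts + length(sser)
      if (pts >= targetPts) {
        stitched <- c(stitched, list(cur)); cur <- list(); pts <- 0
      }
    }
    if (length(cur)) stitched <- c(stitched, list(cur))
    allDwells <- list()
    for (gi in seq_along(stitched)) {
      g <- stitched[[gi]]
      E <- unlist(g, use.names = FALSE)
      if (length(E) < 10) next
      fit <- vbemFit(E, K, restarts = restarts,
        seed = if (is.null(sseed)) NULL else sseed + gi, binWidth = bw)
      st <- new("StitchedTrace", E = E,
        segLengths = vapply(g, length, integer(1)),
        sourceIds = as.character(seq_along(g)), binWidth = bw)
      paths <- unstitchAndClean(st, statePath(fit))
      allDwells <- c(allDwells, list(extractDwells(paths, bw)))
    }
    dw <- do.call(rbind, allDwells)
    k12 <- fitDwellRate(dw, 1, binWidth = bw, minBins = minBins,
      minDwells = minDwells, ...)
    k21 <- fitDwellRate(dw, 2, binWidth = bw, minBins = minBins,
      minDwells = minDwells, ...)
    list(k12 = k12$k, k21 = k21$k, n = k12$n + k21$n)
  }

  series <- lapply(esList, esSeries)
  ref <- analyse(series, seed)
  meanDwell <- 1000 * mean(c(1 / ref$k12, 1 / ref$k21))   # ms
  out <- lapply(seq_along(cutLengths), function(ci) {
    L <- cutLengths[ci]
    nb <- floor(L / bw)
    if (nb < 2) {
      warning("cut length ", L, " ms is below 2 bins; skipped")
      return(NULL)
    }
    ## cut each burst into consecutive pieces of the requested length
    cutSeries <- unlist(lapply(series, function(s) {
      if (is.null(s)) return(NULL)
      np <- length(s) %/% nb
      if (np < 1) return(list(s))
      lapply(seq_len(np), function(j) s[((j - 1) * nb + 1):(j * nb)])
    }), recursive = FALSE)
    r <- analyse(cutSeries, if (is.null(seed)) NULL else seed + 1000 * ci)
    data.frame(cut_ms = L, dwellRatio = L / meanDwell,
      relRate12 = r$k12 / ref$k12, relRate21 = r$k21 / ref$k21,
      relRate = mean(c(r$k12 / ref$k12, r$k21 / ref$k21)), nDwells = r$n)
  })
  do.call(rbind, out)
}

#' Arrhenius fit of temperature-dependent rates
#'
#' Weighted least squares of ln k against 1/T; Ea = -slope * R.
#'
#' @param temperatures absolute temperatures (K)
#' @param rates rate constants (s^-1)
#' @param stderr optional rate standard errors (weights 1/se(ln k)^2)
#' @return list with Ea_kJmol, EaStderr_kJmol, lnPrefactor, fit (lm), and
#'   \code{predictRate(T)} extrapolation helper
#' @export
arrheniusFit <- function(temperatures, rates, stderr = NULL) {
  if (length(temperatures) < 2) stop("need rates at >= 2 temperatures")
  stopifnot(length(rates) == length(temperatures), all(rates > 0),
    all(temperatures > 0))
  R <- 8.314                      # J mol^-1 K^-1
  x <- 1 / temperatures
  y <- log(rates)
  w <- if (is.null(stderr)) NULL else (rates / stderr)^2
  fit <- if (is.null(w)) lm(y ~ x) else lm(y ~ x, weights = w)
  slope <- coef(fit)[["x"]]
  se <- if (length(temperatures) > 2)
    suppressWarnings(sqrt(vcov(fit)["x", "x"])) else NA_real_
  list(Ea_kJmol = -slope * R / 1000,
    EaStderr_kJmol = if (is.na(se)) NA_real_ else se * R / 1000,
    lnPrefactor = coef(fit)[["(Intercept)"]], fit = fit,
    predictRate = function(T) exp(coef(fit)[["(Intercept)"]] + slope / T))
}
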