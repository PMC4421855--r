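## Constructors, accessors and show() methods for the core containers.

#' Construct a confocal detection geometry
#'
#' @param wxy lateral 1/e^2 radius (um)
#' @param kappa aspect ratio wz/wxy (default 3, a typical confocal value)
#' @param wz axial radius (um); overrides \code{kappa} when given
#' @return a \code{ConfocalGeometry}
#' @export
confocalGeometry <- function(wxy, kappa = 3, wz = kappa * wxy) {
  new("ConfocalGeometry", wxy = wxy, wz = wz)
}

#' Calibrate the geometry from a (D, tau_D) anchor
#'
#' FCS relates the diffusion time to the lateral waist through
#' \eqn{\tau_D = w_{xy}^2 / (4 D)}.  The default anchor is a 100-nm
#' liposome-tethered species: D = 3.0 um^2/s with a 20-ms diffusion time,
#' giving wxy ~ 0.49 um.
#'
#' @param D diffusion coefficient (um^2 s^-1)
#' @param tauD diffusion time (ms)
#' @param kappa aspect ratio (default 3)
#' @return a \code{ConfocalGeometry}
#' @export
calibrateGeometry <- function(D = 3.0, tauD = 20, kappa = 3) {
  confocalGeometry(wxy = sqrt(4 * D * tauD / 1000), kappa = kappa)
}

#' @export
setGeneric("wxy", function(object) standardGeneric("wxy"))
#' @export
setGeneric("wz", function(object) standardGeneric("wz"))
#' @export
setGeneric("aspectRatio", function(object) standardGeneric("aspectRatio"))
#' @export
setGeneric("effectiveVolume", function(object) standardGeneric("effectiveVolume"))

#' @describeIn confocalGeometry lateral waist (um)
#' @param object a \code{ConfocalGeometry}
#' @export
setMethod("wxy", "ConfocalGeometry", function(object) object@wxy)
#' @describeIn confocalGeometry axial radius (um)
#' @export
setMethod("wz", "ConfocalGeometry", function(object) object@wz)
#' @describeIn confocalGeometry aspect ratio wz/wxy
#' @export
setMethod("aspectRatio", "ConfocalGeometry", function(object) object@wz / object@wxy)
#' @describeIn confocalGeometry effective volume pi^(3/2) wxy^2 wz (fl)
#' @export
setMethod("effectiveVolume", "ConfocalGeometry",
  function(object) pi^1.5 * object@wxy^2 * object@wz)

setMethod("show", "ConfocalGeometry", function(object) {
  cat(sprintf(
    "ConfocalGeometry: wxy = %.3f um, wz = %.3f um (kappa = %.2f), Veff = %.2f fl\n",
    object@wxy, object@wz, aspectRatio(object), effectiveVolume(object)))
})

#' Convert between diffusion time and diffusion coefficient
#'
#' \eqn{\tau_D = w_{xy}^2/(4D)}.
#'
#' @param geometry a \code{ConfocalGeometry}
#' @param D diffusion coefficient (um^2 s^-1)
#' @param tauD diffusion time (ms)
#' @return \code{diffusionTime}: tau_D in ms; \code{diffusionCoefficient}:
#'   D in um^2 s^-1
#' @export
diffusionTime <- function(geometry, D) 1000 * wxy(geometry)^2 / (4 * D)

#' @rdname diffusionTime
#' @export
diffusionCoefficient <- function(geometry, tauD) 1000 * wxy(geometry)^2 / (4 * tauD)

#' Construct an N-state kinetic scheme
#'
#' @param EStates per-state FRET efficiencies, in [0, 1]
#' @param rateMatrix generator matrix (s^-1); the diagonal is overwritten
#'   with minus the off-diagonal row sums
#' @return a \code{KineticScheme}
#' @export
kineticScheme <- function(EStates, rateMatrix) {
  Q <- as.matrix(rateMatrix)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  new("KineticScheme", EStates = as.numeric(EStates), rateMatrix = Q)
}

#' Two-state Holliday-junction-like scheme
#'
#' Defaults are the two stacked-conformer efficiencies (E = 0.25 and 0.75)
#' with forward/backward rates of about 300 s^-1.
#'
#' @param k12 rate low-E -> high-E (s^-1)
#' @param k21 rate high-E -> low-E (s^-1)
#' @param EStates the two state efficiencies
#' @return a \code{KineticScheme}
#' @export
twoStateScheme <- function(k12 = 300, k21 = 282, EStates = c(0.25, 0.75)) {
  kineticScheme(EStates, matrix(c(0, k12, k21, 0), 2, 2, byrow = TRUE))
}

#' Single-state (static) scheme, e.g. a single-dye species
#' @param E the (static) FRET efficiency
#' @return a \code{KineticScheme}
#' @export
staticScheme <- function(E = 0.05) kineticScheme(E, matrix(0, 1, 1))

#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))
#' @export
setGeneric("EStates", function(object) standardGeneric("EStates"))
#' @export
setGeneric("rateMatrix", function(object) standardGeneric("rateMatrix"))

#' @describeIn kineticScheme number of states
#' @param object a \code{KineticScheme}
#' @export
setMethod("nStates", "KineticScheme", function(object) length(object@EStates))
#' @describeIn kineticScheme state efficiencies
#' @export
setMethod("EStates", "KineticScheme", function(object) object@EStates)
#' @describeIn kineticScheme generator matrix (s^-1)
#' @export
setMethod("rateMatrix", "KineticScheme", function(object) object@rateMatrix)

#' Stationary distribution of a kinetic scheme
#' @param scheme a \code{KineticScheme}
#' @return stationary state probabilities
#' @export
stationaryDistribution <- function(scheme) {
  Q <- rateMatrix(scheme)
  n <- nrow(Q)
  if (n == 1L) return(1)
  if (max(abs(Q)) == 0) return(rep(1 / n, n))   # kinetically dead: uniform
  ## solve pi Q = 0, sum(pi) = 1
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  as.numeric(qr.solve(A, b))
}

setMethod("show", "KineticScheme", function(object) {
  cat(sprintf("KineticScheme: %d state(s), E = %s\n", nStates(object),
    paste(format(object@EStates, digits = 3), collapse = ", ")))
  if (nStates(object) > 1) {
    cat("Exit rates (s^-1):", paste(format(-diag(object@rateMatrix),
      digits = 4), collapse = ", "), "\n")
  }
})

#' Construct a simulation configuration
#'
#' Defaults describe the liposome-tethered operating point: D = 3.0 um^2/s in
#' the calibrated ~2 fl Gaussian volume, 400 detected photons/ms at the
#' centre under donor excitation (photoprotection brightness), ideal ALEX with
#' a 25-us half-period, two-state E = 0.25/0.75 kinetics, and weak uniform
#' background.
#'
#' @param geometry a \code{ConfocalGeometry}
#' @param scheme a \code{KineticScheme}
#' @param D diffusion coefficient (um^2 s^-1)
#' @param peakRate detected photons/ms at the volume centre under donor
#'   excitation
#' @param directExFraction acceptor direct-excitation brightness as a
#'   fraction of \code{peakRate}; 0.67 puts the dual-label stoichiometry
#'   plateau near S = 0.6
#' @param background photons/ms per category (length-3, recycled)
#' @param alexPeriod alternation half-period (us)
#' @param alternation logical; FALSE = continuous donor excitation
#' @param bleachDonor,bleachAcceptor bleach rates at centre (s^-1)
#' @param boxHalfWidth box half-width (um); default 5 wz
#' @param duration simulated time (s)
#' @param dt propagation step (us)
#' @param nMolecules independent diffusers
#' @return a \code{SimConfig}
#' @export
simConfig <- function(geometry = calibrateGeometry(), scheme = twoStateScheme(),
    D = 3.0, peakRate = 400, directExFraction = 0.67,
    background = c(0.1, 0.1, 0.1), alexPeriod = 25, alternation = TRUE,
    bleachDonor = 0, bleachAcceptor = 0,
    boxHalfWidth = 5 * wz(geometry), duration = 1, dt = 10,
    nMolecules = 1L) {
  bg <- rep_len(as.numeric(background), 3L)
  names(bg) <- c("DexDem", "DexAem", "AexAem")
  new("SimConfig", geometry = geometry, scheme = scheme, D = D,
    peakRate = peakRate, directExFraction = directExFraction,
    background = bg, alexPeriod = alexPeriod, alternation = alternation,
    bleachDonor = bleachDonor, bleachAcceptor = bleachAcceptor,
    boxHalfWidth = boxHalfWidth, duration = duration, dt = dt,
    nMolecules = as.integer(nMolecules))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:\n")
  cat(sprintf("  D = %.2f um^2/s (tau_D = %.2f ms), peak rate = %g /ms\n",
    object@D, diffusionTime(object@geometry, object@D), object@peakRate))
  cat(sprintf("  duration = %g s, dt = %g us, ALEX %s, %d molecule(s)\n",
    object@duration, object@dt,
    if (object@alternation) sprintf("half-period %g us", object@alexPeriod)
    else "off", object@nMolecules))
  show(object@geometry); show(object@scheme)
})

#' Construct a photon stream
#'
#' @param timestamps arrival times (us)
#' @param channel integer codes (1 donor, 2 acceptor) or characters "D"/"A"
#' @param excitation integer codes (1 Dex, 2 Aex) or characters "D"/"A"
#' @param truth optional per-photon truth data.frame
#' @return a \code{PhotonStream}
#' @export
photonStream <- function(timestamps = numeric(), channel = integer(),
    excitation = integer(), truth = data.frame()) {
  if (is.character(channel)) channel <- ifelse(channel == "A", 2L, 1L)
  if (is.character(excitation)) excitation <- ifelse(excitation == "A", 2L, 1L)
  new("PhotonStream", timestamps = as.numeric(timestamps),
    channel = as.integer(channel), excitation = as.integer(excitation),
    truth = truth)
}

#' @export
setMethod("length", "PhotonStream", function(x) length(x@timestamps))

#' @export
setGeneric("timestamps", function(object) standardGeneric("timestamps"))
#' @describeIn photonStream photon arrival times (us)
#' @param object a \code{PhotonStream}
#' @export
setMethod("timestamps", "PhotonStream", function(object) object@timestamps)

#' Photon category per event
#'
#' @param stream a \code{PhotonStream}
#' @return factor with levels DexDem, DexAem, AexAem
#' @export
photonCategories <- function(stream) {
  idx <- ifelse(stream@excitation == .EX_ACCEPTOR, 3L,
         ifelse(stream@channel == .CH_ACCEPTOR, 2L, 1L))
  factor(c("DexDem", "DexAem", "AexAem")[idx],
    levels = c("DexDem", "DexAem", "AexAem"))
}

setMethod("show", "PhotonStream", function(object) {
  n <- length(object)
  cat(sprintf("PhotonStream: %d photons", n))
  if (n > 0) {
    cat(sprintf(" over %.1f ms", (object@timestamps[n] - object@timestamps[1]) / 1000))
    tab <- table(photonCategories(object))
    cat(sprintf(" (DexDem %d, DexAem %d, AexAem %d)", tab[1], tab[2], tab[3]))
  }
  if (nrow(object@truth)) cat(" [with truth]")
  cat("\n")
})

#' Construct a binned trace directly from count vectors
#'
#' @param DexDem,DexAem,AexAem per-bin photon counts
#' @param binWidth bin width (ms)
#' @param origin left edge of first bin (ms)
#' @return a \code{BinnedTrace}
#' @export
binnedTrace <- function(DexDem, DexAem, AexAem, binWidth, origin = 0) {
  counts <- cbind(DexDem = as.integer(DexDem), DexAem = as.integer(DexAem),
    AexAem = as.integer(AexAem))
  new("BinnedTrace", binWidth = binWidth, counts = counts, origin = origin)
}

#' @export
setGeneric("binWidth", function(object) standardGeneric("binWidth"))
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))

#' @describeIn binnedTrace bin width (ms)
#' @param object a \code{BinnedTrace}
#' @export
setMethod("binWidth", "BinnedTrace", function(object) object@binWidth)
#' @describeIn binnedTrace (bins x 3) count matrix
#' @export
setMethod("counts", "BinnedTrace", function(object) object@counts)
#' @describeIn binnedTrace number of bins
#' @export
setMethod("nBins", "BinnedTrace", function(object) nrow(object@counts))

setMethod("show", "BinnedTrace", function(object) {
  cat(sprintf("BinnedTrace: %d bins x %.3g ms (totals: DexDem %d, DexAem %d, AexAem %d)\n",
    nBins(object), object@binWidth, sum(object@counts[, 1]),
    sum(object@counts[, 2]), sum(object@counts[, 3])))
})

#' @describeIn computeES per-bin efficiency, stoichiometry and validity
#' @param object an \code{ESTrace}
#' @export
setGeneric("esValues", function(object) standardGeneric("esValues"))
#' @export
setMethod("esValues", "ESTrace", function(object) {
  data.frame(E = object@E, S = object@S, valid = object@valid)
})

#' @export
setGeneric("disposition", function(object) standardGeneric("disposition"))
#' @describeIn computeES filter disposition ("clean", "truncated", "discarded")
#' @export
setMethod("disposition", "ESTrace", function(object) object@disposition)

#' @export
setMethod("length", "ESTrace", function(x) length(x@E))

setMethod("show", "ESTrace", function(object) {
  cat(sprintf("ESTrace [%s]: %d bins x %.3g ms, %s%s\n", object@sourceId,
    length(object@E), object@binWidth, object@disposition,
    if (!is.na(object@truncIndex))
      sprintf(" (truncated at bin %d)", object@truncIndex) else ""))
})

#' @export
setMethod("length", "StitchedTrace", function(x) length(x@E))

#' Interior boundary positions of a stitched trace
#'
#' Index i is a boundary when segment ends at position i; transitions across
#' these indices are stitching artifacts, not physical transitions.
#'
#' @param stitched a \code{StitchedTrace}
#' @return integer vector (possibly empty)
#' @export
boundaries <- function(stitched) {
  cs <- cumsum(stitched@segLengths)
  cs[-length(cs)]
}

setMethod("show", "StitchedTrace", function(object) {
  cat(sprintf("StitchedTrace: %d segments, %d points x %.3g ms\n",
    length(object@segLengths), length(object@E), object@binWidth))
})

#' @export
setGeneric("stateMeans", function(object) standardGeneric("stateMeans"))
#' @export
setGeneric("transitionMatrix", function(object) standardGeneric("transitionMatrix"))
#' @export
setGeneric("evidence", function(object) standardGeneric("evidence"))
#' @export
setGeneric("statePath", function(object) standardGeneric("statePath"))

#' @describeIn vbemFit posterior emission means (sorted ascending)
#' @param object a \code{VBHMMResult}
#' @export
setMethod("stateMeans", "VBHMMResult", function(object) object@mu)
#' @describeIn vbemFit posterior-mean per-step transition matrix
#' @export
setMethod("transitionMatrix", "VBHMMResult", function(object) object@A)
#' @describeIn vbemFit final evidence lower bound
#' @export
setMethod("evidence", "VBHMMResult", function(object) object@evidence)
#' @describeIn vbemFit Viterbi state path
#' @export
setMethod("statePath", "VBHMMResult", function(object) object@path)

setMethod("show", "VBHMMResult", function(object) {
  cat(sprintf("VBHMMResult: K = %d, ELBO = %.3f (%s in %d iter)\n",
    object@K, object@evidence,
    if (object@converged) "converged" else "NOT converged", object@iterations))
  cat("  mu =", paste(format(object@mu, digits = 3), collapse = ", "),
      "; sigma =", paste(format(object@sigma, digits = 3), collapse = ", "), "\n")
})

#' Construct a correlation curve
#' @param lags lag times (ms)
#' @param G amplitudes
#' @param nTraces traces averaged
#' @param type "auto" or "cross"
#' @return a \code{CorrelationCurve}
#' @export
correlationCurve <- function(lags, G, nTraces = 1L, type = "auto") {
  new("CorrelationCurve", lags = as.numeric(lags), G = as.numeric(G),
    nTraces = as.integer(nTraces), type = type)
}

#' @export
setGeneric("lags", function(object) standardGeneric("lags"))
#' @describeIn correlationCurve lag times (ms)
#' @param object a \code{CorrelationCurve}
#' @export
setMethod("lags", "CorrelationCurve", function(object) object@lags)

#' @export
setGeneric("amplitudes", function(object) standardGeneric("amplitudes"))
#' @describeIn correlationCurve correlation amplitudes
#' @export
setMethod("amplitudes", "CorrelationCurve", function(object) object@G)

setMethod("show", "CorrelationCurve", function(object) {
  cat(sprintf("CorrelationCurve (%s): %d lags [%.3g, %.3g] ms, %d trace(s)\n",
    object@type, length(object@lags), min(object@lags), max(object@lags),
    object@nTraces))
})

## Local seed control: set the RNG deterministically without clobbering the
## caller's stream when no seed is requested.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
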