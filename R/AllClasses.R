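#' @import methods
#' @importFrom stats rnorm rpois rexp runif rbinom sd median quantile
#'   lm coef vcov dnorm residuals
#' @importFrom utils head tail read.csv write.csv modifyList
#' @useDynLib tetherFRET, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## Integer codes used in photon containers.  Kept as plain integers (not
## factors) because streams routinely hold 1e6-1e8 events.
.CH_DONOR    <- 1L  # donor emission channel
.CH_ACCEPTOR <- 2L  # acceptor emission channel
.EX_DONOR    <- 1L  # donor-excitation half-period
.EX_ACCEPTOR <- 2L  # acceptor-excitation half-period

#' ConfocalGeometry: 3D-Gaussian confocal detection volume
#'
#' Holds the lateral (\code{wxy}) and axial (\code{wz}) 1/e^2 radii of the
#' molecule-detection function.  The effective volume is
#' \eqn{V_{eff} = \pi^{3/2} w_{xy}^2 w_z} (in fl when radii are in um).
#'
#' @slot wxy lateral 1/e^2 beam-waist radius (um)
#' @slot wz axial 1/e^2 radius (um)
#' @export
setClass("ConfocalGeometry",
  representation(wxy = "numeric", wz = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@wxy) != 1L || !is.finite(object@wxy) || object@wxy <= 0)
      msg <- c(msg, "'wxy' must be a positive scalar")
    if (length(object@wz) != 1L || !is.finite(object@wz) || object@wz < object@wxy)
      msg <- c(msg, "'wz' must be a scalar >= wxy")
    if (length(msg)) msg else TRUE
  })

#' KineticScheme: N-state continuous-time Markov FRET scheme
#'
#' @slot EStates FRET efficiency of each state (dimensionless, in [0, 1])
#' @slot rateMatrix generator matrix Q (s^-1); off-diagonal k_ij >= 0,
#'   diagonal = -(row sum of off-diagonals)
#' @export
setClass("KineticScheme",
  representation(EStates = "numeric", rateMatrix = "matrix"),
  validity = function(object) {
    msg <- character()
    n <- length(object@EStates)
    Q <- object@rateMatrix
    if (any(!is.finite(object@EStates)) || any(object@EStates < 0) ||
        any(object@EStates > 1))
      msg <- c(msg, "'EStates' must lie in [0, 1]")
    if (!is.numeric(Q) || nrow(Q) != n || ncol(Q) != n)
      msg <- c(msg, "'rateMatrix' must be a square numeric matrix matching EStates")
    else {
      offdiag <- Q; diag(offdiag) <- 0
      if (any(offdiag < 0)) msg <- c(msg, "off-diagonal rates must be >= 0")
      if (any(abs(rowSums(Q)) > 1e-8 * (1 + max(abs(Q)))))
        msg <- c(msg, "rows of 'rateMatrix' must sum to 0")
    }
    if (length(msg)) msg else TRUE
  })

#' SimConfig: full configuration of a photon-stream simulation
#'
#' @slot geometry a \code{ConfocalGeometry}
#' @slot scheme a \code{KineticScheme}
#' @slot D diffusion coefficient (um^2 s^-1)
#' @slot peakRate detected count rate at the volume centre under donor
#'   excitation (photons per ms)
#' @slot directExFraction acceptor direct-excitation rate as a fraction of
#'   \code{peakRate} (dimensionless); sets the stoichiometry plateau
#' @slot background per-category background rates (photons per ms), named
#'   \code{DexDem}, \code{DexAem}, \code{AexAem}
#' @slot alexPeriod laser alternation half-period (us)
#' @slot alternation logical; \code{FALSE} simulates continuous single-laser
#'   (donor) excitation with no acceptor-excitation photons
#' @slot bleachDonor,bleachAcceptor excitation-weighted first-order bleaching
#'   rates at the volume centre (s^-1)
#' @slot boxHalfWidth simulation box half-width (um); periodic re-injection
#' @slot duration total simulated time (s)
#' @slot dt propagation step (us)
#' @slot nMolecules number of independent diffusers (FCS concentration mode)
#' @export
setClass("SimConfig",
  representation(geometry = "ConfocalGeometry", scheme = "KineticScheme",
    D = "numeric", peakRate = "numeric", directExFraction = "numeric",
    background = "numeric", alexPeriod = "numeric", alternation = "logical",
    bleachDonor = "numeric", bleachAcceptor = "numeric",
    boxHalfWidth = "numeric", duration = "numeric", dt = "numeric",
    nMolecules = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@D <= 0) msg <- c(msg, "'D' must be > 0")
    if (object@dt <= 0) msg <- c(msg, "'dt' must be > 0 (us)")
    if (object@peakRate < 0) msg <- c(msg, "'peakRate' must be >= 0")
    if (object@duration <= 0) msg <- c(msg, "'duration' must be > 0 (s)")
    if (object@alternation && object@dt > object@alexPeriod)
      msg <- c(msg, "'dt' must not exceed the alternation half-period")
    if (length(object@background) != 3L ||
        !identical(names(object@background), c("DexDem", "DexAem", "AexAem")))
      msg <- c(msg, "'background' must be named c('DexDem','DexAem','AexAem')")
    if (object@boxHalfWidth <= object@geometry@wz)
      msg <- c(msg, "'boxHalfWidth' must exceed wz")
    if (length(msg)) msg else TRUE
  })

#' PhotonStream: timestamped photon events
#'
#' The raw data unit: arrival times with detection channel and excitation
#' period, optionally with ground-truth simulation columns.
#'
#' @slot timestamps arrival times (us), non-decreasing
#' @slot channel integer; 1 = donor emission, 2 = acceptor emission
#' @slot excitation integer; 1 = donor excitation, 2 = acceptor excitation
#' @slot truth data.frame with 0 rows, or per-photon columns
#'   \code{true_state}, \code{donor_alive}, \code{acceptor_alive}
#' @export
setClass("PhotonStream",
  representation(timestamps = "numeric", channel = "integer",
    excitation = "integer", truth = "data.frame"),
  validity = function(object) {
    msg <- character()
    n <- length(object@timestamps)
    if (length(object@channel) != n || length(object@excitation) != n)
      msg <- c(msg, "channel/excitation must match timestamps length")
    if (n > 1 && any(diff(object@timestamps) < 0))
      msg <- c(msg, "timestamps must be non-decreasing")
    if (any(object@excitation == .EX_ACCEPTOR & object@channel != .CH_ACCEPTOR))
      msg <- c(msg, "acceptor-excitation photons must be in the acceptor channel")
    if (nrow(object@truth) > 0 && nrow(object@truth) != n)
      msg <- c(msg, "truth must have 0 or length(timestamps) rows")
    if (length(msg)) msg else TRUE
  })

#' BinnedTrace: the three ALEX intensity series on a fixed bin grid
#'
#' @slot binWidth bin width (ms)
#' @slot counts integer matrix (bins x 3), columns
#'   \code{DexDem}, \code{DexAem}, \code{AexAem}
#' @slot origin time of the left edge of the first bin (ms)
#' @export
setClass("BinnedTrace",
  representation(binWidth = "numeric", counts = "matrix", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@binWidth <= 0) msg <- c(msg, "'binWidth' must be > 0 (ms)")
    if (ncol(object@counts) != 3L ||
        !identical(colnames(object@counts), c("DexDem", "DexAem", "AexAem")))
      msg <- c(msg, "'counts' must have columns DexDem, DexAem, AexAem")
    else if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' ESTrace: per-bin FRET efficiency and stoichiometry of one burst
#'
#' @slot E,S per-bin FRET efficiency and stoichiometry; \code{NA} on invalid
#'   (zero-denominator) bins
#' @slot valid logical flag per bin
#' @slot counts the burst's (bins x 3) count matrix
#' @slot binWidth bin width (ms)
#' @slot disposition one of \code{"clean"}, \code{"truncated"},
#'   \code{"discarded"} (set by the stoichiometry filter)
#' @slot truncIndex first bin of a terminal photobleach jump (NA if none);
#'   analysis uses bins before this index
#' @slot sourceId identifier of the originating burst
#' @slot shortWarning TRUE when the burst was too short for the S filter
#' @export
setClass("ESTrace",
  representation(E = "numeric", S = "numeric", valid = "logical",
    counts = "matrix", binWidth = "numeric", disposition = "character",
    truncIndex = "integer", sourceId = "character", shortWarning = "logical"),
  validity = function(object) {
    msg <- character()
    n <- length(object@E)
    if (length(object@S) != n || length(object@valid) != n)
      msg <- c(msg, "E, S, valid must have equal length")
    ok <- object@valid
    if (any(ok & (is.na(object@E) | object@E < 0 | object@E > 1)))
      msg <- c(msg, "E must lie in [0,1] on valid bins")
    if (!object@disposition %in% c("clean", "truncated", "discarded"))
      msg <- c(msg, "bad disposition")
    if (length(msg)) msg else TRUE
  })

#' StitchedTrace: several burst E series concatenated for HMM fitting
#'
#' @slot E concatenated FRET-efficiency series (valid bins only)
#' @slot segLengths length of each segment (bins); interior boundaries sit
#'   after \code{cumsum(segLengths)[-length(segLengths)]}
#' @slot sourceIds originating burst id per segment
#' @slot binWidth bin width (ms)
#' @export
setClass("StitchedTrace",
  representation(E = "numeric", segLengths = "integer",
    sourceIds = "character", binWidth = "numeric"),
  validity = function(object) {
    msg <- character()
    if (sum(object@segLengths) != length(object@E))
      msg <- c(msg, "segment lengths must sum to length(E)")
    if (length(object@sourceIds) != length(object@segLengths))
      msg <- c(msg, "one sourceId per segment required")
    if (any(object@segLengths <= 0L)) msg <- c(msg, "empty segment")
    if (length(msg)) msg else TRUE
  })

#' VBHMMResult: variational posterior over a Gaussian-emission HMM
#'
#' @slot K number of states
#' @slot mu posterior emission means (E units), sorted ascending
#' @slot sigma posterior emission standard deviations
#' @slot A posterior-mean per-step transition matrix (rows sum to 1)
#' @slot piProb posterior-mean initial-state probabilities
#' @slot evidence final evidence lower bound (ELBO)
#' @slot evidenceTrace ELBO per VBEM iteration (non-decreasing)
#' @slot path Viterbi state sequence under posterior-mean parameters
#' @slot responsibilities (T x K) per-point state responsibilities
#' @slot converged,iterations convergence diagnostics
#' @slot posterior full variational hyperparameters (list)
#' @slot priors the priors used (list)
#' @export
setClass("VBHMMResult",
  representation(K = "integer", mu = "numeric", sigma = "numeric",
    A = "matrix", piProb = "numeric", evidence = "numeric",
    evidenceTrace = "numeric", path = "integer",
    responsibilities = "matrix", converged = "logical",
    iterations = "integer", posterior = "list", priors = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@mu) != object@K) msg <- c(msg, "mu length != K")
    if (is.unsorted(object@mu)) msg <- c(msg, "mu must be sorted ascending")
    if (any(abs(rowSums(object@A) - 1) > 1e-8))
      msg <- c(msg, "rows of A must sum to 1")
    if (length(msg)) msg else TRUE
  })

#' CorrelationCurve: an (auto- or cross-) correlation curve
#'
#' @slot lags lag times (ms), strictly increasing
#' @slot G correlation amplitude per lag
#' @slot nTraces number of traces averaged
#' @slot type "auto" or "cross"
#' @export
setClass("CorrelationCurve",
  representation(lags = "numeric", G = "numeric", nTraces = "integer",
    type = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@lags) != length(object@G))
      msg <- c(msg, "lags and G must have equal length")
    if (length(object@lags) > 1 && any(diff(object@lags) <= 0))
      msg <- c(msg, "lags must be strictly increasing")
    if (any(!is.finite(object@G))) msg <- c(msg, "G must be finite")
    if (length(msg)) msg else TRUE
  })
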