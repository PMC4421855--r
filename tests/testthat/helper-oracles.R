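## Shared generators and small oracles for the test-suite.

## Discrete two-state Markov chain with Gaussian emissions (no sub-bin
## averaging): the textbook HMM setting used to check the inference code
## against closed-form/oracle expectations.
genDiscreteChain <- function(T_, p12 = 0.15, p21 = 0.15, mu = c(0.25, 0.75),
    sigma = 0.05, seed = 1) {
  set.seed(seed)
  z <- integer(T_)
  z[1] <- if (runif(1) < p21 / (p12 + p21)) 1L else 2L
  for (t in 2:T_) {
    p <- if (z[t - 1] == 1L) p12 else p21
    z[t] <- if (runif(1) < p) 3L - z[t - 1] else z[t - 1]
  }
  list(x = rnorm(T_, mu[z], sigma), z = z)
}

## ESTrace wrapper around a bare S (and E) series, for filter tests
mkESTrace <- function(S, E = rep(0.5, length(S)), binWidth = 0.5) {
  new("ESTrace", E = E, S = S, valid = rep(TRUE, length(S)),
    counts = matrix(0L, length(S), 3,
      dimnames = list(NULL, c("DexDem", "DexAem", "AexAem"))),
    binWidth = binWidth, disposition = "clean", truncIndex = NA_integer_,
    sourceId = "synthetic", shortWarning = FALSE)
}

## burst ES list from the binned-burst generator
burstESList <- function(bs) {
  lapply(seq_along(bs$traces), function(i) {
    es <- computeES(bs$traces[[i]])
    es@sourceId <- sprintf("b%03d", i)
    es
  })
}

## pooled dwell-rate recovery for a burst set (fixed K = 2)
recoverRates <- function(esList, binWidth, restarts = 3, seedOff = 100,
    targetPoints = 150, ...) {
  st <- stitchTraces(esList, targetPoints = targetPoints)
  paths <- list()
  for (i in seq_along(st)) {
    f <- vbemFit(st[[i]]@E, 2, restarts = restarts, seed = seedOff + i,
      binWidth = binWidth)
    cc <- collapseSubResolutionStates(f, st[[i]]@E)
    if (length(cc$keptStates) != 2) next
    paths <- c(paths, unstitchAndClean(st[[i]], cc$path))
  }
  dw <- extractDwells(paths, binWidth)
  list(k12 = fitDwellRate(dw, 1, binWidth = binWidth, ...)$k,
    k21 = fitDwellRate(dw, 2, binWidth = binWidth, ...)$k,
    dwells = dw)
}
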