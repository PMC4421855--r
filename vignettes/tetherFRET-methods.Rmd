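---
title: "Simulation and kinetic analysis of liposome-tethered smFRET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation and kinetic analysis of liposome-tethered smFRET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetherFRET)
```

# The measurement this package models

Diffusion-based single-molecule FRET records photon bursts as individual
molecules transit a confocal excitation volume. A free nucleic acid or
protein crosses the volume in about a millisecond, which is too short to
watch conformational dynamics inside a single trace. Tethering the molecule
to a ~100-nm liposome slows its diffusion roughly 15-fold (D ~ 3 rather
than ~46 um^2/s), stretching single transits to tens of milliseconds, and a
photoprotective buffer allows detected count rates of hundreds of photons
per millisecond. Together these permit real-time idealization of FRET time
traces with sub-millisecond bins: kinetics between roughly 100 and
1500 s^-1 become measurable from freely diffusing molecules.

`tetherFRET` implements both halves of that experiment in software:

* a **photon-level simulator** - Brownian motion through a 3D-Gaussian
  detection volume, continuous-time Markov (CTMC) switching between FRET
  states, alternating-laser excitation (ALEX), per-dye photobleaching,
  background - which generates the raw timestamped photon streams the
  instrument would have produced; and
* the **analysis pipeline** - binning, dual-channel burst search, per-bin
  FRET efficiency E and stoichiometry S, the S-based artifact filter, trace
  stitching, variational-Bayes Gaussian-emission HMM idealization with
  evidence-based state-count selection, unstitching, dwell-time rate fits,
  transition-density plots, FCS autocorrelation and donor-acceptor
  cross-correlation, and Arrhenius analysis.

Because every analysis stage can be fed simulated data with known ground
truth, each stage is verifiable end to end without an instrument.

# The optical model and its calibration

The detection profile is the standard 3D Gaussian
$\mathrm{PSF}(x,y,z)=\exp(-2(x^2+y^2)/w_{xy}^2-2z^2/w_z^2)$ with effective
volume $V_\mathrm{eff}=\pi^{3/2}w_{xy}^2w_z$. The literature values this
package targets quote an effective volume of about 1 fl *and* the pair
(D = 3.0 um^2/s, tau_D ~ 20 ms); under common aspect ratios these are not
simultaneously consistent. All quantities this package computes from the
geometry (diffusion times, burst statistics, FCS fits) depend on $w_{xy}$
or on D ratios, not on the absolute volume, so the geometry is calibrated
from the diffusion anchor via $\tau_D = w_{xy}^2/(4D)$:
`calibrateGeometry()` gives $w_{xy}=\sqrt{4\cdot3.0\cdot0.020}\approx0.49$
um, and the aspect ratio defaults to $\kappa=3$, a typical confocal value.
The resulting $V_\mathrm{eff}\approx2$ fl; `fitFCS()` reports the volume
implied by the calibrated geometry rather than resolving the discrepancy.

The simulator propagates one molecule (or several independent ones, for
concentration-dependent FCS checks) with exact Gaussian increments of
per-axis variance $2D\,\Delta t$, wrapping periodically in a box of
half-width $5w_z$ so the time-averaged concentration is uniform. Photons
are generated by thinning an inhomogeneous Poisson process whose rate is
`peakRate * PSF(position)`; the laser phase (25-us ideal alternation
half-periods) is resolved per photon from its timestamp. Donor-excitation
photons are routed to the acceptor channel with probability equal to the
current state's E (and to the donor channel after acceptor bleaching);
acceptor-excitation photons are direct excitation at a configurable
fraction of the peak rate (default 0.67, placing the dual-label
stoichiometry plateau near S = 0.6). Bleaching is first order in the
integrated local excitation. Timestamps are stored at 1 us resolution,
200x finer than the finest 0.2-ms analysis bin.

Far from the volume the propagation step is lengthened adaptively - the
step is bounded so a 4-sigma displacement cannot reach the region where
the detection probability exceeds ~1e-7, and Brownian increments are exact
at any step size - which is what makes the hour-scale simulated times
behind the burst-duration statistics practical on one core. Diffusion
statistics (MSD slopes, FCS decay) are unaffected, as the test-suite
verifies.

Two fidelity limits worth knowing about: the periodic box truncates the
long-lag tail of FCS curves once lags approach the box-crossing time (FCS
checks therefore use a 2.5 w_z half-width box and fit ranges within a few
hundred ms), and laser alternation is ideal and instantaneous, with zero
donor leakage and unit gamma, matching the uncorrected proximity-ratio E
convention used throughout.

# Burst-level synthetic data

Full photon-level simulation of hundreds of 15-50-ms tethered transits is
wasteful when only the analysis chain is under test, so
`simulateBurstSet()` generates data at the binned level: burst durations
are a minimum plus an exponential excess (default 15 + Exp(10) ms,
matching the analyzed length class), state dynamics are an exact CTMC, the
expected efficiency of each bin is the occupancy-weighted mean of the
state efficiencies over the bin (sub-bin averaging, exactly as binned real
data), donor-excitation counts are Poisson with binomial FRET splitting,
and acceptor-excitation counts are Poisson.

The per-bin brightness follows a *transit envelope*: the PSF value of a
Brownian position confined above the burst-search detectability floor
(default 0.3 of peak, the 30-photon/0.5-ms floor at 400 photons/ms). This
matters: with an unrealistic flat envelope at full peak rate every bin
carries ~100 donor-excitation photons (sigma_E ~ 0.04), and the bins that
straddle a state transition - about 14% of bins at 300 s^-1 and 0.5-ms
binning - are then so precisely measured that the HMM evidence can promote
them to a dedicated intermediate state. Under the envelope (and in real
data) the average brightness is roughly half the peak and the blur merges
into the state distributions.

Optional acceptor photobleaching reroutes FRET photons to the donor
channel and drops the red-excitation signal to background, reproducing the
terminal S jump that the stoichiometry filter must truncate.

# E, S, and the stoichiometry filter

Per bin, $E = F_{D_{ex}A_{em}}/(F_{D_{ex}D_{em}}+F_{D_{ex}A_{em}})$ (raw
proximity ratio, no gamma/leakage/direct-excitation corrections) and
$S = F_{D_{ex}}/(F_{D_{ex}}+F_{A_{ex}A_{em}})$. Zero-denominator bins are
flagged invalid and excluded, never propagated as NaN. The dual-channel
burst search requires, per bin, both the donor-excitation sum and the
acceptor-excitation count to exceed the threshold strictly (30 photons for
1- and 0.5-ms bins; 20 for 0.2-ms bins), which admits only dually labelled
molecules. A single sub-threshold bin splits a burst; no gap tolerance is
applied.

The S filter slides two adjacent 5-bin windows and flags a sustained mean
change larger than 0.2. One terminal *rise* persisting to the end of the
burst is the permanent-acceptor-bleach signature: the trace is kept and cut
at the change point. Any other sustained change (transient excursions,
drops, multiple events) marks blinking or spectral-shift photophysics and
discards the trace. The window and threshold are package defaults chosen
so that shot-noise S fluctuation at working brightness (sd ~ 0.04 per bin)
never triggers while a bleach-sized jump (~0.4) always does; the source
experiments state no numeric criterion. Bursts shorter than two windows
pass unfiltered with a warning flag.

# Stitching and the variational HMM

Filtered bursts rarely reach the 100-200 points a stable HMM fit wants, so
bursts are concatenated in acquisition order until a stitched trace
reaches `targetPoints` (150 by default; 15-ms bursts at 0.5-ms bins give
the typical 5-10 segments per stitch). After fitting, the idealized path
is split back at the recorded boundaries: a state change exactly at a
boundary is a stitching artifact and is never counted as a transition, and
the first/last dwell of every segment is censored.

The idealizer is a conjugate variational-Bayes HMM with one Gaussian
emission per state: Dirichlet priors (concentration 1) on the initial
distribution and each transition row, Normal-Gamma priors on the emission
means and precisions (mean prior centred at E = 0.5 with weak coupling
beta0 = 0.25; precision prior shape 1, rate 0.01 - broad, with prior sd
~0.1). The E-step runs scaled forward-backward under the expected natural
parameters (compiled core), the M-step applies the conjugate updates, and
the evidence lower bound - computed as the variational log-normalizer
minus the parameter KL terms - is asserted non-decreasing at every
iteration in the test-suite. Convergence is a relative ELBO change below
1e-6 with a 500-iteration cap; fits take the best of several restarts
(quantile-based means, jittered) and are deterministic under a seed.
Emission noise is learned, not propagated from counts. The state count is
chosen by the maximized evidence over K = 1..Kmax; the pipeline selects one
K for the whole data set by summing evidence over stitched traces.

A plain Baum-Welch maximum-likelihood fitter with the same interface
(`mlBaselineFit()`) serves as the comparison baseline; on fast-switching
traces the variational fit's per-step transition probabilities are at
least as accurate on a majority of replicates, consistent with the
motivation for using variational inference on short noisy traces.

**Sub-resolution states.** On very bright data the evidence can assign the
transition-straddling bins their own state whose Viterbi sojourns last
~1 bin. Such states sit below the temporal resolution of any binned
analysis - the same reason the dwell fits exclude sub-2-bin dwells - so
before dwell analysis the pipeline collapses states whose mean Viterbi
dwell is under 1.5 bins, reassigning their bins to the most likely
remaining state under the fitted emission densities
(`collapseSubResolutionStates()`). Genuine kinetic states at the design
operating points (dwell >= 3 bins at the prescribed binning) are never
collapsed.

# Dwell-time rate estimation

Rates come from the dwell statistics of the separated idealized paths.
Three numerical choices matter, each validated against oracles in the
test-suite:

1. **Censoring.** The last dwell of a segment has an unobserved exit and
   enters the likelihood through its survival probability $(1-p)^{n-1}$;
   an unobserved *entry* needs no correction because the geometric dwell
   law is memoryless. Dropping edge dwells instead (the naive treatment,
   available as `censoring = "exclude"`) keeps only dwells that fit
   strictly inside their segment and over-represents short dwells: on a
   pure geometric oracle cut into segments of four mean dwells it inflates
   rates by ~40%. This selection effect is precisely why rates from short
   traces are unreliable.
2. **Resolution truncation.** Complete dwells shorter than 2 bins are
   dominated by misassignment and are excluded, with the likelihood
   conditioned on $n \ge 2$ (memorylessness again). The closed-form MLE is
   $p = C/(C+\sum(n_\mathrm{exit}-2)+\sum(n_\mathrm{last}-1))$.
3. **Probability-to-rate conversion.** For two-state dwell sets both exit
   probabilities are inverted jointly through the discrete-time embedding
   $p_i=(k_i/s)(1-e^{-s\Delta t})$, $s=k_{12}+k_{21}$, followed by a
   first-order missed-event correction $k_i \leftarrow k_i e^{k_j d}$ with
   dead time $d = \Delta t/2$ (a binned idealization cannot register
   sojourns shorter than about half a bin; this is the classical
   single-channel missed-event treatment, applied by fixed point). The
   plain $k=-\ln(1-p)/\Delta t$ conversion is selectable
   (`conversion = "rounding"`). The combined estimator recovers rates
   within ~5% across 100-1500 s^-1 at the prescribed binnings (0.5 ms up
   to 600 s^-1, 0.2 ms above), which is the claimed dynamic range.

Reported standard errors are $k/\sqrt{n}$ with $n$ the number of complete
dwells. A weighted log-histogram least-squares fit is available as a
cross-check.

**Truncation sensitivity.** `truncationSensitivity()` re-runs the analysis
after cutting every burst into pieces of a given length and stitching the
pieces back to ~100 ms. With the default estimator the error at cuts of
>= 4 mean dwells stays within 10%; at cuts near one mean dwell the HMM
under-resolves transitions inside 6-bin pieces and rates come out *low*.
The historically observed failure mode - strong *over*estimation at short
cuts, shrinking monotonically with piece length - is reproduced exactly
when the naive censored-excluded dwell treatment is selected, and is the
behaviour that motivates the minimum-trace-length rule: keep bursts longer
than four mean dwells (`minimumLengthFilter()`, two-pass: a first-pass fit
on bursts >= 10 ms estimates the mean dwell, then the filter is applied
and rates refitted).

# Correlation analysis

`autocorrelate()` implements the normalized fluctuation autocorrelation
$G(\tau)=\langle\delta I(t)\,\delta I(t+\tau)\rangle/\langle I\rangle^2$
with deviations from the full-series mean and per-lag pair-count
normalization, either directly on a lag grid or with octave-coarsening
multi-tau for long streams; `fitFCS()` fits the 3D diffusion model
$G(\tau)=N^{-1}(1+\tau/\tau_D)^{-1}(1+\tau/(\kappa^2\tau_D))^{-1/2}$ with
$\kappa$ fixed (fitting it on noisy curves is ill-conditioned).

For intra-burst kinetics, `crossCorrelate()` normalizes each bin by the
donor-excitation total - $d+a=1$, which cancels the diffusion brightness
envelope - and averages the normalized cross-covariance of $\delta d$ and
$\delta a$ over traces longer than 25 ms (50-trace averages by default).
Deviations are taken from means pooled across traces: subtracting each
short trace's own sample mean biases the covariance tail by
$O(\tau_\mathrm{corr}/n)$ and visibly distorts the fitted relaxation time.
Lags run from one bin to half the shortest contributing trace.
`fitSingleExponential()` fits $Ae^{-t/\tau}$ with free-signed amplitude
(anticorrelation gives $A<0$) and flags curves indistinguishable from
flat instead of returning a spurious time constant. For a two-state
system the fitted relaxation rate equals $k_{12}+k_{21}$, the identity the
test-suite checks across the dynamic range; for multi-state ladders the
apparent rate reflects the slow eigenmodes, as in the SSB stepping
analysis.

# Arrhenius analysis

`arrheniusFit()` is a weighted least-squares fit of $\ln k$ against $1/T$
(weights $1/\mathrm{se}(\ln k)^2$ when rate standard errors are given),
with $E_a=-\mathrm{slope}\cdot R$, $R = 8.314$ J/(mol K), and an
extrapolation helper for comparing rates across temperatures.

# Problem sizes and determinism

All randomness flows through explicit seeds; identical configuration plus
seed reproduces every output bit for bit, and `runPipeline()` reports a
configuration hash alongside stage-wise counts (bursts found, discarded,
truncated, kept, dwells) so filter behaviour is auditable.

The standard benchmark sizes used by the test-suite and the acceptance
script are the package's own reduced working sizes: 100 traces of 200
points per rate condition for HMM validation; 190 bursts of >= 15 ms for
the conformer-exchange recovery; 50 replicates of 60 bursts for the
truncation analysis; >= 500-1000 detected bursts for the burst-duration
statistics; 150-trace averages for cross-correlation fits. With these
sizes the full suite runs in a couple of minutes on one core. Passing
tests demonstrate correct inference on data generated by the package's own
forward models; they cannot certify instrument-specific effects the models
exclude (detector afterpulsing and dead time, triplet blinking, spectral
cross-talk, non-Gaussian detection profiles, liposome-size dispersity).

# Known limitations

* The simulator's ALEX is ideal: no leakage, no direct-excitation
  correction, gamma = 1. E is always the raw proximity ratio.
* The S filter assumes at most one permanent bleach event per burst;
  multi-step photophysics is discarded rather than modelled.
* The missed-event dead-time correction is first order and calibrated to
  the binned-Viterbi idealization; photon-by-photon analyses would need a
  different treatment.
* Evidence-based state-count selection on very bright, flat-brightness
  data can report a sub-resolution blur state; the pipeline collapses it,
  but `selectModel()` on raw series reports what the evidence finds.
* The FCS box is finite and periodic; fits are reliable for lags well
  below the box-crossing time.
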