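# tetherFRET

Simulation and kinetic analysis of diffusion-based single-molecule FRET
with liposome tethering and alternating-laser excitation (ALEX).

## The problem

Confocal (diffusion-based) smFRET watches one molecule at a time as it
crosses a femtoliter excitation volume, but a free biomolecule transits in
about a millisecond — too short to resolve conformational dynamics within
a single trace. Tethering the molecule to a freely diffusing ~100-nm
liposome slows diffusion ~15-fold (D ≈ 3 vs ≈ 46 µm²/s, diffusion time
τ_D ≈ 20 vs 1.3 ms), and a photoprotective buffer sustains count rates of
hundreds of photons per millisecond. Single bursts then last tens of
milliseconds at sub-millisecond binning, and transition rates between
roughly 100 and 1500 s⁻¹ — e.g. Holliday-junction conformer exchange or
SSB protein migration on ssDNA — become measurable from freely diffusing
molecules.

`tetherFRET` is for people building or validating such analyses. It
provides:

* a photon-level simulator of the experiment (Brownian motion through a 3D
  Gaussian volume, continuous-time Markov FRET switching, ideal ALEX,
  per-dye photobleaching, background), plus a fast burst-level generator;
* the analysis chain: binning into the three ALEX channels F(Dex,Dem),
  F(Dex,Aem), F(Aex,Aem); dual-channel burst search (strict 30-photon
  thresholds on the donor-excitation sum *and* the acceptor-excitation
  channel); per-bin efficiency E = F(Dex,Aem)/F(Dex) and stoichiometry
  S = F(Dex)/(F(Dex)+F(Aex,Aem)); a stoichiometry filter that truncates
  terminal acceptor-bleach jumps and discards other S artifacts; trace
  stitching to 100–200 points; a variational-Bayes Gaussian-emission HMM
  with evidence-selected state count; stitch-aware dwell extraction and
  censoring-correct exponential rate fits; transition-density plots;
  FCS autocorrelation with the 3D diffusion model
  G(τ) = N⁻¹(1+τ/τ_D)⁻¹(1+τ/(κ²τ_D))^(−1/2); donor–acceptor
  cross-correlation whose single-exponential relaxation rate equals
  k₁₂+k₂₁; and Arrhenius fits.

The methods vignette (`vignettes/tetherFRET-methods.Rmd`) documents the
models, priors, estimators and their validation.

## Worked example

Simulate 190 Holliday-junction-like bursts (two states, E = 0.25/0.75,
exchange at 300 and 282 s⁻¹, 0.5-ms bins, 400 photons/ms peak) and run the
full pipeline:

```r
library(tetherFRET)
cfg <- pipelineConfig(simulation = list(nBursts = 190), seed = 42)
res <- runPipeline(cfg, verbose = TRUE)
#> bursts found: 190
#> after S filter: 190 kept (0 truncated, 0 discarded)
#> first-pass mean dwell: 3.47 ms
#> after minimum-length filter (13.9 ms): 190 bursts
res$K
#> [1] 2
round(res$mu, 3)
#> [1] 0.253 0.748
res$rates
#> state1: k = 306 +/- 14 s^-1 (n = 509 dwells)
#> state2: k = 273 +/- 12 s^-1 (n = 504 dwells)
```

The evidence selects two states, the emission means land on the true
conformer efficiencies, and both exchange rates are recovered within a few
percent of the simulation truth. The log records the two-pass
minimum-length rule: a first-pass fit estimates the mean dwell (3.5 ms)
and only bursts longer than four dwell times enter the final fit.

The closed-form FCS relation τ_D = w²xy/(4D), calibrated on the tethered
anchor (D = 3.0 µm²/s, τ_D = 20 ms), predicts the free-dsDNA diffusion
time:

```r
g <- calibrateGeometry()
diffusionTime(g, 46.4)
#> [1] 1.29
```

i.e. 1.3 ms, the ~15-fold change expected from the D ratio.

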