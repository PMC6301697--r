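# scnCoupling

Simulation and analysis of circadian synchrony in the suprachiasmatic
nucleus (SCN), the mammalian master clock. The package is written for
chronobiologists and modelers who work with pixel-level bioluminescence
recordings (PER2::LUC slice movies) and want to connect the observed
spatio-temporal patterns — global synchrony, lobe splitting, loss of
rhythm in clock-gene knockouts, rescue by co-culture — to a mechanistic
network model with **two interacting coupling channels** (VIP and AVP
neuropeptide signaling).

## What it computes

**Single cells** are stochastic amplitude–phase oscillators,

    dx/dt = -λ x r (r - α) - ω y + ξx
    dy/dt = -λ y r (r - α) + ω x + ξy,      r² = x² + y²,

a noisy limit cycle of amplitude α and period 2π/ω with damping λ, radial
noise intensity D_r and phase noise intensity D_φ. The coefficient of
variation CV = sd(amplitude)/α separates self-sustained (CV < 1) from
noisy damped (CV > 1) oscillators. `fitOscillator()` estimates the five
parameters from a measured trace (autocorrelation fitting for period, λ
and D_φ; a bootstrap-calibrated distribution-shape match for CV).

**The network** couples cells on a two-lobed lattice with the dual
diffusive coupling K = a_avp·K_avp + a_vip·K_vip and optional 24-h
sinusoidal forcing I_avp, I_vip (the VIP input phase-delayed by φ),
representing paracrine signaling from a co-cultured wild-type graft.
Genotype/age conditions are one `scenarioPreset()` call each:
`"neonate-wt"`, `"neonate-dko"`, `"neonate-dko-split"`, `"neonate-tko"`,
`"adult-*"`, `"coculture-dko"`, `"coculture-dko-antagonist"`,
`"coculture-tko"`, `"coculture-tko-antagonist"` (the AVP-antagonist
cocktail is the abstraction I_avp = 0).

**The analysis** decomposes movies into empirical orthogonal functions
(EOFs): eigenvectors e_i of the pixel covariance R = AᵀA of the T×N
sample matrix, with temporal modes c_i(t) and normalized eigenvalues
100·Ω_i/ΣΩ_j quantifying each spatial pattern's share of the variance.
Around the EOF core sit the standard circadian metrics: the chi-square
periodogram (count-weighted, family-wise 1% significance line),
acrophase, the Kuramoto synchronization index R(t), the 24-h spectral
component ratio, per-slice summaries, and one-way ANOVA with Fisher LSD
group comparisons.

**Synthetic imaging** (`renderMovie()`, `renderDispersed()`,
`fixtureMovie()`) turns simulations into realistic movies — baseline
decay, photon-counting noise, 2×2 pixels per cell — so the entire
analysis chain is testable without slice data.

## Worked example

Simulate an adult triple-knockout slice rescued by co-culture forcing,
render it as a movie, and summarize:

```r
library(scnCoupling)

sc    <- scenarioPreset("coculture-tko", seed = 1)  # ~240 cells, 6 days
run   <- simulateNetwork(sc)
movie <- renderMovie(run, seed = 1)
summarizeSlice(movie)
#> SliceSummary
#>   period: 23.90 +/- 0.85 h over 532 rhythmic pixels
#>   eigenvalues 1+2: 30.9%   sync index: 0.388 +/- 0.116

round(normalizedEigenvalues(computeEOF(preprocessMovie(movie)))[1:5], 1)
#> [1] 28.0  2.9  2.8  2.5  2.3
```

The rescue signature is exactly what co-culture experiments report: a
dominant first EOF mode well above 20% of the variance (here 28%), a
period distribution centered on the 24-h forcing, and partial synchrony —
while the same preset with AVP antagonists (`"coculture-tko-antagonist"`)
collapses to eigenvalues below 5% everywhere.

Single-cell parameter estimation from a simulated dispersed-cell trace:

```r
p   <- oscillatorPreset("wild-type fit")
tr  <- simulateCell(p, duration = 240, seed = 7)    # 10 days, hourly
fit <- fitOscillator(tr, seed = 7)
#> period 24.03 h, CV 0.15 (self-sustained)
```

A command-line wrapper covering simulate / analyze / estimate / sweep /
report / make-fixture ships as `inst/scripts/scn-cli.R` (see `?runCLI`).

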