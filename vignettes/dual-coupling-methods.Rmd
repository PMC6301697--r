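---
title: "Dual-coupling oscillator networks and EOF analysis: models and methods"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Dual-coupling oscillator networks and EOF analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scnCoupling)
```

This vignette documents the models, the parameter choices, and the
numerical decisions behind `scnCoupling`. It is the package's record of
*why* things are the way they are; the reference pages document *what*
each function does.

## The single-cell model

Each SCN neuron is modeled as a stochastic amplitude–phase oscillator in
Cartesian coordinates $(x, y)$ with radius $r = \sqrt{x^2 + y^2}$:

$$\dot{x} = -\lambda x r (r - \alpha) - \omega y + \xi_x, \qquad
  \dot{y} = -\lambda y r (r - \alpha) + \omega x + \xi_y.$$

The deterministic part has a limit cycle of amplitude $\alpha$ and angular
frequency $\omega$ (period $2\pi/\omega$); perturbations relax back with a
rate set by $\lambda$. The Gaussian noise pair is parameterized by a
radial intensity $D_r$ and a phase intensity $D_\phi$, implemented as
independent increments in the local radial/tangential frame (s.d.
$\sqrt{2 D_r\,dt}$ along the radial unit vector; a rotation by an angle of
s.d. $\sqrt{2 D_\phi\,dt}$). With this convention the two named
intensities are directly interpretable: the radial deviation is an
Ornstein–Uhlenbeck-like process of intensity $D_r$, and the unwrapped
phase diffuses with variance $2 D_\phi t$ (verified by the ensemble tests).

Two consequences of the model's own nonlinearity are worth knowing:

* The radial equation implied by the Cartesian form is
  $\dot{r} = -\lambda r^2 (r - \alpha)$ (note the extra factor $r$
  relative to the quadratic form one might write down first). Its
  linearization about the cycle relaxes at rate $\gamma = \lambda
  \alpha^2$, which is the convention `computeCV()` uses by default; the
  $\lambda\alpha$ and $\lambda$ conventions remain available and all
  three coincide at $\alpha = 1$.
* Phase noise inflates the mean radius (an Itô effect: the stationary
  balance is $D_\phi r = \lambda r^2 (r - \alpha)$), and radial noise
  produces genuine *phase slips* when the state passes near the origin.
  Both are physical features of the model, not artifacts.

**The CV criterion.** The coefficient of variation
$CV = \sqrt{D_r / \gamma}\,/\,\alpha$ is the stationary amplitude s.d.
relative to the cycle amplitude; $CV < 1$ marks a self-sustained
oscillator, $CV > 1$ a noisy damped one.

## Integration

The integrator is stochastic Heun: a second-order predictor–corrector
step for the deterministic drift with explicit Gaussian increments, at
`dt = 0.01` h and hourly sampling. Plain first-order Euler is not
adequate here: its rotational drift inflates the limit-cycle radius by
$\omega^2 dt / (2\lambda)$ — about $10^{-2}$ at the wild-type parameters,
well above the $10^{-3}$ radius-conservation tolerance the test suite
enforces. The Heun drift removes this bias (measured residual
$\sim 2\times 10^{-6}$ over ten periods) at twice the drift cost. A
stability guard rejects steps with
$dt \cdot \max(\lambda\alpha, \omega, \text{coupling degree}) \ge 0.1$.

## The exact model ACF and what it does (not) identify

For autocorrelation fitting the package derives the model ACF exactly
rather than assuming the Ornstein–Uhlenbeck closed form. In the
*signed-radius* representation $x = u \cos\theta$ — continuing the radial
coordinate through the origin so that near-origin passages appear as sign
changes of $u$ instead of $\pi$-slips of $\theta$ — the phase is a clean
Brownian rotation and the ACF factorizes exactly:

$$\rho(\tau) = \hat{C}(\gamma\tau;\, CV)\; e^{-D_\phi \tau} \cos(\omega\tau),$$

where $\hat{C}$ is the normalized autocorrelation of the dimensionless
double-well diffusion $dv = -v^2(v - \mathrm{sgn}\,v)\,ds + \sqrt{2}\,CV\,dW$
whose law depends on CV alone. `modelACF(method = "spectral")` computes
$\hat{C}$ from the eigendecomposition of the discretized radial generator
(a symmetric tridiagonal problem); the construction captures the Kramers
hopping between the $\pm\alpha$ wells, which *is* the phase-slip
decorrelation and dominates for $CV \gtrsim 0.3$. The small-CV closed form
$(1 + CV^2 e^{-\gamma\tau})e^{-D_\phi\tau}\cos(\omega\tau)/(1+CV^2)$ is
kept as `method = "analytic"`, and a Monte-Carlo route as
`method = "simulated"`.

A structural finding, confirmed by fitting the model's own exact ACF:
the normalized ACF is **nearly degenerate in CV**. Above $CV \approx 0.3$
the radial correlation reduces to a hopping exponential that trades off
against $D_\phi$ and $\gamma$ almost perfectly (a distinct parameter set
reproduces the reference ACF to residual $2\times10^{-10}$). Any
ACF-only fit therefore pins down the period sharply, $\gamma$ and
$D_\phi$ loosely, and CV essentially not at all.

## Parameter estimation

`fitOscillator()` consequently splits the problem:

1. **Shape parameters** (period, $\gamma$, $D_\phi$) by bounded
   least-squares fitting of the sample ACF to the spectral model ACF over
   lags $[0, 72]$ h, profiled over a CV grid with multi-start L-BFGS-B
   and golden-section refinement. The model curve is tapered by the
   finite-sample factor $(1 - \tau/T)$, matching the expectation of the
   biased sample ACF; without this taper the fit absorbs the taper into
   $D_\phi$ ($\hat{D}_\phi \approx 1/T$ on a noise-free cosine).
2. **CV** through an independent data channel: fifteen scale-invariant
   statistics of the detrended trace (moment and L-moment shape, |x|
   quantiles, analytic-signal envelope dynamics, and the autocorrelation
   of $x^2$, which probes the amplitude timescale that the second-order
   ACF cannot). For each candidate CV the best-fitting shape parameters
   are re-derived from the ACF and a parametric bootstrap (12 replicates
   of the signed-radius process plus diffusing phase, passed through the
   same detrending operator as the data) predicts the statistics at the
   observed record length; the candidate minimizing the noise-normalized
   distance wins, with quadratic interpolation in log CV. The bootstrap
   self-calibrates the substantial short-record bias of fourth-moment
   statistics.

The amplitude scale is recovered last from
$\mathrm{Var}(x) = \alpha^2 E[v^2]/2$ with $E[v^2]$ the exact second
moment of the radial stationary density, giving $\lambda = \gamma/\alpha^2$
and $D_r = CV^2 \alpha^2 \gamma$.

**Honest performance bounds.** Parameter recovery was measured, not
assumed. The period is recovered within 5% whenever the trace retains an
oscillatory ACF. CV is recovered at the *class* level (self-sustained vs
damped): on 20-day records with $\gamma = 0.3$ the label accuracy is
about 1.00 / 0.85 / 0.55 / 0.70 / 0.75 at true CV 0.2 / 0.5 / 1.0 / 1.5 /
2.0. The residual errors are information-limited, not estimator flaws:
once $\gamma$ must be treated as unknown, the discriminability between
adjacent CV classes near the boundary is of order one noise s.d. per
record, and at $CV \ge 1.5$ with fast amplitude noise the signal
decorrelates within a fraction of a cycle, which simultaneously erodes
the period estimate. Slower amplitude noise preserves the period but
further weakens CV identifiability. Point estimates of CV from a single
record should therefore be treated as class indicators, not quantitative
measurements; population medians over many cells (as in the dispersed
analyses) are reliable.

## The network model

`simulateNetwork()` couples the cells on a two-lobed 4-neighbour disc
lattice (default $2 \times 120$ cells, four inter-lobe bridge edges at a
reduced weight):

$$\dot{x}_i = -\lambda x_i r_i (r_i - \alpha) - \omega_i y_i
  + \sum_{j \in N_i} K (x_j - x_i)
  + I_{avp} \sin(2\pi t/24) + I_{vip} \sin(2\pi (t + \phi)/24) + \xi_{x,i},$$

with the $y$-equation unforced and uncoupled. The coupling strength
decomposes into the two neuropeptide channels,
$K = a_{avp} K_{avp} + a_{vip} K_{vip}$ with channel strengths
$K_{vip} = K_{avp} = 0.5$ so that $K$ spans $[0, 1]$ as the attenuation
factors vary. Because the coupling is diffusive, it is antisymmetric
edge-by-edge and conserves $\sum_i \dot{x}_i$ exactly (tested to
$10^{-10}$), and the dynamics are invariant under rescaling of the signal
units except for the forcing intensities — which is why the amplitude
scale of the knockout cells matters (below).

**Scenario presets.** The attenuation scheme follows the developmental /
knockout logic: VIP coupling attenuated in adults, AVP coupling
attenuated in Cry1/Cry2 double knockouts ($a_{vip} = a_{avp} = 0.1$),
VIP coupling and the VIP receptor absent in the triple knockout
($a_{vip} = 0$; external VIP forcing is ineffective). Co-culture presets
add the graft forcing $I_{vip} = I_{avp} = 0.01$ at a 24-h period with
the VIP input delayed by $\phi = 11$ h — the empirically antagonistic
phase relation ($\phi = 0$ is synergistic, $\phi = 12$ destructive; the
two forcing terms sum to an effective amplitude
$2I\cos(\pi\phi/24) \approx 0.26\,I$ at 11 h). AVP antagonist presets set
$I_{avp} = 0$ and, by default, also silence AVP coupling within the slice
($a_{avp} = 0$; switchable, since the receptor blockade acts on the
recipient cells themselves).

**Cell populations.** Wild-type cells are the unit-amplitude anchor
($\alpha = 1$, $\gamma = 0.05$, $CV = 0.3$, $D_\phi = 0.005$, period
scatter s.d. 1.5 h, dorsomedial cells 1 h faster). Double/triple-knockout
cells sit close to the Hopf bifurcation: $\alpha = 0.008$, $CV = 1.5$,
$D_\phi = 0.45$, period scatter 3 h. The small amplitude and fast phase
diffusion encode two observations at once: fully uncoupled knockout
tissue shows *no* EOF mode above a few percent (which requires the cell
signals to decorrelate within a few hours — the largest normalized
eigenvalue of $N$ independent but temporally smooth traces has a floor of
roughly $(1 + \sqrt{T_{\mathrm{eff}}/N})^2 / T_{\mathrm{eff}}$, about 5%
at $T_{\mathrm{eff}} \approx 50$ effective samples), while the printed
graft forcing $I = 0.01$ must nonetheless entrain them (entrainment
quality is governed by $I/(2\alpha D_\phi) \approx 1.4$ here). Weak
oscillators close to the bifurcation are exactly the cells that tiny
inputs can rescue. These anchors were fixed once by a calibration pass
that places every preset in its qualitative regime — the same procedure
the experimental scenarios themselves use — and are not revisited by any
test.

**Initial conditions and burn-in.** Wild-type (and split) slices start
phase-coherent (s.d. 0.5 rad) because explanted tissue arrives
synchronized to the animal; knockout presets start with uniform random
phases. This matters: a diffusively coupled lattice cannot synchronize
from scratch within a 6-day recording (the diffusive time is
$\mathrm{diam}^2/K \sim 300$ h). All presets discard a 24-h transient
(48 h for co-cultures) before sampling.

**The splitting preset.** The lobe-split regime is represented by the
rhythmic minority of double-knockout slices: intermediate cells
("dko-rhythmic fit", $\alpha = 0.3$, $CV = 0.8$, $D_\phi = 0.02$) on the
synchronized side of the critical coupling border
($a_{vip} = a_{avp} = 0.6$), weak bridges (2% of intra-lobe coupling),
and a right lobe 5 h slower with broader period scatter than the coherent
left lobe. Two of these choices deserve explanation. The 5-h offset makes
the two lobe rhythms complete one full relative cycle over the 144-h
record: with smaller offsets (e.g. 3 h) the 24- and 27-h waveforms remain
~40% correlated over six days, the two lobe eigenvalues are
near-degenerate, and the EOF mixes the lobes into uninterpretable
half-and-half modes — an eigenvector degeneracy, not a simulation
problem. The scatter asymmetry reproduces the variance asymmetry of
observed split slices (dominant modes of ~40% and ~12%), which is what
keeps the eigenvalue gap open. The remaining majority of double-knockout
slices (globally synchronized or fully damped) correspond to the same
preset family with the standard "dko fit" cells, which land on the
desynchronized side at $a = 0.1$.

## Synthetic imaging

`renderMovie()` turns a run into a PER2::LUC-like movie: each cell maps
to a 2×2 block of pixels (a single-cell ROI of ~100 µm² over ~2 µm
pixels), with pixel expectation
$\mathrm{baseline} \cdot e^{-t/\tau} (1 + g\, x_i(t)/\alpha)_+$ and
photon-counting noise (variance = mean), clipped at zero counts. Defaults:
baseline $5\times10^4$ counts (a bright cooled-EMCCD recording at 59-min
exposures), decay $\tau = 120$ h, relative modulation $g = 0.5$ per unit
of the cell's own cycle amplitude — expressing the gain relative to
$\alpha$ keeps rendering invariant to the model's arbitrary signal units.
The zero-clipping slightly biases the dimmest pixels; at the default
brightness it is never active in practice.

What the generator does *not* emulate: optics (no point-spread function),
cell movement, segmentation errors, or slice-to-slice baseline
heterogeneity. Passing tests on these movies therefore validates the
analysis chain and the network model's regimes, not robustness to every
artifact of real microscopy.

## EOF analysis

`computeEOF()` forms the pixel covariance $R = A^T A$ from the
column-centered $T \times N$ sample matrix (centering makes $R$ a true
covariance; the raw second-moment decomposition is available by flag) and
eigendecomposes it — through the dual $T \times T$ problem when pixels
outnumber time points. Eigenvalues are clamped at zero, modes carrying no
variance are dropped, and the normalized eigenvalues
$100\,\Omega_i/\sum_j \Omega_j$ always sum to 100%. The implementation is
cross-checked against an independent SVD oracle to $10^{-8}$, including
reconstruction and orthonormality.

Movies are detrended and variance-normalized first
(`preprocessMovie()`): a centered 24-h moving average is subtracted and
the residual divided by the centered moving s.d. The moving mean uses
symmetrically shrinking edge windows, which removes any linear trend
*exactly* at every sample; the moving s.d. uses clipped windows with at
least five samples so it never degenerates. Whether to run the EOF on
detrended or raw intensities is exposed; detrended is the default since
the decomposition otherwise spends its leading mode on the shared
baseline decay.

`classifyPixels()` labels each pixel by the leading mode with the largest
absolute loading, provided that loading reaches $1/\sqrt{N}$ (the natural
scale of an $N$-pixel mode; the threshold multiplier is exposed). Period
histograms are computed for classified, periodogram-significant pixels
only — the choice of which pixels enter the histograms is a documented
convention, not physics.

## Rhythm metrics

**Chi-square periodogram.** For candidate period $p$ the trace is folded
into $B = \lfloor p/dt \rfloor$ bins and the count-weighted between-bin
sum of squares over the pooled variance is referred to
$\chi^2_{B-1}$. Two deliberate deviations from the textbook recipe:
the statistic weights bins by their occupancy (the equal-weight form is
biased upward for candidates with unequal bin counts and mislocates even
a noiseless cosine's peak by several grid steps), and the default 1%
significance line is Bonferroni-adjusted across the 251-candidate grid
(15–40 h in 0.1-h steps). The adjustment matters: at the pointwise 1%
line, pure white noise is declared rhythmic somewhere on the grid in
about half of all runs; with the family-wise line the type-I rate is
conservative (0/100 in the suite) while a noiseless cosine still clears
the threshold by an order of magnitude. The pointwise line remains
available (`adjust = "none"`).

**Acrophase** is the peak time of a least-squares cosine fit at the
pixel's own significant period, reported modulo the period.

**Synchronization index** is the Kuramoto order parameter
$R(t) = |N^{-1}\sum_k e^{i\theta_k(t)}|$ over 24 hourly time points at
the end of the record, with pixel phases from the discrete analytic
signal (FFT construction — exact for DFT-grid frequencies). For $N$
independent random phases $E[R] \approx \sqrt{\pi}/(2\sqrt{N})$, the
finite-$N$ floor the tests verify.

**24-h component ratio** compares the discrete Fourier amplitude at the
bin nearest $1/24\,\mathrm{h}^{-1}$ of the ensemble-mean trace between
two windows, each trimmed to a whole number of 24-h cycles to avoid
leakage.

**Group statistics** use `stats::aov` for the one-way ANOVA and a
hand-computed Fisher LSD table (pairwise $t$ on the pooled mean square
error, no multiplicity correction, flagged at 1%), cross-checked in the
tests against `pairwise.t.test(pool.sd = TRUE)`.

## Problem sizes and determinism

The study conditions are two lobes of 120 cells, 6 simulated days of
hourly frames after burn-in, and 10-seed medians for all slice-level
quantities; single-cell recovery experiments use 10–20-day records with
20 replicates per parameter set. One root seed spawns named sub-streams
(geometry, periods, dynamics, imaging, bootstrap) via a deterministic
hash, so every stage can be re-seeded independently and full pipelines
are bit-reproducible given the same configuration and seed.

## Known limitations

* The CV of a single cell is a class indicator, not a point measurement
  (see the estimation section); the exactly-critical case $CV = 1$ is
  undecidable from finite records.
* Period estimates lose meaning for heavily damped cells whose signal
  decorrelates within a fraction of a cycle.
* GABA coupling, photoperiod effects, and retinal light input are out of
  scope, as are image registration and segmentation.
* The EOF mixes near-degenerate modes by construction; interpreting the
  second mode requires an eigenvalue gap, which the splitting preset
  engineers explicitly and real slices do not guarantee.
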