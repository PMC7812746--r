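---
title: "Methods: the loop model and the coherence pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the loop model and the coherence pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ctcoh)
```

`ctcoh` studies how cerebellar output shapes coherence between the whisker
regions of primary somatosensory (S1) and motor (M1) cortex. It has two
halves: a laminar firing-rate model of the cortico-thalamo-cerebellar loop,
and an LFP analysis pipeline (trial coherence, difference-of-coherence
testing, spectral Granger causality, behavior-linked regression) that is
exercised entirely on simulated or surrogate data. This vignette documents
the models, the estimators, the tunable parameters and the design choices.

## The firing-rate network

Each population follows

$$\tau_i \dot r_i = -r_i + \phi\!\big(\textstyle\sum_j W_{ij} r_j + I_i(t)
  - g_a a_i + \sigma_i \xi_i(t)\big), \qquad
  \tau_a \dot a_i = r_i - a_i,$$

with transfer function $\phi(x) = x/(1-e^{-x})$ — smooth, strictly
positive, $\phi(0)=1$, slope 1/2 at the origin and asymptotically linear.
Adaptation ($g_a > 0$) is present only in the cerebellar nuclei (CN), where
it produces the characteristic rebound burst after release from Purkinje
inhibition: during a 100 ms Purkinje (PC) pulse the CN rate collapses, the
adaptation variable decays toward the suppressed rate, and at stimulus
offset the reduced adaptation leaves the nuclei transiently hyperexcitable.
This is mechanistic (rate-tracking adaptation, $\tau_a$ = 80 ms by
default), not a scripted injection.

The 15 populations are the trigeminal nuclei (TN); the thalamic relays
VPM, Pom and VL; the zona incerta (ZI); cerebellar PC and CN; and, per
cortical area, supragranular and infragranular excitatory–inhibitory
pairs. Superficial pairs use $\tau_E$ = 6 ms, $\tau_I$ = 8 ms so that their
E–I loop resonates in the gamma band; deep pairs use $\tau_E$ = 30 ms,
$\tau_I$ = 75 ms and resonate at theta/alpha. Subcortical relays use
10 ms. Connectivity follows the anatomy of the loop: TN fans out to VPM,
Pom, the mossy-fiber route to PC, and CN collaterals; PC inhibits CN; CN
excites VL, ZI and (weakly) Pom; ZI sends GABAergic projections to Pom;
VPM targets superficial S1; Pom reaches superficial and deep S1 and
superficial M1 (both E and I populations — its terminals ramify in layers
I and V); VL targets M1; deep S1 projects to superficial M1 and deep M1
back to superficial S1; and an optional reciprocal superficial S1–M1
connection closes the cortico-cortical loop (on by default; the
`s1_m1_superficial_loop = FALSE` variant ablates it). Sign constraints are
enforced at construction: inhibitory sources (PC, ZI, cortical I) can only
carry non-positive weights.

Weight magnitudes are free configuration parameters. The shipped default
set was tuned by the package authors so that the network is linearly
stable in every stimulation condition (fixed point with a damping margin,
checked by the Jacobian spectrum) while reproducing the qualitative
physiology: trigeminal drive raises the superficial gain and with it
shared gamma-band fluctuations between S1 and M1; Purkinje drive
suppresses CN, which both withdraws VL excitation from M1 (damping the
gamma resonance) and disinhibits Pom via ZI, injecting shared
slow fluctuations into both areas (raising theta coherence) while its
I-population targets additionally brake the gamma loop.

**Numerics.** Euler–Maruyama with dt = 0.2 ms (dt must stay below
min $\tau$/5; halving dt moves noise-free steady states by < 1e-3
relative). The white noise $\xi$ sits inside the argument of $\phi$ and is
discretized as $\mathcal N(0,1)/\sqrt{dt}$, i.e. a fixed spectral density
independent of the step size. Rates are clipped at zero (the transfer
function keeps them positive anyway); NaN or runaway trajectories abort
with the name of the first diverging population. Noise-free steady states
come from damped fixed-point iteration (`eta = 0.2`, tolerance 1e-12) with
adaptation at its own fixed point $a = r$.

"Trials" on the model side are independent noise realizations of a
fixed-duration stimulated epoch, started at the noise-free fixed point
with a discarded 0.5 s burn-in, and the LFP proxy of a laminar module is
its mean-subtracted excitatory rate.

## The surrogate generator

The analysis pipeline must be testable against known ground truth, so the
generator builds two-"area" multichannel recordings with exactly
controlled spectral structure. Each channel is

$$x = \sqrt{c}\, s_{\text{area}} + \sqrt{1-c}\, m + b\, n + \text{evoked}
 + \text{line},$$

where $s$ is a stochastically driven damped harmonic oscillator (an AR(2)
process) centred in the requested band, common to all channels of an area
and delayed by a pure sample lag into area 2; $m$ is an independent
oscillator with the *identical* spectrum, private to each channel; and $n$
is broadband background (1/f by default — the noise colour of real
recordings is not constrained by the data the package emulates, so it is a
configuration choice). All three are normalized by their *analytic*
standard deviations, which makes the mixture exact: with $b = 0$ the
analytic coherence between areas equals $c$ at **every** frequency
(both numerator and denominator carry the same AR(2) shape), which is what
the calibration tests exploit. With $b > 0$ coherence peaks inside the
shared band. The directed lag produces a linear phase slope
$2\pi f \tau$ and a Granger asymmetry in the correct direction.

Line noise is a fixed-amplitude 50 Hz sinusoid with random per-trial
phase; the evoked template is a biphasic negative-then-positive transient
returning to baseline within ~200 ms, with per-channel amplitudes for
laminar gradients. Events sit at the midpoint of each trial so a 10 s
trial gives the conventional 5 s pre / 5 s post snippet; the defaults
(14 channels per area, 1 kHz) mirror a dual 14-contact laminar probe
recording. Identical spec + seed reproduces outputs bit-identically.

The behavioral generator draws per-trial protraction amplitudes from a
normal law (default 10 ± 2 degrees — reflexive whisker protractions show
approximately normal intertrial variation) and couples the surrogate's
shared fraction in a link band linearly to the amplitude
(`link_slope`, coherence units per degree, clamped to [0.02, 0.98]).
Whisker traces are a raised-cosine protraction over 0–0.5 s post onset
plus white measurement noise, with an optional slow shared component for
LFP–movement coherence.

## The estimators

**Time–frequency decomposition** uses complex Morlet wavelets with a fixed
cycle count (default 7), L2-normalized, FFT convolution. The "two
oscillations per frequency" convention applies to the *post-onset
averaging window* ($[onset, onset + 2/f)$), not to the wavelet kernel;
both are independently configurable because they control different
resolutions. The two-cycle window is motivated by transient evoked
responses; for the model's stationary stimulated epochs the condition
comparisons average over four cycles instead, which halves the estimator
variance without mixing in pre-onset data.

**Trial coherence.** At each frequency and time,
$C(f,t) = |\sum_k X_k Y_k^*| / \sqrt{\sum_k |X_k|^2 \sum_k |Y_k|^2}$
across trials $k$, then averaged over the two-cycle window (or the
two-cycle pre-onset window in `"baseline"` mode). Self-coherence is
exactly 1; the estimator has the usual positive bias of order
$\sqrt{\pi/4K}$ under independence, which the tests check against a
Monte-Carlo phasor oracle. Band conventions: delta 1–4, theta 4–8, alpha
8–12, beta 12–30, gamma 30–100 Hz, with a lower/higher gamma split at
55/65 Hz skirting line noise; delta and beta edges are package
conventions.

**Line-noise normalization** rescales power in ±1 Hz around 50 Hz to the
level interpolated from 3.5 Hz flanking bands (offset 0.5 Hz), leaves
phases untouched, only ever scales *down*, and only acts when the measured
level exceeds the interpolation by 5% — which makes it a no-op on clean
spectra and idempotent.

**Phase differences** come from the trial- and window-summed
cross-spectrum, wrapped to $(-\pi, \pi]$, positive when the first channel
leads; estimates with cross-spectral phase-locking below 0.1 are flagged
unreliable. For wavelet frequencies outside the band that actually
carries the shared signal the estimated phase is pulled toward the
spectrum-weighted centre frequency of the wavelet passband — an estimator
property worth remembering when interpreting slopes.

**Difference of coherence (DoC).** Coherences are Fisher z-transformed;
the difference is standardized by $\sqrt{1/(2K_A-2) + 1/(2K_B-2)}$ and
squared, giving a $\chi^2(1)$ statistic whose 5% critical value is the
conventional 3.84; two-tailed testing is realized through the squared
statistic. A label-permutation version (`doc_permutation`) serves as a
nonparametric cross-check. Monte-Carlo calibration on null surrogates
shows the test is slightly conservative (empirical size ≈ 0.04 at nominal
0.05) because the two-cycle window average reduces the estimator variance
below the nominal $1/(2K-2)$; at frequencies far outside the surrogate's
band the conservatism grows, so calibration is assessed at in-band
frequencies. Multiple comparisons use Benjamini–Hochberg
(`stats::p.adjust`).

**Spectral Granger causality.** The `"var"` backend fits a bivariate VAR
by per-equation least squares over stacked, per-trial-demeaned trials
(order by BIC, capped at 20; estimated models are checked for stability
via the companion spectral radius) and evaluates the Geweke decomposition
$G_{x\to y}(f) = \ln S_{yy}/(S_{yy} - (\Sigma_{xx} -
\Sigma_{xy}^2/\Sigma_{yy})|H_{yx}|^2)$. The `"nonparametric"` backend
factorizes the Hann-tapered, trial-averaged cross-spectral density
(lightly Daniell-smoothed over 5 bins) with Wilson's iterative
minimum-phase factorization and applies the same formula — no model order
required. The two backends cross-validate each other on simulated VAR
data; the closed-form Geweke spectrum of the test VAR(1) is the
independent oracle.

**Behavioral regression.** Coherence is undefined for a single trial, so
the per-trial "coherence level" is the leave-one-out jackknife
pseudo-value $K C - (K-1) C_{-k}$ per frequency, computed over a
configurable window (the regression uses a longer window than two cycles
— default 40 cycles in the acceptance analyses — because the pseudo-value
variance, not bias, limits predictor quality). Amplitudes are regressed
on the pseudo-value matrix by least squares with optional ridge
(required when trials < 2 × features), leave-one-trial-out
cross-validation, and cross-condition transfer of a fitted model. Trial
stratification offers the median split and eight overlapping groups from
a sliding rank window of width 25% stepped by (100−25)/7 ≈ 10.7%
(fractional rank bounds, so group means increase strictly even for n = 8;
the overlap fraction is a package choice — only the number of groups and
their spanning of the range is constrained by the emulated design).

## Problem sizes and reproducibility

The shipped analyses use deliberately moderate sizes chosen as a
reasonable compromise between statistical resolution and runtime on a
single core: model comparisons use 100 trials × 2 s per condition
(matching the per-condition trial count of the emulated experiments);
estimator calibration uses K = 500 trials; the DoC size calibration uses
1000 null replicates with K = 100; Granger checks use 60 trials × 2 s;
the behavioral recovery uses 150 trials of 8 s, where the long trials
buy down the pseudo-value noise that otherwise caps predictor R².
Every stochastic entry point takes an integer seed, uses an isolated RNG
stream, and reproduces bit-identically; derived child seeds stay below
2^31.

The recording container is a plain-text directory (`signal.tsv` with
17-significant-digit doubles, `meta.json`, `events.tsv`), so round-trips
are bit-exact and the artifacts diff cleanly under version control.

## What the surrogates do and do not show

The surrogate generator provides exact ground truth for coupling
strength, directionality, lag, line contamination and behavioral links —
that is what makes the estimator tests sharp. It does not emulate
volume conduction, non-stationary noise floors, movement artifacts,
electrode drift, or spiking-to-LFP leakage; passing the suite therefore
validates the estimators and their calibration, not the biological
interpretation of any particular recording. Similarly, the rate model
reproduces the qualitative condition contrasts (gamma up under trigeminal
drive, theta up under Purkinje drive, gamma suppression under combined
drive, CN rebound, monotone CN dose-response) with a tuned default weight
set; the exact weight values are not fitted to physiological recordings,
and variants (thalamic-hub weights, superficial-loop ablation,
M1-to-incerta feedback) are exposed as configuration rather than asserted
as a single truth.

## Known limitations

- Granger machinery is bivariate only; no conditional or time-varying
  variants.
- The wavelet estimator's frequency-dependent window makes its effective
  degrees of freedom weakly frequency-dependent; the DoC variance
  convention ignores this, hence the mild conservatism quantified above.
- The line-noise normalization is a flanking-band power rescaling; it
  removes power, not the waveform, and is not a harmonic regression.
- The laminar model has no spiking, conductances, plasticity or
  biophysical LFP forward model; its "LFP" is a rate proxy.
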