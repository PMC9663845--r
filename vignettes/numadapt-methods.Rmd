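---
title: "Models and methods behind numadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind numadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numadapt)
```

## The scientific problem

Numerosity adaptation is a robust psychophysical phenomenon: after a few
seconds of exposure to a highly numerous cloud of dots, a test stimulus shown
at the adapted location appears to contain fewer items than it physically
does, typically by around 20%. Because adaptation changes *perceived*
numerosity while the stimulus itself is unchanged, it is the ideal lever for
asking which stages of the visual ERP track physical versus perceived number.
The experimental logic compares three conditions on identical test stimuli:

* **Baseline** — estimation with no preceding adaptor;
* **Adaptation** — the test appears where a 48-dot adaptor was shown;
* **Neutral** — the test appears where an adaptor matching the test
  numerosity was shown (same brightness exposure, no numerosity bias).

The electrophysiological signature of interest is the posterior positivity
around 200–250 ms (P2p), a component long associated with numerical
processing. A perceived-numerosity account predicts a P2p amplitude
reduction specific to Adaptation versus Neutral, while earlier components
(P1, N1) should track only physical stimulus properties. The package
implements the complete analysis chain for this design and a synthetic
generator that reproduces its statistical structure, so every stage can be
exercised and calibrated without access to recorded data.

## The behavioral model

`behavioral_gen_spec()` / `generate_behavior()` model a verbal estimate of a
test numerosity $N$ as

$$\hat N_{p,t} = \mathrm{round}\big(N (1 - u_p\,[\text{cond}=\text{Adaptation}]) + b_p + \varepsilon_{p,t}\big),\quad
b_p \sim \mathcal N(0, \sigma_b^2),\ \varepsilon_{p,t} \sim \mathcal N(0, \sigma_t^2),$$

truncated at one dot. Defaults: underestimation fraction $u = 0.20$
(Adaptation only), participant bias SD $\sigma_b = 1.5$ dots, trial noise
$\sigma_t = 4$ dots, 80 reported trials per condition for the central
numerosity (one third of 240 presentations; reports are requested on a
random third of trials) and 8 per condition for each filling numerosity
(22, 26, 35, 41). Baseline and Neutral share one expectation, so
$\mathbb E[\text{Adaptation}] / \mathbb E[\text{Neutral}] = 1 - u$ by
construction. The trial-noise and bias values are free parameters of the
generator — direct-estimation variability is not published for this design —
chosen once at magnitudes typical of verbal numerosity estimation in the
20–40 dot range.

## The EEG forward model

`eeg_gen_spec()` / `generate_epochs()` build single trials on a 30-channel
10-20 montage at 250 Hz over a −200..600 ms epoch (half-open sample
convention, 200 samples) as

$$x_{c}(t) = \sum_k (a_k + \eta_k)\, w_{kc}\, e^{-(t-\ell_k)^2/2\sigma_k^2}
  \;+\; n^{1/f}_c(t) + \alpha_c(t) + n^{w}_c(t),$$

with per-trial amplitude jitter $\eta_k \sim \mathcal N(0, 0.5\ \mu V)$,
spectrally shaped $1/f$ noise (exponent 1, 8 µV RMS per trial and channel),
a 10 Hz alpha sinusoid with random phase (3 µV) and white noise (2 µV).
Component topographies $w_{kc}$ are Gaussian fall-offs in great-circle angle
from a peak electrode; latencies sit inside the conventional windows:

| component | latency | width (SD) | peak | condition structure |
|---|---|---|---|---|
| P1 | 100 ms | 15 ms | POz (40°) | elevated in Adaptation *and* Neutral vs Baseline (adaptor brightness aftereffect) |
| N1 | 170 ms | 20 ms | PO7 + PO8 (30°) | equal across adaptation conditions; scales with physical numerosity bilaterally |
| P2p (left) | 220 ms | 20 ms | PO7 (30°) | reduced by 1 µV in Adaptation only |
| P2p (right) | 220 ms | 20 ms | PO8 (30°) | equal across adaptation conditions; scales with physical numerosity |
| P3 | 350 ms | 40 ms | Pz (45°) | mildly elevated after any adaptor |

`default_adaptation_scenario()` packages these together with LowNum/HighNum
variants (pooled 22+26 vs 35+41 dot trials, 96 each) in which N1 scales
bilaterally and P2p scales over right-posterior channels — the physical
counterpart of the left-lateralized perceived effect. Trial counts are 240
per adaptation condition, matching the deliberately over-sampled central
numerosity of the design the scenario emulates.

`simulate_experiment()` adds the participant level: each of the 25
participants carries a latent effect size for behavior and for the P2p
reduction (relative SD 0.25), sharing a common factor so the two effects
correlate at the scenario's `coupling` (default 0.6). This is what a
brain–behavior correlation analysis should be able to recover.

### Sampling participant ERPs directly

Averaging hundreds of generated trials for hundreds of simulated
experiments is wasteful: for this generative model the distribution of the
trial average is known exactly. Gaussian noise components average to
Gaussian noise with SD scaled by $1/\sqrt n$, amplitude jitter likewise, and
the mean of $n$ random-phase sinusoids has Gaussian quadrature coefficients
of variance $a^2/2n$ (asymptotically; excellent for $n \ge$ a few dozen).
`generate_erp()` samples from that distribution directly, and a test
verifies its mean and SD agree with the average of `generate_epochs()`
trials. Simulation studies in this package use `generate_erp()`; trial-level
generation remains available for preprocessing tests and artifact studies.

### What the generator does and does not emulate

It reproduces: the effect structure above, $1/f$-dominated noise spectra,
alpha activity, trial-to-trial amplitude variability, per-participant effect
heterogeneity, behavioral–electrophysiological coupling, and (optionally)
large zero-mean artifact bursts on ~5% of trials so that a 150 µV
peak-to-peak rejection removes roughly the 4–6% of epochs reported for
recordings of this kind. It does **not** emulate: realistic blink/EMG
waveforms (only amplitude bursts), spatially correlated noise between
channels, head-model forward projection (topographies are parametric
Gaussians), latency jitter, or non-stationarities across a session. Passing
tests therefore demonstrate the statistical machinery is correct and
well-calibrated under a realistic noise regime — not that any particular
real dataset will show these effects.

One deliberate realism of the Gaussian topographies is worth flagging: the
left P2p component leaks a mean weight of about 0.09 onto right-cluster
electrodes, the way volume conduction smears any focal source. The
FDR-plus-persistence point-wise contrast still reproduces a right-cluster
null in ~99% of simulated experiments, but the *uncorrected* window
bootstrap — a single, more sensitive test — can exclude zero on the right in
an appreciable fraction of experiments. The two procedures genuinely differ
in sensitivity; results reported from the window bootstrap alone should be
read with that in mind.

## Behavioral statistics

**Pruning.** Estimates outside $[Q_1/2,\ 2 Q_3]$ of a participant's
per-condition response distribution are discarded (type-7 quantiles). The
rule targets response-dialing errors; "below twice the lower quartile" is
interpreted as the reciprocal bound $Q_1/2$, since a literal $2 Q_1$ lower
bound would discard the bulk of well-behaved responses.

**One-way RM-ANOVA** on participant × condition means, with
$F = MS_\text{cond}/MS_\text{error}$, dfs $(k-1, (k-1)(n-1))$, Tukey–Kramer
pairwise p-values from the studentized range on the repeated-measures error
term, and both $\eta^2 = SS_\text{cond}/SS_\text{total}$ (reported by
default) and partial $\eta^2$. With no error variance the statistic is
defined as 0 (no condition effect) or Inf (pure condition effect).

**Two-way RM-ANOVA** (Condition × Numerosity, univariate within-subject
decomposition, each effect tested against its own participant interaction)
checks that Baseline and Neutral estimates agree across the filling
numerosities.

**Power analysis.** `required_sample_size()` finds the smallest $n$ with
noncentral-F power $\ge$ target for the within-factor test, using
$\lambda = f^2 n m/(1-\rho)$, $df_1 = (m-1)\varepsilon$,
$df_2 = (n-1)(m-1)\varepsilon$. With $f = 0.30$, $\alpha = 0.05$, 90% power,
$m = 3$, $\rho = 0.5$, $\varepsilon = 1$ this yields $n = 25$ (power 0.887
at 24, 0.900 at 25).

## ERP preprocessing

The chain mirrors standard practice: zero-phase windowed-sinc (Hamming) FIR
band-pass with nominal −6 dB points at 0.5 and 40.5 Hz (order from the
3.3/transition rule; at the band edges the realized response sits in the
−4 to −8 dB neighborhood because the lower transition band abuts DC);
integer-factor downsampling to 250 Hz behind an anti-alias low-pass;
spherical-spline bad-channel interpolation (stiffness 4, 50 Legendre terms,
$10^{-5}$ regularization — interpolation weights sum to one, so constant
potentials are exact); average reference; epoching with per-trial baseline
correction over −200..0 ms. Epoch samples follow the half-open convention
$[t_0, t_1)$, so −200..600 ms at 250 Hz is exactly 200 samples with the
onset sample included. Manual artifact inspection is replaced by a
configurable peak-to-peak criterion (default 150 µV), and
component-based ocular/muscle cleanup is exposed only as a pluggable
`artifact_removal_hook()` — the generator can produce artifact-free data, so
the hook is exercised structurally, not scientifically.

## Resampling statistics

For each post-stimulus time point the paired condition difference is tested
by resampling *participants* with replacement (20,000 iterations by
default), with the two-sided p-value
$p = \min\big(1,\ 2\min(\tfrac{\#\{\bar d^* \le 0\}+1}{B+1},
\tfrac{\#\{\bar d^* \ge 0\}+1}{B+1})\big)$ — the $+1$ correction keeps
p away from exactly zero. Benjamini–Hochberg FDR is applied across the
post-stimulus time points of each contrast (per contrast, per cluster; the
choice is recorded in the result object), and surviving points are kept only
in runs of at least 4 consecutive samples (16 ms at 250 Hz). The persistence
filter runs *after* FDR. $\alpha$ defaults to 0.05. Window amplitudes
(default 200–250 ms; the component's published window bounds vary between
~200–220 and ~200–250 ms, so the window is a parameter) are compared with
the same participant bootstrap and a central 95% percentile interval, and
brain–behavior association uses Spearman rank correlation.

Calibration facts established by the test suite: the raw per-time-point
test rejects at 5% ± 2% under the null; after FDR and persistence the
per-experiment family-wise false-positive rate over the whole epoch is below
5%; and under the default scenario the left-cluster P2p reduction is
detected (with a right-cluster point-wise null) in well over 80 of 100
simulated experiments.

## Numerical and design choices

* Bootstrap iterations are scaled from 20,000 (the analysis default) to
  2,000 inside simulation studies — 200 null replicates and 100 effect
  replicates at n = 25 — which leaves the Monte-Carlo error of a 0.05-level
  decision far below the effects being counted; single-run examples use the
  full 20,000.
* All randomness flows through explicit integer seeds; every generator and
  bootstrap is bit-reproducible, and the pipeline bundle is a pure function
  of (config, seed). Condition streams derive from the generator seed plus a
  stable offset of the condition label.
* $1/f$ noise is synthesized by frequency-domain shaping of complex white
  noise with the DC bin zeroed, rescaled to unit expected RMS.
* The epochs container is a single self-describing file (JSON header +
  little-endian float64 payload) written and read by the package; continuous
  EEG is read from BrainVision (binary float32/int16, multiplexed or
  vectorized, and ASCII) and EDF/EDF+ (uniform-rate signals; annotation
  channels dropped).
* Degenerate inputs error early and descriptively: missing design cells name
  the participant and condition; unknown condition labels list the known
  ones; an all-rejected epoch set advises raising the threshold.

## Limitations

Bayes factors and psychometric-function fitting are out of scope, as are
source-space statistics and cluster-mass permutation tests (a related but
different inferential family). The preprocessing defaults assume continuous
data were filtered before epoching; epoch-wise filtering is available but
second choice. Real-data reproduction of published group statistics requires
the corresponding public deposit; the package's claims are calibrated on its
own generative model.
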