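---
title: "Fractal-dimension features for motor-imagery EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal-dimension features for motor-imagery EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdbci)
```

## The problem

A motor-imagery brain–computer interface asks a user to rehearse a movement
mentally and tries to detect that state from EEG. The classical features —
mu (8–13 Hz) and beta (13–30 Hz) band power over sensorimotor cortex — can
be weak discriminators in populations such as late-stage ALS, where
cortical reorganization shifts both the informative rhythms and the
informative scalp sites. `fdbci` implements an alternative: treat the EEG
epoch as the output of a dynamical system and use its *complexity*,
summarized by a fractal dimension (FD), as the per-channel feature. Two
estimators are provided, together with the baseline features they are
compared against, an automatic channel-selection step, and a
leave-one-out-validated classification pipeline.

## The estimators

### Grassberger–Procaccia correlation dimension (GPFD)

An epoch $x(1),\dots,x(N)$ is delay-embedded into $M$-dimensional vectors
$y(i) = (x(i), x(i+\tau), \dots, x(i+(M-1)\tau))$, $i = 1,\dots,N-(M-1)\tau$.
The correlation integral

$$C(r) = \frac{2}{N_p (N_p - 1)} \sum_{i<j} H\!\left(r - \lVert y(i)-y(j)\rVert\right),
\qquad N_p = N - (M-1)\tau,$$

is the fraction of vector pairs closer than $r$ (strict inequality:
$H(0)=0$). Over the scaling region, $\log C(r)$ is linear in $\log r$ and
its slope is the correlation dimension $d_c(M)$. As $M$ grows, $d_c(M)$
rises and, for signals with finite-dimensional structure, saturates; the
estimator starts at $M=2$ and stops at the first $M \ge 3$ with
$|d_c(M) - d_c(M-1)| < \epsilon$. The saturation value is the reported FD.
Stochastic broadband signals never saturate — white noise fills every
embedding, so $d_c$ keeps growing — and the result is then flagged
(`saturated = FALSE`) with the last $d_c$ as the value, rather than raised
as an error. Note that the normalization uses unordered vector pairs over
$N_p$, which keeps $C(r) \in [0,1]$; constant factors do not move the
slope.

Defaults: $\tau = 50$ samples (0.1 s at 500 Hz, the value selected by the
delay grid search in the protocol this package follows), $\epsilon = 0.001$,
embedding cap `M_max = 50`.

Two numerical choices are ours because no convention fully determines them:

* **Scaling region.** The radius grid is 24 log-spaced radii between the
  5th and 50th percentile of the pairwise-distance distribution (avoiding
  the noise-dominated small-$r$ tail and the saturated large-$r$ plateau),
  with the percentiles estimated on a deterministic systematic subsample of
  at most 64 vector indices. Both quantiles, the grid size and the sample
  size are configurable via `cd_radius_spec()`; the fit uses only radii
  with $C(r) > 0$ and requires at least five of them.
* **Reference-vector subsampling.** For long embeddings the correlation
  sum pairs every $k$-th vector ("reference points") against all later
  vectors instead of enumerating every pair (`max_ref`, default 300 in
  `gpfd()`). Short embeddings fall below the cap and are computed exactly —
  which is also how the test suite pins the implementation against a naive
  double-loop oracle. Slopes move negligibly; cost drops by the subsampling
  factor, which is what makes 2,400-epoch sessions tractable.

One implementation note: all $d_c(M)$ values for a signal are obtained in a
single pass over vector pairs (the squared distance at $M+1$ extends the one
at $M$ by one coordinate), evaluated in growing blocks of $M$; the stopping
rule is applied to the resulting trajectory. This is algebraically identical
to the literal iterate-and-recompute loop and roughly an order of magnitude
faster.

### Higuchi fractal dimension (HFD)

For interval size $k$ and start index $m \le k$, the curve length

$$L_m(k) = \frac{1}{k}\,\frac{N-1}{\lfloor (N-m)/k\rfloor\, k}
\sum_{i=1}^{\lfloor (N-m)/k\rfloor} |y(m+ik) - y(m+(i-1)k)|$$

is averaged over $m = 1,\dots,k$ to give $L(k)$, and the FD is the
least-squares slope of $\log L(k)$ against $\log(1/k)$ for
$k = 1,\dots,k_{\max}$ (default $k_{\max}=100$). For one-dimensional
signals the value runs from 1 (smooth, deterministic) to 2 (uncorrelated
noise); a noiseless ramp gives exactly 1 because $L(k) \propto 1/k$
identically, and fractional Brownian motion with Hurst exponent $H$ gives
$2 - H$.

Two estimator properties worth knowing:

* **Noise sensitivity.** Broadband measurement noise inflates the
  small-$k$ curve lengths and pushes the estimate toward 2. At a few
  percent noise the planted complexity differences in our synthetic
  sessions remain visible; at 5% they are essentially erased. This is a
  property of the Higuchi method, not of the implementation.
* **Periodic signals.** The power law holds only for $k$ below the
  oscillation period; fitting past it (e.g. $k_{\max}=100$ for a 10-Hz tone
  at 500 Hz, period 50 samples) yields slopes above 2 that are no longer
  dimensions. The validation battery therefore evaluates periodic signals
  with $k_{\max}$ inside their scaling regime.

## Channel selection

Per-channel features over the trials of a two-class task form a
trials-by-channels table. With class priors $P_i = n_i/\sum_j n_j$, the
diagonal within- and between-class scatters are

$$S_w(f) = \sum_i P_i \frac{1}{n_i} \sum_j (x_{ijf} - m_{if})^2,
\qquad S_b(f) = \sum_i P_i (m_{if} - m_f)^2,$$

and the Fisher score is $F(f) = S_b(f)/S_w(f)$ (with a $10^{-12}$ floor on
$S_w$ instead of emitting infinities; floored columns are flagged). The
score is invariant to per-channel affine rescaling, so it ranks channels
regardless of per-site amplitude differences. `select_channels()` takes the
top-$d$ (or worst-$d$, for control analyses) with ties broken by channel
index for determinism.

Where selection happens matters. Scoring channels once on *all* trials and
then cross-validating leaks label information into the folds and inflates
accuracy; this package nests the ranking inside every training fold by
default and keeps the global variant behind `paper_faithful = TRUE` for
comparability with the common practice. A dedicated test verifies the
leakage direction on null data.

## Classification and validation

`loo_cv()` runs one fold per trial; standardization (z-scoring with
training-fold statistics, on by default since FD, band-power and AR
features live on different scales) and nested selection are re-fit per
fold. K-NN uses $K=1$ by default — the protocol never states $K$, and the
nearest-neighbor rule is the simplest member of the family — with
documented tie-breaks (vote, then mean distance, then lower class). LDA
uses pooled covariance and equal priors (classes are balanced 40/40 by
design), with an automatic diagonal-shrinkage fallback when the pooled
covariance is singular. `grid_search()` implements the
smaller-value-wins-ties argmax used for the delay grid
$\tau \in \{20,\dots,70\}$.

CSP is supervised, so its spatial filters are always re-fit per fold
(per-trial covariances are cached; each fold is then one eigenproblem).
Its channel policy, when not `"all"`, ranks channels by Fisher scores of
log band power in the CSP filter band — the paper-style FD ranking does
not apply to a method whose features are not per-channel — and at least
two channels are required, since a single channel has no spatial
covariance to decompose.

## The synthetic generator

No EEG from the original study is deposited, so the package ships a
generator that emulates the *statistical* property the method exploits
rather than cortical physiology: class-dependent signal complexity.
Each epoch and channel is an exact-covariance fractional Brownian motion
(circulant embedding), scaled to unit variance, plus white measurement
noise; on the informative channels, imagery-class epochs use Hurst
$H_0 + \Delta H$ (a complexity shift that both FD estimators respond to
directly), optionally plus a band-limited sinusoid with class-dependent
amplitude for the band-power/CSP baselines.

Defaults mirror the recording protocol: 30 channels with 10–20 montage
names, 500 Hz, 3-s epochs (1500 samples), 40 epochs per class;
$H_0 = 0.6$, $\Delta H = 0.2$, noise SD 0.02. The noise level was fixed
during generator calibration at the value where the Higuchi estimator
retains the planted effect (see its noise sensitivity above);
$\Delta H = 0.3$ serves as the "large effect" configuration in the
recovery and pipeline checks. What passing tests on these sessions shows
is that the chain *complexity shift → FD feature → Fisher ranking →
classifier* works end to end and is calibrated (chance-level on null
data); it does not show that real ALS EEG carries complexity shifts of
this size, which only patient recordings could.

Reference signals with known dimension (`gen_reference()`) close the
loop on the estimators themselves: line and sine (FD 1), white noise
(FD 2 in the Higuchi sense), fBm (FD $2-H$), and the Lorenz system at
the classical parameters $(\sigma, \rho, \beta) = (10, 28, 8/3)$,
integrated with fixed-step RK4 at $dt = 0.01$ with $10^4$ transient steps
discarded (correlation dimension $\approx 2.05$ in the literature; a
brute-force full-pair correlation sum on the 3-D state trajectory is the
oracle used by the test suite).

## Problem sizes used in the shipped checks

The validation suite runs estimator checks at $N = 1500$ (the epoch
length), 20 seeds per stochastic claim; planted-channel recovery over 50
full-size sessions; chance-level calibration over 100 five-channel
null sessions (channel count does not enter a chance-level claim, the
trial count does); and the full GPFD top-5 pipeline on two large-effect
sessions with `M_max = 20` — saturation in EEG-like signals occurs between
$M = 10$ and $30$, and the feature-separation sweep during design showed
the $d_c$ trajectory at $M \approx 20$ to be the stable summary, so the cap
is a problem-size choice, not a different method.

## Known limitations

* EDF ingestion is not implemented; the native format is a delimited
  matrix per trial plus a JSON sidecar.
* The Fisher criterion scores channels marginally; jointly informative
  channel sets with low marginal scores are invisible to it (an explicit
  limitation of the criterion, inherited by design).
* GPFD values at large $M$ rest on few vector pairs and are noisy for
  short epochs; the saturation flag should be consulted before
  interpreting `fd` as an attractor dimension.
* The generator's fBm-plus-noise epochs lack line noise, artifacts,
  volume-conduction correlations between channels, and nonstationarity
  within epochs — all present in real recordings.

## A worked example

```{r example, eval = FALSE}
ses <- gen_session(session_spec(hurst_shift = 0.3, seed = 1))
rep_ <- pipeline_evaluate(ses, "gpfd",
                          channel_policy = list(mode = "top", d = 5),
                          spec = classifier_spec("knn", K = 1),
                          M_max = 20)
print(rep_)
#> LOO-CV: accuracy 98.75% over 80 folds (knn, gpfd, channels: top5)
```
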