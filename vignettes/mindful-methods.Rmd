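---
title: "Measuring iBCI model drift from neural data alone: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring iBCI model drift from neural data alone: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mindful)
```

## The problem

A fixed intracortical brain-computer interface (iBCI) decoder maps binned
neural features (threshold-crossing counts, spike-band power) to cursor
velocity. Over days to months the relationship between recorded activity
and motor intention changes — *model drift* — and closed-loop performance
degrades until the decoder is recalibrated. During unstructured personal
use there are no cued targets, so performance cannot be measured directly;
what is always available is the recorded neural activity itself. This
package implements an unsupervised drift statistic — the MINDFUL score —
that tracks performance from the marginal distribution of derived neural
features, together with the supervised analyses used to validate it and a
closed-loop simulator that generates studies with known ground truth.

## The score

Two collections of time bins are each summarised by the sample mean and
covariance of their derived features, and compared with the closed-form
Kullback-Leibler divergence between Gaussians,

$$
d_{KL}(P_1 \| P_2) = \tfrac12\Big(\operatorname{tr}(\Sigma_2^{-1}\Sigma_1)
 + (\mu_2-\mu_1)^{\top}\Sigma_2^{-1}(\mu_2-\mu_1) - k
 + \ln\tfrac{\det \Sigma_2}{\det \Sigma_1}\Big).
$$

$P_1$ is the *reference*: bins from the session(s) when the decoder was
first deployed, optionally restricted to instants of good control
(angle error below 4 degrees). $P_2$ is a *comparison window*: all bins in
a trailing 60-s window stepped by 1 s. The Gaussian form is a summary
device — nothing downstream assumes the features are Gaussian. Jeffreys,
Bhattacharyya and 2-Wasserstein closed forms are provided as alternates
(`alt_divergence()`); they behave similarly and KLD is the default.

Numerics: divergences are evaluated through Cholesky factors (triangular
solves; log-determinants from factor diagonals), never an explicit
inverse or determinant. A window covariance that is singular or has
condition number above $10^8$ (or is estimated from $n \le k$ bins)
receives a diagonal ridge proportional to $\operatorname{tr}(\Sigma)/k$,
escalating tenfold from $10^{-8}$ until positive definite; the applied
ridge is recorded on the summary. Windows with fewer than $k+2$ valid
bins emit `NA` rather than a value.

The divergence direction is $d_{KL}(\text{ref}\,\|\,\text{window})$ by
default — the comparison covariance is the one inverted — with an
explicit switch, because the asymmetry is material when a window's
covariance collapses (for instance when decoded output stagnates during
poor control: the score spikes, which is informative).

## Derived features

Three column blocks, concatenated in any order (`build_derived_features()`):

* `pc` — the top $M = 5$ principal components of the z-scored channel
  features, with the PCA basis fitted on the *reference bins only* and
  frozen (deterministic sign convention: the largest-magnitude loading of
  each component is positive);
* `xhat` — the decoder's 2-D velocity output;
* `xhat_lag` — the same output one bin (20 ms) earlier.

The default composition `pc + xhat + xhat_lag` has $k = 9$; `xhat` alone
gives $k=2$ and `xhat + xhat_lag` gives $k=4$. Channel features are
z-scored with a *causal* trailing 3-minute window that restarts at block
boundaries, matching the adaptive normalisation used online (a centred
window would leak future information). For the first three minutes of a
block the window expands from the block start; the first 30 s of a block
are flagged invalid and excluded from every reference set and comparison
window, as is the first bin of a block when a lag feature is present.
Variances are clamped at `var_floor` ($10^{-6}$ z-units$^2$) so silent
channels produce zeros rather than blow-ups. Because normalisation is
mean-adaptive, the score is sensitive to changes in tuning structure and
correlation, not to slow mean shifts — which the online systems already
correct.

## Performance ground truth and validation analyses

**Angle error (AE).** The absolute angle between the intended direction
(cursor to target) and the decoded velocity, per 20-ms bin; 0 is perfect,
180 worst. Bins outside trials or with degenerate vectors are masked.
Windowed median AE shares the exact window grid of the score trace so the
two series correlate row-for-row (median, not mean, because AE is
right-skewed; even counts use the mean of the central order statistics;
windows under 50% valid bins emit `NA`; pairs with missing values drop
listwise).

**AE-binned divergence.** Pooling all sessions, bins are grouped into 45
four-degree AE intervals; the KLD from the low-AE reference to each
interval's distribution, regressed on interval midpoints, measures how
linearly distribution shift tracks performance. The first interval *is*
the reference, so its divergence is exactly zero by construction.

**Cosine tuning.** Per feature and session, ordinary least squares of
$y = b_0 + b_1\cos\theta + b_2\sin\theta$ on the 50 bins from 160 ms to
1.16 s after each non-outlier trial's go cue, every bin an observation
sharing the trial's direction (the angle of target minus cursor at the go
cue). Modulation depth $\sqrt{b_1^2+b_2^2}$, preferred direction
$\operatorname{atan2}(b_2,b_1)$, significance by the overall $F$-test at
$p<0.05$ with $(2, n-3)$ df; no multiple-testing correction across
features is applied (flagged here deliberately). Session-to-session
changes use $\Delta MD = MD - MD_{ref}$ and the shorter arc
$|\Delta PD| \in [0,180]$ relative to the first day the feature was
significantly tuned. Change significance is assessed by resampling
*trials* (not bins, which are serially correlated within a trial) with
replacement, B = 1000, refitting from per-trial sufficient statistics,
and asking whether the 95% percentile interval of the paired differences
excludes zero; circular differences are wrapped to $(-180, 180]$ before
the interval. Tuning maps (the $3\times N$ coefficient matrices of
significant features) are compared across sessions by Pearson correlation
over features significant on both days.

**Latent drift.** Condition averages (8 direction sectors, 50 time bins,
Gaussian-smoothed with a 50-ms SD kernel, mass-renormalised at window
edges) are demixed into a direction-independent time course and the
direction-dependent residual. The rank-2 encoder/decoder pair is the
analytic reduced-rank regression of the residual on the full condition
average — the least-squares map (SVD pseudo-inverse, so exactly minimum
norm on rank-deficient averages) projected onto the top-2 principal
subspace of its fitted values. Cross-validated regularisation, as used in
full demixed-PCA implementations, is deliberately not implemented: only
the top two direction components and the variance-accounted-for statistic
$$R^2 = \frac{\|\bar Y\|^2 - \|\bar Y - FD\bar Y\|^2}{\|\bar Y\|^2}$$
are needed, the fits here are far from the small-sample regime where the
regulariser matters, and an unregularised solution is exactly
reproducible. $F$ and $D$ stay frozen from day 0; VAF is invariant to
global rescaling of the target.

## The simulator

`simulate_session()` closes the full loop at 20 ms: cosine-tuned rates
$r_c = \max(0,\, b_c + m_c\cos(\theta - \phi_c))$ (rectified-linear, so
the tuning analysis can recover $m_c, \phi_c$ without link-function
bias), Poisson or Gaussian counts, causal online z-scoring identical to
the analysis rule, a fixed linear decoder $v_t = Wz_t$ smoothed as
$\hat X_t = \alpha\hat X_{t-1} + (1-\alpha)\beta v_t$, speed-capped
cursor integration, center-out-and-back or random-target (500-ms dwell)
trials with a 10-s timeout, and a 160-ms reaction time during which the
population remains tuned to the previous direction. Session-to-session
drift is parameterised per session: preferred-direction rotation (scalar
or per channel), modulation scaling, mean offsets in per-bin count SD
units, channel dropout (baseline-only activity), and injected outlier
events (packet drop, single-bin amplitude excursions).

Defaults and why:

* **48 channels, baselines 5–20 Hz, modulation 4–12 Hz** — multiunit
  threshold-crossing scales; at $\alpha = 0.96$, $\beta = 1.5$ the
  trained decoder yields day-0 windowed median AE around 25 degrees,
  i.e. the stable high-performance baseline from which drift should be
  visible.
* **Two 180-s blocks per session** — a scaled-down session; long enough
  for ~100 windows per block after warm-up, short enough that a whole
  multi-session study simulates in seconds.
* **30-s assisted lead-in per closed-loop block.** The online normaliser
  starts a block empty; if the cursor parks while the window fills, the
  rolling mean absorbs the tuning signal of the constant intent and the
  session can lock into a degenerate slow regime. Real systems warm-start
  normalisation from the previous block or begin with assisted control;
  the simulator drives the cursor along the ideal trajectory for the
  first 30 s, which coincides with the analysis warm-up and is therefore
  excluded from every window anyway.
* **Signed per-channel rotation as the canonical drift** (each channel a
  fixed multiplier in $[0.5, 1.5]$ with random sign, scaled by a
  per-session magnitude). A rigid global rotation of all preferred
  directions leaves the z-scored feature distribution almost unchanged —
  it relabels directions that the task visits roughly uniformly — so it
  is nearly invisible to an unsupervised marginal statistic even while it
  wrecks control; heterogeneous rotation progressively decorrelates the
  population from the frozen decoder the way chronic instability does,
  and both the feature distribution and performance degrade gradedly.

`simulated_drift_study()` packages three regimes used throughout the
test suite: *severe* (10 sessions, rotation ramped to 150 degrees;
median AE climbs from ~25 into the >150-degree range — used for
performance-tracking checks), *moderate* (8 sessions to 90 degrees;
session statistics stay in the graded, monotone regime — used for
tuning-similarity and VAF checks), and *stationary* (16 one-block 300-s
sessions, no drift). The stationary control uses more, shorter sessions
because the null distribution of a trend statistic over the pooled trace
is governed by the number of independent session realisations, not the
number of (heavily overlapping) windows; with 16 sessions the no-trend
check is a sharp statement rather than a noisy one. Trend on stationary
data is assessed on sessions *after* the reference day: the reference
day's windows overlap the reference bins themselves and sit trivially
lower, a selection artefact rather than drift.

What the simulator does **not** emulate: user learning or compensatory
strategy changes, within-session plasticity, non-Poisson spiking
statistics, correlated noise across channels, electrode-array
micromotion dynamics, or the specific RNN/click decoders of real
systems. Passing tests on simulated studies therefore demonstrate that
the statistics recover planted drift under a plausible generative model,
not that effect sizes on real recordings will match.

## Other conventions and degenerate inputs

* Trials are half-open bin spans `[start, end)`, 1-based; coordinates
  are screen units, y up, origin at centre.
* Outlier trials: packet-drop fraction above 5% or any bin above the
  channel mean plus 8 SD (session statistics excluding packet-drop
  trials; zero-variance channels skipped). The amplitude rule has a
  non-trivial false-positive rate on very low-rate Poisson counts —
  an intrinsic property of an 8-SD rule at small means.
* Windows are trailing, right-aligned, anchored at block starts, and
  never straddle blocks; the trace and windowed-AE grids are identical.
* The between-session divergence matrix is asymmetric (KLD is); a
  symmetric view is `(A + t(A)) / 2`. Its diagonal (within-session window
  pairs) is the natural baseline for the off-diagonal entries.
* Empty AE intervals, sessions without complete windows, and feature
  pairs with fewer than two shared significant features propagate `NA`
  and are excluded from fits, never interpolated.
* Bootstrap resamples that produce a rank-deficient design are redrawn,
  capped at 10 B draws.

## Limitations

The score is relative to its reference: a poorly chosen reference (high
AE, one movement direction) weakens the performance correlation, which is
why reference selection is exposed (`select_reference_bins()`) rather
than hidden. The Gaussian summary ignores higher moments; a drift that
preserved mean and covariance would be invisible. Very short windows
reflect direction-to-direction differences rather than drift, which is
the reason for the 60-s default. The dPCA step here is the two-component
unregularised variant only. Ingesting real recordings requires writing
them into the documented session-directory schema; no downloader for
public deposits is included.
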