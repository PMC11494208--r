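# mindful

Unsupervised drift monitoring for chronic intracortical brain–computer
interfaces (iBCIs).

A fixed iBCI decoder turns binned neural features (threshold-crossing
counts, spike-band power at 20 ms resolution) into cursor velocity. Over
days to months the mapping between recorded activity and motor intention
drifts and closed-loop control degrades — but during real personal use
there are no cued targets, so performance cannot be measured directly.
This package is for iBCI researchers and engineers who need to know,
from the neural data alone, when a deployed decoder is drifting and
recalibration is due.

## The statistic

Derived features per 20-ms bin — the top M = 5 principal components of
causally z-scored channel features (basis frozen on the reference data),
the decoded 2-D velocity X̂, and its one-bin lag X̂_lag, k = 9 in total —
are summarised over collections of bins by their sample mean and
covariance. The **MINDFUL score** of a trailing 60-s comparison window
(stepped by 1 s) is the closed-form Kullback–Leibler divergence from a
reference distribution of the same features estimated when control was
known to be good:

    d_KL(P1 ‖ P2) = ½ [ tr(Σ₂⁻¹Σ₁) + (μ₂−μ₁)ᵀΣ₂⁻¹(μ₂−μ₁) − k + ln(det Σ₂ / det Σ₁) ]

with P1 the reference and P2 the window. Rising divergence tracks rising
angle error (the angle between intended direction and decoded velocity)
without ever looking at targets. Around the score the package provides
the full validation machinery — windowed median angle error on the same
grid, divergence binned by angle error, per-feature cosine-tuning drift
(ΔMD/ΔPD with trial-level bootstrap change detection), tuning-map
similarity, direction-demixed latent variance accounted for, pairwise
between-session mean divergence — and a closed-loop cursor-BCI simulator
with parameterised session-to-session drift so everything can be tested
against known ground truth. Sessions read and write a plain
parquet/CSV+JSON directory schema (`read_session()`, `write_session()`).

## Worked example

Score a simulated 10-session study whose population drifts by a ramped,
signed per-channel rotation of preferred directions:

```r
library(mindful)
study <- simulated_drift_study("severe", seed = 7)
ref   <- mindful_reference(study$sessions)   # day-0 bins with AE < 4 deg
trace <- mindful_trace(ref, study$sessions)
med   <- do.call(rbind, lapply(study$sessions, function(s)
  windowed_median_ae(angle_error(s))))
cor_out <- score_performance_correlation(trace, med)
print(ref)
cat(sprintf("windows: %d | Pearson r = %.2f | Spearman rho = %.2f\n",
            cor_out$n, cor_out$pearson_r, cor_out$spearman_rho))
M <- pairwise_session_mean_kld(study$sessions, ref)
print(round(M[1, ], 2))
```

```
<mindful_reference> k = 9 from 925 bins [pc+xhat+xhat_lag]
windows: 2420 | Pearson r = 0.67 | Spearman rho = 0.70
    0    10    20    30    40    50    60    70    80    90
 0.13  0.14  0.26  0.84  3.07 18.69 15.54 12.03 13.75 13.54
```

The reference Gaussian is built from 925 day-0 bins of good control. The
sliding-window divergence rank-correlates with the windowed median angle
error at ρ = 0.70 across 2420 windows — performance is being tracked
without intention labels. The last line is the mean divergence between
day 0 and each session (day 0's own entry, 0.13, is the within-session
baseline): it grows by two orders of magnitude as the planted rotation
ramps up, saturating once control is essentially lost.

A thin command-line front end (`inst/cli/mindful.R`) wraps the same
functions: `simulate`, `score`, `ae-bins`, `pairwise`.

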