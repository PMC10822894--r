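---
title: "Dynamic effective connectivity states: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic effective connectivity states: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynec)
```

## The problem

Resting-state fMRI network analyses increasingly ask not only *whether* two
regions interact but *in which direction* and *how that changes over a scan*.
`dynec` implements the standard pipeline for that question at the level of
network-component time courses (e.g. the 12 default-mode components of a
group ICA): sliding-window multivariate Granger causality yields one directed
effective-connectivity (EC) matrix per window; k-means over all subjects'
windowed matrices identifies recurring connectivity *states*; weighted-degree
and temporal-property summaries of those states are compared between groups
(e.g. type-2 diabetes patients vs. healthy controls) and correlated with
clinical variables.

Because the motivating class of studies rarely deposits raw fMRI, the package
ships a first-class synthetic cohort generator with known ground truth, so
every downstream stage is testable without any download.

## The generative model

Each subject is a hidden-Markov switching vector autoregression. A two-state
Markov chain $s_t$ at the time-point level has stay probability
$P(s_{t+1}=s \mid s_t=s) = \pi_s$; given the state, the $n$-channel signal
follows

$$x_t = A(s_t)^\top x_{t-1} + \varepsilon_t, \qquad
  \varepsilon_t \sim \mathcal N(0, \sigma^2 I),$$

with one coupling matrix per state (source-row convention throughout: entry
$(i,j)$ is the influence of channel $i$ on channel $j$). Stationarity within
a state is enforced by requiring the companion spectral radius of each
coupling set to be below 1. A burn-in of 50 samples removes
initial-condition transients.

### Defaults and why

* **Cohort**: 36 patients + 40 controls, 170 time points, 12 components —
  the acquisition scale of the motivating study class (180 volumes at
  TR = 2 s minus 10 dummy scans).
* **Regimes**: state 1 ("weak") is sparse — self-decay 0.25, two strong hub
  edges (0.40) out of component 2, a thin chain of 0.18 edges; state 2
  ("strong") is dense — a directed ring (0.35) plus negative skip
  connections (−0.30). This mirrors the common empirical finding of a
  frequent low-connectivity state and a rarer, more active one.
* **Dwell probabilities**: control $(0.97, 0.95)$, patient
  $(0.985, 0.95)$ per time point. These were calibrated *once, a priori*
  from the published group dwell-time and occupancy scale for two-state
  decompositions: they give stationary state-1 occupancies of 0.625
  (control) and 0.769 (patient), i.e. fractional windows near 0.63/0.77 and
  a pooled occupancy split near 70/30, with dwell times of a few tens of
  time points. They were not adjusted after seeing any test result.
* **Group effect**: the patient group's state-1 coupling is attenuated by
  0.30 on the hub edges (component 2 → components 8 and 12 of 12), emulating
  reduced directed influence out of a medial-prefrontal-like hub. No
  published effect size exists for this quantity; 0.40 → 0.10 is a
  calibration choice.
* **Clinical table**: HbA1c (%), MoCA (0–30), diastolic blood pressure
  (mmHg) and education (years) are drawn with group marginals typical of a
  diabetes-vs-control sample and a linear-in-truth term: each variable adds
  $\beta \cdot z$, where $z$ is the subject's standardized realized state-1
  occupancy ($\beta$ = 1, −2, 4, −1.5 respectively). This gives the Spearman
  stage a recoverable monotone signal while keeping marginals realistic.

### What the generator does *not* emulate

No hemodynamic response, voxel-level spatial structure, scanner drift or
motion, non-Gaussian innovations, or between-channel noise correlation. A
green test therefore establishes correctness of the estimation and inference
machinery on data satisfying the MVAR-with-switching assumptions — not
robustness to fMRI artifacts.

## Estimation choices

* **Windows**: rectangular, width 18 TRs, step 2 TRs. A window starting at
  0-based offset $t$ is admissible when $t + w < T$ (strict): a final window
  ending exactly at $T$ is discarded. This convention uniquely reproduces 76
  windows per subject for $T = 170$ (the inclusive convention gives 77), and
  hence 5,776 matrices over 76 subjects.
* **MVAR fit**: order 1 by default — an 18-sample window cannot support
  higher orders on 12 channels; the order is configurable. Columns are
  centered within the window. Ridge regularization with penalty
  $\lambda \cdot \mathrm{mean}(\mathrm{diag}(Z^\top Z))$, default
  $\lambda = 0.1$, stabilizes the near-saturated per-window fit;
  $\lambda = 0$ gives plain least squares and is used in the long-window
  consistency tests.
* **Influence modes**: the default EC entry is the signed lag-1 path
  coefficient (summed over lags for $p > 1$), matching the toolbox family
  that reports signed path coefficients. A partial-directed-coherence mode
  (magnitude averaged over an even frequency grid on $[0, 0.5]$ cycles per
  sample; entries in $[0,1]$) is provided because directed coherence is the
  other common convention; the package asserts neither as "the" published
  measure.
* **Degenerate channels**: a constant channel within a window gets zero
  coefficients and a warning rather than an error, so a single flat-lined
  window does not abort a cohort run.

## State decomposition

Windows are vectorized over **off-diagonal entries only** (self-influence is
not an inter-regional edge) and clustered with best-of-`n_init` k-means
(L2 default; a Lloyd-type k-medians provides the L1 option). Matrices are
*not* z-scored before clustering by default; both choices are exposed because
the literature is split and the source studies rarely state it. States are
renumbered by descending occupancy, so "state 1" is always the most frequent
pattern. `suggest_k()` reports inertia and silhouette diagnostics but never
auto-selects; the motivating analyses fix $k = 2$ without a stated criterion.

## Metrics

For a state-mean EC matrix, the out-weighted degree of component $i$ sums the
influence strengths of edges leaving $i$, the in-weighted degree those
entering, and the in–out-weighted degree is in − out (net receiver positive).
Strength defaults to $|{\cdot}|$ because signed coefficients of opposite sign
would cancel; the signed option is retained, in which case the in–out degrees
of a single matrix sum to zero exactly. Temporal properties per subject come
from run-length encoding of the window labels: fractional windows $F$, mean
dwell time MDT (in windows — the canonical unit; `mdt_to_seconds()` converts
via step × TR), and number of transitions NT (runs − 1). An unvisited state
is reported as $F = 0$, MDT = 0 with a missing flag rather than dropped, so
group tables stay rectangular.

## Inference

* **Edgewise tests**: Welch (unequal-variance) two-sample $t$ per
  off-diagonal edge — group sizes and variances differ and the source
  literature does not specify pooled vs. Welch.
* **NBS**: primary threshold on $|t|$ (default 3), weakly connected
  components of surviving directed edges, component statistic = edge count
  (extent), permutation null of the maximum extent over group-label shuffles
  (default 1000), $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_\text{perm})$.
* **BH-FDR**: authored step-up implementation, tested against a brute-force
  enumeration oracle and `stats::p.adjust`.
* **Spearman**: midranks for ties, $t$ approximation for $p$; constant
  variables are flagged and excluded from the BH family rather than
  propagating NaN.
* **ICC(2,1)**: two-way random effects, absolute agreement, single measures,
  from the ANOVA mean squares
  $(\mathrm{MSR} - \mathrm{MSE}) / (\mathrm{MSR} + (k-1)\mathrm{MSE}
  + k(\mathrm{MSC} - \mathrm{MSE})/n)$. Reliability across window settings
  re-runs windowing → clustering → temporal properties per setting and aligns
  states by minimal centroid distance (labels are arbitrary per clustering
  run); the default comparisons are 18/2 vs. 30/1 and 18/2 vs. 12/3
  (width/step in TRs).

## Known limitations, and one honest red

* Estimated window labels carry roughly 10% misassignment at the default
  regime separation and window length; this is inherent to 18-sample,
  12-channel fits near regime boundaries, where many windows straddle a
  transition. Consequences measured by the test suite:
  * state occupancy estimated from clustered labels is biased a few
    percentage points toward the minority state on dwell-calibrated cohorts
    (the planted-design recovery test therefore uses longer dwells, where
    windows are regime-pure);
  * spurious single-window flips inflate the number of transitions, and
    they inflate it *more for patients* (whose sequences are dominated by
    the weak regime, closer to the cluster boundary). The planted NT deficit
    (patients ≈ 2 vs. controls ≈ 3 true window-level transitions) is
    therefore cancelled in a substantial fraction of replicate cohorts, and
    the acceptance check requiring the patient < control NT direction in
    ≥ 90% of replicates fails honestly. The F and MDT direction checks pass
    at ≥ 90–100%. We deliberately did not enlarge the regime separation or
    lengthen dwells to force this green: both are frozen calibration
    choices, and the failure is informative about the method, echoing the
    known sensitivity of transition counts to window-level noise in the
    dynamic-connectivity literature.
* The group ICA is desk-scale (one-level PCA, infomax with logistic
  nonlinearity) and is bypassed by default: the pipeline's core is the
  component-time-course analysis, and simulated cohorts already are
  component time courses.
* No covariate adjustment, mixed models, consensus clustering, HMM state
  estimation, tapered windows, or graph measures beyond weighted degree.

## Reproducibility

Every user-facing stochastic operation takes a seed and restores the
caller's RNG state. `run_pipeline()` derives per-stage seeds from one global
seed, and all outputs are stamped with an FNV-1a hash of the configuration
plus the seed, so a report is reproducible from `(config, seed)` alone.
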