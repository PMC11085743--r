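---
title: "Spectrum-effect screening of multi-batch herbal fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectrum-effect screening of multi-batch herbal fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specfx)
```

## The screening problem

A herbal extract is a mixture of dozens of constituents, and its
pharmacological effect is usually carried by a small subset of them.
Spectrum-effect analysis exploits batch-to-batch variation: different
production batches of the same extract contain slightly different amounts of
each constituent, so a constituent that drives an effect should co-vary,
across batches, with the bioactivity of those batches. `specfx` implements
this screening logic as a pipeline:

1. **Fingerprint construction** — per-batch HPLC peak tables are matched
   across batches by retention time into a *common-peak matrix* (batches
   × peaks), keeping only peaks present in every batch.
2. **Gray relational analysis (GRA)** — a similarity grade between each
   bioactivity indicator series and each peak's area series.
3. **PLS regression with VIP** — per-indicator partial least squares models
   whose variable-importance-in-projection scores rank the peaks.
4. **Binding intersection** — candidates must also appear in a target-cell
   extraction binding list (physical association with the target cells).
5. **Content filter** — trace constituents below a relative-content floor
   are excluded as impractical quality-control markers.
6. **BP neural-network classification** — a small feed-forward network
   trained on labelled peaks consolidates the GRA/VIP/binding/content
   evidence into a final active/inactive call.

The bioactivity panel has four indicators measured on an in-vitro
cardiomyocyte injury model: cell viability (MTT) and ATP production, where
larger is better, and LDH release and ROS level, where larger means more
injury. Orientation is carried as metadata
(`indicator_orientations()`) rather than by pre-negating the series, so the
direction handling is explicit and auditable.

## Gray relational analysis

For a reference series $x_0(k)$ (one indicator over batches $k = 1..K$) and
comparison series $x_i(k)$ (peak areas), each series is first normalized
(default: division by its mean). With deviations
$\Delta_i(k) = |x_0(k) - x_i(k)|$ and global extrema $\Delta_{\min}$,
$\Delta_{\max}$ over all $i,k$, the relational coefficient and grade are

$$\xi_i(k) = \frac{\Delta_{\min} + \rho\,\Delta_{\max}}
                  {\Delta_i(k) + \rho\,\Delta_{\max}},
\qquad r_i = \frac{1}{K}\sum_k \xi_i(k),$$

with the distinguishing coefficient $\rho = 0.5$ by convention. Grades lie
in $(0, 1]$ and equal 1 exactly when the normalized series coincide. Peaks
with $r_i > 0.9$ (strict) are GRA hits.

Two choices here were genuinely open:

* **Normalization.** Mean normalization is the default (the common choice
  in spectrum-effect work); min-max and none are available, and the choice
  is recorded in the result object.
* **Direction of the injury markers.** For LDH and ROS a *protective* batch
  has a *low* value, so using the raw series would reward peaks that
  track injury. With the default `orientation_handling = "protection_score"`
  these series are reflected to `max(series) - series` before analysis —
  the most-injured batch acts as a proxy for an untreated model group, and
  a high grade then reads "tracks protection" for every indicator. The
  `"raw"` mode is kept for sensitivity analysis.

## PLS and VIP

Each indicator is regressed on the autoscaled common-peak matrix with a
single-response PLS (NIPALS, deterministic initialization from $X'y$,
sequential deflation), giving four models in parallel with the four
per-indicator models of spectrum-effect practice. With unit-norm weight
vectors $w_a$ and per-component explained response variance $SS_a$, the
importance of peak $j$ is

$$\mathrm{VIP}_j = \sqrt{\frac{P \sum_a SS_a\, w_{ja}^2}{\sum_a SS_a}},$$

so that $\sum_j \mathrm{VIP}_j^2 = P$ and VIP > 1 (strict) flags
above-average contributors. Two components are fitted by default —
with around a dozen batches, more components mostly chase noise; a
leave-one-out $Q^2$ helper (`pls_q2_loo()`) is provided as a diagnostic
rather than an automatic selector. The sign of an association does not
enter VIP, so no orientation handling is needed at this stage.

## Combining evidence

GRA and PLS see different structure (pointwise profile similarity versus
latent-direction covariance) and each alone can miss true actives, so their
hit sets are combined by **union** by default: a peak is a spectrum-effect
hit if at least `min_indicator_hits` (default 1) of the four indicator
models flag it under either method. An `"intersection"` mode is available
for stricter screens. The hit set is then intersected with the binding set
— binding indicates association, not activity, and spectrum support
without binding is equally insufficient — filtered by mean relative content
(default floor 0.005, i.e. 0.5% of total area; the field excludes
low-content constituents but publishes no number, so the floor is
configurable and reported prominently), and finally passed through the
network classifier.

## The BP neural network

The classifier is a from-scratch single-hidden-layer network (default 8
logistic units, one sigmoid output, cross-entropy loss) trained by
full-batch gradient descent; weights initialize from seeded
Uniform(−0.5, 0.5), so training is fully reproducible. Its 10-dimensional
input per peak — four GRA grades, four VIPs, the binding flag and the
relative content — is min-max scaled to [0, 1]. A learning rate of 0.5 for
10000 epochs is the default: on min-max-scaled features of this size,
full-batch descent with smaller steps routinely stalls short of
convergence, and these values reach a stable low-loss fit in under a
second. An output of exactly 0.5 classifies as inactive, the conservative
choice for a screen. Analytic gradients are verified against central
finite differences in the test suite.

Training labels are supplied by the user: ground truth in a synthetic
study, literature-verified assignments in a real one. In the synthetic
workflow this makes the network act as a learned consolidation of the
upstream features rather than an independent source of evidence — a
deliberate mirror of how such classifiers are used in practice, and the
reason the end-to-end benchmarks below report recovery of *planted* truth.

## What the synthetic generator emulates

`sim_config()` defines a study of 12 batches × 36 common peaks with 7
planted actives inside a 17-peak binding set — the scale of a typical
multi-batch fingerprint study. Defaults, chosen once as field-realistic:

* **Areas** are lognormal, `meanlog = log(10)`, `sdlog = 0.4` (positive,
  right-skewed, roughly 40% batch-to-batch CV — substantial but plausible
  compositional variation between production batches).
* **Effects** are mechanism-specific: the actives are assigned round-robin
  to the four indicators (each indicator is driven by 1–2 constituents,
  each active drives exactly one indicator) with magnitude 2 and
  orientation-correct signs. This mirrors the premise behind measuring
  four indicators at all — different constituents act through different
  mechanisms, and no single indicator model finds everything, which is
  precisely why the union rule exists.
* **Intercepts** of 20 (viability, ATP) and 150 (LDH, ROS) keep all
  readouts positive at the default area scale.
* **Assay noise** is Gaussian with SD 3, about 3% of a 100-scale readout —
  the residual uncertainty of a plate assay after averaging replicate
  wells.
* **Retention times**: 36 peaks spread evenly over 8–127 min of a 145-min
  gradient, with per-batch jitter SD 0.05 min, typical HPLC
  retention-time reproducibility; the default matching tolerance of
  0.5 min is an order of magnitude above the jitter and an order of
  magnitude below the peak spacing.

What the generator does **not** emulate: co-elution and overlapping
clusters at the tolerance scale, correlated (co-regulated) constituents,
heteroscedastic assay noise, batch-level confounders, and UV-spectral
information (the matcher is retention-time-only, a documented
simplification — real common-peak assignment also checks spectra).
Passing tests on this generator therefore demonstrate the correctness of
the statistical machinery and the decision logic, not robustness to every
failure mode of real chromatography.

## Numerical and degenerate-case choices

* Peak matching is greedy and deterministic: clusters seed from the batch
  with the most peaks, other batches assign in elution order to the
  nearest in-tolerance cluster without a member from that batch; distance
  ties go to the earlier-eluting cluster; consensus RTs are member means,
  and clusters violating the tolerance after refinement are dropped with a
  warning.
* All screening thresholds are strict (`>`), so a grade of exactly 0.9 or
  a VIP of exactly 1.0 does not pass.
* Degenerate inputs error early and name the offender: constant series
  under min-max, zero-mean series under mean normalization, constant
  predictor columns under autoscaling, unknown peak ids in a binding file,
  single-class label sets.
* If every comparison equals the reference ($\Delta_{\max} = 0$), all
  grades are defined as 1 with a warning.
* A constant feature column min-max scales to 0 with a warning.

## Problem sizes and what the benchmarks show

The test suite runs the full pipeline at the default 12 × 36 scale. With
assay noise and retention-time jitter both zero, the seven planted actives
are recovered exactly (precision = recall = 1); across 20 replicates at the
default noise level, mean recall stays above 6/7 with mean precision above
0.7. Twelve batches is a genuinely small sample for three dozen predictors:
the sample correlation of an inactive peak with an indicator has a noise
floor of roughly $1/\sqrt{11} \approx 0.3$, so occasional replicates lose a
single active at the spectrum stage even without assay noise — an intrinsic
property of the study design, not of the estimator. For the two asymptotic
properties that require the signal to clear that floor for *every* active
simultaneously (each active's VIP exceeding the median inactive VIP in all
four models; leave-one-out generalization of the network), the tests use
larger simulated studies (96 and 48 batches) under a uniform effect
pattern, where those properties are expected to hold and do.

## Known limitations

* RT-only matching; no UV/MS identity check, no co-elution handling.
* The GRA `> 0.9` rule's meaning depends on the normalization and on
  the amplitude structure of the data; grades, not just hits, are
  therefore always reported.
* PLS component count is fixed by configuration, not selected.
* The BPNN's final-filter role means it can only remove candidates, never
  rescue a peak the spectrum stage missed.
* With `protection_score`, the model-group proxy (per-indicator batch
  maximum) is itself a noisy statistic.
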