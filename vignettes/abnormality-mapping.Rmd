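---
title: "Spared-network abnormality mapping: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spared-network abnormality mapping: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

About a third of patients with drug-resistant temporal lobe epilepsy (TLE)
continue to have seizures after anterior temporal lobe resection (ATLR), and
clinicians cannot reliably predict who. One candidate explanation is that the
epileptogenic network extends beyond the resected tissue: what matters for
outcome is not only how abnormal the brain network is before surgery, but how
much of that abnormality the planned resection will leave behind.

`sparenet` implements this idea as a tested pipeline over diffusion-MRI
structural connectomes:

1. **Edge z-scoring.** For each connection present in a patient (streamline
   count > 0) whose equivalent connection exists in at least `min_controls`
   healthy controls, the patient's mean generalized fractional anisotropy
   (gFA) weight is expressed as
   $z_{ij} = (w_{ij} - \mu_{ij}) / \sigma_{ij}$, with $\mu_{ij}, \sigma_{ij}$
   the sample mean and SD over the controls that possess the edge.
2. **Virtual resection.** Edges whose streamlines intersect the resection
   are removed from the z-network to give the *surgically spared* network.
   Presurgical node degrees $k_i$ are retained.
3. **Node abnormality.** At a z threshold $\tau_z$, node $i$'s abnormality is
   $p_i = 100 \cdot a_i / k_i$, where $a_i$ counts valid links with
   $|z| \ge \tau_z$. At a percentage threshold $\tau_p$, the *abnormality
   load* is the number of nodes with $p_i \ge \tau_p$, evaluated over the
   full grid $\tau_z \in \{2.1, 2.2, \dots, 4.5\}$,
   $\tau_p \in \{1\%, \dots, 50\%\}$.
4. **Regional summaries.** Nodes are relabeled ipsi/contralateral to surgery
   and grouped into six areas per side; the drop in the proportion of
   abnormal nodes from presurgery to spared network is tested per area
   (paired t across patients, BH-corrected).
5. **Outcome prediction.** A linear-kernel SVM over 15 features (13 clinical
   covariates plus presurgery and spared abnormality load) is evaluated by
   nested leave-one-out cross-validation with recursive feature elimination
   (RFE); calibrated decision values are interpreted as the likelihood of
   seizure relapse and related to the ILAE outcome scale and to actual
   relapse in follow-up years 2–5.

Because the package cannot ship clinical MRI data, a synthetic-cohort
generator with planted, recoverable abnormalities is a first-class module:
every downstream stage is tested against known ground truth.

## Standardization choices

* **Only edge-possessing controls enter the reference.** Deterministic
  tractography produces sparse networks; an absent streamline is treated as
  missing evidence, not as a zero weight. Consequently an edge needs at
  least `min_controls = 10` (of 29) controls to be scorable, and an edge
  with zero control variance is marked invalid rather than producing an
  infinite z.
* **Patient-absent edges are never scored.** Absence is not abnormality;
  only connections present in the patient are standardized.
* **Degrees are frozen at the presurgery network.** $k_i$ counts valid
  (z-scorable) presurgery edges and is carried unchanged into the spared
  network, so $p_i$ is always a fraction of the same assessable links and
  spared abnormality can only be lower than presurgical abnormality. Nodes
  fully disconnected by resection stay in the node set with $p_i = 0$.
* **Abnormal links are two-sided by default** ($|z| \ge \tau_z$): epilepsy
  typically reduces anisotropy, but deviation in either direction departs
  from normality. `direction = "negative-only"` / `"positive-only"` restrict
  the tail. All threshold comparisons are inclusive ($\ge$), and the grid is
  generated by integer indexing (21:45 / 10) so no floating-point
  accumulation can shift a cell.

## The synthetic cohort generator

The generator emulates the study design the pipeline targets: 29 controls,
51 patients, a 114-node bilateral parcellation with six areas per
hemisphere, and per-patient ILAE outcome (year 1) plus yearly relapse labels
(years 2–5, with follow-up truncation).

* **Shared scaffold.** All subjects share one scaffold of candidate edges
  (fraction `scaffold_density` of node pairs) with per-edge population gFA
  mean and SD drawn from `gfa_mean_range` = (0.35, 0.65) and
  `gfa_sd_range` = (0.02, 0.05); each subject drops each scaffold edge
  independently with probability `edge_dropout`, and carries
  log-normal streamline counts that define topology but not abnormality.
* **Planted abnormalities.** Each patient receives
  `planted_nodes_per_patient = 8` planted nodes, sampled with weight
  `plant_temporal_weight = 12` on the ipsilateral temporal lobe; every
  present edge incident to a planted node has its gFA mean shifted by
  `planted_sign * planted_effect` = −4 population SDs. The resection removes
  all edges incident to ipsilateral temporal nodes plus a 5% "passthrough"
  sample of remaining edges. The *true spared load* is the number of planted
  nodes that keep at least 10% of their present edges abnormal after
  resection.
* **Outcomes.** An ordinal-latent model generates ILAE classes: latent
  score = intercept + 1.5·(true spared load) + 0.25·(standardized age at
  surgery) + 0.25·(standardized AED count) + standard-logistic noise, cut at
  fixed points into classes 1–5. The latent-noise formulation is needed so
  that with zero slopes the class frequencies have a closed-form
  intercept-only expectation (a tested property); with the default
  coefficients the class frequencies approximate the 34/8/9 split of a
  typical surgical series. Relapse, defined only for patients at ILAE 1–2
  at year 1, follows a yearly logistic hazard
  `plogis(-3.2 + 0.5 · load)` over years 2–5 with follow-up censoring,
  yielding roughly half of initially seizure-free patients relapsing by
  year 5.

### Generator realism and what the tests do (not) show

The default scaffold is much denser (realized edge presence ≈ 0.92) than
real deterministic-tractography networks (typical density 0.2–0.4). This is
a deliberate identifiability choice, not an oversight. A planted node is
recoverable because essentially *all* of its links are abnormal; but each of
its neighbours also inherits one genuinely abnormal link. A neighbour is
falsely flagged at $(\tau_z, \tau_p) = (2.8, 10\%)$ when its abnormal-link
count reaches $k_i / 10$. With only 8 planted nodes, a dense scaffold makes
$k_i / 10 > 8$, so spillover alone can never flag a neighbour and the
non-planted flag rate stays below 5%; at realistic sparse densities the
spillover fraction sits near the threshold with high variance and node-level
specificity of this kind is unattainable. Two consequences follow. First,
passing the recovery tests demonstrates correctness of the pipeline's
bookkeeping, not that node abnormality mapping has 95% specificity on real
sparse connectomes — on real data, nodes adjacent to truly abnormal regions
*should* show elevated abnormality. Second, with so dense a scaffold the
10-of-29 control-presence filter almost never binds on synthetic cohorts
(presence counts concentrate near 28); the filter's semantics are therefore
exercised by hand-built reference fixtures in the unit tests rather than by
the generator.

The generator also does not attempt: community/hub structure, distance-
dependent connectivity, realistic demographic distributions, scanner or site
effects, or any image-domain processing.

## Statistical toolkit

All tests the pipeline reports are implemented in the package and verified
against independent routes:

* **Exact rank-sum.** For combined $n \le 25$ the full null distribution of
  the rank sum (mid-ranks for ties) is computed by dynamic programming over
  subset sums — equivalent to enumerating all $\binom{n}{n_x}$ assignments,
  and tested against literal enumeration for all splits with $n \le 8$.
  Beyond the cap a tie-corrected normal approximation with continuity
  correction is used and flagged in the method descriptor. One-tailed
  directions are always supplied explicitly at call sites.
* **BCa bootstrap.** Bias correction uses the fraction of resample
  statistics below the observed value with ties counted as half (clamped to
  $(1/(B{+}1), B/(B{+}1))$ so lattice-valued statistics such as the median
  cannot degenerate); acceleration comes from leave-one-out jackknife
  skewness; adjusted percentiles use type-6 quantiles. A fully degenerate
  resample distribution collapses to `[obs, obs]` with a warning.
* **BH-FDR** step-up with monotone adjusted p-values (verified against
  `p.adjust`), **Spearman** correlation of mid-ranks with a t-approximation
  p-value, and a **paired t** with t-based CI.
* **Robust slope permutation test.** The slope comes from iteratively
  reweighted least squares with Tukey bisquare weights (tuning constant
  4.685 × MAD scale, OLS start); the permutation p uses the
  $(1 + \#\{|s^\pi| \ge |s|\})/(B+1)$ convention so p = 0 is impossible.
  The bisquare variant is a design choice (the estimator family is
  conventional but not uniquely determined by the application); because the
  permutation p is primary, the variant mainly affects power. Note that a
  redescending M-estimator can latch onto near-collinear subsets in small
  lattice-valued permuted data — the null-uniformity test uses continuous
  covariates for this reason.

## Prediction design

Open choices were resolved as follows, each switchable in
`predict_config()`:

* **Inner validation**: stratified 5-fold CV inside each outer training fold
  selects the SVM cost from a 13-point log grid $10^{-3} \dots 10^3$
  (ties to the smaller, i.e. more regularized, cost).
* **Class imbalance** (~34 seizure-free vs ~9 not): inverse class-frequency
  weights, on by default.
* **Probabilities**: Platt sigmoid fitted by Newton iterations on the
  training-fold decision values with Platt's smoothed targets, so separable
  folds keep finite calibration parameters. The held-out patient's
  probability of a not-seizure-free outcome is the "likelihood of seizure
  relapse".
* **Threshold selection**: the most discriminatory $(\tau_z, \tau_p)$ pair
  (rank-based AUC of load vs label over training patients only) is chosen
  per network kind inside every outer fold, with the deterministic tie-break
  (lowest $\tau_z$, then lowest $\tau_p$).
* **RFE**: feature importance is $|w|$ of the linear SVM, averaged across
  outer folds, normalized to [0, 1] after averaging; the smallest-importance
  feature (ties by column order) is dropped until one remains, giving
  exactly 15 steps for 15 features.
* **ILAE 2 patients** never enter training or the outer loop; they are
  scored by averaging the calibrated probabilities of all outer-fold models
  per step.
* **Reported sensitivity/specificity** use the 0.5 probability cut; the AUC
  is threshold-free.

One property worth knowing: because the elimination path aggregates
importances across all outer folds, the path itself (though not any single
fold's model) has seen every label. Under label-shuffling the mean LOO AUC
therefore sits slightly above 0.5 (~0.55 at n = 51, larger at smaller n).
This mirrors the source methodology's own cross-fold RFE and is verified to
stay within [0.35, 0.65] by the no-leakage null test.

## Problem sizes used by the test suite

The suite regenerates everything from code at run time. The end-to-end
checks use the default study-scale cohort (29 controls, 51 patients,
114 nodes); oracle-equivalence checks use 100 random 20-node networks and
6-node hand-computable toys; BCa coverage uses 500 simulations of n = 30 at
2,000 resamples; the permutation-uniformity check uses 200 datasets at 200
permutations; the label-shuffle null uses 20 repeats with a 3-point cost
grid and 3-fold inner CV. These sizes are the package's choices to keep the
default run brief while leaving every statistical conclusion within its
stated Monte-Carlo tolerance.

## Known limitations

* The artifact consumes already-built connectivity matrices and
  surgery-affected edge lists; tractography, parcellation and resection-mask
  drawing are out of scope.
* The regional comparison interprets the per-area test as a paired t across
  patients on per-patient area proportions; other constructions (e.g. tests
  on pooled counts) exist and would give different statistics. In synthetic
  cohorts where *all* patients' planted nodes concentrate ipsilaterally,
  even poor-outcome patients can show a significant ipsilateral-temporal
  drop — the clinical asymmetry between outcome groups emerges only when
  poor-outcome patients' abnormalities lie outside the resection.
* No covariate adjustment (age/sex) of the control reference, no
  multi-site harmonization, and no survival-time modelling of relapse
  trajectories.
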