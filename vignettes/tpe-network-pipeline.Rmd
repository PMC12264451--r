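---
title: "Brain-network differentiation of temporal-plus and temporal lobe epilepsy: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-network differentiation of TPE and TLE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tpenet` turns a clinical differentiation problem — does a drug-resistant
temporal-lobe epilepsy patient's epileptogenic zone extend into the insula
(temporal-plus epilepsy, TPE)? — into a pipeline of network features
computed from two noninvasive modalities: interictal FDG-PET and scalp
EEG. This vignette is the package's account of the models it implements,
the parameters that matter, and the choices made where the design was
genuinely open.

## The individual metabolic network

Regional uptake is summarized over 56 gray-matter regions of one
hemisphere (Neuromorphometrics-style labels, ventricular and white-matter
structures excluded; the anterior and posterior insula are separate
regions because nodal statistics are reported there). A normal-control
(NC) cohort provides per-region means $\mu_i$, SDs $\sigma_i$ and the full
interregional Pearson correlation matrix $R$ — the group connectivity
prior. A single subject cannot supply a covariance matrix, so the
individual network reweights the prior by the subject's deviation pattern.
With regional effect sizes $e_i = (x_i - \mu_i)/\sigma_i$,

$$W_{ij} = w(|e_i - e_j|)\,R_{ij}, \qquad w(d) = e^{-d}.$$

The kernel was an open design point: the construction is described in the
literature only verbally (a weighting of interregional effect-size
differences applied to the NC correlation matrix). The exponential-decay
kernel was chosen because it is bounded, smooth, and has the right limits:
a subject at the NC mean (or uniformly shifted — only *differences* enter)
reproduces $R$ exactly, and any discordant pair is strictly attenuated,
$|W_{ij}| \le |R_{ij}|$ with equality iff $e_i = e_j$. `weight_fn` is a
plug-in argument of `build_individual_network()`, so an alternative kernel
drops in without touching callers. Diagonals are zeroed and ignored.

A consequence worth knowing: *uniform* regional hypometabolism — however
deep — leaves the network untouched. Only focal, discordant deviation
disrupts topology. That is precisely the observation that motivates
network analysis here: TLE and TPE hypometabolism *levels* in the insula
overlap, while connectivity differs.

## Graph features and the sparsity grid

The weighted network is binarized by keeping the `round(s · 1540)`
strongest edges by $|W_{ij}|$ (1540 = 56·55/2 pairs) at each sparsity $s$
in $\{0.20, 0.25, \ldots, 0.65\}$ — ten grid points. Ties are broken by
lexicographic $(i, j)$ order for determinism; thresholding on magnitude is
the convention because the construction yields signed weights. Per grid
point the package computes:

* **Small-world indices.** $\gamma$ = mean clustering / mean clustering of
  degree-matched random graphs, $\lambda$ = characteristic path length
  ratio, $\sigma = \gamma/\lambda$. The random ensemble is `n_rand`
  degree-preserving Maslov–Sneppen rewirings (default 100, with
  $10\,|E|$ attempted swaps each — standard practice). Disconnected pairs
  are excluded from path lengths (relevant only at the sparse end).
* **Efficiencies.** Global efficiency = mean of $1/d(i,j)$ over ordered
  pairs with $1/\infty = 0$; local efficiency = mean over nodes of the
  global efficiency of the neighbour-induced subgraph.
* **Insular nodal metrics.** Degree centrality and nodal clustering
  coefficient at the anterior and posterior insula, resolved by exact
  label match (the run aborts if either resolves ambiguously).

Each metric-versus-sparsity curve is reduced to one scalar by normalized
trapezoid area (area divided by grid span), so a constant curve aggregates
to itself. This "AUC across sparsities" is the standard single-number
summary when one value per patient is needed; the per-sparsity matrix is
kept as an attribute for inspection. Whether group comparisons should run
per sparsity instead was left open by the source material; the aggregate
is the package default.

## RQA of scalp EEG

Preprocessing follows the usual contract: downsample to 500 Hz (kept, with
a warning, if the input rate is already lower), zero-phase Butterworth
band-pass 1–80 Hz, zero-phase 50 Hz notch, re-reference to the channel
average. Rates at or below 160 Hz are rejected (the band is
unrepresentable). ICA artifact removal is out of scope for synthetic
signals; externally cleaned recordings pass straight in.

Per analysis window the embedding is selected from the data:

* **Delay τ** — first minimum of average mutual information (AMI), maximum
  lag 200. The AMI estimator uses equal-width histograms with
  $\lceil\sqrt{N}\rceil$ bins per marginal — simple and stable at the
  window sizes used. Two practical refinements were needed: the curve is
  lightly smoothed (5-point running mean) because the histogram estimator
  jitters on near-periodic signals, and a *flat* minimum is resolved to
  the centre of its plateau (values within 3% of the curve range of the
  minimum), because for periodic signals the histogram AMI is flat across
  a basin centred on the true quarter-period minimum. A plateau covering
  most of the lag axis means there is no informative delay structure
  (white noise); the fallback then takes the first lag below
  $\mathrm{AMI}(0)/e$.
* **Dimension m** — Kennel false-nearest-neighbour test with the standard
  constants rtol = 10, atol = 2, threshold 1%, $m_{\max} = 10$, and a
  Theiler exclusion of τ in the neighbour search. If the threshold is
  never reached (common for noisy mixtures) the argmin is used with a
  warning. Embedding selection is capped at the first 1200 samples of a
  window for cost; the recurrence plot itself always uses the full window.

The recurrence plot sets $R_{ij} = 1$ iff the embedded points are within
$\varepsilon$ (Euclidean) and $|i - j| >$ Theiler window (= τ; trivial
temporal recurrences never enter any statistic). $\varepsilon$ is found by
bisection on the achieved recurrence rate until it lands in
$\mathrm{RR}_{\mathrm{target}} \pm 0.005$; the target is 5% by default.
Fixing RR rather than ε makes the other features comparable across
subjects whose signal amplitudes differ; a fixed-ε mode exists
(`eps` argument) because the alternative reading — ε fixed, RR varying and
informative — is also defensible. Under fixed RR the per-window ε spread
is retained as an attribute.

The 13 features follow the conventions: diagonal features (DET, L, Lmax,
ENTR) from maximal runs on upper-triangle diagonals beyond the Theiler
band with $l_{\min} = 2$; vertical features (LAM, TT, Vmax) from runs
within each column's two admissible segments with $v_{\min} = 2$;
recurrence times (RTmax, T2, RTE) from white-vertical gaps bounded by
recurrences and from entry-point spacings after collapsing sojourns;
network features (Clust, Trans) treat the Theiler-masked matrix as an
adjacency matrix. Empty histograms give 0. One finite-size subtlety: a
saturated plot has DET slightly below 1 (405/406 at $N' = 30$) because
single-cell corner diagonals fall under $l_{\min}$ — the brute-force
oracle in the test suite reproduces this exactly.

The protocol trims 4 s head and 10 s tail, draws `n_iter` random 10-s
windows per channel (1000 in the full-scale protocol), runs the complete
per-window pipeline, and averages features over windows and then channels.
Embedding is re-selected per window by default; `embed_per = "channel"`
estimates it once per channel — appropriate for stationary synthetic
signals and used in the desk-scale runs. Whether the original procedure
selected embeddings per window, channel or patient is not documented;
both policies are implemented.

## Matching and statistics

Propensity scores come from a logistic model of group membership on
gender, SOZ side, age of onset and epilepsy duration; (quasi-)separation
is rejected with a diagnostic. Matching is greedy 1:1 nearest-neighbour
without replacement with a caliper of 0.1 interpreted on the raw
probability scale — the plain reading of "caliper of 0.1"; a logit-SD
caliper can be had by transforming the scores. Cases are processed in
seeded random order: no processing order is canonical, and randomizing it
avoids the systematic bias of score-sorted greedy matching while staying
reproducible. Balance is reported as standardized mean differences
(pooled-SD denominator) before and after matching.

Feature comparisons apply a Lilliefors gate per feature per group at
α = 0.05 — Wilcoxon signed-rank if either group fails, paired t
otherwise. The Lilliefors p-value is Monte-Carlo (the statistic is
location-scale free, so one simulated null per sample size serves every
test). The signed-rank test drops zeros, mid-ranks ties, and is exact via
the signed-rank null for tie-free data up to n = 50, exact by sign-flip
enumeration for small tied samples, and a tie-corrected normal
approximation with continuity correction otherwise. No correction is made
across the 22 features in the primary comparison — the per-feature raw-p
reporting convention of the underlying study; `fdr_bh()` provides
Benjamini–Hochberg for region-level screens.

## Classifier bench

Stratified 10-fold CV (plain 10-fold can lose a class at n = 50),
out-of-fold scores pooled, hard labels at 0.5, confusion-matrix metrics by
the standard formulas, ROC/AUC on the pooled scores (pooling is also what
aligns subjects for the across-model DeLong comparison). Model
hyperparameters are library defaults except XGBoost, which needs explicit
values: 100 rounds, depth 3, learning rate 0.1, single-threaded for
reproducibility; no tuning anywhere. DeLong's test uses placement values
with the paired variance estimate. SHAP values are exact TreeSHAP for the
boosted tree (per-subject attributions sum to the margin output; pairwise
interactions likewise exact); other models get a sampling approximation,
flagged as such.

## The synthetic cohort: what it emulates and what it does not

The generator exists so that every stage is testable without data:

* **NC uptake** — multivariate normal over 56 regions with a fixed,
  deterministic mean/SD profile (cerebellum-normalized SUVr ≈ 1.2–1.5,
  σ ≈ 0.10–0.12) and a block correlation structure: baseline r = 0.1
  between lobes, r = 0.5 within six lobe-like blocks. The
  baseline-plus-disjoint-blocks construction is positive semi-definite by
  construction, so invalid specs are rejected before any sampling, naming
  the offending block.
* **Patients** — NC-like draws with an `effect_spec()` per group:
  affected regions, uptake shift in NC-SD units (scalar or
  per-region), and a decorrelation strength d that attenuates the
  *generating* correlations of affected pairs by $1-d$ (mixed pairs
  $\sqrt{1-d}$; again PSD by construction). Default study conditions:
  52 NC subjects, 25 patients per group; both groups share temporal
  hypometabolism of −1.5 SD; TPE carries insular decorrelation 0.6
  against TLE's 0.25, and EEG determinism 0.55 against 0.45. These mirror
  the phenomenology the pipeline is meant to detect — matched regional
  hypometabolism, differing insular connectivity — at magnitudes chosen
  once to be plausible for FDG-PET covariance, and a 60/25 pool with
  age-of-onset/duration shifts (+4/+3 years) gives the matching step
  genuine imbalance to correct.
* **The strong-effect setting** (`strong_group_specs()`), used by the
  sensitivity study, deepens the TPE insular shift to −4 SD with complete
  insular decorrelation. The depth matters mechanically: moderate
  decorrelation lowers insular *degree* but barely moves insular
  *clustering*, because at fixed sparsity pruning a node's weakest edges
  leaves its most clustered neighbours in place. Only when the insula's
  deviations decouple deeply from their neighbours' does the similarity
  kernel strip enough edges to depress both Dc and Ncf — at 25 pairs the
  paired Wilcoxon then detects every insular feature with power ≥ 0.9,
  while the same features reject at ≈ 5% under the all-effects-zero null.
  The clustering features' power is additionally sensitive to the
  52-subject NC correlation *estimate* (some NC realizations leave the
  insula's surviving neighbourhood more clustered than others); the −4 SD
  depth is the level at which detection is robust across NC references,
  not just on a favourable draw.
* **EEG** — channels mix a shared continuous-time chaotic source (a Lorenz
  system integrated and resampled so its orbital rhythm lands in the EEG
  band; a continuous flow, not a map, so delay selection is nondegenerate)
  with channel-specific 1–30 Hz filtered noise, at a determinism level
  d ∈ [0, 1]; channels see the three source coordinates through a random
  unit-norm mixing matrix, scaled to ±30 µV. DET and LAM increase with d
  at matched embedding, which is the property the tests pin down.

What the generator does **not** emulate: voxel-level PET images, real EEG
artifacts (blinks, EMG, electrode pops), sleep staging, volume-conduction
geometry, or any correlation between a patient's PET phenotype and EEG
dynamics beyond the group labels. Passing tests therefore demonstrate that
the pipeline recovers implanted effects of the stated kind and stays
calibrated under the null — not that real TLE/TPE cohorts separate with
any particular accuracy.

All generators draw from one master seed split into per-subject streams
(`split_seed`), so cohorts are reproducible while subjects stay
independent.

## Numerical choices and degenerate inputs

* Recurrence-threshold bisection runs a coarse pass on a strided subsample
  of the pairwise distances before full-count refinement; the convergence
  check is always the full count (tolerance ±0.005 on RR). An unreachable
  target rate is an error reporting the achieved rate.
* Embedded windows shorter than 100 points, constant signals (AMI and
  recurrence undefined), zero-variance NC regions, and perfectly separated
  propensity models are all rejected with diagnostics rather than patched
  over.
* Zero paired differences: p = 1 with a warning. Empty RQA histograms:
  feature = 0. Nodes of degree < 2: clustering 0. A complete (or too
  small) graph cannot be rewired and is returned as its own random
  reference with a warning flag — which also makes γ = λ = σ = 1 exact for
  complete graphs, as it should be.
* `threshold_by_sparsity` tie-break and all seed handling are fully
  deterministic; every stochastic routine takes an explicit seed and
  restores the caller's RNG state.

## Problem sizes in the shipped runs

The full-scale protocol (19 channels, 500 Hz, 1000 RQA windows per
channel, 100 random graph references) is what the defaults of the
individual operations encode. The shipped analysis scripts, test suite and
acceptance script run the same code at desk scale, chosen as the sizes at
which the statistical properties under test are already stable: 3 EEG
channels at 200 Hz for 30 s, 20 RQA windows per channel (2 where only the
matrix shape is at stake), 12–20 random references, 100–200 simulated
cohorts for power/calibration studies, and Monte-Carlo nulls of
2 000–20 000 draws. The vignette-level claims above (power ≥ 0.9,
null ≈ 5%, calibrated type-I errors) are exactly the quantities the test
suite and `scripts/acceptance.R` recompute.

## Known limitations

* The reweighting kernel is a documented default, not the (unpublished)
  original; conclusions that depend on its exact shape should treat it as
  one member of a family.
* Graph metrics are binary-graph metrics; weighted variants are out of
  scope.
* The Lilliefors test's power against close-to-normal alternatives is
  modest at n = 25 — the gate will route most real features to the
  Wilcoxon branch, which is the expected behaviour, not a defect.
* SHAP interactions are exact only for the tree model; the sampling
  approximation for other models is noisy at 50 subjects and is flagged.
* The synthetic EEG shares one source across channels; spatial structure
  is not physiological, so channel-resolved analyses should not be read
  into.
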