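# tpenet

Noninvasive brain-network features for separating **temporal-plus epilepsy
(TPE)** — seizure onset in the temporal lobe *plus* adjacent structures, at
least the insula — from classical **temporal lobe epilepsy (TLE)**. The
distinction matters clinically: TPE patients benefit less from standard
anterior temporal lobectomy, so flagging them during the noninvasive
presurgical work-up changes the surgical plan. Insular hypometabolism on
FDG-PET alone does not separate the groups; network topology does better.

`tpenet` implements the full analysis chain as a reusable, tested R
package, plus a synthetic-cohort generator so every stage runs and is
verifiable without patient data:

1. **Individual metabolic networks** from regional FDG-PET uptake
   (56 regions, one hemisphere, cerebellum-normalized). A normal-control
   (NC) cohort supplies regional means μ, SDs σ and the interregional
   Pearson matrix *R*. A subject with regional z-scores
   *e_i = (x_i − μ_i)/σ_i* gets the network

   *W_ij = exp(−|e_i − e_j|) · R_ij*

   — concordant deviation preserves NC connectivity, discordant deviation
   attenuates it (the kernel is pluggable).
2. **Graph-theoretical features**: the weighted network is binarized at
   sparsities 0.20–0.65 (step 0.05, edges ranked by |W|); at each sparsity
   the small-world indices γ, λ, σ = γ/λ (normalized against 100
   degree-preserving Maslov–Sneppen rewirings by default), global and local
   efficiency, and degree centrality (Dc) plus nodal clustering (Ncf) at
   the anterior and posterior insula; each metric is reduced across the
   grid by normalized trapezoid area. 9 features per subject.
3. **Recurrence quantification analysis (RQA)** of scalp EEG: band-pass
   1–80 Hz, 50 Hz notch, average reference; per 10-s window, delay τ by the
   first minimum of average mutual information (max lag 200), dimension m
   by false nearest neighbours; recurrence plot thresholded to a fixed 5%
   recurrence rate with a Theiler window; 13 features (RR, DET, L, Lmax,
   ENTR, LAM, TT, Vmax, RTmax, T2, RTE, Clust, Trans), averaged over
   randomly drawn windows (1000 in the full protocol) and channels.
4. **Propensity-score matching**: logistic model on gender, SOZ side, age
   of onset and epilepsy duration; greedy 1:1 nearest-neighbour matching
   without replacement, caliper 0.1; standardized-mean-difference balance
   report.
5. **Statistics**: Lilliefors normality gate (Monte-Carlo null), Wilcoxon
   signed-rank (exact where possible) or paired t per feature; BH-FDR for
   region-level screens.
6. **Classification**: the subjects × 22 feature matrix feeds XGBoost,
   logistic regression, SVM, random forest and naive Bayes under
   stratified 10-fold CV; accuracy = (TP+TN)/(TP+FN+TN+FP), sensitivity,
   specificity, precision, F1 and pooled-ROC AUC; paired AUCs compared
   with the DeLong test; TreeSHAP feature importance and interactions.

## Worked example

```r
library(tpenet)

# NC cohort and reference
nc  <- gen_nc_uptake(52, seed = 1)
ref <- build_nc_reference(nc)

# a subject 2 SD hypometabolic in the posterior insula
x <- ref$mu
i <- insula_nodes()["pIns"]
x[i] <- ref$mu[i] - 2 * ref$sigma[i]
net <- build_individual_network(x, ref)
round(graph_feature_profile(net, n_rand = 20, seed = 2), 3)
#>    sigma    gamma   lambda e_global  e_local  dc_aIns  dc_pIns ncf_aIns ncf_pIns
#>    1.271    1.310    1.022    0.686    0.774   23.222    0.000    0.576    0.000
```

The deep posterior-insular deviation strips that node's edges — its
aggregated degree centrality collapses to 0 (a subject at the NC mean sits
at ≈ 12.6) while the rest of the network keeps its small-world character
(σ ≈ 1.3 > 1).

```r
# end-to-end synthetic study: 25 TLE + 25 TPE, reduced RQA iterations
res <- run_cohort_pipeline(seed = 42, n_per_group = 25,
                           specs = strong_group_specs(), n_iter = 2)
dim(res$fm$X)
#> [1] 50 22
crossval_evaluate(res$fm, "xgboost", k = 10, seed = 7)$auc
#> [1] 0.96
```

Under the strong implanted TPE phenotype the cross-validated classifier
separates the groups well above chance; with `null_group_specs()` the AUC
falls back to ≈ 0.5.

## The analysis workflow

`analysis/` holds the numbered drivers that reproduce the study narrative
on synthetic data, writing tables under `results/`:

| script | step |
|---|---|
| `01_simulate_cohort.R` | NC cohort + imbalanced 60/25 patient pool |
| `02_match_cohort.R` | propensity matching and balance report |
| `03_network_features.R` | metabolic networks → 9 graph features |
| `04_rqa_features.R` | EEG synthesis → 13 RQA features |
| `05_group_comparison.R` | Lilliefors-gated paired comparisons |
| `06_classification.R` | 5-classifier CV bench, DeLong, SHAP |
| `07_sensitivity_null.R` | power and null calibration of the insular features |

Run them in order from the repository root (`Rscript analysis/01_simulate_cohort.R` …).

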