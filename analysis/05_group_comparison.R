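#!/usr/bin/env Rscript
# Paired TLE-vs-TPE comparison of all 22 features across the matched pairs:
# Lilliefors normality gate per feature per group, Wilcoxon signed-rank
# where normality fails (the usual outcome), paired t otherwise. Raw
# two-sided p-values, mirroring the per-feature reporting convention.

library(tpenet)
pairs <- read.csv("results/pairs.csv", stringsAsFactors = FALSE)
gf <- read.csv("results/graph_features.csv", row.names = 1,
               check.names = FALSE)
rf <- read.csv("results/rqa_features.csv", row.names = 1,
               check.names = FALSE)
covariates <- read.csv("results/covariates.csv", stringsAsFactors = FALSE)

groups <- stats::setNames(covariates$group, covariates$subject_id)
fm <- assemble_feature_matrix(as.matrix(gf), as.matrix(rf),
                              labels = groups[rownames(gf)])

match <- structure(list(pairs = pairs, caliper = 0.1),
                   class = "match_result")
comparison <- paired_group_compare(fm$X, match, seed = 20260924)
write.csv(comparison, "results/comparison.csv", row.names = FALSE)

sig <- comparison[comparison$p < 0.05, c("feature", "test", "p")]
cat("Features significant at p < 0.05:\n")
if (nrow(sig)) print(sig, digits = 3) else cat("  (none)\n")
cat("\nInsular nodal features:\n")
print(comparison[comparison$feature %in%
                   c("dc_aIns", "dc_pIns", "ncf_aIns", "ncf_pIns"), ],
      digits = 3)
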