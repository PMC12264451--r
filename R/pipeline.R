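#' Default group effect specifications
#'
#' The study conditions the generator emulates: both patient groups carry
#' focal temporal-insular hypometabolism (-1.5 NC SDs); the TPE group
#' additionally suffers stronger attenuation of insular connectivity than
#' the TLE group (the phenomenon the nodal metrics are meant to pick up),
#' and a modestly different EEG determinism level.
#'
#' @param tle_decorrelation,tpe_decorrelation Insular connectivity
#'   attenuation per group.
#' @param uptake_shift Regional hypometabolism, NC-SD units.
#' @param tle_determinism,tpe_determinism EEG determinism levels.
#' @return List of two [effect_spec()] objects (TLE first).
#' @export
default_group_specs <- function(tle_decorrelation = 0.25,
                                tpe_decorrelation = 0.6,
                                uptake_shift = -1.5,
                                tle_determinism = 0.45,
                                tpe_determinism = 0.55) {
  temporal <- c("hippocampus", "amygdala", "superior temporal gyrus",
                "middle temporal gyrus", "inferior temporal gyrus",
                "temporal pole", "parahippocampal gyrus", "entorhinal area",
                "fusiform gyrus")
  list(
    effect_spec(c(temporal, "posterior insula"),
                uptake_shift = uptake_shift,
                decorrelation_strength = tle_decorrelation,
                group_label = "TLE", determinism = tle_determinism),
    effect_spec(c(temporal, "anterior insula", "posterior insula"),
                uptake_shift = uptake_shift,
                decorrelation_strength = tpe_decorrelation,
                group_label = "TPE", determinism = tpe_determinism)
  )
}

#' Strong-effect group specifications
#'
#' A pronounced TPE phenotype for sensitivity studies: on top of the shared
#' temporal hypometabolism, the TPE group carries deep focal insular
#' hypometabolism (-4 NC SDs, so insular deviations decouple from their
#' neighbours' and the similarity kernel strips the insula's edges, which
#' depresses both insular degree and insular clustering) with complete
#' attenuation of the insula's generating correlations, plus a larger EEG
#' determinism contrast between the groups.
#'
#' @return List of two [effect_spec()] objects (TLE first).
#' @export
strong_group_specs <- function() {
  temporal <- c("hippocampus", "amygdala", "superior temporal gyrus",
                "middle temporal gyrus", "inferior temporal gyrus",
                "temporal pole", "parahippocampal gyrus", "entorhinal area",
                "fusiform gyrus")
  list(
    effect_spec(temporal, uptake_shift = -1.5,
                decorrelation_strength = 0.2,
                group_label = "TLE", determinism = 0.35),
    effect_spec(c(temporal, "anterior insula", "posterior insula"),
                uptake_shift = c(rep(-1.5, length(temporal)), -4, -4),
                decorrelation_strength = 1.0,
                group_label = "TPE", determinism = 0.65)
  )
}

#' Null group specifications (no implanted effects)
#'
#' @return List of two [effect_spec()] objects with all effects zero and
#'   equal determinism.
#' @export
null_group_specs <- function() {
  list(effect_spec(integer(0), group_label = "TLE", determinism = 0.5),
       effect_spec(integer(0), group_label = "TPE", determinism = 0.5))
}

#' Graph feature profiles for a list of networks
#'
#' @param nets Named list of `individual_network` objects.
#' @param grid Sparsity grid.
#' @param n_rand Random references per grid point.
#' @param seed Integer seed split per subject.
#' @return Matrix (subjects x 9) of graph features, rownames = subject ids.
#' @export
cohort_graph_features <- function(nets, grid = sparsity_grid(),
                                  n_rand = 20, seed = 1) {
  seeds <- split_seed(seed, length(nets))
  out <- t(vapply(seq_along(nets), function(i) {
    graph_feature_profile(nets[[i]], grid = grid, n_rand = n_rand,
                          seed = seeds[i])
  }, numeric(9)))
  rownames(out) <- names(nets)
  out
}

#' Synthesize EEG and compute RQA features for a set of subjects
#'
#' Generates one recording per subject with the determinism level of its
#' group's [effect_spec()], preprocesses it, and runs the random-segment
#' RQA protocol.
#'
#' @param groups Named character vector: subject id -> group label.
#' @param specs Group [effect_spec()] list supplying determinism levels.
#' @param seed Integer seed split per subject.
#' @param n_channels,duration,fs Recording settings.
#' @param n_iter,embed_per RQA protocol settings.
#' @return Matrix (subjects x 13) of RQA features, rownames = subject ids.
#' @export
cohort_rqa_features <- function(groups, specs, seed, n_channels = 3,
                                duration = 30, fs = 200, n_iter = 20,
                                embed_per = "channel") {
  det_by_group <- stats::setNames(
    vapply(specs, `[[`, numeric(1), "determinism"),
    vapply(specs, `[[`, character(1), "group_label"))
  ids <- names(groups)
  seeds <- split_seed(seed, 2L * length(ids))
  out <- t(vapply(seq_along(ids), function(i) {
    rec <- gen_eeg_recording(det_by_group[[groups[[i]]]],
                             n_channels = n_channels, duration = duration,
                             fs = fs, seed = seeds[2 * i - 1])
    rec <- suppressWarnings(preprocess_eeg(rec))
    as.numeric(rqa_protocol(rec, n_iter = n_iter, seed = seeds[2 * i],
                            embed_per = embed_per))
  }, numeric(13)))
  dimnames(out) <- list(ids, rqa_feature_names())
  out
}

#' Run the full cohort pipeline on synthetic data
#'
#' Generates a normal-control cohort and a two-group patient cohort, builds
#' each patient's individual metabolic network and sparsity-aggregated
#' graph features, synthesizes and preprocesses per-patient EEG, runs the
#' random-segment RQA protocol, and assembles the subjects x 22 feature
#' matrix.
#'
#' @param seed Integer master seed.
#' @param n_per_group Patients per group.
#' @param specs Group [effect_spec()] list (default [default_group_specs()]).
#' @param n_nc Control-cohort size.
#' @param n_channels,duration,fs EEG synthesis settings per patient.
#' @param n_iter RQA windows per channel.
#' @param embed_per Embedding policy for [rqa_protocol()].
#' @param n_rand Random references per sparsity for the small-world indices.
#' @param grid Sparsity grid.
#' @param imbalance Covariate imbalance passed to [gen_patient_cohort()].
#' @return List: `fm` (a `feature_matrix`), `graph_feats`, `rqa_feats`,
#'   `cohort`, `nc_ref`.
#' @export
run_cohort_pipeline <- function(seed, n_per_group = 25,
                                specs = default_group_specs(), n_nc = 52,
                                n_channels = 3, duration = 30, fs = 200,
                                n_iter = 20, embed_per = "channel",
                                n_rand = 20, grid = sparsity_grid(),
                                imbalance = list(age_onset = 0, duration = 0)) {
  seeds <- split_seed(seed, 4)
  nc <- gen_nc_uptake(n_nc, seed = seeds[1])
  ref <- build_nc_reference(nc)
  cohort <- gen_patient_cohort(n_per_group, specs, ref, seed = seeds[2],
                               imbalance = imbalance)
  nets <- build_cohort_networks(cohort$uptake, ref)
  graph_feats <- cohort_graph_features(nets, grid = grid, n_rand = n_rand,
                                       seed = seeds[3])
  groups <- stats::setNames(cohort$covariates$group,
                            cohort$covariates$subject_id)
  rqa_feats <- cohort_rqa_features(groups, specs, seed = seeds[4],
                                   n_channels = n_channels,
                                   duration = duration, fs = fs,
                                   n_iter = n_iter, embed_per = embed_per)
  fm <- assemble_feature_matrix(graph_feats, rqa_feats, labels = groups)
  list(fm = fm, graph_feats = graph_feats, rqa_feats = rqa_feats,
       cohort = cohort, nc_ref = ref)
}
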