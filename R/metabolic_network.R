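#' Normal-control reference for individual network construction
#'
#' Summarizes a control uptake cohort into the three ingredients the
#' individual metabolic network needs: per-region means `mu` and SDs
#' `sigma`, and the full interregional Pearson correlation matrix `R`
#' (the group connectivity prior).
#'
#' @param nc An `uptake_matrix` of controls (>= 10 subjects).
#' @return Object of class `nc_reference`: `mu`, `sigma`, `R`, `n_nc`,
#'   `region_labels`.
#' @export
build_nc_reference <- function(nc) {
  stopifnot(inherits(nc, "uptake_matrix"))
  v <- nc$values
  if (nrow(v) < 10) stop("need at least 10 control subjects")
  sigma <- apply(v, 2, sd)
  if (any(sigma == 0)) {
    stop("zero-variance region(s): ",
         paste(nc$region_labels[sigma == 0], collapse = ", "))
  }
  R <- cor(v)
  diag(R) <- 1
  structure(list(mu = colMeans(v), sigma = sigma, R = R, n_nc = nrow(v),
                 region_labels = nc$region_labels),
            class = "nc_reference")
}

#' Subject-versus-control regional effect sizes
#'
#' The per-region deviation of one subject's uptake from the control cohort,
#' in control-SD units: `e_i = (x_i - mu_i) / sigma_i`.
#'
#' @param x Numeric vector of 56 regional uptake values (or a 1-row matrix).
#' @param ref An `nc_reference`.
#' @return Numeric 56-vector of z-scores, named by region.
#' @export
subject_effect_sizes <- function(x, ref) {
  stopifnot(inherits(ref, "nc_reference"))
  x <- as.numeric(x)
  if (length(x) != length(ref$mu))
    stop("subject uptake has ", length(x), " regions; reference has ",
         length(ref$mu))
  if (!all(is.finite(x))) stop("subject uptake must be finite")
  stats::setNames((x - ref$mu) / ref$sigma, ref$region_labels)
}

#' Exponential-decay similarity weight (default kernel)
#'
#' Maps the absolute difference of two regional effect sizes to a weight in
#' (0, 1]: identical deviation preserves the control connectivity in full,
#' discordant deviation attenuates it smoothly.
#'
#' @param de Nonnegative numeric: `|e_i - e_j|`.
#' @return `exp(-de)`.
#' @export
weight_exp_decay <- function(de) exp(-de)

#' Build the individual metabolic brain network
#'
#' A subject's network is the control Pearson matrix reweighted by how
#' discordantly each region pair deviates from the control mean:
#' `W_ij = w(|e_i - e_j|) * R_ij`, with `w` the (pluggable) similarity
#' kernel, defaulting to [weight_exp_decay()]. A subject at the control mean
#' reproduces `R` exactly; larger pairwise deviation differences attenuate
#' the corresponding edge. The diagonal is set to 0 and ignored downstream.
#'
#' @param x Subject regional uptake (56-vector).
#' @param ref An `nc_reference`.
#' @param weight_fn Kernel mapping `|e_i - e_j| >= 0` to a weight in (0, 1].
#' @param subject_id Optional id carried on the result.
#' @return Object of class `individual_network`: `W` (56 x 56 symmetric,
#'   zero diagonal), `subject_id`, `region_labels`.
#' @export
build_individual_network <- function(x, ref, weight_fn = weight_exp_decay,
                                     subject_id = NULL) {
  e <- subject_effect_sizes(x, ref)
  de <- abs(outer(e, e, `-`))
  W <- weight_fn(de) * ref$R
  W <- (W + t(W)) / 2   # guard symmetry against kernel round-off
  diag(W) <- 0
  dimnames(W) <- list(ref$region_labels, ref$region_labels)
  structure(list(W = W, subject_id = subject_id,
                 region_labels = ref$region_labels),
            class = "individual_network")
}

#' Build individual networks for a whole cohort
#'
#' @param uptake An `uptake_matrix` of patients.
#' @param ref An `nc_reference`.
#' @inheritParams build_individual_network
#' @return Named list of `individual_network`, one per subject row.
#' @export
build_cohort_networks <- function(uptake, ref, weight_fn = weight_exp_decay) {
  stopifnot(inherits(uptake, "uptake_matrix"))
  nets <- lapply(seq_along(uptake$subject_ids), function(i) {
    build_individual_network(uptake$values[i, ], ref, weight_fn,
                             subject_id = uptake$subject_ids[i])
  })
  stats::setNames(nets, uptake$subject_ids)
}
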