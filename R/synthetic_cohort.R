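#' Block correlation structure for the normal-control metabolic covariance
#'
#' Describes the interregional correlation prior as a baseline correlation
#' plus lobe-like blocks with stronger within-block correlation. The
#' construction `R = r0*J + sum_b (r_b - r0)*J_b + D` (with `D` diagonal,
#' restoring unit diagonal) is positive semi-definite whenever
#' `0 <= r0 <= r_b <= 1` and blocks are disjoint, so validity is guaranteed
#' by construction rather than checked after the fact.
#'
#' @param baseline Baseline interregional correlation (applies between lobes).
#' @param blocks Named list of integer index vectors (disjoint region sets).
#' @param within Within-block correlation; either a single value recycled or
#'   a vector named like `blocks`.
#' @return An object of class `corr_spec`.
#' @export
corr_spec <- function(baseline = 0.1, blocks = region_lobe_blocks(),
                      within = 0.5) {
  if (length(within) == 1L) within <- stats::setNames(rep(within, length(blocks)), names(blocks))
  structure(list(baseline = baseline, blocks = blocks, within = within),
            class = "corr_spec")
}

# Realize a corr_spec into a 56 x 56 correlation matrix, rejecting any block
# whose parameters could break positive semi-definiteness.
build_corr_matrix <- function(spec, p = 56L) {
  if (is.matrix(spec)) {
    if (!isSymmetric(spec) || any(diag(spec) != 1))
      stop("correlation matrix must be symmetric with unit diagonal")
    ev <- min(eigen(spec, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8) stop("correlation matrix is not positive semi-definite")
    return(spec)
  }
  stopifnot(inherits(spec, "corr_spec"))
  r0 <- spec$baseline
  if (r0 < 0 || r0 > 1) stop("baseline correlation must lie in [0, 1]")
  seen <- integer(0)
  R <- matrix(r0, p, p)
  for (nm in names(spec$blocks)) {
    idx <- spec$blocks[[nm]]
    rb <- spec$within[[nm]]
    if (any(idx < 1L | idx > p)) stop("block '", nm, "' references regions outside 1..", p)
    if (any(idx %in% seen)) stop("block '", nm, "' overlaps another block; PSD not guaranteed")
    if (rb < r0 || rb > 1) {
      stop("block '", nm, "' has within-block correlation ", rb,
           " outside [baseline, 1]; PSD not guaranteed")
    }
    seen <- c(seen, idx)
    R[idx, idx] <- rb
  }
  diag(R) <- 1
  R
}

# Fixed, deterministic region-level mean/SD profile for cerebellum-normalized
# uptake: cortical SUVr around 1.2-1.5, subcortical slightly higher variance.
default_uptake_profile <- function(p = 56L) {
  i <- seq_len(p)
  mu <- 1.30 + 0.15 * sin(i / 5) + 0.05 * cos(i / 2)
  sigma <- 0.10 + 0.02 * (1 + sin(i / 7)) / 2
  list(mu = mu, sigma = sigma)
}

#' Generate a normal-control regional uptake cohort
#'
#' Draws `n_subjects` rows from a multivariate normal with a structured
#' interregional correlation matrix and region-specific means/SDs, emulating
#' a healthy-control FDG-PET cohort of cerebellum-normalized regional uptake
#' values. Draws are shifted to positivity if the tail ever crosses zero
#' (with the default profile it does not).
#'
#' @param n_subjects Number of control subjects (>= 10).
#' @param corr A [corr_spec()] or an explicit 56 x 56 correlation matrix.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param profile List with `mu`, `sigma` (length-56 vectors); defaults to
#'   the package profile.
#' @return An object of class `uptake_matrix`: list with `values`
#'   (subjects x 56), `region_labels`, `subject_ids`.
#' @export
gen_nc_uptake <- function(n_subjects, corr = corr_spec(), seed,
                          profile = default_uptake_profile()) {
  if (n_subjects < 10) stop("need at least 10 control subjects")
  labs <- atlas_regions()
  p <- length(labs)
  R <- build_corr_matrix(corr, p)
  Sigma <- diag(profile$sigma) %*% R %*% diag(profile$sigma)
  vals <- with_seed(seed, MASS::mvrnorm(n_subjects, mu = profile$mu, Sigma = Sigma))
  if (min(vals) <= 0) vals <- vals - min(vals) + 1e-3
  uptake_matrix(vals, labs, sprintf("NC%03d", seq_len(n_subjects)))
}

uptake_matrix <- function(values, region_labels, subject_ids) {
  values <- as.matrix(values)
  if (ncol(values) != length(region_labels))
    stop("values must have one column per region label")
  if (anyDuplicated(region_labels)) stop("region labels must be unique")
  if (!all(is.finite(values)) || any(values <= 0))
    stop("uptake values must be finite and positive")
  dimnames(values) <- list(subject_ids, region_labels)
  structure(list(values = values, region_labels = region_labels,
                 subject_ids = subject_ids),
            class = "uptake_matrix")
}

#' Group-effect specification for patient generation
#'
#' Encodes what a patient group does to regional uptake and to the
#' normal-control connectivity: focal hypometabolism (`uptake_shift`, in
#' z-units of the NC regional SD) in `affected_regions`, and attenuation of
#' those regions' interregional correlations (`decorrelation_strength` in
#' \[0,1\]; pairs with both members affected are attenuated by
#' `1 - d`, mixed pairs by `sqrt(1 - d)`, which keeps the generating
#' correlation matrix positive semi-definite by construction).
#'
#' @param affected_regions Integer region indices (1-based) or label strings.
#' @param uptake_shift Signed shift in NC-SD units (hypometabolism < 0);
#'   scalar, or one value per affected region for focal gradients.
#' @param decorrelation_strength Fraction in \[0, 1\].
#' @param group_label `"TLE"` or `"TPE"`.
#' @param determinism EEG determinism level in \[0, 1\] passed to
#'   [gen_eeg_recording()] for this group's recordings.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(affected_regions, uptake_shift = 0,
                        decorrelation_strength = 0,
                        group_label = c("TLE", "TPE"),
                        determinism = 0.5) {
  group_label <- match.arg(group_label)
  labs <- atlas_regions()
  if (is.character(affected_regions)) {
    idx <- match(affected_regions, labs)
    if (anyNA(idx)) stop("unknown region label(s): ",
                         paste(affected_regions[is.na(idx)], collapse = ", "))
    affected_regions <- idx
  }
  if (length(affected_regions) &&
      any(affected_regions < 1L | affected_regions > length(labs)))
    stop("affected_regions out of range 1..56")
  if (!length(uptake_shift) %in% c(1L, max(1L, length(affected_regions))))
    stop("uptake_shift must be scalar or one value per affected region")
  if (decorrelation_strength < 0 || decorrelation_strength > 1)
    stop("decorrelation_strength must lie in [0, 1]")
  if (determinism < 0 || determinism > 1)
    stop("determinism must lie in [0, 1]")
  structure(list(affected_regions = as.integer(affected_regions),
                 uptake_shift = uptake_shift,
                 decorrelation_strength = decorrelation_strength,
                 group_label = group_label,
                 determinism = determinism),
            class = "effect_spec")
}

# Attenuate affected-region correlations of R by strength d, preserving PSD:
# scale rows/cols by s = sqrt(1 - d) and restore the unit diagonal.
attenuate_correlation <- function(R, affected, d) {
  if (!length(affected) || d == 0) return(R)
  s <- rep(1, nrow(R)); s[affected] <- sqrt(1 - d)
  Rp <- R * tcrossprod(s)
  diag(Rp) <- 1
  Rp
}

#' Generate a patient cohort with implanted group effects
#'
#' Each patient's regional uptake is an NC-like multivariate-normal draw
#' whose affected-region means are shifted by `uptake_shift` NC SDs and whose
#' affected-region correlations are attenuated per the group's
#' [effect_spec()]. Covariates (gender, SOZ side, age of onset, duration) are
#' drawn with a controllable between-group imbalance so propensity matching
#' has something to correct.
#'
#' @param n_per_group Patients per group (>= 2); a single count or one per
#'   group (imbalanced pools for matching studies). Groups are taken from
#'   `specs` in order.
#' @param specs List of two [effect_spec()] objects (one per group).
#' @param nc_ref [build_nc_reference()] result supplying means/SDs and the
#'   NC correlation matrix.
#' @param seed Integer seed split into per-subject streams.
#' @param imbalance Named list of additive shifts applied to the *second*
#'   group's covariate means, e.g. `list(age_onset = 4, duration = 3)`; the
#'   default 0s generate exchangeable covariates.
#' @return List with `uptake` (an `uptake_matrix` of all patients),
#'   `covariates` (data.frame with subject_id, gender, soz_side, age_onset,
#'   duration, group), `specs`.
#' @export
gen_patient_cohort <- function(n_per_group, specs, nc_ref, seed,
                               imbalance = list(age_onset = 0, duration = 0)) {
  stopifnot(length(specs) == 2L)
  n_group <- rep_len(n_per_group, 2L)
  if (any(n_group < 2)) stop("need at least 2 patients per group")
  n_total <- sum(n_group)
  labs <- atlas_regions()
  p <- length(labs)
  seeds <- split_seed(seed, n_total + 1L)
  rows <- vector("list", n_total)
  k <- 0L
  for (g in 1:2) {
    sp <- specs[[g]]
    mu <- nc_ref$mu
    mu[sp$affected_regions] <- mu[sp$affected_regions] +
      sp$uptake_shift * nc_ref$sigma[sp$affected_regions]
    Rg <- attenuate_correlation(nc_ref$R, sp$affected_regions,
                                sp$decorrelation_strength)
    Sigma <- diag(nc_ref$sigma) %*% Rg %*% diag(nc_ref$sigma)
    for (i in seq_len(n_group[g])) {
      k <- k + 1L
      rows[[k]] <- with_seed(seeds[k], {
        x <- MASS::mvrnorm(1, mu = mu, Sigma = Sigma)
        shift <- if (g == 2L) imbalance else list(age_onset = 0, duration = 0)
        list(x = x,
             gender = rbinom(1, 1, 0.5),
             soz_side = rbinom(1, 1, 0.72),  # right-sided majority
             age_onset = max(0, rnorm(1, 10 + (shift$age_onset %||% 0), 7.5)),
             duration = max(0, rnorm(1, 10.9 + (shift$duration %||% 0), 6.9)))
      })
    }
  }
  ids <- sprintf("P%03d", seq_len(n_total))
  vals <- do.call(rbind, lapply(rows, `[[`, "x"))
  vals[vals <= 0] <- 1e-3
  covariates <- data.frame(
    subject_id = ids,
    gender = vapply(rows, `[[`, numeric(1), "gender"),
    soz_side = vapply(rows, `[[`, numeric(1), "soz_side"),
    age_onset = vapply(rows, `[[`, numeric(1), "age_onset"),
    duration = vapply(rows, `[[`, numeric(1), "duration"),
    group = rep(vapply(specs, `[[`, character(1), "group_label"),
                times = n_group),
    stringsAsFactors = FALSE
  )
  list(uptake = uptake_matrix(vals, labs, ids),
       covariates = covariates, specs = specs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic multichannel EEG-like recording
#'
#' Each channel is a mixture `d * s + (1 - d) * n` of a shared nonlinear
#' deterministic source (a Lorenz system integrated in continuous time and
#' resampled to `fs`, so delay selection by mutual information is
#' nondegenerate) and channel-specific band-limited stochastic noise, both
#' standardized before mixing; `d` is the determinism level. Channels see the
#' three Lorenz coordinates through a random mixing matrix. Output is scaled
#' to a scalp-EEG-like amplitude (microvolts).
#'
#' @param determinism_level Fraction in \[0, 1\].
#' @param n_channels Number of channels (10-20 montage has 19).
#' @param duration Seconds; >= 30 for the downstream RQA protocol.
#' @param fs Sampling rate, Hz; must be able to represent the 1-80 Hz band.
#' @param seed Integer seed.
#' @return Object of class `eeg_recording`: `data` (channels x samples),
#'   `fs`, `channel_labels`.
#' @export
gen_eeg_recording <- function(determinism_level, n_channels = 19L,
                              duration = 60, fs = 500, seed) {
  if (determinism_level < 0 || determinism_level > 1)
    stop("determinism_level must lie in [0, 1]")
  if (fs < 160) stop("fs too low to represent the 1-80 Hz band (need >= 160 Hz)")
  n <- round(duration * fs)
  with_seed(seed, {
    # Lorenz source: integrate at a fixed internal step, then resample so the
    # dominant oscillation lands in the EEG band regardless of fs.
    lorenz <- function(t, y, parms) {
      list(c(10 * (y[2] - y[1]),
             y[1] * (28 - y[3]) - y[2],
             y[1] * y[2] - 8 / 3 * y[3]))
    }
    # ~12.5 internal time-units per second puts the Lorenz orbital frequency
    # (~1.3 cycles/unit) near 16 Hz.
    t_units <- duration * 12.5
    times <- seq(0, t_units, length.out = n + 500L)
    y0 <- c(1, 1, 20) + rnorm(3, 0, 0.5)
    sol <- deSolve::ode(y0, times, lorenz, NULL)
    src <- scale(sol[tail(seq_len(nrow(sol)), n), 2:4])  # drop transient
    mix <- matrix(rnorm(n_channels * 3), n_channels, 3)
    mix <- mix / sqrt(rowSums(mix^2))
    det_part <- mix %*% t(src)                     # channels x samples
    # stochastic part: white noise band-limited to 1-30 Hz
    bf <- signal::butter(2, c(1, 30) / (fs / 2), type = "pass")
    noise <- t(vapply(seq_len(n_channels), function(i) {
      x <- signal::filtfilt(bf, rnorm(n + 200L))
      x <- x[101:(100 + n)]
      as.numeric(scale(x))
    }, numeric(n)))
    det_part <- det_part / pmax(apply(det_part, 1, sd), 1e-12)
    dat <- 30 * (determinism_level * det_part +
                   (1 - determinism_level) * noise)
    structure(list(data = dat, fs = fs,
                   channel_labels = sprintf("CH%02d", seq_len(n_channels))),
              class = "eeg_recording")
  })
}

#' Write/read cohort tables
#'
#' Uptake and covariate tables round-trip through plain CSV with subject ids
#' in the first column and region labels / covariate names in the header.
#'
#' @param x `uptake_matrix` or covariate data.frame.
#' @param path File path.
#' @export
write_uptake_csv <- function(x, path) {
  stopifnot(inherits(x, "uptake_matrix"))
  df <- data.frame(subject_id = x$subject_ids, x$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

#' @rdname write_uptake_csv
#' @export
read_uptake_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  uptake_matrix(as.matrix(df[, -1, drop = FALSE]),
                colnames(df)[-1], df[[1]])
}

#' Plain-text EEG container
#'
#' Recordings round-trip through a simple documented text format: a first
#' comment line `# fs=<Hz>` carrying the sampling rate, then a CSV of one
#' row per channel (first column the channel label, remaining columns the
#' samples in microvolts).
#'
#' @param rec An `eeg_recording`.
#' @param path File path.
#' @export
write_eeg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%s", format(rec$fs)), con)
  utils::write.table(
    data.frame(channel = rec$channel_labels, rec$data, check.names = FALSE),
    con, sep = ",", row.names = FALSE, col.names = FALSE, qmethod = "double")
}

#' @rdname write_eeg_csv
#' @export
read_eeg_csv <- function(path) {
  header <- readLines(path, n = 1)
  fs <- as.numeric(sub("^# fs=", "", header))
  if (!is.finite(fs)) stop("missing '# fs=' header in ", path)
  df <- utils::read.csv(path, header = FALSE, skip = 1,
                        stringsAsFactors = FALSE)
  structure(list(data = as.matrix(df[, -1, drop = FALSE]),
                 fs = fs, channel_labels = as.character(df[[1]])),
            class = "eeg_recording")
}
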