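#' Propensity scores from the four preoperative covariates
#'
#' Multivariable logistic regression of group membership on gender, SOZ
#' side, age of seizure onset and epilepsy duration; the fitted probability
#' of belonging to the case group is the propensity score.
#'
#' @param cov Covariate data.frame with columns `gender`, `soz_side`,
#'   `age_onset`, `duration`, `group` (two levels; the *second* sorted level
#'   is coded as the case).
#' @return Numeric vector of scores in (0, 1), named by `subject_id` when
#'   present; attribute `"model"` carries the glm fit.
#' @export
propensity_scores <- function(cov) {
  req <- c("gender", "soz_side", "age_onset", "duration", "group")
  miss <- setdiff(req, names(cov))
  if (length(miss)) stop("missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(complete.cases(cov[req]))) stop("covariates must be complete")
  lv <- sort(unique(as.character(cov$group)))
  if (length(lv) != 2) stop("need exactly two groups")
  if (min(table(cov$group)) < 2) stop("need >= 2 subjects per group")
  y <- as.integer(as.character(cov$group) == lv[2])
  fit <- suppressWarnings(
    glm(y ~ gender + soz_side + age_onset + duration,
        data = cov, family = binomial())
  )
  p <- as.numeric(fitted(fit))
  if (any(p < 1e-8 | p > 1 - 1e-8)) {
    stop("propensity model shows (quasi-)perfect separation; ",
         "scores degenerate at 0/1")
  }
  if (!is.null(cov$subject_id)) names(p) <- cov$subject_id
  structure(p, model = fit, case_level = lv[2])
}

#' Greedy 1:1 caliper matching on the propensity score
#'
#' Nearest-neighbour matching without replacement: cases are processed in a
#' seeded random order, each taking the closest remaining control within
#' the caliper; cases with no admissible control stay unmatched.
#'
#' @param scores Propensity scores (named or indexed like `groups`).
#' @param groups Two-level group vector; the *second* sorted level is the
#'   case group.
#' @param caliper Maximal absolute score difference within a pair
#'   (raw propensity scale).
#' @param seed Integer seed for the processing order.
#' @return Object of class `match_result`: `pairs` (data.frame `case_id`,
#'   `control_id`, `case_score`, `control_score`), `scores`, `unmatched`,
#'   `caliper`.
#' @export
match_pairs <- function(scores, groups, caliper = 0.1, seed = 1) {
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  if (length(lv) != 2) stop("need exactly two groups")
  ids <- if (!is.null(names(scores))) names(scores) else as.character(seq_along(scores))
  case_idx <- which(groups == lv[2])
  ctrl_idx <- which(groups == lv[1])
  order_cases <- with_seed(seed, sample(case_idx))
  taken <- logical(length(scores))
  pairs <- list()
  for (ci in order_cases) {
    free <- ctrl_idx[!taken[ctrl_idx]]
    if (!length(free)) next
    d <- abs(scores[free] - scores[ci])
    j <- free[which.min(d)]
    if (min(d) <= caliper) {
      taken[j] <- TRUE
      taken[ci] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(
        case_id = ids[ci], control_id = ids[j],
        case_score = unname(scores[ci]), control_score = unname(scores[j]),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(case_id = character(0), control_id = character(0),
               case_score = numeric(0), control_score = numeric(0))
  if (!nrow(pairs)) warning("no pairs possible within caliper ", caliper)
  structure(list(pairs = pairs, scores = scores,
                 unmatched = ids[!taken & seq_along(ids) %in% c(case_idx, ctrl_idx)],
                 caliper = caliper, case_level = lv[2]),
            class = "match_result")
}

# Standardized mean difference with pooled-SD denominator.
smd <- function(x, g) {
  g <- as.factor(g)
  m <- tapply(x, g, mean)
  v <- tapply(x, g, var)
  denom <- sqrt((v[1] + v[2]) / 2)
  if (denom == 0) return(0)
  unname((m[2] - m[1]) / denom)
}

#' Covariate balance before and after matching
#'
#' @param cov Covariate data.frame (same shape as [propensity_scores()]).
#' @param match A `match_result`.
#' @return data.frame with one row per covariate: `smd_before`, `smd_after`.
#' @export
balance_report <- function(cov, match) {
  stopifnot(inherits(match, "match_result"))
  vars <- c("gender", "soz_side", "age_onset", "duration")
  matched_ids <- c(match$pairs$case_id, match$pairs$control_id)
  sub <- cov[cov$subject_id %in% matched_ids, ]
  data.frame(
    covariate = vars,
    smd_before = vapply(vars, function(v) smd(cov[[v]], cov$group), numeric(1)),
    smd_after = vapply(vars, function(v) {
      if (nrow(sub) < 4) return(NA_real_)
      smd(sub[[v]], sub$group)
    }, numeric(1)),
    row.names = NULL
  )
}
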