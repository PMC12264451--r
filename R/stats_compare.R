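#' Lilliefors normality test with Monte-Carlo null
#'
#' Kolmogorov-Smirnov statistic of the sample against a normal distribution
#' with mean and SD estimated from the sample; because the parameters are
#' estimated, the p-value comes from a seeded Monte-Carlo null of `n_mc`
#' standard-normal samples of the same size (the statistic is
#' location-scale free, so the standard normal suffices).
#'
#' @param sample Numeric sample, n >= 4.
#' @param n_mc Monte-Carlo replicates for the null distribution.
#' @param seed Integer seed for the null simulation.
#' @param null_stats Optional precomputed null statistics (e.g. from
#'   [lilliefors_null_stats()]) shared across many tests of the same n.
#' @return List: `statistic` (D), `p`, `n`.
#' @export
lilliefors_test <- function(sample, n_mc = 10000, seed = 1,
                            null_stats = NULL) {
  n <- length(sample)
  if (n < 4) stop("need at least 4 observations")
  if (sd(sample) == 0) stop("constant sample: normality test undefined")
  d <- lilliefors_stat(sample)
  if (is.null(null_stats)) null_stats <- lilliefors_null_stats(n, n_mc, seed)
  p <- (1 + sum(null_stats >= d)) / (length(null_stats) + 1)
  list(statistic = d, p = p, n = n)
}

# KS distance between the empirical CDF and N(mean(x), sd(x)).
lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  fz <- pnorm(z)
  max(seq_len(n) / n - fz, fz - (seq_len(n) - 1) / n)
}

#' @rdname lilliefors_test
#' @param n Sample size of the null draws.
#' @export
lilliefors_null_stats <- function(n, n_mc = 10000, seed = 1) {
  with_seed(seed, vapply(seq_len(n_mc), function(i) {
    lilliefors_stat(rnorm(n))
  }, numeric(1)))
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Zeros are dropped, ties get mid-ranks. The two-sided p-value is exact for
#' tie-free data up to `exact_n` (signed-rank null distribution), exact by
#' full sign-flip enumeration for tied data with few nonzero differences,
#' and otherwise uses the normal approximation with tie correction and
#' continuity correction.
#'
#' @param d Numeric vector of paired differences.
#' @param exact_n Largest n for the exact tie-free path (default 50).
#' @param enum_n Largest n for exhaustive sign-flip enumeration under ties.
#' @return List: `statistic` (V, sum of positive ranks), `p`, `n_nonzero`,
#'   `method`.
#' @export
signed_rank_test <- function(d, exact_n = 50, enum_n = 14) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences zero; p = 1")
    return(list(statistic = 0, p = 1, n_nonzero = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0
  if (!has_ties && n <= exact_n) {
    p <- 2 * min(psignrank(v, n), 1 - psignrank(v - 1, n))
    return(list(statistic = v, p = min(1, p), n_nonzero = n,
                method = "exact"))
  }
  if (has_ties && n <= enum_n) {
    # enumerate all 2^n sign assignments of the observed mid-ranks
    vs <- colSums(r * (t(expand.grid(rep(list(0:1), n))) == 1))
    mu <- n * (n + 1) / 4
    p <- mean(abs(vs - mu) >= abs(v - mu) - 1e-12)
    return(list(statistic = v, p = p, n_nonzero = n, method = "enumeration"))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
  list(statistic = v, p = min(1, 2 * pnorm(-abs(z))), n_nonzero = n,
       method = "normal-approximation")
}

#' Paired feature comparison with a Lilliefors normality gate
#'
#' For every feature column: Lilliefors normality is tested in each group;
#' if either group departs from normality at `alpha`, the Wilcoxon
#' signed-rank test is applied to the paired differences, otherwise a
#' paired t-test. Raw two-sided p-values are reported (no correction across
#' features by default; [fdr_bh()] is available where a region-level screen
#' needs it).
#'
#' @param features Numeric matrix (subjects x features) with rownames =
#'   subject ids.
#' @param match A `match_result` pairing cases to controls.
#' @param alpha Normality-gate level.
#' @param n_mc,seed Monte-Carlo controls for the Lilliefors null.
#' @return data.frame: `feature`, `test`, `statistic`, `p`,
#'   `normality_p_case`, `normality_p_control`.
#' @export
paired_group_compare <- function(features, match, alpha = 0.05,
                                 n_mc = 2000, seed = 1) {
  stopifnot(inherits(match, "match_result"))
  ids <- rownames(features)
  if (is.null(ids)) stop("features must carry subject ids as rownames")
  missing_ids <- setdiff(c(match$pairs$case_id, match$pairs$control_id), ids)
  if (length(missing_ids))
    stop("feature rows missing for: ", paste(missing_ids, collapse = ", "))
  xs <- features[match$pairs$case_id, , drop = FALSE]
  ys <- features[match$pairs$control_id, , drop = FALSE]
  null_stats <- lilliefors_null_stats(nrow(xs), n_mc, seed)
  out <- lapply(colnames(features), function(f) {
    x <- xs[, f]; y <- ys[, f]
    npc <- tryCatch(
      lilliefors_test(x, null_stats = null_stats)$p, error = function(e) 0)
    npk <- tryCatch(
      lilliefors_test(y, null_stats = null_stats)$p, error = function(e) 0)
    d <- x - y
    if (all(d == 0)) {
      warning("all paired differences zero for feature '", f, "'; p = 1")
      return(data.frame(feature = f, test = "degenerate", statistic = 0,
                        p = 1, normality_p_case = npc,
                        normality_p_control = npk))
    }
    if (npc < alpha || npk < alpha) {
      w <- suppressWarnings(signed_rank_test(d))
      data.frame(feature = f, test = "wilcoxon-signed-rank",
                 statistic = w$statistic, p = w$p,
                 normality_p_case = npc, normality_p_control = npk)
    } else {
      tt <- t.test(x, y, paired = TRUE)
      data.frame(feature = f, test = "paired-t",
                 statistic = unname(tt$statistic), p = tt$p.value,
                 normality_p_case = npc, normality_p_control = npk)
    }
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg significance mask
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @param q FDR level.
#' @return Logical vector: `TRUE` where the BH-adjusted p-value is <= q.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH") <= q
}
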