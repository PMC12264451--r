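#' Preprocess a scalp EEG recording
#'
#' Standard preprocessing contract ahead of RQA: downsample to 500 Hz (kept
#' at the input rate, with a warning, when the input is already below 500),
#' zero-phase Butterworth band-pass 1-80 Hz, zero-phase 50 Hz notch, and
#' re-referencing to the average of all channels. Artifact removal (ICA) is
#' assumed to have happened upstream for real data; synthetic recordings do
#' not need it.
#'
#' @param rec An `eeg_recording`.
#' @return A preprocessed `eeg_recording` (fs possibly changed).
#' @export
preprocess_eeg <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs <= 2 * 80) stop("sampling rate ", fs,
                         " Hz cannot represent the 1-80 Hz band (need > 160 Hz)")
  dat <- rec$data
  if (fs > 500) {
    q <- fs / 500
    if (abs(q - round(q)) < 1e-9) {
      dat <- t(apply(dat, 1, function(x) signal::decimate(x, round(q))))
      fs <- 500
    } else {
      # non-integer ratio: anti-alias then linear resample onto a 500 Hz grid
      lp <- signal::butter(4, (0.8 * 250) / (fs / 2), type = "low")
      t_old <- seq(0, (ncol(dat) - 1)) / fs
      t_new <- seq(0, max(t_old), by = 1 / 500)
      dat <- t(apply(dat, 1, function(x) {
        stats::approx(t_old, signal::filtfilt(lp, x), xout = t_new)$y
      }))
      fs <- 500
    }
  } else if (fs < 500) {
    warning("input rate ", fs, " Hz below 500 Hz; kept unchanged")
  }
  bp <- signal::butter(4, c(1, 80) / (fs / 2), type = "pass")
  notch <- signal::butter(2, c(48, 52) / (fs / 2), type = "stop")
  dat <- t(apply(dat, 1, function(x) {
    signal::filtfilt(notch, signal::filtfilt(bp, x))
  }))
  if (nrow(dat) >= 2) {
    dat <- sweep(dat, 2, colMeans(dat))   # average reference
  } else {
    warning("single-channel recording: average reference skipped")
  }
  structure(list(data = dat, fs = fs, channel_labels = rec$channel_labels),
            class = "eeg_recording")
}

#' Select the embedding delay by average mutual information
#'
#' Computes the average mutual information AMI(lag) between `x(t)` and
#' `x(t + lag)` with equal-width histogram estimation
#' (`ceiling(sqrt(N))` bins per marginal) and returns the first minimum of
#' the (lightly smoothed) AMI curve, taking the centre of the plateau when
#' the minimum is flat — the histogram AMI of periodic signals forms a
#' basin centred on the true quarter-period minimum. Signals whose curve
#' sits at the floor across most lags have no informative delay structure;
#' the first lag where AMI drops below `AMI(0)/e` is then used (attribute
#' `fallback = TRUE`).
#'
#' @param x Numeric signal, length > `4 * max_lag`.
#' @param max_lag Maximum lag searched, in samples.
#' @return Integer delay `tau` (attribute `"ami"` holds the curve for lags
#'   0..max_lag).
#' @export
select_delay_ami <- function(x, max_lag = 200) {
  n <- length(x)
  if (n <= 4 * max_lag) stop("signal too short for max_lag = ", max_lag)
  if (sd(x) == 0) stop("constant signal: AMI undefined")
  nb <- ceiling(sqrt(n))
  brk <- seq(min(x), max(x), length.out = nb + 1)
  ix <- findInterval(x, brk, rightmost.closed = TRUE, all.inside = TRUE)
  ami <- vapply(0:max_lag, function(lag) {
    a <- ix[seq_len(n - lag)]
    b <- ix[seq_len(n - lag) + lag]
    joint <- tabulate(a + nb * (b - 1L), nbins = nb * nb)
    joint <- joint[joint > 0] / (n - lag)
    pa <- tabulate(a, nbins = nb) / (n - lag)
    pb <- tabulate(b, nbins = nb) / (n - lag)
    ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
    hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
    hab <- -sum(joint * log(joint))
    ha + hb - hab
  }, numeric(1))
  # First robust minimum of the curve: the first lag from which no lag in
  # the next `W` drops more than the jitter tolerance (3% of the curve
  # range) below it. The histogram AMI of near-periodic signals is flat
  # across a basin centred on the true minimum, so the delay is the centre
  # of the contiguous plateau of values indistinguishable from that
  # minimum. A plateau spanning most of the lag axis means the signal has
  # no informative delay structure (e.g. white noise): the fallback then
  # picks the first lag where AMI drops below AMI(0)/e.
  # 5-point running mean suppresses the alternating-lag binning jitter the
  # histogram estimator shows on commensurately sampled periodic signals
  sm <- as.numeric(stats::filter(ami, rep(1 / 5, 5), sides = 2))
  sm[is.na(sm)] <- ami[is.na(sm)]
  lagv <- sm[-1]                       # values at lags 1..max_lag
  tol <- 0.03 * diff(range(lagv))      # scale excludes the lag-0 peak
  W <- 10L
  l0 <- NA_integer_
  for (l in seq_len(max_lag)) {
    ahead <- lagv[seq(min(l + 1, max_lag), min(l + W, max_lag))]
    if (all(ahead >= lagv[l] - tol)) { l0 <- l; break }
  }
  fallback <- FALSE
  if (is.na(l0)) {
    l0 <- which.min(lagv)
  }
  plateau <- l0
  while (plateau[length(plateau)] < max_lag &&
         lagv[plateau[length(plateau)] + 1] <= lagv[l0] + tol)
    plateau <- c(plateau, plateau[length(plateau)] + 1)
  if (length(plateau) > 0.5 * max_lag) {
    hit <- which(lagv < ami[1] / exp(1))
    tau <- if (length(hit)) hit[1] else 1L
    fallback <- TRUE
  } else {
    tau <- round(mean(range(plateau)))
  }
  structure(as.integer(tau), ami = ami, fallback = fallback)
}

#' Select the embedding dimension by false nearest neighbours
#'
#' Kennel-style FNN: for each dimension `m` the fraction of nearest
#' neighbours (Theiler-excluded) that become distant when the
#' `(m+1)`-th delay coordinate is added. Returns the smallest `m` whose FNN
#' fraction falls below `fnn_threshold`; if none does, the argmin with a
#' warning.
#'
#' @param x Numeric signal.
#' @param tau Embedding delay (from [select_delay_ami()]).
#' @param m_max Largest dimension tried.
#' @param rtol,atol Kennel criteria constants (distance-ratio and
#'   attractor-size tests).
#' @param fnn_threshold Acceptance threshold on the FNN fraction.
#' @param theiler Temporal exclusion for the neighbour search (default `tau`).
#' @return Integer `m` with attribute `"fnn"` (fractions for m = 1..m_max).
#' @export
select_dim_fnn <- function(x, tau, m_max = 10, rtol = 10, atol = 2,
                           fnn_threshold = 0.01, theiler = tau) {
  n <- length(x)
  if (n - m_max * tau < 20)
    stop("series too short for m_max = ", m_max, " at tau = ", tau)
  fr <- cpp_fnn_fractions(as.numeric(x), as.integer(tau), as.integer(m_max),
                          rtol, atol, as.integer(theiler))
  ok <- which(!is.na(fr) & fr < fnn_threshold)
  if (length(ok)) {
    m <- ok[1]
  } else {
    m <- which.min(fr)
    warning("FNN fraction never fell below ", fnn_threshold,
            "; using argmin m = ", m)
  }
  structure(as.integer(m), fnn = fr)
}

#' Build a recurrence plot at a fixed recurrence rate (or fixed epsilon)
#'
#' Embeds `x` with delay `tau` and dimension `m`, then thresholds the
#' pairwise Euclidean distance matrix. By default the threshold `eps` is
#' found by bisection so the achieved recurrence rate over admissible pairs
#' (|i-j| > `theiler`) lands within `rr_target +/- 0.005`; passing `eps`
#' directly switches to fixed-threshold mode.
#'
#' @param x Numeric signal.
#' @param tau,m Embedding parameters.
#' @param rr_target Target recurrence rate (ignored when `eps` is given).
#' @param theiler Theiler exclusion half-width in samples (default `tau`).
#' @param eps Optional fixed threshold in signal units.
#' @return Object of class `recurrence_plot`: `R` (binary, Theiler band
#'   zeroed), `eps`, `theiler`, `rr_target`, `rr` (achieved), `tau`, `m`.
#' @export
recurrence_matrix <- function(x, tau, m, rr_target = 0.05, theiler = tau,
                              eps = NULL) {
  x <- as.numeric(x)
  np <- length(x) - (m - 1) * tau
  if (np < 100) stop("embedded trajectory too short (", np, " < 100 points)")
  if (sd(x) == 0) stop("zero-variance trajectory")
  tau <- as.integer(tau); m <- as.integer(m); theiler <- as.integer(theiler)
  sol <- cpp_recurrence_plot(x, tau, m, theiler, rr_target, 0.005, 60L,
                             eps %||% -1, !is.null(eps))
  if (sol$converged == 0) {
    stop("recurrence rate ", rr_target, " unattainable; achieved ",
         signif(sol$rr, 3), " at eps = ", signif(sol$eps, 3))
  }
  structure(list(R = sol$R, eps = sol$eps, theiler = theiler,
                 rr_target = rr_target, rr = sol$rr, tau = tau, m = m),
            class = "recurrence_plot")
}

#' Canonical order of the 13 RQA feature names
#' @return Character vector of feature names.
#' @export
rqa_feature_names <- function() {
  c("RR", "DET", "L", "Lmax", "ENTR", "LAM", "TT", "Vmax", "RTmax",
    "T2", "RTE", "Clust", "Trans")
}

shannon_entropy <- function(lengths) {
  if (!length(lengths)) return(0)
  p <- tabulate(lengths) / length(lengths)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' The 13 RQA features of a recurrence plot
#'
#' Diagonal-line features (DET, L, Lmax, ENTR) come from maximal runs on
#' upper-triangle diagonals beyond the Theiler band; vertical features
#' (LAM, TT, Vmax) from runs within each column's admissible segments;
#' recurrence-time features (RTmax, T2, RTE) from white-vertical gaps and
#' entry times; network features (Clust, Trans) treat the Theiler-masked
#' matrix as an adjacency matrix. Empty histograms yield 0.
#'
#' @param rp A `recurrence_plot`.
#' @param lmin Minimal diagonal line length counted (default 2).
#' @param vmin Minimal vertical line length counted (default 2).
#' @return Named numeric vector of the 13 features, in the canonical order
#'   `RR, DET, L, Lmax, ENTR, LAM, TT, Vmax, RTmax, T2, RTE, Clust, Trans`.
#' @export
rqa_features <- function(rp, lmin = 2, vmin = 2) {
  stopifnot(inherits(rp, "recurrence_plot"))
  R <- rp$R
  np <- nrow(R); th <- rp$theiler
  adm <- np * (np - 1) / 2 - sum(pmax(np - seq_len(min(th, np - 1)), 0))
  rr <- if (adm > 0) sum(R) / 2 / adm else 0
  dl <- cpp_diag_lengths(R, th)
  det <- if (sum(dl) > 0) sum(dl[dl >= lmin]) / sum(dl) else 0
  lmean <- if (any(dl >= lmin)) mean(dl[dl >= lmin]) else 0
  lmax <- if (length(dl)) max(dl) else 0
  entr <- shannon_entropy(dl[dl >= lmin])
  vs <- cpp_vertical_structures(R, th)
  v <- vs$vertical
  lam <- if (sum(v) > 0) sum(v[v >= vmin]) / sum(v) else 0
  tt <- if (any(v >= vmin)) mean(v[v >= vmin]) else 0
  vmax <- if (length(v)) max(v) else 0
  rtmax <- if (length(vs$white)) max(vs$white) else 0
  rte <- shannon_entropy(vs$white)
  t2 <- if (length(vs$t2)) mean(vs$t2) else 0
  ct <- cpp_clust_trans(R)
  stats::setNames(
    c(rr, det, lmean, lmax, entr, lam, tt, vmax, rtmax, t2, rte,
      ct[1], ct[2]),
    rqa_feature_names()
  )
}

# Full single-window RQA: embedding selection + recurrence plot + features.
rqa_single_window <- function(x, rr_target = 0.05, max_lag = 200,
                              m_max = 10, lmin = 2, vmin = 2,
                              embed = NULL, embed_max_n = 1200) {
  if (is.null(embed)) {
    xe <- if (length(x) > embed_max_n) x[seq_len(embed_max_n)] else x
    tau <- select_delay_ami(xe, max_lag = min(max_lag, floor(length(xe) / 5)))
    m <- suppressWarnings(select_dim_fnn(xe, tau, m_max = m_max))
    embed <- list(tau = as.integer(tau), m = as.integer(m))
  }
  rp <- recurrence_matrix(x, embed$tau, embed$m, rr_target = rr_target)
  f <- rqa_features(rp, lmin = lmin, vmin = vmin)
  attr(f, "embed") <- embed
  attr(f, "eps") <- rp$eps
  f
}

#' Random-segment RQA averaging protocol for one recording
#'
#' For every channel, draws `n_iter` random `seg_len`-second windows from
#' the span remaining after trimming `head_trim` seconds from the start and
#' `tail_trim` seconds from the end, runs the full RQA pipeline on each
#' window, averages the 13 features over windows, and finally averages
#' across channels to one feature vector per recording.
#'
#' @param rec A (preprocessed) `eeg_recording` longer than
#'   `head_trim + tail_trim + seg_len` seconds.
#' @param seg_len Window length, seconds.
#' @param n_iter Windows per channel.
#' @param head_trim,tail_trim Excluded leading/trailing spans, seconds.
#' @param seed Integer seed; fixed seed gives an identical feature set.
#' @param rr_target Target recurrence rate per window.
#' @param embed_per `"window"` re-estimates tau/m per window (default);
#'   `"channel"` estimates once per channel on the first admissible window
#'   and reuses it (faster, appropriate for stationary signals).
#' @param channels Optional subset of channel indices.
#' @param ... Passed to the single-window pipeline (`m_max`, `lmin`, ...).
#' @return Named 13-vector of channel-averaged features; attribute
#'   `"per_channel"` keeps the channel-level means, `"eps_sd"` the SD of the
#'   per-window thresholds.
#' @export
rqa_protocol <- function(rec, seg_len = 10, n_iter = 1000, head_trim = 4,
                         tail_trim = 10, seed, rr_target = 0.05,
                         embed_per = c("window", "channel"),
                         channels = seq_len(nrow(rec$data)), ...) {
  stopifnot(inherits(rec, "eeg_recording"))
  embed_per <- match.arg(embed_per)
  fs <- rec$fs
  n <- ncol(rec$data)
  need <- (head_trim + tail_trim + seg_len) * fs
  if (n < need) {
    stop("recording too short: ", n / fs, " s < required minimum ",
         need / fs, " s")
  }
  wlen <- round(seg_len * fs)
  first <- round(head_trim * fs) + 1L
  last_start <- n - round(tail_trim * fs) - wlen + 1L
  ch_seeds <- split_seed(seed, length(channels))
  eps_all <- numeric(0)
  per_channel <- vapply(seq_along(channels), function(ci) {
    x <- rec$data[channels[ci], ]
    with_seed(ch_seeds[ci], {
      starts <- if (last_start > first) {
        sample(first:last_start, n_iter, replace = TRUE)
      } else rep(first, n_iter)
      embed <- NULL
      if (embed_per == "channel") {
        f0 <- rqa_single_window(x[first:(first + wlen - 1L)],
                                rr_target = rr_target, ...)
        embed <- attr(f0, "embed")
      }
      acc <- matrix(NA_real_, n_iter, 13L)
      for (it in seq_len(n_iter)) {
        w <- x[starts[it]:(starts[it] + wlen - 1L)]
        f <- rqa_single_window(w, rr_target = rr_target, embed = embed, ...)
        acc[it, ] <- f
        eps_all <<- c(eps_all, attr(f, "eps"))
      }
      colMeans(acc)
    })
  }, numeric(13))
  out <- stats::setNames(rowMeans(per_channel), rqa_feature_names())
  attr(out, "per_channel") <- per_channel
  attr(out, "eps_sd") <- if (length(eps_all) > 1) sd(eps_all) else 0
  out
}
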