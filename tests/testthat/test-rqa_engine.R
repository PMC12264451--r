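test_that("preprocessing: average reference, band edges, notch", {
  rec <- gen_eeg_recording(0.5, n_channels = 4, duration = 35, fs = 500,
                           seed = 1)
  out <- preprocess_eeg(rec)
  expect_equal(out$fs, 500)
  expect_lt(max(abs(colMeans(out$data))), 1e-9)   # re-referenced

  # attenuation probes: inject pure tones and measure pass-through power
  fs <- 500; t <- seq(0, 20, by = 1 / fs)[-1]
  probe <- function(freq) {
    sig <- matrix(rep(sin(2 * pi * freq * t), 2), nrow = 2, byrow = TRUE)
    sig[2, ] <- -sig[2, ]   # keep the average reference from cancelling it
    rec <- structure(list(data = sig, fs = fs,
                          channel_labels = c("a", "b")),
                     class = "eeg_recording")
    out <- preprocess_eeg(rec)$data[1, ]
    mid <- seq(2000, length(out) - 2000)
    10 * log10(mean(out[mid]^2) / mean(sig[1, mid]^2))
  }
  expect_gt(probe(10), -3)      # passband intact
  expect_lt(probe(50), -20)     # notch
  expect_lt(probe(100), -20)    # above band
  expect_error(preprocess_eeg(structure(list(
    data = matrix(rnorm(300), 2), fs = 150, channel_labels = c("a", "b")),
    class = "eeg_recording")), "represent")
})

test_that("downsampling to 500 Hz preserves in-band content", {
  fs <- 1000; t <- seq(0, 35, by = 1 / fs)[-1]
  sig <- rbind(sin(2 * pi * 12 * t), cos(2 * pi * 12 * t))
  rec <- structure(list(data = sig, fs = fs, channel_labels = c("a", "b")),
                   class = "eeg_recording")
  out <- preprocess_eeg(rec)
  expect_equal(out$fs, 500)
  expect_equal(ncol(out$data), length(t) / 2)
})

test_that("AMI delay: quarter period for a sine, fallback for white noise", {
  fs <- 500
  x <- sin(2 * pi * seq_len(4000) / 100)          # period 100 samples
  tau <- select_delay_ami(x, max_lag = 200)
  expect_true(abs(as.integer(tau) - 25) <= 2)
  # engine's AMI curve matches the independent estimator
  ami <- attr(tau, "ami")
  for (lag in c(1, 10, 25)) {
    expect_equal(unname(ami[lag + 1]), unname(oracle_ami(x, lag)),
                 tolerance = 1e-10)
  }
  set.seed(5)
  wn <- rnorm(2000)
  tau_wn <- select_delay_ami(wn, max_lag = 100)
  expect_true(isTRUE(attr(tau_wn, "fallback")) || as.integer(tau_wn) <= 10)
  expect_error(select_delay_ami(rep(1, 1000), max_lag = 100), "constant")
  expect_error(select_delay_ami(rnorm(100), max_lag = 200), "too short")
})

test_that("FNN dimension: Henon gives 2, Lorenz gives 3, matching brute force", {
  xh <- henon_series(1000)
  mh <- select_dim_fnn(xh, tau = 1, m_max = 6)
  expect_equal(as.integer(mh), 2)
  expect_equal(attr(mh, "fnn"), oracle_fnn(xh, 1, 6, theiler = 1),
               tolerance = 1e-12)

  xl <- lorenz_series(1200)
  taul <- select_delay_ami(xl, max_lag = 100)
  ml <- select_dim_fnn(xl, tau = taul, m_max = 8)
  expect_equal(as.integer(ml), 3)
  expect_equal(attr(ml, "fnn"),
               oracle_fnn(xl, as.integer(taul), 8, theiler = as.integer(taul)),
               tolerance = 1e-12)

  # noise: FNN decays slowly, warning path exercised
  set.seed(8)
  expect_warning(mn <- select_dim_fnn(rnorm(600), tau = 1, m_max = 5,
                                      fnn_threshold = 0.001), "argmin")
})

test_that("recurrence matrix hits the target rate and the eps limits", {
  set.seed(3)
  x <- sin(2 * pi * seq_len(600) / 40) + rnorm(600, 0, 0.3)
  rp <- recurrence_matrix(x, tau = 10, m = 2, rr_target = 0.05)
  expect_true(abs(rp$rr - 0.05) <= 0.005)
  expect_identical(rp$R, t(rp$R))
  band <- abs(row(rp$R) - col(rp$R)) <= rp$theiler
  expect_true(all(rp$R[band] == 0))
  # achieved rate equals the direct count on the admissible region
  np <- nrow(rp$R)
  adm <- sum(!band) / 2
  expect_equal(sum(rp$R) / 2 / adm, rp$rr, tolerance = 1e-12)

  # eps = 0: no recurrences; eps >= diameter: all admissible cells recur
  rp0 <- recurrence_matrix(x, 10, 2, eps = 0)
  expect_equal(sum(rp0$R), 0)
  rp1 <- recurrence_matrix(x, 10, 2, eps = diff(range(x)) * 4)
  expect_equal(rp1$rr, 1)
  expect_error(recurrence_matrix(rep(1, 500), 1, 2), "zero-variance")
  expect_error(recurrence_matrix(x[1:80], 1, 2), "too short")
})

test_that("hand-written 8x8 recurrence matrix reproduces every feature", {
  R <- matrix(0L, 8, 8)
  pairs <- rbind(c(1, 3), c(2, 4), c(3, 5), c(1, 6), c(2, 6), c(3, 6),
                 c(5, 7), c(6, 8), c(4, 8), c(4, 6))
  for (k in seq_len(nrow(pairs))) {
    R[pairs[k, 1], pairs[k, 2]] <- 1L
    R[pairs[k, 2], pairs[k, 1]] <- 1L
  }
  rp <- structure(list(R = R, eps = 1, theiler = 1, rr_target = NA,
                       rr = NA, tau = 1, m = 1), class = "recurrence_plot")
  f <- rqa_features(rp, lmin = 2, vmin = 2)
  expect_equal(unname(f), unname(oracle_rqa_features(R, theiler = 1)),
               tolerance = 1e-12)
})

test_that("saturated plot: RR = 1, DET and LAM at the finite-size ceiling", {
  n <- 30
  R <- matrix(1L, n, n)
  R[abs(row(R) - col(R)) <= 1] <- 0L
  rp <- structure(list(R = R, eps = 1, theiler = 1, rr_target = NA,
                       rr = NA, tau = 1, m = 1), class = "recurrence_plot")
  f <- rqa_features(rp)
  expect_equal(unname(f["RR"]), 1)
  # the single length-1 corner diagonal/segment keeps DET, LAM at
  # 405/406 rather than exactly 1 under the lmin = vmin = 2 convention
  expect_gte(unname(f["DET"]), 0.99)
  expect_gte(unname(f["LAM"]), 0.99)
  expect_equal(unname(f["DET"]),
               unname(oracle_rqa_features(R, 1)["DET"]), tolerance = 1e-12)
})

test_that("engine features equal the brute-force oracle on random signals", {
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(150:320, 1)
    kind <- rep %% 3
    x <- if (kind == 0) rnorm(n)
    else if (kind == 1) sin(2 * pi * seq_len(n) / sample(20:60, 1)) +
      rnorm(n, 0, 0.2)
    else henon_series(n) + rnorm(n, 0, 0.05)
    tau <- sample(1:4, 1); m <- sample(2:4, 1)
    rp <- recurrence_matrix(x, tau, m, rr_target = 0.08, theiler = tau)
    # oracle rebuilds the matrix from scratch at the engine's eps
    R_o <- oracle_recurrence_matrix(x, tau, m, rp$eps, tau)
    expect_true(all(rp$R == R_o))
    expect_equal(unname(rqa_features(rp)),
                 unname(oracle_rqa_features(R_o, tau)), tolerance = 1e-12)
  }
})

test_that("DET separates periodic from stochastic signals at matched RR", {
  for (seed in 1:3) {
    set.seed(seed)
    per <- sin(2 * pi * seq_len(500) / 25.3)
    noi <- rnorm(500)
    fp <- rqa_features(recurrence_matrix(per, 6, 2, rr_target = 0.05))
    fn <- rqa_features(recurrence_matrix(noi, 6, 2, rr_target = 0.05))
    expect_gte(fp[["DET"]], 0.95)
    expect_gt(fp[["DET"]], fn[["DET"]])
  }
})

test_that("protocol: determinism, degenerate window, convergence", {
  rec <- gen_eeg_recording(0.6, n_channels = 2, duration = 30, fs = 200,
                           seed = 31)
  rec <- suppressWarnings(preprocess_eeg(rec))
  p1 <- rqa_protocol(rec, n_iter = 3, seed = 5, embed_per = "channel")
  p2 <- rqa_protocol(rec, n_iter = 3, seed = 5, embed_per = "channel")
  expect_identical(as.numeric(p1), as.numeric(p2))
  expect_named(p1, tpenet:::rqa_feature_names())

  # recording exactly seg_len long after trims: every draw is the same
  # window, so the protocol mean equals the single-window features
  one <- rec
  one$data <- one$data[, 1:(24 * 200)]
  pw <- rqa_protocol(one, n_iter = 2, seed = 9)
  f1 <- tpenet:::rqa_single_window(one$data[1, (4 * 200 + 1):(14 * 200)])
  f2 <- tpenet:::rqa_single_window(one$data[2, (4 * 200 + 1):(14 * 200)])
  expect_equal(as.numeric(pw), (as.numeric(f1) + as.numeric(f2)) / 2,
               tolerance = 1e-10)

  expect_error(rqa_protocol(rec, seg_len = 10, head_trim = 10,
                            tail_trim = 11), "too short")

  # protocol mean approaches the long-window value as iterations grow
  pa <- rqa_protocol(rec, n_iter = 12, seed = 11, embed_per = "channel")
  expect_lt(abs(pa[["DET"]] - p1[["DET"]]), 0.2)
})
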