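# Independent brute-force oracles used to verify the package's
# implementations. Everything here is written from the definitions, using
# only base R primitives (and stats::dist), never the package's own code
# paths.

# ---- Pearson correlation from the textbook formula -------------------------
oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# ---- graph metrics by exhaustive enumeration -------------------------------
# Shortest paths via repeated boolean matrix products (paths of length k).
oracle_shortest_paths <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  reach <- diag(n)
  Ak <- diag(n)
  for (k in seq_len(n)) {
    Ak <- (Ak %*% A) > 0
    newly <- Ak & !reach & is.infinite(d)
    d[newly] <- k
    reach <- reach | Ak
  }
  d
}

oracle_global_efficiency <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  d <- oracle_shortest_paths(A)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

oracle_char_path <- function(A) {
  d <- oracle_shortest_paths(A)
  off <- d[row(d) != col(d)]
  off <- off[is.finite(off)]
  if (!length(off)) NA_real_ else mean(off)
}

oracle_node_clustering <- function(A, i) {
  nb <- which(A[i, ] > 0)
  k <- length(nb)
  if (k < 2) return(0)
  t <- 0
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      if (A[nb[a], nb[b]] > 0) t <- t + 1
    }
  }
  2 * t / (k * (k - 1))
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(A[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

# ---- RQA from the definitions ---------------------------------------------
oracle_embed <- function(x, tau, m) {
  np <- length(x) - (m - 1) * tau
  E <- matrix(NA_real_, np, m)
  for (k in seq_len(m)) E[, k] <- x[seq_len(np) + (k - 1) * tau]
  E
}

oracle_recurrence_matrix <- function(x, tau, m, eps, theiler) {
  E <- oracle_embed(x, tau, m)
  D <- as.matrix(dist(E))
  R <- (D <= eps) * 1L
  np <- nrow(R)
  band <- abs(row(R) - col(R)) <= theiler
  R[band] <- 0L
  R
}

# All 13 features from a (Theiler-masked) binary matrix, by direct scans.
oracle_rqa_features <- function(R, theiler, lmin = 2, vmin = 2) {
  np <- nrow(R)
  # recurrence rate over admissible upper-triangle cells
  adm <- 0; rec <- 0
  for (i in seq_len(np - 1)) {
    for (j in (i + 1):np) {
      if (j - i > theiler) {
        adm <- adm + 1
        rec <- rec + R[i, j]
      }
    }
  }
  rr <- if (adm > 0) rec / adm else 0
  runs_of <- function(v, val) {
    r <- rle(v)
    r$lengths[r$values == val]
  }
  # diagonal lines (upper-triangle offsets beyond the band)
  dl <- integer(0)
  for (k in (theiler + 1):(np - 1)) {
    i <- seq_len(np - k)
    dl <- c(dl, runs_of(R[cbind(i, i + k)], 1L))
  }
  det <- if (sum(dl) > 0) sum(dl[dl >= lmin]) / sum(dl) else 0
  lmean <- if (any(dl >= lmin)) mean(dl[dl >= lmin]) else 0
  lmax <- if (length(dl)) max(dl) else 0
  ent <- function(lens) {
    if (!length(lens)) return(0)
    p <- table(lens) / length(lens)
    -sum(p * log(p))
  }
  entr <- ent(dl[dl >= lmin])
  # vertical / white / T2 per column over the two admissible segments
  vl <- integer(0); wl <- integer(0); t2 <- integer(0)
  for (j in seq_len(np)) {
    segs <- list(seq_len(max(0, j - theiler - 1)),
                 if (j + theiler + 1 <= np) (j + theiler + 1):np else integer(0))
    for (seg in segs) {
      if (!length(seg)) next
      v <- R[seg, j]
      vl <- c(vl, runs_of(v, 1L))
      recs <- seg[v == 1]
      if (length(recs) >= 2) {
        gaps <- diff(recs) - 1
        wl <- c(wl, gaps[gaps > 0])
      }
      # entries: first points of consecutive runs
      if (length(recs)) {
        entries <- recs[c(TRUE, diff(recs) > 1)]
        if (length(entries) >= 2) t2 <- c(t2, diff(entries))
      }
    }
  }
  lam <- if (sum(vl) > 0) sum(vl[vl >= vmin]) / sum(vl) else 0
  tt <- if (any(vl >= vmin)) mean(vl[vl >= vmin]) else 0
  vmax <- if (length(vl)) max(vl) else 0
  rtmax <- if (length(wl)) max(wl) else 0
  rte <- ent(wl)
  t2m <- if (length(t2)) mean(t2) else 0
  # recurrence network: mean local clustering and transitivity
  cc <- numeric(np); tri2 <- 0; triples <- 0
  for (i in seq_len(np)) {
    cc[i] <- oracle_node_clustering(R, i)
    k <- sum(R[i, ])
    if (k >= 2) {
      ti <- cc[i] * k * (k - 1) / 2
      tri2 <- tri2 + ti
      triples <- triples + k * (k - 1) / 2
    }
  }
  clust <- mean(cc)
  trans <- if (triples > 0) tri2 / triples else 0
  c(RR = rr, DET = det, L = lmean, Lmax = lmax, ENTR = entr, LAM = lam,
    TT = tt, Vmax = vmax, RTmax = rtmax, T2 = t2m, RTE = rte,
    Clust = clust, Trans = trans)
}

# ---- FNN fractions from the Kennel definition ------------------------------
oracle_fnn <- function(x, tau, m_max, rtol = 10, atol = 2, theiler = tau) {
  n <- length(x)
  sdx <- sd(x)
  out <- rep(NA_real_, m_max)
  for (m in seq_len(m_max)) {
    np <- n - m * tau
    if (np < 2 * (theiler + 1)) break
    E <- oracle_embed(x[seq_len(n)], tau, m)[seq_len(np), , drop = FALSE]
    D <- as.matrix(dist(E))
    D[abs(row(D) - col(D)) <= theiler] <- Inf
    fn <- 0; valid <- 0
    for (i in seq_len(np)) {
      j <- which.min(D[i, ])
      dm <- D[i, j]
      if (!is.finite(dm) || dm <= 0) next
      valid <- valid + 1
      extra <- abs(x[i + m * tau] - x[j + m * tau])
      if (extra / dm > rtol || sqrt(dm^2 + extra^2) / sdx > atol) fn <- fn + 1
    }
    out[m] <- if (valid > 0) fn / valid else NA_real_
  }
  out
}

# ---- AMI with equal-width sqrt(N) binning ----------------------------------
oracle_ami <- function(x, lag) {
  n <- length(x)
  nb <- ceiling(sqrt(n))
  brk <- seq(min(x), max(x), length.out = nb + 1)
  b <- cut(x, breaks = brk, include.lowest = TRUE, labels = FALSE)
  a <- b[seq_len(n - lag)]
  bb <- b[seq_len(n - lag) + lag]
  jt <- table(a, bb) / (n - lag)
  pa <- rowSums(jt); pb <- colSums(jt)
  mi <- 0
  for (i in seq_len(nrow(jt))) {
    for (j in seq_len(ncol(jt))) {
      if (jt[i, j] > 0) mi <- mi + jt[i, j] * log(jt[i, j] / (pa[i] * pb[j]))
    }
  }
  mi
}

# ---- DeLong components by explicit loops -----------------------------------
oracle_delong <- function(sa, sb, y) {
  pos <- which(y == 1); neg <- which(y == 0)
  m <- length(pos); n <- length(neg)
  comp <- lapply(list(sa, sb), function(s) {
    P <- matrix(0, m, n)
    for (i in seq_len(m)) {
      for (j in seq_len(n)) {
        P[i, j] <- if (s[pos[i]] > s[neg[j]]) 1 else if (s[pos[i]] == s[neg[j]]) 0.5 else 0
      }
    }
    list(auc = mean(P), v10 = rowMeans(P), v01 = colMeans(P))
  })
  s10 <- cov(cbind(comp[[1]]$v10, comp[[2]]$v10))
  s01 <- cov(cbind(comp[[1]]$v01, comp[[2]]$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  z <- (comp[[1]]$auc - comp[[2]]$auc) / sqrt(var_diff)
  list(auc_a = comp[[1]]$auc, auc_b = comp[[2]]$auc, z = z,
       p = 2 * pnorm(-abs(z)))
}

# ---- signed-rank permutation oracle ----------------------------------------
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  total <- 0; extreme <- 0
  for (mask in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(mask))[seq_len(n)]
    vv <- sum(r[signs == 1])
    total <- total + 1
    if (abs(vv - mu) >= abs(v - mu) - 1e-12) extreme <- extreme + 1
  }
  extreme / total
}

# ---- convenient small graph fixtures ---------------------------------------
make_binary_graph <- function(A, sparsity = NA_real_) {
  structure(list(adjacency = A, sparsity = sparsity,
                 n_edges = sum(A) / 2),
            class = "binary_graph")
}

random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  ut <- which(upper.tri(A))
  A[ut] <- rbinom(length(ut), 1, p)
  A + t(A)
}

# ---- chaotic test signals --------------------------------------------------
henon_series <- function(n, burn = 200) {
  x <- numeric(n + burn); y <- numeric(n + burn)
  x[1] <- 0.1; y[1] <- 0.1
  for (i in 2:(n + burn)) {
    x[i] <- 1 - 1.4 * x[i - 1]^2 + y[i - 1]
    y[i] <- 0.3 * x[i - 1]
  }
  x[(burn + 1):(burn + n)]
}

lorenz_series <- function(n, dt = 0.02, burn = 200) {
  f <- function(t, y, p) list(c(10 * (y[2] - y[1]),
                                y[1] * (28 - y[3]) - y[2],
                                y[1] * y[2] - 8 / 3 * y[3]))
  sol <- deSolve::ode(c(1, 1, 20), seq(0, (n + burn) * dt, by = dt), f, NULL)
  as.numeric(sol[(burn + 1):(burn + n), 2])
}

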