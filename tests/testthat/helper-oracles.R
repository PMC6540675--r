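# Independent oracle implementations, deliberately written from the
# published formulas rather than by calling package internals.

# Weir & Cockerham (1984) a/b/c components computed directly from the
# definitional sums for one locus; pop_alleles is a list of n_i x 2
# matrices.
oracle_wc <- function(pop_alleles) {
  r <- length(pop_alleles)
  ni <- vapply(pop_alleles, nrow, 1L)
  nbar <- mean(ni)
  nc <- if (r > 1) (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1) else NA
  alleles <- sort(unique(unlist(pop_alleles)))
  A <- B <- C <- 0
  for (al in alleles) {
    p <- vapply(pop_alleles, function(m) sum(m == al) / (2 * nrow(m)), 1)
    h <- vapply(pop_alleles, function(m)
      sum((m[, 1] == al) + (m[, 2] == al) == 1) / nrow(m), 1)
    pbar <- sum(ni * p) / sum(ni)
    hbar <- sum(ni * h) / sum(ni)
    s2 <- if (r > 1) sum(ni * (p - pbar)^2) / ((r - 1) * nbar) else 0
    term <- pbar * (1 - pbar) - if (r > 1) (r - 1) / r * s2 else 0
    if (r > 1)
      A <- A + nbar / nc *
        (s2 - (term - hbar / 4) / (nbar - 1))
    B <- B + nbar / (nbar - 1) *
      (term - (2 * nbar - 1) / (4 * nbar) * hbar)
    C <- C + hbar / 2
  }
  list(a = A, b = B, c = C,
       theta = A / (A + B + C), f = 1 - C / (B + C))
}

# Jost's Dest for two demes at one locus via the Nei-Chesser unbiased
# estimators, written out longhand.
oracle_dest_locus <- function(m1, m2) {
  n1 <- nrow(m1); n2 <- nrow(m2)
  alleles <- sort(unique(c(m1, m2)))
  p1 <- vapply(alleles, function(al) sum(m1 == al) / (2 * n1), 1)
  p2 <- vapply(alleles, function(al) sum(m2 == al) / (2 * n2), 1)
  ho <- (sum(m1[, 1] != m1[, 2]) + sum(m2[, 1] != m2[, 2])) / (n1 + n2)
  nh <- 2 / (1 / n1 + 1 / n2)
  hs <- 1 - (sum(p1^2) + sum(p2^2)) / 2
  ht <- 1 - sum(((p1 + p2) / 2)^2)
  hs_est <- nh / (nh - 1) * (hs - ho / (2 * nh))
  ht_est <- ht + hs_est / (4 * nh)
  (ht_est - hs_est) / (1 - hs_est) * 2
}

# AMOVA Phi-ST from first principles: sums of squared distances about
# group centroids in the metric where d_ij plays the squared distance.
oracle_phist <- function(d, pops) {
  N <- nrow(d); grp <- unique(pops); k <- length(grp)
  sst <- sum(d[upper.tri(d)]) / N
  ssw <- 0; nk <- numeric(k)
  for (i in seq_len(k)) {
    sel <- pops == grp[i]; nk[i] <- sum(sel)
    dg <- d[sel, sel, drop = FALSE]
    ssw <- ssw + sum(dg[upper.tri(dg)]) / nk[i]
  }
  msa <- (sst - ssw) / (k - 1)
  msw <- ssw / (N - k)
  n0 <- (N - sum(nk^2) / N) / (k - 1)
  va <- (msa - msw) / n0
  va / (va + msw)
}

# Tajima's D from the published constants, recomputed symbol by symbol.
oracle_tajima_d <- function(S, kbar, n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (kbar - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# Exact unsigned Stirling numbers of the first kind (doubles; fine for
# the small n used in tests) and the Ewens-distribution Fu's Fs.
oracle_stirling <- function(n) {
  S <- matrix(0, n, n); S[1, 1] <- 1
  if (n > 1) for (m in 2:n) {
    S[m, 1] <- (m - 1) * S[m - 1, 1]
    for (k in 2:m) S[m, k] <- (m - 1) * S[m - 1, k] + S[m - 1, k - 1]
  }
  S[n, ]
}

oracle_fu_fs <- function(n, theta, H_obs) {
  sn <- oracle_stirling(n)
  probs <- sn * theta^seq_len(n) / prod(theta + 0:(n - 1))
  sprime <- sum(probs[H_obs:n])
  log(sprime / (1 - sprime))
}

# Composite-likelihood LD statistic via direct numerical maximization
# over the gamete-frequency simplex (softmax parametrization), not EM.
oracle_ld_lr <- function(ga, gb) {
  aa <- sort(unique(c(ga))); bb <- sort(unique(c(gb)))
  ia <- matrix(match(ga, aa), ncol = 2)
  ib <- matrix(match(gb, bb), ncol = 2)
  ka <- length(aa); kb <- length(bb)
  loglik <- function(h) {
    sum(vapply(seq_len(nrow(ia)), function(i) {
      x <- ia[i, 1]; y <- ia[i, 2]; u <- ib[i, 1]; v <- ib[i, 2]
      p1 <- h[x, u] * h[y, v] * ifelse(x != y | u != v, 2, 1)
      p2 <- if (x == y || u == v) 0 else h[x, v] * h[y, u] * 2
      log(p1 + p2)
    }, 1))
  }
  obj <- function(par) {
    w <- exp(c(0, par))
    -loglik(matrix(w / sum(w), ka, kb))
  }
  n <- nrow(ia)
  pa <- tabulate(c(ia), ka) / (2 * n)
  pb <- tabulate(c(ib), kb) / (2 * n)
  h0 <- outer(pa, pb)
  init <- log(pmax(c(h0), 1e-6)); init <- init[-1] - init[1]
  opt <- stats::optim(init, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-12))
  2 * (-opt$value - loglik(h0))
}
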