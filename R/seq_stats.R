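# Mitochondrial sequence diversity and neutrality statistics.

# Mean pairwise nucleotide differences of a haplotype spectrum.
mean_pairwise_diff <- function(spec) {
  n <- spec$n
  if (n < 2) stop("need >= 2 sequences")
  cnt <- rowSums(spec$counts)
  H <- length(spec$haplotypes)
  if (H == 1) return(0)
  tot <- 0
  for (i in seq_len(H - 1)) for (j in (i + 1):H) {
    tot <- tot + cnt[i] * cnt[j] * hap_dist(spec$haplotypes[i],
                                            spec$haplotypes[j])
  }
  tot / (n * (n - 1) / 2)
}

#' Sequence diversity summary
#'
#' Haplotype diversity `h = n/(n-1) (1 - sum p_i^2)` with its sampling
#' standard deviation (Nei 1987), and nucleotide diversity `pi` = mean
#' pairwise nucleotide differences per site, with its sampling SD.
#'
#' @param spec a [collapse_haplotypes()] spectrum.
#' @param L alignment length in sites used to scale `pi` (defaults to the
#'   original alignment length recorded in the spectrum).
#' @return object of class `seq_diversity` with `n`, `H`, `S`, `h`,
#'   `h_sd`, `pi`, `pi_sd`, `kbar`.
#' @export
seq_diversity <- function(spec, L = spec$L_original) {
  n <- spec$n
  if (n < 2) stop("need >= 2 sequences")
  cnt <- rowSums(spec$counts)
  p <- cnt / n
  sp2 <- sum(p^2)
  h <- n / (n - 1) * (1 - sp2)
  hvar <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - sp2^2) + sp2 - sp2^2)
  kbar <- mean_pairwise_diff(spec)
  pi <- kbar / L
  pivar <- (n + 1) / (3 * (n - 1)) * pi / L +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  structure(list(n = n, H = length(spec$haplotypes),
                 S = length(spec$seg_sites),
                 h = h, h_sd = sqrt(max(0, hvar)),
                 pi = pi, pi_sd = sqrt(max(0, pivar)),
                 kbar = kbar, L = L),
            class = "seq_diversity")
}

#' @export
print.seq_diversity <- function(x, ...) {
  cat(sprintf("n = %d, H = %d, S = %d\n", x$n, x$H, x$S))
  cat(sprintf("h  = %.4f (SD %.4f)\n", x$h, x$h_sd))
  cat(sprintf("pi = %.5f (SD %.5f) over %d sites\n", x$pi, x$pi_sd, x$L))
  invisible(x)
}

# Tajima's D from S, mean pairwise differences and sample size.
tajima_d_from <- function(S, kbar, n) {
  if (S < 1) return(NaN)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (kbar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Tajima's D
#'
#' @param spec a [collapse_haplotypes()] spectrum.
#' @param n sample size (defaults to the spectrum's).
#' @return the statistic; `NaN` with attribute `undefined` when `S = 0`.
#' @export
tajima_d <- function(spec, n = spec$n) {
  S <- length(spec$seg_sites)
  if (S == 0) {
    out <- NaN; attr(out, "undefined") <- TRUE
    return(out)
  }
  tajima_d_from(S, mean_pairwise_diff(spec), n)
}

# --- unsigned Stirling numbers of the first kind -------------------------

.stirling_cache <- new.env(parent = emptyenv())

# Exact (double precision) triangular table, rows 1..n; safe for n <= 60
# where the largest entry (n-1)! is far below double overflow.
stirling_exact <- function(n) {
  key <- paste0("exact", n)
  if (!is.null(.stirling_cache[[key]])) return(.stirling_cache[[key]])
  S <- matrix(0, n, n)
  S[1, 1] <- 1
  if (n > 1) for (m in 2:n) {
    S[m, 1] <- (m - 1) * S[m - 1, 1]
    for (k in 2:m)
      S[m, k] <- (m - 1) * S[m - 1, k] + S[m - 1, k - 1]
  }
  .stirling_cache[[key]] <- S
  S
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# Log-domain table for arbitrary n (cached up to n = 200 on first use).
stirling_log <- function(n) {
  key <- paste0("log", n)
  if (!is.null(.stirling_cache[[key]])) return(.stirling_cache[[key]])
  S <- matrix(-Inf, n, n)
  S[1, 1] <- 0
  if (n > 1) for (m in 2:n) {
    S[m, 1] <- log(m - 1) + S[m - 1, 1]
    for (k in 2:m) {
      t1 <- log(m - 1) + S[m - 1, k]
      t2 <- S[m - 1, k - 1]
      S[m, k] <- if (t1 == -Inf) t2
      else if (t2 == -Inf) t1
      else max(t1, t2) + log1p(exp(-abs(t1 - t2)))
    }
  }
  .stirling_cache[[key]] <- S
  S
}

# log P(K = k) terms of the Ewens sampling distribution for theta, n:
# |S(n,k)| theta^k / theta_(n) with theta_(n) the rising factorial.
ewens_log_terms <- function(n, theta, exact = n <= 60) {
  lrise <- sum(log(theta + 0:(n - 1)))
  lS <- if (exact) log(stirling_exact(n)[n, ]) else stirling_log(n)[n, ]
  lS + seq_len(n) * log(theta) - lrise
}

#' Fu's Fs
#'
#' `S' = P(K >= H_obs | theta = kbar, n)` under the Ewens sampling
#' distribution (unsigned Stirling numbers of the first kind), and
#' `Fs = ln(S' / (1 - S'))`.  Evaluated in log-domain so it is stable for
#' large samples; a direct exact path is used for `n <= 60`.
#'
#' @param spec a [collapse_haplotypes()] spectrum (or `NULL` if `kbar`,
#'   `H_obs` given directly).
#' @param n sample size.
#' @param kbar mean pairwise differences (defaults from `spec`).
#' @param H_obs observed haplotype count (defaults from `spec`).
#' @return the statistic; `NaN` (undefined) if `kbar = 0`; `Inf`/`-Inf`
#'   with attribute `boundary` when S' is numerically 0 or 1.
#' @export
fu_fs <- function(spec = NULL, n = spec$n,
                  kbar = mean_pairwise_diff(spec),
                  H_obs = length(spec$haplotypes)) {
  if (kbar <= 0) {
    out <- NaN; attr(out, "undefined") <- TRUE
    return(out)
  }
  lt <- ewens_log_terms(n, kbar)
  upper <- logsumexp(lt[H_obs:n])
  lower <- if (H_obs > 1) logsumexp(lt[seq_len(H_obs - 1)]) else -Inf
  if (lower == -Inf) {
    out <- Inf; attr(out, "boundary") <- TRUE
    return(out)
  }
  if (upper == -Inf) {
    out <- -Inf; attr(out, "boundary") <- TRUE
    return(out)
  }
  upper - lower
}

#' Neutrality tests with a simulated constant-size null
#'
#' Simulates `n_null` constant-size coalescent samples conditioned on
#' `theta = kbar` of the observed data (infinite-sites mutations) and
#' reports one-sided lower-tail p-values for Tajima's D and Fu's Fs
#' (negative values indicate expansion; the conventional significance
#' threshold for Fs is 0.02).  A two-sided option is available for D.
#'
#' @param spec a [collapse_haplotypes()] spectrum.
#' @param n sample size (defaults from the spectrum).
#' @param n_null number of null samples (>= 100; the field convention is
#'   1e5).
#' @param seed optional integer seed.
#' @param alternative `"less"` (default, expansion) or `"two.sided"` for D.
#' @return object of class `neutrality_stats`: `tajima_d`, `fu_fs`, `p_d`,
#'   `p_fs`, `n_null`.
#' @export
neutrality_pvalues <- function(spec, n = spec$n, n_null = 1e5, seed = NULL,
                               alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_null < 100) stop("n_null must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  obs_d <- tajima_d(spec, n)
  kbar <- mean_pairwise_diff(spec)
  obs_fs <- fu_fs(spec, n)
  if (kbar <= 0) {
    return(structure(list(tajima_d = obs_d, fu_fs = obs_fs,
                          p_d = NA_real_, p_fs = NA_real_, n_null = n_null),
                     class = "neutrality_stats"))
  }
  null <- .sim_infsites_cpp(as.integer(n), kbar, as.integer(n_null))
  null_d <- tajima_d_from_vec(null[, "S"], null[, "kbar"], n)
  ok_d <- !is.nan(null_d)
  p_d <- if (is.nan(obs_d)) NA_real_ else {
    if (alternative == "less")
      (1 + sum(null_d[ok_d] <= obs_d)) / (1 + sum(ok_d))
    else {
      p1 <- (1 + sum(null_d[ok_d] <= obs_d)) / (1 + sum(ok_d))
      p2 <- (1 + sum(null_d[ok_d] >= obs_d)) / (1 + sum(ok_d))
      min(1, 2 * min(p1, p2))
    }
  }
  ok_fs <- null[, "kbar"] > 0
  null_fs <- vapply(which(ok_fs), function(r)
    as.numeric(fu_fs(NULL, n = n, kbar = null[r, "kbar"],
                     H_obs = null[r, "H"])), 1)
  p_fs <- if (!is.finite(obs_fs)) NA_real_
  else (1 + sum(null_fs <= obs_fs)) / (1 + sum(ok_fs))
  structure(list(tajima_d = obs_d, fu_fs = obs_fs, p_d = p_d, p_fs = p_fs,
                 n_null = n_null),
            class = "neutrality_stats")
}

# vectorized Tajima's D over replicate (S, kbar) pairs
tajima_d_from_vec <- function(S, kbar, n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  out <- (kbar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  out[S < 1] <- NaN
  out
}

#' @export
print.neutrality_stats <- function(x, ...) {
  cat(sprintf("Tajima's D = %.3f (p = %s)\n", x$tajima_d,
              format(x$p_d, digits = 3)))
  cat(sprintf("Fu's Fs    = %.3f (p = %s; significance threshold 0.02)\n",
              x$fu_fs, format(x$p_fs, digits = 3)))
  cat(sprintf("null: %d constant-size coalescent samples\n", x$n_null))
  invisible(x)
}
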