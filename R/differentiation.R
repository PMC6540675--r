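# Pairwise population differentiation: Weir-Cockerham theta, Jost's Dest,
# AMOVA Phi-ST, permutation significance and FDR correction.

#' Pairwise Weir--Cockerham FST (theta)
#'
#' Variance components are summed over alleles and loci before forming the
#' ratio.  The estimator may be slightly negative; values are reported as
#' computed.
#'
#' @param g a [genotype_matrix()].
#' @param popA,popB population labels.
#' @return theta estimate; `NaN` with attribute `undefined` if no shared
#'   polymorphic locus exists.
#' @export
pairwise_fst <- function(g, popA, popB) {
  comp <- wc_components(g, c(popA, popB))
  den <- comp$a + comp$b + comp$c
  if (comp$n_polymorphic == 0L || den == 0) {
    out <- NaN; attr(out, "undefined") <- TRUE
    return(out)
  }
  comp$a / den
}

#' Pairwise Jost's Dest
#'
#' Per locus `Dest = [(HT - HS)/(1 - HS)] * n/(n-1)` with `n = 2` demes and
#' the Nei--Chesser (1983) unbiased estimators of HS and HT; the multilocus
#' value is by default the arithmetic mean over polymorphic loci, with a
#' harmonic-mean alternative.
#'
#' @inheritParams pairwise_fst
#' @param combine `"arithmetic"` (default) or `"harmonic"` mean over loci.
#' @return Dest estimate.
#' @export
pairwise_dest <- function(g, popA, popB,
                          combine = c("arithmetic", "harmonic")) {
  combine <- match.arg(combine)
  vals <- numeric()
  for (l in seq_along(g$loci)) {
    ms <- lapply(c(popA, popB), function(p) {
      m <- g$calls[g$population == p, l, , drop = FALSE][, 1, ]
      if (is.null(dim(m))) m <- matrix(m, 1)
      m[!is.na(m[, 1]), , drop = FALSE]
    })
    ni <- vapply(ms, nrow, 1L)
    if (any(ni < 1)) next
    alleles <- sort(unique(c(ms[[1]], ms[[2]])))
    if (length(alleles) < 2) next
    p1 <- tabulate(match(c(ms[[1]]), alleles), length(alleles)) / (2 * ni[1])
    p2 <- tabulate(match(c(ms[[2]]), alleles), length(alleles)) / (2 * ni[2])
    ho <- mean(c(ms[[1]][, 1] != ms[[1]][, 2], ms[[2]][, 1] != ms[[2]][, 2]))
    nh <- 2 / (1 / ni[1] + 1 / ni[2])      # harmonic mean sample size
    hs <- 1 - mean(c(sum(p1^2), sum(p2^2)))
    pbar <- (p1 + p2) / 2
    ht <- 1 - sum(pbar^2)
    hs_est <- (nh / (nh - 1)) * (hs - ho / (2 * nh))
    ht_est <- ht + hs_est / (4 * nh)
    if (hs_est >= 1) next                 # degenerate locus, skip with flag
    vals <- c(vals, (ht_est - hs_est) / (1 - hs_est) * 2)
  }
  if (!length(vals)) {
    out <- NaN; attr(out, "undefined") <- TRUE
    return(out)
  }
  if (combine == "arithmetic") mean(vals)
  else 1 / mean(1 / pmax(vals, .Machine$double.eps))
}

#' Pairwise AMOVA Phi-ST for sequence data
#'
#' Analysis of molecular variance on the matrix of pairwise nucleotide
#' differences (pairwise deletion of ambiguous sites by default);
#' `PhiST = sigma2_among / (sigma2_among + sigma2_within)`.
#'
#' @param aln a [dna_alignment()].
#' @param popA,popB population labels.
#' @param deletion `"pairwise"` (default) or `"complete"` handling of
#'   ambiguous sites in the distance computation.
#' @return PhiST estimate; 0 with attribute `monomorphic` when all
#'   sequences are identical.
#' @export
pairwise_phist <- function(aln, popA, popB,
                           deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  idx <- aln$population %in% c(popA, popB)
  seqs <- unname(aln$seq[idx])
  pops <- unname(aln$population[idx])
  if (sum(pops == popA) < 2 || sum(pops == popB) < 2)
    stop("need >= 2 sequences per population")
  d <- seq_diff_matrix(seqs, deletion)
  phist_from_dist(d, pops)
}

# Phi-ST from a squared-distance matrix and group labels (two or more
# groups).  The count of nucleotide differences plays the role of the
# squared Euclidean distance, as in standard molecular AMOVA.
phist_from_dist <- function(d, pops) {
  if (all(d == 0)) {
    out <- 0; attr(out, "monomorphic") <- TRUE
    return(out)
  }
  N <- nrow(d)
  grp <- unique(pops)
  k <- length(grp)
  ss_total <- sum(d[upper.tri(d)]) / N
  ss_within <- 0
  nk <- numeric(k)
  for (gi in seq_len(k)) {
    sel <- pops == grp[gi]
    nk[gi] <- sum(sel)
    dg <- d[sel, sel, drop = FALSE]
    ss_within <- ss_within + sum(dg[upper.tri(dg)]) / nk[gi]
  }
  ss_among <- ss_total - ss_within
  df_among <- k - 1
  df_within <- N - k
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n0 <- (N - sum(nk^2) / N) / (k - 1)
  s2_within <- ms_within
  # negative among-group variance components are truncated at zero
  s2_among <- max(0, (ms_among - ms_within) / n0)
  denom <- s2_among + s2_within
  if (denom <= 0) return(0)
  s2_among / denom
}

#' Permutation p-value for a pairwise differentiation metric
#'
#' Individuals (genotype data) or sequences are permuted between the two
#' populations, holding sample sizes fixed; `p = (1 + #perm >= obs) /
#' (1 + n_perm)`.
#'
#' @param metric_fn one of [pairwise_fst()], [pairwise_dest()],
#'   [pairwise_phist()] or any function with the same signature.
#' @param data a [genotype_matrix()] or [dna_alignment()].
#' @param popA,popB population labels.
#' @param n_perm permutations (default 10000).
#' @param seed optional integer seed.
#' @return list with `value`, `p`, `n_perm`.
#' @export
permutation_pvalue <- function(metric_fn, data, popA, popB,
                               n_perm = 10000, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  obs <- metric_fn(data, popA, popB)
  if (is.nan(obs)) stop("metric undefined on observed data")
  idx <- which(data$population %in% c(popA, popB))
  labels <- data$population[idx]
  exceed <- 0L
  n_undef <- 0L
  for (b in seq_len(n_perm)) {
    perm <- data
    perm$population[idx] <- sample(labels)
    v <- metric_fn(perm, popA, popB)
    if (is.nan(v)) { n_undef <- n_undef + 1L; next }
    if (v >= obs - 1e-12) exceed <- exceed + 1L
  }
  if (n_undef > 0.1 * n_perm)
    stop("metric undefined on more than 10% of permutations")
  list(value = as.numeric(obs), p = (1 + exceed) / (1 + n_perm),
       n_perm = n_perm)
}

#' Benjamini--Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with enforced monotonicity (wrapper around
#' `stats::p.adjust`).
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return adjusted vector of the same length.
#' @export
fdr_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  stats::p.adjust(pvalues, method = "BH")
}

#' All pairwise differentiation values with permutation significance
#'
#' Computes the chosen metric for every population pair, permutation
#' p-values, and FDR-adjusted p-values (the FDR family is all pairs of one
#' metric on one dataset).
#'
#' @param data a [genotype_matrix()] (`metric` `"fst"`/`"dest"`) or
#'   [dna_alignment()] (`"phist"`).
#' @param metric `"fst"`, `"dest"` or `"phist"`.
#' @param n_perm permutations per pair.
#' @param seed optional integer seed.
#' @return data frame of class `differentiation_result` with columns
#'   `popA`, `popB`, `metric`, `value`, `p_raw`, `p_fdr`, `n_perm`.
#' @export
pairwise_differentiation <- function(data, metric = c("fst", "dest", "phist"),
                                     n_perm = 10000, seed = NULL) {
  metric <- match.arg(metric)
  if (!is.null(seed)) set.seed(seed)
  fn <- switch(metric, fst = pairwise_fst, dest = pairwise_dest,
               phist = pairwise_phist)
  pops <- unique(unname(data$population))
  prs <- utils::combn(pops, 2)
  res <- data.frame(popA = prs[1, ], popB = prs[2, ], metric = metric,
                    value = NA_real_, p_raw = NA_real_, p_fdr = NA_real_,
                    n_perm = n_perm, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(prs))) {
    pv <- permutation_pvalue(fn, data, prs[1, i], prs[2, i], n_perm)
    res$value[i] <- pv$value
    res$p_raw[i] <- pv$p
  }
  res$p_fdr <- fdr_adjust(res$p_raw)
  class(res) <- c("differentiation_result", "data.frame")
  res
}

#' Render a differentiation result as a square matrix
#'
#' Values in the lower triangle, p-values (FDR-adjusted) in the upper
#' triangle; negative estimates are clipped at 0 for display only.
#'
#' @param res a result of [pairwise_differentiation()].
#' @return numeric matrix.
#' @export
differentiation_matrix <- function(res) {
  pops <- unique(c(res$popA, res$popB))
  m <- matrix(NA_real_, length(pops), length(pops),
              dimnames = list(pops, pops))
  for (i in seq_len(nrow(res))) {
    m[res$popB[i], res$popA[i]] <- max(0, res$value[i])
    m[res$popA[i], res$popB[i]] <- res$p_fdr[i]
  }
  m
}
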