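# Weir & Cockerham (1984) variance components and per-population
# microsatellite diversity.

# Per-locus, per-allele WC84 components a (among populations), b (among
# individuals within populations), c (within individuals).  `pop_calls` is
# a list with one n_i x 2 allele matrix per population (rows with NA are
# ignored).  With a single population the among-population terms vanish
# and only b and c are meaningful.
wc_components_locus <- function(pop_calls) {
  pop_calls <- lapply(pop_calls, function(m) m[!is.na(m[, 1]), , drop = FALSE])
  pop_calls <- pop_calls[vapply(pop_calls, nrow, 1L) > 0L]
  r <- length(pop_calls)
  if (!r) return(NULL)
  alleles <- sort(unique(unlist(pop_calls)))
  if (length(alleles) < 2L)
    return(list(a = 0, b = 0, c = 0, monomorphic = TRUE))
  ni <- vapply(pop_calls, nrow, 1L)
  nbar <- mean(ni)
  if (nbar <= 1) return(NULL)
  nc <- if (r > 1) (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1) else NA_real_
  a_tot <- b_tot <- c_tot <- 0
  for (al in alleles) {
    p_i <- vapply(pop_calls, function(m) mean(m == al), 1)
    h_i <- vapply(pop_calls, function(m)
      mean((m[, 1] == al) != (m[, 2] == al)), 1)
    pbar <- sum(ni * p_i) / (r * nbar)
    hbar <- sum(ni * h_i) / (r * nbar)
    s2 <- if (r > 1) sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar) else 0
    rfrac <- if (r > 1) (r - 1) / r else 0
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - rfrac * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a <- if (r > 1)
      (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                       (pbar * (1 - pbar) - rfrac * s2 - hbar / 4))
    else 0
    a_tot <- a_tot + a; b_tot <- b_tot + b; c_tot <- c_tot + cc
  }
  list(a = a_tot, b = b_tot, c = c_tot, monomorphic = FALSE)
}

# Sum WC84 components over loci for a genotype matrix restricted to the
# given populations (NULL = all).
wc_components <- function(g, pops = NULL) {
  if (is.null(pops)) pops <- unique(g$population)
  idx <- lapply(pops, function(p) which(g$population == p))
  a <- b <- cc <- 0
  n_poly <- 0L
  for (l in seq_along(g$loci)) {
    pc <- lapply(idx, function(ii) g$calls[ii, l, , drop = FALSE][, 1, ])
    pc <- lapply(pc, function(m) if (is.null(dim(m))) matrix(m, 1) else m)
    comp <- wc_components_locus(pc)
    if (is.null(comp)) next
    if (!comp$monomorphic) n_poly <- n_poly + 1L
    a <- a + comp$a; b <- b + comp$b; cc <- cc + comp$c
  }
  list(a = a, b = b, c = cc, n_polymorphic = n_poly)
}

#' Multilocus inbreeding coefficient (Weir--Cockerham f)
#'
#' Variance components are summed over alleles and loci before the ratio
#' is formed, following Weir & Cockerham (1984).
#'
#' @param g a [genotype_matrix()].
#' @param pop population label.
#' @return FIS estimate; `NaN` with attribute `undefined = TRUE` when no
#'   locus is polymorphic in the population.
#' @export
fis_multilocus <- function(g, pop) {
  comp <- wc_components(subset_pops(g, pop), pop)
  den <- comp$b + comp$c
  if (comp$n_polymorphic == 0L || den == 0) {
    out <- NaN
    attr(out, "undefined") <- TRUE
    return(out)
  }
  1 - comp$c / den
}

# Fast single-locus b and c sums (r = 1) for permutation testing:
# `am` is an n x 2 allele matrix without missing rows.
fis_bc_locus <- function(am) {
  n <- nrow(am)
  alleles <- sort.int(unique(c(am)))
  k <- length(alleles)
  if (n < 2 || k < 2) return(NULL)
  i1 <- match(am[, 1], alleles); i2 <- match(am[, 2], alleles)
  p <- (tabulate(i1, k) + tabulate(i2, k)) / (2 * n)
  het <- i1 != i2
  hbar <- (tabulate(i1[het], k) + tabulate(i2[het], k)) / n
  c(b = (n / (n - 1)) * sum(p * (1 - p) - (2 * n - 1) / (4 * n) * hbar),
    c = sum(hbar) / 2)
}

fis_locus_fast <- function(am) {
  bc <- fis_bc_locus(am)
  if (is.null(bc) || sum(bc) == 0) return(NA_real_)
  unname(1 - bc[2] / sum(bc))
}

subset_pops <- function(g, pops) {
  idx <- which(g$population %in% pops)
  if (!length(idx)) stop("population not found: ", paste(pops, collapse = ","))
  genotype_matrix(g$calls[idx, , , drop = FALSE], g$individuals[idx],
                  g$loci, g$population[idx])
}

# Rarefied allelic richness for one locus: counts is the named allele
# count vector, N the number of sampled gene copies, g the rarefied
# number of copies.
rarefied_richness <- function(counts, N, g) {
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Per-population microsatellite diversity
#'
#' Mean number of alleles, observed heterozygosity, Nei (1978) unbiased
#' expected heterozygosity, multilocus Weir--Cockerham FIS, and rarefied
#' allelic richness `Ar(g)` and private allelic richness `Arp(g)` at `g`
#' gene copies.  Rarefaction follows the hypergeometric formula
#' `Ar(g) = sum_i [1 - C(N - N_i, g)/C(N, g)]`; private richness is the
#' expected number of alleles present in a rarefied sample of the focal
#' population and absent from rarefied samples of every other population.
#' Loci at which any population has fewer than `g` non-missing gene copies
#' are dropped from the Ar/Arp means (locus-matched across populations).
#'
#' @param g a [genotype_matrix()].
#' @param pop focal population label.
#' @param rarefaction_g number of gene copies to rarefy to (>= 2).
#' @return an object of class `diversity_stats`.
#' @export
diversity_stats <- function(g, pop, rarefaction_g = 16) {
  if (rarefaction_g < 2) stop("rarefaction_g must be >= 2")
  if (!pop %in% g$population) stop("population not found: ", pop)
  pops <- unique(g$population)
  L <- length(g$loci)
  per <- data.frame(locus = g$loci, n = NA_integer_, Na = NA_real_,
                    Ho = NA_real_, He = NA_real_, Ar = NA_real_,
                    Arp = NA_real_, stringsAsFactors = FALSE)
  skipped <- character()
  for (l in seq_len(L)) {
    # allele counts per population at this locus
    cnts <- lapply(pops, function(p) {
      m <- g$calls[g$population == p, l, , drop = FALSE][, 1, ]
      if (is.null(dim(m))) m <- matrix(m, 1)
      m <- m[!is.na(m[, 1]), , drop = FALSE]
      table(factor(c(m), levels = sort(unique(c(g$calls[, l, ])))))
    })
    names(cnts) <- pops
    am <- g$calls[g$population == pop, l, , drop = FALSE][, 1, ]
    if (is.null(dim(am))) am <- matrix(am, 1)
    am <- am[!is.na(am[, 1]), , drop = FALSE]
    n <- nrow(am)
    if (n == 0) { skipped <- c(skipped, g$loci[l]); next }
    per$n[l] <- n
    focal <- cnts[[pop]]
    focal <- focal[focal > 0]
    per$Na[l] <- length(focal)
    per$Ho[l] <- mean(am[, 1] != am[, 2])
    p2 <- sum((focal / (2 * n))^2)
    per$He[l] <- 2 * n / (2 * n - 1) * (1 - p2)
    Ns <- vapply(cnts, sum, 1)
    if (all(Ns >= rarefaction_g)) {
      per$Ar[l] <- rarefied_richness(as.numeric(focal), Ns[[pop]],
                                     rarefaction_g)
      # private richness: allele in rarefied focal sample, absent from
      # rarefied samples of all other populations
      all_alleles <- names(cnts[[1]])
      arp <- 0
      for (al in all_alleles) {
        nfoc <- as.numeric(cnts[[pop]][al])
        if (nfoc == 0) next
        pres <- 1 - exp(lchoose(Ns[[pop]] - nfoc, rarefaction_g) -
                          lchoose(Ns[[pop]], rarefaction_g))
        abs_other <- 1
        for (q in setdiff(pops, pop)) {
          nq <- as.numeric(cnts[[q]][al])
          abs_other <- abs_other *
            exp(lchoose(Ns[[q]] - nq, rarefaction_g) -
                  lchoose(Ns[[q]], rarefaction_g))
        }
        arp <- arp + pres * abs_other
      }
      per$Arp[l] <- arp
    } else {
      skipped <- c(skipped, g$loci[l])
    }
  }
  if (length(skipped))
    warning("loci dropped from rarefied means (insufficient gene copies): ",
            paste(unique(skipped), collapse = ", "))
  fis <- fis_multilocus(g, pop)
  se <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
  }
  structure(list(
    population = pop,
    n = sum(g$population == pop),
    rarefaction_g = rarefaction_g,
    per_locus = per,
    Na = mean(per$Na, na.rm = TRUE),
    Ho = mean(per$Ho, na.rm = TRUE),
    He = mean(per$He, na.rm = TRUE),
    Ar = mean(per$Ar, na.rm = TRUE),
    Arp = mean(per$Arp, na.rm = TRUE),
    FIS = fis,
    se = c(Na = se(per$Na), Ho = se(per$Ho), He = se(per$He),
           Ar = se(per$Ar), Arp = se(per$Arp))
  ), class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf("Population %s: N = %d, %d loci (rarefied to g = %d copies)\n",
              x$population, x$n, nrow(x$per_locus), x$rarefaction_g))
  cat(sprintf("  Na = %.2f  Ho = %.3f  He = %.3f  FIS = %.3f\n",
              x$Na, x$Ho, x$He, x$FIS))
  cat(sprintf("  Ar(%d) = %.2f (%.2f)  Arp(%d) = %.2f (%.2f)\n",
              x$rarefaction_g, x$Ar, x$se[["Ar"]],
              x$rarefaction_g, x$Arp, x$se[["Arp"]]))
  invisible(x)
}

#' Permutation test for Hardy--Weinberg equilibrium
#'
#' The null distribution is generated by shuffling the pooled alleles of a
#' population among its individuals at each locus; the statistic is the
#' absolute Weir--Cockerham f.  P-values use the add-one estimator
#' `(1 + #permuted >= observed) / (1 + n_perm)`.  Monomorphic loci have
#' p = 1 by convention.
#'
#' @param g a [genotype_matrix()].
#' @param pop population label.
#' @param n_perm number of permutations (default 5000).
#' @param seed optional integer seed.
#' @return list with `per_locus` (data frame: locus, fis, p) and `overall`
#'   (multilocus |FIS| p-value).
#' @export
hwe_test <- function(g, pop, n_perm = 5000, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sub <- pop_subset(g, pop)
  L <- length(g$loci)
  locus_mats <- lapply(seq_len(L), function(l) {
    m <- sub$calls[, l, , drop = FALSE][, 1, ]
    if (is.null(dim(m))) m <- matrix(m, 1)
    m[!is.na(m[, 1]), , drop = FALSE]
  })
  obs_f <- vapply(locus_mats, fis_locus_fast, 1)
  poly <- !is.na(obs_f)
  # multilocus observed FIS
  ml_fis <- fis_multilocus(g, pop)
  exceed <- integer(L)
  exceed_ml <- 0L
  for (b in seq_len(n_perm)) {
    cperm <- bperm <- 0
    for (l in seq_len(L)) {
      if (!poly[l]) next
      m <- locus_mats[[l]]
      shuffled <- matrix(sample(c(m)), ncol = 2)
      bc <- fis_bc_locus(shuffled)
      if (is.null(bc)) next
      if (sum(bc) != 0) {
        f <- 1 - bc[2] / sum(bc)
        if (abs(f) >= abs(obs_f[l]) - 1e-12)
          exceed[l] <- exceed[l] + 1L
      }
      bperm <- bperm + bc[1]; cperm <- cperm + bc[2]
    }
    if (!is.nan(ml_fis) && (bperm + cperm) != 0) {
      fml <- 1 - cperm / (bperm + cperm)
      if (abs(fml) >= abs(ml_fis) - 1e-12) exceed_ml <- exceed_ml + 1L
    }
  }
  p <- ifelse(poly, (1 + exceed) / (1 + n_perm), 1)
  list(per_locus = data.frame(locus = g$loci, fis = obs_f, p = p,
                              stringsAsFactors = FALSE),
       overall = if (is.nan(ml_fis)) 1 else (1 + exceed_ml) / (1 + n_perm),
       fis = ml_fis, n_perm = n_perm)
}

# EM estimation of two-locus gametic frequencies with unknown phase.
# ga, gb: n x 2 allele matrices (complete cases).  Returns haplotype
# frequency matrix, log-likelihoods under association and independence,
# and convergence flag.
em_gametes <- function(ga, gb, max_iter = 1000, tol = 1e-8) {
  aa <- sort(unique(c(ga))); bb <- sort(unique(c(gb)))
  ka <- length(aa); kb <- length(bb)
  ia <- matrix(match(ga, aa), ncol = 2)
  ib <- matrix(match(gb, bb), ncol = 2)
  n <- nrow(ia)
  pa <- tabulate(c(ia), ka) / (2 * n)
  pb <- tabulate(c(ib), kb) / (2 * n)
  # group identical two-locus genotypes
  key <- paste(pmin(ia[, 1], ia[, 2]), pmax(ia[, 1], ia[, 2]),
               pmin(ib[, 1], ib[, 2]), pmax(ib[, 1], ib[, 2]))
  grp <- table(key)
  gkey <- do.call(rbind, lapply(strsplit(names(grp), " "), as.integer))
  w <- as.numeric(grp)
  lik_terms <- function(h) {
    # for each genotype class: the two phase resolutions and their probs
    x <- gkey[, 1]; y <- gkey[, 2]; u <- gkey[, 3]; v <- gkey[, 4]
    p1 <- h[cbind(x, u)] * h[cbind(y, v)] *
      ifelse(x != y | u != v, 2, 1)
    same_phase <- (x == y) | (u == v)   # phases coincide
    p2 <- ifelse(same_phase, 0, h[cbind(x, v)] * h[cbind(y, u)] * 2)
    cbind(p1, p2)
  }
  h <- outer(pa, pb)
  ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    pt <- lik_terms(h)
    tot <- pt[, 1] + pt[, 2]
    ll <- sum(w * log(tot))
    # E-step: expected gamete counts
    cnt <- matrix(0, ka, kb)
    w1 <- w * pt[, 1] / tot
    w2 <- w * pt[, 2] / tot
    for (cl in seq_len(nrow(gkey))) {
      x <- gkey[cl, 1]; y <- gkey[cl, 2]; u <- gkey[cl, 3]; v <- gkey[cl, 4]
      cnt[x, u] <- cnt[x, u] + w1[cl]
      cnt[y, v] <- cnt[y, v] + w1[cl]
      if (w2[cl] > 0) {
        cnt[x, v] <- cnt[x, v] + w2[cl]
        cnt[y, u] <- cnt[y, u] + w2[cl]
      }
    }
    h <- cnt / (2 * n)
    if (abs(ll - ll_old) < tol) { converged <- TRUE; ll_old <- ll; break }
    ll_old <- ll
  }
  h0 <- outer(pa, pb)
  pt0 <- lik_terms(h0)
  ll0 <- sum(w * log(pt0[, 1] + pt0[, 2]))
  list(h = h, loglik = ll_old, loglik0 = ll0,
       lr = 2 * (ll_old - ll0), converged = converged)
}

#' Likelihood-ratio permutation test for linkage disequilibrium
#'
#' Compares EM-estimated two-locus gametic frequencies (phase unknown)
#' against the product of single-locus allele frequencies; the null
#' distribution is generated by permuting the second locus' genotypes
#' among individuals.
#'
#' @param g a [genotype_matrix()].
#' @param pop population label.
#' @param locus_pair character or integer vector of length 2.
#' @param n_perm permutations (default 10000).
#' @param seed optional integer seed.
#' @return list with `lr` (observed statistic), `p`, `converged`, `n_perm`.
#' @export
ld_test <- function(g, pop, locus_pair, n_perm = 10000, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.character(locus_pair)) locus_pair <- match(locus_pair, g$loci)
  if (length(locus_pair) != 2 || anyNA(locus_pair))
    stop("locus_pair must name two loci present in the data")
  sub <- pop_subset(g, pop)
  ga <- sub$calls[, locus_pair[1], , drop = FALSE][, 1, ]
  gb <- sub$calls[, locus_pair[2], , drop = FALSE][, 1, ]
  if (is.null(dim(ga))) ga <- matrix(ga, 1)
  if (is.null(dim(gb))) gb <- matrix(gb, 1)
  ok <- !is.na(ga[, 1]) & !is.na(gb[, 1])
  ga <- ga[ok, , drop = FALSE]; gb <- gb[ok, , drop = FALSE]
  if (length(unique(c(ga))) < 2 || length(unique(c(gb))) < 2)
    stop("both loci must be polymorphic in the population")
  obs <- em_gametes(ga, gb)
  n <- nrow(ga)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- em_gametes(ga, gb[sample.int(n), , drop = FALSE])
    if (perm$lr >= obs$lr - 1e-9) exceed <- exceed + 1L
  }
  list(lr = obs$lr, p = (1 + exceed) / (1 + n_perm),
       converged = obs$converged, n_perm = n_perm)
}
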