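# Small in-code fixtures shared across test files.

# Genotype matrix from a list of populations, each a list of individuals,
# each a list of c(a1, a2) calls per locus (NA for missing).
toy_genotypes <- function(pops, loci = NULL) {
  inds <- list(); labels <- character()
  for (p in names(pops)) {
    for (ind in pops[[p]]) {
      inds[[length(inds) + 1L]] <- ind
      labels <- c(labels, p)
    }
  }
  L <- length(inds[[1]])
  if (is.null(loci)) loci <- sprintf("L%02d", seq_len(L))
  calls <- array(NA_integer_, c(length(inds), L, 2))
  for (i in seq_along(inds))
    for (l in seq_len(L)) calls[i, l, ] <- inds[[i]][[l]]
  genotype_matrix(calls, sprintf("i%02d", seq_along(inds)), loci, labels)
}

# Alignment from named sequence vector and parallel population labels.
toy_alignment <- function(seqs, pops) {
  dna_alignment(seqs, pops, ids = paste0("s", seq_along(seqs)))
}

# Hardy-Weinberg genotypes: n individuals, one locus, alleles drawn iid
# from `freqs` (named allele states).
panmictic_genotypes <- function(n, freqs, n_loci = 1) {
  states <- as.integer(names(freqs))
  calls <- array(NA_integer_, c(n, n_loci, 2))
  for (l in seq_len(n_loci)) {
    calls[, l, 1] <- sample(states, n, TRUE, prob = freqs)
    calls[, l, 2] <- sample(states, n, TRUE, prob = freqs)
  }
  genotype_matrix(calls, sprintf("i%03d", seq_len(n)),
                  sprintf("L%02d", seq_len(n_loci)), rep("P1", n))
}

# A deterministic two-haplotype spectrum: counts c1:c2, differing at one
# site, in an alignment of length L.
two_hap_spectrum <- function(c1, c2, L = 2452) {
  base <- strrep("A", L)
  alt <- paste0("T", strrep("A", L - 1))
  aln <- toy_alignment(c(rep(base, c1), rep(alt, c2)),
                       rep("P1", c1 + c2))
  collapse_haplotypes(aln)
}
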