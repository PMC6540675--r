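fixed_diff_genotypes <- function(n_per = 8) {
  toy_genotypes(list(
    P1 = replicate(n_per, list(c(10L, 10L)), simplify = FALSE),
    P2 = replicate(n_per, list(c(12L, 12L)), simplify = FALSE)))
}

test_that("FST boundary identities and the WC84 oracle", {
  expect_equal(pairwise_fst(fixed_diff_genotypes(), "P1", "P2"), 1)

  # identical allele-frequency compositions -> theta ~ 0
  ind_list <- c(replicate(20, list(c(1L, 1L)), simplify = FALSE),
                replicate(20, list(c(1L, 2L)), simplify = FALSE),
                replicate(10, list(c(2L, 2L)), simplify = FALSE))
  g0 <- toy_genotypes(list(P1 = ind_list, P2 = ind_list))
  expect_lt(abs(pairwise_fst(g0, "P1", "P2")), 0.02)

  # toy 2-pop x 4-individual table vs direct variance-component oracle
  p1 <- list(list(c(1L, 1L)), list(c(1L, 2L)), list(c(2L, 2L)),
             list(c(1L, 2L)))
  p2 <- list(list(c(1L, 2L)), list(c(2L, 2L)), list(c(2L, 2L)),
             list(c(2L, 3L)))
  g <- toy_genotypes(list(P1 = p1, P2 = p2))
  m1 <- do.call(rbind, lapply(p1, `[[`, 1))
  m2 <- do.call(rbind, lapply(p2, `[[`, 1))
  expect_equal(pairwise_fst(g, "P1", "P2"),
               oracle_wc(list(m1, m2))$theta, tolerance = 1e-12)

  # symmetry
  expect_equal(pairwise_fst(g, "P1", "P2"), pairwise_fst(g, "P2", "P1"))
})

test_that("Jost's Dest: boundaries, oracle, symmetry", {
  expect_equal(pairwise_dest(fixed_diff_genotypes(), "P1", "P2"), 1)

  ind_list <- c(replicate(10, list(c(1L, 2L)), simplify = FALSE),
                replicate(10, list(c(1L, 1L)), simplify = FALSE))
  g0 <- toy_genotypes(list(P1 = ind_list, P2 = ind_list))
  expect_lt(abs(pairwise_dest(g0, "P1", "P2")), 0.03)

  p1 <- list(list(c(1L, 1L)), list(c(1L, 2L)), list(c(2L, 2L)),
             list(c(1L, 1L)))
  p2 <- list(list(c(2L, 2L)), list(c(2L, 3L)), list(c(3L, 3L)),
             list(c(2L, 3L)))
  g <- toy_genotypes(list(P1 = p1, P2 = p2))
  m1 <- do.call(rbind, lapply(p1, `[[`, 1))
  m2 <- do.call(rbind, lapply(p2, `[[`, 1))
  expect_equal(pairwise_dest(g, "P1", "P2"), oracle_dest_locus(m1, m2),
               tolerance = 1e-12)
  expect_equal(pairwise_dest(g, "P1", "P2"), pairwise_dest(g, "P2", "P1"))
})

test_that("Phi-ST: boundaries and the AMOVA sums-of-squares oracle", {
  # identical haplotype compositions in both populations -> 0
  seqs <- c("AAAA", "AATA", "AAAA", "AAAA", "AATA", "AAAA")
  pops <- c("P1", "P1", "P1", "P2", "P2", "P2")
  expect_equal(pairwise_phist(toy_alignment(seqs, pops), "P1", "P2"), 0,
               tolerance = 1e-12)

  # fixed different haplotypes -> 1
  seqs2 <- c(rep("AAAA", 3), rep("TTAA", 3))
  expect_equal(pairwise_phist(toy_alignment(seqs2, pops), "P1", "P2"), 1)

  # 3+3 toy set vs direct oracle
  seqs3 <- c("AAAA", "AATA", "ACTA", "TTAA", "TTAC", "TAAA")
  aln <- toy_alignment(seqs3, pops)
  d <- outer(seqs3, seqs3, Vectorize(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])))
  expect_equal(pairwise_phist(aln, "P1", "P2"),
               oracle_phist(d, pops), tolerance = 1e-12)

  # every within- and between-distance equal -> 0
  seqs4 <- c("AAAA", "TAAA", "CAAA", "GAAA")
  aln4 <- toy_alignment(seqs4, c("P1", "P1", "P2", "P2"))
  expect_equal(pairwise_phist(aln4, "P1", "P2"), 0, tolerance = 1e-12)
})

test_that("permutation p-values: bounds, determinism, degenerate obs", {
  g <- fixed_diff_genotypes(8)
  pv <- permutation_pvalue(pairwise_fst, g, "P1", "P2", n_perm = 400,
                           seed = 5)
  expect_equal(pv$value, 1)
  expect_lte(pv$p, 3 / 401)     # near the attainable minimum 1/401

  pv2 <- permutation_pvalue(pairwise_fst, g, "P1", "P2", n_perm = 400,
                            seed = 5)
  expect_identical(pv, pv2)

  # observed at the null centre -> large p
  ind_list <- c(replicate(6, list(c(1L, 1L)), simplify = FALSE),
                replicate(6, list(c(1L, 2L)), simplify = FALSE))
  g0 <- toy_genotypes(list(P1 = ind_list, P2 = ind_list))
  pv0 <- permutation_pvalue(pairwise_fst, g0, "P1", "P2", n_perm = 200,
                            seed = 6)
  expect_gte(pv0$p, 0.5)
})

test_that("FDR adjustment follows the step-up rule", {
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_identical(fdr_adjust(numeric(0)), numeric(0))
})

test_that("pairwise tables carry values, p-values and FDR per matrix", {
  set.seed(10)
  fx <- make_multipop_fixture(sizes = c(A = 6, B = 6, C = 6),
                              seq_sizes = c(A = 4, B = 4, C = 4),
                              panmixia = FALSE,
                              params = c(N0 = 2000, mu_msat = 5e-4,
                                         p_geom = 0.2, mu_seq = 5e-8),
                              seed = 12, n_loci = 4, L = 300)
  res <- pairwise_differentiation(fx$genotypes, "fst", n_perm = 50,
                                  seed = 1)
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_raw > 0 & res$p_raw <= 1))
  expect_equal(res$p_fdr, fdr_adjust(res$p_raw))
  m <- differentiation_matrix(res)
  expect_true(all(m[lower.tri(m)] >= 0))   # display clipping
})
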