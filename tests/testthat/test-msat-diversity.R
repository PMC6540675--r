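test_that("diversity indices on monomorphic and simple loci", {
  g <- toy_genotypes(list(P1 = replicate(8, list(c(10L, 10L)),
                                         simplify = FALSE)))
  ds <- diversity_stats(g, "P1", rarefaction_g = 4)
  expect_equal(ds$Na, 1)
  expect_equal(ds$Ho, 0)
  expect_equal(ds$He, 0)
  expect_equal(ds$Ar, 1)

  # 8 diploids, allele counts {10: 12, 12: 4}; g = 16 copies = all -> Ar = Na
  inds <- c(replicate(4, list(c(10L, 10L)), simplify = FALSE),
            replicate(2, list(c(10L, 12L)), simplify = FALSE),
            replicate(2, list(c(12L, 12L)), simplify = FALSE))
  g2 <- toy_genotypes(list(P1 = inds))
  ds2 <- diversity_stats(g2, "P1", rarefaction_g = 16)
  expect_equal(ds2$Ar, 2)
  expect_equal(ds2$Na, 2)
})

test_that("rarefied richness matches the exact hypergeometric evaluation", {
  # counts {A: 3, B: 1} in 2 diploids, g = 2:
  # Ar(2) = [1 - C(1,2)/C(4,2)] + [1 - C(3,2)/C(4,2)] = 1 + 0.5 = 1.5
  g <- toy_genotypes(list(P1 = list(list(c(10L, 10L)),
                                    list(c(10L, 12L)))))
  ds <- diversity_stats(g, "P1", rarefaction_g = 2)
  expect_equal(ds$Ar, 1.5)

  # Ar(g) non-decreasing in g, and Ar(total copies) = Na exactly
  set.seed(42)
  fx <- make_fixture(7, params = c(N0 = 3000), preset = "desk", seed = 5)
  ar <- vapply(c(2, 6, 12, 20, 30, 60), function(gg)
    diversity_stats(fx$genotypes, "RUN", rarefaction_g = gg)$Ar, 1)
  expect_true(all(diff(ar) >= -1e-12))
  ds_full <- diversity_stats(fx$genotypes, "RUN", rarefaction_g = 60)
  expect_equal(ds_full$Ar, ds_full$Na)

  expect_error(diversity_stats(fx$genotypes, "RUN", rarefaction_g = 1),
               ">= 2")
})

test_that("private allelic richness is bounded and private-only", {
  # P1 carries a private allele 14; P2 does not
  g <- toy_genotypes(list(
    P1 = list(list(c(10L, 14L)), list(c(10L, 10L))),
    P2 = list(list(c(10L, 12L)), list(c(12L, 12L)))))
  ds1 <- diversity_stats(g, "P1", rarefaction_g = 2)
  ds2 <- diversity_stats(g, "P2", rarefaction_g = 2)
  expect_true(ds1$Arp > 0)
  expect_lte(ds1$Arp, ds1$Ar)
  expect_lte(ds2$Arp, ds2$Ar)
  # an allele shared by all populations contributes little privateness
  gshared <- toy_genotypes(list(
    P1 = list(list(c(10L, 10L)), list(c(10L, 12L))),
    P2 = list(list(c(10L, 10L)), list(c(10L, 12L)))))
  dsh <- diversity_stats(gshared, "P1", rarefaction_g = 2)
  expect_lt(dsh$Arp, 0.5)
})

test_that("multilocus FIS hits the boundary cases and the WC84 oracle", {
  # all heterozygous A/B -> FIS = -1
  ghet <- toy_genotypes(list(P1 = replicate(6, list(c(1L, 2L)),
                                            simplify = FALSE)))
  expect_equal(fis_multilocus(ghet, "P1"), -1)

  # half AA, half BB -> FIS = 1
  ghom <- toy_genotypes(list(P1 = c(replicate(3, list(c(1L, 1L)),
                                              simplify = FALSE),
                                    replicate(3, list(c(2L, 2L)),
                                              simplify = FALSE))))
  expect_equal(fis_multilocus(ghom, "P1"), 1)

  # monomorphic data -> undefined
  gmono <- toy_genotypes(list(P1 = replicate(4, list(c(5L, 5L)),
                                             simplify = FALSE)))
  expect_true(is.nan(fis_multilocus(gmono, "P1")))

  # mixed 6-diploid, 2-locus table against the direct WC84 evaluation
  inds <- list(list(c(1L, 1L), c(3L, 4L)),
               list(c(1L, 2L), c(3L, 3L)),
               list(c(2L, 2L), c(4L, 4L)),
               list(c(1L, 2L), c(3L, 4L)),
               list(c(1L, 1L), c(3L, 5L)),
               list(c(2L, 3L), c(5L, 5L)))
  g <- toy_genotypes(list(P1 = inds))
  m1 <- do.call(rbind, lapply(inds, function(x) x[[1]]))
  m2 <- do.call(rbind, lapply(inds, function(x) x[[2]]))
  o1 <- oracle_wc(list(m1)); o2 <- oracle_wc(list(m2))
  expect_equal(fis_multilocus(g, "P1"),
               1 - (o1$c + o2$c) / (o1$b + o2$b + o1$c + o2$c),
               tolerance = 1e-12)
})

test_that("HWE permutation test: conventions and power on inbred data", {
  gmono <- toy_genotypes(list(P1 = replicate(5, list(c(5L, 5L)),
                                             simplify = FALSE)))
  expect_equal(hwe_test(gmono, "P1", n_perm = 50, seed = 1)$per_locus$p, 1)

  ghom <- toy_genotypes(list(P1 = c(replicate(5, list(c(1L, 1L)),
                                              simplify = FALSE),
                                    replicate(5, list(c(2L, 2L)),
                                              simplify = FALSE))))
  hw <- hwe_test(ghom, "P1", n_perm = 2000, seed = 2)
  expect_lte(hw$per_locus$p, 0.01)
  expect_lte(hw$overall, 0.01)

  # seeded reproducibility, bit-exact
  g <- panmictic_genotypes(20, c(`10` = 0.5, `12` = 0.3, `14` = 0.2))
  p1 <- hwe_test(g, "P1", n_perm = 200, seed = 11)
  p2 <- hwe_test(g, "P1", n_perm = 200, seed = 11)
  expect_identical(p1, p2)
})

test_that("LD likelihood-ratio test: oracle, duplication, determinism", {
  # worked 4-individual example: EM equals direct likelihood maximization
  ga <- rbind(c(1L, 2L), c(1L, 1L), c(2L, 2L), c(1L, 2L))
  gb <- rbind(c(3L, 4L), c(3L, 3L), c(4L, 4L), c(3L, 3L))
  g <- toy_genotypes(list(P1 = lapply(seq_len(4), function(i)
    list(ga[i, ], gb[i, ]))))
  fit <- ld_test(g, "P1", c(1, 2), n_perm = 1, seed = 1)
  expect_equal(fit$lr, oracle_ld_lr(ga, gb), tolerance = 1e-4)
  expect_true(fit$converged)

  # two perfectly duplicated loci -> minimal attainable p
  set.seed(8)
  a <- cbind(sample(1:3, 12, TRUE), sample(1:3, 12, TRUE))
  gdup <- toy_genotypes(list(P1 = lapply(seq_len(12), function(i)
    list(a[i, ], a[i, ] + 10L))))
  res <- ld_test(gdup, "P1", c(1, 2), n_perm = 200, seed = 3)
  expect_lte(res$p, 5 / 201)

  res2 <- ld_test(gdup, "P1", c(1, 2), n_perm = 200, seed = 3)
  expect_identical(res, res2)

  gmono <- toy_genotypes(list(P1 = lapply(seq_len(4), function(i)
    list(c(1L, 1L), c(2L, 3L)))))
  expect_error(ld_test(gmono, "P1", c(1, 2), n_perm = 10),
               "polymorphic")
})
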