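test_that("haplotype and nucleotide diversity match the worked example", {
  # n = 8, haplotype counts 6:2, one segregating site, 2,452 sites
  spec <- two_hap_spectrum(6, 2, L = 2452)
  sv <- seq_diversity(spec)
  expect_equal(sv$h, (8 / 7) * (1 - 36 / 64 - 4 / 64))
  expect_equal(round(sv$h, 2), 0.43)
  expect_equal(sv$pi, (6 * 2 / 28) / 2452)
  # exact arithmetic gives 0.000175 at the full 2,452 sites; this agrees
  # with the reported 0.00018 to one unit at the printed precision (the
  # small residual traces to gap-excluded net site counts in the source
  # software)
  expect_equal(round(sv$pi, 6), 0.000175)
  expect_lt(abs(sv$pi - 0.00018), 1e-5)

  # monomorphic sample
  mono <- collapse_haplotypes(toy_alignment(rep("ACGTACGT", 6),
                                            rep("P1", 6)))
  svm <- seq_diversity(mono, L = 8)
  expect_equal(svm$h, 0)
  expect_equal(svm$pi, 0)
  expect_equal(svm$h_sd, 0)

  # two distinct haplotypes at n = 2 -> h = 1
  sv2 <- seq_diversity(two_hap_spectrum(1, 1, L = 100))
  expect_equal(sv2$h, 1)

  expect_error(seq_diversity(collapse_haplotypes(
    toy_alignment("ACGT", "P1"))), ">= 2")
})

test_that("pi agrees between spectrum and raw-alignment computation", {
  set.seed(21)
  fx <- make_fixture(7, params = c(N0 = 5000, mu_seq = 9e-8),
                     preset = "desk", seed = 22)
  spec <- collapse_haplotypes(fx$sequences)
  sv <- seq_diversity(spec)
  d <- gcpop:::seq_diff_matrix(unname(fx$sequences$seq))
  pi_direct <- mean(d[upper.tri(d)]) / fx$sequences$length
  expect_equal(sv$pi, pi_direct, tolerance = 1e-12)
})

test_that("Tajima's D: undefined at S=0, matches the constants oracle, and
           centres near zero under neutrality", {
  mono <- collapse_haplotypes(toy_alignment(rep("AAAA", 5), rep("P1", 5)))
  expect_true(is.nan(tajima_d(mono)))

  # n = 4, haplotypes 2:2 differing at 3 sites
  aln <- toy_alignment(c("AAA", "AAA", "TTT", "TTT"), rep("P1", 4))
  spec <- collapse_haplotypes(aln)
  kbar <- 2 * 2 * 3 / 6
  expect_equal(tajima_d(spec), oracle_tajima_d(3, kbar, 4),
               tolerance = 1e-12)

  # constant-size neutral simulation: mean D within +-0.15 of 0
  set.seed(30)
  null <- gcpop:::.sim_infsites_cpp(30L, 5, 1000L)
  d <- gcpop:::tajima_d_from_vec(null[, "S"], null[, "kbar"], 30)
  expect_lt(abs(mean(d, na.rm = TRUE)), 0.15)
})

test_that("Fu's Fs: boundary, Ewens/Stirling oracle, log-domain path", {
  # a single haplotype gives S' = 1 -> +Inf at the boundary
  fs1 <- fu_fs(NULL, n = 6, kbar = 0.4, H_obs = 1)
  expect_true(is.infinite(fs1) && fs1 > 0)
  expect_true(isTRUE(attr(fs1, "boundary")))

  # kbar = 0 undefined
  expect_true(is.nan(fu_fs(NULL, n = 6, kbar = 0, H_obs = 2)))

  # n = 5, kbar = 1.2, H = 3 against the exact Stirling-table oracle
  expect_equal(as.numeric(fu_fs(NULL, n = 5, kbar = 1.2, H_obs = 3)),
               oracle_fu_fs(5, 1.2, 3), tolerance = 1e-10)

  # exact and log-domain paths agree at n <= 60
  for (n in c(10, 35, 60)) {
    lt_e <- gcpop:::ewens_log_terms(n, 2.5, exact = TRUE)
    lt_l <- gcpop:::ewens_log_terms(n, 2.5, exact = FALSE)
    expect_equal(lt_e, lt_l, tolerance = 1e-9)
  }

  # simulated post-expansion (star-like) samples give negative Fs in the
  # vast majority of replicates
  set.seed(31)
  pars <- c(N0 = 50000, N1 = 50, t2 = 2000, mu_msat = 5e-4,
            p_geom = 0.2, mu_seq = 1e-6)
  neg <- 0; informative <- 0
  for (r in 1:100) {
    sim <- simulate_coalescent(4, pars, n_ind = 1, n_seq = 25,
                               n_loci = 1, L = 800)
    spec <- collapse_haplotypes(sim$sequences)
    fs <- fu_fs(spec)
    if (!is.finite(fs)) next
    informative <- informative + 1
    if (as.numeric(fs) < 0) neg <- neg + 1
  }
  expect_gte(informative, 50)
  expect_gte(neg / informative, 0.9)
})

test_that("neutrality p-values are seeded, one-sided and sane", {
  spec <- two_hap_spectrum(10, 5, L = 500)
  nt1 <- neutrality_pvalues(spec, n_null = 300, seed = 7)
  nt2 <- neutrality_pvalues(spec, n_null = 300, seed = 7)
  expect_identical(nt1, nt2)
  expect_true(nt1$p_d > 0 && nt1$p_d <= 1)
  expect_true(nt1$p_fs > 0 && nt1$p_fs <= 1)

  # monomorphic data: statistics undefined, p NA
  mono <- collapse_haplotypes(toy_alignment(rep("AAAA", 6), rep("P1", 6)))
  ntm <- neutrality_pvalues(mono, n_null = 150, seed = 8)
  expect_true(is.nan(ntm$tajima_d))
  expect_true(is.na(ntm$p_d))
})
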