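test_that("prior draws respect scenario constraints and bounds", {
  set.seed(1)
  d7 <- sample_prior(7)
  expect_equal(unname(d7["N0"]), unname(d7["N1"]))

  draws6 <- t(replicate(2000, sample_prior(6)))
  expect_true(all(draws6[, "Nb"] < pmin(draws6[, "N0"], draws6[, "N1"])))
  expect_true(all(draws6[, "t"] > 5))

  draws2 <- t(replicate(500, sample_prior(2)))
  expect_true(all(draws2[, "t2"] >= 1e3 & draws2[, "t2"] <= 5e5))
  expect_true(all(draws2[, "N0"] < draws2[, "N1"]))
})

test_that("coalescent simulator: degenerate and calibration cases", {
  # a single sampled sequence is monomorphic whatever the demography
  set.seed(2)
  sim <- simulate_coalescent(1, c(N0 = 50, N1 = 9000, t1 = 100,
                                  mu_msat = 1e-3, p_geom = 0.2,
                                  mu_seq = 1e-7),
                             n_ind = 1, n_seq = 1, n_loci = 2, L = 200)
  expect_equal(length(sim$sequences$ids), 1)
  spec <- collapse_haplotypes(sim$sequences)
  expect_equal(length(spec$haplotypes), 1)

  # E[T2] = 2N generations for a diploid locus (M = 2N)
  set.seed(3)
  tm <- gcpop:::.sim_tmrca_cpp(2L, 0, 2 * 1000, 4000L)
  se <- stats::sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2000), 3 * se)

  expect_error(simulate_coalescent(7, c(N0 = 0, mu_msat = 1e-3,
                                        p_geom = 0.2, mu_seq = 1e-7),
                                   1, 2, 1, 100), "zero-size")
})

test_that("summary panel: monomorphic vector, permutation invariance,
           cross-module consistency", {
  g <- toy_genotypes(list(RUN = replicate(5, list(c(20L, 20L)),
                                          simplify = FALSE)))
  aln <- toy_alignment(rep("ACGT", 4), rep("RUN", 4))
  sv <- summarize(g, aln)
  expect_equal(unname(sv),
               c(1, 0, 0, 1, 1, 0, 0, 0, 0, 0))

  set.seed(4)
  fx <- make_fixture(7, params = c(N0 = 6000, mu_seq = 9e-8),
                     preset = "desk", seed = 40)
  sv1 <- summarize(fx$genotypes, fx$sequences)

  # permuting individuals leaves the panel unchanged
  perm <- sample(length(fx$genotypes$individuals))
  gp <- genotype_matrix(fx$genotypes$calls[perm, , , drop = FALSE],
                        fx$genotypes$individuals[perm],
                        fx$genotypes$loci, fx$genotypes$population[perm])
  expect_equal(summarize(gp, fx$sequences), sv1)

  # panel entries equal the module-level statistics computed separately
  ds <- diversity_stats(fx$genotypes, "RUN", rarefaction_g = 2)
  expect_equal(unname(sv1["msat_na"]), ds$Na)
  expect_equal(unname(sv1["msat_he"]), ds$He, tolerance = 1e-12)
  spec <- collapse_haplotypes(fx$sequences)
  sq <- seq_diversity(spec)
  expect_equal(unname(sv1["seq_H"]), as.numeric(sq$H))
  expect_equal(unname(sv1["seq_S"]), as.numeric(sq$S))
  expect_equal(unname(sv1["seq_h"]), sq$h, tolerance = 1e-12)
  expect_equal(unname(sv1["seq_pi"]), sq$pi, tolerance = 1e-12)
  if (sq$S > 0)
    expect_equal(unname(sv1["seq_D"]), as.numeric(tajima_d(spec)),
                 tolerance = 1e-12)
})

test_that("reference table: shape, determinism, normalization, round-trip", {
  t1 <- build_reference_table(n_per_scenario = 100, seed = 99)
  expect_equal(nrow(t1$stats), 700)
  expect_equal(as.integer(table(t1$scenario)), rep(100L, 7))
  expect_true(all(t1$scale > 0))

  t2 <- build_reference_table(n_per_scenario = 100, seed = 99)
  expect_identical(t1$stats, t2$stats)
  expect_identical(t1$params, t2$params)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_reference_table(t1, path)
  t3 <- read_reference_table(path)
  expect_equal(t3$scenario, t1$scenario)
  expect_equal(unname(t3$stats), unname(t1$stats), tolerance = 1e-12)
  expect_equal(t3$config$n_ind, t1$config$n_ind)
})

test_that("scenario choice: degenerate retention, normalization, duplication", {
  tab <- build_reference_table(n_per_scenario = 100, seed = 77)
  obs <- tab$stats[123, ]
  # tolerance retaining a single row: that row's scenario gets direct = 1
  ch1 <- suppressWarnings(choose_scenario(obs, tab,
                                          tolerance_frac = 1 / 700))
  expect_equal(ch1$n_retained, 1)
  expect_equal(ch1$posterior$direct[ch1$posterior$scenario ==
                                      tab$scenario[123]], 1)

  ch <- suppressWarnings(choose_scenario(obs, tab, tolerance_frac = 0.05))
  expect_equal(sum(ch$posterior$direct), 1, tolerance = 1e-9)
  expect_equal(sum(ch$posterior$logistic), 1, tolerance = 1e-9)

  # duplicating every row leaves the posterior unchanged
  tab2 <- tab
  tab2$scenario <- rep(tab$scenario, 2)
  tab2$params <- rbind(tab$params, tab$params)
  tab2$stats <- rbind(tab$stats, tab$stats)
  ch2 <- suppressWarnings(choose_scenario(obs, tab2,
                                          tolerance_frac = 0.05))
  expect_equal(ch2$posterior$direct, ch$posterior$direct)
  # the logistic fit is iterative; duplication changes nothing beyond
  # optimizer noise
  expect_equal(ch2$posterior$logistic, ch$posterior$logistic,
               tolerance = 1e-2)
})

test_that("parameter posterior: identity under zero regressors and
           affine-rescaling invariance", {
  tab <- build_reference_table(n_per_scenario = 150, seed = 55)
  obs <- tab$stats[which(tab$scenario == 6)[10], ]
  pp <- suppressWarnings(estimate_parameters(obs, tab, scenario = 6,
                                             tolerance_frac = 0.5))
  expect_true(all(c("N0", "N1", "Nb", "t") %in% rownames(pp$estimates)))
  est <- pp$estimates
  expect_true(all(est[, "q025"] <= est[, "median"] &
                    est[, "median"] <= est[, "q975"]))
  expect_equal(sum(pp$weights), 1, tolerance = 1e-9)

  # zero regressor: constant statistics -> unadjusted retained quantiles
  tabc <- tab
  tabc$stats[] <- 1
  tabc$scale[] <- 1
  ppc <- suppressWarnings(estimate_parameters(tabc$stats[1, ], tabc,
                                              scenario = 6,
                                              tolerance_frac = 0.5))
  rows <- which(tabc$scenario == 6)
  sel <- rows[seq_len(ceiling(0.5 * length(rows)))]
  vals <- sort(tab$params[sel, "Nb"])
  expected <- vals[which(seq_along(vals) / length(vals) >= 0.5)[1]]
  expect_equal(unname(ppc$estimates["Nb", "median"]), expected,
               tolerance = 1e-6)

  # rescaling the normalization leaves posterior medians invariant
  tabr <- tab
  tabr$scale <- tab$scale * 3
  ppr <- suppressWarnings(estimate_parameters(obs, tab, scenario = 6,
                                              tolerance_frac = 0.5))
  ppr2 <- suppressWarnings(estimate_parameters(obs, tabr, scenario = 6,
                                               tolerance_frac = 0.5))
  expect_equal(ppr2$estimates[, "median"], ppr$estimates[, "median"],
               tolerance = 1e-8)
})

test_that("predictive check flags extremes and reports sane quantiles", {
  tab <- build_reference_table(n_per_scenario = 100, seed = 33)
  obs <- tab$stats[50, ]
  pc <- predictive_check(obs, tab)
  expect_true(all(pc$quantile >= 0 & pc$quantile <= 1))
  expect_lte(sum(pc$flagged), 3)

  far <- obs
  far["msat_na"] <- max(tab$stats[, "msat_na"]) + 10
  pcf <- predictive_check(far, tab)
  expect_true(all(pcf$flagged[pcf$statistic == "msat_na"]))
})

test_that("generation-time conversion", {
  expect_equal(unname(generations_to_years(319)), c(2233, 3190))
  expect_equal(unname(generations_to_years(0)), c(0, 0))
  expect_equal(unname(generations_to_years(500)), c(3500, 5000))
  expect_error(generations_to_years(-1), ">= 0")
})

test_that("the fitted-model interface works end to end", {
  tab <- build_reference_table(n_per_scenario = 150, seed = 88)
  set.seed(5)
  fx <- make_fixture(6, params = c(N0 = 5000, N1 = 5000, Nb = 50,
                                   t = 300),
                     preset = "desk", seed = 50)
  fit <- suppressWarnings(abc_fit(fx$genotypes, fx$sequences, tab))
  expect_s3_class(fit, "gcpop_abc")
  expect_true(fit$choice$selected %in% 1:7)
  expect_true(all(names(coef(fit)) %in%
                    c("N0", "N1", "Nb", "Ne", "t", "t1", "t2")))
  expect_output(print(fit), "Selected scenario")

  # predict on a fresh dataset returns a posterior over all scenarios
  fx2 <- make_fixture(7, params = c(N0 = 2000), preset = "desk",
                      seed = 51)
  pr <- suppressWarnings(predict(fit, list(genotypes = fx2$genotypes,
                                           sequences = fx2$sequences)))
  expect_equal(sum(pr$posterior$logistic), 1, tolerance = 1e-9)

  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_equal(dim(sims), c(3L, 10L))
  expect_true(all(is.finite(sims)))
})
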