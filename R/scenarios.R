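# Seven single-population piecewise-constant demographic scenarios.
#
# Parameters (diploid effective sizes, times in generations before
# present): N0 current size, N1 ancestral size, Nb bottleneck size,
# Ne expansion size, t1 recent change time, t2 ancient change time,
# t onset of the bottleneck/expansion phase (scenarios 5-6, whose recent
# end is fixed at 5 generations before present).
#
#  1  recent decrease:   N0 < N1, change at t1
#  2  ancient decrease:  N0 < N1, change at t2
#  3  recent expansion:  N0 > N1, change at t1
#  4  ancient expansion: N0 > N1, change at t2
#  5  expansion phase:   Ne > N0, Ne > N1; epochs [0,5) N0, [5,t) Ne, N1 after
#  6  bottleneck phase:  Nb < N0, Nb < N1; epochs [0,5) N0, [5,t) Nb, N1 after
#  7  constant size:     N0 = N1

PHASE_END_GEN <- 5   # end of the scenario 5/6 phase, generations ago

#' Default parameter priors for the demographic scenarios
#'
#' Uniform priors: sizes `N0, N1, Nb, Ne ~ U[10, 10000]` diploid
#' individuals; times `t1 ~ U[5, 500]`, `t2 ~ U[1000, 5e5]`,
#' `t ~ U[10, 1000]` generations.  Scenario-specific inequalities are
#' enforced by rejection sampling.  Mutation hyperparameters: mean
#' microsatellite rate `mu_msat ~ U[1e-4, 1e-3]` per locus per generation
#' (per-locus rates Gamma with shape 2 scaled to the mean), geometric step
#' parameter `P ~ U[0.1, 0.3]`, 40 contiguous allele states with
#' reflecting bounds; sequence rate `mu_seq ~ U[1e-8, 1e-7]` per site per
#' generation under HKY85 with `kappa = 10`.
#'
#' @return a named list of `c(min, max)` bounds, usable in
#'   [sample_prior()] and stored with reference tables.
#' @export
default_priors <- function() {
  list(N0 = c(10, 10000), N1 = c(10, 10000), Nb = c(10, 10000),
       Ne = c(10, 10000), t1 = c(5, 500), t2 = c(1000, 5e5),
       t = c(10, 1000),
       mu_msat = c(1e-4, 1e-3), p_geom = c(0.1, 0.3),
       mu_seq = c(1e-8, 1e-7))
}

#' Default mutation model settings
#'
#' Generalized stepwise microsatellite model and HKY85 sequence model.
#'
#' @return named list: `n_states`, `anc_state`, `gamma_shape`, `kappa`,
#'   `base_freq`.
#' @export
default_mutation_model <- function() {
  list(n_states = 40L, anc_state = 20L, gamma_shape = 2,
       kappa = 10, base_freq = c(A = 0.31, C = 0.25, G = 0.13, T = 0.31))
}

# Which parameters a scenario uses.
scenario_params <- function(scenario) {
  switch(as.character(scenario),
         `1` = c("N0", "N1", "t1"),
         `2` = c("N0", "N1", "t2"),
         `3` = c("N0", "N1", "t1"),
         `4` = c("N0", "N1", "t2"),
         `5` = c("N0", "N1", "Ne", "t"),
         `6` = c("N0", "N1", "Nb", "t"),
         `7` = c("N0"),
         stop("scenario must be 1..7"))
}

# Check the scenario inequality constraints; returns TRUE/FALSE or, with
# `why = TRUE`, a character naming the violated constraint (or "").
check_scenario <- function(scenario, pars, why = FALSE) {
  bad <- ""
  if (scenario %in% c(1, 2) && !(pars[["N0"]] < pars[["N1"]]))
    bad <- "N0 < N1"
  if (scenario %in% c(3, 4) && !(pars[["N0"]] > pars[["N1"]]))
    bad <- "N0 > N1"
  if (scenario == 5 &&
      !(pars[["Ne"]] > pars[["N0"]] && pars[["Ne"]] > pars[["N1"]]))
    bad <- "Ne > max(N0, N1)"
  if (scenario == 6 &&
      !(pars[["Nb"]] < pars[["N0"]] && pars[["Nb"]] < pars[["N1"]]))
    bad <- "Nb < min(N0, N1)"
  if (scenario %in% 5:6 && pars[["t"]] <= PHASE_END_GEN)
    bad <- "t > 5"
  if (why) bad else !nzchar(bad)
}

#' Draw scenario parameters from the prior
#'
#' Rejection sampling against the scenario constraints (resample cap
#' 1e6); mutation hyperparameters are drawn alongside the demographic
#' parameters.
#'
#' @param scenario integer 1..7.
#' @param priors bounds as from [default_priors()].
#' @return named numeric vector: the scenario's demographic parameters
#'   plus `mu_msat`, `p_geom`, `mu_seq`.
#' @export
sample_prior <- function(scenario, priors = default_priors()) {
  wanted <- scenario_params(scenario)
  for (att in seq_len(1e6)) {
    pars <- vapply(wanted, function(p)
      stats::runif(1, priors[[p]][1], priors[[p]][2]), 1)
    if (scenario == 7) pars <- c(pars, N1 = unname(pars["N0"]))
    if (check_scenario(scenario, pars)) {
      hyper <- vapply(c("mu_msat", "p_geom", "mu_seq"), function(p)
        stats::runif(1, priors[[p]][1], priors[[p]][2]), 1)
      return(c(pars, hyper))
    }
  }
  stop("prior rejection cap reached; violated constraint: ",
       check_scenario(scenario, pars, why = TRUE))
}

# Backward-in-time epochs (start generation, diploid size N) for a
# scenario and parameter draw.
scenario_epochs <- function(scenario, pars) {
  p <- function(x) unname(pars[[x]])
  switch(as.character(scenario),
         `1` = ,
         `3` = list(start = c(0, p("t1")), N = c(p("N0"), p("N1"))),
         `2` = ,
         `4` = list(start = c(0, p("t2")), N = c(p("N0"), p("N1"))),
         `5` = list(start = c(0, PHASE_END_GEN, p("t")),
                    N = c(p("N0"), p("Ne"), p("N1"))),
         `6` = list(start = c(0, PHASE_END_GEN, p("t")),
                    N = c(p("N0"), p("Nb"), p("N1"))),
         `7` = list(start = 0, N = p("N0")),
         stop("scenario must be 1..7"))
}

#' Simulate a dataset under a demographic scenario
#'
#' Coalescent simulation of unlinked microsatellite loci (independent gene
#' trees on `2 * n_ind` copies, pairwise coalescence rate
#' `C(k,2)/(2N(t))`) and one mtDNA sequence locus (tree on `n_seq` copies
#' with rate `C(k,2)/(N(t)/4)`, reflecting maternal haploid inheritance at
#' even sex ratio).  Microsatellite mutations are Poisson on branches with
#' geometric step sizes reflected at the state-range bounds; sequence
#' mutations are Poisson events under HKY85.
#'
#' @param scenario integer 1..7.
#' @param pars named parameter vector (see [sample_prior()]); must contain
#'   the scenario's demographic parameters and `mu_msat`, `p_geom`,
#'   `mu_seq`.
#' @param n_ind diploid individuals to sample.
#' @param n_seq haploid sequences to sample.
#' @param n_loci microsatellite loci.
#' @param L sequence length (sites).
#' @param model mutation model settings ([default_mutation_model()]).
#' @param pop_label population label for the sampled data.
#' @return list with elements `genotypes` ([genotype_matrix()]) and
#'   `sequences` ([dna_alignment()]).
#' @export
simulate_coalescent <- function(scenario, pars, n_ind, n_seq,
                                n_loci = 27, L = 2452,
                                model = default_mutation_model(),
                                pop_label = "RUN") {
  if (n_ind < 1 || n_seq < 1) stop("sample sizes must be >= 1")
  ep <- scenario_epochs(scenario, pars)
  if (any(ep$N < 1)) stop("zero-size epoch")
  raw <- simulate_raw(ep, pars, n_ind, n_seq, n_loci, L, model)
  # genotypes: consecutive copy pairs form individuals
  calls <- array(NA_integer_, c(n_ind, n_loci, 2))
  for (l in seq_len(n_loci)) {
    al <- raw$msat[, l]
    calls[, l, 1] <- al[seq(1, 2 * n_ind, by = 2)]
    calls[, l, 2] <- al[seq(2, 2 * n_ind, by = 2)]
  }
  ids <- sprintf("ind%03d", seq_len(n_ind))
  g <- genotype_matrix(calls, ids, sprintf("L%02d", seq_len(n_loci)),
                       rep(pop_label, n_ind))
  bases <- c("A", "C", "G", "T")
  seqs <- apply(raw$seq, 1, function(rw) paste(bases[rw + 1], collapse = ""))
  names(seqs) <- sprintf("seq%03d", seq_len(n_seq))
  aln <- dna_alignment(seqs, rep(pop_label, n_seq))
  list(genotypes = g, sequences = aln)
}

# Low-level simulation: returns the msat copy-by-locus matrix and the
# integer base matrix, without container overhead (used by the reference
# table builder).
simulate_raw <- function(ep, pars, n_ind, n_seq, n_loci, L, model) {
  n_copies <- 2L * n_ind
  ep_start <- as.numeric(ep$start)
  msat_M <- 2 * ep$N          # gene copies for an autosomal locus
  seq_M <- ep$N / 4           # maternal haploid equivalent
  mu_loci <- stats::rgamma(n_loci, shape = model$gamma_shape,
                           rate = model$gamma_shape / pars[["mu_msat"]])
  msat <- matrix(NA_integer_, n_copies, n_loci)
  for (l in seq_len(n_loci)) {
    msat[, l] <- .sim_msat_locus_cpp(n_copies, ep_start, msat_M,
                                     mu_loci[l], pars[["p_geom"]],
                                     model$n_states, model$anc_state)
  }
  seqm <- .sim_seq_locus_cpp(as.integer(n_seq), ep_start, seq_M,
                             pars[["mu_seq"]], as.integer(L),
                             model$kappa, as.numeric(model$base_freq))
  list(msat = msat, seq = seqm)
}

#' Convert generations to calendar years
#'
#' Uses the species' generation-time range (default 7--10 years).
#'
#' @param gens generation count (>= 0).
#' @param generation_time_years length-2 range in years.
#' @return named numeric vector `c(min, max)` in years.
#' @export
generations_to_years <- function(gens, generation_time_years = c(7, 10)) {
  if (gens < 0) stop("gens must be >= 0")
  c(min = gens * generation_time_years[1],
    max = gens * generation_time_years[2])
}
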