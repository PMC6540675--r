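# Study-shaped synthetic datasets with known demographic truth.

#' Fixture presets
#'
#' `"run"` mirrors the island sampling configuration the demographic
#' analysis targets: 167 diploid individuals x 27 microsatellite loci and
#' 39 mtDNA sequences of 2,452 sites.  `"desk"` is a small configuration
#' (30 diploids x 10 loci, 15 sequences x 600 sites) for fast runs.
#'
#' @param preset `"run"` or `"desk"`.
#' @return list `n_ind`, `n_loci`, `n_seq`, `L`.
#' @export
fixture_preset <- function(preset = c("desk", "run")) {
  preset <- match.arg(preset)
  if (preset == "run")
    list(n_ind = 167L, n_loci = 27L, n_seq = 39L, L = 2452L)
  else
    list(n_ind = 30L, n_loci = 10L, n_seq = 15L, L = 600L)
}

# Complete a user parameter vector: validate constraints, draw missing
# mutation hyperparameters from the priors.
complete_params <- function(scenario, params, priors) {
  if (is.null(params)) return(sample_prior(scenario, priors))
  params <- unlist(params)
  if (scenario == 7 && !"N1" %in% names(params))
    params <- c(params, N1 = unname(params[["N0"]]))
  need <- scenario_params(scenario)
  miss <- setdiff(need, names(params))
  if (length(miss))
    stop("missing parameter(s) for scenario ", scenario, ": ",
         paste(miss, collapse = ", "))
  bad <- check_scenario(scenario, params, why = TRUE)
  if (nzchar(bad))
    stop("parameters violate scenario ", scenario, " constraint: ", bad)
  for (h in c("mu_msat", "p_geom", "mu_seq"))
    if (!h %in% names(params))
      params <- c(params, stats::setNames(
        stats::runif(1, priors[[h]][1], priors[[h]][2]), h))
  params
}

#' Generate a single-population study fixture with known truth
#'
#' Simulates genotypes and sequences under one demographic scenario and
#' records the generating truth alongside the data, so every downstream
#' analysis can be validated against known parameters.
#'
#' @param scenario integer 1..7.
#' @param params named parameter vector, or `NULL` to draw from the
#'   priors.
#' @param preset `"desk"` or `"run"` (see [fixture_preset()]), or a list
#'   with `n_ind`, `n_loci`, `n_seq`, `L`.
#' @param seed integer seed; the fixture is bit-reproducible from
#'   `(scenario, params, seed)`.
#' @param priors prior bounds used for any drawn parameters.
#' @param model mutation model settings.
#' @param pop_label population label.
#' @return object of class `study_fixture`: `truth`, `genotypes`,
#'   `sequences`.
#' @export
make_fixture <- function(scenario = 7, params = NULL, preset = "desk",
                         seed = 1, priors = default_priors(),
                         model = default_mutation_model(),
                         pop_label = "RUN") {
  cfg <- if (is.list(preset)) preset else fixture_preset(preset)
  set.seed(seed)
  params <- complete_params(scenario, params, priors)
  sim <- simulate_coalescent(scenario, params, cfg$n_ind, cfg$n_seq,
                             cfg$n_loci, cfg$L, model, pop_label)
  structure(list(truth = list(scenario = scenario,
                              params = as.list(params),
                              model = model, seed = seed, config = cfg),
                 genotypes = sim$genotypes,
                 sequences = sim$sequences),
            class = "study_fixture")
}

#' @export
print.study_fixture <- function(x, ...) {
  cat("Study fixture (scenario", x$truth$scenario, ", seed",
      x$truth$seed, ")\n")
  print(x$genotypes)
  print(x$sequences)
  invisible(x)
}

#' Generate a multi-population fixture
#'
#' Under `panmixia = TRUE`, all individuals are drawn from one coalescent
#' population and labelled by sampling location (the regime of a weakly
#' structured species); otherwise each location is an independent
#' population (for differentiation power tests).
#'
#' @param sizes named integer vector of diploid sample sizes per
#'   location; defaults to the study's seven-location configuration.
#' @param seq_sizes named integer vector of sequence sample sizes per
#'   location (default: the mitochondrial sampling of the same seven
#'   locations).
#' @param panmixia logical.
#' @param scenario,params,seed,priors,model as in [make_fixture()].
#' @param n_loci,L marker configuration.
#' @return a `study_fixture` with multi-population labels.
#' @export
make_multipop_fixture <- function(sizes = c(ZAN = 8, SEY = 24, RUN = 167,
                                            SAF = 34, AUS1 = 9, AUS2 = 10,
                                            NCA = 23),
                                  seq_sizes = c(ZAN = 8, SEY = 20,
                                                SAF = 23, RUN = 39,
                                                AUS1 = 9, AUS2 = 10,
                                                NCA = 18),
                                  panmixia = TRUE, scenario = 7,
                                  params = NULL, seed = 1,
                                  priors = default_priors(),
                                  model = default_mutation_model(),
                                  n_loci = 10, L = 600) {
  if (length(sizes) < 2) stop("need >= 2 populations")
  set.seed(seed)
  params <- complete_params(scenario, params, priors)
  pops <- names(sizes)
  if (panmixia) {
    sim <- simulate_coalescent(scenario, params, sum(sizes),
                               sum(seq_sizes), n_loci, L, model, "ALL")
    g <- sim$genotypes
    g$population[] <- rep(pops, sizes)
    aln <- sim$sequences
    aln$population[] <- rep(pops, seq_sizes)
  } else {
    parts <- lapply(pops, function(p)
      simulate_coalescent(scenario, params, sizes[[p]], seq_sizes[[p]],
                          n_loci, L, model, p))
    calls <- do.call(abind3, lapply(parts, function(x) x$genotypes$calls))
    ids <- sprintf("ind%03d", seq_len(sum(sizes)))
    g <- genotype_matrix(calls, ids, parts[[1]]$genotypes$loci,
                         rep(pops, sizes))
    seqs <- unlist(lapply(parts, function(x) unname(x$sequences$seq)))
    names(seqs) <- sprintf("seq%03d", seq_len(sum(seq_sizes)))
    aln <- dna_alignment(seqs, rep(pops, seq_sizes))
  }
  structure(list(truth = list(scenario = scenario,
                              params = as.list(params),
                              model = model, seed = seed,
                              sizes = as.list(sizes),
                              seq_sizes = as.list(seq_sizes),
                              panmixia = panmixia,
                              config = list(n_loci = n_loci, L = L)),
                 genotypes = g, sequences = aln),
            class = "study_fixture")
}

abind3 <- function(...) {
  mats <- list(...)
  n <- sum(vapply(mats, function(m) dim(m)[1], 1L))
  out <- array(NA_integer_, c(n, dim(mats[[1]])[2], 2))
  at <- 0L
  for (m in mats) {
    out[at + seq_len(dim(m)[1]), , ] <- m
    at <- at + dim(m)[1]
  }
  out
}

#' Write a fixture directory
#'
#' Genepop genotypes, FASTA alignment, two-column popmap and a JSON truth
#' record.
#'
#' @param fixture a `study_fixture`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genepop(fixture$genotypes, file.path(dir, "genotypes.gen"))
  write_alignment(fixture$sequences, file.path(dir, "sequences.fasta"),
                  file.path(dir, "popmap.tsv"))
  jsonlite::write_json(fixture$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
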