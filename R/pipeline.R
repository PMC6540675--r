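# End-to-end analysis pipeline: diversity -> differentiation -> network
# -> neutrality -> ABC, from one configuration, with a JSON run manifest.

#' Default pipeline configuration
#'
#' Permutation counts follow the field's standard settings (HWE 5,000;
#' differentiation 10,000; neutrality null 1e5); they can be lowered for
#' quick runs.  Either `input` (paths `genepop`, `fasta`, `popmap`) or
#' `fixture` (arguments to [make_fixture()]) must describe the data.
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(seed = 1,
       out_dir = "gcpop_out",
       input = NULL,
       fixture = list(scenario = 7, preset = "desk"),
       rarefaction_g = 16,
       stages = list(diversity = TRUE, differentiation = TRUE,
                     seqstats = TRUE, network = TRUE, abc = TRUE),
       hwe_perm = 5000,
       diff_perm = 10000,
       neutrality_null = 1e5,
       network_threshold = 0.95,
       abc = list(n_per_scenario = 200, tolerance_frac = 0.01,
                  n_direct = 500))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full analysis pipeline
#'
#' Emits delimited reports (per-population diversity, sequence diversity,
#' pairwise differentiation matrices, neutrality tests, ABC posterior), a
#' GraphML haplotype network and a JSON run manifest.  Every stage draws
#' from a stage-specific seed derived from the run seed, so disabling one
#' stage leaves the others byte-identical.
#'
#' @param config a configuration list (see [default_config()]) or the
#'   path to a YAML file with the same structure.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "gcpop",
                   version = as.character(utils::packageVersion("gcpop")),
                   seed = cfg$seed, config = cfg, stages = list())
  t0 <- Sys.time()

  # --- data -----------------------------------------------------------
  if (!is.null(cfg$input)) {
    g <- read_genepop(cfg$input$genepop,
                      dialect = cfg$input$dialect %||% "genepop")
    aln <- read_alignment(cfg$input$fasta, cfg$input$popmap)
    manifest$inputs <- as.list(tools::md5sum(
      unlist(cfg$input[c("genepop", "fasta", "popmap")])))
  } else {
    fxargs <- cfg$fixture[setdiff(names(cfg$fixture), "seed")]
    fx <- do.call(make_fixture, c(fxargs, list(seed = cfg$seed)))
    g <- fx$genotypes
    aln <- fx$sequences
    manifest$truth <- fx$truth[c("scenario", "params")]
  }
  pops <- unique(unname(g$population))
  spops <- unique(unname(aln$population))

  run_stage <- function(name, offset, fun) {
    if (!isTRUE(cfg$stages[[name]])) {
      manifest$stages[[name]] <<- list(status = "disabled")
      return(invisible(NULL))
    }
    set.seed(stage_seed(cfg$seed, offset))
    st <- Sys.time()
    res <- tryCatch(fun(), error = function(e) e)
    el <- as.numeric(difftime(Sys.time(), st, units = "secs"))
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(res),
                                       seconds = el)
    } else {
      manifest$stages[[name]] <<- list(status = "ok", seconds = el)
    }
  }

  run_stage("diversity", 1L, function() {
    rows <- lapply(pops, function(p) {
      ds <- suppressWarnings(diversity_stats(g, p, cfg$rarefaction_g))
      hw <- hwe_test(g, p, n_perm = cfg$hwe_perm)
      data.frame(population = p, N = ds$n, Na = ds$Na,
                 Ar = ds$Ar, Ar_se = ds$se[["Ar"]],
                 Arp = ds$Arp, Arp_se = ds$se[["Arp"]],
                 Ho = ds$Ho, He = ds$He, FIS = ds$FIS,
                 HWE_p = hw$overall)
    })
    utils::write.csv(do.call(rbind, rows),
                     file.path(cfg$out_dir, "diversity.csv"),
                     row.names = FALSE)
  })

  run_stage("seqstats", 2L, function() {
    rows <- lapply(spops, function(p) {
      sub <- subset_alignment(aln, p)
      if (length(sub$ids) < 2) return(NULL)
      spec <- collapse_haplotypes(sub)
      sv <- seq_diversity(spec, L = aln$length)
      nt <- neutrality_pvalues(spec, n_null = cfg$neutrality_null)
      data.frame(population = p, N = sv$n, H = sv$H, S = sv$S,
                 h = sv$h, h_sd = sv$h_sd, pi = sv$pi, pi_sd = sv$pi_sd,
                 tajima_d = as.numeric(nt$tajima_d), p_d = nt$p_d,
                 fu_fs = as.numeric(nt$fu_fs), p_fs = nt$p_fs)
    })
    utils::write.csv(do.call(rbind, rows),
                     file.path(cfg$out_dir, "seq_diversity.csv"),
                     row.names = FALSE)
  })

  run_stage("differentiation", 3L, function() {
    if (length(pops) > 1) {
      for (metric in c("fst", "dest")) {
        res <- pairwise_differentiation(g, metric, n_perm = cfg$diff_perm)
        utils::write.csv(res, file.path(cfg$out_dir,
                                        paste0(metric, "_pairs.csv")),
                         row.names = FALSE)
        utils::write.csv(differentiation_matrix(res),
                         file.path(cfg$out_dir,
                                   paste0(metric, "_matrix.csv")))
      }
    }
    if (length(spops) > 1 &&
        all(table(aln$population) >= 2)) {
      res <- pairwise_differentiation(aln, "phist",
                                      n_perm = cfg$diff_perm)
      utils::write.csv(res, file.path(cfg$out_dir, "phist_pairs.csv"),
                       row.names = FALSE)
      utils::write.csv(differentiation_matrix(res),
                       file.path(cfg$out_dir, "phist_matrix.csv"))
    }
  })

  run_stage("network", 4L, function() {
    spec <- collapse_haplotypes(aln)
    lim <- parsimony_limit(spec$L, cfg$network_threshold)
    net <- build_network(spec, lim)
    write_network(net, file.path(cfg$out_dir, "network.graphml"))
  })

  run_stage("abc", 5L, function() {
    tab <- build_reference_table(
      n_per_scenario = cfg$abc$n_per_scenario,
      n_ind = length(g$individuals), n_seq = length(aln$ids),
      n_loci = length(g$loci), L = aln$length,
      seed = stage_seed(cfg$seed, 5L))
    # ABC is defined for a single population; use the largest sample
    main_pop <- names(which.max(table(g$population)))
    gg <- subset_pops(g, main_pop)
    aa <- if (main_pop %in% aln$population)
      subset_alignment(aln, main_pop) else aln
    fit <- suppressWarnings(abc_fit(gg, aa, tab,
                                    tolerance_frac = cfg$abc$tolerance_frac,
                                    n_direct = cfg$abc$n_direct))
    utils::write.csv(fit$choice$posterior,
                     file.path(cfg$out_dir, "abc_scenario_posterior.csv"),
                     row.names = FALSE)
    est <- data.frame(parameter = rownames(fit$params$estimates),
                      fit$params$estimates, row.names = NULL)
    utils::write.csv(est, file.path(cfg$out_dir, "abc_parameters.csv"),
                     row.names = FALSE)
    utils::write.csv(fit$check,
                     file.path(cfg$out_dir, "abc_predictive_check.csv"),
                     row.names = FALSE)
  })

  manifest$seconds_total <- as.numeric(difftime(Sys.time(), t0,
                                                units = "secs"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 1299709) %% 2147483647)
}

subset_alignment <- function(aln, pops) {
  keep <- aln$population %in% pops
  dna_alignment(aln$seq[keep], aln$population[keep], aln$ids[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
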