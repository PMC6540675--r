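# Summary statistics and the ABC reference table.

SUMMARY_STAT_NAMES <- c("msat_na", "msat_he", "msat_var", "msat_mratio",
                        "seq_H", "seq_S", "seq_h", "seq_pi", "seq_D",
                        "seq_D_def")

# Panel from raw matrices: msat = copies x loci integer allele states,
# seqm = sequences x sites integer bases (0..3), L = sites.
summarize_raw <- function(msat, seqm, L) {
  n_copies <- nrow(msat)
  per <- apply(msat, 2, function(al) {
    cnt <- tabulate(match(al, unique(al)))
    na <- length(cnt)
    p2 <- sum((cnt / n_copies)^2)
    he <- if (na > 1) n_copies / (n_copies - 1) * (1 - p2) else 0
    v <- if (na > 1) stats::var(al) else 0
    mr <- na / (max(al) - min(al) + 1)
    c(na, he, v, mr)
  })
  msat_panel <- rowMeans(per)
  n <- nrow(seqm)
  var_site <- which(matrixStats_colAnyDiff(seqm))
  if (length(var_site)) {
    sub <- seqm[, var_site, drop = FALSE]
    key <- apply(sub, 1, paste, collapse = ",")
    hcnt <- as.numeric(table(key))
    # mean pairwise differences summed over variable sites
    kbar <- sum(vapply(seq_along(var_site), function(j) {
      cc <- tabulate(match(sub[, j], unique(sub[, j])))
      (n^2 - sum(cc^2)) / 2
    }, 1)) / (n * (n - 1) / 2)
    S <- length(var_site)
  } else {
    hcnt <- n; kbar <- 0; S <- 0
  }
  H <- length(hcnt)
  h <- if (H > 1) n / (n - 1) * (1 - sum((hcnt / n)^2)) else 0
  D <- tajima_d_from(S, kbar, n)
  d_def <- as.numeric(!is.nan(D))
  if (is.nan(D)) D <- 0
  stats::setNames(c(msat_panel, H, S, h, kbar / L, D, d_def),
                  SUMMARY_STAT_NAMES)
}

matrixStats_colAnyDiff <- function(m) {
  if (nrow(m) == 1L) return(rep(FALSE, ncol(m)))
  colSums(m != matrix(m[1, ], nrow(m), ncol(m), byrow = TRUE)) > 0
}

#' Summary-statistic vector for observed data
#'
#' The fixed, ordered panel used throughout the ABC machinery:
#' microsatellites -- mean allele number, mean unbiased expected
#' heterozygosity, mean allele-size variance, mean M-ratio
#' (Garza--Williamson, `alleles / (allele range + 1)`); sequences --
#' haplotype count H, segregating sites S, haplotype diversity h,
#' nucleotide diversity pi, Tajima's D (imputed as 0 with an appended
#' 0/1 indicator when undefined at S = 0).
#'
#' @param g a [genotype_matrix()] (one population).
#' @param aln a [dna_alignment()] (same population).
#' @return named numeric vector of length 10.
#' @export
summarize <- function(g, aln) {
  n_ind <- length(g$individuals)
  msat <- rbind(matrix(g$calls[, , 1], nrow = n_ind),
                matrix(g$calls[, , 2], nrow = n_ind))
  if (anyNA(msat)) stop("summary panel requires complete genotype data")
  mat <- do.call(rbind, strsplit(unname(aln$seq), ""))
  bases <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  if (any(!mat %in% names(bases)))
    stop("summary panel requires unambiguous sequence data")
  seqm <- matrix(bases[mat], nrow(mat))
  summarize_raw(msat, seqm, aln$length)
}

#' Build an ABC reference table
#'
#' Simulates `n_per_scenario` datasets per scenario with parameters drawn
#' from the priors, computes the summary panel for each, and records
#' per-statistic robust scales (median absolute deviation over all rows)
#' used to normalize distances.  Rows are generated in seeded chunks of
#' 1000 so serial and chunk-parallel execution give identical tables.
#'
#' @param scenarios integer vector of scenario ids (default 1:7).
#' @param priors prior bounds ([default_priors()]).
#' @param model mutation model ([default_mutation_model()]).
#' @param n_per_scenario simulations per scenario (>= 100).
#' @param n_ind,n_seq,n_loci,L sampling configuration (defaults: the
#'   desk preset 30 diploids x 10 loci, 15 sequences x 600 sites).
#' @param seed integer seed governing the whole table.
#' @param progress print per-scenario progress.
#' @return object of class `abc_reftable`.
#' @export
build_reference_table <- function(scenarios = 1:7,
                                  priors = default_priors(),
                                  model = default_mutation_model(),
                                  n_per_scenario = 1000,
                                  n_ind = 30, n_seq = 15,
                                  n_loci = 10, L = 600,
                                  seed = 1, progress = FALSE) {
  if (n_per_scenario < 100) stop("n_per_scenario must be >= 100")
  chunk_size <- 1000L
  par_names <- c("N0", "N1", "Nb", "Ne", "t", "t1", "t2",
                 "mu_msat", "p_geom", "mu_seq")
  n_total <- length(scenarios) * n_per_scenario
  stats_mat <- matrix(NA_real_, n_total, length(SUMMARY_STAT_NAMES),
                      dimnames = list(NULL, SUMMARY_STAT_NAMES))
  par_mat <- matrix(NA_real_, n_total, length(par_names),
                    dimnames = list(NULL, par_names))
  scen_vec <- integer(n_total)
  row <- 0L
  for (sc in scenarios) {
    n_chunks <- ceiling(n_per_scenario / chunk_size)
    done <- 0L
    for (ch in seq_len(n_chunks)) {
      set.seed(chunk_seed(seed, sc, ch))
      m <- min(chunk_size, n_per_scenario - done)
      for (i in seq_len(m)) {
        rec <- simulate_table_row(sc, priors, model, n_ind, n_seq,
                                  n_loci, L)
        row <- row + 1L
        scen_vec[row] <- sc
        par_mat[row, names(rec$pars)] <- rec$pars
        stats_mat[row, ] <- rec$stats
      }
      done <- done + m
    }
    if (progress) message("scenario ", sc, ": ", done, " rows")
  }
  scale <- apply(stats_mat, 2, stats::mad)
  fallback <- apply(stats_mat, 2, stats::sd)
  scale[scale == 0] <- fallback[scale == 0]
  scale[scale == 0 | is.na(scale)] <- 1
  structure(list(scenario = scen_vec, params = par_mat, stats = stats_mat,
                 scale = scale, priors = priors, model = model,
                 config = list(n_ind = n_ind, n_seq = n_seq,
                               n_loci = n_loci, L = L),
                 n_per_scenario = n_per_scenario, seed = seed),
            class = "abc_reftable")
}

chunk_seed <- function(seed, scenario, chunk) {
  as.integer((as.numeric(seed) * 7919 + scenario * 104729 + chunk * 131) %%
               2147483647)
}

# One reference-table row; retries a failed simulation once.
simulate_table_row <- function(sc, priors, model, n_ind, n_seq, n_loci, L) {
  for (attempt in 1:2) {
    res <- tryCatch({
      pars <- sample_prior(sc, priors)
      ep <- scenario_epochs(sc, pars)
      raw <- simulate_raw(ep, pars, n_ind, n_seq, n_loci, L, model)
      list(pars = pars, stats = summarize_raw(raw$msat, raw$seq, L))
    }, error = function(e) e)
    if (!inherits(res, "error")) return(res)
    if (attempt == 2)
      stop("simulation failed twice for scenario ", sc, ": ",
           conditionMessage(res))
  }
}

#' @export
print.abc_reftable <- function(x, ...) {
  cat("ABC reference table:", nrow(x$stats), "rows (",
      x$n_per_scenario, "per scenario ), scenarios:",
      paste(unique(x$scenario), collapse = " "), "\n")
  cat("Sampling configuration:", x$config$n_ind, "diploids x",
      x$config$n_loci, "msat loci;", x$config$n_seq, "sequences x",
      x$config$L, "sites\n")
  invisible(x)
}

#' Write / read a reference table as delimited text with a JSON header
#'
#' @param table an `abc_reftable`.
#' @param path output file (tab-delimited; header line carries JSON
#'   metadata prefixed with `#`).
#' @export
write_reference_table <- function(table, path) {
  meta <- jsonlite::toJSON(list(priors = table$priors,
                                model = table$model,
                                config = table$config,
                                n_per_scenario = table$n_per_scenario,
                                seed = table$seed,
                                stat_names = colnames(table$stats)),
                           auto_unbox = TRUE, digits = NA)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("#", meta), con)
  df <- data.frame(scenario = table$scenario, table$params, table$stats,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_reference_table
#' @param path file written by [write_reference_table()].
#' @export
read_reference_table <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- jsonlite::fromJSON(sub("^#", "", hdr))
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                          check.names = FALSE)
  stats_mat <- as.matrix(df[, meta$stat_names, drop = FALSE])
  par_cols <- setdiff(names(df), c("scenario", meta$stat_names))
  scale <- apply(stats_mat, 2, stats::mad)
  fallback <- apply(stats_mat, 2, stats::sd)
  scale[scale == 0] <- fallback[scale == 0]
  scale[scale == 0 | is.na(scale)] <- 1
  model <- meta$model
  model$base_freq <- unlist(model$base_freq)
  structure(list(scenario = df$scenario,
                 params = as.matrix(df[, par_cols, drop = FALSE]),
                 stats = stats_mat, scale = scale,
                 priors = lapply(meta$priors, as.numeric),
                 model = model, config = meta$config,
                 n_per_scenario = meta$n_per_scenario, seed = meta$seed),
            class = "abc_reftable")
}
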