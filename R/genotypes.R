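#' Construct a diploid genotype matrix
#'
#' Container for codominant diploid genotypes (microsatellite allele states
#' as positive integers) with population labels and a missing-data mask.
#' Calls are unordered allele pairs; they are stored sorted so that two
#' objects with the same genotypes compare equal regardless of allele
#' order in the input.
#'
#' @param calls integer array of dimension `c(n_individuals, n_loci, 2)`;
#'   both slots of a call are `NA` for missing data.
#' @param individuals character vector of individual identifiers.
#' @param loci character vector of locus names.
#' @param population character vector (or factor) of population labels,
#'   one per individual.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, individuals, loci, population) {
  if (length(dim(calls)) != 3L || dim(calls)[3] != 2L)
    stop("'calls' must be an n x loci x 2 array")
  n <- dim(calls)[1]; L <- dim(calls)[2]
  if (length(individuals) != n) stop("length(individuals) != nrow(calls)")
  if (length(loci) != L) stop("length(loci) != ncol(calls)")
  if (length(population) != n)
    stop("'population' must give one label per individual")
  storage.mode(calls) <- "integer"
  half <- xor(is.na(calls[, , 1, drop = FALSE]), is.na(calls[, , 2, drop = FALSE]))
  if (any(half))
    stop("calls must carry two alleles or be entirely missing")
  if (any(calls <= 0L, na.rm = TRUE))
    stop("allele states must be positive integers")
  empty <- apply(calls[, , 1, drop = FALSE], 2, function(x) all(is.na(x)))
  if (any(empty))
    stop("loci with no non-missing call: ",
         paste(loci[empty], collapse = ", "))
  # store unordered pairs in sorted order
  a1 <- pmin(calls[, , 1], calls[, , 2])
  a2 <- pmax(calls[, , 1], calls[, , 2])
  calls[, , 1] <- a1; calls[, , 2] <- a2
  dimnames(calls) <- list(individuals, loci, c("a1", "a2"))
  structure(list(individuals = as.character(individuals),
                 loci = as.character(loci),
                 calls = calls,
                 population = stats::setNames(as.character(population),
                                              individuals)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Diploid genotype matrix:", length(x$individuals), "individuals x",
      length(x$loci), "loci\n")
  tab <- table(x$population)
  cat("Populations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  miss <- mean(is.na(x$calls[, , 1]))
  cat(sprintf("Missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals and loci
#' @param g a `genotype_matrix`.
#' @return named integer vector.
#' @export
dim_genotypes <- function(g) {
  c(individuals = length(g$individuals), loci = length(g$loci))
}

# Drop loci with no data anywhere (reader-side policy: warn and drop).
drop_empty_loci <- function(calls, loci, quiet = FALSE) {
  empty <- apply(calls[, , 1, drop = FALSE], 2, function(x) all(is.na(x)))
  if (any(empty)) {
    if (!quiet)
      warning("dropping loci with no non-missing calls: ",
              paste(loci[empty], collapse = ", "))
    calls <- calls[, !empty, , drop = FALSE]
    loci <- loci[!empty]
  }
  list(calls = calls, loci = loci)
}

#' Read microsatellite genotypes
#'
#' Reads the classic Genepop format (2- or 3-digit allele coding,
#' auto-detected per locus; `"00"`/`"000"` alleles are missing) or a
#' delimited table with columns `individual`, `population`, then two
#' columns per locus.
#'
#' @param path file path.
#' @param dialect `"genepop"` or `"delimited"`.
#' @return a [genotype_matrix()].
#' @export
read_genepop <- function(path, dialect = c("genepop", "delimited")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "delimited") return(read_genotypes_delimited(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3) stop("not a Genepop file: too few lines")
  # locus names: one per line, or comma-separated on one line
  pop_idx <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (!length(pop_idx)) stop("no POP separator found")
  locus_lines <- lines[2:(pop_idx[1] - 1)]
  loci <- unlist(strsplit(paste(locus_lines, collapse = ","), ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("no locus names found")
  L <- length(loci)
  ids <- character(); pops <- character(); rows <- list()
  pop_no <- 0L
  for (i in seq_along(lines)) {
    if (i <= pop_idx[1] - 1) next
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) {
      pop_no <- pop_no + 1L
      next
    }
    if (pop_no == 0L) stop("line ", i, ": genotype line before first POP")
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2)
      stop("line ", i, ": expected 'identifier , genotypes'")
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != L)
      stop("line ", i, ": ", length(toks), " genotype fields for ",
           L, " loci")
    row <- matrix(NA_integer_, L, 2)
    for (l in seq_len(L)) {
      tok <- toks[l]
      nc <- nchar(tok)
      if (nc == 4L) d <- 2L
      else if (nc == 6L) d <- 3L
      else stop("line ", i, ", locus ", loci[l],
                ": allele field '", tok, "' is not 4 or 6 digits")
      a <- c(as.integer(substr(tok, 1, d)),
             as.integer(substr(tok, d + 1, 2 * d)))
      if (anyNA(a)) stop("line ", i, ": non-numeric genotype '", tok, "'")
      if (all(a > 0L)) row[l, ] <- a   # any zero allele -> missing call
    }
    ids <- c(ids, id)
    pops <- c(pops, sprintf("pop%d", pop_no))
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) stop("no genotype rows found")
  calls <- array(NA_integer_, c(length(rows), L, 2))
  for (r in seq_along(rows)) calls[r, , ] <- rows[[r]]
  keep <- drop_empty_loci(calls, loci)
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  genotype_matrix(keep$calls, ids, keep$loci, pops)
}

read_genotypes_delimited <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 4 || (ncol(df) - 2) %% 2 != 0)
    stop("delimited genotype table needs individual, population, ",
         "then two columns per locus")
  gcols <- names(df)[-(1:2)]
  loci <- unique(sub("\\.[12]$", "", gcols))
  if (length(loci) * 2 != length(gcols))
    stop("odd allele column count: expected <locus>.1/<locus>.2 pairs")
  n <- nrow(df); L <- length(loci)
  calls <- array(NA_integer_, c(n, L, 2))
  for (l in seq_len(L)) {
    a1 <- suppressWarnings(as.integer(df[[paste0(loci[l], ".1")]]))
    a2 <- suppressWarnings(as.integer(df[[paste0(loci[l], ".2")]]))
    ok <- !is.na(a1) & !is.na(a2) & a1 > 0L & a2 > 0L
    calls[ok, l, 1] <- a1[ok]; calls[ok, l, 2] <- a2[ok]
  }
  keep <- drop_empty_loci(calls, loci)
  genotype_matrix(keep$calls, as.character(df[[1]]), keep$loci,
                  as.character(df[[2]]))
}

#' Write genotypes in Genepop format
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @param digits 2 or 3 digits per allele.
#' @param title first (comment) line of the file.
#' @export
write_genepop <- function(g, path, digits = 3, title = "gcpop export") {
  mx <- max(g$calls, na.rm = TRUE)
  if (mx >= 10^digits)
    stop("allele state ", mx, " does not fit in ", digits, " digits")
  fmt <- paste0("%0", digits, "d")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(g$loci, con)
  for (p in unique(g$population)) {
    writeLines("POP", con)
    for (i in which(g$population == p)) {
      a1 <- g$calls[i, , 1]; a2 <- g$calls[i, , 2]
      tok <- ifelse(is.na(a1), strrep("0", 2 * digits),
                    paste0(sprintf(fmt, a1), sprintf(fmt, a2)))
      writeLines(paste0(g$individuals[i], " , ", paste(tok, collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Write genotypes as a delimited table
#'
#' Two columns per locus (`<locus>.1`, `<locus>.2`), blank for missing.
#'
#' @inheritParams write_genepop
#' @param sep field separator (`","` or `"\t"`).
#' @export
write_genotypes_delimited <- function(g, path, sep = ",") {
  n <- length(g$individuals); L <- length(g$loci)
  out <- data.frame(individual = g$individuals,
                    population = unname(g$population),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (l in seq_len(L)) {
    out[[paste0(g$loci[l], ".1")]] <- g$calls[, l, 1]
    out[[paste0(g$loci[l], ".2")]] <- g$calls[, l, 2]
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, na = "",
                     quote = FALSE)
  invisible(path)
}

# Subset a genotype matrix to one population (internal).
pop_subset <- function(g, pop) {
  idx <- which(g$population == pop)
  if (!length(idx)) stop("population not found: ", pop)
  list(calls = g$calls[idx, , , drop = FALSE], idx = idx)
}
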