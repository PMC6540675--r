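#' Construct a haploid sequence alignment
#'
#' Equal-length DNA sequences (alphabet `A`, `C`, `G`, `T`, `N`, `-`) with
#' population labels, e.g. concatenated mitochondrial markers.
#'
#' @param sequences named character vector of sequences (names are
#'   identifiers), or unnamed with `ids` supplied.
#' @param population character vector of population labels, one per
#'   sequence, or a named map identifier -> population.
#' @param ids optional identifiers if `sequences` is unnamed.
#' @return an object of class `dna_alignment`.
#' @export
dna_alignment <- function(sequences, population, ids = NULL) {
  if (is.null(ids)) ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  sequences <- toupper(as.character(sequences))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("sequences differ in length: ", paste(unique(lens), collapse = ", "))
  bad <- grepl("[^ACGTN-]", sequences)
  if (any(bad))
    stop("sequences contain characters outside {A,C,G,T,N,-}: ",
         paste(ids[bad], collapse = ", "))
  if (!is.null(names(population))) {
    miss <- setdiff(ids, names(population))
    if (length(miss))
      stop("identifiers missing from population map: ",
           paste(miss, collapse = ", "))
    population <- population[ids]
  }
  if (length(population) != length(sequences))
    stop("'population' must give one label per sequence")
  structure(list(ids = as.character(ids),
                 seq = stats::setNames(sequences, ids),
                 length = lens[1],
                 population = stats::setNames(as.character(population), ids)),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("DNA alignment:", length(x$ids), "sequences x", x$length, "sites\n")
  tab <- table(x$population)
  cat("Populations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Read a FASTA alignment with a population map
#'
#' @param path FASTA file (aligned, equal lengths).
#' @param popmap two-column whitespace/tab-delimited file mapping sequence
#'   identifier to population label, or a named character vector.
#' @return a [dna_alignment()].
#' @export
read_alignment <- function(path, popmap) {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), function(s)
    paste(s, collapse = ""), character(1))
  names(seqs) <- sub("\\s.*$", "", names(dna))
  if (is.character(popmap) && length(popmap) == 1L && file.exists(popmap)) {
    pm <- utils::read.table(popmap, header = FALSE,
                            stringsAsFactors = FALSE)
    popmap <- stats::setNames(as.character(pm[[2]]), as.character(pm[[1]]))
  }
  dna_alignment(seqs, population = popmap)
}

#' Write a FASTA alignment and its population map
#'
#' @param aln a [dna_alignment()].
#' @param path FASTA output file.
#' @param popmap_path optional popmap output (two-column TSV).
#' @export
write_alignment <- function(aln, path, popmap_path = NULL) {
  mat <- do.call(rbind, strsplit(aln$seq, ""))
  rownames(mat) <- aln$ids
  ape::write.FASTA(ape::as.DNAbin(mat), path)
  if (!is.null(popmap_path))
    utils::write.table(data.frame(aln$ids, unname(aln$population)),
                       popmap_path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse an alignment into a haplotype spectrum
#'
#' Distinct haplotypes with per-population counts and segregating-site
#' indices.  Ambiguous data (`N` or `-`) are handled by the
#' `missing_policy`: `"drop_sites"` removes every column containing an
#' ambiguous character before comparison (complete deletion);
#' `"drop_sequences"` removes sequences containing any ambiguity.
#'
#' @param aln a [dna_alignment()].
#' @param missing_policy `"drop_sites"` (default) or `"drop_sequences"`.
#' @return an object of class `hap_spectrum` with elements `haplotypes`
#'   (character vector over retained sites), `counts` (haplotype x
#'   population matrix), `seg_sites` (original column indices),
#'   `n` (sequences analysed), `L` (retained sites) and `L_original`.
#' @export
collapse_haplotypes <- function(aln,
                                missing_policy = c("drop_sites",
                                                   "drop_sequences")) {
  missing_policy <- match.arg(missing_policy)
  if (!length(aln$ids)) stop("empty alignment")
  mat <- do.call(rbind, strsplit(unname(aln$seq), ""))
  pops <- unname(aln$population)
  amb <- mat == "N" | mat == "-"
  site_idx <- seq_len(ncol(mat))
  if (missing_policy == "drop_sites") {
    keep <- !apply(amb, 2, any)
    if (!any(keep)) stop("all sites contain ambiguous data; nothing to compare")
    mat <- mat[, keep, drop = FALSE]
    site_idx <- site_idx[keep]
  } else {
    keep <- !apply(amb, 1, any)
    if (!any(keep)) stop("all sequences contain ambiguous data")
    mat <- mat[keep, , drop = FALSE]
    pops <- pops[keep]
  }
  haps <- apply(mat, 1, paste, collapse = "")
  uh <- sort(unique(haps))
  counts <- table(factor(haps, levels = uh), factor(pops))
  counts <- matrix(counts, nrow = length(uh),
                   dimnames = list(NULL, colnames(counts)))
  seg <- site_idx[apply(mat, 2, function(col) length(unique(col)) > 1L)]
  structure(list(haplotypes = uh,
                 counts = counts,
                 seg_sites = seg,
                 n = nrow(mat),
                 L = ncol(mat),
                 L_original = aln$length),
            class = "hap_spectrum")
}

#' @export
print.hap_spectrum <- function(x, ...) {
  cat("Haplotype spectrum:", length(x$haplotypes), "haplotypes,",
      x$n, "sequences,", length(x$seg_sites), "segregating sites\n")
  invisible(x)
}

# Hamming distance between two equal-length haplotype strings.
hap_dist <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Pairwise nucleotide difference matrix for a set of sequences with
# pairwise (default) or complete deletion of ambiguous sites.
seq_diff_matrix <- function(seqs, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  mat <- do.call(rbind, strsplit(seqs, ""))
  amb <- mat == "N" | mat == "-"
  if (deletion == "complete") {
    keep <- !apply(amb, 2, any)
    mat <- mat[, keep, drop = FALSE]
    amb <- amb[, keep, drop = FALSE]
  }
  n <- nrow(mat)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !amb[i, ] & !amb[j, ]
    d[i, j] <- d[j, i] <- sum(mat[i, ok] != mat[j, ok])
  }
  d
}
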