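# Statistical-parsimony haplotype networks.

#' Parsimony connection limit
#'
#' Largest number of mutational steps `j` for which the estimated
#' probability that a j-step connection between two haplotypes is free of
#' homoplasy is at least `prob_threshold`.  The probability is the
#' coalescent-free approximation
#' `P_j = prod_{i=0}^{j-1} (1 - i/L)`:
#' under a uniform-sites mutation model, a j-step path is parsimonious
#' when all j changes hit distinct sites, and `P_j` is the probability of
#' that event for an alignment of `L` sites (a birthday-problem bound on
#' superimposed change).  `P_1 = 1`, so single-step connections are always
#' trusted; the limit is non-decreasing in `L`.
#'
#' @param L alignment length in sites.
#' @param prob_threshold parsimony probability (default 0.95).
#' @return integer step count (>= 1).
#' @export
parsimony_limit <- function(L, prob_threshold = 0.95) {
  if (L < 1) stop("L must be >= 1")
  if (prob_threshold <= 0 || prob_threshold >= 1)
    stop("prob_threshold must be in (0, 1)")
  j <- 1L
  p <- 1
  repeat {
    p_next <- p * (1 - j / L)          # P_{j+1}
    if (p_next < prob_threshold || j >= L) break
    p <- p_next
    j <- j + 1L
  }
  j
}

#' Build a statistical-parsimony haplotype network
#'
#' Agglomeratively joins haplotype clusters in increasing order of
#' inter-cluster Hamming distance up to `limit` mutational steps,
#' inserting `distance - 1` intermediate (unsampled) nodes per join so
#' every edge spans exactly one mutational step.  Ties in distance are
#' broken by joining the pair whose larger cluster carries the higher
#' total sample count, then by lexicographic haplotype order, making the
#' construction deterministic.
#'
#' @param spec a [collapse_haplotypes()] spectrum.
#' @param limit maximal number of steps joined (e.g. from
#'   [parsimony_limit()]).
#' @return object of class `parsimony_network`: `nodes` (data frame with
#'   `name`, `type` observed/inferred, `size`, per-population counts),
#'   `edges` (data frame `from`, `to`, `inferred`), `components`
#'   (membership vector over observed haplotypes), `limit`.
#' @export
build_network <- function(spec, limit) {
  H <- length(spec$haplotypes)
  hap_names <- paste0("H", seq_len(H))
  sizes <- rowSums(spec$counts)
  nodes <- data.frame(name = hap_names, type = "observed",
                      size = as.numeric(sizes),
                      stringsAsFactors = FALSE)
  for (p in colnames(spec$counts)) nodes[[p]] <- spec$counts[, p]
  edges <- data.frame(from = character(), to = character(),
                      inferred = logical(), stringsAsFactors = FALSE)
  comp <- seq_len(H)
  if (H > 1) {
    d <- matrix(0L, H, H)
    for (i in seq_len(H - 1)) for (j in (i + 1):H)
      d[i, j] <- d[j, i] <- hap_dist(spec$haplotypes[i], spec$haplotypes[j])
    n_interm <- 0L
    repeat {
      # candidate joins: minimal-distance observed pair across components
      best <- NULL
      for (i in seq_len(H - 1)) for (j in (i + 1):H) {
        if (comp[i] == comp[j]) next
        dij <- d[i, j]
        if (dij > limit) next
        csize <- function(cid) sum(sizes[comp == cid])
        key <- list(dist = dij,
                    bigger = max(csize(comp[i]), csize(comp[j])),
                    h1 = min(spec$haplotypes[i], spec$haplotypes[j]),
                    h2 = max(spec$haplotypes[i], spec$haplotypes[j]),
                    i = i, j = j)
        if (is.null(best) ||
            key$dist < best$dist ||
            (key$dist == best$dist && key$bigger > best$bigger) ||
            (key$dist == best$dist && key$bigger == best$bigger &&
             (key$h1 < best$h1 ||
              (key$h1 == best$h1 && key$h2 < best$h2))))
          best <- key
      }
      if (is.null(best)) break
      i <- best$i; j <- best$j
      # path i -> j changing differing sites in ascending site order
      si <- strsplit(spec$haplotypes[i], "")[[1]]
      sj <- strsplit(spec$haplotypes[j], "")[[1]]
      diff_sites <- which(si != sj)
      prev <- hap_names[i]
      cur <- si
      if (length(diff_sites) > 1) {
        for (sstep in diff_sites[-length(diff_sites)]) {
          cur[sstep] <- sj[sstep]
          n_interm <- n_interm + 1L
          nm <- paste0("m", n_interm)
          newnode <- nodes[1, ]
          newnode[1, ] <- NA
          newnode$name <- nm; newnode$type <- "inferred"; newnode$size <- 0
          for (p in colnames(spec$counts)) newnode[[p]] <- 0
          nodes <- rbind(nodes, newnode)
          edges <- rbind(edges, data.frame(from = prev, to = nm,
                                           inferred = TRUE,
                                           stringsAsFactors = FALSE))
          prev <- nm
        }
      }
      edges <- rbind(edges, data.frame(from = prev, to = hap_names[j],
                                       inferred = length(diff_sites) > 1,
                                       stringsAsFactors = FALSE))
      comp[comp == comp[j]] <- comp[i]
    }
  }
  comp <- match(comp, unique(comp))
  structure(list(nodes = nodes, edges = edges, components = comp,
                 limit = limit),
            class = "parsimony_network")
}

#' @export
print.parsimony_network <- function(x, ...) {
  cat("Parsimony network:", sum(x$nodes$type == "observed"),
      "haplotypes,", sum(x$nodes$type == "inferred"),
      "inferred intermediates,", nrow(x$edges), "edges\n")
  cat("Connection limit:", x$limit, "steps;",
      length(unique(x$components)), "component(s)\n")
  invisible(x)
}

#' Export a parsimony network
#'
#' Writes GraphML (node attributes: haplotype id, type, size,
#' per-population counts; edge attribute: inferred) via igraph, or a flat
#' edge-list TSV.
#'
#' @param net a [build_network()] result.
#' @param path output file.
#' @param format `"graphml"` or `"tsv"`.
#' @export
write_network <- function(net, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(net$edges, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(path))
  }
  gr <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                      vertices = net$nodes)
  igraph::write_graph(gr, path, format = "graphml")
  invisible(path)
}
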