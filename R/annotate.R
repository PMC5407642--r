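# Genomic context of accepted precursors: genic/intergenic calls, 10-kb
# clustering, antiparallel clusters, per-chromosome tallies.

#' Genic/intergenic call for precursor intervals
#'
#' A precursor is genic iff its interval overlaps any gene interval by at
#' least 1 nt (strand-agnostic, gene-level features only).
#'
#' @param precursors data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param genes data.frame of gene models ([read_gff3()] layout).
#' @return character vector, `"genic"` or `"intergenic"`, one per precursor.
#' @export
classify_genic <- function(precursors, genes) {
  vapply(seq_len(nrow(precursors)), function(k) {
    hit <- genes$chrom == precursors$chrom[k] &
      intervals_overlap(precursors$start[k], precursors$end[k],
                        genes$start, genes$end)
    if (any(hit)) "genic" else "intergenic"
  }, character(1L))
}

#' Cluster MIR loci within a maximum genomic gap
#'
#' Single-linkage chaining per chromosome: consecutive precursors (by start)
#' whose end-to-start gap is at most `max_gap` nt (inclusive) join one
#' cluster.  Singletons are not clusters.  A cluster is antiparallel when
#' its members occupy both strands.
#'
#' @param precursors data.frame with `id`, `chrom`, `start`, `end`, `strand`.
#' @param max_gap maximum gap between consecutive members, nt (default
#'   10,000, inclusive); measured `next.start - previous.end`.
#' @return data.frame with one row per cluster: `cluster_id`, `chrom`,
#'   `start`, `end`, `n_members`, `members` (semicolon-joined ids),
#'   `antiparallel`.
#' @export
cluster_precursors <- function(precursors, max_gap = 10000L) {
  stopifnot(max_gap >= 0)
  empty <- data.frame(cluster_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), n_members = integer(),
                      members = character(), antiparallel = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(precursors)) return(empty)
  out <- list()
  for (chrom in sort(unique(precursors$chrom))) {
    p <- precursors[precursors$chrom == chrom, , drop = FALSE]
    p <- p[order(p$start, p$end), , drop = FALSE]
    grp <- integer(nrow(p)); cur <- 1L; grp[1L] <- 1L
    prev_end <- p$end[1L]
    for (k in seq_len(nrow(p))[-1L]) {
      if (p$start[k] - prev_end > max_gap) cur <- cur + 1L
      grp[k] <- cur
      prev_end <- max(prev_end, p$end[k])
    }
    for (g in unique(grp)) {
      m <- p[grp == g, , drop = FALSE]
      if (nrow(m) < 2L) next
      out[[length(out) + 1L]] <- data.frame(
        cluster_id = sprintf("%s_cluster_%d", chrom, g), chrom = chrom,
        start = min(m$start), end = max(m$end), n_members = nrow(m),
        members = paste(m$id, collapse = ";"),
        antiparallel = length(unique(m$strand)) > 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summary statistics of an accepted precursor set
#'
#' Per-chromosome, per-family and genic/intergenic tallies, count of
#' clustered precursors, mature-length histogram, and first-5'-nucleotide
#' frequencies, all with deterministic ordering.
#'
#' @param precursors data.frame with `id`, `chrom`, `family`, `genic`
#'   (`"genic"`/`"intergenic"`), `mature`, and optionally `first_nt`.
#' @param clusters data.frame from [cluster_precursors()].
#' @return list of class `mir_summary`.
#' @export
summarize_mir <- function(precursors, clusters = NULL) {
  tab <- function(x) {
    t <- table(x)
    if (!length(t)) return(t)
    t[order(names(t))]
  }
  n <- nrow(precursors)
  clustered <- if (!is.null(clusters) && nrow(clusters)) {
    length(unique(unlist(strsplit(clusters$members, ";", fixed = TRUE))))
  } else 0L
  mat_len <- if (n) nchar(precursors$mature) else integer()
  first_nt <- if (n) {
    if (!is.null(precursors$first_nt)) precursors$first_nt
    else dna_to_rna(substr(precursors$mature, 1L, 1L))
  } else character()
  res <- list(
    n_precursors = n,
    per_chromosome = tab(precursors$chrom),
    per_family = tab(precursors$family),
    genic = sum(precursors$genic == "genic"),
    intergenic = sum(precursors$genic == "intergenic"),
    n_clusters = if (is.null(clusters)) 0L else nrow(clusters),
    n_clustered = clustered,
    n_antiparallel_clusters = if (is.null(clusters) || !nrow(clusters)) 0L
      else sum(clusters$antiparallel),
    mature_length_hist = tab(mat_len),
    first_nt_freq = tab(first_nt)
  )
  class(res) <- "mir_summary"
  res
}

#' @export
print.mir_summary <- function(x, ...) {
  cat(sprintf("%d precursor(s): %d genic, %d intergenic; %d in %d cluster(s) (%d antiparallel)\n",
              x$n_precursors, x$genic, x$intergenic, x$n_clustered,
              x$n_clusters, x$n_antiparallel_clusters))
  if (length(x$per_chromosome)) {
    modal <- names(x$per_chromosome)[which.max(x$per_chromosome)]
    cat(sprintf("modal chromosome: %s (%d loci)\n", modal, max(x$per_chromosome)))
  }
  if (length(x$first_nt_freq)) {
    modal <- names(x$first_nt_freq)[which.max(x$first_nt_freq)]
    cat(sprintf("preferred first 5' nucleotide: %s (%.0f%%)\n", modal,
                100 * max(x$first_nt_freq) / sum(x$first_nt_freq)))
  }
  invisible(x)
}
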