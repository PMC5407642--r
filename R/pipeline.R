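# End-to-end discovery: seed -> window -> inverted-repeat scan -> fold ->
# filter cascade -> overlap resolution -> genomic annotation.

#' Run the precursor discovery pipeline
#'
#' Stages are executed in order; every candidate carries provenance (its
#' window, seed, and filter decision), and the run manifest records all
#' parameters and the engine identity.  With the fallback folding engine the
#' whole run is deterministic.
#'
#' @param genome named character vector of chromosome sequences (DNA).
#' @param references reference matures (data.frame with `mirna_id`,
#'   `family`, `residues`, or named character vector).
#' @param genes gene models ([read_gff3()] layout) for genic/intergenic
#'   calls; may be `NULL`.
#' @param blocklist repeat/ncRNA intervals (`chrom`, `start`, `end`); any
#'   overlap rejects a candidate.
#' @param thresholds a [filter_thresholds()].
#' @param ir an [ir_params()].
#' @param max_seed_mismatches Hamming tolerance of the homology seeding.
#' @param flank window flank each side of a seed (nt).
#' @param engine folding engine, `"fallback"` or `"vienna"`.
#' @param cluster_gap maximum MIR cluster gap (nt, inclusive).
#' @param compute_ensemble compute ensemble statistics (requires the vienna
#'   engine for precursors longer than 30 nt; otherwise reported `NA`).
#' @return object of class `mir_discovery`: `precursors` (accepted set),
#'   `decisions` (all candidates with reasons), `clusters`, `summary`,
#'   `seeds`, `windows`, `manifest`.
#' @export
run_discovery <- function(genome, references, genes = NULL, blocklist = NULL,
                          thresholds = filter_thresholds(), ir = ir_params(),
                          max_seed_mismatches = 3L, flank = 336L,
                          engine = c("fallback", "vienna"),
                          cluster_gap = 10000L, compute_ensemble = FALSE) {
  engine <- match.arg(engine)
  refs <- .as_reference_df(references)
  if (!"family" %in% names(refs)) {
    refs$family <- toupper(sub(".*?(mir[0-9]+).*", "\\1", refs$mirna_id,
                               ignore.case = TRUE))
  }
  seeds <- if (nrow(refs)) seed_by_homology(genome, refs, max_seed_mismatches)
           else data.frame(mirna_id = character(), chrom = character(),
                           start = integer(), end = integer(),
                           strand = character(), mismatches = integer())
  windows <- window_candidates(seeds, genome, flank)

  candidates <- list(); decisions <- list()
  cand_n <- 0L
  for (w in seq_len(nrow(windows))) {
    win <- windows[w, ]
    wseq <- substr(genome[[win$chrom]], win$start + 1L, win$end)
    irs <- scan_inverted_repeats(wseq, ir)
    wseeds <- seeds[seeds$chrom == win$chrom & seeds$start >= win$start &
                      seeds$end <= win$end, , drop = FALSE]
    for (r in seq_len(nrow(irs))) {
      cstart <- win$start + irs$left_start[r]
      cend <- win$start + irs$right_end[r]
      inside <- wseeds[wseeds$start >= cstart & wseeds$end <= cend, , drop = FALSE]
      if (!nrow(inside)) next
      inside <- inside[order(inside$mismatches,
                             match(inside$strand, c("+", "-")),
                             inside$start), , drop = FALSE]
      seed <- inside[1L, ]
      cand_n <- cand_n + 1L
      id <- sprintf("cand_%03d", cand_n)
      gseq <- substr(genome[[win$chrom]], cstart + 1L, cend)
      if (seed$strand == "+") {
        pseq <- gseq
        ms <- seed$start - cstart; me <- seed$end - cstart
      } else {
        pseq <- revcomp(gseq)
        ms <- cend - seed$end; me <- cend - seed$start
      }
      fl <- fold_rna(pseq, engine = engine)
      comp <- base_composition(pseq)
      plen <- nchar(pseq)
      a <- amfe(fl$mfe, plen)
      mi <- if (comp$GC > 0) mfei(a, comp$GC) else NA_real_
      pm <- place_mature(fl, ms, me)
      mature <- substr(pseq, ms + 1L, me)
      af <- assign_family(mature, refs, thresholds$mature_max_mismatches)
      ens <- list(mfee = NA_real_, diversity = NA_real_, frequency = NA_real_)
      if (compute_ensemble && (engine == "vienna" || plen <= 30L)) {
        ens <- ensemble_stats(pseq, engine = engine)
      }
      cand <- list(id = id, chrom = win$chrom, start = cstart, end = cend,
                   strand = seed$strand, length = plen, sequence = pseq,
                   structure = fl$structure, gc = comp$GC, mfe = fl$mfe,
                   amfe = a, mfei = mi, mfee = ens$mfee,
                   diversity = ens$diversity, frequency = ens$frequency,
                   mature = mature, mature_start = ms, mature_end = me,
                   arm = pm$arm, first_nt = pm$first_nt,
                   mature_valid = pm$valid, mature_mismatches = af$mismatches,
                   family = af$family, seed_ref = seed$mirna_id,
                   window_id = win$window_id, ir_score = irs$score[r],
                   composition = comp)
      dec <- apply_cascade(cand, thresholds, blocklist)
      candidates[[id]] <- cand
      decisions[[id]] <- data.frame(
        candidate_id = id, window_id = win$window_id, seed_ref = seed$mirna_id,
        chrom = win$chrom, start = cstart, end = cend, strand = seed$strand,
        accepted = dec$accepted,
        reasons = paste(dec$reasons, collapse = ";"), stringsAsFactors = FALSE)
    }
  }
  decisions <- if (length(decisions)) do.call(rbind, decisions) else
    data.frame(candidate_id = character(), window_id = character(),
               seed_ref = character(), chrom = character(), start = integer(),
               end = integer(), strand = character(), accepted = logical(),
               reasons = character(), stringsAsFactors = FALSE)
  rownames(decisions) <- NULL

  acc_ids <- decisions$candidate_id[decisions$accepted]
  to_df <- function(ids) {
    if (!length(ids)) {
      return(data.frame(id = character(), chrom = character(), start = integer(),
                        end = integer(), strand = character(), length = integer(),
                        family = character(), mfe = numeric(), amfe = numeric(),
                        mfei = numeric(), gc = numeric(), mature = character(),
                        mature_start = integer(), mature_end = integer(),
                        arm = character(), first_nt = character(),
                        mfee = numeric(), diversity = numeric(),
                        frequency = numeric(), sequence = character(),
                        structure = character(), seed_ref = character(),
                        window_id = character(), stringsAsFactors = FALSE))
    }
    do.call(rbind, lapply(ids, function(i) {
      c0 <- candidates[[i]]
      data.frame(id = c0$id, chrom = c0$chrom, start = c0$start, end = c0$end,
                 strand = c0$strand, length = c0$length, family = c0$family,
                 mfe = c0$mfe, amfe = c0$amfe, mfei = c0$mfei, gc = c0$gc,
                 mature = c0$mature, mature_start = c0$mature_start,
                 mature_end = c0$mature_end, arm = c0$arm,
                 first_nt = c0$first_nt, mfee = c0$mfee,
                 diversity = c0$diversity, frequency = c0$frequency,
                 sequence = c0$sequence, structure = c0$structure,
                 seed_ref = c0$seed_ref, window_id = c0$window_id,
                 stringsAsFactors = FALSE)
    }))
  }
  acc <- to_df(acc_ids)
  ro <- resolve_overlaps(acc)
  prec <- ro$kept
  if (nrow(prec)) {
    prec$name <- .mir_locus_names(prec$family, prec$chrom, prec$start)
    prec$genic <- if (!is.null(genes) && nrow(genes)) classify_genic(prec, genes)
                  else rep("intergenic", nrow(prec))
    prec <- prec[order(prec$chrom, prec$start), , drop = FALSE]
    rownames(prec) <- NULL
  } else {
    prec$name <- character(); prec$genic <- character()
  }
  clusters <- cluster_precursors(prec, max_gap = cluster_gap)
  summ <- summarize_mir(prec, clusters)

  manifest <- list(engine = engine, thresholds = unclass(thresholds),
                   ir_params = unclass(ir),
                   max_seed_mismatches = max_seed_mismatches, flank = flank,
                   cluster_gap = cluster_gap,
                   n_references = nrow(refs), n_seeds = nrow(seeds),
                   n_windows = nrow(windows), n_candidates = cand_n,
                   n_accepted = nrow(prec),
                   package_version = as.character(utils::packageVersion("mirdiscover")))

  structure(list(precursors = prec, decisions = decisions, dropped = ro$dropped,
                 clusters = clusters, summary = summ, seeds = seeds,
                 windows = windows, manifest = manifest),
            class = "mir_discovery")
}

#' @export
print.mir_discovery <- function(x, ...) {
  cat(sprintf("miRNA discovery run (%s engine): %d seed(s), %d window(s), %d candidate(s), %d accepted precursor(s)\n",
              x$manifest$engine, x$manifest$n_seeds, x$manifest$n_windows,
              x$manifest$n_candidates, nrow(x$precursors)))
  invisible(x)
}

#' @export
summary.mir_discovery <- function(object, ...) {
  print(object)
  print(object$summary)
  invisible(object$summary)
}

#' Locus report of accepted precursors (1-based inclusive coordinates)
#'
#' One row per accepted precursor: locus name, genomic position and strand,
#' genic/intergenic call, mature arm, position within the precursor, size
#' and first 5' nucleotide.
#'
#' @param x a `mir_discovery`.
#' @return data.frame.
#' @export
precursor_report <- function(x) {
  stopifnot(inherits(x, "mir_discovery"))
  p <- x$precursors
  data.frame(name = p$name, family = p$family, chromosome = p$chrom,
             start = p$start + 1L, end = p$end, strand = p$strand,
             location = p$genic, arm = p$arm,
             mature_start = p$mature_start + 1L, mature_end = p$mature_end,
             mature_size = nchar(p$mature), first_nt = p$first_nt,
             mature = dna_to_rna(p$mature), stringsAsFactors = FALSE)
}

#' Thermodynamic/compositional descriptor report of accepted precursors
#'
#' @param x a `mir_discovery`.
#' @return data.frame with MFE, AMFE, MFEI, MFEE, Diversity, Frequency and
#'   base composition per precursor.
#' @export
descriptor_report <- function(x) {
  stopifnot(inherits(x, "mir_discovery"))
  p <- x$precursors
  comp <- lapply(p$sequence, base_composition)
  gv <- function(f) vapply(comp, `[[`, numeric(1L), f)
  data.frame(name = p$name, length = p$length, MFE = p$mfe, AMFE = p$amfe,
             MFEI = p$mfei, MFEE = p$mfee, Diversity = p$diversity,
             Frequency = p$frequency, A = gv("A"), U = gv("U"), C = gv("C"),
             G = gv("G"), GC = gv("GC"), AU = gv("AU"),
             GC_ratio = gv("GC_ratio"), AU_ratio = gv("AU_ratio"),
             engine = x$manifest$engine, stringsAsFactors = FALSE)
}

#' Precision/recall of a discovery run against a planted truth table
#'
#' A truth entry is recovered when an accepted precursor on the same
#' chromosome overlaps its interval (strand-agnostic: a perfect fold-back
#' is orientation-symmetric, so the detected strand of a hairpin locus is
#' legitimately ambiguous).
#'
#' @param x a `mir_discovery`.
#' @param truth truth table from [synth_genome()].
#' @return list: `recall`, `precision`, `n_truth`, `n_accepted`,
#'   `matched_truth`, `matched_accepted`.
#' @export
evaluate_discovery <- function(x, truth) {
  p <- x$precursors
  match_t <- vapply(seq_len(nrow(truth)), function(k) {
    any(p$chrom == truth$chrom[k] &
          intervals_overlap(p$start, p$end, truth$start[k], truth$end[k]))
  }, logical(1L))
  match_p <- vapply(seq_len(nrow(p)), function(k) {
    any(truth$chrom == p$chrom[k] &
          intervals_overlap(truth$start, truth$end, p$start[k], p$end[k]))
  }, logical(1L))
  list(recall = if (nrow(truth)) mean(match_t) else NA_real_,
       precision = if (nrow(p)) mean(match_p) else NA_real_,
       n_truth = nrow(truth), n_accepted = nrow(p),
       matched_truth = sum(match_t), matched_accepted = sum(match_p))
}
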