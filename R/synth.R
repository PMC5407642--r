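# Synthetic genomes, reference miRNA sets, gene models and protein sets with
# known ground truth, so the whole pipeline can be exercised offline.

.MIR_FAMILY_POOL <- c(
  "MIR156", "MIR159", "MIR160", "MIR164", "MIR166", "MIR167", "MIR168",
  "MIR169", "MIR171", "MIR172", "MIR390", "MIR393", "MIR394", "MIR395",
  "MIR396", "MIR397", "MIR398", "MIR399", "MIR408", "MIR482"
)

.rand_dna <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

.mutate_dna <- function(s, k) {
  if (k == 0L) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  pos <- sample(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Configuration for the synthetic genome generator
#'
#' Defaults emulate the statistical structure of a plant genome-wide MIR
#' survey at desk scale: mature miRNAs of 19-25 nt with a 21-nt mode and a
#' 5' uracil bias, fold-back precursors whose length and GC content fall in
#' the plant-typical windows (precursors 60-338 nt, GC 20-65%), roughly one
#' fifth of MIR loci inside genes, and transposon-like decoy hairpins whose
#' intervals form the repeat blocklist.
#'
#' @param seed integer seed driving the single pseudo-random stream.
#' @param n_chromosomes number of chromosomes; ids are `chr0` (the unplaced
#'   pseudochromosome, treated as ordinary) through `chr<n-1>`.
#' @param chrom_length chromosome length in nt.
#' @param n_plants number of planted precursors.
#' @param arm_range inclusive range of stem arm lengths (nt).
#' @param loop_range inclusive range of terminal loop lengths (nt).
#' @param per_arm_mismatches substitutions applied to the arm opposite the
#'   mature-bearing arm (0 = perfect fold-back).
#' @param background_gc background GC fraction (i.i.d. composition).
#' @param mature_lengths,mature_length_probs mature size distribution.
#' @param first_u_prob probability the mature 5' nucleotide is U.
#' @param genic_fraction fraction of plants placed inside gene models
#'   (held exactly after rounding).
#' @param n_decoy_repeats transposon-like decoy hairpins; their intervals are
#'   emitted as the blocklist fixture.
#' @param ref_mismatches substitutions between each planted mature and its
#'   "known ortholog" in the reference set.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(seed,
                         n_chromosomes = 12L,
                         chrom_length = 20000L,
                         n_plants = 20L,
                         arm_range = c(50L, 110L),
                         loop_range = c(8L, 30L),
                         per_arm_mismatches = 0L,
                         background_gc = 0.38,
                         mature_lengths = 19:25,
                         mature_length_probs = c(0.04, 0.08, 0.52, 0.14, 0.10, 0.07, 0.05),
                         first_u_prob = 0.6,
                         genic_fraction = 0.2,
                         n_decoy_repeats = 5L,
                         ref_mismatches = 1L) {
  stopifnot(length(mature_lengths) == length(mature_length_probs),
            all(mature_length_probs >= 0), sum(mature_length_probs) > 0,
            background_gc > 0, background_gc < 1,
            genic_fraction >= 0, genic_fraction <= 1,
            arm_range[1L] <= arm_range[2L], loop_range[1L] <= loop_range[2L],
            arm_range[1L] > max(mature_lengths) + 3L)
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length), n_plants = as.integer(n_plants),
              arm_range = as.integer(arm_range), loop_range = as.integer(loop_range),
              per_arm_mismatches = as.integer(per_arm_mismatches),
              background_gc = background_gc, mature_lengths = as.integer(mature_lengths),
              mature_length_probs = mature_length_probs / sum(mature_length_probs),
              first_u_prob = first_u_prob, genic_fraction = genic_fraction,
              n_decoy_repeats = as.integer(n_decoy_repeats),
              ref_mismatches = as.integer(ref_mismatches))
  class(cfg) <- "synth_config"
  cfg
}

.sample_mature <- function(cfg, len = NULL) {
  if (is.null(len)) len <- sample(cfg$mature_lengths, 1L, prob = cfg$mature_length_probs)
  first <- if (runif(1L) < cfg$first_u_prob) "T" else sample(c("A", "C", "G"), 1L)
  paste0(first, .rand_dna(len - 1L, gc = 0.45))
}

# Largest-remainder apportionment of n items over the configured
# distribution, so planted histograms match it exactly.
.alloc_counts <- function(probs, n) {
  raw <- probs * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0L) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1L
  }
  as.integer(cnt)
}

# Build one fold-back precursor carrying `mature` on `arm`; the opposite arm
# receives `mism` substitutions.  Returns precursor sequence plus the mature
# offset (0-based within precursor).
.build_hairpin <- function(mature, arm, arm_len, loop_len, mism, gc) {
  mat_len <- nchar(mature)
  offset <- sample.int(arm_len - mat_len + 1L, 1L) - 1L
  left <- if (offset > 0L) .rand_dna(offset, gc) else ""
  right_len <- arm_len - mat_len - offset
  right <- if (right_len > 0L) .rand_dna(right_len, gc) else ""
  # the mature-bearing arm carries the mature verbatim (5'->3' in precursor
  # orientation); the opposite arm is its reverse complement
  carrier <- paste0(left, mature, right)
  other <- .mutate_dna(revcomp(carrier), mism)
  loop <- .rand_dna(loop_len, 0.25)
  if (arm == "5p") {
    list(seq = paste0(carrier, loop, other),
         mature_start = offset, mature_end = offset + mat_len)
  } else {
    ms <- arm_len + loop_len + offset
    list(seq = paste0(other, loop, carrier),
         mature_start = ms, mature_end = ms + mat_len)
  }
}

#' Generate a synthetic genome with planted miRNA precursors
#'
#' Emits a multi-chromosome genome with fold-back precursors at known
#' positions, gene models realising the configured genic fraction exactly,
#' transposon-like decoy hairpins (their intervals are the blocklist), and a
#' miRBase-style reference set containing, for every planted family, a known
#' ortholog mature within the configured mismatch budget.  Deterministic for
#' a fixed seed.
#'
#' @param config a [synth_config()].
#' @return list of class `synth_genome` with elements `genome` (named
#'   character vector), `genes`, `truth`, `references`, `blocklist`, `config`.
#' @export
synth_genome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, .synth_genome_impl(config))
}

.synth_genome_impl <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes) - 1L)
  occupied <- stats::setNames(vector("list", length(chroms)), chroms)
  margin <- 600L
  n_total <- cfg$n_plants + cfg$n_decoy_repeats
  max_prec <- 2L * cfg$arm_range[2L] + cfg$loop_range[2L]
  if (n_total > 0L &&
      cfg$n_chromosomes * max(0L, cfg$chrom_length - 2L * margin) <
        n_total * (max_prec + 2L * margin)) {
    stop("chromosomes too short to host the requested planted hairpins")
  }

  place <- function(len) {
    for (try in 1:2000) {
      chrom <- sample(chroms, 1L)
      start <- sample.int(max(1L, cfg$chrom_length - len - 2L * margin), 1L) + margin
      iv <- c(start, start + len)
      occ <- occupied[[chrom]]
      clash <- any(vapply(occ, function(o) iv[1L] < o[2L] + margin && o[1L] < iv[2L] + margin,
                          logical(1L)))
      if (!clash) {
        occupied[[chrom]][[length(occupied[[chrom]]) + 1L]] <<- iv
        return(list(chrom = chrom, start = start))
      }
    }
    stop("chromosomes too short to host the requested planted hairpins")
  }

  # families drawn without replacement while the pool lasts; mature lengths
  # apportioned exactly to the configured distribution
  fam_pool <- sample(.MIR_FAMILY_POOL)
  fams <- if (cfg$n_plants > 0L) {
    if (cfg$n_plants <= length(fam_pool)) fam_pool[seq_len(cfg$n_plants)]
    else sample(fam_pool, cfg$n_plants, replace = TRUE)
  } else character()
  mat_lens <- sample(rep(cfg$mature_lengths,
                         .alloc_counts(cfg$mature_length_probs, cfg$n_plants)))
  fam_mature <- list()

  truth <- list()
  inserts <- list()
  for (i in seq_len(cfg$n_plants)) {
    fam <- fams[i]
    if (is.null(fam_mature[[fam]])) {
      mature <- .sample_mature(cfg, mat_lens[i])
      fam_mature[[fam]] <- mature
    } else {
      # family drawn twice (only when n_plants exceeds the family pool):
      # paralogous loci share the family mature
      mature <- fam_mature[[fam]]
    }
    arm <- sample(c("5p", "3p"), 1L)
    arm_len <- sample(seq(cfg$arm_range[1L], cfg$arm_range[2L]), 1L)
    loop_len <- sample(seq(cfg$loop_range[1L], cfg$loop_range[2L]), 1L)
    gc <- runif(1L, 0.33, 0.55)
    repeat {
      hp <- .build_hairpin(mature, arm, arm_len, loop_len, cfg$per_arm_mismatches, gc)
      gcp <- .gc_percent(hp$seq)
      if (gcp >= 22 && gcp <= 62) break
    }
    strand <- sample(c("+", "-"), 1L)
    loc <- place(nchar(hp$seq))
    truth[[i]] <- data.frame(
      plant_id = sprintf("plant_%02d", i), chrom = loc$chrom,
      start = loc$start, end = loc$start + nchar(hp$seq), strand = strand,
      family = fam, mature = mature, arm = arm,
      mature_start = hp$mature_start, mature_end = hp$mature_end,
      precursor = hp$seq, stringsAsFactors = FALSE)
    inserts[[length(inserts) + 1L]] <- list(
      chrom = loc$chrom, start = loc$start,
      seq = if (strand == "+") hp$seq else revcomp(hp$seq))
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(plant_id = character(), chrom = character(), start = numeric(),
               end = numeric(), strand = character(), family = character(),
               mature = character(), arm = character(), mature_start = numeric(),
               mature_end = numeric(), precursor = character(), stringsAsFactors = FALSE)

  # decoys: same fold-back construction (so they seed and scan like real
  # candidates) but their intervals go to the blocklist
  blocklist <- list()
  for (d in seq_len(cfg$n_decoy_repeats)) {
    fam <- if (length(fam_mature)) sample(names(fam_mature), 1L) else {
      f <- fam_pool[length(fam_pool)]
      fam_mature[[f]] <- .sample_mature(cfg)
      f
    }
    hp <- .build_hairpin(fam_mature[[fam]], "5p",
                         sample(seq(cfg$arm_range[1L], cfg$arm_range[2L]), 1L),
                         sample(seq(cfg$loop_range[1L], cfg$loop_range[2L]), 1L),
                         0L, 0.42)
    loc <- place(nchar(hp$seq))
    blocklist[[d]] <- data.frame(
      chrom = loc$chrom, start = loc$start, end = loc$start + nchar(hp$seq),
      name = sprintf("decoy_repeat_%02d", d), stringsAsFactors = FALSE)
    inserts[[length(inserts) + 1L]] <- list(chrom = loc$chrom, start = loc$start, seq = hp$seq)
  }
  blocklist <- if (length(blocklist)) do.call(rbind, blocklist) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               name = character(), stringsAsFactors = FALSE)

  # background genome, then splice the planted sequences in
  genome <- stats::setNames(
    vapply(chroms, function(ch) .rand_dna(cfg$chrom_length, cfg$background_gc),
           character(1L)), chroms)
  for (ins in inserts) {
    s <- genome[[ins$chrom]]
    genome[[ins$chrom]] <- paste0(substr(s, 1L, ins$start),
                                  ins$seq,
                                  substr(s, ins$start + nchar(ins$seq) + 1L, nchar(s)))
  }

  # gene models: exactly round(genic_fraction * n_plants) plants fall inside
  # genes; background genes avoid all planted/decoy intervals
  n_genic <- as.integer(round(cfg$genic_fraction * cfg$n_plants))
  genic_idx <- if (n_genic > 0L) sort(sample.int(cfg$n_plants, n_genic)) else integer()
  genes <- list()
  for (k in seq_along(genic_idx)) {
    tr <- truth[genic_idx[k], ]
    gs <- max(0L, tr$start - sample(100:400, 1L))
    ge <- min(cfg$chrom_length, tr$end + sample(100:400, 1L))
    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = sprintf("gene_mir_%02d", k), chrom = tr$chrom, start = gs, end = ge,
      strand = tr$strand, stringsAsFactors = FALSE)
  }
  all_iv <- rbind(truth[, c("chrom", "start", "end")], blocklist[, c("chrom", "start", "end")])
  for (b in seq_len(10L)) {
    for (try in 1:200) {
      chrom <- sample(chroms, 1L)
      gs <- sample.int(cfg$chrom_length - 1500L, 1L)
      ge <- gs + sample(400:1200, 1L)
      hit <- all_iv$chrom == chrom & all_iv$start < ge & gs < all_iv$end
      if (!any(hit)) {
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = sprintf("gene_bg_%02d", b), chrom = chrom, start = gs, end = ge,
          strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
        break
      }
    }
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(), chrom = character(), start = numeric(),
               end = numeric(), strand = character(), stringsAsFactors = FALSE)

  # reference set: one known-ortholog mature per planted family
  fams_used <- names(fam_mature)
  refs <- data.frame(
    mirna_id = sprintf("ath-%sa", sub("MIR", "miR", fams_used)),
    family = fams_used,
    residues = vapply(fams_used, function(f) .mutate_dna(fam_mature[[f]], cfg$ref_mismatches),
                      character(1L)),
    stringsAsFactors = FALSE)
  refs$length <- nchar(refs$residues)
  rownames(refs) <- NULL

  structure(list(genome = genome, genes = genes, truth = truth,
                 references = refs, blocklist = blocklist, config = cfg),
            class = "synth_genome")
}

#' @export
print.synth_genome <- function(x, ...) {
  cat(sprintf("Synthetic genome: %d chromosome(s) x %d nt, %d planted precursor(s), %d decoy repeat(s), %d gene model(s)\n",
              length(x$genome), x$config$chrom_length, nrow(x$truth),
              nrow(x$blocklist), nrow(x$genes)))
  invisible(x)
}

#' Write all fixtures of a synthetic genome to a directory
#'
#' Emits genome FASTA, reference mature FASTA (RNA alphabet), gene GFF3,
#' truth and blocklist TSVs.  Byte-identical across runs for a fixed seed.
#'
#' @param x a `synth_genome`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_genome <- function(x, dir) {
  stopifnot(inherits(x, "synth_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(x$genome, file.path(dir, "genome.fa"))
  refs <- stats::setNames(x$references$residues, x$references$mirna_id)
  write_fasta(refs, file.path(dir, "mature_refs.fa"), as_rna = TRUE)
  write_gff3(x$genes, file.path(dir, "genes.gff3"))
  write_tsv(x$truth, file.path(dir, "truth.tsv"))
  write_tsv(x$blocklist, file.path(dir, "blocklist.tsv"))
  invisible(dir)
}
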