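# Stage 1-2 of discovery: homology seeding against known matures, then
# einverted-style inverted-repeat detection inside candidate windows.

.WC <- c(A = "T", C = "G", G = "C", T = "A")

.as_reference_df <- function(references) {
  if (is.character(references)) {
    references <- data.frame(mirna_id = names(references),
                             residues = rna_to_dna(toupper(unname(references))),
                             stringsAsFactors = FALSE)
  }
  stopifnot(all(c("mirna_id", "residues") %in% names(references)))
  references$residues <- rna_to_dna(toupper(references$residues))
  references
}

#' Seed candidate regions by homology to known mature miRNAs
#'
#' Reports every genome window whose ungapped Hamming distance to a reference
#' mature (forward or reverse complement) is at most `max_mismatches`, once
#' per (reference, position, strand).  Mature miRNAs are too short for
#' meaningful gapped seeds, so no gapped alignment is attempted at this stage.
#'
#' @param genome named character vector of chromosome sequences (DNA).
#' @param references reference matures: named character vector or data.frame
#'   with columns `mirna_id`, `residues` (RNA accepted, normalized to DNA).
#' @param max_mismatches maximum Hamming distance (default 3).
#' @param both_strands also scan the reverse complement.
#' @return data.frame with columns `mirna_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `mismatches`.
#' @export
seed_by_homology <- function(genome, references, max_mismatches = 3L,
                             both_strands = TRUE) {
  refs <- .as_reference_df(references)
  short <- nchar(refs$residues) < 15L
  if (any(short)) {
    warning(sprintf("rejecting reference(s) shorter than 15 nt: %s",
                    paste(refs$mirna_id[short], collapse = ",")))
    refs <- refs[!short, , drop = FALSE]
  }
  out <- list()
  for (chrom in names(genome)) {
    gch <- strsplit(genome[[chrom]], "", fixed = TRUE)[[1L]]
    nc <- length(gch)
    for (r in seq_len(nrow(refs))) {
      pats <- list(`+` = refs$residues[r])
      if (both_strands) pats[["-"]] <- revcomp(refs$residues[r])
      for (strand in names(pats)) {
        pch <- strsplit(pats[[strand]], "", fixed = TRUE)[[1L]]
        L <- length(pch)
        if (L > nc) next
        nwin <- nc - L + 1L
        mism <- integer(nwin)
        for (t in seq_len(L)) {
          mism <- mism + (gch[t:(t + nwin - 1L)] != pch[t])
        }
        hit <- which(mism <= max_mismatches)
        if (length(hit)) {
          out[[length(out) + 1L]] <- data.frame(
            mirna_id = refs$mirna_id[r], chrom = chrom,
            start = hit - 1L, end = hit - 1L + L, strand = strand,
            mismatches = mism[hit], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(mirna_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$mirna_id, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Inverted-repeat scan parameters
#'
#' einverted-style scoring: the tool's documented defaults (+3 match, -4
#' mismatch, 12 per gap position, linear) with the study's threshold of 25
#' and maximum repeat extent of 336 nt.
#'
#' @param match,mismatch,gap alignment scores (gap is a positive penalty,
#'   applied per gap position, linear).
#' @param threshold minimum reported score.
#' @param max_extent maximum total extent (outer span) of a repeat, nt.
#' @param min_loop minimum unpaired spacer between the arms, nt.
#' @param hard_cap maximum window length accepted (caller must pre-window).
#' @return object of class `ir_params`.
#' @export
ir_params <- function(match = 3L, mismatch = -4L, gap = 12L, threshold = 25L,
                      max_extent = 336L, min_loop = 3L, hard_cap = 10000L) {
  stopifnot(threshold > 0, max_extent >= 2, gap >= 0)
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 threshold = threshold, max_extent = max_extent,
                 min_loop = min_loop, hard_cap = hard_cap),
            class = "ir_params")
}

# Fill the fold-alignment score matrix S[i, j] = best local score of an
# inverted repeat whose outermost aligned positions are exactly covered by
# [i, j].  Recurrence: pair i:j, or gap either arm (linear penalty); local
# floor at 0.  The in-row (gap on the right arm) dependence is resolved with
# a running-maximum transform, so the whole fill is vectorised per row.
.ir_fill <- function(x, p) {
  n <- length(x)
  S <- matrix(0, n, n)
  compx <- unname(.WC[x])            # NA for N
  for (i in seq(n - 1L, 1L)) {
    js <- seq(i + 1L, n)
    m <- length(js)
    subv <- ifelse(!is.na(compx[i]) & x[js] == compx[i], p$match, p$mismatch)
    inner <- numeric(m)              # S[i+1, j-1]; empty interior -> 0
    if (m >= 3L) inner[3:m] <- S[i + 1L, seq(i + 2L, n - 1L)]
    pairterm <- subv + inner
    fresh <- inner == 0 & (js - i - 1L) < p$min_loop
    pairterm[fresh] <- -Inf
    upterm <- S[i + 1L, js] - p$gap
    if (js[1L] == i + 1L) upterm[1L] <- -p$gap   # S[i+1, i+1] is empty = 0
    A <- pmax(pairterm, upterm)
    idx <- seq_len(m)
    B <- cummax(A + p$gap * idx) - p$gap * idx
    S[i, js] <- pmax(B, 0)
  }
  S
}

.ir_traceback <- function(S, x, p, i, j) {
  compx <- unname(.WC[x])
  sc <- function(a, b) if (b > a) S[a, b] else 0
  a <- i; b <- j
  pairs <- matrix(integer(), 0L, 2L)
  matches <- 0L; gaps <- 0L
  repeat {
    val <- sc(a, b)
    inner <- if (b - 1L > a + 1L) S[a + 1L, b - 1L] else 0
    sub <- if (!is.na(compx[a]) && x[b] == compx[a]) p$match else p$mismatch
    pair_ok <- (inner > 0) || (b - a - 1L) >= p$min_loop
    if (pair_ok && val == sub + inner) {
      pairs <- rbind(pairs, c(a, b))
      if (sub == p$match) matches <- matches + 1L
      if (inner == 0) break
      a <- a + 1L; b <- b - 1L
    } else if (val == sc(a + 1L, b) - p$gap) {
      gaps <- gaps + 1L; a <- a + 1L
    } else if (val == sc(a, b - 1L) - p$gap) {
      gaps <- gaps + 1L; b <- b - 1L
    } else {
      stop("internal error: inconsistent traceback")   # nocov
    }
  }
  last <- pairs[nrow(pairs), ]
  list(pairs = pairs, matches = matches, gaps = gaps,
       left_end = last[1L], right_start = last[2L])
}

#' Detect inverted repeats in a window
#'
#' Local alignment of the window against its own reverse complement with
#' linear gap penalties.  Reported repeats score at least the threshold, do
#' not exceed the maximum extent, do not overlap each other, and are sorted
#' by score (descending), then leftmost start, then shortest extent.
#'
#' @param sequence window sequence (DNA, one string).
#' @param params an [ir_params()].
#' @return data.frame with 0-based half-open arm intervals (`left_start`,
#'   `left_end`, `right_start`, `right_end`), `loop_len`, `score`,
#'   `identity` (percent of aligned columns that are Watson-Crick matches),
#'   `n_pairs`, `n_gaps`.
#' @export
scan_inverted_repeats <- function(sequence, params = ir_params()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- rna_to_dna(toupper(sequence))
  n <- nchar(sequence)
  if (n > params$hard_cap) {
    stop(sprintf("window of %d nt exceeds the hard cap (%d); pre-window the input",
                 n, params$hard_cap))
  }
  empty <- data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      loop_len = integer(), score = numeric(),
                      identity = numeric(), n_pairs = integer(),
                      n_gaps = integer(), stringsAsFactors = FALSE)
  if (n < 2L * 1L + params$min_loop) return(empty)
  x <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  S <- .ir_fill(x, params)
  cand <- which(S >= params$threshold, arr.ind = TRUE)
  if (nrow(cand)) {
    span <- cand[, 2L] - cand[, 1L] + 1L
    cand <- cand[span <= params$max_extent, , drop = FALSE]
  }
  if (!nrow(cand)) return(empty)
  sc <- S[cand]
  ord <- order(-sc, cand[, 1L], cand[, 2L] - cand[, 1L])
  cand <- cand[ord, , drop = FALSE]; sc <- sc[ord]
  taken <- matrix(integer(), 0L, 2L)
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (nrow(taken) &&
        any(intervals_overlap(i, j + 1L, taken[, 1L], taken[, 2L] + 1L))) next
    tb <- .ir_traceback(S, x, params, i, j)
    taken <- rbind(taken, c(i, j))
    ncols <- nrow(tb$pairs) + tb$gaps
    rows[[length(rows) + 1L]] <- data.frame(
      left_start = i - 1L, left_end = tb$left_end,
      right_start = tb$right_start - 1L, right_end = j,
      loop_len = tb$right_start - tb$left_end - 1L,
      score = sc[k], identity = 100 * tb$matches / ncols,
      n_pairs = nrow(tb$pairs), n_gaps = tb$gaps, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res <- res[order(-res$score, res$left_start,
                   res$right_end - res$left_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Expand seeds into merged candidate windows
#'
#' Windows are centered on each seed with `flank` nt each side (default one
#' maximum repeat extent), clipped at chromosome ends, and merged when they
#' overlap; seed provenance is retained.
#'
#' @param seeds data.frame from [seed_by_homology()].
#' @param genome named character vector of chromosome sequences.
#' @param flank flank size in nt.
#' @return data.frame with `window_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `seed_ids` (semicolon-joined row indices into `seeds`),
#'   `n_seeds`.
#' @export
window_candidates <- function(seeds, genome, flank = 336L) {
  empty <- data.frame(window_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      seed_ids = character(), n_seeds = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(seeds)) return(empty)
  out <- list()
  for (chrom in unique(seeds$chrom)) {
    clen <- nchar(genome[[chrom]])
    s <- seeds[seeds$chrom == chrom, , drop = FALSE]
    ws <- pmax(0L, s$start - flank)
    we <- pmin(clen, s$end + flank)
    ord <- order(ws, we)
    ws <- ws[ord]; we <- we[ord]; ids <- rownames(s)[ord]
    cur_s <- ws[1L]; cur_e <- we[1L]; cur_ids <- ids[1L]
    flush <- function() {
      out[[length(out) + 1L]] <<- data.frame(
        window_id = sprintf("%s:%d-%d", chrom, cur_s, cur_e),
        chrom = chrom, start = cur_s, end = cur_e,
        seed_ids = paste(cur_ids, collapse = ";"),
        n_seeds = length(cur_ids), stringsAsFactors = FALSE)
    }
    for (k in seq_along(ws)[-1L]) {
      if (ws[k] <= cur_e) {
        cur_e <- max(cur_e, we[k]); cur_ids <- c(cur_ids, ids[k])
      } else {
        flush(); cur_s <- ws[k]; cur_e <- we[k]; cur_ids <- ids[k]
      }
    }
    flush()
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
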