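# psRNATarget-style miRNA target scoring: per-position penalty sum
# (mismatch 1, G:U wobble 0.5, gap 2), doubled inside the 5' seed region
# (miRNA positions 2-13), with a maximum-expectation cutoff and the central
# mismatch (positions 9-11) translational-inhibition call.

#' Target scoring parameters
#'
#' Defaults follow the published psRNATarget scoring schema (V1) with the
#' study's settings: maximum expectation 2.0, complementarity window
#' (hspsize) 20 nt, central mismatch window 9-11 for the translational
#' inhibition call.  The UPE (target accessibility) cutoff is carried
#' through as a recorded field; the energy itself is not computed.
#'
#' @param expectation_cutoff maximum expectation reported (inclusive).
#' @param hspsize complementarity scoring window (nt).
#' @param seed_window miRNA positions (from the 5' end) whose penalties are
#'   doubled.
#' @param mismatch_penalty,gu_penalty,gap_penalty per-position penalties.
#' @param central_window miRNA positions whose mismatch calls translational
#'   inhibition.
#' @param max_gaps maximum gaps per duplex (0 or 1).
#' @param upe_cutoff recorded UPE cutoff (pass-through only).
#' @return object of class `target_params`.
#' @export
target_params <- function(expectation_cutoff = 2.0, hspsize = 20L,
                          seed_window = c(2L, 13L), mismatch_penalty = 1.0,
                          gu_penalty = 0.5, gap_penalty = 2.0,
                          central_window = c(9L, 11L), max_gaps = 1L,
                          upe_cutoff = 25) {
  stopifnot(expectation_cutoff >= 0, max_gaps %in% 0:1,
            seed_window[1L] <= seed_window[2L])
  structure(list(expectation_cutoff = expectation_cutoff,
                 hspsize = as.integer(hspsize), seed_window = as.integer(seed_window),
                 mismatch_penalty = mismatch_penalty, gu_penalty = gu_penalty,
                 gap_penalty = gap_penalty, central_window = as.integer(central_window),
                 max_gaps = as.integer(max_gaps), upe_cutoff = upe_cutoff),
            class = "target_params")
}

.pos_mult <- function(t, params) {
  ifelse(t >= params$seed_window[1L] & t <= params$seed_window[2L], 2, 1)
}

# Penalty of one miRNA base (DNA alphabet) against one target base.
.pair_penalty <- function(m, s, params) {
  comp <- .WC[m]
  gu <- (m == "G" & s == "T") | (m == "T" & s == "G")
  ifelse(!is.na(comp) & s == comp, 0, ifelse(gu, params$gu_penalty,
                                             params$mismatch_penalty))
}

#' Score one miRNA/target-site duplex
#'
#' The site is given in transcript orientation (5'->3') and is paired
#' antiparallel to the miRNA.  Expectation is the sum of per-position
#' penalties, doubled at miRNA seed positions; at most one gap (site bulge
#' or miRNA bulge) is allowed, its position enumerated exhaustively and the
#' best alignment kept.
#'
#' @param mirna mature miRNA (RNA or DNA, 5'->3').
#' @param site target site (transcript orientation; length within the gap
#'   tolerance of the miRNA length).
#' @param params a [target_params()].
#' @return list: `expectation`, `alignment` (three-row text), `mismatch_at`
#'   (miRNA positions of mismatches), `gu_at`, `gap_at`, `inhibition`.
#' @export
score_duplex <- function(mirna, site, params = target_params()) {
  m <- strsplit(rna_to_dna(toupper(mirna)), "", fixed = TRUE)[[1L]]
  s <- strsplit(rna_to_dna(toupper(site)), "", fixed = TRUE)[[1L]]
  L <- length(m); Ls <- length(s)
  if (abs(Ls - L) > params$max_gaps) {
    stop(sprintf("site length %d outside gap tolerance of miRNA length %d", Ls, L))
  }
  # candidate alignments: site index paired with each miRNA position
  # (NA = miRNA base bulged), plus the position charged for a site bulge
  layouts <- list()
  if (Ls == L) {
    layouts[[1L]] <- list(map = Ls + 1L - seq_len(L), gap_at = integer())
  } else if (Ls == L - 1L) {
    for (g in seq_len(L)) {
      map <- integer(L)
      ts <- seq_len(L)
      map[ts < g] <- Ls + 1L - ts[ts < g]
      map[ts > g] <- Ls + 2L - ts[ts > g]
      map[g] <- NA_integer_
      layouts[[length(layouts) + 1L]] <- list(map = map, gap_at = g)
    }
  } else {
    for (g in seq_len(L - 1L)) {
      ts <- seq_len(L)
      map <- ifelse(ts <= g, Ls + 1L - ts, Ls - ts)
      layouts[[length(layouts) + 1L]] <- list(map = map, gap_at = g)
    }
  }
  best <- NULL
  for (lay in layouts) {
    t_idx <- which(!is.na(lay$map))
    pen <- .pair_penalty(m[t_idx], s[lay$map[t_idx]], params) * .pos_mult(t_idx, params)
    gpen <- if (length(lay$gap_at)) params$gap_penalty * .pos_mult(lay$gap_at, params) else 0
    tot <- sum(pen) + sum(gpen)
    if (is.null(best) || tot < best$tot) best <- list(tot = tot, lay = lay, pen = pen)
  }
  lay <- best$lay
  t_idx <- which(!is.na(lay$map))
  raw <- .pair_penalty(m[t_idx], s[lay$map[t_idx]], params)
  mismatch_at <- t_idx[raw == params$mismatch_penalty]
  gu_at <- t_idx[raw == params$gu_penalty]
  cw <- params$central_window
  bad <- c(mismatch_at, lay$gap_at)
  inhibition <- if (any(bad >= cw[1L] & bad <= cw[2L])) "translation" else "cleavage"
  bond <- function(t) {
    if (t %in% mismatch_at) " " else if (t %in% gu_at) "o" else "|"
  }
  bonds <- if (Ls == L) {
    paste(vapply(seq_len(Ls), function(c) bond(L + 1L - c), character(1L)),
          collapse = "")
  } else {
    strrep("~", Ls)    # gapped duplex: per-column bonds not displayed
  }
  site_line <- paste(s, collapse = "")
  mirna_line <- paste(rev(dna_to_rna(m)), collapse = "")
  list(expectation = best$tot,
       alignment = paste0("5' ", dna_to_rna(site_line), " 3' (target)\n   ",
                          bonds, "\n3' ", mirna_line, " 5' (miRNA)"),
       mismatch_at = mismatch_at, gu_at = gu_at,
       gap_at = lay$gap_at, inhibition = inhibition)
}

#' Find miRNA target sites in transcripts
#'
#' All sites with expectation at or below the cutoff are reported; per
#' miRNA, overlapping candidate sites are resolved leftmost-best (lowest
#' expectation, then leftmost).  Inhibition is `"translation"` iff at least
#' one mismatched or unpaired position falls wholly within the central
#' window (miRNA positions 9-11), else `"cleavage"`.
#'
#' @param mirnas named character vector of mature miRNAs (RNA or DNA).
#' @param transcripts named character vector of transcript sequences.
#' @param params a [target_params()].
#' @return data.frame: `mirna_id`, `transcript_id`, `start`, `end` (1-based
#'   inclusive site coordinates), `expectation`, `inhibition`, `upe`
#'   (pass-through, `NA`).
#' @export
find_targets <- function(mirnas, transcripts, params = target_params()) {
  rows <- list()
  for (mid in names(mirnas)) {
    m <- strsplit(rna_to_dna(toupper(mirnas[[mid]])), "", fixed = TRUE)[[1L]]
    L <- length(m)
    for (tid in names(transcripts)) {
      tx <- strsplit(rna_to_dna(toupper(transcripts[[tid]])), "", fixed = TRUE)[[1L]]
      n <- length(tx)
      cand <- list()
      site_lens <- unique(pmax(1L, L + seq(-params$max_gaps, params$max_gaps)))
      for (Ls in site_lens) {
        if (Ls > n) next
        np <- n - Ls + 1L
        # gapless core: expectation for every start, vectorised over starts
        if (Ls == L) {
          pen <- numeric(np)
          for (t in seq_len(L)) {
            tb <- tx[seq_len(np) + Ls - t]
            pen <- pen + .pair_penalty(m[t], tb, params) * .pos_mult(t, params)
          }
          hit <- which(pen <= params$expectation_cutoff)
          for (p in hit) cand[[length(cand) + 1L]] <- c(p, Ls, pen[p])
        } else {
          gs <- if (Ls < L) seq_len(L) else seq_len(L - 1L)
          best <- rep(Inf, np)
          for (g in gs) {
            pen <- rep(params$gap_penalty * .pos_mult(g, params), np)
            for (t in seq_len(L)) {
              if (Ls < L && t == g) next
              w <- if (Ls < L) { if (t < g) Ls + 1L - t else Ls + 2L - t }
                   else { if (t <= g) Ls + 1L - t else Ls - t }
              tb <- tx[seq_len(np) + w - 1L]
              pen <- pen + .pair_penalty(m[t], tb, params) * .pos_mult(t, params)
            }
            best <- pmin(best, pen)
          }
          hit <- which(best <= params$expectation_cutoff)
          for (p in hit) cand[[length(cand) + 1L]] <- c(p, Ls, best[p])
        }
      }
      if (!length(cand)) next
      cm <- do.call(rbind, cand)
      cm <- cm[order(cm[, 3L], cm[, 1L]), , drop = FALSE]
      kept <- matrix(numeric(), 0L, 3L)
      for (k in seq_len(nrow(cm))) {
        s0 <- cm[k, 1L]; e0 <- cm[k, 1L] + cm[k, 2L] - 1L
        if (nrow(kept) &&
            any(kept[, 1L] <= e0 & s0 <= kept[, 1L] + kept[, 2L] - 1L)) next
        kept <- rbind(kept, cm[k, ])
      }
      for (k in seq_len(nrow(kept))) {
        p <- kept[k, 1L]; Ls <- kept[k, 2L]
        site <- paste(tx[p:(p + Ls - 1L)], collapse = "")
        sd <- score_duplex(paste(m, collapse = ""), site, params)
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = mid, transcript_id = tid, start = p, end = p + Ls - 1L,
          expectation = sd$expectation, inhibition = sd$inhibition,
          upe = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      start = integer(), end = integer(), expectation = numeric(),
                      inhibition = character(), upe = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$mirna_id, res$expectation, res$transcript_id, res$start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

.mir_family_of <- function(id) {
  m <- regmatches(id, regexpr("[Mm][Ii][Rr][0-9]+", id))
  ifelse(lengths(regmatches(id, gregexpr("[Mm][Ii][Rr][0-9]+", id))) > 0,
         toupper(sub("miR", "MIR", m, ignore.case = TRUE)), id)
}

#' Tally targets per miRNA family and miRNAs per transcript
#'
#' @param hits data.frame from [find_targets()].
#' @return list: `per_family` (distinct target transcripts per miRNA
#'   family), `per_transcript` (distinct miRNAs per transcript).
#' @export
summarize_targets <- function(hits) {
  if (!nrow(hits)) {
    return(list(per_family = table(character()),
                per_transcript = table(character())))
  }
  fam <- vapply(hits$mirna_id, function(id) {
    m <- regmatches(id, regexpr("[Mm][Ii][Rr][0-9]+", id))
    if (length(m)) toupper(m) else id
  }, character(1L), USE.NAMES = FALSE)
  per_family <- vapply(split(hits$transcript_id, fam),
                       function(x) length(unique(x)), integer(1L))
  per_transcript <- vapply(split(hits$mirna_id, hits$transcript_id),
                           function(x) length(unique(x)), integer(1L))
  list(per_family = per_family[order(names(per_family))],
       per_transcript = per_transcript[order(names(per_transcript))])
}
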