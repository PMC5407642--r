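# The filter cascade turning hairpin candidates into accepted precursors,
# with per-candidate rejection reasons.

#' Filter thresholds for precursor acceptance
#'
#' Inclusive windows.  The GC window (20-65%) is the study's stated filter;
#' the MFEI minimum of 0.7 and the precursor length window bracket the
#' accepted plant-precursor range (observed 68-338 nt, MFEI 0.7-1.7); MFE is
#' only required to be negative; any overlap with a blocklist interval
#' (repeats, ncRNAs) rejects.
#'
#' @param gc_window inclusive GC%% window.
#' @param mfei_min minimum MFEI.
#' @param length_window inclusive precursor length window (nt).
#' @param mature_max_mismatches maximum mismatches between the candidate
#'   mature and its closest reference.
#' @return object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(gc_window = c(20, 65), mfei_min = 0.7,
                              length_window = c(60L, 338L),
                              mature_max_mismatches = 3L) {
  stopifnot(gc_window[1L] <= gc_window[2L],
            length_window[1L] <= length_window[2L],
            is.finite(mfei_min))
  structure(list(gc_window = gc_window, mfei_min = mfei_min,
                 length_window = length_window,
                 mature_max_mismatches = as.integer(mature_max_mismatches)),
            class = "filter_thresholds")
}

#' Closed vocabulary of rejection reason codes
#' @export
FILTER_REASONS <- c("LENGTH", "GC_RANGE", "MFE_SIGN", "MFEI_MIN",
                    "MATURE_PLACEMENT", "MATURE_HOMOLOGY", "BLOCKLIST")

.need <- function(candidate, field) {
  v <- candidate[[field]]
  if (is.null(v) || (length(v) == 1L && is.na(v) && field != "mature_mismatches")) {
    stop(sprintf("candidate '%s' is missing descriptor '%s'",
                 candidate$id %||% "?", field))
  }
  v
}

#' Apply the acceptance filter cascade to one candidate
#'
#' Filters are evaluated in fixed order (length, GC window, MFE < 0, MFEI
#' minimum, valid mature placement, mature homology, blocklist overlap) and
#' all failures are reported, not just the first.
#'
#' @param candidate list or one-row data.frame with fields `id`, `length`,
#'   `gc`, `mfe`, `mfei`, `mature_valid`, `mature_mismatches`, `chrom`,
#'   `start`, `end`.
#' @param thresholds a [filter_thresholds()].
#' @param blocklist data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), or `NULL`.
#' @return list: `candidate_id`, `accepted`, `reasons` (character vector
#'   drawn from [FILTER_REASONS]; empty iff accepted).
#' @export
apply_cascade <- function(candidate, thresholds = filter_thresholds(),
                          blocklist = NULL) {
  reasons <- character()
  len <- .need(candidate, "length")
  if (len < thresholds$length_window[1L] || len > thresholds$length_window[2L]) {
    reasons <- c(reasons, "LENGTH")
  }
  gc <- .need(candidate, "gc")
  if (gc < thresholds$gc_window[1L] || gc > thresholds$gc_window[2L]) {
    reasons <- c(reasons, "GC_RANGE")
  }
  mfe <- .need(candidate, "mfe")
  if (!(mfe < 0)) reasons <- c(reasons, "MFE_SIGN")
  mfei_v <- .need(candidate, "mfei")
  if (mfei_v < thresholds$mfei_min) reasons <- c(reasons, "MFEI_MIN")
  if (!isTRUE(.need(candidate, "mature_valid"))) {
    reasons <- c(reasons, "MATURE_PLACEMENT")
  }
  mm <- candidate$mature_mismatches
  if (is.null(mm)) stop(sprintf("candidate '%s' is missing descriptor 'mature_mismatches'",
                                candidate$id %||% "?"))
  if (is.na(mm) || mm > thresholds$mature_max_mismatches) {
    reasons <- c(reasons, "MATURE_HOMOLOGY")
  }
  if (!is.null(blocklist) && nrow(blocklist)) {
    hit <- blocklist$chrom == candidate$chrom &
      intervals_overlap(candidate$start, candidate$end, blocklist$start, blocklist$end)
    if (any(hit)) reasons <- c(reasons, "BLOCKLIST")
  }
  list(candidate_id = candidate$id %||% NA_character_,
       accepted = length(reasons) == 0L, reasons = reasons)
}

#' Resolve overlapping accepted candidates to one precursor per locus
#'
#' Among candidates overlapping on the same chromosome and strand, the one
#' with the lowest MFE is kept; ties go to the longest, then leftmost.
#'
#' @param candidates data.frame with `id`, `chrom`, `start`, `end`,
#'   `strand`, `mfe`.
#' @return list: `kept` (subset of `candidates`), `dropped` (with a
#'   `superseded_by` provenance column).
#' @export
resolve_overlaps <- function(candidates) {
  if (!nrow(candidates)) {
    return(list(kept = candidates,
                dropped = cbind(candidates, superseded_by = character())))
  }
  keep <- logical(nrow(candidates))
  superseded <- rep(NA_character_, nrow(candidates))
  for (key in unique(paste(candidates$chrom, candidates$strand))) {
    idx <- which(paste(candidates$chrom, candidates$strand) == key)
    idx <- idx[order(candidates$start[idx])]
    # connected components of the overlap graph by interval chaining
    comp <- integer(length(idx)); cur <- 0L; maxe <- -Inf
    for (k in seq_along(idx)) {
      if (candidates$start[idx[k]] >= maxe) cur <- cur + 1L
      comp[k] <- cur
      maxe <- max(maxe, candidates$end[idx[k]])
    }
    for (g in unique(comp)) {
      members <- idx[comp == g]
      lens <- candidates$end[members] - candidates$start[members]
      ord <- order(candidates$mfe[members], -lens, candidates$start[members])
      win <- members[ord[1L]]
      keep[win] <- TRUE
      superseded[setdiff(members, win)] <- candidates$id[win]
    }
  }
  dropped <- candidates[!keep, , drop = FALSE]
  dropped$superseded_by <- superseded[!keep]
  list(kept = candidates[keep, , drop = FALSE], dropped = dropped)
}

#' Assign a MIR family by closest reference mature
#'
#' @param mature candidate mature sequence (DNA or RNA).
#' @param references data.frame with `mirna_id`, `family`, `residues`.
#' @param max_mismatches maximum accepted mismatch count.
#' @return list: `family`, `mismatches`, `mirna_id`; family is `NA` when no
#'   reference is within `max_mismatches`.
#' @export
assign_family <- function(mature, references, max_mismatches = 3L) {
  stopifnot(nrow(references) > 0L)
  mature <- rna_to_dna(toupper(mature))
  mm <- vapply(references$residues, function(ref) {
    ref <- rna_to_dna(toupper(ref))
    a <- mature; b <- ref
    if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
    la <- nchar(a); lb <- nchar(b)
    ach <- strsplit(a, "", fixed = TRUE)[[1L]]
    bch <- strsplit(b, "", fixed = TRUE)[[1L]]
    best <- Inf
    for (off in 0:(lb - la)) {
      best <- min(best, sum(ach != bch[(off + 1L):(off + la)]))
    }
    best + (lb - la)
  }, numeric(1L), USE.NAMES = FALSE)
  ok <- which(mm <= max_mismatches)
  if (!length(ok)) {
    return(list(family = NA_character_, mismatches = NA_integer_,
                mirna_id = NA_character_))
  }
  ord <- ok[order(mm[ok], references$family[ok])]
  best <- ord[1L]
  list(family = references$family[best], mismatches = as.integer(mm[best]),
       mirna_id = references$mirna_id[best])
}

# ccp-style locus names: per family, letter suffix by genomic order.
.mir_locus_names <- function(families, chrom, start) {
  out <- character(length(families))
  for (f in unique(families)) {
    idx <- which(families == f)
    idx <- idx[order(chrom[idx], start[idx])]
    suffix <- if (length(idx) == 1L) "" else letters[seq_along(idx)]
    out[idx] <- paste0("ccp-", f, suffix)
  }
  out
}
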