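# Folding and thermodynamic/compositional descriptors of candidate
# precursors.  The folding engine is pluggable: the built-in fallback engine
# is a deterministic base-pair maximisation with a stacking bonus (integer
# energies, no external dependency); the "vienna" engine shells out to
# RNAfold when it is on the PATH.

RT_KCAL <- 0.61633   # kcal/mol at 37 C

.PAIR_ENERGY <- c("GC" = -3, "CG" = -3, "AT" = -2, "TA" = -2, "GT" = -1, "TG" = -1)
.STACK_BONUS <- -1
.MIN_LOOP <- 3L

.pair_energy <- function(a, b) {
  e <- .PAIR_ENERGY[paste0(a, b)]
  unname(e)
}

.check_fold_input <- function(sequence) {
  sequence <- rna_to_dna(toupper(sequence))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (mean(chars == "N") > 0.10) {
    stop("sequence has more than 10% N; refusing to fold")
  }
  chars
}

.score_structure <- function(chars, pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(0)
  e <- sum(.PAIR_ENERGY[paste0(chars[pairs[, 1L]], chars[pairs[, 2L]])])
  key <- paste(pairs[, 1L], pairs[, 2L])
  stacked <- sum(paste(pairs[, 1L] + 1L, pairs[, 2L] - 1L) %in% key)
  e + .STACK_BONUS * stacked
}

.pairs_to_dotbracket <- function(pairs, n) {
  db <- rep(".", n)
  if (!is.null(pairs) && nrow(pairs)) {
    db[pairs[, 1L]] <- "("
    db[pairs[, 2L]] <- ")"
  }
  paste(db, collapse = "")
}

.dotbracket_to_pairs <- function(db) {
  chars <- strsplit(db, "", fixed = TRUE)[[1L]]
  stack <- integer(); out <- list()
  for (k in seq_along(chars)) {
    if (chars[k] == "(") stack <- c(stack, k)
    else if (chars[k] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      out[[length(out) + 1L]] <- c(stack[length(stack)], k)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  if (!length(out)) matrix(integer(), 0L, 2L) else do.call(rbind, out)
}

# Fallback MFE fold: minimise integer energy (pair energies + stacking bonus,
# minimum hairpin loop of 3) by dynamic programming; traceback prefers
# pairing the 5'-most base, with the outermost admissible partner.
.fallback_fold <- function(chars) {
  n <- length(chars)
  if (n < .MIN_LOOP + 2L) {
    return(list(pairs = matrix(integer(), 0L, 2L), mfe = 0))
  }
  P <- matrix(Inf, n, n)   # best energy with (i,j) paired
  M <- matrix(0, n, n)     # best energy of segment [i,j] (<= 0; empty allowed)
  U <- matrix(0, n, n)     # best energy with i,j not paired to each other
  for (i in seq(n - .MIN_LOOP - 1L, 1L)) {
    for (j in seq(i + .MIN_LOOP + 1L, n)) {
      pe <- .pair_energy(chars[i], chars[j])
      if (!is.na(pe)) {
        a <- i + 1L; b <- j - 1L
        interior <- min(U[a, b], P[a, b] + .STACK_BONUS)
        P[i, j] <- pe + min(0, interior)
      }
      ls <- seq(i + .MIN_LOOP + 1L, j)
      after <- c(if (length(ls) > 1L) M[cbind(ls[-length(ls)] + 1L, j)], 0)
      vals <- P[i, ls] + after
      U[i, j] <- min(M[i + 1L, j], vals[-length(vals)], Inf)
      M[i, j] <- min(U[i, j], P[i, j])
    }
  }
  pairs <- matrix(integer(), 0L, 2L)
  trace_M <- function(i, j) {
    while (j - i > .MIN_LOOP) {
      ls <- seq(j, i + .MIN_LOOP + 1L)    # outermost partner first
      hit <- FALSE
      for (l in ls) {
        after <- if (l < j) M[l + 1L, j] else 0
        if (is.finite(P[i, l]) && P[i, l] + after == M[i, j]) {
          trace_P(i, l)
          if (l < j) { i2 <- l + 1L; i <- i2 } else return(invisible())
          hit <- TRUE
          break
        }
      }
      if (!hit) i <- i + 1L
    }
  }
  trace_P <- function(i, j) {
    repeat {
      pairs <<- rbind(pairs, c(i, j))
      a <- i + 1L; b <- j - 1L
      if (b - a <= .MIN_LOOP) return(invisible())
      pe <- .pair_energy(chars[i], chars[j])
      interior <- min(0, U[a, b], P[a, b] + .STACK_BONUS)
      if (is.finite(P[a, b]) && interior == P[a, b] + .STACK_BONUS) {
        i <- a; j <- b          # stacked continuation
      } else if (interior == 0 && U[a, b] >= 0) {
        return(invisible())     # hairpin loop
      } else {
        trace_M(a, b)
        return(invisible())
      }
    }
  }
  if (M[1L, n] < 0) trace_M(1L, n)
  mfe <- min(0, M[1L, n])
  if (nrow(pairs)) pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  stopifnot(.score_structure(chars, pairs) == mfe)
  list(pairs = pairs, mfe = mfe)
}

.vienna_run <- function(sequence, partition = FALSE) {
  rnafold <- Sys.which("RNAfold")
  if (!nzchar(rnafold)) stop("RNAfold not found on PATH; vienna engine unavailable")
  old <- setwd(tempdir()); on.exit(setwd(old))
  args <- c("--noPS")
  if (partition) args <- c(args, "-p")
  out <- system2(rnafold, args, input = dna_to_rna(sequence), stdout = TRUE)
  out
}

#' Predict the minimum-free-energy secondary structure
#'
#' @param sequence RNA or DNA sequence (one string; stored alphabet is DNA).
#' @param engine `"fallback"` (built-in base-pair maximisation with stacking
#'   bonus; deterministic, integer energies) or `"vienna"` (RNAfold).
#' @return list of class `rna_fold`: `structure` (dot-bracket), `pairs`
#'   (2-column matrix, 1-based), `mfe`, `engine`, `sequence`.
#' @export
fold_rna <- function(sequence, engine = c("fallback", "vienna")) {
  engine <- match.arg(engine)
  chars <- .check_fold_input(sequence)
  n <- length(chars)
  if (engine == "fallback") {
    f <- .fallback_fold(chars)
    res <- list(structure = .pairs_to_dotbracket(f$pairs, n), pairs = f$pairs,
                mfe = f$mfe, engine = "fallback",
                sequence = paste(chars, collapse = ""))
  } else {
    out <- .vienna_run(paste(chars, collapse = ""))
    m <- regmatches(out[2L], regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", out[2L]))[[1L]]
    if (length(m) != 3L) stop("could not parse RNAfold output")
    res <- list(structure = m[2L], pairs = .dotbracket_to_pairs(m[2L]),
                mfe = as.numeric(m[3L]), engine = "vienna",
                sequence = paste(chars, collapse = ""))
  }
  class(res) <- "rna_fold"
  res
}

#' @export
print.rna_fold <- function(x, ...) {
  cat(dna_to_rna(x$sequence), "\n", x$structure,
      sprintf("  (MFE %.2f, %s engine)\n", x$mfe, x$engine), sep = "")
  invisible(x)
}

# Exact partition function over all nested structures (min hairpin loop 3)
# under the fallback energy model: inside recursions for Zp (pair i:j), ZU
# (i and j not paired together) and ZM (all structures).  `ban` zeroes the
# Boltzmann weight of one specific pair, which is how pair probabilities
# are obtained (p = 1 - Z_without_pair / Z).
.pf_inside <- function(chars, ban = NULL) {
  n <- length(chars)
  wb <- exp(-.STACK_BONUS / RT_KCAL)
  W <- matrix(0, n, n)
  if (n >= .MIN_LOOP + 2L) {
    for (i in seq_len(n - .MIN_LOOP - 1L)) {
      js <- seq(i + .MIN_LOOP + 1L, n)
      e <- .PAIR_ENERGY[paste0(chars[i], chars[js])]
      W[i, js] <- ifelse(is.na(e), 0, exp(-e / RT_KCAL))
    }
  }
  if (!is.null(ban)) W[ban[1L], ban[2L]] <- 0
  ZM <- matrix(1, n, n); ZU <- matrix(1, n, n); Zp <- matrix(0, n, n)
  if (n >= .MIN_LOOP + 2L) {
    for (i in seq(n - .MIN_LOOP - 1L, 1L)) {
      for (j in seq(i + .MIN_LOOP + 1L, n)) {
        Zp[i, j] <- W[i, j] * (ZU[i + 1L, j - 1L] + wb * Zp[i + 1L, j - 1L])
        ls <- seq(i + .MIN_LOOP + 1L, j)
        lt <- ls[ls < j]
        ZU[i, j] <- ZM[i + 1L, j] +
          (if (length(lt)) sum(Zp[i, lt] * ZM[cbind(lt + 1L, j)]) else 0)
        ZM[i, j] <- ZU[i, j] + Zp[i, j]
      }
    }
  }
  list(Z = ZM[1L, n], Zp = Zp)
}

#' Ensemble thermodynamics of a sequence
#'
#' Computes the ensemble free energy `MFEE = -RT ln Z`, the frequency of the
#' MFE structure in the ensemble `exp((MFEE - MFE)/RT)`, and the ensemble
#' diversity (expected base-pair distance between two structures drawn from
#' the Boltzmann ensemble).  The fallback engine enumerates the complete
#' structure ensemble exhaustively and therefore refuses sequences longer
#' than 30 nt; configure the `vienna` engine for full-length precursors.
#'
#' @inheritParams fold_rna
#' @return list: `mfee`, `diversity`, `frequency`, `mfe`, `engine`.
#' @export
ensemble_stats <- function(sequence, engine = c("fallback", "vienna")) {
  engine <- match.arg(engine)
  chars <- .check_fold_input(sequence)
  n <- length(chars)
  if (engine == "fallback") {
    if (n > 30L) {
      stop("engine required: the fallback ensemble is summed exhaustively and is limited to 30 nt")
    }
    pf <- .pf_inside(chars)
    Z <- pf$Z
    mfe <- .fallback_fold(chars)$mfe
    mfee <- -RT_KCAL * log(Z)
    freq <- exp((mfee - mfe) / RT_KCAL)
    # pair probabilities by banning each admissible pair in turn
    cand <- which(pf$Zp > 0, arr.ind = TRUE)
    diversity <- 0
    for (r in seq_len(nrow(cand))) {
      p <- 1 - .pf_inside(chars, ban = cand[r, ])$Z / Z
      diversity <- diversity + 2 * p * (1 - p)
    }
    list(mfee = mfee, diversity = diversity, frequency = freq,
         mfe = mfe, engine = "fallback")
  } else {
    out <- .vienna_run(paste(chars, collapse = ""), partition = TRUE)
    mfe_m <- regmatches(out[2L], regexec("\\(\\s*(-?[0-9.]+)\\)\\s*$", out[2L]))[[1L]]
    ens_m <- regmatches(out[3L], regexec("\\[\\s*(-?[0-9.]+)\\]\\s*$", out[3L]))[[1L]]
    last <- out[grepl("frequency of mfe structure", out)]
    fr_m <- regmatches(last, regexec("ensemble\\s+([0-9.eE+-]+);", last))[[1L]]
    dv_m <- regmatches(last, regexec("diversity\\s+([0-9.eE+-]+)", last))[[1L]]
    if (length(mfe_m) != 2L || length(ens_m) != 2L) stop("could not parse RNAfold -p output")
    list(mfee = as.numeric(ens_m[2L]), diversity = as.numeric(dv_m[2L]),
         frequency = as.numeric(fr_m[2L]), mfe = as.numeric(mfe_m[2L]),
         engine = "vienna")
  }
}

#' Length-adjusted minimum free energy
#'
#' `AMFE = (MFE / length) * 100`, i.e. the MFE normalized to a 100-nt
#' sequence (kcal/mol per 100 nt).
#'
#' @param mfe minimum free energy (kcal/mol, non-positive).
#' @param length sequence length in nt (> 0).
#' @return AMFE.
#' @export
amfe <- function(mfe, length) {
  stopifnot(all(length > 0))
  (mfe / length) * 100
}

#' Minimal free energy index
#'
#' `MFEI = |AMFE| / GC%`, reported as a positive magnitude; the convention
#' that reproduces the plant-miRNA literature scale (values around 0.7-1.7
#' for genuine precursors).
#'
#' @param amfe adjusted MFE (kcal/mol per 100 nt).
#' @param gc_percent GC content in percent (> 0).
#' @return MFEI (dimensionless).
#' @export
mfei <- function(amfe, gc_percent) {
  if (any(gc_percent <= 0)) stop("MFEI undefined for GC% = 0")
  abs(amfe) / gc_percent
}

.gc_percent <- function(sequence) {
  chars <- strsplit(rna_to_dna(toupper(sequence)), "", fixed = TRUE)[[1L]]
  chars <- chars[chars != "N"]
  100 * mean(chars %in% c("G", "C"))
}

#' Base composition of a sequence
#'
#' Percentages are computed over non-N residues; T is reported as U (RNA
#' display convention).  Ratios with a zero denominator are reported as `NA`.
#'
#' @param sequence RNA or DNA sequence (one string).
#' @return named list: `A`, `U`, `C`, `G`, `GC`, `AU` (percent), `GC_ratio`
#'   (G/C), `AU_ratio` (A/U).
#' @export
base_composition <- function(sequence) {
  stopifnot(nzchar(sequence))
  chars <- strsplit(rna_to_dna(toupper(sequence)), "", fixed = TRUE)[[1L]]
  chars <- chars[chars != "N"]
  n <- length(chars)
  cnt <- vapply(c("A", "T", "C", "G"), function(b) sum(chars == b), numeric(1L))
  pct <- 100 * cnt / n
  list(A = pct[["A"]], U = pct[["T"]], C = pct[["C"]], G = pct[["G"]],
       GC = pct[["G"]] + pct[["C"]], AU = pct[["A"]] + pct[["T"]],
       GC_ratio = if (cnt[["C"]] > 0) cnt[["G"]] / cnt[["C"]] else NA_real_,
       AU_ratio = if (cnt[["T"]] > 0) cnt[["A"]] / cnt[["T"]] else NA_real_)
}

# Hairpin loops of a structure: maximal unpaired runs enclosed by an
# innermost pair.  Returns a list of loops (start, end, 1-based inclusive,
# stem depth = number of enclosing pairs) and the index of the dominant loop
# (deepest stem; leftmost on ties).
.structure_loops <- function(pairs, n) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(list(loops = list(), dominant = NA_integer_))
  innermost <- vapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    !any(pairs[, 1L] > i & pairs[, 2L] < j)
  }, logical(1L))
  loops <- list()
  for (r in which(innermost)) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    depth <- sum(pairs[, 1L] <= i & pairs[, 2L] >= j)
    loops[[length(loops) + 1L]] <- list(start = i + 1L, end = j - 1L, depth = depth)
  }
  ord <- order(-vapply(loops, `[[`, numeric(1L), "depth"),
               vapply(loops, `[[`, numeric(1L), "start"))
  loops <- loops[ord]
  list(loops = loops, dominant = 1L)
}

#' Assign a mature miRNA to a precursor arm
#'
#' The arm is 5p iff the mature lies entirely left of the dominant terminal
#' loop (the hairpin loop closing the deepest stem); placements overlapping
#' the loop, or in structures without a single dominant loop at the mature
#' site, are rejected.
#'
#' @param fold an `rna_fold` (or dot-bracket string).
#' @param mature_start,mature_end mature interval within the precursor,
#'   0-based half-open.
#' @param sequence precursor sequence (needed when `fold` is a string and
#'   the first 5' nucleotide is to be reported).
#' @return list: `valid`, `arm` (`"5p"`/`"3p"` or `NA`), `start`, `end`
#'   (1-based inclusive, report convention), `first_nt` (RNA letter),
#'   `reason` (when invalid).
#' @export
place_mature <- function(fold, mature_start, mature_end, sequence = NULL) {
  if (inherits(fold, "rna_fold")) {
    pairs <- fold$pairs; n <- nchar(fold$structure)
    sequence <- sequence %||% fold$sequence
  } else {
    pairs <- .dotbracket_to_pairs(fold); n <- nchar(fold)
  }
  ms <- mature_start + 1L; me <- mature_end    # 1-based inclusive
  stopifnot(ms >= 1L, me <= n, ms <= me)
  first_nt <- if (!is.null(sequence)) dna_to_rna(substr(sequence, ms, ms)) else NA_character_
  bad <- function(reason) list(valid = FALSE, arm = NA_character_, start = ms,
                               end = me, first_nt = first_nt, reason = reason)
  sl <- .structure_loops(pairs, n)
  if (!length(sl$loops)) return(bad("no hairpin loop in structure"))
  dom <- sl$loops[[sl$dominant]]
  if (ms <= dom$end && dom$start <= me) return(bad("mature spans the terminal loop"))
  others <- sl$loops[-sl$dominant]
  if (me < dom$start) {
    left_of <- any(vapply(others, function(L) L$end < ms, logical(1L)))
    overlap <- any(vapply(others, function(L) ms <= L$end && L$start <= me, logical(1L)))
    if (left_of || overlap) return(bad("ambiguous hairpin: multi-branched at the mature site"))
    arm <- "5p"
  } else {
    right_of <- any(vapply(others, function(L) L$start > me, logical(1L)))
    overlap <- any(vapply(others, function(L) ms <= L$end && L$start <= me, logical(1L)))
    if (right_of || overlap) return(bad("ambiguous hairpin: multi-branched at the mature site"))
    arm <- "3p"
  }
  list(valid = TRUE, arm = arm, start = ms, end = me, first_nt = first_nt,
       reason = NA_character_)
}
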