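# Synthetic machinery protein sets with known expected catalytic reports.

.parse_corruption <- function(rule, family) {
  if (family == "AGO") {
    m <- regexec("^([DH])(760|845|986|798)->([A-Z])$", rule)[[1L]]
    if (m[1L] > 0L) {
      parts <- regmatches(rule, regexec("^([DH])(760|845|986|798)->([A-Z])$", rule))[[1L]]
      return(list(kind = "ago", anchor = paste0(parts[2L], parts[3L]),
                  to = parts[4L]))
    }
  }
  if (family == "DCL") {
    parts <- regmatches(rule, regexec("^RIBOc([12]):([1-4])->([A-Z])$", rule))[[1L]]
    if (length(parts) == 4L) {
      return(list(kind = "dcl", domain = as.integer(parts[2L]),
                  slot = as.integer(parts[3L]), to = parts[4L]))
    }
  }
  if (family == "RDR") {
    parts <- regmatches(rule, regexec("^DLDGD->([A-Z]{5})$", rule))[[1L]]
    if (length(parts) == 2L) return(list(kind = "rdr_motif", to = parts[2L]))
    parts <- regmatches(rule, regexec("^CSGS->([A-Z]{4})$", rule))[[1L]]
    if (length(parts) == 2L) return(list(kind = "rdr_subseq", to = parts[2L]))
  }
  stop(sprintf("unknown corruption rule '%s' for family %s", rule, family))
}

#' Generate a synthetic silencing-machinery protein set with known truth
#'
#' Proteins are derived from the bundled synthetic family scaffolds, with
#' benign substitutions at non-critical positions and the requested
#' corruption rules applied to the catalytic residues (e.g. `"H798->S"` for
#' an AGO, `"RIBOc1:1->Q"` for a DCL, `"DLDGD->DFDGD"` or `"CSGS->ASGS"`
#' for an RDR).  The emitted expected reports match the machinery-module
#' output on the emitted proteins.
#'
#' @param seed integer seed.
#' @param n_ago,n_dcl,n_rdr number of proteins per family.
#' @param corruptions named list: protein id (e.g. `"synAGO2"`) -> character
#'   vector of rules.  Unknown rules are an error.
#' @param benign_rate per-residue substitution rate away from catalytic
#'   positions and motif windows.
#' @return list of class `synth_proteins`: `proteins` (named character),
#'   `domains` (annotation data.frame), `expected` (data.frame of expected
#'   motif strings per protein), `families` (named character).
#' @export
synth_proteins <- function(seed, n_ago = 1L, n_dcl = 1L, n_rdr = 1L,
                           corruptions = list(), benign_rate = 0.02) {
  tpl <- machinery_templates()
  with_seed(seed, {
    proteins <- character(); domains <- list(); expected <- list()
    families <- character()

    benign <- function(seq, protect) {
      chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
      n <- length(chars)
      k <- stats::rbinom(1L, n, benign_rate)
      if (k > 0L) {
        pos <- setdiff(sample.int(n, min(n, k * 2L)), protect)[seq_len(min(k, n))]
        pos <- pos[!is.na(pos)]
        for (p in pos) chars[p] <- sample(setdiff(.AA20, chars[p]), 1L)
      }
      paste(chars, collapse = "")
    }

    emit <- function(id, family, seq, dom, exp_row) {
      proteins[[id]] <<- seq
      families[[id]] <<- family
      dom$protein_id <- id
      domains[[length(domains) + 1L]] <<- dom[, c("protein_id", "domain_name", "start", "end")]
      expected[[length(expected) + 1L]] <<- exp_row
    }

    for (k in seq_len(n_ago)) {
      id <- sprintf("synAGO%d", k)
      anchors <- tpl$ago$anchors
      residues <- c(D760 = "D", D845 = "D", H986 = "H", H798 = "H")
      seq <- benign(tpl$ago$seq, protect = unname(anchors))
      for (rule in corruptions[[id]] %||% character()) {
        pr <- .parse_corruption(rule, "AGO")
        residues[[pr$anchor]] <- pr$to
      }
      seq <- .set_residues(seq, unname(anchors[names(residues)]), unname(residues))
      motif <- paste0(residues[["D760"]], residues[["D845"]], residues[["H986"]],
                      "/", residues[["H798"]])
      emit(id, "AGO", seq, tpl$ago$domains,
           data.frame(protein_id = id, family = "AGO", motif = motif,
                      clade = NA_character_, subseq = NA_character_,
                      stringsAsFactors = FALSE))
    }

    for (k in seq_len(n_dcl)) {
      id <- sprintf("synDCL%d", k)
      cat_pos <- tpl$dcl$catalytic            # 2 x 4 absolute positions
      residues <- matrix(rep(c("E", "D", "D", "E"), each = 1L), 2L, 4L, byrow = TRUE)
      seq <- benign(tpl$dcl$seq, protect = as.vector(cat_pos))
      for (rule in corruptions[[id]] %||% character()) {
        pr <- .parse_corruption(rule, "DCL")
        residues[pr$domain, pr$slot] <- pr$to
      }
      for (d in 1:2) seq <- .set_residues(seq, cat_pos[d, ], residues[d, ])
      motif <- paste(apply(residues, 1L, paste, collapse = ""), collapse = "/")
      emit(id, "DCL", seq, tpl$dcl$domains,
           data.frame(protein_id = id, family = "DCL", motif = motif,
                      clade = NA_character_, subseq = NA_character_,
                      stringsAsFactors = FALSE))
    }

    for (k in seq_len(n_rdr)) {
      id <- sprintf("synRDR%d", k)
      motif5 <- "DLDGD"; sub4 <- "CSGS"
      ms <- tpl$rdr$motif_start; ss <- tpl$rdr$subseq_start
      seq <- benign(tpl$rdr$seq, protect = c(ms + 0:4, ss + 0:3))
      for (rule in corruptions[[id]] %||% character()) {
        pr <- .parse_corruption(rule, "RDR")
        if (pr$kind == "rdr_motif") motif5 <- pr$to else sub4 <- pr$to
      }
      seq <- .set_residues(seq, ms + 0:4, strsplit(motif5, "")[[1L]])
      seq <- .set_residues(seq, ss + 0:3, strsplit(sub4, "")[[1L]])
      protect <- c(ms + 0:4, ss + 0:3)
      seq <- .scrub_motif(seq, "D[LF]DGD",
                          if (grepl("^D[LF]DGD$", motif5)) ms else -1L, protect)
      seq <- .scrub_motif(seq, "[CA]SG[SG]",
                          if (grepl("^[CA]SG[SG]$", sub4)) ss else -1L, protect)
      evaluable <- grepl("^D[LF]DGD$", motif5)
      clade <- if (!evaluable) NA_character_
        else if (substr(motif5, 2L, 2L) == "L") "alpha" else "gamma"
      emit(id, "RDR", seq, tpl$rdr$domains,
           data.frame(protein_id = id, family = "RDR",
                      motif = if (evaluable) motif5 else "?",
                      clade = clade,
                      subseq = if (grepl("^[CA]SG[SG]$", sub4)) sub4 else NA_character_,
                      stringsAsFactors = FALSE))
    }

    bad <- setdiff(names(corruptions), names(proteins))
    if (length(bad)) {
      stop(sprintf("corruption rules for unknown protein(s): %s",
                   paste(bad, collapse = ",")))
    }
    structure(list(proteins = proteins,
                   domains = do.call(rbind, domains),
                   expected = do.call(rbind, expected),
                   families = families),
              class = "synth_proteins")
  })
}
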