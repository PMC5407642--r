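#' @importFrom utils read.delim write.table head tail
NULL

.ALPHABETS <- list(
  dna     = c("A", "C", "G", "T", "N"),
  rna     = c("A", "C", "G", "U", "N"),
  protein = c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], "X")
)

#' Controlled vocabulary of silencing-machinery domain names
#' @export
DOMAIN_VOCABULARY <- c(
  "DExD", "Helicase-C", "DUF283", "PAZ", "RIBOc", "DSRM",
  "Gly-rich_Ago1", "ArgoN", "ArgoMid", "Piwi", "RdRP"
)

# Accept either a file path or raw FASTA/GFF3/TSV text (contains a newline).
.as_lines <- function(x) {
  if (length(x) == 1L && grepl("[\n\t]", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1L]]
  } else if (length(x) > 1L) {
    x
  } else {
    readLines(x, warn = FALSE)
  }
}

#' Read FASTA sequences
#'
#' Parses FASTA text into a named character vector, uppercases residues and
#' normalizes U/T to the requested alphabet (DNA is the storage alphabet
#' throughout the package; RNA inputs are converted on read when
#' `alphabet = "dna"`).
#'
#' @param file path to a FASTA file, or FASTA text containing newlines.
#' @param alphabet one of `"dna"`, `"rna"`, `"protein"`.
#' @return named character vector of sequences, in input order.
#' @export
read_fasta <- function(file, alphabet = c("dna", "rna", "protein")) {
  alphabet <- match.arg(alphabet)
  lines <- .as_lines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty FASTA input")
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("FASTA input does not start with '>'")
  id <- sub("^>\\s*", "", lines[hdr])
  id <- sub("\\s.*$", "", id)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1L))
  out <- character(length(id))
  names(out) <- id
  present <- as.integer(names(seqs))
  out[present] <- unname(seqs)
  out <- toupper(gsub("[ \t]", "", out))
  if (alphabet == "dna") out <- rna_to_dna(out)
  if (alphabet == "rna") out <- dna_to_rna(out)
  allowed <- .ALPHABETS[[alphabet]]
  for (i in seq_along(out)) {
    if (!nzchar(out[i])) {
      stop(sprintf("empty FASTA record '%s'", names(out)[i]))
    }
    chars <- unique(strsplit(out[i], "", fixed = TRUE)[[1L]])
    bad <- setdiff(chars, allowed)
    if (length(bad)) {
      stop(sprintf("illegal %s character(s) %s in record '%s'",
                   alphabet, paste(bad, collapse = ","), names(out)[i]))
    }
  }
  out
}

#' Write FASTA sequences
#'
#' @param seqs named character vector of sequences.
#' @param file output path.
#' @param width line wrap width (nt per line).
#' @param as_rna write DNA-stored sequences with U instead of T.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(seqs, file, width = 60L, as_rna = FALSE) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  if (as_rna) seqs <- dna_to_rna(seqs)
  con <- base::file(file, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(file)
}

#' Read gene models from GFF3
#'
#' GFF3 rows are 1-based inclusive; internal coordinates are 0-based
#' half-open.  Only rows whose type matches `feature` are retained.
#'
#' @param file path or GFF3 text.
#' @param feature feature type(s) to keep (default `"gene"`).
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @export
read_gff3 <- function(file, feature = "gene") {
  lines <- .as_lines(file)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  out <- list()
  for (ln in rows) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L) stop(sprintf("GFF3 line %d: expected 9 columns", ln))
    if (!(f[3L] %in% feature)) next
    s <- suppressWarnings(as.numeric(f[4L])); e <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(s) || is.na(e)) stop(sprintf("GFF3 line %d: non-numeric coordinates", ln))
    if (e < s) stop(sprintf("GFF3 line %d: end (%g) < start (%g)", ln, e, s))
    attrs <- f[9L]
    id <- sub(".*ID=([^;]+).*", "\\1", attrs)
    if (identical(id, attrs)) id <- sprintf("feature_%d", ln)
    out[[length(out) + 1L]] <- data.frame(
      gene_id = id, chrom = f[1L], start = s - 1, end = e,
      strand = if (f[7L] %in% c("+", "-")) f[7L] else "+",
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Write gene models as GFF3
#'
#' Re-exports internal 0-based half-open intervals as 1-based inclusive rows,
#' so `read_gff3(write_gff3(x))` is lossless.
#'
#' @param genes data.frame as returned by [read_gff3()].
#' @param file output path.
#' @param source,feature GFF3 column 2 / 3 values.
#' @return `file`, invisibly.
#' @export
write_gff3 <- function(genes, file, source = "mirdiscover", feature = "gene") {
  con <- base::file(file, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$chrom, source, feature,
                       as.integer(genes$start) + 1L, as.integer(genes$end),
                       genes$strand, genes$gene_id), con)
  }
  invisible(file)
}

#' Read a protein domain-coordinate table
#'
#' TSV with columns `protein_id`, `domain_name`, `start`, `end` (1-based
#' inclusive amino-acid positions, as emitted by domain-scan tools).  Rows
#' with a domain name outside the controlled vocabulary are kept but flagged
#' `"other"` (the original name is preserved in `raw_name`); rows with
#' `start > end` are rejected with a warning.
#'
#' @param file path or TSV text.
#' @param proteins optional named character vector of protein sequences used
#'   to validate coordinates.
#' @return data.frame with columns `protein_id`, `domain_name`, `raw_name`,
#'   `start`, `end`.
#' @export
read_domain_table <- function(file, proteins = NULL) {
  lines <- .as_lines(file)
  df <- read.delim(text = paste(lines, collapse = "\n"),
                   header = grepl("protein_id", lines[1L], fixed = TRUE),
                   stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("domain table needs 4 columns: protein_id, domain_name, start, end")
  names(df)[1:4] <- c("protein_id", "domain_name", "start", "end")
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  bad <- which(df$start > df$end | df$start < 1L)
  if (length(bad)) {
    warning(sprintf("rejecting %d domain row(s) with start > end or start < 1", length(bad)))
    df <- df[-bad, , drop = FALSE]
  }
  df$raw_name <- df$domain_name
  unknown <- !(df$domain_name %in% DOMAIN_VOCABULARY)
  if (any(unknown)) {
    warning(sprintf("%d domain name(s) outside the controlled vocabulary flagged 'other': %s",
                    sum(unknown), paste(unique(df$raw_name[unknown]), collapse = ",")))
    df$domain_name[unknown] <- "other"
  }
  if (!is.null(proteins)) {
    plen <- nchar(proteins)[df$protein_id]
    over <- which(!is.na(plen) & df$end > plen)
    if (length(over)) {
      stop(sprintf("domain end exceeds protein length for %s",
                   paste(unique(df$protein_id[over]), collapse = ",")))
    }
  }
  rownames(df) <- NULL
  df[, c("protein_id", "domain_name", "raw_name", "start", "end")]
}

#' Write a tab-separated report
#'
#' @param df data.frame.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_tsv <- function(df, file) {
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
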