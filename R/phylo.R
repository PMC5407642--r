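# Distance-based phylogenetics: pairwise distances from pre-aligned
# sequences, neighbor-joining with deterministic tie-breaking, bootstrap
# majority-rule consensus with <50% collapse.  Trees are ape "phylo"
# objects; newick I/O goes through ape.

.aln_chars <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  else toupper(x)
}

.TRANSITIONS <- c(AG = TRUE, GA = TRUE, CT = TRUE, TC = TRUE)

#' Kimura two-parameter distance between two aligned nucleotide rows
#'
#' Sites with a gap in either row are excluded pairwise.  With P and Q the
#' transition and transversion proportions over included sites,
#' `d = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]`.  Saturated pairs (log argument
#' <= 0) are flagged `Inf`.
#'
#' @param row_i,row_j aligned sequences (strings with `-` gaps, or character
#'   vectors).
#' @return distance (substitutions per site), possibly `Inf`.
#' @export
k2p_distance <- function(row_i, row_j) {
  a <- rna_to_dna(.aln_chars(row_i)); b <- rna_to_dna(.aln_chars(row_j))
  stopifnot(length(a) == length(b))
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("zero included sites after gap exclusion")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  ts <- diff & !is.na(.TRANSITIONS[paste0(a, b)])
  P <- mean(ts); Q <- mean(diff & !ts)
  arg1 <- 1 - 2 * P - Q; arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) return(Inf)
  -0.5 * log(arg1 * sqrt(arg2))
}

#' Protein distance between two aligned rows
#'
#' `p-distance` is the mismatch fraction over gap-free sites; `poisson` is
#' the Poisson correction `-ln(1 - p)` (`Inf` when p = 1).
#'
#' @inheritParams k2p_distance
#' @param model `"p-distance"` or `"poisson"`.
#' @return distance.
#' @export
protein_distance <- function(row_i, row_j, model = c("p-distance", "poisson")) {
  model <- match.arg(model)
  a <- .aln_chars(row_i); b <- .aln_chars(row_j)
  stopifnot(length(a) == length(b))
  ok <- a != "-" & b != "-" & a != "X" & b != "X"
  if (!any(ok)) stop("zero included sites after gap exclusion")
  p <- mean(a[ok] != b[ok])
  if (model == "p-distance") return(p)
  if (p >= 1) return(Inf)
  -log(1 - p)
}

#' Pairwise distance matrix from an alignment
#'
#' @param msa named character vector of equal-length aligned rows.
#' @param type `"nucleotide"` (Kimura two-parameter) or `"protein"`.
#' @param model protein model, see [protein_distance()].
#' @param gap_handling `"complete"` (all columns containing a gap removed
#'   before any comparison, as in the study's tree legends) or `"pairwise"`.
#' @return symmetric matrix with taxon dimnames.
#' @export
dist_matrix <- function(msa, type = c("nucleotide", "protein"),
                        model = "poisson",
                        gap_handling = c("complete", "pairwise")) {
  type <- match.arg(type); gap_handling <- match.arg(gap_handling)
  stopifnot(length(msa) >= 2L, length(unique(nchar(msa))) == 1L,
            !is.null(names(msa)))
  rows <- lapply(msa, .aln_chars)
  if (gap_handling == "complete") {
    gap <- Reduce(`|`, lapply(rows, function(r) r == "-" | r == "N"))
    rows <- lapply(rows, function(r) r[!gap])
    if (!length(rows[[1L]])) stop("no sites remain after complete deletion")
  }
  n <- length(rows)
  D <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    d <- if (type == "nucleotide") k2p_distance(rows[[i]], rows[[j]])
         else protein_distance(rows[[i]], rows[[j]], model)
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration with deterministic tie-breaking (lowest index
#' pair in the current node order).  Negative branch lengths are clamped to
#' zero; the total clamped deficit is recorded in the `clamp_deficit`
#' attribute.
#'
#' @param D symmetric distance matrix with taxon dimnames (>= 3 taxa, all
#'   finite).
#' @return unrooted `phylo` object (ape).
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) >= 3L, !is.null(rownames(D)))
  if (any(!is.finite(D))) {
    bad <- which(!is.finite(D), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite distance between '%s' and '%s'",
                 rownames(D)[bad[1L]], colnames(D)[bad[2L]]))
  }
  taxa <- rownames(D)
  n <- length(taxa)
  ids <- seq_len(n)                 # tips 1..n; internals n+1, n+2, ...
  next_id <- n + 1L
  edges <- matrix(integer(), 0L, 2L); lens <- numeric()
  deficit <- 0
  d <- D
  active <- ids
  clamp <- function(x) { if (x < 0) { deficit <<- deficit - x; 0 } else x }
  while (length(active) > 3L) {
    r <- length(active)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, `+`)
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1L] < best[, 2L], , drop = FALSE]
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
    i <- best[1L]; j <- best[2L]
    la <- 0.5 * d[i, j] + (R[i] - R[j]) / (2 * (r - 2))
    lb <- d[i, j] - la
    u <- next_id; next_id <- next_id + 1L
    edges <- rbind(edges, c(u, active[i]), c(u, active[j]))
    lens <- c(lens, clamp(la), clamp(lb))
    du <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    active <- c(active[keep], u)
  }
  x <- active[1L]; y <- active[2L]; z <- active[3L]
  root <- next_id
  lx <- (d[1L, 2L] + d[1L, 3L] - d[2L, 3L]) / 2
  ly <- (d[1L, 2L] + d[2L, 3L] - d[1L, 3L]) / 2
  lz <- (d[1L, 3L] + d[2L, 3L] - d[1L, 2L]) / 2
  edges <- rbind(edges, c(root, x), c(root, y), c(root, z))
  lens <- c(lens, clamp(lx), clamp(ly), clamp(lz))
  # renumber internals so the root is n+1 (ape convention)
  K <- root - n
  remap <- function(v) ifelse(v <= n, v, n + 1L + (root - v))
  tree <- list(edge = cbind(remap(edges[, 1L]), remap(edges[, 2L])),
               edge.length = lens, tip.label = taxa, Nnode = K)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "clamp_deficit") <- deficit
  tree
}

# Internal-edge bipartitions of a phylo, keyed by the sorted tip labels of
# the side not containing the reference taxon (lexicographically smallest
# label), so keys are invariant to input order and rooting.
.tree_bipartitions <- function(tree, with_lengths = FALSE) {
  n <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1L]
  desc <- vector("list", n + tree$Nnode)
  for (k in seq_len(n)) desc[[k]] <- tree$tip.label[k]
  for (e in ape::postorder(tree)) {   # children accumulate before parents
    p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[c]])
  }
  root <- n + 1L
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    if (child <= n) next
    side <- desc[[child]]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2L || length(side) > n - 2L) next
    key <- paste(sort(side), collapse = "|")
    out[[length(out) + 1L]] <- list(key = key, length = tree$edge.length[e])
  }
  out
}

.pendant_lengths <- function(tree) {
  n <- length(tree$tip.label)
  tip_edge <- match(seq_len(n), tree$edge[, 2L])
  stats::setNames(tree$edge.length[tip_edge], tree$tip.label)
}

#' Bootstrap NJ tree with majority-rule consensus supports
#'
#' Alignment columns are resampled with replacement for each replicate, an
#' NJ tree is built per replicate, and the majority-rule consensus is
#' returned: internal branches whose bipartition is reproduced in fewer
#' than 50% of replicates are collapsed, and supports are attached as
#' integer percentages (node labels).  Consensus branch lengths are the
#' mean lengths over the replicates containing each branch.
#'
#' @param msa named character vector of aligned rows.
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed for the resampling stream.
#' @param type,model,gap_handling passed to [dist_matrix()].
#' @return `phylo` with `node.label` percentages.
#' @export
bootstrap_consensus <- function(msa, n_replicates, seed,
                                type = c("nucleotide", "protein"),
                                model = "poisson",
                                gap_handling = c("complete", "pairwise")) {
  type <- match.arg(type); gap_handling <- match.arg(gap_handling)
  stopifnot(n_replicates >= 1L, length(msa) >= 3L)
  msa <- msa[order(names(msa))]   # canonical taxon order: supports do not
                                  # depend on input order even at NJ ties
  rows <- lapply(msa, .aln_chars)
  L <- length(rows[[1L]])
  taxa <- names(msa)
  counts <- new.env(parent = emptyenv())
  lensum <- new.env(parent = emptyenv())
  pend <- stats::setNames(numeric(length(taxa)), taxa)
  with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_msa <- vapply(rows, function(r) paste(r[cols], collapse = ""), character(1L))
      tr <- neighbor_joining(dist_matrix(rep_msa, type = type, model = model,
                                         gap_handling = gap_handling))
      for (bp in .tree_bipartitions(tr)) {
        counts[[bp$key]] <- (counts[[bp$key]] %||% 0L) + 1L
        lensum[[bp$key]] <- (lensum[[bp$key]] %||% 0) + bp$length
      }
      pend <- pend + .pendant_lengths(tr)[taxa]
    }
  })
  pend <- pend / n_replicates
  keys <- ls(counts)
  support <- vapply(keys, function(k) 100 * counts[[k]] / n_replicates, numeric(1L))
  meanlen <- vapply(keys, function(k) lensum[[k]] / counts[[k]], numeric(1L))
  keep <- support >= 50
  clades <- lapply(keys[keep], function(k) strsplit(k, "|", fixed = TRUE)[[1L]])
  csup <- support[keep]; clen <- meanlen[keep]
  # ensure compatibility (ties at exactly 50% could conflict): greedy by
  # support, then key, keeping pairwise-compatible clades only
  ref <- sort(taxa)[1L]
  ord <- order(-csup, keys[keep])
  sel <- list(); ssup <- numeric(); slen <- numeric()
  compatible <- function(a, b) {
    i <- length(intersect(a, b))
    i == 0L || i == length(a) || i == length(b)
  }
  for (k in ord) {
    if (all(vapply(sel, compatible, logical(1L), b = clades[[k]]))) {
      sel[[length(sel) + 1L]] <- clades[[k]]
      ssup <- c(ssup, csup[k]); slen <- c(slen, clen[k])
    }
  }
  # build the consensus newick by nesting the (laminar) selected clades,
  # rooted at the reference taxon
  others <- setdiff(taxa, ref)
  build <- function(idxset, members) {
    tops <- idxset[vapply(idxset, function(k) {
      !any(vapply(setdiff(idxset, k),
                  function(q) all(sel[[k]] %in% sel[[q]]), logical(1L)))
    }, logical(1L))]
    parts <- character(); used <- character()
    for (k in tops) {
      inner <- setdiff(idxset[vapply(idxset, function(q)
        all(sel[[q]] %in% sel[[k]]), logical(1L))], k)
      parts <- c(parts, sprintf("%s%d:%.8f", build(inner, sel[[k]]),
                                round(ssup[k]), slen[k]))
      used <- c(used, sel[[k]])
    }
    loose <- setdiff(members, used)
    if (length(loose)) parts <- c(parts, sprintf("%s:%.8f", loose, pend[loose]))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  inner <- build(seq_along(sel), others)
  nwk <- paste0("(", substr(inner, 2L, nchar(inner) - 1L), ",",
                sprintf("%s:%.8f", ref, pend[[ref]]), ");")
  ape::read.tree(text = nwk)
}
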