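# Independent reference implementations used as oracles.  These deliberately
# use different decompositions / plain loops than the package internals.

.ocomp <- c(A = "T", C = "G", G = "C", T = "A")

# Best admissible inverted-repeat score by top-down recursion over the fold
# alignment space (pair the outer bases, or gap either arm), memoised.
oracle_ir_best <- function(seq, params = ir_params()) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(x)
  S <- matrix(NA_real_, n, n)
  rec <- function(i, j) {
    if (j <= i) return(0)
    if (!is.na(S[i, j])) return(S[i, j])
    sub <- if (!is.na(.ocomp[x[i]]) && x[j] == .ocomp[x[i]]) params$match else params$mismatch
    inner <- rec(i + 1L, j - 1L)
    pairterm <- if (inner > 0 || (j - i - 1L) >= params$min_loop) sub + inner else -Inf
    val <- max(0, pairterm, rec(i + 1L, j) - params$gap, rec(i, j - 1L) - params$gap)
    S[i, j] <<- val
    val
  }
  best <- 0
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (j - i + 1L <= params$max_extent) best <- max(best, rec(i, j))
  }
  best
}

# Best strictly gapless arm-pair score: enumerate every outer pair (i, j)
# and every arm length (lower bound for the gapped optimum).
oracle_ir_gapless <- function(seq, params = ir_params()) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(x)
  best <- 0
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (j - i + 1L > params$max_extent) next
    sc <- 0; L <- 0L
    while (i + L < j - L - params$min_loop) {
      a <- x[i + L]; b <- x[j - L]
      sc <- sc + if (!is.na(.ocomp[a]) && b == .ocomp[a]) params$match else params$mismatch
      L <- L + 1L
      best <- max(best, sc)
    }
  }
  best
}

.opair_e <- c(GC = -3, CG = -3, AT = -2, TA = -2, GT = -1, TG = -1)

oracle_score_structure <- function(chars, p) {
  if (!nrow(p)) return(0)
  e <- sum(.opair_e[paste0(chars[p[, 1L]], chars[p[, 2L]])])
  key <- paste(p[, 1L], p[, 2L])
  e - sum(paste(p[, 1L] + 1L, p[, 2L] - 1L) %in% key)
}

# All nested structures, decomposing on the partner of the RIGHT end
# (the package decomposes on the left end).
oracle_enum_structures <- function(seq) {
  chars <- strsplit(chartr("U", "T", toupper(seq)), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  pairable <- function(a, b) paste0(a, b) %in% names(.opair_e)
  rec <- function(i, j) {
    if (j - i < 4L) return(list(matrix(integer(), 0L, 2L)))
    out <- rec(i, j - 1L)
    for (k in seq(i, j - 4L)) {
      if (!pairable(chars[k], chars[j])) next
      left <- if (k > i) rec(i, k - 1L) else list(matrix(integer(), 0L, 2L))
      inner <- rec(k + 1L, j - 1L)
      for (s1 in left) for (s2 in inner) {
        out[[length(out) + 1L]] <- rbind(s1, c(k, j), s2)
      }
    }
    out
  }
  rec(1L, n)
}

oracle_ensemble <- function(seq) {
  chars <- strsplit(chartr("U", "T", toupper(seq)), "", fixed = TRUE)[[1L]]
  st <- oracle_enum_structures(seq)
  E <- vapply(st, function(p) oracle_score_structure(chars, p), numeric(1L))
  RT <- 0.61633
  w <- exp(-E / RT); Z <- sum(w)
  pw <- new.env(parent = emptyenv())
  for (k in seq_along(st)) {
    p <- st[[k]]
    if (nrow(p)) for (r in seq_len(nrow(p))) {
      key <- paste(p[r, 1L], p[r, 2L])
      assign(key, (if (exists(key, pw)) get(key, pw) else 0) + w[k], pw)
    }
  }
  probs <- unlist(mget(ls(pw), pw)) / Z
  list(n_struct = length(st), mfe = min(E), mfee = -RT * log(Z),
       frequency = exp((-RT * log(Z) - min(E)) / RT),
       diversity = if (length(probs)) 2 * sum(probs * (1 - probs)) else 0)
}

# Minimum energy only, memoised, right-end decomposition (fast to 30 nt).
oracle_fold_mfe <- function(seq) {
  chars <- strsplit(chartr("U", "T", toupper(seq)), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  M <- new.env(parent = emptyenv())
  memo <- function(env, key, fn) {
    if (exists(key, env)) return(get(key, env))
    v <- fn(); assign(key, v, env); v
  }
  recP <- function(i, j) memo(M, paste("P", i, j), function() {
    e <- .opair_e[paste0(chars[i], chars[j])]
    if (is.na(e) || j - i < 4L) return(Inf)
    unname(e) + min(recU(i + 1L, j - 1L), recP(i + 1L, j - 1L) - 1)
  })
  recM <- function(i, j) memo(M, paste("M", i, j), function() {
    if (j - i < 4L) return(0)
    best <- recM(i, j - 1L)
    for (k in seq(i, j - 4L)) {
      pk <- recP(k, j)
      if (is.finite(pk)) best <- min(best, (if (k > i) recM(i, k - 1L) else 0) + pk)
    }
    best
  })
  recU <- function(i, j) memo(M, paste("U", i, j), function() {
    if (j - i < 4L) return(0)
    best <- recM(i, j - 1L)          # j unpaired
    for (k in seq(i + 1L, j)) {      # j paired to k > i (excludes (i,j))
      if (j - k < 4L) break
      pk <- recP(k, j)
      if (is.finite(pk)) best <- min(best, recM(i, k - 1L) + pk)
    }
    best
  })
  min(0, recM(1L, n))
}

# Direct per-position penalty summation for a duplex, plain loops.
oracle_duplex <- function(mirna, site, params = target_params()) {
  m <- strsplit(chartr("U", "T", toupper(mirna)), "", fixed = TRUE)[[1L]]
  s <- strsplit(chartr("U", "T", toupper(site)), "", fixed = TRUE)[[1L]]
  L <- length(m); Ls <- length(s)
  mult <- function(t) if (t >= params$seed_window[1L] && t <= params$seed_window[2L]) 2 else 1
  pen1 <- function(mb, sb) {
    if (!is.na(.ocomp[mb]) && sb == .ocomp[mb]) 0
    else if ((mb == "G" && sb == "T") || (mb == "T" && sb == "G")) params$gu_penalty
    else params$mismatch_penalty
  }
  score_map <- function(map, gap_at) {
    tot <- 0
    for (t in seq_len(L)) {
      if (is.na(map[t])) next
      tot <- tot + pen1(m[t], s[map[t]]) * mult(t)
    }
    for (g in gap_at) tot <- tot + params$gap_penalty * mult(g)
    tot
  }
  best <- Inf
  if (Ls == L) {
    best <- score_map(Ls + 1L - seq_len(L), integer())
  } else if (Ls == L - 1L) {
    for (g in seq_len(L)) {
      map <- integer(L)
      for (t in seq_len(L)) {
        map[t] <- if (t < g) Ls + 1L - t else if (t > g) Ls + 2L - t else NA_integer_
      }
      best <- min(best, score_map(map, g))
    }
  } else if (Ls == L + 1L) {
    for (g in seq_len(L - 1L)) {
      map <- integer(L)
      for (t in seq_len(L)) map[t] <- if (t <= g) Ls + 1L - t else Ls - t
      best <- min(best, score_map(map, g))
    }
  }
  best
}

# ---- phylogenetics oracles -------------------------------------------------

# All unrooted topologies on n labelled leaves by sequential edge insertion.
# A topology is an edge matrix; leaves 1..n, internals n+1, n+2, ...
oracle_topologies <- function(n) {
  start <- list(list(edges = rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L)),
                     next_int = n + 2L))
  tops <- start
  for (leaf in seq(4L, length.out = max(0L, n - 3L))) {
    nxt <- list()
    for (tp in tops) {
      for (e in seq_len(nrow(tp$edges))) {
        a <- tp$edges[e, 1L]; b <- tp$edges[e, 2L]
        mnode <- tp$next_int
        edges <- rbind(tp$edges[-e, , drop = FALSE],
                       c(a, mnode), c(mnode, b), c(mnode, leaf))
        nxt[[length(nxt) + 1L]] <- list(edges = edges, next_int = mnode + 1L)
      }
    }
    tops <- nxt
  }
  lapply(tops, `[[`, "edges")
}

# Leaf-pair path incidence matrix (rows: pairs i<j, cols: edges).
oracle_incidence <- function(edges, n) {
  nodes <- sort(unique(as.vector(edges)))
  adj <- lapply(seq_len(max(nodes)), function(i) integer())
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1L]; b <- edges[e, 2L]
    adj[[a]] <- c(adj[[a]], e); adj[[b]] <- c(adj[[b]], e)
  }
  other <- function(e, v) if (edges[e, 1L] == v) edges[e, 2L] else edges[e, 1L]
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  A <- matrix(0, nrow(pairs), nrow(edges))
  for (p in seq_len(nrow(pairs))) {
    src <- pairs[p, 1L]; dst <- pairs[p, 2L]
    # DFS from src to dst
    stack <- list(list(v = src, path = integer()))
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (cur$v == dst) { A[p, cur$path] <- 1; break }
      for (e in adj[[cur$v]]) {
        if (!(e %in% cur$path)) {
          stack[[length(stack) + 1L]] <- list(v = other(e, cur$v),
                                              path = c(cur$path, e))
        }
      }
    }
  }
  A
}

# Canonical bipartition keys of a topology given tip labels.
oracle_splits <- function(edges, n, labels) {
  ref <- sort(labels)[1L]
  out <- character()
  for (e in seq_len(nrow(edges))) {
    if (edges[e, 1L] <= n || edges[e, 2L] <= n) next   # pendant edge
    # leaves on the edges[e,2] side after cutting edge e
    sub <- edges[-e, , drop = FALSE]
    comp <- edges[e, 2L]
    repeat {
      hit <- sub[, 1L] %in% comp | sub[, 2L] %in% comp
      newn <- unique(as.vector(sub[hit, , drop = FALSE]))
      if (all(newn %in% comp)) break
      comp <- union(comp, newn)
      sub <- sub[!hit, , drop = FALSE]
      if (!nrow(sub)) break
    }
    side <- labels[intersect(comp, seq_len(n))]
    if (ref %in% side) side <- setdiff(labels, side)
    if (length(side) >= 2L && length(side) <= n - 2L) {
      out <- c(out, paste(sort(side), collapse = "|"))
    }
  }
  sort(unique(out))
}

# Least-squares fit over all topologies; returns the splits of the best one
# and its residual sum of squares.
oracle_ls_best <- function(D) {
  n <- nrow(D)
  labels <- rownames(D)
  dvec <- D[upper.tri(D)]
  # upper.tri order is column-major; rebuild in (i<j) row-major pair order
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  dvec <- D[pairs]
  best <- NULL
  for (edges in oracle_topologies(n)) {
    A <- oracle_incidence(edges, n)
    fit <- qr.solve(A, dvec)
    sse <- sum((A %*% fit - dvec)^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(sse = sse, splits = oracle_splits(edges, n, labels))
    }
  }
  best
}

# Random additive tree: random topology by sequential insertion with random
# positive branch lengths; returns the exact distance matrix and its splits.
random_additive_tree <- function(n, labels = paste0("t", seq_len(n))) {
  edges <- rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L))
  next_int <- n + 2L
  for (leaf in seq(4L, length.out = max(0L, n - 3L))) {
    e <- sample.int(nrow(edges), 1L)
    a <- edges[e, 1L]; b <- edges[e, 2L]
    edges <- rbind(edges[-e, , drop = FALSE],
                   c(a, next_int), c(next_int, b), c(next_int, leaf))
    next_int <- next_int + 1L
  }
  lens <- round(runif(nrow(edges), 0.2, 1.5), 3)
  A <- oracle_incidence(edges, n)
  dvec <- as.vector(A %*% lens)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  D[pairs] <- dvec
  D <- D + t(D)
  list(D = D, splits = oracle_splits(edges, n, labels))
}

# Canonical bipartition keys of an ape phylo (via ape::prop.part).
phylo_splits <- function(tree) {
  n <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1L]
  pp <- ape::prop.part(tree)
  out <- character()
  for (p in pp) {
    side <- tree$tip.label[p]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) >= 2L && length(side) <= n - 2L) {
      out <- c(out, paste(sort(side), collapse = "|"))
    }
  }
  sort(unique(out))
}

# Deterministic random DNA/RNA helpers for fixtures.
rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
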