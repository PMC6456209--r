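## Independent oracles used across the suite.  These deliberately share
## no code with the package implementation paths they check.

## --- exhaustive enumeration of nested structures ----------------------
## All pair tables on n positions with hairpin loops >= min_loop, as a
## plain recursion on intervals (memoized per call).
enumerate_structures <- function(seq, min_loop = 3L) {
  ch <- strsplit(chartr("T", "U", toupper(seq)), "")[[1L]]
  n <- length(ch)
  ok_pair <- function(i, j) paste0(ch[i], ch[j]) %in%
    c("AU", "UA", "CG", "GC", "GU", "UG")
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i >= j) return(list(list()))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1L, j)                      # i unpaired
    for (k in (i + min_loop + 1L):j) {
      if (k > j) break
      if (!ok_pair(i, k)) next
      left <- rec(i + 1L, k - 1L)
      right <- rec(k + 1L, j)
      for (L in left) for (R in right)
        out <- c(out, list(c(list(c(i, k)), L, R)))
    }
    memo[[key]] <- out
    out
  }
  if (n < min_loop + 2L) return(list(list()))
  rec(1L, n)
}

pairs_list_to_db <- function(pl, n) {
  ch <- rep(".", n)
  for (p in pl) { ch[p[1]] <- "("; ch[p[2]] <- ")" }
  paste(ch, collapse = "")
}

## brute-force MFE by scoring every enumerated structure with the
## package's standalone loop-decomposition evaluator
oracle_mfe <- function(seq, params = folding_params()) {
  n <- nchar(seq)
  structs <- enumerate_structures(seq, params$min_loop)
  best <- Inf; best_db <- strrep(".", n)
  for (pl in structs) {
    db <- pairs_list_to_db(pl, n)
    e <- eval_structure_energy(seq, db, params)
    if (e < best) { best <- e; best_db <- db }
  }
  list(energy = best, db = best_db)
}

## --- brute-force affine-gap global alignment score --------------------
brute_align_score <- function(a, b, S, go, ge) {
  n <- length(a); m <- length(b)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- go + (i - 1) * ge
  for (j in seq_len(m)) Y[1, j + 1] <- go + (j - 1) * ge
  for (i in seq_len(n)) for (j in seq_len(m)) {
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + S[a[i], b[j]]
    X[i + 1, j + 1] <- max(M[i, j + 1] + go, Y[i, j + 1] + go,
                           X[i, j + 1] + ge)
    Y[i + 1, j + 1] <- max(M[i + 1, j] + go, X[i + 1, j] + go,
                           Y[i + 1, j] + ge)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

## --- independent CBC scan over aligned rows ---------------------------
## Works directly on the gapped dot-bracket strings: matches brackets
## within each aligned row (skipping gaps), then scans every co-paired
## column pair.
oracle_cbc <- function(alignment, x, y) {
  rows <- alignment$rows
  kx <- match(x, rows$id); ky <- match(y, rows$id)
  match_cols <- function(db) {
    ch <- strsplit(db, "")[[1L]]
    p <- integer(length(ch)); st <- integer(0)
    for (i in seq_along(ch)) {
      if (ch[i] == "(") st <- c(st, i)
      else if (ch[i] == ")") { j <- st[length(st)]; st <- st[-length(st)]
        p[i] <- j; p[j] <- i }
    }
    p
  }
  px <- match_cols(rows$db[kx]); py <- match_cols(rows$db[ky])
  sx <- strsplit(rows$seq[kx], "")[[1L]]
  sy <- strsplit(rows$seq[ky], "")[[1L]]
  valid <- c("AU", "UA", "CG", "GC", "GU", "UG")
  cbc <- 0L; hemi <- 0L
  for (ci in which(px > seq_along(px))) {
    cj <- px[ci]
    if (py[ci] != cj) next
    if (sx[ci] == "-" || sx[cj] == "-" || sy[ci] == "-" || sy[cj] == "-")
      next
    if (!paste0(sx[ci], sx[cj]) %in% valid) next
    if (!paste0(sy[ci], sy[cj]) %in% valid) next
    d1 <- sx[ci] != sy[ci]; d2 <- sx[cj] != sy[cj]
    if (d1 && d2) cbc <- cbc + 1L else if (d1 || d2) hemi <- hemi + 1L
  }
  list(cbc = cbc, hemi = hemi)
}

## --- exact minimal CBC-free partition by full partition enumeration ---
all_partitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  smaller <- all_partitions(n - 1L)
  out <- list()
  for (p in smaller) {
    for (b in seq_along(p))
      out <- c(out, list(`[[<-`(p, b, c(p[[b]], n))))
    out <- c(out, list(c(p, list(n))))
  }
  out
}

oracle_min_partition <- function(adj) {
  n <- nrow(adj)
  best <- n
  for (p in all_partitions(n)) {
    ok <- TRUE
    for (b in p) {
      if (length(b) > 1L) {
        pr <- combn(b, 2L)
        if (any(adj[t(pr)])) { ok <- FALSE; break }
      }
    }
    if (ok) best <- min(best, length(p))
  }
  best
}

## random RNA-ish sequence
random_seq <- function(n, gc = 0.5) {
  paste(sample(c("G", "C", "A", "U"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}
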