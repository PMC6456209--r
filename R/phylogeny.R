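## Sequence-structure phylogeny: distances on the 12-letter encoding
## (p-distance or Poisson-corrected for a 12-state alphabet), canonical
## neighbor-joining, and column-resampling bootstrap with supports mapped
## onto the full-data tree.

#' Pairwise distances on a structural alignment
#'
#' `p-distance`: mismatching co-ungapped columns / co-ungapped columns on
#' the 12-letter encoding.  `poisson-12`: the Poisson-type correction for
#' a 12-state alphabet, d = -(11/12) ln(1 - (12/11) p), capped at
#' `max_dist` (and flagged) when p approaches saturation (p >= 11/12).
#'
#' @param alignment a `struct_alignment` with >= 3 records.
#' @param model `"p-distance"` or `"poisson-12"`.
#' @param max_dist saturation cap for the corrected distance (default 5).
#' @return Symmetric numeric matrix with record ids as dimnames; a
#'   `"saturated"` attribute lists capped pairs.
#' @export
distance_matrix <- function(alignment, model = c("p-distance", "poisson-12"),
                            max_dist = 5) {
  model <- match.arg(model)
  ids <- alignment$rows$id
  n <- length(ids)
  if (n < 3L) stop("distance matrix needs >= 3 records")
  ch <- do.call(rbind, strsplit(alignment$rows$enc, ""))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  saturated <- character(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- ch[i, ] != "-" & ch[j, ] != "-"
    if (!any(ok))
      stop("no co-ungapped columns for pair ", ids[i], " / ", ids[j])
    p <- mean(ch[i, ok] != ch[j, ok])
    d <- if (model == "p-distance") p else {
      arg <- 1 - 12 * p / 11
      if (arg <= 0) { saturated <- c(saturated, paste(ids[i], ids[j])); max_dist }
      else min(-(11 / 12) * log(arg), max_dist)
    }
    D[i, j] <- D[j, i] <- d
  }
  attr(D, "model") <- model
  attr(D, "saturated") <- saturated
  D
}

#' Neighbor-joining tree
#'
#' Canonical NJ (Saitou-Nei Q-criterion).  Ties in Q are broken toward
#' the lexicographically smallest joined label pair; negative branch
#' lengths are clamped to zero with the deficit moved to the sister
#' branch.
#'
#' @param d symmetric distance matrix with row/column names.
#' @return An unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(d) {
  if (!isSymmetric(unname(as.matrix(d))))
    stop("distance matrix must be symmetric")
  D <- as.matrix(d)
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("t", seq_len(nrow(D)))
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs >= 3 records")
  ## active clusters hold partial newick strings
  nwk <- labs
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  clamp2 <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  while (nrow(D) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      pr <- sort(c(nwk[ij[1]], nwk[ij[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    ll <- clamp2(li, lj)
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    merged <- paste0("(", nwk[i], ":", fmt(ll[1]), ",",
                     nwk[j], ":", fmt(ll[2]), ")")
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    D <- D2
    nwk <- c(nwk[keep], merged)
  }
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- paste0("(", nwk[1], ":", fmt(l1), ",", nwk[2], ":", fmt(l2), ",",
                nwk[3], ":", fmt(l3), ");")
  ape::read.tree(text = txt)
}

#' Bootstrap supports for the sequence-structure NJ tree
#'
#' Alignment columns are resampled with replacement per pseudo-replicate,
#' a NJ tree built for each, and supports (% of replicates containing
#' each bipartition) mapped onto the full-data NJ tree as node labels.
#' The majority-rule (>50%) consensus of the replicate trees is returned
#' alongside.  Deterministic under `seed`.
#'
#' @param alignment a `struct_alignment` with >= 4 records.
#' @param replicates number of pseudo-replicates (default 1000).
#' @param seed integer seed controlling resampling.
#' @param model distance model, as in [distance_matrix()].
#' @return List of class `bootstrap_phylo`: `tree` (full-data NJ with
#'   integer supports as node labels), `consensus` (majority-rule),
#'   `replicates`.
#' @export
bootstrap_consensus <- function(alignment, replicates = 1000L, seed = 1L,
                                model = "poisson-12") {
  if (replicates < 1L) stop("replicates must be >= 1")
  if (length(alignment$rows$id) < 4L) stop("need >= 4 records")
  full <- neighbor_joining(distance_matrix(alignment, model))
  width <- alignment$width
  rows <- strsplit(alignment$rows$enc, "")
  set.seed(seed)
  reps <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    cols <- sample.int(width, width, replace = TRUE)
    enc_b <- vapply(rows, function(x) paste(x[cols], collapse = ""),
                    character(1))
    al_b <- list(rows = data.frame(id = alignment$rows$id, enc = enc_b,
                                   stringsAsFactors = FALSE),
                 width = width)
    class(al_b) <- "struct_alignment"
    Db <- tryCatch(distance_matrix(al_b, model), error = function(e) NULL)
    reps[[b]] <- if (is.null(Db)) NULL else neighbor_joining(Db)
  }
  reps <- Filter(Negate(is.null), reps)
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supp <- round(100 * counts / length(reps))
  full$node.label <- as.character(supp)
  cons <- ape::consensus(reps, p = 0.5)
  out <- list(tree = full, consensus = cons, replicates = length(reps))
  class(out) <- "bootstrap_phylo"
  out
}
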