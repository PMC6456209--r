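## Sequence-structure alignment in a combined 12-letter alphabet
## ({A,C,G,U} x {unpaired, open, close}) and the substitution bookkeeping
## driving species delimitation: compensatory base changes (CBCs),
## hemi-CBCs, transitions/transversions and INDEL events.

ENC_TABLE <- local({
  res <- c("A", "C", "G", "U")
  data.frame(residue = rep(res, 3L),
             state = rep(c(".", "(", ")"), each = 4L),
             code = c("A", "C", "G", "U",
                      "B", "D", "H", "V",
                      "E", "F", "I", "W"),
             stringsAsFactors = FALSE)
})

#' The 12-letter sequence-structure encoding table
#' @return Data frame with columns `residue`, `state`, `code`.
#' @export
encoding_table <- function() ENC_TABLE

enc_lookup <- local({
  x <- ENC_TABLE$code
  names(x) <- paste0(ENC_TABLE$residue, ENC_TABLE$state)
  x
})
dec_residue <- local({
  x <- ENC_TABLE$residue; names(x) <- ENC_TABLE$code; c(x, "-" = "-")
})
dec_state <- local({
  x <- ENC_TABLE$state; names(x) <- ENC_TABLE$code; c(x, "-" = "-")
})

#' Encode a sequence and its structure into the 12-letter alphabet
#'
#' Each position maps bijectively from (residue, pairing state) to one of
#' 12 single-letter codes, so the encoding decodes losslessly.
#'
#' @param sequence RNA/DNA string (T is converted to U).
#' @param structure an `its2_structure`, or a dot-bracket string of the
#'   same length.
#' @param id record id (defaults to the structure's id).
#' @return Object of class `encoded_sequence`: list with `id`, `enc`,
#'   `seq` (RNA) and `db`.
#' @export
encode_structure <- function(sequence, structure, id = NULL) {
  db <- if (is.character(structure)) structure else structure$db
  if (is.null(id) && !is.character(structure)) id <- structure$id
  rna <- chartr("T", "U", toupper(sequence))
  if (nchar(rna) != nchar(db))
    stop("sequence and structure lengths differ")
  ch <- strsplit(rna, "")[[1L]]
  st <- strsplit(db, "")[[1L]]
  key <- paste0(ch, st)
  if (any(!key %in% names(enc_lookup)))
    stop("cannot encode position ", which(!key %in% names(enc_lookup))[1L],
         " (residue must be A/C/G/U)")
  out <- list(id = id, enc = paste(enc_lookup[key], collapse = ""),
              seq = rna, db = db)
  class(out) <- "encoded_sequence"
  out
}

#' Decode a 12-letter encoded string
#' @param enc encoded string (gaps allowed).
#' @return List with `seq` and `db` (gaps preserved in both).
#' @export
decode_structure <- function(enc) {
  ch <- strsplit(enc, "")[[1L]]
  if (any(!ch %in% names(dec_residue)))
    stop("invalid encoded character: ", ch[!ch %in% names(dec_residue)][1L])
  list(seq = paste(dec_residue[ch], collapse = ""),
       db = paste(dec_state[ch], collapse = ""))
}

#' Default 12x12 sequence-structure scoring matrix
#'
#' +3 when both residue and pairing state match, +1 when only the state
#' matches, -1 when only the residue matches, -2 when neither does: the
#' qualitative ordering structure > sequence assumed by
#' sequence-structure alignment.  Any published ITS2-specific matrix with
#' the same dimnames can be dropped in instead.
#'
#' @return A 12x12 numeric matrix with the encoding codes as dimnames.
#' @export
default_score_matrix <- function() {
  codes <- ENC_TABLE$code
  res <- ENC_TABLE$residue
  st <- ENC_TABLE$state
  S <- matrix(-2, 12, 12, dimnames = list(codes, codes))
  for (i in 1:12) for (j in 1:12) {
    rm <- res[i] == res[j]; sm <- st[i] == st[j]
    S[i, j] <- if (rm && sm) 3 else if (sm) 1 else if (rm) -1 else -2
  }
  S
}

new_struct_alignment <- function(id, enc, score = NA_real_) {
  dec <- lapply(enc, decode_structure)
  rows <- data.frame(id = id, enc = enc,
                     seq = vapply(dec, `[[`, "", "seq"),
                     db = vapply(dec, `[[`, "", "db"),
                     stringsAsFactors = FALSE)
  if (length(unique(nchar(enc))) != 1L)
    stop("alignment rows have unequal lengths")
  structure(list(rows = rows, score = score, width = nchar(enc[1L])),
            class = "struct_alignment")
}

#' @export
print.struct_alignment <- function(x, ...) {
  cat("Structural alignment:", nrow(x$rows), "records x", x$width,
      "columns\n")
  invisible(x)
}

#' Globally align two encoded sequences (affine gaps)
#'
#' Optimal global alignment over the 12-letter alphabet under the given
#' scoring matrix and affine gap costs.  Ties are broken
#' deterministically: match/mismatch preferred over gaps, then a gap in
#' the first sequence.
#'
#' @param a,b `encoded_sequence` objects.
#' @param matrix 12x12 scoring matrix (default [default_score_matrix()]).
#' @param gap_open,gap_extend gap penalties (defaults -5, -1; a run of L
#'   gaps costs `gap_open + (L-1)*gap_extend`).
#' @return A `struct_alignment` of the two records with `$score`.
#' @export
align_pair <- function(a, b, matrix = default_score_matrix(),
                       gap_open = -5, gap_extend = -1) {
  ea <- strsplit(a$enc, "")[[1L]]
  eb <- strsplit(b$enc, "")[[1L]]
  if (length(ea) == 0L || length(eb) == 0L) stop("empty sequence")
  S <- matrix[ea, eb, drop = FALSE]
  al <- c_affine_align(S, gap_open, gap_extend)
  ga <- ifelse(al$a > 0L, ea[pmax(al$a, 1L)], "-")
  gb <- ifelse(al$b > 0L, eb[pmax(al$b, 1L)], "-")
  new_struct_alignment(c(a$id, b$id),
                       c(paste(ga, collapse = ""), paste(gb, collapse = "")),
                       score = al$score)
}

## profile = 12 x L frequency matrix over encoding codes (gaps drop out)
profile_of <- function(enc_rows) {
  ch <- do.call(rbind, strsplit(enc_rows, ""))
  L <- ncol(ch)
  F <- matrix(0, 12, L, dimnames = list(ENC_TABLE$code, NULL))
  for (code in ENC_TABLE$code)
    F[code, ] <- colSums(ch == code)
  F / length(enc_rows)
}

merge_profiles <- function(rows_a, rows_b, matrix, gap_open, gap_extend) {
  Fa <- profile_of(rows_a); Fb <- profile_of(rows_b)
  S <- t(Fa) %*% matrix %*% Fb
  al <- c_affine_align(S, gap_open, gap_extend)
  expand <- function(rows, idx) {
    ch <- strsplit(rows, "")
    vapply(ch, function(x)
      paste(ifelse(idx > 0L, x[pmax(idx, 1L)], "-"), collapse = ""),
      character(1))
  }
  list(a = expand(rows_a, al$a), b = expand(rows_b, al$b))
}

#' Progressive multiple alignment of encoded sequences
#'
#' Pairwise alignment scores give a score-derived distance
#' (d(a,b) = (s(a,a)+s(b,b))/2 - s(a,b)); a UPGMA guide tree on those
#' distances orders profile-profile merges with the same affine-gap DP
#' kernel as [align_pair()].
#'
#' @param records list of `encoded_sequence` (>= 2).
#' @inheritParams align_pair
#' @return A `struct_alignment` with one row per input record, in input
#'   order.
#' @export
align_progressive <- function(records, matrix = default_score_matrix(),
                              gap_open = -5, gap_extend = -1) {
  n <- length(records)
  if (n < 2L) stop("progressive alignment needs at least 2 records")
  ids <- vapply(records, function(r) r$id %||% NA_character_, character(1))
  if (anyDuplicated(ids)) stop("duplicate record ids")
  if (n == 2L)
    return(align_pair(records[[1L]], records[[2L]], matrix,
                      gap_open, gap_extend))
  selfscore <- function(r) {
    e <- strsplit(r$enc, "")[[1L]]
    sum(matrix[cbind(e, e)])
  }
  ss <- vapply(records, selfscore, numeric(1))
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sc <- align_pair(records[[i]], records[[j]], matrix,
                     gap_open, gap_extend)$score
    D[i, j] <- D[j, i] <- (ss[i] + ss[j]) / 2 - sc
  }
  hc <- hclust(as.dist(D), method = "average")
  groups <- lapply(seq_len(n), function(i)
    list(idx = i, rows = records[[i]]$enc))
  for (step in seq_len(n - 1L)) {
    m1 <- hc$merge[step, 1L]; m2 <- hc$merge[step, 2L]
    g1 <- if (m1 < 0) groups[[-m1]] else groups[[n + m1]]
    g2 <- if (m2 < 0) groups[[-m2]] else groups[[n + m2]]
    mg <- merge_profiles(g1$rows, g2$rows, matrix, gap_open, gap_extend)
    groups[[n + step]] <- list(idx = c(g1$idx, g2$idx),
                               rows = c(mg$a, mg$b))
  }
  final <- groups[[2L * n - 1L]]
  ord <- order(final$idx)
  new_struct_alignment(ids[final$idx][ord], final$rows[ord])
}

row_of <- function(alignment, id) {
  k <- match(id, alignment$rows$id)
  if (is.na(k)) stop("record not in alignment: ", id)
  k
}

## map: alignment column -> original (ungapped) position, 0 at gaps
col_to_pos <- function(enc_row) {
  ch <- strsplit(enc_row, "")[[1L]]
  pos <- cumsum(ch != "-")
  pos[ch == "-"] <- 0L
  pos
}

#' Count CBCs and hemi-CBCs between two aligned records
#'
#' For every pair of alignment columns paired in both records (a pair in
#' x whose two columns also form a pair in y): a CBC when both residues
#' differ and both pairs are canonical/wobble; a hemi-CBC when exactly
#' one residue differs and both pairs remain valid.  Columns carrying a
#' gap in either record, or pairings not maintained in both structures,
#' contribute to neither count.
#'
#' @param alignment a `struct_alignment`.
#' @param x,y record ids.
#' @return List with `cbc` and `hemi` counts.
#' @export
count_cbc <- function(alignment, x, y) {
  kx <- row_of(alignment, x); ky <- row_of(alignment, y)
  rx <- alignment$rows[kx, ]; ry <- alignment$rows[ky, ]
  sx <- strsplit(rx$seq, "")[[1L]]; sy <- strsplit(ry$seq, "")[[1L]]
  dbx_g <- gsub("-", "", rx$db); dby_g <- gsub("-", "", ry$db)
  px <- db_to_pairs(dbx_g); py <- db_to_pairs(dby_g)
  posx <- col_to_pos(rx$enc); posy <- col_to_pos(ry$enc)
  colx <- match(seq_along(px), posx)  # original position -> column
  coly <- match(seq_along(py), posy)
  cbc <- 0L; hemi <- 0L
  for (i in which(px > seq_along(px))) {
    ci <- colx[i]; cj <- colx[px[i]]
    oi <- posy[ci]; oj <- posy[cj]
    if (oi == 0L || oj == 0L) next           # gap in y
    if (py[oi] != oj) next                   # pairing not maintained
    a1 <- sx[ci]; a2 <- sx[cj]; b1 <- sy[ci]; b2 <- sy[cj]
    if (!paste0(a1, a2) %in% PAIR_OK || !paste0(b1, b2) %in% PAIR_OK)
      next                                   # non-canonical "pair"
    d1 <- a1 != b1; d2 <- a2 != b2
    if (d1 && d2) cbc <- cbc + 1L
    else if (d1 || d2) hemi <- hemi + 1L
  }
  list(cbc = cbc, hemi = hemi)
}

#' Pairwise CBC/hemi-CBC matrices for a structural alignment
#'
#' @param alignment a `struct_alignment` with >= 2 records.
#' @return Object of class `cbc_matrix`: list with symmetric integer
#'   matrices `cbc` and `hemi` (zero diagonals) and `ids`.
#' @export
cbc_matrix <- function(alignment) {
  ids <- alignment$rows$id
  n <- length(ids)
  if (n < 2L) stop("need >= 2 records")
  cbc <- matrix(0L, n, n, dimnames = list(ids, ids))
  hemi <- cbc
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ct <- count_cbc(alignment, ids[i], ids[j])
    cbc[i, j] <- cbc[j, i] <- ct$cbc
    hemi[i, j] <- hemi[j, i] <- ct$hemi
  }
  structure(list(cbc = cbc, hemi = hemi, ids = ids), class = "cbc_matrix")
}

#' Transitions, transversions and INDEL events between two records
#'
#' Substitutions are counted over columns where both records carry a
#' residue: transitions are A<->G and C<->U, transversions all other
#' residue changes.  INDEL events are maximal runs of columns where
#' exactly one record has a gap; `indel_columns` is their total length.
#'
#' @inheritParams count_cbc
#' @return List: `ts`, `tv`, `indel_events`, `indel_columns`.
#' @export
count_variation <- function(alignment, x, y) {
  kx <- row_of(alignment, x); ky <- row_of(alignment, y)
  sx <- strsplit(alignment$rows$seq[kx], "")[[1L]]
  sy <- strsplit(alignment$rows$seq[ky], "")[[1L]]
  gx <- sx == "-"; gy <- sy == "-"
  both <- !gx & !gy
  diffs <- both & sx != sy
  pur <- c("A", "G")
  ts <- sum(diffs & ((sx %in% pur) == (sy %in% pur)))
  tv <- sum(diffs) - ts
  xorgap <- xor(gx, gy)
  r <- rle(xorgap)
  list(ts = ts, tv = tv,
       indel_events = sum(r$values),
       indel_columns = sum(xorgap))
}
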