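## ITS2 excision from full ITS sequences by conserved-motif flank search
## (3' end of 5.8S, 5' start of 28S; IUPAC-degenerate, mismatch-tolerant)
## and the 20-nt flank padding applied before folding.

IUPAC <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))

#' Default conserved flank motifs (fungal rDNA consensus proxies:
#' 3' end of 5.8S, 5' start of 28S)
#' @name flank_motifs
#' @export
MOTIF_5P_DEFAULT <- "GCATCGATGAAGAACGCAGC"
#' @rdname flank_motifs
#' @export
MOTIF_3P_DEFAULT <- "TTGACCTCGGATCAGGTAGG"

## all windows where `motif` (IUPAC-degenerate) matches `seq` with the
## mismatch count of each window
scan_motif <- function(seq, motif) {
  s <- strsplit(chartr("U", "T", toupper(seq)), "")[[1L]]
  m <- strsplit(toupper(motif), "")[[1L]]
  L <- length(m); n <- length(s)
  if (n < L) return(data.frame(start = integer(0), mism = integer(0)))
  allowed <- IUPAC[m]
  if (any(vapply(allowed, is.null, logical(1))))
    stop("invalid IUPAC code in motif: ", motif)
  nw <- n - L + 1L
  mism <- integer(nw)
  for (k in seq_len(L)) {
    ok <- s[k:(k + nw - 1L)] %in% allowed[[k]]
    mism <- mism + !ok
  }
  data.frame(start = seq_len(nw), mism = mism)
}

best_match <- function(seq, motif, max_mismatch, tie = c("leftmost", "rightmost")) {
  tie <- match.arg(tie)
  sc <- scan_motif(seq, motif)
  if (nrow(sc) == 0L) return(NULL)
  best <- min(sc$mism)
  hits <- sc$start[sc$mism == best]
  pos <- if (tie == "leftmost") hits[1L] else hits[length(hits)]
  list(start = pos, end = pos + nchar(motif) - 1L, mism = best,
       ok = best <= max_mismatch)
}

#' Extract the ITS2 region from a full ITS sequence
#'
#' The ITS2 is the span strictly between a 5' flank motif (anchored in
#' the 3' end of 5.8S) and a 3' flank motif (5' start of 28S), each
#' located by an IUPAC-degenerate scan allowing up to `max_mismatch`
#' mismatches.  The best match has the fewest mismatches; ties resolve
#' to the leftmost 5.8S and the rightmost 28S hit.  With
#' `extract = FALSE` the record is passed through as bare ITS2 (no
#' padding possible).
#'
#' @param record a single-row [sequence_set()] (or list with `id`,
#'   `seq`, optional `host`).
#' @param motif_5p,motif_3p IUPAC-degenerate flank motifs.
#' @param max_mismatch maximum mismatches per motif (default 2).
#' @param pad flank padding width in nt (default 20; 0 disables).
#' @param extract set FALSE for input that is already bare ITS2.
#' @return Object of class `its2_record`: `id`, `host`, `its2`,
#'   `padded`, `span` (1-based inclusive ITS2 interval on the source),
#'   `source`, `flags`.
#' @export
extract_its2 <- function(record, motif_5p = MOTIF_5P_DEFAULT,
                         motif_3p = MOTIF_3P_DEFAULT, max_mismatch = 2L,
                         pad = 20L, extract = TRUE) {
  id <- record$id
  seq <- toupper(record$seq)
  host <- record$host %||% NA_character_
  if (!extract) {
    out <- list(id = id, host = host, its2 = seq, padded = seq,
                span = c(1L, nchar(seq)), source = seq,
                flags = "passthrough")
    class(out) <- "its2_record"
    return(out)
  }
  m5 <- best_match(seq, motif_5p, max_mismatch, "leftmost")
  if (is.null(m5) || !m5$ok)
    stop("flank not found (5'): best partial match ",
         if (is.null(m5)) "none" else
           paste0("at ", m5$start, " with ", m5$mism, " mismatches"),
         " for record '", id, "'")
  rest <- substr(seq, m5$end + 1L, nchar(seq))
  m3r <- best_match(rest, motif_3p, max_mismatch, "rightmost")
  if (is.null(m3r) || !m3r$ok)
    stop("flank not found (3'): best partial match ",
         if (is.null(m3r)) "none" else
           paste0("at ", m3r$start + m5$end, " with ", m3r$mism,
                  " mismatches"),
         " for record '", id, "'")
  s <- m5$end + 1L
  e <- m5$end + m3r$start - 1L
  if (e < s) stop("empty ITS2 span for record '", id, "'")
  out <- list(id = id, host = host, its2 = substr(seq, s, e),
              padded = NA_character_, span = c(s, e), source = seq,
              flags = character(0))
  class(out) <- "its2_record"
  pad_flanks(out, n = pad)
}

#' Pad an ITS2 record with flanking source bases
#'
#' Adds up to `n` source bases on each side of the ITS2 span.  Bases
#' beyond the source boundaries are never invented: the padding is
#' truncated to what the source provides and the truncation logged.
#'
#' @param its2 an `its2_record` with known `span` and `source`.
#' @param n padding width per side (default 20).
#' @return The record with `padded` (and `padded_span`) filled in.
#' @export
pad_flanks <- function(its2, n = 20L) {
  s <- its2$span[1L]; e <- its2$span[2L]
  src <- its2$source
  ps <- max(1L, s - n); pe <- min(nchar(src), e + n)
  if (n > 0L && (ps > s - n || pe < e + n)) {
    log_msg("pad_flanks: padding truncated to source for '",
            its2$id %||% "?", "' (", s - ps, " nt 5', ", pe - e, " nt 3')")
    its2$flags <- union(its2$flags, "padding truncated")
  }
  its2$padded <- substr(src, ps, pe)
  its2$padded_span <- c(ps, pe)
  its2
}

#' Length and GC content of a sequence set
#'
#' GC = (G+C) / (A+C+G+T/U) x 100, N excluded from numerator and
#' denominator, reported to two decimals.
#'
#' @param set a [sequence_set()], or a list of `its2_record` (the bare
#'   ITS2 is then used).
#' @return Data frame: `id`, `length`, `gc`.
#' @export
sequence_stats <- function(set) {
  if (inherits(set, "sequence_set") || is.data.frame(set)) {
    ids <- set$id; seqs <- set$seq
  } else {
    ids <- vapply(set, function(r) r$id, character(1))
    seqs <- vapply(set, function(r) r$its2, character(1))
  }
  if (length(ids) == 0L) stop("empty sequence set")
  gc <- vapply(seqs, function(s) {
    ch <- strsplit(toupper(s), "")[[1L]]
    denom <- sum(ch %in% c("A", "C", "G", "T", "U"))
    if (denom == 0L) return(NA_real_)
    round(100 * sum(ch %in% c("G", "C")) / denom, 2)
  }, numeric(1))
  data.frame(id = ids, length = nchar(seqs), gc = unname(gc),
             stringsAsFactors = FALSE)
}
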