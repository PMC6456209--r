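## File formats: FASTA, Vienna dot-bracket triplets, Newick, TSV tables,
## flat YAML config.  Readers validate and refuse malformed records rather
## than repairing them silently.

VALID_BASES <- c("A", "C", "G", "T", "U", "N")

#' Sequence set
#'
#' A validated collection of named nucleotide sequences: a data frame with
#' columns \code{id}, \code{desc} and \code{seq}.  Ids must be unique,
#' sequences non-empty and restricted to the alphabet A, C, G, T, U, N
#' (case-insensitive on input, stored uppercase).
#'
#' @param id character vector of unique record ids.
#' @param seq character vector of sequences.
#' @param desc optional descriptions (default "").
#' @return An object of class \code{sequence_set}.
#' @export
sequence_set <- function(id, seq, desc = "") {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq))
    stop("`id` and `seq` must have the same length")
  if (anyDuplicated(id))
    stop("duplicate sequence id: ", id[duplicated(id)][1L])
  if (any(!nzchar(seq)))
    stop("empty sequence for id: ", id[!nzchar(seq)][1L])
  bad <- vapply(strsplit(seq, ""), function(x) any(!x %in% VALID_BASES),
                logical(1))
  if (any(bad))
    stop("invalid characters in sequence: ", id[bad][1L])
  out <- data.frame(id = id, desc = rep_len(as.character(desc), length(id)),
                    seq = seq, stringsAsFactors = FALSE)
  class(out) <- c("sequence_set", "data.frame")
  out
}

#' Read a FASTA file into a sequence set
#'
#' Multi-line records are concatenated with whitespace stripped; both T and
#' U are accepted.  Malformed input (sequence data before the first header,
#' empty sequences, duplicate ids) raises an error naming the offending
#' line.
#'
#' @param path path to a FASTA file.
#' @return A [sequence_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- seq_along(lines)[keep]
  lines <- trimws(lines[keep])
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L])
    stop("FASTA parse error at line ", lineno[1L], ": sequence before header")
  rec <- cumsum(is_hdr)
  hdr <- sub("^>", "", lines[is_hdr])
  hdr_line <- lineno[is_hdr]
  if (any(!nzchar(hdr)))
    stop("FASTA parse error at line ", hdr_line[!nzchar(hdr)][1L],
         ": empty header")
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seqs <- vapply(split(lines[!is_hdr], factor(rec[!is_hdr], levels = seq_along(hdr))),
                 function(x) gsub("\\s", "", paste(x, collapse = "")),
                 character(1))
  if (any(!nzchar(seqs)))
    stop("FASTA parse error at line ", hdr_line[!nzchar(seqs)][1L],
         ": record '", id[!nzchar(seqs)][1L], "' has no sequence")
  if (anyDuplicated(id))
    stop("FASTA parse error at line ",
         hdr_line[duplicated(id)][1L], ": duplicate id '",
         id[duplicated(id)][1L], "'")
  sequence_set(id, seqs, desc)
}

#' Write a sequence set as FASTA
#'
#' @param x a [sequence_set()] (or data frame with `id`, `seq`, optional
#'   `desc`).
#' @param path output path.
#' @param width line width for wrapping (default 70).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path, width = 70L) {
  hdr <- ifelse(!is.null(x$desc) & nzchar(x$desc %||% ""),
                paste(x$id, x$desc), x$id)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(x))) {
    writeLines(paste0(">", hdr[k]), con)
    s <- x$seq[k]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check that a dot-bracket string is balanced
#' @param db dot-bracket string over "()." characters.
#' @return TRUE invisibly; error otherwise.
#' @keywords internal
check_dotbracket <- function(db) {
  ch <- strsplit(db, "")[[1L]]
  if (any(!ch %in% c("(", ")", ".")))
    stop("invalid dot-bracket character: ",
         ch[!ch %in% c("(", ")", ".")][1L])
  depth <- cumsum((ch == "(") - (ch == ")"))
  if (any(depth < 0L) || depth[length(depth)] != 0L)
    stop("unbalanced dot-bracket string")
  invisible(TRUE)
}

#' Read a Vienna (dot-bracket) file
#'
#' Records are header / sequence / structure line triplets; the structure
#' line may carry a trailing energy token such as \code{(-12.30)}.  Missing
#' energies are stored as \code{NA}, never as 0.
#'
#' @param path path to a Vienna file.
#' @return A data frame of class \code{vienna_set} with columns \code{id},
#'   \code{seq}, \code{db} and \code{energy} (kcal/mol).
#' @export
read_vienna <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 3L != 0L)
    stop("Vienna file must consist of header/sequence/structure triplets")
  n <- length(lines) / 3L
  id <- character(n); seqs <- character(n); db <- character(n)
  energy <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    h <- trimws(lines[3L * k - 2L])
    if (!startsWith(h, ">")) stop("expected header, got: ", h)
    id[k] <- sub("\\s.*$", "", sub("^>", "", h))
    seqs[k] <- toupper(gsub("\\s", "", lines[3L * k - 1L]))
    sline <- trimws(lines[3L * k])
    epat <- "\\(\\s*(-?[0-9]+(\\.[0-9]+)?)\\s*\\)\\s*$"
    m <- regmatches(sline, regexec(epat, sline))[[1L]]
    if (length(m) >= 2L) {
      energy[k] <- as.numeric(m[2L])
      sline <- trimws(sub(epat, "", sline))
    }
    db[k] <- sline
    check_dotbracket(db[k])
    if (nchar(seqs[k]) != nchar(db[k]))
      stop("sequence/structure length mismatch for record '", id[k], "'")
  }
  out <- data.frame(id = id, seq = seqs, db = db, energy = energy,
                    stringsAsFactors = FALSE)
  class(out) <- c("vienna_set", "data.frame")
  out
}

#' Write Vienna (dot-bracket) records
#'
#' @param x data frame with columns `id`, `seq`, `db` and optionally
#'   `energy`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_vienna <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(x))) {
    check_dotbracket(x$db[k])
    if (nchar(x$seq[k]) != nchar(x$db[k]))
      stop("sequence/structure length mismatch for record '", x$id[k], "'")
    writeLines(paste0(">", x$id[k]), con)
    writeLines(x$seq[k], con)
    e <- if (!is.null(x$energy)) x$energy[k] else NA_real_
    writeLines(if (is.na(e)) x$db[k]
               else sprintf("%s (%.2f)", x$db[k], e), con)
  }
  invisible(path)
}

#' Write a phylogenetic tree in Newick format
#'
#' Branch lengths are kept; integer bootstrap supports stored in
#' \code{tree$node.label} become internal node labels.
#'
#' @param tree an [ape::phylo] object with labelled leaves.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  if (is.null(tree) || !inherits(tree, "phylo") || is.null(tree$tip.label) ||
      length(tree$tip.label) == 0L)
    stop("tree must be a non-empty 'phylo' object with labelled leaves")
  if (any(is.na(tree$tip.label)) || any(!nzchar(tree$tip.label)))
    stop("tree has an unlabelled leaf")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a flat-key YAML configuration file
#' @param path path to a YAML file of pipeline parameters.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Timestamped log line to standard error
#' @param ... message parts, pasted together.
#' @return Invisibly, the formatted line.
#' @export
log_msg <- function(...) {
  line <- paste0("[", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "] ",
                 paste0(..., collapse = ""))
  message(line)
  invisible(line)
}
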