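## Helix-level annotation of dot-bracket structures: parse the exterior
## (central) loop and its radiating stems, recognize "extended subdomain"
## stems (short enclosing stems bearing a second-level multiloop),
## classify the five ITS2 topology types, find the UGGC/CGGC motif at the
## base of helix III, and build conservation-annotated consensus
## structures from a structural alignment.

## walk a stem chain from its outermost pair; stop at hairpin or multiloop
walk_stem <- function(p, i) {
  npairs <- 0L
  a <- i; b <- p[i]
  repeat {
    npairs <- npairs + 1L
    k <- a + 1L
    children <- integer(0)
    while (k < b) {
      if (p[k] > k) { children <- c(children, k); k <- p[k] + 1L }
      else k <- k + 1L
    }
    if (length(children) == 1L) { a <- children[1L]; b <- p[a] }
    else return(list(npairs = npairs, children = children,
                     loop_size = if (length(children) == 0L) b - a - 1L else NA_integer_,
                     inner = c(a, b)))
  }
}

#' Build a helix tree from a secondary structure
#'
#' The central loop is the exterior (outermost) loop; a helix "radiates
#' from the central loop" when its outermost pair borders that loop.  A
#' top-level stem of at most `subdomain_max_stem` pairs that encloses a
#' second-level multiloop is treated as an extended subdomain of the
#' central bulge: the helices it bears are annotated with origin
#' `"subdomain"`.  Principal helices are labelled I, II, ... 5' to 3';
#' small helices (<= `iia_max_pairs` pairs) lying between two larger ones
#' are labelled IIa-style and excluded from the principal count.
#'
#' @param structure an `its2_structure`, or any list with a `db` field
#'   (and optionally `pairs`).
#' @param subdomain_max_stem maximum stem size (pairs) of an enclosing
#'   subdomain stem (default 3).
#' @param iia_max_pairs maximum stem size of a IIa-type small helix
#'   (default 3).
#' @return An object of class `helix_tree`: list with `helices` (data
#'   frame: label, start, end, npairs, loop_size, origin, principal),
#'   `central_loop` (index set of exterior unpaired positions), `db`, `n`.
#'   A structure with no pairs yields zero helices, not an error.
#' @export
build_helix_tree <- function(structure, subdomain_max_stem = 3L,
                             iia_max_pairs = 3L) {
  db <- if (is.character(structure)) structure else structure$db
  p <- if (!is.character(structure) && !is.null(structure$pairs))
    structure$pairs else db_to_pairs(db)
  n <- length(p)
  ## top-level units
  top <- integer(0)
  k <- 1L
  while (k <= n) {
    if (p[k] > k) { top <- c(top, k); k <- p[k] + 1L } else k <- k + 1L
  }
  rows <- list()
  for (i in top) {
    w <- walk_stem(p, i)
    if (length(w$children) >= 2L && w$npairs <= subdomain_max_stem) {
      for (ci in w$children) {
        cw <- walk_stem(p, ci)
        rows[[length(rows) + 1L]] <-
          data.frame(start = ci, end = p[ci], npairs = cw$npairs,
                     loop_size = cw$loop_size, origin = "subdomain",
                     stringsAsFactors = FALSE)
      }
    } else {
      rows[[length(rows) + 1L]] <-
        data.frame(start = i, end = p[i], npairs = w$npairs,
                   loop_size = w$loop_size, origin = "central",
                   stringsAsFactors = FALSE)
    }
  }
  hel <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), end = integer(0), npairs = integer(0),
               loop_size = integer(0), origin = character(0),
               stringsAsFactors = FALSE)
  hel <- hel[order(hel$start), , drop = FALSE]
  ## IIa-style small helices between two larger neighbours
  m <- nrow(hel)
  principal <- rep(TRUE, m)
  if (m >= 3L) {
    for (k in 2L:(m - 1L)) {
      if (hel$npairs[k] <= iia_max_pairs &&
          hel$npairs[k - 1L] > iia_max_pairs &&
          hel$npairs[k + 1L] > iia_max_pairs)
        principal[k] <- FALSE
    }
  }
  hel$principal <- principal
  lab <- character(m)
  lab[principal] <- as.character(as.roman(seq_len(sum(principal))))
  if (any(!principal))
    lab[!principal] <- paste0(
      ifelse(cumsum(principal)[!principal] > 0,
             as.character(as.roman(cumsum(principal)[!principal])), "0"), "a")
  hel$label <- lab
  hel <- hel[, c("label", "start", "end", "npairs", "loop_size",
                 "origin", "principal")]
  exterior <- setdiff(which(p == 0L),
                      unlist(mapply(seq, hel$start, hel$end,
                                    SIMPLIFY = FALSE)))
  out <- list(helices = hel, central_loop = exterior, db = db, n = n)
  class(out) <- "helix_tree"
  out
}

#' Classify the ITS2 topology type of a helix tree
#'
#' Five canonical layouts are distinguished: (1) three helices radiating
#' directly from the central bulge; (2) helix I central, helices II and
#' III on an extended subdomain; (3) as 2 with an additional small helix
#' IIa between II and III; (4) four helices radiating from the central
#' bulge; (5) helices I and II on a subdomain, III and IV central.  Trees
#' matching none of these get type code 0 ("unclassified"), which never
#' aborts a pipeline run.
#'
#' @param tree a [build_helix_tree()] result.
#' @return List of class `topology_type`: `type` (0-5), `n_central`,
#'   `subdomain_present`, `iia_present`.
#' @export
classify_topology <- function(tree) {
  hel <- tree$helices
  ph <- hel[hel$principal, , drop = FALSE]
  orig <- ph$origin
  iia <- any(!hel$principal)
  np <- nrow(ph)
  type <- 0L
  if (np == 3L && all(orig == "central") && !iia) type <- 1L
  else if (np == 3L && identical(orig, c("central", "subdomain", "subdomain")))
    type <- if (iia) 3L else 2L
  else if (np == 4L && all(orig == "central") && !iia) type <- 4L
  else if (np == 4L &&
           identical(orig, c("subdomain", "subdomain", "central", "central")))
    type <- 5L
  structure(list(type = type,
                 n_central = sum(orig == "central"),
                 subdomain_present = any(hel$origin == "subdomain"),
                 iia_present = iia),
            class = "topology_type")
}

#' Detect the UGGC/CGGC motif at the base of helix III
#'
#' Helix III is taken as the third principal helix 5' to 3'; a warning is
#' logged when that helix is not also the longest.  The first six
#' nucleotides of its 5' strand are scanned for UGGC, then for the CGGC
#' variant.
#'
#' @param tree a [build_helix_tree()] result.
#' @param sequence the RNA/DNA sequence the tree was built from.
#' @return List: `motif` (matched window or NA) and `variant`
#'   (`"UGGC"`, `"CGGC"` or `"absent"`).
#' @export
detect_basal_motif <- function(tree, sequence) {
  hel <- tree$helices
  ph <- hel[hel$principal, , drop = FALSE]
  if (nrow(ph) < 3L) {
    warning("fewer than 3 principal helices; no helix III")
    return(list(motif = NA_character_, variant = "absent"))
  }
  h3 <- ph[3L, ]
  if (h3$npairs < max(ph$npairs))
    log_msg("helix III (positional) is not the longest helix; ",
            "positional labelling kept")
  rna <- chartr("T", "U", toupper(sequence))
  window <- substr(rna, h3$start, min(h3$start + 5L, nchar(rna)))
  if (grepl("UGGC", window, fixed = TRUE))
    list(motif = "UGGC", variant = "UGGC")
  else if (grepl("CGGC", window, fixed = TRUE))
    list(motif = "CGGC", variant = "CGGC")
  else list(motif = NA_character_, variant = "absent")
}

#' Consensus sequence and structure of a structural alignment
#'
#' Per alignment column the majority residue among non-gap entries and
#' its frequency (conservation), plus the consensus pairing state: the
#' state ("(", ")" or ".") held by more than half of the records.  A
#' column is flagged conserved when its residue conservation exceeds
#' 0.51.  Majority open/close states are re-matched into a well-formed
#' dot-bracket; unmatched brackets revert to unpaired, which is how a
#' helix paired in fewer than half the records drops out of the
#' consensus.
#'
#' @param alignment a `struct_alignment` (see [align_progressive()]).
#' @param conserved_threshold conservation threshold (default 0.51).
#' @return Object of class `consensus_structure`: `columns` data frame
#'   (residue, conservation, state, conserved), `seq`, `db`.
#' @export
build_consensus <- function(alignment, conserved_threshold = 0.51) {
  rows <- alignment$rows
  if (length(rows$id) < 2L) stop("consensus requires at least 2 records")
  seqm <- do.call(rbind, strsplit(rows$seq, ""))
  dbm <- do.call(rbind, strsplit(rows$db, ""))
  nc <- ncol(seqm)
  nr <- nrow(seqm)
  residue <- character(nc); conservation <- numeric(nc)
  state <- character(nc)
  for (j in seq_len(nc)) {
    col <- seqm[, j]
    nong <- col[col != "-"]
    if (length(nong) == 0L) {
      residue[j] <- "-"; conservation[j] <- 0
    } else {
      tab <- sort(table(nong), decreasing = TRUE)
      residue[j] <- names(tab)[1L]
      conservation[j] <- tab[[1L]] / length(nong)
    }
    stab <- table(factor(dbm[, j], levels = c("(", ")", ".")))
    state[j] <- if (max(stab) > nr / 2) names(stab)[which.max(stab)] else "."
  }
  ## re-match majority brackets into a nested structure
  db <- state
  stack <- integer(0)
  for (j in seq_len(nc)) {
    if (db[j] == "(") stack <- c(stack, j)
    else if (db[j] == ")") {
      if (length(stack) == 0L) db[j] <- "."
      else stack <- stack[-length(stack)]
    }
  }
  db[stack] <- "."
  cols <- data.frame(residue = residue, conservation = conservation,
                     state = db,
                     conserved = conservation > conserved_threshold,
                     stringsAsFactors = FALSE)
  structure(list(columns = cols,
                 seq = paste(residue, collapse = ""),
                 db = paste(db, collapse = "")),
            class = "consensus_structure")
}
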