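## Species delimitation rules: a CBC between two records always separates
## species; absolute structural identity with a named reference transfers
## that name; everything else stays at genus level as "type-NN" blocks.

#' Minimal number of species compatible with a CBC matrix
#'
#' Records are partitioned into the minimum number of blocks such that no
#' within-block pair shows a CBC: the chromatic number of the
#' CBC-incompatibility graph (vertices = records, edges where cbc >= 1).
#' Solved exactly by branch and bound for up to `exact_limit` records,
#' greedy (largest-degree-first) beyond that, with an `exact` flag in the
#' result.
#'
#' @param cbc a `cbc_matrix` (or a plain symmetric count matrix).
#' @param exact_limit largest record count for the exact search
#'   (default 16).
#' @return List of class `species_partition`: `count`, `blocks` (list of
#'   id vectors), `assignment` (integer block per record), `exact`.
#' @export
minimal_species_count <- function(cbc, exact_limit = 16L) {
  M <- if (inherits(cbc, "cbc_matrix")) cbc$cbc else cbc
  if (!isSymmetric(unname(M))) stop("CBC matrix must be symmetric")
  ids <- rownames(M) %||% as.character(seq_len(nrow(M)))
  n <- nrow(M)
  adj <- M >= 1L
  diag(adj) <- FALSE
  if (n <= exact_limit) {
    res <- exact_coloring(adj)
    exact <- TRUE
  } else {
    res <- greedy_coloring(adj)
    exact <- FALSE
  }
  blocks <- split(ids, res)
  names(blocks) <- NULL
  out <- list(count = length(blocks), blocks = blocks,
              assignment = setNames(res, ids), exact = exact)
  class(out) <- "species_partition"
  out
}

## exact graph coloring: branch and bound over vertices in degree order
exact_coloring <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(integer(0))
  ord <- order(-colSums(adj))
  best_k <- n
  best <- seq_len(n)
  color <- integer(n)
  rec <- function(pos, used) {
    if (used >= best_k) return()
    if (pos > n) {
      best_k <<- used
      best <<- color
      return()
    }
    v <- ord[pos]
    nb <- which(adj[v, ] & color > 0L)
    forbidden <- unique(color[nb])
    for (cc in seq_len(min(used + 1L, best_k - 1L))) {
      if (cc %in% forbidden) next
      color[v] <<- cc
      rec(pos + 1L, max(used, cc))
      color[v] <<- 0L
    }
  }
  rec(1L, 0L)
  ## renumber blocks by first appearance in input order
  map <- integer(0)
  out <- integer(n)
  for (i in seq_len(n)) {
    c0 <- best[i]
    if (is.na(match(c0, map))) map <- c(map, c0)
    out[i] <- match(c0, map)
  }
  out
}

greedy_coloring <- function(adj) {
  n <- nrow(adj)
  ord <- order(-colSums(adj))
  color <- integer(n)
  for (v in ord) {
    forbidden <- color[adj[v, ] & color > 0L]
    color[v] <- min(setdiff(seq_len(n), forbidden))
  }
  map <- unique(color)
  match(color, map)
}

#' Absolute identity of two folded records
#'
#' `strict` mode (default): the records align gap-free with zero
#' substitutions and identical pairing, i.e. identical sequence and
#' identical dot-bracket.  `structure-only`: identical dot-bracket
#' regardless of sequence.
#'
#' @param x,y lists with `seq` and `db` fields (e.g. `its2_structure` or
#'   `encoded_sequence`).
#' @param mode `"strict"` or `"structure-only"`.
#' @return Logical.
#' @export
absolute_identity <- function(x, y, mode = c("strict", "structure-only")) {
  mode <- match.arg(mode)
  sx <- chartr("T", "U", toupper(x$seq)); sy <- chartr("T", "U", toupper(y$seq))
  if (mode == "strict") identical(sx, sy) && identical(x$db, y$db)
  else identical(x$db, y$db)
}

#' Assign species labels to query records
#'
#' A query takes a reference species name iff it is absolutely identical
#' to that reference and shows no CBC against it.  Identity against two
#' references with different names is an error, as is identity combined
#' with cbc >= 1 for the same pair (an upstream alignment fault).
#' Remaining queries are grouped, within their genus, into minimal
#' CBC-free blocks labelled "<Genus> sp. type-NN", numbered by first
#' occurrence in input order.  A query with a CBC against every
#' reference and every query of its genus is flagged as a putative new
#' species.
#'
#' @param queries character vector of query record ids.
#' @param references data frame with columns `id`, `species` (may have
#'   zero rows).
#' @param cbc a `cbc_matrix` covering queries and references.
#' @param identity logical matrix (queries x references) of
#'   [absolute_identity()] results; may be `NULL` when no references.
#' @param genus named character vector: genus label per query id.
#' @return A `species_partition` with an `assignment_table` data frame
#'   (id, label, block, flag).
#' @export
assign_species <- function(queries, references, cbc, identity = NULL,
                           genus) {
  M <- cbc$cbc
  if (any(!queries %in% rownames(M)))
    stop("query missing from CBC matrix")
  if (any(!queries %in% names(genus)))
    stop("every query needs a genus label")
  nref <- if (is.null(references)) 0L else nrow(references)
  label <- setNames(rep(NA_character_, length(queries)), queries)
  flag <- setNames(rep("", length(queries)), queries)
  if (nref > 0L) {
    if (is.null(identity)) stop("identity matrix required with references")
    for (q in queries) {
      hits <- which(identity[q, ])
      if (length(hits) == 0L) next
      rid <- references$id[hits]
      bad <- rid[M[q, rid] >= 1L]
      if (length(bad))
        stop("inconsistency: query '", q, "' identical to reference '",
             bad[1L], "' but cbc >= 1 (upstream alignment fault)")
      sp <- unique(references$species[hits])
      if (length(sp) > 1L)
        stop("query '", q, "' identical to references of different species: ",
             paste(sp, collapse = ", "))
      label[q] <- sp
    }
  }
  ## genus-level type-NN blocks for unnamed queries
  for (g in unique(genus[queries])) {
    gq <- queries[genus[queries] == g & is.na(label[queries])]
    if (length(gq) == 0L) next
    sub <- M[gq, gq, drop = FALSE]
    part <- minimal_species_count(structure(list(cbc = sub), class = "cbc_matrix"))
    for (b in seq_along(part$blocks))
      label[part$blocks[[b]]] <- sprintf("%s sp. type-%02d", g, b)
  }
  ## putative new species: CBC against all same-genus queries and all refs
  for (q in queries) {
    others <- setdiff(queries[genus[queries] == genus[[q]]], q)
    refids <- if (nref > 0L) intersect(references$id, colnames(M)) else character(0)
    vs <- c(others, refids)
    if (length(vs) > 0L && all(M[q, vs] >= 1L))
      flag[q] <- "putative new species"
  }
  blocks <- split(queries, label[queries])
  names(blocks) <- NULL
  out <- list(count = length(blocks), blocks = blocks,
              assignment = setNames(match(label[queries], unique(label[queries])),
                                    queries),
              exact = TRUE,
              assignment_table = data.frame(
                id = queries, label = unname(label[queries]),
                block = match(label[queries], unique(label[queries])),
                flag = unname(flag[queries]), stringsAsFactors = FALSE))
  class(out) <- "species_partition"
  out
}
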