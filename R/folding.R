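## Secondary-structure prediction: MFE folding with a simplified
## nearest-neighbour stacking model, bounded suboptimal enumeration, and
## the topology-aware structure-selection rule (lowest-energy candidate
## with the canonical 3-4-helix ITS2 layout).

BASE_CODE <- c(A = 0L, C = 1L, G = 2L, U = 3L, T = 3L, N = 4L)
PAIR_OK <- c("AU", "UA", "CG", "GC", "GU", "UG")

#' Folding parameters
#'
#' @param min_loop minimum hairpin loop size in nt (default 3).
#' @param subopt_percent suboptimality window as percent of the MFE
#'   (default 5): suboptimal structures within this energy band are kept.
#' @param max_structures upper bound on the number of structures returned
#'   (default 50).
#' @param max_loop maximum interior/bulge loop size in unpaired nt
#'   (default 30).
#' @param energy_model `"stacking-simplified"` (default) or `"pair-count"`.
#' @param temperature display label only (the simplified model is not
#'   temperature-interpolated); default `"37C"`.
#' @return A list of class `folding_params`.
#' @export
folding_params <- function(min_loop = 3L, subopt_percent = 5,
                           max_structures = 50L, max_loop = 30L,
                           energy_model = c("stacking-simplified", "pair-count"),
                           temperature = "37C") {
  energy_model <- match.arg(energy_model)
  if (subopt_percent < 0 || subopt_percent > 100)
    stop("subopt_percent must be in [0, 100]")
  stopifnot(max_structures >= 1L, min_loop >= 1L)
  structure(list(min_loop = as.integer(min_loop),
                 subopt_percent = subopt_percent,
                 max_structures = as.integer(max_structures),
                 max_loop = as.integer(max_loop),
                 energy_model = energy_model,
                 temperature = temperature),
            class = "folding_params")
}

# Simplified stacking table (kcal/mol, outer pair x inner pair; order
# AU, CG, GC, UA, GU, UG).  Values are rounded literature-like stacking
# energies; they reproduce topology-level behaviour, not Turner energies.
STACK_KCAL <- matrix(c(
  -0.9, -2.2, -2.1, -1.1, -0.6, -1.4,
  -2.1, -3.3, -2.4, -2.1, -1.4, -2.1,
  -2.4, -3.4, -3.3, -2.2, -1.5, -2.5,
  -1.3, -2.4, -2.1, -0.9, -1.0, -1.3,
  -1.3, -2.5, -2.1, -1.4, -0.5, -0.5,
  -1.0, -1.5, -1.4, -0.6, -0.3, -0.5), 6, 6, byrow = TRUE,
  dimnames = list(PAIR_OK[c(1, 3, 4, 2, 5, 6)], NULL))

hairpin_penalty <- function(s) ifelse(s < 3, Inf,
  ifelse(s == 3, 5.4, ifelse(s == 4, 5.6,
  ifelse(s == 5, 5.7, 5.7 + 1.08 * log(s / 5)))))
bulge_penalty <- function(s) ifelse(s == 1, 3.8, 2.8 + 1.08 * log(s))
interior_penalty <- function(s) 1.7 + 1.08 * log(s / 2)

## integer parameter block for the C++ kernel (energies x100)
fold_par_int <- function(n, params) {
  kc <- function(x) as.integer(round(100 * x))
  if (params$energy_model == "pair-count") {
    list(hairpin = integer(n + 1L) * 0L,
         bulge = integer(params$max_loop + 1L),
         interior = integer(params$max_loop + 1L),
         stack = matrix(0L, 6, 6),
         pair_bonus = -100L, ml_a = 0L, ml_b = 0L, ml_c = 0L,
         min_loop = params$min_loop, max_loop = params$max_loop)
  } else {
    hp <- hairpin_penalty(0:n)
    hp[!is.finite(hp)] <- 9e5
    list(hairpin = kc(pmin(hp, 9e3)),
         bulge = kc(bulge_penalty(pmax(0:params$max_loop, 1L))),
         interior = kc(interior_penalty(pmax(0:params$max_loop, 2L))),
         stack = matrix(as.integer(round(100 * STACK_KCAL)), 6, 6),
         pair_bonus = 0L, ml_a = 340L, ml_b = 40L, ml_c = 10L,
         min_loop = params$min_loop, max_loop = params$max_loop)
  }
}

#' Convert a dot-bracket string to a pair table
#' @param db dot-bracket string.
#' @return Integer vector `p` with `p[i] = j` if i pairs j, 0 if unpaired.
#' @export
db_to_pairs <- function(db) {
  check_dotbracket(db)
  ch <- strsplit(db, "")[[1L]]
  p <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j; p[j] <- i
    }
  }
  p
}

#' Convert a pair table to a dot-bracket string
#' @param pairs integer pair table as from [db_to_pairs()].
#' @return Dot-bracket string.
#' @export
pairs_to_db <- function(pairs) {
  ch <- rep(".", length(pairs))
  ch[pairs > seq_along(pairs)] <- "("
  ch[pairs > 0 & pairs < seq_along(pairs)] <- ")"
  paste(ch, collapse = "")
}

rna_codes <- function(sequence) {
  s <- chartr("T", "U", toupper(sequence))
  ch <- strsplit(s, "")[[1L]]
  if (any(!ch %in% names(BASE_CODE)))
    stop("non-IUPAC character in sequence: ", ch[!ch %in% names(BASE_CODE)][1L])
  list(rna = s, code = unname(BASE_CODE[ch]))
}

new_structure <- function(id, rna, pairs, energy, rank = 0L, flags = character(0)) {
  structure(list(id = id, seq = rna, db = pairs_to_db(pairs),
                 pairs = pairs, energy = energy, rank = rank, flags = flags),
            class = "its2_structure")
}

#' @export
print.its2_structure <- function(x, ...) {
  cat(">", x$id %||% "<unnamed>", "\n", x$seq, "\n", x$db,
      sprintf(" (%.2f)\n", x$energy), sep = "")
  invisible(x)
}

#' Validate a secondary structure object
#'
#' Checks nesting, minimum loop size, pair-alphabet validity (AU, UA, CG,
#' GC, GU, UG) and dot-bracket/pair-table consistency.
#'
#' @param x an `its2_structure`.
#' @param min_loop minimum hairpin loop size.
#' @return TRUE invisibly; error on violation.
#' @export
validate_structure <- function(x, min_loop = 3L) {
  p <- x$pairs
  ch <- strsplit(x$seq, "")[[1L]]
  stopifnot(length(p) == length(ch))
  if (pairs_to_db(p) != x$db) stop("dot-bracket inconsistent with pair table")
  idx <- which(p > seq_along(p))
  for (i in idx) {
    j <- p[i]
    if (j - i - 1L < min_loop) stop("loop below minimum size at pair ", i)
    if (!paste0(ch[i], ch[j]) %in% PAIR_OK)
      stop("invalid base pair ", ch[i], "-", ch[j], " at ", i, ",", j)
  }
  ## nesting: db_to_pairs round trip already guarantees balance
  invisible(TRUE)
}

#' Predict the minimum-free-energy secondary structure
#'
#' Dynamic-programming MFE folding under the package's simplified
#' nearest-neighbour stacking model (or a pure pair-count model).  T is
#' converted to U; folding is deterministic, with traceback ties broken
#' toward the 5'-most pairing and then toward longer helices.
#'
#' @param sequence DNA/RNA string.
#' @param params a [folding_params()] object.
#' @param id optional record id carried into the result.
#' @return An `its2_structure` with fields `seq` (RNA), `db`, `pairs`,
#'   `energy` (kcal/mol, <= 0) and `rank` (0 = MFE).
#' @export
fold_mfe <- function(sequence, params = folding_params(), id = NULL) {
  rc <- rna_codes(sequence)
  n <- length(rc$code)
  if (n < params$min_loop + 2L)
    stop("sequence shorter than min_loop + 2")
  res <- c_fold(rc$code, fold_par_int(n, params))
  new_structure(id, rc$rna, res$pair, res$energy / 100)
}

#' Enumerate suboptimal secondary structures
#'
#' Complete enumeration (Wuchty-style, over the same unambiguous folding
#' grammar as the MFE recursion) of all structures within
#' `subopt_percent` percent of the MFE energy, truncated to
#' `max_structures` after sorting by energy.  Structures have mutually
#' distinct pair sets.
#'
#' @inheritParams fold_mfe
#' @return List of `its2_structure`, energies non-decreasing, element 1
#'   an MFE structure.
#' @export
fold_suboptimal <- function(sequence, params = folding_params(), id = NULL) {
  rc <- rna_codes(sequence)
  n <- length(rc$code)
  if (n < params$min_loop + 2L)
    stop("sequence shorter than min_loop + 2")
  pint <- fold_par_int(n, params)
  mfe <- c_fold(rc$code, pint)$energy
  delta <- as.integer(floor(abs(mfe) * params$subopt_percent / 100))
  res <- c_subopt(rc$code, pint, delta,
                  max_emit = max(2000L, 40L * params$max_structures))
  if (isTRUE(res$truncated))
    log_msg("fold_suboptimal: enumeration truncated for ", id %||% "sequence")
  st <- res$structures
  if (length(st) == 0L)
    return(list(new_structure(id, rc$rna, integer(n), 0)))
  en <- vapply(st, function(s) s$energy, numeric(1))
  dbs <- vapply(st, function(s) pairs_to_db(s$pair), character(1))
  keep <- !duplicated(dbs)
  st <- st[keep]; en <- en[keep]; dbs <- dbs[keep]
  o <- order(en, dbs)
  o <- o[seq_len(min(length(o), params$max_structures))]
  lapply(seq_along(o), function(k) {
    s <- st[[o[k]]]
    new_structure(id, rc$rna, s$pair, s$energy / 100, rank = k - 1L)
  })
}

#' Select the reported structure among folding candidates
#'
#' Applies the selection rule used for ITS2: among the candidate
#' structures (sorted or not), return the lowest-energy one whose helix
#' topology shows 3 or 4 principal helices radiating from the central
#' loop (directly or via an extended subdomain).  If none qualifies the
#' MFE structure is returned carrying a `"non-canonical topology"` flag.
#'
#' @param candidates list of `its2_structure` (e.g. from
#'   [fold_suboptimal()]).
#' @param helix_range admissible number of principal helices (default
#'   `c(3, 4)`).
#' @return A single `its2_structure`.
#' @export
select_structure <- function(candidates, helix_range = c(3L, 4L)) {
  if (length(candidates) == 0L) stop("empty candidate list")
  en <- vapply(candidates, function(s) s$energy, numeric(1))
  ord <- order(en)
  for (k in ord) {
    tree <- build_helix_tree(candidates[[k]])
    nh <- sum(tree$helices$principal)
    if (nh >= helix_range[1L] && nh <= helix_range[2L])
      return(candidates[[k]])
  }
  mfe <- candidates[[ord[1L]]]
  mfe$flags <- union(mfe$flags, "non-canonical topology")
  mfe
}

#' Recompute the model energy of a given structure
#'
#' Independent loop-decomposition evaluator for a (sequence, dot-bracket)
#' pair under the package's energy model: decomposes the structure into
#' hairpin, stacked-pair, interior/bulge and multibranch loops and sums
#' their contributions.  Shares no code with the folding recursion.
#'
#' @param sequence DNA/RNA string.
#' @param db dot-bracket string of the same length.
#' @param params a [folding_params()].
#' @return Energy in kcal/mol.
#' @export
eval_structure_energy <- function(sequence, db, params = folding_params()) {
  rc <- rna_codes(sequence)
  ch <- strsplit(rc$rna, "")[[1L]]
  p <- db_to_pairs(db)
  if (length(p) != length(ch)) stop("length mismatch")
  pair_name <- function(i) paste0(ch[i], ch[p[i]])
  pc <- params$energy_model == "pair-count"
  total <- if (pc) -sum(p > seq_along(p)) else 0
  if (pc) return(total)
  rn <- rownames(STACK_KCAL)
  opens <- which(p > seq_along(p))
  for (i in opens) {
    j <- p[i]
    ## children: outermost pairs strictly inside (i,j)
    k <- i + 1L
    children <- integer(0)
    while (k < j) {
      if (p[k] > k) { children <- c(children, k); k <- p[k] + 1L }
      else k <- k + 1L
    }
    unp <- (j - i - 1L) - sum(p[children] - children + 1L)
    if (length(children) == 0L) {
      total <- total + hairpin_penalty(j - i - 1L)
    } else if (length(children) == 1L) {
      s1 <- children[1L] - i - 1L
      s2 <- j - p[children[1L]] - 1L
      if (s1 == 0L && s2 == 0L) {
        total <- total + STACK_KCAL[match(pair_name(i), rn),
                                    match(pair_name(children[1L]), rn)]
      } else if (s1 == 0L || s2 == 0L) {
        total <- total + bulge_penalty(s1 + s2)
      } else {
        total <- total + interior_penalty(s1 + s2)
      }
    } else {
      total <- total + 3.4 + 0.4 * (length(children) + 1L) + 0.1 * unp
    }
  }
  round(total, 2)
}
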