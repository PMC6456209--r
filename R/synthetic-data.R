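## Seeded generators: ITS2-like sequences with planted secondary
## structures and mutation events (CBC / hemi-CBC / unpaired substitution
## / INDEL), and host x segment community sampling tables.  Every
## downstream stage of the pipeline is testable against the planted
## truth these return.

## conserved rDNA flank proxies shared with the extractor defaults
FLANK_5P_DEFAULT <- MOTIF_5P_DEFAULT
FLANK_3P_DEFAULT <- MOTIF_3P_DEFAULT

#' ITS2 structure template
#'
#' Defines the planted fold: an ordered set of helices (stem length in
#' bp, apical loop length in nt) radiating from a central loop, spacer
#' lengths between them, and conserved 5'/3' flank motifs standing in
#' for the adjacent 5.8S/28S rDNA.  Helix III (the third) carries the
#' TGGC (UGGC on RNA) motif at the base of its 5' strand.  Defaults give
#' a three-helix fold of ~152 nt, within the 145-181 nt range typical of
#' fungal ITS2.
#'
#' @param stems integer vector of stem lengths (bp), one per helix
#'   (each >= 2).
#' @param loops apical loop lengths (nt, each >= 3).
#' @param spacers unpaired spacer lengths: length(stems) + 1 values
#'   (before helix 1, between helices, after the last).
#' @param flank_5p,flank_3p conserved flank motif strings.
#' @return List of class `structure_template`.
#' @export
structure_template <- function(stems = c(13L, 17L, 25L),
                               loops = c(5L, 6L, 8L),
                               spacers = c(6L, 5L, 5L, 7L),
                               flank_5p = FLANK_5P_DEFAULT,
                               flank_3p = FLANK_3P_DEFAULT) {
  stopifnot(length(loops) == length(stems),
            length(spacers) == length(stems) + 1L,
            all(stems >= 2L), all(loops >= 3L), all(spacers >= 0L))
  total <- sum(2L * stems + loops) + sum(spacers)
  out <- list(stems = as.integer(stems), loops = as.integer(loops),
              spacers = as.integer(spacers), flank_5p = toupper(flank_5p),
              flank_3p = toupper(flank_3p), its2_length = total)
  class(out) <- "structure_template"
  out
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

## instantiate the ancestral ITS2: characters (DNA), pairing table,
## per-position annotation (helix index, role)
instantiate_template <- function(tpl) {
  nh <- length(tpl$stems)
  chars <- character(0); helix <- integer(0); role <- character(0)
  pair <- integer(0)
  rnd <- function(n, gc) {
    if (n == 0L) return(character(0))
    sample(c("G", "C", "A", "T"), n, replace = TRUE,
           prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
  }
  ## loops and spacers use an A/C-only alphabet: no two of {A,C} form a
  ## canonical or wobble pair, so the planted stems are the only
  ## favourable pairings and the template is the MFE structure
  rnd_unpaired <- function(n) {
    if (n == 0L) return(character(0))
    sample(c("A", "C"), n, replace = TRUE, prob = c(0.65, 0.35))
  }
  add <- function(ch, hx, rl) {
    chars <<- c(chars, ch)
    helix <<- c(helix, rep(hx, length(ch)))
    role <<- c(role, rep(rl, length(ch)))
    pair <<- c(pair, integer(length(ch)))
  }
  add(rnd_unpaired(tpl$spacers[1L]), 0L, "spacer")
  for (h in seq_len(nh)) {
    st <- tpl$stems[h]
    five <- rnd(st, 0.75)
    if (h == 3L && st >= 6L) five[1:4] <- c("T", "G", "G", "C")
    start5 <- length(chars) + 1L
    add(five, h, "stem5")
    add(rnd_unpaired(tpl$loops[h]), h, "loop")
    start3 <- length(chars) + 1L
    add(unname(COMPLEMENT[rev(five)]), h, "stem3")
    for (t in seq_len(st)) {
      i <- start5 + t - 1L
      j <- start3 + st - t
      pair[i] <- j; pair[j] <- i
    }
    add(rnd_unpaired(tpl$spacers[h + 1L]), 0L, "spacer")
  }
  list(chars = chars, pair = pair, helix = helix, role = role)
}

## stem pair slots eligible for planted mutations: >= 2 pairs from both
## helix ends; helix III base pairs 1-5 reserved for the TGGC motif
eligible_slots <- function(tpl, inst) {
  slots <- list()
  for (h in seq_along(tpl$stems)) {
    st <- tpl$stems[h]
    lo <- if (h == 3L) 6L else 3L
    hi <- st - 2L
    if (hi < lo) next
    i5 <- which(inst$helix == h & inst$role == "stem5")
    for (t in lo:hi)
      slots[[length(slots) + 1L]] <- c(i5[t], inst$pair[i5[t]])
  }
  slots
}

CANONICAL <- c("AT", "TA", "GC", "CG", "GT", "TG")

cbc_variant <- function(b5, b3) {
  cand <- CANONICAL[substr(CANONICAL, 1, 1) != b5 &
                    substr(CANONICAL, 2, 2) != b3]
  cand[sample.int(length(cand), 1L)]
}

hemi_variant <- function(b5, b3) {
  cand <- CANONICAL[xor(substr(CANONICAL, 1, 1) != b5,
                        substr(CANONICAL, 2, 2) != b3)]
  cand[sample.int(length(cand), 1L)]
}

#' Generate an ITS2-like species set with planted truth
#'
#' Builds an ancestral sequence from the template, then derives
#' `n_species` species by planting `cbc_between` compensatory base
#' changes per species at disjoint stem slots (so every between-species
#' pair carries at least `cbc_between` CBCs and conspecific pairs carry
#' none), and `n_per_species` individuals per species differing by
#' planted hemi-CBCs, unpaired substitutions and INDELs only.  Flank
#' motifs are attached so the records resemble ITS with conserved
#' 5.8S/28S borders.  Deterministic under `seed`.
#'
#' @param template a [structure_template()].
#' @param n_species number of species (>= 1).
#' @param n_per_species individuals per species.
#' @param cbc_between planted CBCs distinguishing each species (>= 1
#'   when `n_species > 1`).
#' @param hemicbc_within planted hemi-CBCs per non-founder individual.
#' @param sub_within planted unpaired substitutions per non-founder
#'   individual.
#' @param indel_rate per-site INDEL probability at unpaired ITS2
#'   positions of non-founder individuals.
#' @param seed integer seed.
#' @return List with `seqs` (a [sequence_set()] of full flank+ITS2+flank
#'   records) and `truth`: species assignment, per-record ITS2 sequence,
#'   dot-bracket and 1-based span, and planted per-pair count matrices
#'   (`cbc`, `hemi`, `sub`, `indel`).
#' @export
generate_species_set <- function(template = structure_template(),
                                 n_species = 3L, n_per_species = 2L,
                                 cbc_between = 2L, hemicbc_within = 0L,
                                 sub_within = 0L, indel_rate = 0,
                                 seed = 1L) {
  stopifnot(n_species >= 1L, n_per_species >= 1L)
  if (n_species > 1L && cbc_between < 1L)
    stop("cbc_between must be >= 1 when n_species > 1")
  with_seed(seed, {
    inst <- instantiate_template(template)
    slots <- eligible_slots(template, inst)
    n_ind <- n_species * n_per_species
    need <- n_species * cbc_between +
      n_species * max(n_per_species - 1L, 0L) * hemicbc_within
    if (need > length(slots))
      stop("template stems too short to host the requested planted events")
    slot_order <- sample.int(length(slots))
    next_slot <- 0L
    take_slots <- function(k) {
      if (k == 0L) return(integer(0))
      idx <- slot_order[next_slot + seq_len(k)]
      next_slot <<- next_slot + k
      idx
    }
    unpaired_pos <- which(inst$pair == 0L)
    sub_order <- sample(unpaired_pos)
    next_sub <- 0L
    take_subs <- function(k) {
      if (k == 0L) return(integer(0))
      idx <- sub_order[next_sub + seq_len(k)]
      next_sub <<- next_sub + k
      idx
    }
    ids <- character(0); species <- character(0)
    its2 <- character(0); dbs <- character(0)
    n_sub <- integer(0); n_indel <- integer(0); n_hemi <- integer(0)
    for (sp in seq_len(n_species)) {
      sp_chars <- inst$chars
      for (sl in take_slots(cbc_between)) {
        ij <- slots[[sl]]
        v <- cbc_variant(sp_chars[ij[1L]], sp_chars[ij[2L]])
        sp_chars[ij[1L]] <- substr(v, 1, 1)
        sp_chars[ij[2L]] <- substr(v, 2, 2)
      }
      for (m in seq_len(n_per_species)) {
        ch <- sp_chars
        pr <- inst$pair
        hemi_m <- 0L; sub_m <- 0L; indel_m <- 0L
        if (m > 1L) {
          for (sl in take_slots(hemicbc_within)) {
            ij <- slots[[sl]]
            v <- hemi_variant(ch[ij[1L]], ch[ij[2L]])
            ch[ij[1L]] <- substr(v, 1, 1)
            ch[ij[2L]] <- substr(v, 2, 2)
            hemi_m <- hemi_m + 1L
          }
          for (ps in take_subs(sub_within)) {
            ch[ps] <- sample(setdiff(c("A", "C", "G", "T"), ch[ps]), 1L)
            sub_m <- sub_m + 1L
          }
        }
        keep <- rep(TRUE, length(ch))
        ins_after <- rep(0L, length(ch))
        if (m > 1L && indel_rate > 0) {
          for (ps in which(pr == 0L)) {
            if (runif(1) < indel_rate) {
              if (runif(1) < 0.5) keep[ps] <- FALSE
              else ins_after[ps] <- 1L
              indel_m <- indel_m + 1L
            }
          }
        }
        ## apply indels
        out_ch <- character(0); out_st <- character(0)
        st <- ifelse(pr == 0L, ".", ifelse(pr > seq_along(pr), "(", ")"))
        for (ps in seq_along(ch)) {
          if (keep[ps]) { out_ch <- c(out_ch, ch[ps]); out_st <- c(out_st, st[ps]) }
          if (ins_after[ps] > 0L) {
            out_ch <- c(out_ch, sample(c("A", "T", "C", "G"), 1L,
                                       prob = c(.35, .35, .15, .15)))
            out_st <- c(out_st, ".")
          }
        }
        id <- sprintf("S%02d_%02d", sp, m)
        ids <- c(ids, id)
        species <- c(species, sprintf("species%02d", sp))
        its2 <- c(its2, paste(out_ch, collapse = ""))
        dbs <- c(dbs, paste(out_st, collapse = ""))
        n_hemi <- c(n_hemi, hemi_m); n_sub <- c(n_sub, sub_m)
        n_indel <- c(n_indel, indel_m)
      }
    }
    full <- paste0(template$flank_5p, its2, template$flank_3p)
    span <- cbind(start = nchar(template$flank_5p) + 1L,
                  end = nchar(template$flank_5p) + nchar(its2))
    rownames(span) <- ids
    ## planted per-pair truth: disjoint slots make pair counts additive
    mk <- function(per_ind, between = NULL) {
      M <- matrix(0L, n_ind, n_ind, dimnames = list(ids, ids))
      for (i in 1:(n_ind - 1)) for (j in (i + 1):n_ind) {
        v <- per_ind[i] + per_ind[j]
        if (!is.null(between) && species[i] != species[j])
          v <- v + between
        M[i, j] <- M[j, i] <- v
      }
      storage.mode(M) <- "integer"
      M
    }
    cbcM <- matrix(0L, n_ind, n_ind, dimnames = list(ids, ids))
    for (i in 1:(n_ind - 1)) for (j in (i + 1):n_ind)
      if (species[i] != species[j])
        cbcM[i, j] <- cbcM[j, i] <- 2L * cbc_between
    storage.mode(cbcM) <- "integer"
    truth <- list(species = setNames(species, ids),
                  its2 = setNames(its2, ids),
                  db = setNames(dbs, ids),
                  span = span,
                  planted = list(cbc = cbcM,
                                 cbc_min_between = cbc_between,
                                 hemi = mk(n_hemi),
                                 sub = mk(n_sub),
                                 indel = mk(n_indel)))
    list(seqs = sequence_set(ids, full,
                             desc = paste("synthetic", species)),
         truth = truth)
  })
}

#' Generate a host x segment community table
#'
#' Each host contributes `segments_per_host` leaf segments split evenly
#' over sampling events and the two leaf regions (midrib/lamina).  A
#' segment is infected with probability `infection_prob` (recycled over
#' hosts) and an infected segment yields one isolate.  Species labels
#' follow a sequential urn scheme whose expected richness obeys
#' Fisher's log-series relation E[S] = alpha ln(1 + N/alpha), with at
#' most `species_pool` distinct species per host.  Deterministic under
#' `seed`.
#'
#' @param n_hosts number of host plants.
#' @param segments_per_host segments screened per host.
#' @param infection_prob per-segment infection probability (scalar or
#'   one per host, in [0,1]).
#' @param alpha log-series alpha per host (scalar or vector).
#' @param species_pool maximum distinct species per host (> 0 whenever
#'   infection can occur).
#' @param events number of sampling events (default 2).
#' @param seed integer seed.
#' @return A [community_table()] (possibly with zero rows).
#' @export
generate_community <- function(n_hosts = 3L, segments_per_host = 300L,
                               infection_prob = 0.3, alpha = 10,
                               species_pool = 50L, events = 2L, seed = 1L) {
  if (any(infection_prob < 0) || any(infection_prob > 1))
    stop("infection_prob must be in [0, 1]")
  if (species_pool == 0L && any(infection_prob > 0))
    stop("species_pool = 0 with positive infection probability")
  infection_prob <- rep_len(infection_prob, n_hosts)
  alpha <- rep_len(alpha, n_hosts)
  with_seed(seed, {
    rows <- list()
    for (h in seq_len(n_hosts)) {
      host <- sprintf("host%02d", h)
      cells <- expand.grid(event = seq_len(events),
                           region = c("midrib", "lamina"),
                           stringsAsFactors = FALSE)
      per_cell <- segments_per_host %/% nrow(cells)
      labels <- character(0)  # species of isolates drawn so far (urn)
      for (ci in seq_len(nrow(cells))) {
        inf <- runif(per_cell) < infection_prob[h]
        for (sg in which(inf)) {
          i <- length(labels) + 1L
          new_sp <- runif(1) < alpha[h] / (alpha[h] + i - 1)
          n_seen <- length(unique(labels))
          sp <- if ((new_sp && n_seen < species_pool) || n_seen == 0L)
            sprintf("sp%03d", n_seen + 1L)
          else sample(labels, 1L)
          labels <- c(labels, sp)
          rows[[length(rows) + 1L]] <- data.frame(
            species = sp, host = host, region = cells$region[ci],
            event = cells$event[ci],
            segment = sprintf("%s_e%d_%s_%03d", host, cells$event[ci],
                              cells$region[ci], sg),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows) == 0L) {
      out <- data.frame(species = character(0), host = character(0),
                        region = character(0), event = integer(0),
                        segment = character(0), stringsAsFactors = FALSE)
      class(out) <- c("community_table", "data.frame")
      return(out)
    }
    community_table(do.call(rbind, rows))
  })
}
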