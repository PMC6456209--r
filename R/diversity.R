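## Diversity statistics for endophyte community tables: colonization
## frequency, endophytic infection rate, relative percentage occurrence,
## Shannon, unbiased inverse Simpson, Fisher's log-series alpha, Chao1,
## ACE, shared-species and similarity indices, and sample-based
## accumulation curves.

#' Build/validate a community table
#'
#' One row per isolate with species label, host, leaf region
#' (midrib/lamina), sampling event and segment id.  Segment ids must be
#' unique within host x event x region.
#'
#' @param x data frame with columns `species`, `host`, `region`,
#'   `event`, `segment` (extra columns kept).
#' @return The validated data frame with class `community_table`.
#' @export
community_table <- function(x) {
  need <- c("species", "host", "region", "event", "segment")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(x$region %in% c("midrib", "lamina")))
    stop("region must be 'midrib' or 'lamina'")
  class(x) <- c("community_table", "data.frame")
  x
}

#' Read a community table from TSV
#' @param path TSV path with a header row.
#' @return A [community_table()].
#' @export
read_community <- function(path) {
  community_table(read.delim(path, stringsAsFactors = FALSE))
}

#' Abundance vector of a community (or one host's community)
#' @param ct a [community_table()].
#' @param host optional host filter.
#' @return Named integer vector of isolates per species.
#' @export
abundance_vector <- function(ct, host = NULL) {
  if (!is.null(host)) ct <- ct[ct$host == host, , drop = FALSE]
  tab <- table(ct$species)
  setNames(as.integer(tab), names(tab))
}

#' Colonization frequency (CF)
#'
#' Isolates recovered per 100 screened segments.
#'
#' @param n_isolates isolate count.
#' @param n_segments segments screened (> 0).
#' @return Percentage, rounded to 1 decimal.
#' @export
colonization_frequency <- function(n_isolates, n_segments) {
  if (any(n_segments <= 0)) stop("n_segments must be > 0")
  round(100 * n_isolates / n_segments, 1)
}

#' Endophytic infection rate (EIR)
#'
#' Infected segments per 100 screened segments.
#'
#' @param n_infected infected segment count.
#' @param n_segments segments screened.
#' @return Percentage, rounded to 1 decimal.
#' @export
endophytic_infection_rate <- function(n_infected, n_segments) {
  if (any(n_segments <= 0)) stop("n_segments must be > 0")
  if (any(n_infected > n_segments))
    stop("infected segments exceed screened segments")
  round(100 * n_infected / n_segments, 1)
}

#' Relative percentage of occurrence (RPO)
#'
#' One group's colonization density as a percentage of total density.
#'
#' @param group_density colonization density of the group.
#' @param total_density total colonization density (> 0, >= group).
#' @return Percentage.
#' @export
relative_percentage_occurrence <- function(group_density, total_density) {
  if (any(total_density <= 0)) stop("total_density must be > 0")
  if (any(group_density > total_density))
    stop("group density exceeds total")
  100 * group_density / total_density
}

#' Shannon diversity index (natural log)
#' @param abundances positive count vector (zeros dropped).
#' @return H' in nats.
#' @export
shannon <- function(abundances) {
  x <- abundances[abundances > 0]
  if (length(x) == 0L) stop("no positive abundances")
  p <- x / sum(x)
  -sum(p * log(p))
}

#' Inverse Simpson index (unbiased finite-sample form)
#'
#' 1/D with D = sum n_i (n_i - 1) / (N (N - 1)); the plug-in
#' 1 / sum p_i^2 version is available with `unbiased = FALSE`.
#'
#' @param abundances count vector with total N >= 2.
#' @param unbiased use the finite-sample form (default TRUE).
#' @return Inverse Simpson index (>= 1).
#' @export
simpson_inverse <- function(abundances, unbiased = TRUE) {
  x <- abundances[abundances > 0]
  N <- sum(x)
  if (N < 2) stop("need at least 2 isolates")
  D <- if (unbiased) sum(x * (x - 1)) / (N * (N - 1)) else sum((x / N)^2)
  if (D == 0) Inf else 1 / D
}

#' Fisher's log-series alpha
#'
#' Solves S = alpha ln(1 + N/alpha) for alpha by bracketed root-finding
#' (tolerance 1e-8).
#'
#' @param S observed species count (1 <= S < N).
#' @param N total isolate count.
#' @return alpha.
#' @export
fisher_alpha <- function(S, N) {
  if (S < 1) stop("S must be >= 1")
  if (S >= N) stop("alpha diverges as S approaches N")
  f <- function(a) a * log(1 + N / a) - S
  lo <- 1e-8
  hi <- 2
  while (f(hi) < 0) hi <- hi * 2
  uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' Expected species count of a log-series community
#' @param alpha Fisher's alpha.
#' @param N isolate count.
#' @return Expected S = alpha ln(1 + N/alpha).
#' @export
fisher_expected_s <- function(alpha, N) alpha * log(1 + N / alpha)

#' Chao1 species-richness estimate
#'
#' Bias-corrected form (default): S_obs + F1 (F1 - 1) / (2 (F2 + 1)).
#' The classic form S_obs + F1^2 / (2 F2) is available with
#' `bias_corrected = FALSE` (it falls back to the corrected form when
#' F2 = 0).
#'
#' @param abundances count vector.
#' @param bias_corrected logical, default TRUE.
#' @return Chao1 estimate (>= S_obs).
#' @export
chao1 <- function(abundances, bias_corrected = TRUE) {
  x <- abundances[abundances > 0]
  S <- length(x)
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  if (bias_corrected || f2 == 0) S + f1 * (f1 - 1) / (2 * (f2 + 1))
  else S + f1^2 / (2 * f2)
}

#' ACE species-richness estimate
#'
#' Abundance-based coverage estimator with rare cutoff `rare_cutoff`
#' (default 10): S_abund + S_rare / C_ACE + (F1 / C_ACE) gamma^2, with
#' sample coverage C_ACE = 1 - F1 / N_rare and squared coefficient of
#' variation gamma^2 of the rare class.  Falls back to [chao1()] when
#' C_ACE = 0 (e.g. an all-singleton sample).
#'
#' @param abundances count vector.
#' @param rare_cutoff rare-class abundance threshold (default 10).
#' @return ACE estimate (>= S_obs).
#' @export
ace <- function(abundances, rare_cutoff = 10) {
  x <- abundances[abundances > 0]
  rare <- x[x <= rare_cutoff]
  s_abund <- sum(x > rare_cutoff)
  s_rare <- length(rare)
  if (s_rare == 0L) return(length(x))
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) return(chao1(abundances))
  fk <- vapply(seq_len(rare_cutoff), function(k) sum(rare == k), numeric(1))
  gamma2 <- max(s_rare / c_ace *
                  sum(seq_len(rare_cutoff) * (seq_len(rare_cutoff) - 1) * fk) /
                  (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' Shared-species and similarity indices of two communities
#'
#' Incidence-based Jaccard C / (S1 + S2 - C); Bray-Curtis similarity
#' 2 sum min(n_i, m_i) / (N1 + N2); the abundance-based Chao-Jaccard
#' index U V / (U + V - U V) with the coverage-adjusted U and V of the
#' Chao et al. (2005) estimator; and a Chao-type shared-species richness
#' estimate correcting the observed shared count with the
#' singleton/doubleton structure of the shared species
#' (bias-corrected denominators).
#'
#' @param a,b named abundance vectors (shared species matched by name).
#' @return List: `shared`, `chao_shared`, `jaccard`, `chao_jaccard`,
#'   `bray_curtis`.
#' @export
shared_indices <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b)))
    stop("abundance vectors must be named by species")
  if (anyDuplicated(names(a)) || anyDuplicated(names(b)))
    stop("duplicate species labels")
  a <- a[a > 0]; b <- b[b > 0]
  s1 <- length(a); s2 <- length(b)
  shared <- intersect(names(a), names(b))
  C <- length(shared)
  jac <- if (s1 + s2 - C > 0) C / (s1 + s2 - C) else 0
  all_sp <- union(names(a), names(b))
  av <- setNames(rep(0, length(all_sp)), all_sp); av[names(a)] <- a
  bv <- setNames(rep(0, length(all_sp)), all_sp); bv[names(b)] <- b
  bc <- if (sum(av) + sum(bv) > 0)
    2 * sum(pmin(av, bv)) / (sum(av) + sum(bv)) else 0
  ## Chao-Jaccard (abundance-based, Chao et al. 2005)
  n <- sum(a); m <- sum(b)
  xs <- av[shared]; ys <- bv[shared]
  if (C == 0L) {
    cj <- 0; chao_sh <- 0
  } else {
    f1p <- sum(ys == 1); f2p <- sum(ys == 2)
    fp1 <- sum(xs == 1); fp2 <- sum(xs == 2)
    ## published convention: doubleton count 0 is replaced by 1
    U <- sum(xs / n) + (m - 1) / m * f1p / (2 * max(f2p, 1)) *
      sum(xs[ys == 1] / n)
    V <- sum(ys / m) + (n - 1) / n * fp1 / (2 * max(fp2, 1)) *
      sum(ys[xs == 1] / m)
    U <- min(U, 1); V <- min(V, 1)
    cj <- if (U + V - U * V > 0) U * V / (U + V - U * V) else 0
    ## Chao-type shared richness (bias-corrected denominators)
    f11 <- sum(xs == 1 & ys == 1)
    chao_sh <- C + fp1 * (fp1 - 1) / (2 * (fp2 + 1)) +
      f1p * (f1p - 1) / (2 * (f2p + 1)) +
      fp1 * f1p * f11 / (4 * (fp2 + 1) * (f2p + 1))
  }
  list(shared = C, chao_shared = chao_sh, jaccard = jac,
       chao_jaccard = cj, bray_curtis = bc)
}

#' Sample-based species accumulation curve
#'
#' Mean species count over `resamples` random orderings of the samples
#' (rows of the incidence matrix), with the resampling SD; deterministic
#' under `seed`.  The endpoint equals the total observed richness.
#'
#' @param incidence sample x species incidence (or abundance) matrix.
#' @param resamples number of random orderings (default 100).
#' @param seed integer seed.
#' @return Data frame of class `accumulation_curve`: `samples`,
#'   `mean_species`, `sd_species`.
#' @export
accumulation_curve <- function(incidence, resamples = 100L, seed = 1L) {
  inc <- as.matrix(incidence) > 0
  ns <- nrow(inc)
  if (ns < 1L) stop("need at least one sample")
  set.seed(seed)
  acc <- matrix(0, resamples, ns)
  for (r in seq_len(resamples)) {
    ord <- sample.int(ns)
    seen <- rep(FALSE, ncol(inc))
    for (k in seq_len(ns)) {
      seen <- seen | inc[ord[k], ]
      acc[r, k] <- sum(seen)
    }
  }
  out <- data.frame(samples = seq_len(ns),
                    mean_species = colMeans(acc),
                    sd_species = apply(acc, 2L, sd))
  class(out) <- c("accumulation_curve", "data.frame")
  out
}

#' Per-host diversity report
#'
#' Mirrors the standard endophyte-survey summary: isolates, observed
#' species, Shannon H', inverse Simpson, Fisher's alpha, Chao1 and ACE
#' per host, plus CF and EIR when segment bookkeeping is supplied.
#'
#' @param ct a [community_table()].
#' @param segments optional data frame with columns `host`,
#'   `n_segments`, `n_infected` (totals per host).
#' @return Data frame, one row per host.
#' @export
diversity_report <- function(ct, segments = NULL) {
  hosts <- unique(ct$host)
  rows <- lapply(hosts, function(h) {
    ab <- abundance_vector(ct, h)
    N <- sum(ab)
    data.frame(host = h, isolates = N, s_obs = length(ab),
               shannon = round(shannon(ab), 2),
               simpson_inverse = if (N >= 2) round(simpson_inverse(ab), 2) else NA,
               fisher_alpha = if (length(ab) < N)
                 round(fisher_alpha(length(ab), N), 2) else NA,
               chao1 = round(chao1(ab), 2),
               ace = round(ace(ab), 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(segments)) {
    m <- match(out$host, segments$host)
    out$cf <- colonization_frequency(out$isolates, segments$n_segments[m])
    out$eir <- endophytic_infection_rate(segments$n_infected[m],
                                         segments$n_segments[m])
  }
  out
}

#' Pairwise shared-species report across hosts
#' @param ct a [community_table()].
#' @return Data frame, one row per host pair, with the
#'   [shared_indices()] columns.
#' @export
shared_report <- function(ct) {
  hosts <- unique(ct$host)
  if (length(hosts) < 2L) stop("need >= 2 hosts")
  pairs <- combn(hosts, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    si <- shared_indices(abundance_vector(ct, pairs[1L, k]),
                         abundance_vector(ct, pairs[2L, k]))
    data.frame(host1 = pairs[1L, k], host2 = pairs[2L, k],
               shared = si$shared,
               chao_shared = round(si$chao_shared, 2),
               jaccard = round(si$jaccard, 3),
               chao_jaccard = round(si$chao_jaccard, 3),
               bray_curtis = round(si$bray_curtis, 3),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Midrib vs lamina fold-excess of isolate counts
#'
#' (midrib - lamina) / lamina per host.
#'
#' @param ct a [community_table()].
#' @return Named numeric vector per host, rounded to 2 decimals.
#' @export
midrib_fold_excess <- function(ct) {
  hosts <- unique(ct$host)
  out <- vapply(hosts, function(h) {
    mid <- sum(ct$host == h & ct$region == "midrib")
    lam <- sum(ct$host == h & ct$region == "lamina")
    if (lam == 0) return(NA_real_)
    round((mid - lam) / lam, 2)
  }, numeric(1))
  setNames(out, hosts)
}
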