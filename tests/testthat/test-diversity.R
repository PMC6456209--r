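sampling <- read.delim(system.file("extdata", "endophyte_sampling.tsv",
                                   package = "its2morph"))
richness <- read.delim(system.file("extdata", "endophyte_richness.tsv",
                                   package = "its2morph"))

test_that("colonization frequency reproduces the survey percentages", {
  expect_equal(colonization_frequency(221, 300), 73.7)
  expect_equal(colonization_frequency(66, 300), 22.0)
  expect_equal(colonization_frequency(105, 300), 35.0)
  expect_equal(colonization_frequency(0, 300), 0.0)
  expect_error(colonization_frequency(10, 0), "> 0")
})

test_that("infection rate follows from the sampling-table sums", {
  inf <- tapply(sampling$infected, sampling$host, sum)
  seg <- tapply(sampling$segments, sampling$host, sum)
  expect_equal(as.vector(seg), c(300, 300, 300))
  expect_equal(endophytic_infection_rate(inf[["Aglaia elaeagnoidea"]], 300),
               21.3)
  expect_equal(endophytic_infection_rate(inf[["Flacourtia inermis"]], 300),
               30.7)
  ## the third host computes to 66.3 from these inputs (199/300); the
  ## implementation reports what the inputs give
  expect_equal(endophytic_infection_rate(inf[["Premna serratifolia"]], 300),
               66.3)
  expect_equal(endophytic_infection_rate(300, 300), 100.0)
  expect_error(endophytic_infection_rate(301, 300), "exceed")
})

test_that("RPO is conservative: group percentages sum to 100", {
  expect_equal(relative_percentage_occurrence(5, 20), 25)
  expect_equal(relative_percentage_occurrence(20, 20), 100)
  set.seed(1)
  g <- rpois(7, 12) + 1
  rpo <- relative_percentage_occurrence(g, sum(g))
  expect_lt(abs(sum(rpo) - 100), 0.1)
  expect_error(relative_percentage_occurrence(5, 0), "> 0")
})

test_that("Shannon index: uniform, single-species and bound cases", {
  expect_equal(shannon(c(1, 1, 1, 1)), log(4))
  expect_equal(shannon(5), 0)
  expect_error(shannon(c(0, 0)), "positive")
  set.seed(2)
  for (k in 1:20) {
    ab <- rpois(sample(2:30, 1), 5) + 1
    h <- shannon(ab)
    expect_gte(h, 0)
    expect_lte(h, log(length(ab)) + 1e-12)
  }
})

test_that("inverse Simpson uses the unbiased finite-sample form", {
  expect_equal(simpson_inverse(c(10, 10)), 1 / (2 * 90 / 380))
  expect_equal(simpson_inverse(7), 1)
  expect_error(simpson_inverse(1), "at least 2")
  ## equal-abundance limit approaches S from below
  expect_lt(simpson_inverse(rep(1000, 5)) - 5, 0.01)
  ## plug-in flag
  expect_equal(simpson_inverse(c(10, 10), unbiased = FALSE), 2)
})

test_that("Fisher's alpha reproduces the survey table and inverts", {
  expect_equal(round(fisher_alpha(21, 66), 2), 10.63)
  expect_equal(round(fisher_alpha(20, 105), 2), 7.33)
  expect_equal(round(fisher_alpha(23, 221), 2), 6.46)
  expect_error(fisher_alpha(10, 10), "diverges")
  expect_error(fisher_alpha(0, 10), ">= 1")
  ## round-trip alpha -> E[S] -> alpha
  for (alpha in c(0.5, 3, 10.63, 40)) {
    S <- fisher_expected_s(alpha, 500)
    expect_lt(abs(fisher_alpha(S, 500) - alpha), 1e-6)
  }
  ## independent solver agreement
  skip_if_not_installed("vegan")
  set.seed(3)
  ab <- rpois(25, 3) + 1
  expect_lt(abs(fisher_alpha(length(ab), sum(ab)) -
                  vegan::fisher.alpha(ab)), 0.02)
})

test_that("Chao1 matches its formula and its estimator bounds", {
  expect_equal(chao1(c(5, 4, 3, 3, 2)), 5)            # no singletons
  expect_equal(chao1(c(3, 3, 1, 1, 2)), 5.5)          # S=5, F1=2, F2=1
  expect_equal(chao1(c(1, 1, 2, 5), bias_corrected = FALSE),
               4 + 4 / (2 * 1))
  set.seed(4)
  for (k in 1:30) {
    ab <- rpois(sample(3:40, 1), 2) + 1
    expect_gte(chao1(ab), length(ab))
  }
})

test_that("ACE covers its regular, degenerate and fallback paths", {
  expect_equal(ace(c(20, 30, 15)), 3)                  # no rare class
  expect_equal(ace(rep(1, 6)), chao1(rep(1, 6)))       # C_ACE = 0 fallback
  set.seed(5)
  for (k in 1:30) {
    ab <- c(rpois(sample(3:30, 1), 2) + 1, sample(12:60, 3))
    expect_gte(ace(ab) + 1e-9, length(ab))
  }
  skip_if_not_installed("vegan")
  ab <- c(1, 1, 1, 2, 2, 3, 4, 4, 5, 7, 9, 14, 22)
  est <- vegan::estimateR(ab)
  expect_equal(ace(ab), unname(est["S.ACE"]), tolerance = 1e-6)
  expect_equal(chao1(ab), unname(est["S.chao1"]), tolerance = 1e-6)
})

test_that("shared-species indices match the survey table and their bounds", {
  sh <- richness$species
  shared <- c(6, 8, 6)
  jac <- c(shared[1] / (sh[1] + sh[2] - shared[1]),
           shared[2] / (sh[1] + sh[3] - shared[2]),
           shared[3] / (sh[2] + sh[3] - shared[3]))
  expect_equal(round(jac, 3), c(0.171, 0.222, 0.162))

  a <- c(x = 5, y = 3, z = 2)
  same <- shared_indices(a, a)
  expect_equal(same$jaccard, 1)
  expect_equal(same$bray_curtis, 1)
  expect_equal(same$shared, 3)
  disj <- shared_indices(a, c(q = 4, r = 1))
  expect_equal(disj$jaccard, 0)
  expect_equal(disj$chao_jaccard, 0)
  expect_equal(disj$bray_curtis, 0)
  expect_error(shared_indices(unname(a), a), "named")

  set.seed(6)
  for (k in 1:20) {
    na <- sample(3:12, 1); nb <- sample(3:12, 1)
    av <- setNames(rpois(na, 3) + 1, sample(letters, na))
    bv <- setNames(rpois(nb, 3) + 1, sample(letters, nb))
    si <- shared_indices(av, bv)
    expect_true(si$jaccard >= 0 && si$jaccard <= 1)
    expect_true(si$chao_jaccard >= 0 && si$chao_jaccard <= 1)
    expect_true(si$bray_curtis >= 0 && si$bray_curtis <= 1)
    expect_gte(si$chao_shared, si$shared)
  }
})

test_that("Chao-Jaccard agrees with the vegan abundance-based form", {
  skip_if_not_installed("vegan")
  set.seed(7)
  for (k in 1:10) {
    sp <- paste0("s", 1:12)
    av <- setNames(rpois(12, 4), sp); av[av == 0] <- 1
    bv <- setNames(rpois(12, 4), sp)
    bv[sample(12, 4)] <- 0
    keep_b <- bv > 0
    si <- shared_indices(av, bv[keep_b])
    M <- rbind(av, c(bv))
    d <- as.numeric(vegan::vegdist(M, method = "chao"))
    expect_equal(si$chao_jaccard, 1 - d, tolerance = 1e-8)
  }
})

test_that("accumulation curves are monotone with the right endpoint", {
  inc <- matrix(c(1, 0, 0, 1, 1, 0, 0, 1, 1, 1, 0, 1), 4, 3, byrow = TRUE)
  ac <- accumulation_curve(inc, resamples = 50, seed = 2)
  expect_equal(nrow(ac), 4L)
  expect_false(is.unsorted(ac$mean_species))
  expect_equal(ac$mean_species[4], 3)

  single <- accumulation_curve(matrix(c(1, 1, 0), 1, 3), seed = 1)
  expect_equal(nrow(single), 1L)
  expect_equal(single$mean_species, 2)

  flat <- accumulation_curve(matrix(1, 5, 4), seed = 1)
  expect_true(all(flat$mean_species == 4))
  expect_identical(accumulation_curve(inc, resamples = 20, seed = 9),
                   accumulation_curve(inc, resamples = 20, seed = 9))
})

test_that("midrib fold-excess reproduces the survey contrasts", {
  ## expand the sampling table into one row per isolate
  rows <- sampling[rep(seq_len(nrow(sampling)), sampling$isolates), ]
  ct <- community_table(data.frame(species = "unknown", host = rows$host,
                                   region = rows$region, event = rows$event,
                                   segment = seq_len(nrow(rows))))
  fe <- midrib_fold_excess(ct)
  expect_equal(unname(fe[c("Aglaia elaeagnoidea", "Flacourtia inermis",
                           "Premna serratifolia")]),
               c(0.64, 1.00, 0.43))
})

test_that("reports assemble per-host and pairwise tables", {
  ct <- generate_community(n_hosts = 3, segments_per_host = 200,
                           infection_prob = 0.4, alpha = 8,
                           species_pool = 40, seed = 30)
  segs <- data.frame(host = unique(ct$host), n_segments = 200,
                     n_infected = as.numeric(table(ct$host)[unique(ct$host)]))
  rep1 <- diversity_report(ct, segs)
  expect_equal(nrow(rep1), 3L)
  expect_true(all(c("shannon", "chao1", "ace", "cf", "eir") %in% names(rep1)))
  expect_true(all(rep1$chao1 >= rep1$s_obs))
  rep2 <- shared_report(ct)
  expect_equal(nrow(rep2), 3L)
  expect_true(all(rep2$jaccard >= 0 & rep2$jaccard <= 1))
})
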