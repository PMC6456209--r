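cbc_from <- function(M) {
  out <- list(cbc = M, hemi = 0 * M, ids = rownames(M))
  class(out) <- "cbc_matrix"
  out
}

test_that("minimal species counts solve small cases exactly", {
  ids <- LETTERS[1:5]
  M <- matrix(0L, 5, 5, dimnames = list(ids, ids))
  p0 <- minimal_species_count(cbc_from(M))
  expect_equal(p0$count, 1L)
  expect_true(p0$exact)

  ## path A-B, B-C: two blocks {A,C} {B}
  M2 <- matrix(0L, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  M2["A", "B"] <- M2["B", "A"] <- 1L
  M2["B", "C"] <- M2["C", "B"] <- 2L
  p2 <- minimal_species_count(cbc_from(M2))
  expect_equal(p2$count, 2L)
  expect_setequal(p2$blocks[[which(sapply(p2$blocks, length) == 2)]],
                  c("A", "C"))

  ## triangle: three blocks
  M3 <- matrix(1L, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  diag(M3) <- 0L
  expect_equal(minimal_species_count(cbc_from(M3))$count, 3L)

  expect_error(minimal_species_count(matrix(c(0, 1, 0, 0), 2, 2)),
               "symmetric")
})

test_that("exact solver equals full partition enumeration up to n = 8", {
  set.seed(31)
  for (k in 1:12) {
    n <- sample(4:8, 1)
    adj <- matrix(FALSE, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      adj[i, j] <- adj[j, i] <- runif(1) < 0.35
    M <- matrix(0L, n, n, dimnames = list(letters[1:n], letters[1:n]))
    M[adj] <- 1L
    got <- minimal_species_count(cbc_from(M))$count
    expect_equal(got, oracle_min_partition(adj))
  }
})

test_that("adding a record never decreases the minimal species count", {
  set.seed(32)
  for (k in 1:8) {
    n <- 7
    M <- matrix(0L, n, n, dimnames = list(letters[1:n], letters[1:n]))
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      M[i, j] <- M[j, i] <- as.integer(runif(1) < 0.3)
    full <- minimal_species_count(cbc_from(M))$count
    sub <- minimal_species_count(cbc_from(M[1:(n - 1), 1:(n - 1)]))$count
    expect_lte(sub, full)
  }
})

test_that("greedy fallback kicks in above the exact limit and stays valid", {
  set.seed(33)
  n <- 20
  M <- matrix(0L, n, n, dimnames = list(paste0("r", 1:n), paste0("r", 1:n)))
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    M[i, j] <- M[j, i] <- as.integer(runif(1) < 0.25)
  p <- minimal_species_count(cbc_from(M))
  expect_false(p$exact)
  for (b in p$blocks)
    if (length(b) > 1)
      expect_true(all(M[b, b] == 0))
})

test_that("absolute identity distinguishes strict from structure-only", {
  x <- list(seq = "GGGAAACCC", db = "(((...)))")
  y <- list(seq = "GGGAAACCC", db = "(((...)))")
  expect_true(absolute_identity(x, y))
  y2 <- list(seq = "GGGACACCC", db = "(((...)))")  # loop substitution
  expect_false(absolute_identity(x, y2, "strict"))
  expect_true(absolute_identity(x, y2, "structure-only"))
})

test_that("species assignment follows the naming rules", {
  ids <- c("q1", "q2", "q3", "ref1")
  M <- matrix(0L, 4, 4, dimnames = list(ids, ids))
  M["q3", c("q1", "q2", "ref1")] <- 1L
  M[c("q1", "q2", "ref1"), "q3"] <- 1L
  cm <- cbc_from(M)
  refs <- data.frame(id = "ref1", species = "Genusx alpha",
                     stringsAsFactors = FALSE)
  idm <- matrix(FALSE, 3, 1, dimnames = list(c("q1", "q2", "q3"), "ref1"))
  idm["q1", "ref1"] <- TRUE
  genus <- setNames(rep("Genusx", 3), c("q1", "q2", "q3"))
  part <- assign_species(c("q1", "q2", "q3"), refs, cm, idm, genus)
  tab <- part$assignment_table
  expect_equal(tab$label[tab$id == "q1"], "Genusx alpha")
  expect_match(tab$label[tab$id == "q2"], "type-01")
  expect_equal(tab$flag[tab$id == "q3"], "putative new species")

  ## two CBC-free non-identical queries share one type block
  expect_equal(tab$label[tab$id == "q2"], "Genusx sp. type-01")

  ## identity with cbc >= 1 signals an upstream fault
  idm2 <- idm; idm2["q3", "ref1"] <- TRUE
  expect_error(assign_species(c("q1", "q2", "q3"), refs, cm, idm2, genus),
               "inconsistency")
})

test_that("delimitation recovers the planted partition on clean sets", {
  for (seed in 1:5) {
    gen <- generate_species_set(n_species = 4, n_per_species = 2,
                                cbc_between = 1, indel_rate = 0, seed = seed)
    enc <- lapply(gen$seqs$id, function(id)
      encode_structure(gen$truth$its2[id], unname(gen$truth$db[id]), id = id))
    part <- minimal_species_count(cbc_matrix(align_progressive(enc)))
    expect_equal(part$count, 4L)
    got <- unname(split(names(part$assignment), part$assignment))
    want <- unname(split(names(gen$truth$species), gen$truth$species))
    expect_setequal(lapply(got, sort), lapply(want, sort))
  }
})
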