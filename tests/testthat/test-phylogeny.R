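mk_aln <- function(encs, ids) {
  dec <- lapply(encs, its2morph::decode_structure)
  out <- list(rows = data.frame(
    id = ids, enc = encs,
    seq = vapply(dec, `[[`, "", "seq"),
    db = vapply(dec, `[[`, "", "db"), stringsAsFactors = FALSE),
    width = nchar(encs[1]))
  class(out) <- "struct_alignment"
  out
}

test_that("p-distance and its Poisson correction follow the closed forms", {
  ## 100 columns, 11 mismatches between r1 and r2
  a <- strrep("A", 100)
  b <- paste0(strrep("C", 11), strrep("A", 89))
  aln <- mk_aln(c(a, b, strrep("G", 100)), c("r1", "r2", "r3"))
  P <- distance_matrix(aln, "p-distance")
  expect_equal(P["r1", "r2"], 0.11)
  expect_equal(diag(P), setNames(c(0, 0, 0), c("r1", "r2", "r3")))
  D <- distance_matrix(aln, "poisson-12")
  expect_equal(D["r1", "r2"], -(11 / 12) * log(1 - 0.12), tolerance = 1e-9)
  ## correction always >= p, saturation capped
  expect_true(all(D >= P - 1e-12))
  expect_equal(D["r1", "r3"], 5)  # p = 1: saturated, capped and flagged
  expect_true(length(attr(D, "saturated")) > 0)
})

test_that("identical rows are at distance zero", {
  aln <- mk_aln(rep("GGAAUU", 3), c("a", "b", "c"))
  expect_true(all(distance_matrix(aln) == 0))
})

test_that("NJ reconstructs additive trees exactly", {
  set.seed(71)
  for (k in 1:40) {
    tr <- ape::rtree(6, br = function(n) runif(n, 0.05, 1))
    D <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), nj)), 0)
    expect_equal(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)], D,
                 tolerance = 1e-9)
  }
})

test_that("three records give the closed-form star", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(el[["A"]], 1)  # (3+4-5)/2
  expect_equal(el[["B"]], 2)
  expect_equal(el[["C"]], 3)
})

test_that("NJ is invariant to input order and validates input", {
  set.seed(72)
  tr <- ape::rtree(7, br = function(n) runif(n, 0.1, 1))
  D <- ape::cophenetic.phylo(tr)
  o <- sample(rownames(D))
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D[o, o])
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
  bad <- D; bad[1, 2] <- bad[1, 2] + 1
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("bootstrap supports behave: range, determinism, trivial cases", {
  gen <- generate_species_set(n_species = 4, n_per_species = 2,
                              cbc_between = 2, sub_within = 4, seed = 19)
  enc <- lapply(gen$seqs$id, function(id)
    encode_structure(gen$truth$its2[id], unname(gen$truth$db[id]), id = id))
  aln <- align_progressive(enc)
  bp <- bootstrap_consensus(aln, replicates = 60, seed = 4)
  supp <- as.numeric(bp$tree$node.label)
  expect_true(all(supp >= 0 & supp <= 100))
  bp2 <- bootstrap_consensus(aln, replicates = 60, seed = 4)
  expect_identical(bp$tree$node.label, bp2$tree$node.label)
  expect_s3_class(bp$consensus, "phylo")
  expect_error(bootstrap_consensus(aln, replicates = 0), "replicates")

  ## conspecific duplicates resample to a 100% cherry
  ids <- gen$seqs$id
  same <- which(gen$truth$species == gen$truth$species[1])
  cherry <- ape::prop.part(bp$tree)
  expect_true(any(vapply(ape::prop.part(bp$tree), function(p)
    setequal(bp$tree$tip.label[p], ids[same]), NA)))
})

test_that("well-separated planted species get strong bipartition support", {
  gen <- generate_species_set(n_species = 4, n_per_species = 2,
                              cbc_between = 3, sub_within = 5,
                              indel_rate = 0, seed = 23)
  enc <- lapply(gen$seqs$id, function(id)
    encode_structure(gen$truth$its2[id], unname(gen$truth$db[id]), id = id))
  aln <- align_progressive(enc)
  bp <- bootstrap_consensus(aln, replicates = 200, seed = 9)
  ## supports of the species cherries (true bipartitions)
  pp <- ape::prop.part(bp$tree)
  labs <- bp$tree$tip.label
  species <- gen$truth$species[labs]
  node_supp <- as.numeric(bp$tree$node.label)
  for (sp in unique(species)) {
    members <- labs[species == sp]
    hit <- which(vapply(pp, function(p) setequal(labs[p], members), NA))
    expect_length(hit, 1L)
    expect_gte(node_supp[hit], 95)
  }
})
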