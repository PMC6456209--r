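test_that("helix trees parse central and subdomain stems correctly", {
  tr <- build_helix_tree("..((...))..((...))..((....)).")
  expect_equal(nrow(tr$helices), 3L)
  expect_true(all(tr$helices$origin == "central"))

  tr2 <- build_helix_tree("((..((...))..((...))..))")
  expect_equal(nrow(tr2$helices), 2L)
  expect_true(all(tr2$helices$origin == "subdomain"))

  tr3 <- build_helix_tree("............")
  expect_equal(nrow(tr3$helices), 0L)
})

test_that("helix trees are invariant under dot-bracket re-serialization", {
  gen <- generate_species_set(seed = 21)
  st <- fold_mfe(gen$truth$its2[1])
  t1 <- build_helix_tree(st)
  t2 <- build_helix_tree(pairs_to_db(st$pairs))
  expect_identical(t1$helices, t2$helices)
})

test_that("the five canonical topologies classify as described", {
  H <- function(n) paste0(strrep("(", n), "....", strrep(")", n))
  ## type 1: three central helices
  db1 <- paste0("..", H(5), "..", H(6), "..", H(7), "..")
  expect_equal(classify_topology(build_helix_tree(db1))$type, 1L)
  ## type 2: helix I central; II and III on an extended subdomain
  db2 <- paste0("..", H(5), "..((..", H(6), "..", H(7), "..))..")
  tt2 <- classify_topology(build_helix_tree(db2))
  expect_equal(tt2$type, 2L)
  expect_true(tt2$subdomain_present)
  ## type 3: as type 2 plus small IIa between II and III
  db3 <- paste0("..", H(5), "..((..", H(6), "..((...))..", H(7), "..))..")
  tt3 <- classify_topology(build_helix_tree(db3))
  expect_equal(tt3$type, 3L)
  expect_true(tt3$iia_present)
  ## type 4: four central helices
  db4 <- paste0(".", H(5), ".", H(6), ".", H(7), ".", H(5), ".")
  expect_equal(classify_topology(build_helix_tree(db4))$type, 4L)
  ## type 5: I and II on subdomain, III and IV central
  db5 <- paste0("..((..", H(5), "..", H(6), "..))..", H(7), "..", H(5), "..")
  expect_equal(classify_topology(build_helix_tree(db5))$type, 5L)
  ## unclassified falls back to 0 without error
  db0 <- paste0("..", H(5), "..", H(6), "..")
  expect_equal(classify_topology(build_helix_tree(db0))$type, 0L)
})

test_that("generator templates classify as their planted type", {
  gen3 <- generate_species_set(seed = 2)
  for (id in gen3$seqs$id)
    expect_equal(classify_topology(build_helix_tree(
      fold_mfe(gen3$truth$its2[id])))$type, 1L)
  tpl4 <- structure_template(stems = c(12, 14, 20, 8),
                             loops = c(5, 6, 8, 4),
                             spacers = c(5, 4, 4, 4, 6))
  gen4 <- generate_species_set(tpl4, n_species = 2, n_per_species = 1,
                               cbc_between = 1, seed = 2)
  for (id in gen4$seqs$id)
    expect_equal(classify_topology(build_helix_tree(
      fold_mfe(gen4$truth$its2[id])))$type, 4L)
})

test_that("the helix III basal motif is detected with its variant", {
  gen <- generate_species_set(seed = 15)
  st <- fold_mfe(gen$truth$its2[1])
  mot <- detect_basal_motif(build_helix_tree(st), st$seq)
  expect_equal(mot$variant, "UGGC")

  ## replace the motif with the CGGC variant at the helix III base itself
  tr1 <- build_helix_tree(st)
  h3 <- tr1$helices[tr1$helices$principal, ][3, ]
  seq2 <- st$seq
  substr(seq2, h3$start, h3$start) <- "C"   # UGGC -> CGGC, pairing intact (C-A invalid; re-fold)
  mot2 <- detect_basal_motif(build_helix_tree(st), seq2)
  expect_equal(mot2$variant, "CGGC")

  ## fewer than three helices: absent with a warning
  tr <- build_helix_tree("..((((....))))..((((....))))..")
  expect_warning(m3 <- detect_basal_motif(tr, strrep("A", 30)), "helix III")
  expect_equal(m3$variant, "absent")
})

test_that("consensus columns follow majority rules", {
  mk_aln <- function(seqs, dbs) {
    enc <- lapply(seq_along(seqs), function(k)
      encode_structure(seqs[k], dbs[k], id = paste0("r", k)))
    align_progressive(enc)
  }
  ## identical records: full conservation, structure preserved
  aln <- mk_aln(rep("GGGAAACCCA", 3), rep("(((...))).", 3))
  cons <- build_consensus(aln)
  expect_equal(cons$db, "(((...))).")
  expect_true(all(cons$columns$conservation == 1))
  expect_true(all(cons$columns$conserved))

  ## A/A/A/G column: conservation 0.75, conserved at the 0.51 threshold
  aln2 <- mk_aln(c("AAAAAA", "AAAAAA", "AAAAAA", "GAAAAA"),
                 rep("......", 4))
  cons2 <- build_consensus(aln2)
  expect_equal(cons2$columns$residue[1], "A")
  expect_equal(cons2$columns$conservation[1], 0.75)
  expect_true(cons2$columns$conserved[1])

  ## helix paired in 4 of 10 records drops out of the consensus
  seqs <- rep("GGGGAAACCCCA", 10)
  dbs <- c(rep("((((...))))." , 4), rep("............", 6))
  cons3 <- build_consensus(mk_aln(seqs, dbs))
  expect_equal(cons3$db, strrep(".", 12))

  ## idempotence: duplicating the set leaves the consensus unchanged
  aln4 <- mk_aln(c("GGGAAACCCA", "GGGAAACCCA", "GGGAAACCCA",
                   "GGGAAACCCA", "GGGAAACCCA", "GGGAAACCCA"),
                 rep("(((...))).", 6))
  expect_equal(build_consensus(aln4)$db, cons$db)

  expect_error(build_consensus(
    structure(list(rows = data.frame(id = "a", enc = "A", seq = "A",
                                     db = ".")), class = "struct_alignment")),
    "at least 2")
})
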