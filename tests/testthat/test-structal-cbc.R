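enc_of <- function(seq, db, id = "x") encode_structure(seq, db, id = id)

test_that("the 12-letter encoding is bijective and lossless", {
  expect_equal(encode_structure("A", ".")$enc, "A")
  expect_equal(encode_structure("GGAAACC", "((...))")$enc, "HHAAAFF")
  expect_error(encode_structure("GGAAAC", "((...))"), "length")
  expect_error(encode_structure("GGNAACC", "((...))"), "encode")

  gen <- generate_species_set(seed = 17, indel_rate = 0.05,
                              n_per_species = 3)
  for (id in gen$seqs$id) {
    e <- encode_structure(gen$truth$its2[id], unname(gen$truth$db[id]))
    d <- decode_structure(e$enc)
    expect_identical(d$seq, chartr("T", "U", unname(gen$truth$its2[id])))
    expect_identical(d$db, unname(gen$truth$db[id]))
  }
})

test_that("pairwise alignment is optimal, symmetric and gap-correct", {
  a <- enc_of("GGGAAACCC", "(((...)))", "a")
  ident <- align_pair(a, a)
  S <- default_score_matrix()
  ea <- strsplit(a$enc, "")[[1]]
  expect_equal(ident$score, sum(S[cbind(ea, ea)]))
  expect_false(grepl("-", ident$rows$enc[1], fixed = TRUE))

  ## one inserted unpaired base: exactly one gap column, score by brute DP
  b <- enc_of("GGGAAAACCC", "(((....)))", "b")
  al <- align_pair(a, b)
  expect_equal(sum(strsplit(al$rows$enc[1], "")[[1]] == "-"), 1L)
  eb <- strsplit(b$enc, "")[[1]]
  expect_equal(al$score, brute_align_score(ea, eb, S, -5, -1))

  ## score symmetry over random structured pairs
  set.seed(5)
  for (k in 1:6) {
    gen <- generate_species_set(n_species = 2, n_per_species = 1,
                                cbc_between = 2, indel_rate = 0, seed = k)
    x <- enc_of(gen$truth$its2[1], unname(gen$truth$db[1]), "x")
    y <- enc_of(gen$truth$its2[2], unname(gen$truth$db[2]), "y")
    expect_equal(align_pair(x, y)$score, align_pair(y, x)$score)
  }
  expect_error(align_pair(enc_of("", ""), a), "empty")
})

test_that("alignment scores agree with an independent aligner", {
  skip_if_not_installed("Biostrings")
  S <- default_score_matrix()
  for (k in 1:5) {
    gen <- generate_species_set(n_species = 2, n_per_species = 2,
                                cbc_between = 2, indel_rate = 0.06,
                                sub_within = 3, seed = 30 + k)
    x <- enc_of(gen$truth$its2[2], unname(gen$truth$db[2]), "x")
    y <- enc_of(gen$truth$its2[4], unname(gen$truth$db[4]), "y")
    ours <- align_pair(x, y)$score
    ## Biostrings charges gapOpening on top of the first gapExtension
    bs <- Biostrings::pairwiseAlignment(
      x$enc, y$enc, substitutionMatrix = S, gapOpening = 4,
      gapExtension = 1, type = "global")
    expect_equal(ours, Biostrings::score(bs))
  }
})

test_that("progressive alignment handles identical and indel-free sets", {
  recs <- lapply(1:3, function(k) enc_of("GGGAAACCC", "(((...)))",
                                         paste0("r", k)))
  aln <- align_progressive(recs)
  expect_false(any(grepl("-", aln$rows$enc, fixed = TRUE)))

  gen <- generate_species_set(n_species = 3, n_per_species = 2,
                              cbc_between = 2, indel_rate = 0, seed = 8)
  enc <- lapply(gen$seqs$id, function(id)
    enc_of(gen$truth$its2[id], unname(gen$truth$db[id]), id))
  aln2 <- align_progressive(enc)
  expect_false(any(grepl("-", aln2$rows$enc, fixed = TRUE)))
  expect_identical(aln2$rows$id, gen$seqs$id)
  expect_error(align_progressive(enc[1]), "at least 2")
})

test_that("CBC and hemi-CBC counting matches their definitions", {
  ## planted single CBC: G-C in x vs A-U in y at the same stem slot
  x <- enc_of("AGGGAAACCCA", ".(((...))).", "x")
  y <- enc_of("AAGGAAACCUA", ".(((...))).", "y")
  ct <- count_cbc(align_pair(x, y), "x", "y")
  expect_equal(ct$cbc, 1L)
  expect_equal(ct$hemi, 0L)

  ## hemi: G-C vs G-U
  z <- enc_of("AGGGAAACCUA", ".(((...))).", "z")
  ct2 <- count_cbc(align_pair(x, z), "x", "z")
  expect_equal(ct2$cbc, 0L)
  expect_equal(ct2$hemi, 1L)

  ## identity
  x2 <- enc_of("AGGGAAACCCA", ".(((...))).", "x2")
  ct3 <- count_cbc(align_pair(x, x2), "x", "x2")
  expect_equal(c(ct3$cbc, ct3$hemi), c(0L, 0L))
})

test_that("CBC counts equal a brute-force column-pair scan", {
  set.seed(44)
  tpl <- structure_template(stems = c(6, 8, 12), loops = c(4, 4, 5),
                            spacers = c(3, 3, 3, 3))
  for (k in 1:8) {
    gen <- generate_species_set(tpl, n_species = 3, n_per_species = 2,
                                cbc_between = 2, hemicbc_within = 1,
                                sub_within = 2, indel_rate = 0.04,
                                seed = 100 + k)
    enc <- lapply(gen$seqs$id, function(id)
      enc_of(gen$truth$its2[id], unname(gen$truth$db[id]), id))
    aln <- align_progressive(enc)
    ids <- aln$rows$id
    for (i in 1:(length(ids) - 1)) for (j in (i + 1):length(ids)) {
      got <- count_cbc(aln, ids[i], ids[j])
      orc <- oracle_cbc(aln, ids[i], ids[j])
      expect_identical(got, orc)
    }
  }
})

test_that("CBC matrices are symmetric with zero diagonal and order-invariant", {
  gen <- generate_species_set(n_species = 3, n_per_species = 2,
                              cbc_between = 2, seed = 5)
  enc <- lapply(gen$seqs$id, function(id)
    enc_of(gen$truth$its2[id], unname(gen$truth$db[id]), id))
  cm <- cbc_matrix(align_progressive(enc))
  expect_identical(cm$cbc, t(cm$cbc))
  expect_true(all(diag(cm$cbc) == 0))
  ## record order invariance (indel-free: alignment path unchanged)
  cm2 <- cbc_matrix(align_progressive(rev(enc)))
  expect_identical(cm2$cbc[rownames(cm$cbc), colnames(cm$cbc)], cm$cbc)
  ## duplicate records: zero entry between duplicates
  dup <- c(enc, list(enc_of(gen$truth$its2[1], unname(gen$truth$db[1]),
                            "dup")))
  cmd <- cbc_matrix(align_progressive(dup))
  expect_equal(cmd$cbc["dup", gen$seqs$id[1]], 0L)
  ## cbc + hemi bounded by co-paired column pairs
  npairs <- sum(db_to_pairs(gen$truth$db[1]) > 0) / 2
  expect_true(all(cm$cbc + cm$hemi <= npairs))
})

test_that("variation summaries count Ts/Tv and INDEL runs correctly", {
  a <- enc_of("AAAAAA", "......", "a")
  g <- enc_of("GAAAAA", "......", "g")
  v <- count_variation(align_pair(a, g), "a", "g")
  expect_equal(c(v$ts, v$tv), c(1L, 0L))

  cc <- enc_of("CAAAAA", "......", "c")
  v2 <- count_variation(align_pair(a, cc), "a", "c")
  expect_equal(c(v2$ts, v2$tv), c(0L, 1L))

  ins <- enc_of("AAAUUUAAA", ".........", "i")
  base <- enc_of("AAAAAA", "......", "b")
  v3 <- count_variation(align_pair(ins, base), "i", "b")
  expect_equal(v3$indel_events, 1L)
  expect_equal(v3$indel_columns, 3L)

  v4 <- count_variation(align_pair(a, enc_of("AAAAAA", "......", "a2")),
                        "a", "a2")
  expect_equal(c(v4$ts, v4$tv, v4$indel_events, v4$indel_columns),
               c(0L, 0L, 0L, 0L))
})
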