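# Data model and format round trips.

test_that("FASTA parsing transcribes, preserves ids, and validates", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT"), fa)
  recs <- parse_fasta(fa, region = "OTHER")
  expect_length(recs, 1L)
  expect_identical(recs[[1]]$seq, "ACGU")
  expect_identical(recs[[1]]$id, "a")
  expect_identical(nrow(recs[[1]]$pairs), 0L)

  writeLines(c(">a", "ACGT", ">a", "GGGG"), fa)
  expect_error(parse_fasta(fa), "duplicate")

  writeLines(c(">a", "AC-GU"), fa)
  expect_error(parse_fasta(fa, alphabet_policy = "strict"), "position 3")
  expect_identical(parse_fasta(fa, alphabet_policy = "iupac")[[1]]$seq,
                   "ACGU")

  writeLines(c(">lower", "acgu"), fa)
  expect_identical(parse_fasta(fa)[[1]]$seq, "ACGU")
})

test_that("parse -> write -> parse is the identity on ids and sequences", {
  set.seed(11)
  recs <- lapply(1:5, function(k) {
    seq_struct_record(sprintf("rec%02d", k), random_rna(40 + k))
  })
  fa <- tempfile(fileext = ".fasta")
  write_fasta(recs, fa)
  back <- parse_fasta(fa, region = "OTHER")
  expect_identical(vapply(back, `[[`, "", "id"),
                   vapply(recs, `[[`, "", "id"))
  expect_identical(vapply(back, `[[`, "", "seq"),
                   vapply(recs, `[[`, "", "seq"))
})

test_that("dot-bracket conversion handles the worked cases", {
  expect_identical(dotbracket_to_pairs("((...))"),
                   normalize_pairs(rbind(c(1, 7), c(2, 6))))
  expect_identical(nrow(dotbracket_to_pairs(".......")), 0L)
  expect_error(dotbracket_to_pairs("((.)"), "unbalanced")
  expect_error(dotbracket_to_pairs("(.))"), "unbalanced.*position 4")
  expect_error(dotbracket_to_pairs("(<.>)"), "invalid")
})

test_that("dot-bracket <-> pairs round-trips losslessly on random structures", {
  set.seed(23)
  for (k in 1:1000) {
    n <- sample(10:60, 1L)
    pr <- random_structure(n)
    db <- pairs_to_dotbracket(pr, n)
    expect_identical(dotbracket_to_pairs(db), normalize_pairs(pr))
    expect_identical(pairs_to_dotbracket(dotbracket_to_pairs(db), n), db)
  }
})

test_that("record invariants are enforced", {
  expect_error(seq_struct_record("x", "ACGUACGU",
                                 pairs = rbind(c(1, 8), c(2, 8))),
               "more than one pair")
  expect_error(seq_struct_record("x", "ACGUACGU",
                                 pairs = rbind(c(1, 4))), "hairpin")
  expect_error(seq_struct_record("x", "ACGUACGU",
                                 pairs = rbind(c(1, 9))), "outside")
  expect_error(seq_struct_record("x", "ACGUACGUAC",
                                 pairs = rbind(c(1, 7), c(3, 9))),
               "pseudoknot")
  expect_error(seq_struct_record("x", "ACXGU"), "position 3")
})

test_that("Vienna files round-trip records with energies", {
  rec1 <- seq_struct_record("r1", "GGGAAACCC",
                            pairs = rbind(c(1, 9), c(2, 8), c(3, 7)),
                            energy = -3.4, source = "folded_external")
  rec2 <- seq_struct_record("r2", "AAAAUUUU")
  path <- tempfile(fileext = ".db")
  write_vienna(list(rec1, rec2), path)
  back <- read_vienna(path)
  expect_identical(back[[1]]$seq, rec1$seq)
  expect_identical(back[[1]]$pairs, rec1$pairs)
  expect_equal(back[[1]]$energy, -3.4)
  expect_true(is.na(back[[2]]$energy))
})

test_that("Newick round trip preserves topology, lengths and support", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  path <- tempfile(fileext = ".nwk")
  write_newick(tr, path)
  expect_identical(trimws(readLines(path)), "(A:0.1,B:0.1);")

  set.seed(5)
  tr8 <- ape::rtree(8)
  write_newick(tr8, path)
  back <- read_newick(path)
  expect_identical(rf_distance(tr8, back), 0L)
  expect_equal(sort(back$edge.length), sort(tr8$edge.length),
               tolerance = 1e-6)

  tr$node.label <- "87"
  write_newick(tr, path)
  expect_match(paste(readLines(path), collapse = ""), "87")

  empty <- list(tip.label = character(0))
  class(empty) <- "phylo"
  expect_error(write_newick(empty, path), "empty")
})

test_that("group maps read and write with validation", {
  path <- tempfile(fileext = ".tsv")
  write_group_map(c(t1 = "H", t2 = "S"), path)
  gm <- read_group_map(path)
  expect_identical(gm, c(t1 = "H", t2 = "S"))
  writeLines(c("t1\tH", "t1\tS"), path)
  expect_error(read_group_map(path), "duplicate")
})
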