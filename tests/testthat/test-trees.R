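# NJ / UPGMA construction, bootstrap support, RF distance.

test_that("NJ recovers the generating 4-taxon topology from an additive matrix", {
  # additive distances for ((A,B),(C,D)) with internal branch 0.3
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 0.2
  d["C", "D"] <- d["D", "C"] <- 0.2
  for (x in c("A", "B")) for (y in c("C", "D")) {
    d[x, y] <- d[y, x] <- 0.1 + 0.3 + 0.1
  }
  tr <- nj_tree(d)
  want <- ape::read.tree(text = "((A,B),(C,D));")
  expect_identical(rf_distance(tr, want), 0L)
  # brute force: the recovered topology beats the two alternatives
  alts <- list("((A,C),(B,D));", "((A,D),(B,C));")
  for (alt in alts) {
    expect_gt(rf_distance(tr, ape::read.tree(text = alt)), 0L)
  }
})

test_that("3-taxon NJ matches the three-point formulas", {
  d <- matrix(c(0, 0.3, 0.4,
                0.3, 0, 0.5,
                0.4, 0.5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2L]])
  expect_equal(unname(bl["A"]), (0.3 + 0.4 - 0.5) / 2)
  expect_equal(unname(bl["B"]), (0.3 + 0.5 - 0.4) / 2)
  expect_equal(unname(bl["C"]), (0.4 + 0.5 - 0.3) / 2)
})

test_that("NJ recovers noiseless additive topologies up to 12 taxa", {
  for (n in c(6, 9, 12)) {
    for (sd in 1:5) {
      gen <- random_additive(n, seed = 100 * n + sd)
      tr <- nj_tree(gen$d)
      expect_identical(rf_distance(tr, gen$tree), 0L,
                       info = sprintf("n=%d seed=%d", n, sd))
      expect_true(all(tr$edge.length >= 0))
    }
  }
})

test_that("NJ and UPGMA agree on ultrametric matrices", {
  set.seed(71)
  tr0 <- ape::rcoal(8)
  d <- ape::cophenetic.phylo(tr0)
  expect_identical(rf_distance(nj_tree(d), upgma_tree(d)), 0L)
})

test_that("UPGMA handles the degenerate worked cases", {
  d2 <- matrix(c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("A", "B"),
                                                        c("A", "B")))
  tr <- upgma_tree(d2)
  expect_equal(sort(tr$edge.length), c(0.1, 0.1))

  dz <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  trz <- upgma_tree(dz)
  expect_true(all(trz$edge.length == 0))

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("UPGMA on a planted CBC matrix groups taxa sharing CBC history", {
  # two 3-taxon blocks; CBCs only across blocks
  taxa <- paste0("t", 1:6)
  M <- matrix(0L, 6, 6, dimnames = list(taxa, taxa))
  M[1:3, 4:6] <- 2L
  M[4:6, 1:3] <- 2L
  tr <- upgma_tree(M)
  want <- ape::read.tree(text = "((t1,t2,t3),(t4,t5,t6));")
  # every bipartition of the block tree is compatible: RF counts only the
  # block split, which must be present
  parts <- oracle_bipartitions(tr)
  expect_true("t1,t2,t3" %in% parts || "t4,t5,t6" %in% parts)
})

test_that("bootstrap support is seed-reproducible and saturates on blocks", {
  fam <- generate_family(synth_config(n_taxa = 6, seed = 44))
  aln <- fam$truth$alignment
  b1 <- bootstrap_support(aln, nj_tree, reps = 30L, seed = 4L)
  b2 <- bootstrap_support(aln, nj_tree, reps = 30L, seed = 4L)
  expect_identical(b1$node.label, b2$node.label)
  expect_true(all(b1$node.label >= 0 & b1$node.label <= 100))

  # two divergent 4-taxon blocks with many diagnostic columns
  blockA <- paste(rep("AAGGCCAAGGCC", 6), collapse = "")
  blockB <- paste(rep("GGAAUUGGAAUU", 6), collapse = "")
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]; ch[k] <- "U"; paste(ch, collapse = "")
  }
  recs <- c(lapply(1:4, function(k) {
    seq_struct_record(paste0("a", k), mut(blockA, k))
  }), lapply(1:4, function(k) {
    seq_struct_record(paste0("b", k), mut(blockB, k + 4L))
  }))
  states <- do.call(rbind, lapply(recs, encode12))
  rownames(states) <- vapply(recs, `[[`, "", "id")
  aln2 <- itsstruct:::new_ssalignment(states)
  bt <- bootstrap_support(aln2, nj_tree, reps = 100L, seed = 2L)
  # the a-vs-b bipartition is on the tree and fully supported
  parts <- oracle_bipartitions(bt)
  expect_true("a1,a2,a3,a4" %in% parts || "b1,b2,b3,b4" %in% parts)
  node_of_block <- which(bt$node.label == 100)
  expect_gt(length(node_of_block), 0L)

  # reps = 1: all supports 0 or 100
  b3 <- bootstrap_support(aln2, nj_tree, reps = 1L, seed = 1L)
  expect_true(all(b3$node.label %in% c(0, 100)))
  expect_error(bootstrap_support(aln2, nj_tree, reps = 0L), "reps")
})

test_that("RF distance matches the brute-force bipartition oracle", {
  expect_identical(rf_distance(ape::read.tree(text = "((A,B),(C,D));"),
                               ape::read.tree(text = "((A,B),(C,D));")), 0L)
  expect_identical(rf_distance(ape::read.tree(text = "((A,B),(C,D));"),
                               ape::read.tree(text = "((A,C),(B,D));")), 2L)
  set.seed(83)
  for (k in 1:10) {
    t1 <- ape::rtree(8)
    t2 <- ape::rtree(8)
    expect_identical(rf_distance(t1, t2), oracle_rf(t1, t2))
  }
  expect_error(rf_distance(ape::rtree(5), ape::rtree(6)), "leaf sets")
})

test_that("collapsing low support yields the published-figure convention", {
  fam <- generate_family(synth_config(n_taxa = 8, seed = 13))
  bt <- bootstrap_support(fam$truth$alignment, nj_tree, reps = 50L, seed = 3L)
  coll <- collapse_low_support(bt, cutoff = 50)
  expect_lte(coll$Nnode, bt$Nnode)
})
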