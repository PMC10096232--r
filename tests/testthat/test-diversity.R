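# GC content, diversity indices, and group distance tables.

test_that("GC content follows the definition", {
  expect_equal(unname(gc_content(c(a = "GCGC"))), 1)
  expect_equal(unname(gc_content(c(a = "AUAU"))), 0)
  expect_equal(unname(gc_content(c(a = "GCAU"))), 0.5)
  # ambiguity codes excluded from numerator and denominator
  expect_equal(unname(gc_content(c(a = "GCRN"))), 1)
  expect_error(gc_content(c(a = "NNN")), "empty")
  # group means
  g <- gc_content(c(x = "GCGC", y = "AUAU", z = "GCAU"),
                  groups = c(x = "A", y = "A", z = "B"))
  expect_equal(unname(g["A"]), 0.5)
  expect_equal(unname(g["B"]), 0.5)
})

test_that("the worked three-sequence example reproduces the derived values", {
  m <- rbind(t1 = c("A", "C", "G", "U"),
             t2 = c("A", "C", "G", "A"),
             t3 = c("A", "C", "G", "A"))
  d <- diversity_indices(m)
  expect_identical(d$S, 1L)
  expect_identical(d$haplotypes, 2L)
  expect_equal(d$Pi, 2 / 12, tolerance = 1e-12)
  expect_equal(d$hap_diversity, 2 / 3, tolerance = 1e-12)
  expect_identical(d$Eta, 1L)
  expect_identical(d$singletons, 1L)
  expect_identical(d$parsimony_informative, 0L)
})

test_that("identical sequences give null diversity", {
  m <- matrix("A", 4, 10, dimnames = list(paste0("t", 1:4), NULL))
  d <- diversity_indices(m)
  expect_identical(d$S, 0L)
  expect_equal(d$Pi, 0)
  expect_equal(d$hap_diversity, 0)
  expect_identical(d$haplotypes, 1L)
})

test_that("a three-allele column contributes 2 to Eta and 1 to S", {
  m <- rbind(t1 = c("A", "A"), t2 = c("C", "A"), t3 = c("G", "A"))
  d <- diversity_indices(m)
  expect_identical(d$S, 1L)
  expect_identical(d$Eta, 2L)
})

test_that("Pi equals the brute-force pairwise mean on random alignments", {
  set.seed(61)
  for (k in 1:25) {
    n <- sample(3:8, 1L)
    L <- sample(10:40, 1L)
    m <- matrix(sample(c("A", "C", "G", "U"), n * L, replace = TRUE), n, L,
                dimnames = list(paste0("t", 1:n), NULL))
    # sprinkle gaps
    m[sample(length(m), round(length(m) * 0.05))] <- NA
    d <- diversity_indices(m)
    expect_equal(d$Pi, oracle_pi(m), tolerance = 1e-12)
  }
})

test_that("indel sites and haplotypes come from the gap matrix", {
  m <- rbind(t1 = c("A", "C", "G", "U"),
             t2 = c("A", NA, "G", "U"),
             t3 = c("A", NA, "G", NA))
  d <- diversity_indices(m)
  expect_identical(d$indel_sites, 2L)
  expect_identical(d$indel_haplotypes, 3L)
})

test_that("pairwise p-distance and group means follow the worked examples", {
  m <- rbind(a = strsplit("AAAA", "")[[1]], b = strsplit("AAAU", "")[[1]])
  D <- itsstruct:::p_distance_matrix(m)
  expect_equal(D["a", "b"], 0.25)

  # two groups, identical within, 1 of 10 sites different between
  s1 <- strsplit("AAAAAAAAAA", "")[[1]]
  s2 <- s1; s2[1] <- "G"
  m2 <- rbind(a1 = s1, a2 = s1, b1 = s2, b2 = s2)
  gt <- group_distances(m2, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"),
                        se_reps = 0L)
  expect_equal(gt$between["A", "B"], 0.1)
  expect_equal(unname(gt$within["A"]), 0)
  expect_equal(unname(gt$within["B"]), 0)
  expect_null(gt$between_se)

  # singleton group flagged not-applicable
  gt2 <- group_distances(m2, c(a1 = "A", a2 = "A", b1 = "B", b2 = "C"),
                         se_reps = 0L)
  expect_true(is.na(gt2$within["C"]))
})

test_that("bootstrap standard errors are seed-reproducible", {
  fam <- generate_family(synth_config(n_taxa = 8, seed = 2))
  aln <- fam$truth$alignment
  groups <- stats::setNames(rep(c("X", "Y"), each = 4L), aln$taxa)
  g1 <- group_distances(aln, groups, se_reps = 40L, seed = 9L)
  g2 <- group_distances(aln, groups, se_reps = 40L, seed = 9L)
  expect_identical(g1$between_se, g2$between_se)
  expect_identical(g1$within_se, g2$within_se)
  expect_true(all(g1$between_se[upper.tri(g1$between_se)] >= 0))
})

test_that("group means are invariant to taxon order", {
  fam <- generate_family(synth_config(n_taxa = 6, seed = 6))
  aln <- fam$truth$alignment
  groups <- stats::setNames(rep(c("X", "Y"), 3L), aln$taxa)
  m <- itsstruct:::aln_base_matrix(aln)
  g1 <- group_distances(m, groups, se_reps = 0L)
  perm <- sample(nrow(m))
  g2 <- group_distances(m[perm, ], groups, se_reps = 0L)
  expect_equal(g1$between, g2$between)
  expect_equal(g1$within, g2$within)
})
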