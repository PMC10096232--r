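# CBC / hCBC / Nst classification and event tabulation.

test_that("pair-change classifier agrees with the truth-table oracle", {
  bases <- c("A", "C", "G", "U")
  grid <- expand.grid(a5 = bases, a3 = bases, b5 = bases, b3 = bases,
                      stringsAsFactors = FALSE)
  expect_identical(nrow(grid), 256L)
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    got <- classify_pair_change(c(g$a5, g$a3), c(g$b5, g$b3))
    want <- oracle_classify(g$a5, g$a3, g$b5, g$b3)
    expect_identical(got, want,
                     info = sprintf("%s:%s vs %s:%s", g$a5, g$a3, g$b5, g$b3))
    # symmetry
    expect_identical(got, classify_pair_change(c(g$b5, g$b3), c(g$a5, g$a3)))
  }
})

test_that("the published transition cases classify as printed", {
  expect_identical(classify_pair_change(c("U", "G"), c("A", "U")), "CBC")
  expect_identical(classify_pair_change(c("U", "A"), c("U", "G")), "hCBC")
  expect_identical(classify_pair_change(c("A", "U"), c("A", "U")), "silent")
  expect_identical(classify_pair_change(c("U", "A"), c("C", "A")), "Nst")
  expect_identical(classify_pair_change(c("U", "A"), c("C", "G")), "CBC")
  expect_identical(classify_pair_change(c("G", "C"), c("A", "U")), "CBC")
  # lenient mode admits C:A as a weak pair, reproducing the published call
  expect_identical(classify_pair_change(c("U", "A"), c("C", "A"),
                                        lenient = TRUE), "hCBC")
  expect_error(classify_pair_change(c("N", "A"), c("C", "A")), "ambiguity")
})

test_that("unpaired changes are silent, Nst, or indel", {
  expect_identical(classify_unpaired_change("A", "A"), "silent")
  expect_identical(classify_unpaired_change("A", "G"), "Nst")
  expect_identical(classify_unpaired_change(NA, "A"), "indel")
})

test_that("the printed-exemplar toy set reproduces the published calls", {
  toy <- make_toy_cbc_set()
  ev <- tabulate_events(toy$alignment, toy$groups,
                        mode = "taxon_pairwise")$events
  at <- function(a, b, col) {
    r <- ev[((ev$a == a & ev$b == b) | (ev$a == b & ev$b == a)) &
              ev$aligned_col == col, ]
    if (nrow(r) == 0L) "silent" else r$class
  }
  # Helix I 39/70: U:A block vs C:G block
  expect_identical(at("CEGO", "Taverniera", 39L), "CBC")
  expect_identical(at("cladeS", "cladeM", 39L), "CBC")
  # the U:G exception is an hCBC against both blocks' states
  expect_identical(at("H_pabulare", "CEGO", 39L), "hCBC")
  expect_identical(at("H_pabulare", "Taverniera", 39L), "hCBC")
  # Helix III 148/186: U:G vs A:U
  expect_identical(at("Alhagi", "cladeH", 148L), "CBC")
  expect_identical(at("H_tibeticum", "cladeC", 148L), "CBC")
  # Helix I 47/64: G:C vs A:U between the printed species
  expect_identical(at("H_longigynophorum", "H_macranthum", 47L), "CBC")
  # Helix II 85/113 and 97/101
  expect_identical(at("H_elymaiticum", "H_longigynophorum", 85L), "CBC")
  expect_identical(at("H_astragaloides", "H_praticola", 97L), "CBC")
  # exemplars are identical at unprinted columns
  expect_identical(at("CEGO", "cladeS", 150L), "silent")
  # C:A is not an allowed pair: Nst under the default classifier
  expect_identical(at("H_papillosum", "CEGO", 39L), "Nst")
})

test_that("identical records yield zero events and a zero CBC matrix", {
  t2 <- its2_template()
  recs <- list(seq_struct_record("a", t2$seq, t2$pairs),
               seq_struct_record("b", t2$seq, t2$pairs))
  aln <- align_seqstruct(recs)
  res <- tabulate_events(aln, mode = "taxon_pairwise")
  expect_identical(nrow(res$events), 0L)
  M <- cbc_matrix(res$events, aln$taxa)
  expect_true(all(M == 0L))
})

test_that("planted events are recovered exactly from the true alignment", {
  for (sd in c(2, 14)) {
    fam <- generate_family(synth_config(n_taxa = 8, seed = sd))
    aln <- fam$truth$alignment
    res <- tabulate_events(aln, mode = "taxon_pairwise")
    ev <- res$events
    for (a in seq_len(7L)) {
      for (b in (a + 1L):8L) {
        ta <- aln$taxa[a]; tb <- aln$taxa[b]
        planted <- truth_path_counts(fam$truth, ta, tb)
        sub <- ev[(ev$a == ta & ev$b == tb) | (ev$a == tb & ev$b == ta), ]
        obs <- table(factor(sub$class, levels = names(planted)))
        expect_identical(as.integer(obs), unname(planted),
                         info = sprintf("seed %d %s-%s", sd, ta, tb))
      }
    }
  }
})

test_that("the CBC matrix mirrors pairwise CBC events symmetrically", {
  fam <- generate_family(synth_config(n_taxa = 8, seed = 5))
  aln <- fam$truth$alignment
  ev <- tabulate_events(aln, mode = "taxon_pairwise")$events
  M <- cbc_matrix(ev, aln$taxa)
  expect_true(isSymmetric(M))
  expect_true(all(diag(M) == 0L))
  # entries equal the planted CBC path counts
  for (a in 1:7) {
    for (b in (a + 1L):8L) {
      planted <- truth_path_counts(fam$truth, aln$taxa[a], aln$taxa[b])
      expect_identical(M[a, b], unname(planted["CBC"]))
    }
  }
})

test_that("event classes partition all observed column differences", {
  fam <- generate_family(synth_config(n_taxa = 6, seed = 8))
  aln <- fam$truth$alignment
  ev <- tabulate_events(aln, mode = "taxon_pairwise")$events
  st <- aln$states
  for (a in 1:5) {
    for (b in (a + 1L):6L) {
      ta <- aln$taxa[a]; tb <- aln$taxa[b]
      sub <- ev[(ev$a == ta & ev$b == tb) | (ev$a == tb & ev$b == ta), ]
      # every differing column is covered by an event (at the column or its
      # partner), and silent columns produce none
      diff_cols <- which(ifelse(st[a, ] == 0L, "-", state_base(st[a, ])) !=
                           ifelse(st[b, ] == 0L, "-", state_base(st[b, ])))
      covered <- sort(unique(c(sub$aligned_col, sub$partner_col)))
      expect_true(all(diff_cols %in% covered))
    }
  }
})

test_that("group-level tabulation excludes polymorphic columns as exceptions", {
  toy <- make_toy_cbc_set()
  res <- tabulate_events(toy$alignment, toy$groups, mode = "group_level")
  # group H is polymorphic at 148 (H_tibeticum U:G vs others A:U) and at
  # 47/97 through the printed exceptions
  expect_true(!is.null(res$exceptions))
  expect_true(any(res$exceptions$group == "H" &
                    res$exceptions$aligned_col %in% c(148L, 186L)))
  # groups that stay unanimous at column 39 (CEGO vs Taverniera) still show
  # the Helix I CBC; the U:G exception makes group M polymorphic there
  ev <- res$events
  expect_true(any(ev$aligned_col == 39L & ev$class == "CBC" &
                    ((ev$a == "CEGO" & ev$b == "Taverniera") |
                       (ev$a == "Taverniera" & ev$b == "CEGO"))))
  expect_true(any(res$exceptions$group == "M" &
                    res$exceptions$aligned_col == 39L))
  # unmapped taxon errors
  expect_error(tabulate_events(toy$alignment, toy$groups[-1],
                               mode = "group_level"), "not mapped")
})
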