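# The 12-state encoding and the progressive sequence-structure aligner.

test_that("encode12 maps bases and roles as specified", {
  rec <- seq_struct_record("x", "GAAAAC", pairs = rbind(c(1, 6)))
  st <- encode12(rec)
  expect_identical(state_base(st), c("G", "A", "A", "A", "A", "C"))
  expect_identical(state_role(st),
                   c("open", rep("unpaired", 4L), "close"))
  all_un <- encode12(seq_struct_record("y", "ACGU"))
  expect_true(all(state_role(all_un) == "unpaired"))
  amb <- seq_struct_record("z", "ACGR")
  expect_error(encode12(amb), "ambiguity")
})

test_that("encode -> decode round-trips on random records", {
  set.seed(17)
  for (k in 1:1000) {
    n <- sample(12:50, 1L)
    rec <- seq_struct_record("r", random_rna(n), pairs = random_structure(n))
    back <- decode12(encode12(rec), id = "r")
    expect_identical(back$seq, rec$seq)
    expect_identical(back$pairs, rec$pairs)
  }
})

test_that("identical records align without gaps at identity 1", {
  t2 <- its2_template()
  recs <- list(seq_struct_record("a", t2$seq, t2$pairs),
               seq_struct_record("b", t2$seq, t2$pairs))
  aln <- align_seqstruct(recs)
  expect_identical(ncol(aln$states), nchar(t2$seq))
  expect_true(all(aln$states != 0L))
  expect_true(all(aln$states[1, ] == aln$states[2, ]))
  expect_error(align_seqstruct(recs[1]), "at least two")
})

test_that("a single loop insertion yields exactly one gap column in the loop", {
  t2 <- its2_template()
  ch <- strsplit(t2$seq, "")[[1]]
  # insert into the central loop between helices I and II (positions 59-70)
  at <- 63L
  seq2 <- paste(c(ch[1:at], "A", ch[(at + 1L):length(ch)]), collapse = "")
  p2 <- t2$pairs
  p2[p2 > at] <- p2[p2 > at] + 1L
  aln <- align_seqstruct(list(seq_struct_record("a", t2$seq, t2$pairs),
                              seq_struct_record("b", seq2, p2)))
  gap_cols <- which(colSums(aln$states == 0L) > 0L)
  expect_length(gap_cols, 1L)
  expect_gt(gap_cols, 58L)
  expect_lt(gap_cols, 72L)
})

test_that("pairwise DP score equals the exhaustive oracle on short toys", {
  set.seed(41)
  score <- ss_score_params()
  for (k in 1:12) {
    na <- sample(4:8, 1L); nb <- sample(4:8, 1L)
    ra <- seq_struct_record("a", random_rna(na))
    rb <- seq_struct_record("b", random_rna(nb))
    sa <- encode12(ra); sb <- encode12(rb)
    got <- align_profiles(matrix(sa, 1, dimnames = list("a", NULL)),
                          matrix(sb, 1, dimnames = list("b", NULL)),
                          score)$score
    expect_equal(got, oracle_align_score(as.integer(sa), as.integer(sb),
                                         score),
                 info = paste(ra$seq, rb$seq))
  }
})

test_that("induced pairwise scores beat the unaligned diagonal baseline", {
  fam <- generate_family(synth_config(n_taxa = 5, seed = 12))
  score <- ss_score_params()
  recs <- lapply(fam$records, function(r) {
    iv <- fam$truth$intervals[[r$id]]$ITS2
    pr <- r$pairs
    keep <- pr[, 1L] >= iv[1L] & pr[, 2L] <= iv[2L]
    seq_struct_record(r$id, substr(r$seq, iv[1L], iv[2L]),
                      pairs = pr[keep, , drop = FALSE] - iv[1L] + 1L)
  })
  aln <- align_seqstruct(recs)
  M <- score$matrix
  for (a in 1:(length(recs) - 1L)) {
    for (b in (a + 1L):length(recs)) {
      ra <- aln$states[a, ]; rb <- aln$states[b, ]
      both <- ra != 0L & rb != 0L
      induced <- sum(M[cbind(ra[both], rb[both])])
      # diagonal baseline: position k against position k, no gaps
      sa <- ra[ra != 0L]; sb <- rb[rb != 0L]
      L <- min(length(sa), length(sb))
      baseline <- sum(M[cbind(sa[1:L], sb[1:L])])
      expect_gte(induced, baseline)
    }
  }
})

test_that("alignment is invariant to input order up to row permutation", {
  fam <- generate_family(synth_config(n_taxa = 5, seed = 21))
  recs <- lapply(fam$records, function(r) {
    iv <- fam$truth$intervals[[r$id]]$ITS2
    pr <- r$pairs
    keep <- pr[, 1L] >= iv[1L] & pr[, 2L] <= iv[2L]
    seq_struct_record(r$id, substr(r$seq, iv[1L], iv[2L]),
                      pairs = pr[keep, , drop = FALSE] - iv[1L] + 1L)
  })
  a1 <- align_seqstruct(recs)
  a2 <- align_seqstruct(rev(recs))
  expect_identical(a1$states[sort(a1$taxa), ], a2$states[sort(a2$taxa), ])
})

test_that("ungapping any row reproduces the original record", {
  fam <- generate_family(synth_config(n_taxa = 6, seed = 33))
  aln <- fam$truth$alignment
  for (rec in fam$records) {
    back <- aln_record(aln, rec$id)
    expect_identical(back$seq, rec$seq)
    expect_identical(back$pairs, rec$pairs)
  }
})

test_that("paired_columns respects the vote threshold", {
  # 4 rows pairing (2, 9); then break the pair in half the rows
  mk <- function(seq, db) {
    seq_struct_record("r", seq, pairs = dotbracket_to_pairs(db))
  }
  rows <- list(mk("AGAAAAAACA", ".(......)."),
               mk("AGAAAAAACA", ".(......)."),
               mk("AGAAAAAACA", ".........."),
               mk("AGAAAAAACA", ".........."))
  states <- do.call(rbind, lapply(rows, encode12))
  rownames(states) <- paste0("t", 1:4)
  aln <- itsstruct:::new_ssalignment(states, threshold = 0.5)
  expect_identical(unname(aln$paired_cols), cbind(2L, 9L))
  expect_identical(nrow(paired_columns(aln, threshold = 0.8)), 0L)
  # unanimous pairing reported at any threshold
  aln2 <- itsstruct:::new_ssalignment(states[1:2, ], threshold = 1)
  expect_identical(unname(aln2$paired_cols), cbind(2L, 9L))
})

test_that("externally supplied alignments load through the gapped interface", {
  aln <- ssalignment_from_gapped(
    c("a", "b"),
    c("AG-AAAAAACA", "AGUAAAAAACA"),
    c(".(.......).", ".(.......)."))
  expect_identical(ncol(aln$states), 11L)
  expect_identical(sum(aln$states == 0L), 1L)
  expect_identical(unname(aln$paired_cols), cbind(2L, 10L))
})
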