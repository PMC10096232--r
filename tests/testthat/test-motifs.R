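# Motif scanning and the pseudogene screen.

test_that("IUPAC degeneracy is honored", {
  h <- scan_motif("AAGUGCCAA", "GYGCC")
  expect_identical(h$start, 3L)
  expect_identical(h$end, 7L)
  h2 <- scan_motif("AAGCGCCAA", "GYGCC")
  expect_identical(h2$start, 3L)
  expect_identical(nrow(scan_motif("AAGAGCCAA", "GYGCC")), 0L)
  expect_error(scan_motif("ACGU", "GZG"), "non-IUPAC")
})

test_that("overlapping hits are all reported left to right", {
  # the printed Alhagi UGGU-region string contains GGU twice
  h <- scan_motif("GAUCGACGGUGGUUG", "GGU")
  expect_identical(h$start, c(8L, 11L))
  expect_identical(nrow(scan_motif("AAAAAA", "GGU")), 0L)
  h2 <- scan_motif("GGGG", "GG")
  expect_identical(h2$start, 1:3)
})

test_that("scan_motif equals the regex / Hamming oracle on random sequences", {
  set.seed(53)
  patterns <- c(ITS1_CORE_BLOCK2, MOTIF_5_8S_I, MOTIF_5_8S_II,
                MOTIF_5_8S_III, BOUNDARY_5_8S_ITS2, "UGGU", "AAA", "GYGCC")
  for (k in 1:1000) {
    seq <- random_rna(sample(30:120, 1L))
    pat <- sample(patterns, 1L)
    mm <- sample(0:1, 1L)
    got <- scan_motif(seq, pat, max_mismatches = mm)$start
    want <- oracle_motif_starts(seq, pat, mm)
    expect_identical(got, want, info = sprintf("%s in %s (mm=%d)", pat, seq, mm))
  }
})

test_that("two-block motifs respect the spacer range and shared budget", {
  seq <- paste0("AAA", "GGCGC", "ACAG", "GCGCCAAGGAA", "AAA")
  h <- scan_motif(seq, "GGCGC", block2 = "GYGCCAAGGAA",
                  spacer_range = c(3L, 6L), max_mismatches = 1L,
                  motif_name = "core")
  expect_identical(nrow(h), 1L)
  expect_identical(h$spacer_len, 4L)
  expect_identical(h$start, 4L)
  expect_identical(h$end, 23L)
  # spacer too long
  seq2 <- paste0("AAA", "GGCGC", "ACAGAAAA", "GCGCCAAGGAA", "AAA")
  expect_identical(nrow(scan_motif(seq2, "GGCGC", block2 = "GYGCCAAGGAA",
                                   spacer_range = c(3L, 6L))), 0L)
})

test_that("the packaged templates carry their diagnostic motifs", {
  its1 <- its1_template(); f58 <- rrna_5_8s_template(); its2 <- its2_template()
  expect_identical(nrow(scan_motif(its1$seq, ITS1_CORE_BLOCK1,
                                   block2 = ITS1_CORE_BLOCK2,
                                   spacer_range = c(3L, 6L))), 1L)
  for (m in c(MOTIF_5_8S_I, MOTIF_5_8S_II, MOTIF_5_8S_III)) {
    expect_identical(nrow(scan_motif(f58$seq, m)), 1L)
  }
  # boundary motif ends the 5.8S
  b <- scan_motif(f58$seq, BOUNDARY_5_8S_ITS2)
  expect_identical(b$end[nrow(b)], nchar(f58$seq))
  # UGGU on the 5' side of Helix III
  dec <- enumerate_helices(its2)
  h3 <- dec$helices[[3]]
  u <- scan_motif(its2$seq, "UGGU")
  expect_true(any(u$start >= h3$fiveprime_arm[1L] &
                    u$end <= h3$fiveprime_arm[2L]))
  # the conserved AAA spacer sits between helices II and III
  h2 <- dec$helices[[2]]
  a <- scan_motif(its2$seq, "AAA")
  expect_true(any(a$start > h2$threeprime_arm[2L] &
                    a$end < h3$fiveprime_arm[1L]))
  # Motif II sits 25 nt downstream (end-to-start) of the AAGAA copy in the
  # Helix 1 loop (Motif I itself contains another AAGAA)
  aagaa <- scan_motif(f58$seq, "AAGAA")
  loop_hit <- aagaa[aagaa$start > 16L, ][1L, ]
  m2 <- scan_motif(f58$seq, MOTIF_5_8S_II)
  expect_identical(m2$start[1L] - loop_hit$end - 1L, 25L)
})

test_that("the pseudogene screen passes clean synthetic records", {
  fam <- generate_family(synth_config(n_taxa = 6, seed = 10))
  for (rec in fam$records) {
    ann <- annotate_regions(rec)
    v <- screen_pseudogene(rec, ann)
    expect_true(v$pass, info = rec$id)
    expect_length(v$reasons, 0L)
  }
})

test_that("a heavily mutated 5.8S motif fails the screen with a reason", {
  fam <- generate_family(synth_config(n_taxa = 6, seed = 10))
  rec <- fam$records[[1]]
  ann <- annotate_regions(rec)
  iv <- ann$intervals$`5.8S`
  ch <- strsplit(rec$seq, "")[[1]]
  # mutate 3 positions of Motif I (budget is 1)
  m1_start <- iv[1L]
  ch[m1_start + c(1L, 5L, 9L)] <- c("C", "C", "C")
  mut <- seq_struct_record(rec$id, paste(ch, collapse = ""),
                           region = "FULL_ITS")
  v <- screen_pseudogene(mut, ann)
  expect_false(v$pass)
  expect_true(any(grepl("Motif I missing", v$reasons)))
})

test_that("length and GC bounds are enforced and the screen is monotone", {
  fam <- generate_family(synth_config(n_taxa = 6, seed = 10))
  rec <- fam$records[[1]]
  ann <- annotate_regions(rec)
  tight <- default_screen_bounds()
  tight$len$`5.8S` <- c(120L, 121L)
  v <- screen_pseudogene(rec, ann, len_bounds = tight$len)
  expect_false(v$pass)
  expect_true(any(grepl("5.8S length out of range", v$reasons)))
  # relaxing a bound never turns a pass into a fail
  loose <- default_screen_bounds()
  loose$gc <- lapply(loose$gc, function(x) c(0, 1))
  loose$len <- lapply(loose$len, function(x) c(0L, 10000L))
  v0 <- screen_pseudogene(rec, ann)
  v1 <- screen_pseudogene(rec, ann, gc_bounds = loose$gc,
                          len_bounds = loose$len)
  expect_true(!v0$pass || v1$pass)
  expect_true(v1$pass)
  # unresolved annotation errors
  bad <- ann
  bad$intervals$ITS2 <- c(NA_integer_, NA_integer_)
  expect_error(screen_pseudogene(rec, bad), "unresolved")
})
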