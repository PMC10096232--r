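# Packaged synthetic templates for the three ITS regions.
#
# These embody the canonical architecture of the plant nrDNA internal
# transcribed spacers: a four-helix ITS2 radiating from a central loop (with
# the UGGU landmark on the 5' side of Helix III, a U-U mismatch in Helix II
# and the conserved AAA spacer between helices II and III), a 5.8S gene of
# 160 nt carrying the three angiosperm motifs and ending in the CAUAU
# boundary motif, and an ITS1 whose universal core motif folds into a small
# hairpin. They are synthetic stand-ins constructed to satisfy every screen
# the package applies; no GenBank material is bundled.

rna_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# --- tiny structure builder -------------------------------------------------
# Elements: el_ss(seq) for unpaired runs; el_helix(arm5, interior, arm3, mask)
# for stems (arm3 defaults to the reverse complement of arm5; mask marks which
# stem rungs actually pair, allowing designed mismatches such as U-U).

el_ss <- function(seq) list(type = "ss", seq = seq)

el_helix <- function(arm5, interior, arm3 = rna_revcomp(arm5),
                     mask = rep(TRUE, nchar(arm5))) {
  stopifnot(nchar(arm5) == nchar(arm3), length(mask) == nchar(arm5))
  if (!is.list(interior) || !is.null(interior$type)) interior <- list(interior)
  list(type = "helix", arm5 = arm5, arm3 = arm3, mask = mask,
       interior = interior)
}

compile_elements <- function(elems, offset = 0L) {
  seq <- ""
  pairs <- list()
  pos <- offset
  for (e in elems) {
    if (e$type == "ss") {
      seq <- paste0(seq, e$seq)
      pos <- pos + nchar(e$seq)
    } else {
      n5 <- nchar(e$arm5)
      inner <- compile_elements(e$interior, offset = pos + n5)
      block_len <- n5 + nchar(inner$seq) + nchar(e$arm3)
      open_at <- pos + seq_len(n5)
      close_at <- pos + block_len + 1L - seq_len(n5)
      pairs <- c(pairs, list(cbind(open_at[e$mask], close_at[e$mask])),
                 list(inner$pairs))
      seq <- paste0(seq, e$arm5, inner$seq, e$arm3)
      pos <- pos + block_len
    }
  }
  list(seq = seq, pairs = do.call(rbind, c(pairs, list(matrix(integer(0), ncol = 2)))))
}

# Build a record from an element list, padding the 3' tail with `filler`
# (recycled) to reach `target_len` when given.
build_template <- function(id, elems, region, target_len = NULL,
                           filler = "ACUGAUCGUAGCAUCG") {
  comp <- compile_elements(elems)
  seq <- comp$seq
  if (!is.null(target_len)) {
    pad <- target_len - nchar(seq)
    if (pad < 0L) stop("template longer than target length")
    if (pad > 0L) {
      f <- paste(rep(filler, ceiling(pad / nchar(filler))), collapse = "")
      seq <- paste0(seq, substr(f, 1L, pad))
    }
  }
  seq_struct_record(id, seq, pairs = comp$pairs, region = region,
                    source = "user_supplied")
}

#' Packaged ITS2 template (four helices around a central loop)
#'
#' A synthetic 224-nt ITS2 whose structure shows the canonical eukaryote
#' architecture: four helices radiating from one central (multibranch) loop,
#' Helix III the longest with a `UGGU` motif on its 5' side near the apex,
#' a U-U mismatch in Helix II, and the conserved `AAA` spacer between
#' helices II and III.
#'
#' @return A [seq_struct_record()] with `region = "ITS2"`.
#' @export
its2_template <- function() {
  elems <- list(
    el_ss("ACGCAUCGAC"),
    # Helix I: 14-bp outer stem, 2-nt internal loop, 6-bp inner stem
    el_helix("GGCAGCAUGCAGGC",
             list(el_ss("AA"),
                  el_helix("GGGUCA", el_ss("UUCG")),
                  el_ss("UU"))),
    el_ss("UACAGACUGCAG"),
    # Helix II: 8-bp outer stem, designed U-U mismatch, 4-bp inner stem
    el_helix("GCUAGGCA",
             list(el_ss("U"),
                  el_helix("CAGC", el_ss("GCAA")),
                  el_ss("U"))),
    el_ss("AAA"),
    # Helix III (longest): 18-bp outer stem, 8-bp apical stem ending in UGGU
    el_helix("GACGGCCAUGCGUAGGCU",
             list(el_ss("CA"),
                  el_helix("GGCAUGGU", el_ss("GAAAC")),
                  el_ss("AG"))),
    el_ss("CACAGUAG"),
    # Helix IV: short 8-bp stem
    el_helix("GGUGCUAC", el_ss("GCGA"))
  )
  build_template("ITS2_template", elems, region = "ITS2", target_len = 224L,
                 filler = "AUCAGUGACCGAUUCAGA")
}

#' Packaged 5.8S template (central loop with four helices)
#'
#' A synthetic 160-nt 5.8S gene model: one central loop from which four
#' helices radiate, carrying the three conserved angiosperm motifs
#' (Motif I `CGAUGAAGAACGUAGC` at the 5' end, Motif II `GAAUUGCAGAAUCC`
#' placed 25 nt downstream of the `AAGAA` loop sequence of Helix 1, and
#' Motif III `UUUGAACGCA`), and ending in the `CAUAU` boundary motif that
#' marks the 5.8S-ITS2 junction. The final 10 nt are the 5' strand of the
#' proximal stem (they hybridize with the first 10 nt of 28S).
#'
#' @param extra Extra filler nucleotides (0-2) extending the gene to the
#'   observed 160-162 nt length range; default 0 (160 nt).
#' @return A [seq_struct_record()] with `region = "5.8S"`.
#' @export
rrna_5_8s_template <- function(extra = 0L) {
  stopifnot(extra >= 0L, extra <= 2L)
  elems <- list(
    el_ss(MOTIF_5_8S_I),
    # Helix 1; its loop carries the conserved AAGAA block
    el_helix("GGCUGAGCUC", el_ss("AAGAAU")),
    el_ss("CACGUCAUCGGAUC"),        # 14-nt spacer: Motif II starts 25 nt
    el_ss(MOTIF_5_8S_II),           # after the end of AAGAA
    el_helix("GGCAGC", el_ss("UUCG")),   # Helix 2
    el_ss("AC"),
    el_ss(MOTIF_5_8S_III),
    el_helix("GGAUGCGC", el_ss("GCAA")), # Helix 3
    el_ss("GU"),
    el_helix("GCAGU", el_ss("UUAC")),    # Helix 4
    el_ss(paste0("CAGUGACCGAUGCAGA", substr("GUA", 1L, extra))),
    el_ss(PROXIMAL_STEM_5_8S)       # 3' strand ending in CAUAU
  )
  rec <- build_template("5.8S_template", elems, region = "5.8S")
  stopifnot(nchar(rec$seq) == 160L + extra)
  rec
}

#' Packaged ITS1 template
#'
#' A synthetic 240-nt ITS1 with several hairpins; the angiosperm universal
#' core motif `GGCGC-(4n)-GYGCCAAGGAA` is present with its `GGCGC`/`GCGCC`
#' blocks base-paired to each other, so the motif itself forms a hairpin
#' (the arrangement expected of functional ITS copies).
#'
#' @return A [seq_struct_record()] with `region = "ITS1"`.
#' @export
its1_template <- function() {
  elems <- list(
    el_ss("GCAUCCGUAC"),
    el_helix("GGCAUGCGGAUC", el_ss("UGCAA")),      # Helix 1
    el_ss("AGCAUCCG"),
    el_helix("GCCAGUCGAC", el_ss("AAUG")),         # Helix 2
    el_ss("UCGAUACCUAGCGUA"),
    el_helix("GGCGC", el_ss("ACAG")),              # Helix 3: the core motif
    el_ss("AAGGAA"),
    el_ss("CUGAUCCAGUA"),
    el_helix("GGAUCGCAGA", el_ss("UUCG")),         # Helix 4
    el_ss("GAUCAGUCAAUGCA")
  )
  build_template("ITS1_template", elems, region = "ITS1", target_len = 240L,
                 filler = "AGUCAUCGAUGGACUA")
}

# Conserved motif constants (RNA alphabet).
MOTIF_5_8S_I <- "CGAUGAAGAACGUAGC"
MOTIF_5_8S_II <- "GAAUUGCAGAAUCC"
MOTIF_5_8S_III <- "UUUGAACGCA"
BOUNDARY_5_8S_ITS2 <- "CAUAU"
ITS1_CORE_BLOCK1 <- "GGCGC"
ITS1_CORE_BLOCK2 <- "GYGCCAAGGAA"

# 5.8S 3' strand of the proximal stem; ends in the CAUAU boundary motif.
PROXIMAL_STEM_5_8S <- "GGCACCAUAU"
# First 30 nt of the (synthetic) 28S; its head is the reverse complement of
# the 5.8S proximal-stem strand, closing the ITS2 multiloop when flanked.
HEAD_28S <- paste0(rna_revcomp(PROXIMAL_STEM_5_8S), "GACCUCAGAUCAGACGUGGC")

#' Flanked ITS2 template with proximal stem
#'
#' The packaged ITS2 template extended by 25 nt of 5.8S on the 5' side and
#' 25 nt of 28S on the 3' side; the terminal 10 nt of 5.8S hybridize with
#' the first 10 nt of 28S, forming the proximal stem that closes the ITS2
#' central loop.
#'
#' @param flank_len Flank length in nt (default 25).
#' @return A [seq_struct_record()] with `region = "OTHER"` and an attribute
#'   `"its2_offset"` giving the flank length.
#' @export
its2_proximal_template <- function(flank_len = 25L) {
  its2 <- its2_template()
  f58 <- rrna_5_8s_template()$seq
  ext <- add_flanks(its2$seq, f58, HEAD_28S, flank_len = flank_len)
  L <- nchar(its2$seq)
  stem_n <- nchar(PROXIMAL_STEM_5_8S)
  # flank positions flank_len-stem_n+1 .. flank_len pair with the first
  # stem_n positions of the 28S flank, outermost first
  k <- seq_len(stem_n)
  stem_pairs <- cbind(flank_len - stem_n + k, flank_len + L + stem_n + 1L - k)
  rec <- seq_struct_record("ITS2_proximal_template", ext$seq,
                           pairs = rbind(its2$pairs + flank_len, stem_pairs),
                           region = "OTHER", source = "user_supplied")
  attr(rec, "its2_offset") <- ext$offset
  rec
}
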