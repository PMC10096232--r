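# Diagnostic motif scanning (IUPAC patterns with a mismatch budget, single
# or two-block with a spacer range) and the pseudogene screen.

#' Scan a sequence for an IUPAC motif
#'
#' Reports every window (left to right, overlaps allowed) matching the
#' pattern within the mismatch budget; IUPAC degeneracy in the pattern is
#' honored (`Y` matches `C`/`U`, etc.). Two-block motifs are given as
#' `pattern` plus `block2` with a spacer length range; their hits span from
#' the start of block 1 to the end of block 2 and carry `spacer_len`, with
#' the mismatch budget shared across both blocks.
#'
#' @param seq RNA (or DNA, transcribed) sequence string.
#' @param pattern IUPAC pattern (block 1 for two-block motifs).
#' @param max_mismatches Total mismatch budget (default 0).
#' @param block2 Optional second block pattern.
#' @param spacer_range Length-2 integer range of allowed spacer lengths
#'   between the blocks (used only with `block2`).
#' @param motif_name Name reported in the hit table.
#' @return Data frame: `motif`, `start`, `end` (1-based inclusive),
#'   `mismatches`, `spacer_len` (`NA` for single-block motifs).
#' @export
scan_motif <- function(seq, pattern, max_mismatches = 0L, block2 = NULL,
                       spacer_range = c(0L, 0L), motif_name = pattern) {
  seq <- normalize_rna(seq, context = "scan_motif")
  pattern <- normalize_rna(pattern, context = "motif pattern")
  if (is.null(block2)) {
    h <- iupac_hits(seq, pattern, max_mismatches)
    return(data.frame(motif = rep(motif_name, nrow(h)), start = h$start,
                      end = h$end, mismatches = h$mismatches,
                      spacer_len = rep(NA_integer_, nrow(h))))
  }
  block2 <- normalize_rna(block2, context = "motif pattern")
  h1 <- iupac_hits(seq, pattern, max_mismatches)
  h2 <- iupac_hits(seq, block2, max_mismatches)
  out <- list()
  for (a in seq_len(nrow(h1))) {
    for (b in seq_len(nrow(h2))) {
      spacer <- h2$start[b] - h1$end[a] - 1L
      if (spacer >= spacer_range[1L] && spacer <= spacer_range[2L] &&
          h1$mismatches[a] + h2$mismatches[b] <= max_mismatches) {
        out[[length(out) + 1L]] <- data.frame(
          motif = motif_name, start = h1$start[a], end = h2$end[b],
          mismatches = h1$mismatches[a] + h2$mismatches[b],
          spacer_len = spacer)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0),
                      spacer_len = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

# All windows of `seq` matching the IUPAC `pattern` within `max_mismatches`,
# via Biostrings (degeneracy honored in the pattern only).
iupac_hits <- function(seq, pattern, max_mismatches) {
  subj <- Biostrings::DNAString(chartr("U", "T", seq))
  pat <- Biostrings::DNAString(chartr("U", "T", pattern))
  m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatches,
                                fixed = "subject")
  starts <- Biostrings::start(m)
  # drop partial matches hanging off either end of the subject
  inb <- starts >= 1L & starts + nchar(pattern) - 1L <= nchar(seq)
  starts <- starts[inb]
  if (length(starts) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0)))
  }
  mm <- vapply(starts, function(s) {
    iupac_mismatch_count(substr(seq, s, s + nchar(pattern) - 1L), pattern)
  }, 0L)
  data.frame(start = starts, end = starts + nchar(pattern) - 1L,
             mismatches = mm)
}

# Mismatches between a concrete window and an IUPAC pattern of equal length.
iupac_mismatch_count <- function(window, pattern) {
  w <- strsplit(window, "", fixed = TRUE)[[1]]
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  sum(vapply(seq_along(p), function(k) {
    !(w[k] %in% IUPAC_RNA[[p[k]]])
  }, TRUE))
}

#' The packaged motif catalog
#'
#' The diagnostic motifs screened by the package: the ITS1 angiosperm
#' universal core motif (`GGCGC` + 3-6 nt spacer + `GYGCCAAGGAA`), the three
#' conserved 5.8S motifs, the 5.8S/ITS2 boundary motif `CAUAU`, and the
#' ITS2 landmarks (`UGGU` variants on the 5' side of Helix III, the `AAA`
#' spacer between helices II and III).
#'
#' @return Data frame: `motif`, `region`, `pattern`, `block2`,
#'   `spacer_min`, `spacer_max`, `max_mismatches`.
#' @export
packaged_motifs <- function() {
  data.frame(
    motif = c("ITS1_core", "5.8S_motif_I", "5.8S_motif_II", "5.8S_motif_III",
              "5.8S_ITS2_boundary", "ITS2_UGGU", "ITS2_AAA_spacer"),
    region = c("ITS1", "5.8S", "5.8S", "5.8S", "5.8S", "ITS2", "ITS2"),
    pattern = c(ITS1_CORE_BLOCK1, MOTIF_5_8S_I, MOTIF_5_8S_II,
                MOTIF_5_8S_III, BOUNDARY_5_8S_ITS2, "UGGU", "AAA"),
    block2 = c(ITS1_CORE_BLOCK2, NA, NA, NA, NA, NA, NA),
    spacer_min = c(3L, NA, NA, NA, NA, NA, NA),
    spacer_max = c(6L, NA, NA, NA, NA, NA, NA),
    max_mismatches = c(1L, 1L, 1L, 1L, 0L, 0L, 0L),
    stringsAsFactors = FALSE
  )
}

#' Scan a record's regions for the packaged motifs
#'
#' @param record A [seq_struct_record()] (full ITS).
#' @param annotation A `RegionAnnotation` for the record.
#' @return Data frame of hits with a `region` column; coordinates are
#'   within-region (1-based).
#' @export
scan_packaged_motifs <- function(record, annotation) {
  cat_ <- packaged_motifs()
  out <- list()
  for (k in seq_len(nrow(cat_))) {
    reg <- cat_$region[k]
    iv <- annotation$intervals[[reg]]
    if (is.null(iv) || anyNA(iv)) next
    sub <- substr(record$seq, iv[1L], iv[2L])
    h <- scan_motif(sub, cat_$pattern[k],
                    max_mismatches = cat_$max_mismatches[k],
                    block2 = if (is.na(cat_$block2[k])) NULL else cat_$block2[k],
                    spacer_range = c(cat_$spacer_min[k], cat_$spacer_max[k]),
                    motif_name = cat_$motif[k])
    if (nrow(h) > 0L) {
      h$region <- reg
      h$record_id <- record$id
      out[[length(out) + 1L]] <- h
    }
  }
  if (length(out) == 0L) {
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0),
                      spacer_len = integer(0), region = character(0),
                      record_id = character(0)))
  }
  do.call(rbind, out)
}

#' Default per-region GC and length bounds for the pseudogene screen
#'
#' GC bounds are 45-60% for all regions; length bounds follow the observed
#' tribe-level ranges (ITS1 230-256 nt, 5.8S 160-162 nt, ITS2 220-228 nt).
#'
#' @return List with `gc` and `len`, each a named list of `c(min, max)`.
#' @export
default_screen_bounds <- function() {
  list(
    gc = list(ITS1 = c(0.45, 0.60), `5.8S` = c(0.45, 0.60),
              ITS2 = c(0.45, 0.60)),
    len = list(ITS1 = c(230L, 256L), `5.8S` = c(160L, 162L),
               ITS2 = c(220L, 228L))
  )
}

#' Screen a record for pseudogene signatures
#'
#' A record passes when the three conserved 5.8S motifs and the ITS1 core
#' motif are present within their mismatch budgets and every region's GC
#' content and length lie inside the bounds; the verdict enumerates every
#' failure. Functional rDNA copies are expected to pass; paralogs that lost
#' a motif or drifted in GC/length fail.
#'
#' @param record A [seq_struct_record()].
#' @param annotation A resolved `RegionAnnotation` for the record.
#' @param gc_bounds,len_bounds Per-region bounds as in
#'   [default_screen_bounds()].
#' @param motif_results Optional precomputed [scan_packaged_motifs()] table.
#' @return List of class `PseudogeneVerdict`: `record_id`, `pass`,
#'   `reasons`.
#' @export
screen_pseudogene <- function(record, annotation,
                              gc_bounds = default_screen_bounds()$gc,
                              len_bounds = default_screen_bounds()$len,
                              motif_results = NULL) {
  needed <- c("ITS1", "5.8S", "ITS2")
  for (reg in needed) {
    iv <- annotation$intervals[[reg]]
    if (is.null(iv) || anyNA(iv)) {
      stop(sprintf("%s: annotation unresolved for %s", record$id, reg))
    }
  }
  if (is.null(motif_results)) {
    motif_results <- scan_packaged_motifs(record, annotation)
  }
  reasons <- character(0)
  required <- c("5.8S_motif_I" = "5.8S Motif I missing",
                "5.8S_motif_II" = "5.8S Motif II missing",
                "5.8S_motif_III" = "5.8S Motif III missing",
                "ITS1_core" = "ITS1 core motif missing")
  for (m in names(required)) {
    if (!m %in% motif_results$motif) reasons <- c(reasons, required[[m]])
  }
  for (reg in needed) {
    iv <- annotation$intervals[[reg]]
    sub <- substr(record$seq, iv[1L], iv[2L])
    len <- nchar(sub)
    gc <- gc_content_seq(sub)
    lb <- len_bounds[[reg]]
    gb <- gc_bounds[[reg]]
    if (!is.null(lb) && (len < lb[1L] || len > lb[2L])) {
      reasons <- c(reasons, sprintf("%s length out of range (%d)", reg, len))
    }
    if (!is.null(gb) && (gc < gb[1L] || gc > gb[2L])) {
      reasons <- c(reasons, sprintf("%s GC out of range (%.3f)", reg, gc))
    }
  }
  structure(list(record_id = record$id, pass = length(reasons) == 0L,
                 reasons = unname(reasons)),
            class = "PseudogeneVerdict")
}

#' @export
print.PseudogeneVerdict <- function(x, ...) {
  cat(sprintf("<PseudogeneVerdict %s> %s%s\n", x$record_id,
              if (x$pass) "pass" else "FAIL",
              if (length(x$reasons) > 0L) {
                paste0(": ", paste(x$reasons, collapse = "; "))
              } else ""))
  invisible(x)
}
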