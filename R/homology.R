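# Template-based homology modeling: transfer a template's base pairs onto a
# target sequence through a global alignment, and decompose structures into
# helices around the central loop.

#' Transfer a template structure onto a target sequence
#'
#' The target is globally aligned to the template sequence; a template pair
#' `(i, j)` is transferred iff both columns align to target bases (no gap)
#' and those bases form an allowed pair (AU, GC or GU in either
#' orientation). Modeling a template against itself returns the template
#' pair set unchanged.
#'
#' @param target Target RNA sequence (string) or [seq_struct_record()].
#' @param template A [seq_struct_record()] with the template structure.
#' @param min_identity Minimum fraction of matching bases over aligned
#'   (ungapped) columns; below it the operation fails with
#'   "template too distant". Default 0.75.
#' @param gap_open,gap_extend Alignment gap penalties.
#' @param id Id for the returned record (defaults to the target's).
#' @return A [seq_struct_record()] with `source = "template_modeled"`.
#' @export
model_from_template <- function(target, template, min_identity = 0.75,
                                gap_open = 10, gap_extend = 0.5,
                                id = NULL) {
  stopifnot(inherits(template, "SeqStructRecord"),
            min_identity >= 0, min_identity <= 1)
  if (inherits(target, "SeqStructRecord")) {
    if (is.null(id)) id <- target$id
    tseq <- target$seq
    region <- target$region
  } else {
    if (is.null(id)) id <- "modeled"
    tseq <- normalize_rna(target, context = id)
    region <- template$region
  }
  if (!nzchar(tseq) || !nzchar(template$seq)) stop("empty input")
  map <- global_map(tseq, template$seq, gap_open, gap_extend)
  if (map$identity < min_identity) {
    stop(sprintf("template too distant: identity %.3f < %.3f",
                 map$identity, min_identity))
  }
  tch <- strsplit(tseq, "", fixed = TRUE)[[1]]
  tp <- template$pairs
  keep <- list()
  for (k in seq_len(nrow(tp))) {
    ti <- map$template_to_target[tp[k, 1L]]
    tj <- map$template_to_target[tp[k, 2L]]
    if (!is.na(ti) && !is.na(tj) &&
        is_allowed_pair(tch[ti], tch[tj])) {
      keep[[length(keep) + 1L]] <- c(ti, tj)
    }
  }
  seq_struct_record(id, tseq, pairs = do.call(rbind, keep), region = region,
                    source = "template_modeled")
}

# Global alignment of two unambiguous RNA sequences (Biostrings), returning
# the template-position -> target-position map and the fraction of identical
# bases over aligned ungapped columns.
global_map <- function(target, template, gap_open = 10, gap_extend = 0.5) {
  dna <- function(s) Biostrings::DNAString(chartr("U", "T", s))
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(dna(target), dna(template),
                                      type = "global",
                                      substitutionMatrix = sub,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  su <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  t2t <- rep(NA_integer_, nchar(template))
  pi_ <- 0L; si <- 0L; matches <- 0L; aligned_cols <- 0L
  for (k in seq_along(pa)) {
    if (pa[k] != "-") pi_ <- pi_ + 1L
    if (su[k] != "-") si <- si + 1L
    if (pa[k] != "-" && su[k] != "-") {
      t2t[si] <- pi_
      aligned_cols <- aligned_cols + 1L
      if (pa[k] == su[k]) matches <- matches + 1L
    }
  }
  list(template_to_target = t2t,
       identity = if (aligned_cols > 0L) matches / aligned_cols else 0)
}

#' Decompose a structure into helices around its central loop
#'
#' A helix is a maximal run of nested pairs in which consecutive pairs are
#' separated by at most `bulge_merge` unpaired nucleotides on either strand
#' (so small bulges and internal loops do not split a helix). Helices
#' attached directly to the outermost multiloop are labeled with Roman
#' numerals in 5' to 3' order; a stem that encloses that multiloop (the
#' 5.8S/28S hybrid in flanked ITS2 structures) is reported as the proximal
#' stem.
#'
#' @param record A [seq_struct_record()] with at least one pair.
#' @param bulge_merge Maximum unpaired run (nt, per strand) merged into a
#'   helix; default 6.
#' @return List of class `HelixDecomposition`: `helices` (each with
#'   `label`, `pairs`, `fiveprime_arm`, `threeprime_arm`), `proximal_stem`
#'   (pair matrix, possibly empty), `central_loop` (unpaired positions of
#'   the multiloop).
#' @export
enumerate_helices <- function(record, bulge_merge = 6L) {
  stopifnot(inherits(record, "SeqStructRecord"))
  pairs <- record$pairs
  if (nrow(pairs) == 0L) stop(sprintf("%s: unstructured record", record$id))
  n <- nchar(record$seq)
  np <- nrow(pairs)
  # parent pair of each pair (innermost enclosing), via a stack over sorted i
  parent <- rep(NA_integer_, np)
  children <- vector("list", np)
  stack <- integer(0)
  ord <- order(pairs[, 1L])
  for (k in ord) {
    while (length(stack) > 0L && pairs[stack[length(stack)], 2L] < pairs[k, 1L]) {
      stack <- stack[-length(stack)]
    }
    if (length(stack) > 0L) {
      parent[k] <- stack[length(stack)]
      children[[stack[length(stack)]]] <-
        c(children[[stack[length(stack)]]], k)
    }
    stack <- c(stack, k)
  }
  # group pairs into helices: a pair joins its parent's group iff it is the
  # parent's only child pair and the bulges on both strands are small
  group <- rep(NA_integer_, np)
  n_groups <- 0L
  for (k in ord) {
    p <- parent[k]
    if (!is.na(p) && length(children[[p]]) == 1L &&
        pairs[k, 1L] - pairs[p, 1L] - 1L <= bulge_merge &&
        pairs[p, 2L] - pairs[k, 2L] - 1L <= bulge_merge) {
      group[k] <- group[p]
    } else {
      n_groups <- n_groups + 1L
      group[k] <- n_groups
    }
  }
  # group adjacency: child groups of a group = groups of child pairs outside it
  outermost <- vapply(seq_len(n_groups), function(g) {
    ks <- which(group == g)
    ks[which.min(pairs[ks, 1L])]
  }, 0L)
  innermost <- vapply(seq_len(n_groups), function(g) {
    ks <- which(group == g)
    ks[which.max(pairs[ks, 1L])]
  }, 0L)
  group_parent <- vapply(seq_len(n_groups), function(g) {
    pp <- parent[outermost[g]]
    if (is.na(pp)) NA_integer_ else group[pp]
  }, 0L)
  group_children <- lapply(seq_len(n_groups), function(g) {
    which(group_parent == g)
  })
  # find the outermost multiloop: descend through single-child chain groups
  # (accumulated as the proximal stem) until a level with >= 2 groups; each
  # helix then owns its whole subtree of groups, so deeply nested stems
  # (separated by loops larger than bulge_merge) stay inside their helix
  top <- which(is.na(group_parent))
  stem_groups <- integer(0)
  level <- top
  while (length(level) == 1L && length(group_children[[level]]) >= 2L ||
         length(level) == 1L && length(group_children[[level]]) == 1L) {
    stem_groups <- c(stem_groups, level)
    kids <- group_children[[level]]
    level <- kids
    if (length(kids) >= 2L) break
  }
  if (length(level) == 1L && length(stem_groups) > 0L &&
      length(group_children[[level]]) == 0L) {
    # pure hairpin chain: nothing encloses a multiloop; the whole chain is
    # one helix, no proximal stem
    level <- stem_groups[1L]
    stem_groups <- integer(0)
  }
  helix_groups <- level[order(pairs[outermost[level], 1L])]
  subtree_groups <- function(g) {
    acc <- g
    queue <- group_children[[g]]
    while (length(queue) > 0L) {
      acc <- c(acc, queue[1L])
      queue <- c(queue[-1L], group_children[[queue[1L]]])
    }
    acc
  }
  helices <- lapply(seq_along(helix_groups), function(h) {
    gs <- subtree_groups(helix_groups[h])
    gp <- normalize_pairs(pairs[group %in% gs, , drop = FALSE])
    list(label = as.character(utils::as.roman(h)),
         pairs = gp,
         fiveprime_arm = c(min(gp[, 1L]), max(gp[, 1L])),
         threeprime_arm = c(min(gp[, 2L]), max(gp[, 2L])))
  })
  stem_pairs <- normalize_pairs(
    pairs[group %in% stem_groups, , drop = FALSE])
  # central loop: unpaired positions of the multiloop region not covered by
  # any helix span
  if (nrow(stem_pairs) > 0L) {
    inner <- stem_pairs[which.max(stem_pairs[, 1L]), ]
    loop_range <- (inner[1L] + 1L):(inner[2L] - 1L)
  } else {
    loop_range <- seq_len(n)
  }
  covered <- unlist(lapply(helices, function(h) {
    h$fiveprime_arm[1L]:h$threeprime_arm[2L]
  }))
  central_loop <- setdiff(loop_range, covered)
  central_loop <- central_loop[!central_loop %in% as.vector(pairs)]
  structure(list(helices = helices, proximal_stem = stem_pairs,
                 central_loop = central_loop, bulge_merge = bulge_merge),
            class = "HelixDecomposition")
}

#' @export
print.HelixDecomposition <- function(x, ...) {
  cat(sprintf("<HelixDecomposition> %d helices%s; central loop %d nt\n",
              length(x$helices),
              if (nrow(x$proximal_stem) > 0L) {
                sprintf(" + proximal stem (%d bp)", nrow(x$proximal_stem))
              } else "",
              length(x$central_loop)))
  for (h in x$helices) {
    cat(sprintf("  Helix %-4s %2d bp  5' %d-%d / 3' %d-%d\n", h$label,
                nrow(h$pairs), h$fiveprime_arm[1L], h$fiveprime_arm[2L],
                h$threeprime_arm[1L], h$threeprime_arm[2L]))
  }
  invisible(x)
}

#' Flatten a decomposition back to one pair matrix
#'
#' Union of the proximal-stem pairs and every helix's pairs; by the
#' partition property this equals the decomposed record's pair set.
#'
#' @param decomp A `HelixDecomposition`.
#' @return Two-column integer pair matrix.
#' @export
decomposition_pairs <- function(decomp) {
  normalize_pairs(rbind(decomp$proximal_stem,
                        do.call(rbind, lapply(decomp$helices, `[[`, "pairs"))))
}

#' Per-position helix labels of a decomposed structure
#'
#' Positions inside a helix's arms (including merged bulges) get the helix
#' label, proximal-stem arm positions get `"skeleton"`, everything else
#' (central loop, hairpin loops, tails) gets `"loop"`.
#'
#' @param decomp A `HelixDecomposition`.
#' @param len Sequence length.
#' @return Character vector of length `len`.
#' @export
position_helix_labels <- function(decomp, len) {
  lab <- rep("loop", len)
  if (nrow(decomp$proximal_stem) > 0L) {
    sp <- decomp$proximal_stem
    lab[min(sp[, 1L]):max(sp[, 1L])] <- "skeleton"
    lab[min(sp[, 2L]):max(sp[, 2L])] <- "skeleton"
  }
  for (h in decomp$helices) {
    lab[h$fiveprime_arm[1L]:h$fiveprime_arm[2L]] <- h$label
    lab[h$threeprime_arm[1L]:h$threeprime_arm[2L]] <- h$label
  }
  lab
}

#' Map a reference taxon's helix labels onto alignment columns
#'
#' @param aln A `SeqStructAlignment`.
#' @param taxon Reference taxon whose structure was decomposed.
#' @param decomp [enumerate_helices()] result for that taxon's record.
#' @return Character vector, one label per aligned column (`"loop"` where
#'   the reference row is gapped).
#' @export
column_helix_labels <- function(aln, taxon, decomp) {
  r <- match(taxon, aln$taxa)
  if (is.na(r)) stop(sprintf("taxon not in alignment: %s", taxon))
  row <- aln$states[r, ]
  pos_lab <- position_helix_labels(decomp, sum(row != 0L))
  out <- rep("loop", ncol(aln$states))
  out[row != 0L] <- pos_lab
  out
}
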