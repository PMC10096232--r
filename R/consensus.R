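# Per-group consensus sequence-structures, 100%-conserved positions and
# pairs, and per-helix statistics.

#' Subset an alignment to a set of taxa
#'
#' Rows are subset and column pairing votes recomputed; columns are kept
#' (all-gap columns may remain, preserving column numbering).
#'
#' @param aln A `SeqStructAlignment`.
#' @param taxa Taxa to keep.
#' @param threshold Pairing vote threshold for the recomputed
#'   `paired_cols`.
#' @return A `SeqStructAlignment`.
#' @export
aln_subset <- function(aln, taxa, threshold = 0.5) {
  missing <- setdiff(taxa, aln$taxa)
  if (length(missing) > 0L) {
    stop(sprintf("taxon not in alignment: %s", missing[1L]))
  }
  new_ssalignment(aln$states[taxa, , drop = FALSE], threshold = threshold)
}

#' Build a per-group consensus sequence-structure
#'
#' The consensus base of a column is the minimal IUPAC code covering the
#' bases observed in ungapped rows; its conservation is the plurality
#' fraction (share of ungapped rows carrying the most common base).
#' Consensus pairs are the column pairs supported by at least
#' `pair_threshold` of the pairing votes ([paired_columns()]); the
#' 100%-conserved subset contains those pairs that every member ungapped at
#' both columns pairs with an allowed base pair.
#'
#' @param aln A `SeqStructAlignment`.
#' @param group_members Taxa of the group (at least 2).
#' @param group Group label carried in the result.
#' @param pair_threshold Vote threshold for consensus pairs (default 0.5).
#' @return List of class `ConsensusModel`: `group`, `members`,
#'   `consensus_seq` (IUPAC, `-` for all-gap columns), `consensus_pairs`,
#'   `conserved_pairs_100`, `conservation` (per column, `NA` where all
#'   rows are gapped).
#' @export
build_consensus <- function(aln, group_members, group = "group",
                            pair_threshold = 0.5) {
  if (length(group_members) < 2L) {
    stop("consensus requires a group of at least 2 members")
  }
  sub <- aln_subset(aln, group_members, threshold = pair_threshold)
  bases <- aln_base_matrix(sub)
  L <- ncol(bases)
  consensus_seq <- character(L)
  conservation <- rep(NA_real_, L)
  for (col in seq_len(L)) {
    obs <- bases[, col]
    obs <- obs[!is.na(obs)]
    if (length(obs) == 0L) {
      consensus_seq[col] <- "-"
      next
    }
    consensus_seq[col] <- merge_iupac(unique(obs))
    tab <- table(obs)
    conservation[col] <- max(tab) / length(obs)
  }
  consensus_pairs <- sub$paired_cols
  conserved <- logical(nrow(consensus_pairs))
  for (k in seq_len(nrow(consensus_pairs))) {
    p <- consensus_pairs[k, 1L]; q <- consensus_pairs[k, 2L]
    ok <- TRUE
    for (r in seq_len(nrow(sub$states))) {
      if (sub$states[r, p] == 0L || sub$states[r, q] == 0L) next
      role_p <- state_role(sub$states[r, p])
      partner_ok <- FALSE
      if (role_p == "open") {
        ng <- which(sub$states[r, ] != 0L)
        partner <- partner_from_states(sub$states[r, ng])
        kpos <- match(p, ng)
        partner_ok <- !is.na(partner[kpos]) && ng[partner[kpos]] == q
      }
      if (!partner_ok ||
          !is_allowed_pair(bases[r, p], bases[r, q])) {
        ok <- FALSE
        break
      }
    }
    conserved[k] <- ok
  }
  structure(list(group = group, members = group_members,
                 consensus_seq = paste(consensus_seq, collapse = ""),
                 consensus_pairs = consensus_pairs,
                 conserved_pairs_100 =
                   consensus_pairs[conserved, , drop = FALSE],
                 conservation = conservation,
                 alignment = sub),
            class = "ConsensusModel")
}

# Minimal IUPAC code covering a set of RNA bases.
merge_iupac <- function(bases) {
  bases <- sort(unique(bases))
  dna <- chartr("U", "T", paste(bases, collapse = ""))
  chartr("T", "U", Biostrings::mergeIUPACLetters(dna))
}

#' @export
print.ConsensusModel <- function(x, ...) {
  cat(sprintf("<ConsensusModel %s> %d members, %d columns, %d consensus pairs (%d at 100%%)\n",
              x$group, length(x$members), nchar(x$consensus_seq),
              nrow(x$consensus_pairs), nrow(x$conserved_pairs_100)))
  invisible(x)
}

#' Consensus model as a sequence-structure record
#'
#' Ungapped consensus sequence with the consensus pairs mapped to ungapped
#' coordinates; writable with [write_vienna()].
#'
#' @param model A `ConsensusModel`.
#' @return A [seq_struct_record()].
#' @export
consensus_record <- function(model) {
  ch <- strsplit(model$consensus_seq, "", fixed = TRUE)[[1]]
  keep <- ch != "-"
  newpos <- cumsum(keep)
  pr <- model$consensus_pairs
  pr <- pr[keep[pr[, 1L]] & keep[pr[, 2L]], , drop = FALSE]
  seq_struct_record(paste0("consensus_", model$group),
                    paste(ch[keep], collapse = ""),
                    pairs = cbind(newpos[pr[, 1L]], newpos[pr[, 2L]]))
}

#' Per-helix statistics of a consensus model
#'
#' For every helix of the decomposition: length in pairs, GC and G-U pair
#' fractions (computed on the plurality consensus bases), variability
#' (columns with at least two observed states over helix columns), and
#' transition / transversion counts (distinct derived bases per column
#' relative to the plurality base; transitions are A-G and C-U).
#'
#' @param model A `ConsensusModel`.
#' @param decomp A `HelixDecomposition` of the consensus structure, in
#'   alignment-column coordinates (e.g. `enumerate_helices` on a record
#'   built from the consensus columns).
#' @return Data frame with one row per helix (and one for the proximal
#'   stem when present).
#' @export
helix_stats <- function(model, decomp) {
  bases <- aln_base_matrix(model$alignment)
  plurality <- function(col) {
    obs <- bases[, col]; obs <- obs[!is.na(obs)]
    if (length(obs) == 0L) return(NA_character_)
    tab <- table(obs)
    names(tab)[which.max(tab)]
  }
  one <- function(label, pairs) {
    cols <- as.vector(pairs)
    b5 <- vapply(pairs[, 1L], plurality, "")
    b3 <- vapply(pairs[, 2L], plurality, "")
    ty <- pair_type(b5, b3)
    n_var <- 0L; ti <- 0L; tv <- 0L
    for (col in cols) {
      obs <- bases[, col]; obs <- obs[!is.na(obs)]
      ub <- unique(obs)
      if (length(ub) >= 2L) n_var <- n_var + 1L
      cons <- plurality(col)
      for (b in setdiff(ub, cons)) {
        if (paste0(sort(c(b, cons)), collapse = "") %in% c("AG", "CU")) {
          ti <- ti + 1L
        } else {
          tv <- tv + 1L
        }
      }
    }
    data.frame(helix = label, length_pairs = nrow(pairs),
               gc_fraction = mean(!is.na(ty) & ty == "GC"),
               gu_fraction = mean(!is.na(ty) & ty == "GU"),
               variability = if (length(cols) > 0L) n_var / length(cols) else NA,
               ti = ti, tv = tv)
  }
  rows <- lapply(decomp$helices, function(h) one(h$label, h$pairs))
  if (nrow(decomp$proximal_stem) > 0L) {
    rows <- c(rows, list(one("proximal_stem", decomp$proximal_stem)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a consensus model as a Vienna file plus conservation table
#'
#' @param model A `ConsensusModel`.
#' @param vienna_path,conservation_path Output paths (either may be `NULL`
#'   to skip).
#' @return Invisibly, the paths written.
#' @export
write_consensus <- function(model, vienna_path = NULL,
                            conservation_path = NULL) {
  if (!is.null(vienna_path)) {
    write_vienna(list(consensus_record(model)), vienna_path)
  }
  if (!is.null(conservation_path)) {
    utils::write.table(
      data.frame(column = seq_along(model$conservation),
                 consensus = strsplit(model$consensus_seq, "")[[1]],
                 conservation = model$conservation),
      conservation_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(vienna_path, conservation_path))
}
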