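# Synchronized sequence-structure alignment: records are encoded in the
# 12-state joint alphabet (4 bases x 3 structural roles) and aligned
# progressively along an NJ guide tree, profile against profile, with an
# affine-gap Needleman-Wunsch on expected joint-state scores.

#' Scoring parameters for the joint 12-state alphabet
#'
#' The substitution score of two joint states is the sum of a sequence
#' component (match / transition / transversion) and a structure component
#' (same role / unpaired vs paired / open vs close). The matrix is a
#' declared parameter of the method, not an empirical claim.
#'
#' @param seq_match,seq_transition,seq_transversion Sequence component.
#' @param struct_same,struct_unpaired_paired,struct_open_close Structure
#'   component.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return List of class `SSScoreParams` with the 12x12 matrix in `$matrix`.
#' @export
ss_score_params <- function(seq_match = 2, seq_transition = -1,
                            seq_transversion = -2, struct_same = 1,
                            struct_unpaired_paired = -2,
                            struct_open_close = -3,
                            gap_open = 5, gap_extend = 1) {
  bases <- rep(RNA_BASES, each = 3L)
  roles <- rep(ROLES, times = 4L)
  n <- 12L
  M <- matrix(0, n, n)
  transitions <- c(AG = TRUE, GA = TRUE, CU = TRUE, UC = TRUE)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (bases[s] == bases[t]) {
        sc <- seq_match
      } else if (isTRUE(transitions[paste0(bases[s], bases[t])])) {
        sc <- seq_transition
      } else {
        sc <- seq_transversion
      }
      if (roles[s] == roles[t]) {
        st <- struct_same
      } else if (all(c(roles[s], roles[t]) %in% c("open", "close"))) {
        st <- struct_open_close
      } else {
        st <- struct_unpaired_paired
      }
      M[s, t] <- sc + st
    }
  }
  structure(list(matrix = M, gap_open = gap_open, gap_extend = gap_extend),
            class = "SSScoreParams")
}

# Affine-gap global alignment of two score grids, vectorized along
# anti-diagonals. G is the (LA x LB) expected-score grid. Returns the
# aligned index paths (0 = gap) and the optimal score.
affine_align_grid <- function(G, gap_open, gap_extend) {
  LA <- nrow(G); LB <- ncol(G)
  nr <- LA + 1L; nc <- LB + 1L
  NEG <- -1e18
  M <- matrix(NEG, nr, nc); X <- matrix(NEG, nr, nc); Y <- matrix(NEG, nr, nc)
  M[1L, 1L] <- 0
  if (LA > 0L) X[2L:nr, 1L] <- -gap_open - (0L:(LA - 1L)) * gap_extend
  if (LB > 0L) Y[1L, 2L:nc] <- -gap_open - (0L:(LB - 1L)) * gap_extend
  for (d in 3L:(nr + nc)) {
    i <- max(2L, d - nc):min(nr, d - 1L)
    j <- d - i
    keep <- j >= 1L & j <= nc
    i <- i[keep]; j <- j[keep]
    if (length(i) == 0L) next
    ij <- i + (j - 1L) * nr
    # X: gap in the second profile (consume row of first)
    up <- (i - 1L) + (j - 1L) * nr
    X[ij] <- pmax(M[up] - gap_open, X[up] - gap_extend, Y[up] - gap_open)
    # Y: gap in the first profile
    left <- i + (j - 2L) * nr
    ok <- j >= 2L
    Y[ij[ok]] <- pmax(M[left[ok]] - gap_open, X[left[ok]] - gap_open,
                      Y[left[ok]] - gap_extend)
    # M: aligned pair of columns
    okm <- i >= 2L & j >= 2L
    if (any(okm)) {
      diag <- (i[okm] - 1L) + (j[okm] - 2L) * nr
      g <- G[(i[okm] - 1L) + (j[okm] - 2L) * LA]
      M[ij[okm]] <- g + pmax(M[diag], X[diag], Y[diag])
    }
  }
  # traceback; ties broken M > X > Y (prefer substitution over gaps)
  i <- nr; j <- nc
  vals <- c(M[i, j], X[i, j], Y[i, j])
  layer <- which.max(vals)
  score <- vals[layer]
  pa <- integer(0); pb <- integer(0)
  eps <- 1e-9
  while (i > 1L || j > 1L) {
    if (layer == 1L) {
      g <- G[i - 1L, j - 1L]
      prev <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      layer_next <- which(abs(prev + g - M[i, j]) < eps)[1L]
      pa <- c(i - 1L, pa); pb <- c(j - 1L, pb)
      i <- i - 1L; j <- j - 1L
      layer <- layer_next
    } else if (layer == 2L) {
      prev <- c(M[i - 1L, j] - gap_open, X[i - 1L, j] - gap_extend,
                Y[i - 1L, j] - gap_open)
      layer_next <- which(abs(prev - X[i, j]) < eps)[1L]
      pa <- c(i - 1L, pa); pb <- c(0L, pb)
      i <- i - 1L
      layer <- layer_next
    } else {
      prev <- c(M[i, j - 1L] - gap_open, X[i, j - 1L] - gap_open,
                Y[i, j - 1L] - gap_extend)
      layer_next <- which(abs(prev - Y[i, j]) < eps)[1L]
      pa <- c(0L, pa); pb <- c(j - 1L, pb)
      j <- j - 1L
      layer <- layer_next
    }
    if (is.na(layer)) stop("alignment traceback failed")
  }
  list(path_a = pa, path_b = pb, score = score)
}

# Frequency matrix (12 x L) of a profile's non-gap states; column sums may
# be < 1 where rows are gapped (gaps contribute score 0).
profile_freq <- function(states) {
  n <- nrow(states); L <- ncol(states)
  F <- matrix(0, 12L, L)
  for (s in seq_len(12L)) F[s, ] <- colSums(states == s)
  F / n
}

# Align two profiles (integer state matrices); returns the merged matrix.
align_profiles <- function(A, B, score) {
  G <- crossprod(profile_freq(A), score$matrix %*% profile_freq(B))
  al <- affine_align_grid(G, score$gap_open, score$gap_extend)
  L <- length(al$path_a)
  out <- matrix(0L, nrow(A) + nrow(B), L,
                dimnames = list(c(rownames(A), rownames(B)), NULL))
  out[seq_len(nrow(A)), al$path_a > 0L] <- A[, al$path_a[al$path_a > 0L], drop = FALSE]
  out[nrow(A) + seq_len(nrow(B)), al$path_b > 0L] <-
    B[, al$path_b[al$path_b > 0L], drop = FALSE]
  list(states = out, score = al$score)
}

# Construct the alignment object from a state matrix with rownames = taxa.
new_ssalignment <- function(states, records = NULL, threshold = 0.5) {
  taxa <- rownames(states)
  col_map <- lapply(seq_len(nrow(states)), function(r) {
    cm <- rep(NA_integer_, ncol(states))
    ng <- states[r, ] != 0L
    cm[ng] <- seq_len(sum(ng))
    cm
  })
  names(col_map) <- taxa
  aln <- structure(list(taxa = taxa, states = states, col_map = col_map,
                        paired_cols = NULL),
                   class = "SeqStructAlignment")
  aln$paired_cols <- paired_columns(aln, threshold = threshold)
  aln
}

#' @export
print.SeqStructAlignment <- function(x, ...) {
  cat(sprintf("<SeqStructAlignment> %d taxa x %d columns, %d paired columns\n",
              nrow(x$states), ncol(x$states), nrow(x$paired_cols)))
  invisible(x)
}

#' Progressive synchronized sequence-structure alignment
#'
#' Records are encoded with [encode12()] and aligned progressively along a
#' neighbor-joining guide tree built from pairwise joint-state p-distances.
#' The result is deterministic for fixed inputs; input order only permutes
#' rows.
#'
#' @param records List of at least two [seq_struct_record()] objects with
#'   unique ids.
#' @param score A [ss_score_params()] object.
#' @param threshold Column-pairing vote threshold passed to
#'   [paired_columns()].
#' @return A `SeqStructAlignment`: `taxa`, `states` (rows = taxa, 0 = gap),
#'   `col_map` (aligned column to original position per taxon), and
#'   `paired_cols`.
#' @export
align_seqstruct <- function(records, score = ss_score_params(),
                            threshold = 0.5) {
  if (length(records) < 2L) stop("need at least two records to align")
  ids <- vapply(records, function(r) r$id, "")
  if (anyDuplicated(ids)) stop("duplicate record ids")
  enc <- lapply(records, function(r) {
    st <- encode12(r)
    matrix(st, nrow = 1L, dimnames = list(r$id, NULL))
  })
  n <- length(enc)
  if (n == 2L) {
    merged <- align_profiles(enc[[1L]], enc[[2L]], score)$states
    rownames(merged) <- ids
    return(new_ssalignment(merged, threshold = threshold))
  }
  # guide distances: joint-state p-distance on each pairwise alignment
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      m <- align_profiles(enc[[a]], enc[[b]], score)$states
      both <- m[1L, ] != 0L & m[2L, ] != 0L
      D[a, b] <- D[b, a] <- if (any(both)) {
        mean(m[1L, both] != m[2L, both])
      } else 1
    }
  }
  guide <- phangorn::midpoint(ape::nj(stats::as.dist(D)))
  merged <- merge_along_tree(guide, enc, score)
  merged <- merged[ids, , drop = FALSE]
  new_ssalignment(merged, threshold = threshold)
}

# Postorder profile merging along a rooted guide tree.
merge_along_tree <- function(tree, enc, score) {
  ids <- vapply(enc, function(m) rownames(m), "")
  n_tip <- length(tree$tip.label)
  profiles <- vector("list", n_tip + tree$Nnode)
  for (k in seq_len(n_tip)) {
    profiles[[k]] <- enc[[match(tree$tip.label[k], ids)]]
  }
  edges <- tree$edge
  po <- ape::postorder(tree)
  for (e in po) {
    parent <- edges[e, 1L]; child <- edges[e, 2L]
    if (is.null(profiles[[parent]])) {
      profiles[[parent]] <- profiles[[child]]
    } else {
      profiles[[parent]] <- align_profiles(profiles[[parent]],
                                           profiles[[child]], score)$states
    }
  }
  root <- n_tip + 1L
  profiles[[root]]
}

#' Structurally complementary column pairs of an alignment
#'
#' A column pair `(p, q)` is reported when at least `threshold` of the rows
#' that are ungapped at `p` carry an opening state at `p` whose structural
#' partner maps to `q`. Gapped rows do not vote. Columns are used at most
#' once; conflicts are resolved by vote count, then by smaller `p`.
#'
#' @param aln A `SeqStructAlignment`.
#' @param threshold Fraction in (0, 1].
#' @return Two-column integer matrix `(p, q)` sorted by `p`.
#' @export
paired_columns <- function(aln, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  states <- aln$states
  n <- nrow(states); L <- ncol(states)
  votes <- new.env(hash = TRUE)
  ungapped <- colSums(states != 0L)
  for (r in seq_len(n)) {
    row <- states[r, ]
    ng <- which(row != 0L)
    orig_states <- row[ng]
    rec_partner <- partner_from_states(orig_states)
    open_here <- which(state_role(orig_states) == "open")
    for (k in open_here) {
      p <- ng[k]; q <- ng[rec_partner[k]]
      key <- paste0(p, "_", q)
      votes[[key]] <- (if (is.null(votes[[key]])) 0L else votes[[key]]) + 1L
    }
  }
  keys <- ls(votes)
  if (length(keys) == 0L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("p", "q"))))
  }
  pq <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
  p <- as.integer(pq[, 1L]); q <- as.integer(pq[, 2L])
  v <- vapply(keys, function(k) votes[[k]], 0L)
  keep <- v >= threshold * ungapped[p] & ungapped[p] > 0L
  p <- p[keep]; q <- q[keep]; v <- v[keep]
  ord <- order(-v, p, q)
  used <- logical(L)
  sel <- logical(length(ord))
  for (k in ord) {
    if (!used[p[k]] && !used[q[k]]) {
      used[p[k]] <- used[q[k]] <- TRUE
      sel[k] <- TRUE
    }
  }
  out <- cbind(p = p[sel], q = q[sel])
  out[order(out[, 1L]), , drop = FALSE]
}

# Partner indices (in ungapped coordinates) recovered from a gap-free state
# vector by matching open/close roles with a stack.
partner_from_states <- function(states) {
  role <- state_role(states)
  n <- length(states)
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  for (k in seq_len(n)) {
    if (role[k] == "open") {
      stack <- c(stack, k)
    } else if (role[k] == "close") {
      if (length(stack) == 0L) stop("unbalanced structural roles in row")
      partner[k] <- stack[length(stack)]
      partner[stack[length(stack)]] <- k
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0L) stop("unbalanced structural roles in row")
  partner
}

#' Extract one row of an alignment as a record
#'
#' Ungaps the row and decodes it; by construction this reproduces the
#' original sequence and structure.
#'
#' @param aln A `SeqStructAlignment`.
#' @param taxon Taxon id.
#' @return A [seq_struct_record()].
#' @export
aln_record <- function(aln, taxon) {
  r <- match(taxon, aln$taxa)
  if (is.na(r)) stop(sprintf("taxon not in alignment: %s", taxon))
  row <- aln$states[r, ]
  decode12(row[row != 0L], id = taxon)
}

# Character matrix of bases (NA for gaps): sequence projection of the
# alignment, used by the diversity and distance modules.
aln_base_matrix <- function(aln) {
  m <- matrix(state_base(aln$states), nrow = nrow(aln$states),
              dimnames = list(aln$taxa, NULL))
  m
}

#' Build an alignment object from pre-aligned records
#'
#' Supports externally produced (e.g. hand-adjusted) alignments: rows are
#' supplied as gapped sequences plus gapped dot-bracket structures.
#'
#' @param ids Character vector of taxon ids.
#' @param gapped_seqs Gapped sequences (equal lengths, `-` for gaps).
#' @param gapped_dbs Gapped dot-bracket strings matching `gapped_seqs`.
#' @param threshold Pairing vote threshold for [paired_columns()].
#' @return A `SeqStructAlignment`.
#' @export
ssalignment_from_gapped <- function(ids, gapped_seqs, gapped_dbs,
                                    threshold = 0.5) {
  stopifnot(length(ids) == length(gapped_seqs),
            length(ids) == length(gapped_dbs))
  L <- unique(nchar(gapped_seqs))
  if (length(L) != 1L || any(nchar(gapped_dbs) != L)) {
    stop("gapped rows must share one length")
  }
  states <- matrix(0L, length(ids), L, dimnames = list(ids, NULL))
  for (r in seq_along(ids)) {
    sch <- strsplit(normalize_rna(gapped_seqs[r], allow_gap = TRUE,
                                  context = ids[r]), "", fixed = TRUE)[[1]]
    dch <- strsplit(gapped_dbs[r], "", fixed = TRUE)[[1]]
    ng <- sch != "-"
    if (any(dch[!ng] != "-" & dch[!ng] != ".")) {
      stop(sprintf("%s: structure present where sequence is gapped", ids[r]))
    }
    rec <- seq_struct_record(ids[r], paste(sch[ng], collapse = ""),
                             pairs = dotbracket_to_pairs(
                               paste(dch[ng], collapse = "")))
    states[r, ng] <- encode12(rec)
  }
  new_ssalignment(states, threshold = threshold)
}
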