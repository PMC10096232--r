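# Independent oracles used across the suite. Each is written from first
# principles and deliberately shares no code path with the implementation.

# --- exhaustive folding oracle ----------------------------------------------
# Enumerate every nested structure (as pair matrices) of a character vector,
# honoring the minimum hairpin size, and return the best score under the
# given parameters (stacking bonus applied when (i+1, j-1) is also paired).

oracle_can_pair <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

oracle_enum_structures <- function(ch, mh = 3L) {
  n <- length(ch)
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    if (i > j) return(list(matrix(integer(0), ncol = 2)))
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- lapply(rec(i + 1L, j), identity)      # i unpaired
    for (k in seq_len(j)) {
      if (k - i <= mh || !oracle_can_pair(ch[i], ch[k])) next
      inner <- rec(i + 1L, k - 1L)
      outer <- rec(k + 1L, j)
      for (a in inner) {
        for (b in outer) {
          out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
        }
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

oracle_score_structure <- function(pairs, ch, params) {
  if (nrow(pairs) == 0L) return(0)
  has <- paste(pairs[, 1L], pairs[, 2L])
  total <- 0
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    base <- if (params$scoring == "pair_count") 1 else {
      ty <- c(AU = "AU", UA = "AU", GC = "GC", CG = "GC",
              GU = "GU", UG = "GU")[paste0(ch[i], ch[j])]
      unname(params$pair_scores[ty])
    }
    stackb <- if (params$scoring == "pair_count") 0 else params$stack_bonus
    total <- total + base +
      if (paste(i + 1L, j - 1L) %in% has) stackb else 0
  }
  total
}

oracle_best_fold_score <- function(seq, params) {
  ch <- strsplit(seq, "")[[1]]
  structs <- oracle_enum_structures(ch, params$min_hairpin)
  max(vapply(structs, oracle_score_structure, 0, ch = ch, params = params))
}

# --- exhaustive pairwise alignment oracle -----------------------------------
# Max global alignment score of two state vectors under the joint matrix and
# affine gaps, by plain recursion over (i, j, previous move) with memoization.

oracle_align_score <- function(sa, sb, score) {
  M <- score$matrix; go <- score$gap_open; ge <- score$gap_extend
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, prev) {
    if (i == 0L && j == 0L) return(0)
    key <- paste(i, j, prev)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    if (i > 0L && j > 0L) {
      best <- max(best, rec(i - 1L, j - 1L, "m") + M[sa[i], sb[j]])
    }
    if (i > 0L) {
      cost <- if (prev == "a") ge else go
      best <- max(best, rec(i - 1L, j, "a") - cost)
    }
    if (j > 0L) {
      cost <- if (prev == "b") ge else go
      best <- max(best, rec(i, j - 1L, "b") - cost)
    }
    memo[[key]] <- best
    best
  }
  rec(length(sa), length(sb), "m")
}

# --- classifier truth-table oracle ------------------------------------------
# Built from the definitions: complementarity via a complement map plus the
# G-U wobble; class from the number of changed partners and whether both
# states remain pairable.

oracle_classify <- function(a5, a3, b5, b3) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  pairable <- function(x, y) {
    comp[[x]] == y || (x == "G" && y == "U") || (x == "U" && y == "G")
  }
  if (a5 == b5 && a3 == b3) return("silent")
  changed <- (a5 != b5) + (a3 != b3)
  if (pairable(a5, a3) && pairable(b5, b3)) {
    if (changed == 2L) "CBC" else "hCBC"
  } else {
    "Nst"
  }
}

# --- motif regex oracle -------------------------------------------------------
# Overlapping exact-IUPAC matching via lookahead regex (mismatch budget 0),
# and a sliding Hamming scan for budgets > 0.

iupac_class <- c(A = "A", C = "C", G = "G", U = "U", R = "[AG]", Y = "[CU]",
                 S = "[CG]", W = "[AU]", K = "[GU]", M = "[AC]",
                 B = "[CGU]", D = "[AGU]", H = "[ACU]", V = "[ACG]",
                 N = "[ACGU]")

oracle_motif_starts <- function(seq, pattern, max_mismatches = 0L) {
  if (max_mismatches == 0L) {
    rx <- paste0("(?=", paste(iupac_class[strsplit(pattern, "")[[1]]],
                              collapse = ""), ")")
    m <- gregexpr(rx, seq, perl = TRUE)[[1]]
    return(if (m[1L] == -1L) integer(0) else as.integer(m))
  }
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(seq, "")[[1]]
  sets <- list(A = "A", C = "C", G = "G", U = "U", R = c("A", "G"),
               Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
               K = c("G", "U"), M = c("A", "C"), B = c("C", "G", "U"),
               D = c("A", "G", "U"), H = c("A", "C", "U"),
               V = c("A", "C", "G"), N = c("A", "C", "G", "U"))
  out <- integer(0)
  for (st in seq_len(length(s) - length(p) + 1L)) {
    mm <- sum(vapply(seq_along(p), function(k) {
      !(s[st + k - 1L] %in% sets[[p[k]]])
    }, TRUE))
    if (mm <= max_mismatches) out <- c(out, st)
  }
  out
}

# --- RF oracle ----------------------------------------------------------------
# Bipartition sets from scratch: for each internal edge, the tip set below
# it, canonicalized against its complement.

oracle_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  n_tip <- length(tree$tip.label)
  tips <- sort(tree$tip.label)
  below <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    unlist(lapply(kids, below))
  }
  parts <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    if (child <= n_tip) next
    side <- sort(below(child))
    other <- setdiff(tips, side)
    if (length(side) < 2L || length(other) < 2L) next
    key <- if (paste(side, collapse = ",") < paste(other, collapse = ",")) {
      paste(side, collapse = ",")
    } else {
      paste(other, collapse = ",")
    }
    parts <- c(parts, key)
  }
  unique(parts)
}

oracle_rf <- function(t1, t2) {
  b1 <- oracle_bipartitions(t1)
  b2 <- oracle_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# --- diversity brute force ----------------------------------------------------

oracle_pi <- function(m) {
  n <- nrow(m)
  vals <- c()
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      both <- !is.na(m[a, ]) & !is.na(m[b, ])
      vals <- c(vals, sum(m[a, both] != m[b, both]) / sum(both))
    }
  }
  mean(vals)
}

# --- published motif strings (restated independently of the package) ----------

MOTIF_5_8S_I <- "CGAUGAAGAACGUAGC"
MOTIF_5_8S_II <- "GAAUUGCAGAAUCC"
MOTIF_5_8S_III <- "UUUGAACGCA"
BOUNDARY_5_8S_ITS2 <- "CAUAU"
ITS1_CORE_BLOCK1 <- "GGCGC"
ITS1_CORE_BLOCK2 <- "GYGCCAAGGAA"

# --- misc helpers -------------------------------------------------------------

random_rna <- function(n, bases = c("A", "C", "G", "U")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# A random nested structure over 1..n (used for round-trip properties).
random_structure <- function(n, p_pair = 0.4, mh = 3L) {
  pairs <- list()
  free <- rep(TRUE, n)
  attempt <- 0L
  while (attempt < 2L * n) {
    attempt <- attempt + 1L
    i <- sample.int(n, 1L)
    j <- sample.int(n, 1L)
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    if (j - i < mh + 1L || !all(free[i:j])) next
    if (stats::runif(1) > p_pair) next
    pairs[[length(pairs) + 1L]] <- c(i, j)
    free[c(i, j)] <- FALSE
    # enclose: allow nested pairs inside by keeping interior free
  }
  if (length(pairs) == 0L) return(matrix(integer(0), ncol = 2))
  do.call(rbind, pairs)
}

# Random additive distance matrix from a random topology with positive
# branch lengths; returns the matrix and the generating tree.
random_additive <- function(n_tip, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tip)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.5)
  list(d = ape::cophenetic.phylo(tr), tree = tr)
}
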