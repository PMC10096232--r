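# Secondary-structure prediction: an internal base-pair-maximization /
# stacking dynamic program (Nussinov-style, in the spirit of the Zuker-
# Stiegler recursion but with a simplified scoring model), plus an optional
# external thermodynamic backend (ViennaRNA's RNAfold binary). The internal
# engine reports a score in arbitrary units; kcal/mol free energies are only
# emitted by the external backend, whose nearest-neighbor model they require.

#' Folding parameters
#'
#' @param scoring `"stacking"` (default) scores pairs by type with a bonus
#'   for helix continuation; `"pair_count"` maximizes the number of pairs.
#' @param pair_scores Named scores for the three pair types (`GC`, `AU`,
#'   `GU`); must be positive.
#' @param stack_bonus Bonus added when a pair sits directly on another pair.
#' @param min_hairpin Minimum number of unpaired bases enclosed by a pair
#'   (default 3, the steric minimum).
#' @param flank_len Flank length used by [add_flanks()] (default 25 nt).
#' @param backend `"internal"` or `"external"` (RNAfold).
#' @return A list of class `FoldParams`.
#' @export
fold_params <- function(scoring = c("stacking", "pair_count"),
                        pair_scores = c(GC = 3, AU = 2, GU = 1),
                        stack_bonus = 1, min_hairpin = 3L, flank_len = 25L,
                        backend = c("internal", "external")) {
  scoring <- match.arg(scoring)
  backend <- match.arg(backend)
  stopifnot(min_hairpin >= 3L, flank_len >= 0L,
            all(pair_scores > 0), all(c("GC", "AU", "GU") %in% names(pair_scores)))
  structure(list(scoring = scoring, pair_scores = pair_scores,
                 stack_bonus = stack_bonus, min_hairpin = as.integer(min_hairpin),
                 flank_len = as.integer(flank_len), backend = backend),
            class = "FoldParams")
}

#' Add 5.8S and 28S flanks to an ITS2 sequence
#'
#' Folding the spacer together with short flanks of the surrounding rRNA
#' genes lets the proximal stem (the 5.8S/28S hybrid that closes the ITS2
#' central loop) form. Returns the extended sequence and the offset needed
#' to map structure indices back to ITS2 coordinates.
#'
#' @param its2_seq ITS2 sequence.
#' @param upstream_5_8S 5.8S sequence (its last `flank_len` nt are used).
#' @param downstream_28S 28S sequence (its first `flank_len` nt are used).
#' @param flank_len Flank length in nt (default 25).
#' @return List with `seq` (extended sequence) and `offset` (= `flank_len`);
#'   ITS2 position `i` sits at `offset + i` in the extended sequence.
#' @export
add_flanks <- function(its2_seq, upstream_5_8S, downstream_28S,
                       flank_len = 25L) {
  flank_len <- as.integer(flank_len)
  stopifnot(flank_len >= 0L)
  if (flank_len == 0L) return(list(seq = its2_seq, offset = 0L))
  if (nchar(upstream_5_8S) < flank_len) {
    stop(sprintf("5.8S flank shorter than flank_len (%d < %d)",
                 nchar(upstream_5_8S), flank_len))
  }
  if (nchar(downstream_28S) < flank_len) {
    stop(sprintf("28S flank shorter than flank_len (%d < %d)",
                 nchar(downstream_28S), flank_len))
  }
  up <- substr(upstream_5_8S, nchar(upstream_5_8S) - flank_len + 1L,
               nchar(upstream_5_8S))
  down <- substr(downstream_28S, 1L, flank_len)
  list(seq = paste0(up, its2_seq, down), offset = flank_len)
}

# Pair type of two bases: "GC", "AU", "GU" (orientation-free) or NA.
pair_type <- function(b1, b2) {
  key <- paste0(pmin(b1, b2), pmax(b1, b2))
  c(AU = "AU", CG = "GC", GU = "GU")[key]
}

#' Predict the optimal nested structure of an RNA sequence
#'
#' With `backend = "internal"`, runs the package's dynamic program over all
#' nested structures (allowed pairs: Watson-Crick plus G-U wobble) and
#' returns the score-optimal one; the score (arbitrary units) is attached as
#' attribute `"score"` and `energy` is `NA`. With `backend = "external"`,
#' delegates to the RNAfold binary and returns its structure and free energy
#' unchanged.
#'
#' Ties in the internal engine are broken deterministically: the traceback
#' prefers pairing over bifurcation and, among equal-scoring pairings for a
#' closing position, the one with the smallest opening index.
#'
#' @param seq RNA sequence over `A`, `C`, `G`, `U` (no ambiguity codes).
#' @param params A [fold_params()] object.
#' @param id Id for the returned record.
#' @param region Region label for the returned record.
#' @return A [seq_struct_record()] with `source = "folded_internal"` or
#'   `"folded_external"`.
#' @export
fold_mfe <- function(seq, params = fold_params(), id = "folded",
                     region = "OTHER") {
  seq <- normalize_rna(seq, context = id)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (any(!ch %in% RNA_BASES)) {
    stop(sprintf("%s: cannot fold sequences with ambiguity codes", id))
  }
  if (length(ch) < params$min_hairpin + 2L) {
    stop(sprintf("%s: sequence shorter than min_hairpin + 2", id))
  }
  if (params$backend == "external") {
    return(fold_external(seq, id = id, region = region))
  }
  fit <- nussinov_fold(ch, params)
  rec <- seq_struct_record(id, seq, pairs = fit$pairs, region = region,
                           source = "folded_internal")
  attr(rec, "score") <- fit$score
  rec
}

# Score of pairing bases b1:b2 under the params, or NA when unpairable.
pair_score_of <- function(b1, b2, params) {
  ty <- pair_type(b1, b2)
  ifelse(is.na(ty), NA_real_,
         if (params$scoring == "pair_count") 1
         else unname(params$pair_scores[ty]))
}

# Internal DP. W[i,j] = best score of subsequence i..j; V[i,j] = best score
# given (i,j) paired. Recursion:
#   V[i,j] = s(i,j) + max(V[i+1,j-1] + stack_bonus, W[i+1,j-1])
#   W[i,j] = max(W[i,j-1], max_k { W[i,k-1] + V[k,j] })
nussinov_fold <- function(ch, params) {
  n <- length(ch)
  mh <- params$min_hairpin
  stack <- if (params$scoring == "pair_count") 0 else params$stack_bonus
  S <- outer(ch, ch, function(a, b) pair_score_of(a, b, params))
  W <- matrix(0, n, n)
  V <- matrix(-Inf, n, n)
  for (span in (mh + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      if (!is.na(S[i, j])) {
        inner <- if (span == mh + 1L) 0 else {
          max(V[i + 1L, j - 1L] + stack, W[i + 1L, j - 1L])
        }
        V[i, j] <- S[i, j] + inner
      }
      ks <- i:(j - mh - 1L)
      left <- c(0, W[i, ks[-1L] - 1L])
      cand <- left + V[ks, j]
      W[i, j] <- max(W[i, j - 1L], cand, 0)
    }
  }
  pairs <- traceback_nussinov(ch, params, W, V, S)
  list(score = W[1L, n], pairs = pairs)
}

traceback_nussinov <- function(ch, params, W, V, S) {
  n <- length(ch)
  mh <- params$min_hairpin
  stack <- if (params$scoring == "pair_count") 0 else params$stack_bonus
  eps <- 1e-9
  pairs <- list()
  # stack of segments to resolve: (i, j, paired?) where paired means (i,j)
  # is a committed pair and its interior must be resolved
  todo <- list(c(1L, n, 0L))
  while (length(todo) > 0L) {
    seg <- todo[[length(todo)]]
    todo[[length(todo)]] <- NULL
    i <- seg[1L]; j <- seg[2L]; committed <- seg[3L]
    if (committed) {
      # interior of pair (i,j)
      ii <- i + 1L; jj <- j - 1L
      if (jj - ii >= mh + 1L &&
          !is.na(S[ii, jj]) && is.finite(V[ii, jj]) &&
          abs((V[ii, jj] + stack) -
              (V[i, j] - pair_score_of(ch[i], ch[j], params))) < eps) {
        pairs[[length(pairs) + 1L]] <- c(ii, jj)
        todo[[length(todo) + 1L]] <- c(ii, jj, 1L)
      } else if (jj >= ii) {
        todo[[length(todo) + 1L]] <- c(ii, jj, 0L)
      }
      next
    }
    if (j <= i || j - i < mh + 1L || W[i, j] < eps) next
    done <- FALSE
    for (k in i:(j - mh - 1L)) {
      left <- if (k > i) W[i, k - 1L] else 0
      if (is.finite(V[k, j]) && abs(left + V[k, j] - W[i, j]) < eps) {
        pairs[[length(pairs) + 1L]] <- c(k, j)
        todo[[length(todo) + 1L]] <- c(k, j, 1L)
        if (k > i) todo[[length(todo) + 1L]] <- c(i, k - 1L, 0L)
        done <- TRUE
        break
      }
    }
    if (!done) todo[[length(todo) + 1L]] <- c(i, j - 1L, 0L)
  }
  if (length(pairs) == 0L) {
    matrix(integer(0), ncol = 2L)
  } else {
    do.call(rbind, pairs)
  }
}

# External backend: the RNAfold binary (ViennaRNA). Never falls back
# silently; an absent binary is an explicit error.
fold_external <- function(seq, id = "folded", region = "OTHER") {
  bin <- Sys.which("RNAfold")
  if (!nzchar(bin)) {
    stop("external folding backend requested but RNAfold is not on PATH")
  }
  out <- system2(bin, args = c("--noPS"), input = seq, stdout = TRUE)
  sline <- out[2L]
  m <- regmatches(sline, regexec("^([().]+)\\s+\\(\\s*(-?[0-9.]+)\\)", sline))[[1]]
  if (length(m) != 3L) stop("could not parse RNAfold output")
  seq_struct_record(id, seq, pairs = dotbracket_to_pairs(m[2L]),
                    region = region, energy = as.numeric(m[3L]),
                    source = "folded_external")
}
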