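# GC content, DnaSP-style diversity indices, and within/between-group mean
# genetic distances with bootstrap standard errors.

# GC fraction of one ungapped sequence; ambiguity codes are excluded from
# both numerator and denominator.
gc_content_seq <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  ch <- ch[ch %in% RNA_BASES | ch == "T"]
  if (length(ch) == 0L) stop("empty sequence (no unambiguous bases)")
  mean(ch %in% c("G", "C"))
}

#' GC content of sequences
#'
#' @param seqs Character vector of sequences, or list of
#'   [seq_struct_record()] objects.
#' @param groups Optional named group map; when given, per-group means are
#'   returned instead of per-record values.
#' @return Named numeric vector of GC fractions.
#' @export
gc_content <- function(seqs, groups = NULL) {
  if (is.list(seqs) && length(seqs) > 0L &&
      inherits(seqs[[1L]], "SeqStructRecord")) {
    v <- vapply(seqs, function(r) gc_content_seq(r$seq), 0)
    names(v) <- vapply(seqs, function(r) r$id, "")
  } else {
    v <- vapply(seqs, gc_content_seq, 0)
    if (is.null(names(v)) && !is.null(names(seqs))) names(v) <- names(seqs)
  }
  if (is.null(groups)) return(v)
  g <- groups[names(v)]
  if (anyNA(g)) stop("gc_content: unmapped sequence id in group map")
  tapply(v, g, mean)
}

#' DnaSP-style diversity indices of an alignment
#'
#' Computed on the base matrix of an alignment (gaps as missing):
#' segregating sites `S`, parsimony-informative sites, singleton sites,
#' total mutations `Eta` (distinct derived bases per segregating site),
#' nucleotide diversity `Pi` (mean pairwise difference per compared site,
#' pairwise deletion), haplotype count and Nei's haplotype diversity `h`
#' (on gap-free columns), and indel sites / indel haplotypes from the gap
#' presence-absence matrix.
#'
#' @param aln A `SeqStructAlignment`, or a character matrix of bases with
#'   `NA` or `-` for gaps (rows = taxa).
#' @param label Label carried in the result.
#' @return One-row data frame of class `DiversityReport`.
#' @export
diversity_indices <- function(aln, label = "all") {
  m <- as_base_matrix(aln)
  n <- nrow(m); L <- ncol(m)
  if (n < 2L) stop("diversity indices need at least 2 sequences")
  S <- 0L; eta <- 0L; pars_inf <- 0L; singletons <- 0L
  for (col in seq_len(L)) {
    obs <- m[, col]
    obs <- obs[!is.na(obs)]
    if (length(obs) < 2L) next
    tab <- table(obs)
    if (length(tab) >= 2L) {
      S <- S + 1L
      eta <- eta + length(tab) - 1L
      if (sum(tab >= 2L) >= 2L) pars_inf <- pars_inf + 1L
      if (all(sort(tab, decreasing = TRUE)[-1L] == 1L)) {
        singletons <- singletons + 1L
      }
    }
  }
  # Pi: mean over pairs of (differences / compared sites)
  pair_pi <- c()
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      both <- !is.na(m[a, ]) & !is.na(m[b, ])
      pair_pi <- c(pair_pi,
                   if (any(both)) mean(m[a, both] != m[b, both]) else NA)
    }
  }
  Pi <- mean(pair_pi, na.rm = TRUE)
  # haplotypes on gap-free columns
  complete <- colSums(is.na(m)) == 0L
  hap_key <- apply(m[, complete, drop = FALSE], 1L, paste, collapse = "")
  hap_n <- length(unique(hap_key))
  p_i <- table(hap_key) / n
  h <- if (n > 1L) (n / (n - 1L)) * (1 - sum(p_i^2)) else 0
  # indels
  gap <- is.na(m)
  indel_sites <- sum(colSums(gap) > 0L)
  indel_hap <- length(unique(apply(gap, 1L, paste, collapse = "")))
  structure(
    data.frame(label = label, n = n, sites = L, S = S,
               parsimony_informative = pars_inf, singletons = singletons,
               Eta = eta, Pi = Pi, haplotypes = hap_n, hap_diversity = h,
               indel_sites = indel_sites, indel_haplotypes = indel_hap),
    class = c("DiversityReport", "data.frame"))
}

as_base_matrix <- function(aln) {
  if (inherits(aln, "SeqStructAlignment")) {
    m <- aln_base_matrix(aln)
  } else {
    m <- aln
    m[m == "-"] <- NA_character_
  }
  if (is.null(dim(m))) stop("expected a matrix of aligned bases")
  m
}

# Pairwise p-distance matrix with pairwise deletion (ape backend).
p_distance_matrix <- function(m, model = c("p_distance", "K2P")) {
  model <- match.arg(model)
  chars <- tolower(chartr("U", "T", ifelse(is.na(m), "-", m)))
  bin <- ape::as.DNAbin(chars)
  d <- ape::dist.dna(bin, model = if (model == "p_distance") "raw" else "K80",
                     pairwise.deletion = TRUE)
  as.matrix(d)
}

#' Within- and between-group mean genetic distances
#'
#' Pairwise distances are p-distances with pairwise deletion of gaps (a
#' Kimura 2-parameter option is provided for sensitivity); group means
#' average over intra- or cross-group taxon pairs. Standard errors are
#' obtained by bootstrapping alignment columns.
#'
#' @param aln A `SeqStructAlignment` or base matrix (as in
#'   [diversity_indices()]).
#' @param groups Named character vector mapping every taxon to a group.
#' @param model `"p_distance"` (default) or `"K2P"`.
#' @param se_reps Bootstrap replicates for the standard errors (0 = no SE).
#' @param seed Seed for the bootstrap.
#' @return List of class `DistanceTable`: `between` (symmetric matrix of
#'   means), `between_se`, `within` (named vector, `NA` for singleton
#'   groups), `within_se`, `pairwise` (the full distance matrix).
#' @export
group_distances <- function(aln, groups, model = c("p_distance", "K2P"),
                            se_reps = 1000L, seed = 1L) {
  model <- match.arg(model)
  m <- as_base_matrix(aln)
  taxa <- rownames(m)
  unmapped <- setdiff(taxa, names(groups))
  if (length(unmapped) > 0L) {
    stop(sprintf("taxon not mapped to a group: %s", unmapped[1L]))
  }
  g <- unname(groups[taxa])
  glab <- sort(unique(g))
  summarize <- function(mat) {
    D <- p_distance_matrix(mat, model)
    between <- matrix(NA_real_, length(glab), length(glab),
                      dimnames = list(glab, glab))
    within <- stats::setNames(rep(NA_real_, length(glab)), glab)
    for (x in seq_along(glab)) {
      ix <- which(g == glab[x])
      if (length(ix) >= 2L) {
        within[x] <- mean(D[ix, ix][upper.tri(D[ix, ix])])
      }
      for (y in seq_along(glab)) {
        if (y <= x) next
        iy <- which(g == glab[y])
        between[x, y] <- between[y, x] <- mean(D[ix, iy, drop = FALSE])
      }
    }
    diag(between) <- 0
    list(between = between, within = within, D = D)
  }
  full <- summarize(m)
  between_se <- NULL; within_se <- NULL
  if (se_reps > 0L) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    bs_b <- array(NA_real_, c(length(glab), length(glab), se_reps))
    bs_w <- matrix(NA_real_, length(glab), se_reps)
    for (r in seq_len(se_reps)) {
      cols <- sample.int(ncol(m), replace = TRUE)
      s <- summarize(m[, cols, drop = FALSE])
      bs_b[, , r] <- s$between
      bs_w[, r] <- s$within
    }
    between_se <- apply(bs_b, c(1L, 2L), stats::sd)
    dimnames(between_se) <- list(glab, glab)
    within_se <- apply(bs_w, 1L, stats::sd)
    names(within_se) <- glab
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }
  structure(list(between = full$between, between_se = between_se,
                 within = full$within, within_se = within_se,
                 pairwise = full$D, model = model),
            class = "DistanceTable")
}

#' @export
print.DistanceTable <- function(x, ...) {
  cat(sprintf("<DistanceTable> model=%s\n", x$model))
  cat("between-group means:\n")
  print(round(x$between, 4))
  cat("within-group means:\n")
  print(round(x$within, 4))
  invisible(x)
}
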