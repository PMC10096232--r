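# Core data model: a sequence plus its nested base-pair set.

RNA_BASES <- c("A", "C", "G", "U")
REGIONS <- c("ITS1", "5.8S", "ITS2", "FULL_ITS", "OTHER")
SOURCES <- c("folded_internal", "folded_external", "template_modeled",
             "user_supplied")

# IUPAC nucleotide codes (RNA form) and the base sets they cover.
IUPAC_RNA <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

ALLOWED_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Construct a sequence-structure record
#'
#' A `SeqStructRecord` couples one RNA sequence with a nested set of base
#' pairs (its secondary structure) and an optional folding free energy.
#' DNA input is transcribed on construction (`T` becomes `U`); lowercase is
#' uppercased. Coordinates are 1-based throughout the package.
#'
#' @param id Record identifier (non-empty string).
#' @param seq Sequence string over the IUPAC nucleotide alphabet.
#' @param pairs Two-column integer matrix of paired positions `(i, j)` with
#'   `i < j`, or `NULL` for an unstructured record.
#' @param region One of `"ITS1"`, `"5.8S"`, `"ITS2"`, `"FULL_ITS"`, `"OTHER"`.
#' @param energy Optional free energy in kcal/mol (only meaningful for
#'   externally folded structures); `NA` otherwise.
#' @param source Provenance of the structure: `"folded_internal"`,
#'   `"folded_external"`, `"template_modeled"` or `"user_supplied"`.
#'
#' @return An object of class `SeqStructRecord`.
#' @details Invariants enforced: pairs are nested (no crossing), each position
#'   appears in at most one pair, every pair encloses at least 3 unpaired
#'   positions (`j - i >= 4`), and all indices lie within the sequence.
#' @export
seq_struct_record <- function(id, seq, pairs = NULL, region = "OTHER",
                              energy = NA_real_, source = "user_supplied") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  region <- match.arg(region, REGIONS)
  source <- match.arg(source, SOURCES)
  seq <- normalize_rna(seq, context = id)
  pairs <- normalize_pairs(pairs)
  validate_pairs(pairs, nchar(seq), context = id)
  structure(
    list(id = id, region = region, seq = seq, pairs = pairs,
         energy = as.numeric(energy), source = source),
    class = "SeqStructRecord"
  )
}

#' @export
print.SeqStructRecord <- function(x, ...) {
  cat(sprintf("<SeqStructRecord %s> region=%s length=%d pairs=%d source=%s%s\n",
              x$id, x$region, nchar(x$seq), nrow(x$pairs), x$source,
              if (is.na(x$energy)) "" else sprintf(" energy=%.2f", x$energy)))
  invisible(x)
}

# Uppercase, transcribe T->U, and reject non-IUPAC characters (naming the
# offending position). Gaps are rejected: records hold ungapped sequences.
normalize_rna <- function(seq, context = "sequence", allow_gap = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop(sprintf("%s: empty sequence", context))
  s <- chartr("t", "u", toupper(seq))
  s <- chartr("T", "U", s)
  ok <- names(IUPAC_RNA)
  if (allow_gap) ok <- c(ok, "-")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% ok)
  if (length(bad) > 0L) {
    stop(sprintf("%s: non-IUPAC character '%s' at position %d",
                 context, ch[bad[1L]], bad[1L]))
  }
  s
}

#' Canonicalize a pair matrix
#'
#' Orders each pair as `(i, j)` with `i < j`, sorts rows by `i`, and names
#' the columns; `NULL` becomes an empty pair matrix.
#'
#' @param pairs Two-column matrix-like of paired positions, or `NULL`.
#' @return Two-column integer matrix with columns `i`, `j`.
#' @export
normalize_pairs <- function(pairs) {
  if (is.null(pairs) || length(pairs) == 0L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  }
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  swap <- pairs[, 1L] > pairs[, 2L]
  if (any(swap)) pairs[swap, ] <- pairs[swap, c(2L, 1L)]
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("i", "j"))
  pairs
}

validate_pairs <- function(pairs, len, context = "record",
                           min_hairpin = 3L) {
  if (nrow(pairs) == 0L) return(invisible(TRUE))
  if (any(pairs < 1L) || any(pairs > len)) {
    stop(sprintf("%s: paired index outside sequence (length %d)", context, len))
  }
  idx <- as.vector(pairs)
  if (anyDuplicated(idx)) {
    stop(sprintf("%s: position %d appears in more than one pair",
                 context, idx[duplicated(idx)][1L]))
  }
  if (any(pairs[, 2L] - pairs[, 1L] < min_hairpin + 1L)) {
    stop(sprintf("%s: hairpin constraint violated (pair encloses < %d bases)",
                 context, min_hairpin))
  }
  # Nestedness: with pairs sorted by i, every pair must either enclose or
  # precede the next; crossing (i < k < j < l) is rejected.
  if (nrow(pairs) > 1L) {
    i <- pairs[, 1L]; j <- pairs[, 2L]
    for (a in seq_len(nrow(pairs) - 1L)) {
      b <- a + 1L
      later <- b:nrow(pairs)
      cross <- i[later] < j[a] & j[later] > j[a]
      if (any(cross)) {
        k <- later[which(cross)[1L]]
        stop(sprintf("%s: crossing pairs (%d,%d) and (%d,%d) (pseudoknot)",
                     context, i[a], j[a], i[k], j[k]))
      }
    }
  }
  invisible(TRUE)
}

#' Convert dot-bracket notation to a pair matrix
#'
#' @param db Dot-bracket string over the characters `(`, `)` and `.`.
#'   One bracket level only; pseudoknots are not representable.
#' @return Two-column integer matrix of 1-based pairs `(i, j)`, `i < j`.
#' @export
dotbracket_to_pairs <- function(db) {
  stopifnot(is.character(db), length(db) == 1L)
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% c("(", ")", "."))
  if (length(bad) > 0L) {
    stop(sprintf("invalid dot-bracket character '%s' at position %d",
                 ch[bad[1L]], bad[1L]))
  }
  stack <- integer(0)
  out <- vector("list", sum(ch == "("))
  n_out <- 0L
  for (k in seq_along(ch)) {
    if (ch[k] == "(") {
      stack <- c(stack, k)
    } else if (ch[k] == ")") {
      if (length(stack) == 0L) {
        stop(sprintf("unbalanced dot-bracket: unmatched ')' at position %d", k))
      }
      n_out <- n_out + 1L
      out[[n_out]] <- c(stack[length(stack)], k)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0L) {
    stop(sprintf("unbalanced dot-bracket: unmatched '(' at position %d",
                 stack[length(stack)]))
  }
  normalize_pairs(do.call(rbind, out[seq_len(n_out)]))
}

#' Convert a pair matrix to dot-bracket notation
#'
#' @param pairs Two-column integer matrix of 1-based pairs.
#' @param len Sequence length (number of characters to emit).
#' @return Dot-bracket string of length `len`.
#' @export
pairs_to_dotbracket <- function(pairs, len) {
  pairs <- normalize_pairs(pairs)
  validate_pairs(pairs, len, min_hairpin = 0L)
  ch <- rep(".", len)
  ch[pairs[, 1L]] <- "("
  ch[pairs[, 2L]] <- ")"
  paste(ch, collapse = "")
}

# Character vector view of a record's sequence.
seq_chars <- function(record) strsplit(record$seq, "", fixed = TRUE)[[1]]

# Per-position partner vector: partner[i] = j if (i,j) or (j,i) paired, else NA.
partner_vector <- function(pairs, len) {
  p <- rep(NA_integer_, len)
  if (nrow(pairs) > 0L) {
    p[pairs[, 1L]] <- pairs[, 2L]
    p[pairs[, 2L]] <- pairs[, 1L]
  }
  p
}

#' Test whether two bases form an allowed pair
#'
#' Watson-Crick pairs plus the G-U wobble by default.
#'
#' @param b1,b2 Single bases (`A`, `C`, `G`, `U`).
#' @param allowed Character vector of allowed pair types, e.g. `"GU"`.
#' @return Logical.
#' @export
is_allowed_pair <- function(b1, b2, allowed = ALLOWED_PAIRS) {
  paste0(b1, b2) %in% allowed
}
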