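# Classification of aligned changes between taxa or groups as compensatory
# (CBC), hemi-compensatory (hCBC), non-structural (Nst) or silent, and their
# tabulation per group pair and per helix.

#' Classify a change at a paired column
#'
#' A CBC substitutes both partners of a base pair while both states remain
#' allowed pairs (e.g. U:G vs A:U); an hCBC substitutes exactly one partner
#' with both states still allowed (e.g. U:A vs U:G); identical states are
#' silent; everything else - any change that breaks or lacks allowed pairing
#' - is Nst. Symmetric in its two arguments.
#'
#' @param state_a,state_b Length-2 character vectors `(base5, base3)`.
#' @param allowed Allowed pair types; defaults to Watson-Crick plus G-U.
#' @param lenient If `TRUE`, additionally admits `C:A`/`A:C` as weak pairs
#'   (replication of published calls that treated U:A to C:A as an hCBC);
#'   the default keeps the standard definition.
#' @return One of `"CBC"`, `"hCBC"`, `"Nst"`, `"silent"`.
#' @export
classify_pair_change <- function(state_a, state_b, allowed = ALLOWED_PAIRS,
                                 lenient = FALSE) {
  stopifnot(length(state_a) == 2L, length(state_b) == 2L)
  if (any(!c(state_a, state_b) %in% RNA_BASES)) {
    stop("classify_pair_change: ambiguity codes must be resolved or skipped")
  }
  if (lenient) allowed <- union(allowed, c("CA", "AC"))
  if (identical(unname(state_a), unname(state_b))) return("silent")
  ok_a <- is_allowed_pair(state_a[1L], state_a[2L], allowed)
  ok_b <- is_allowed_pair(state_b[1L], state_b[2L], allowed)
  n_diff <- sum(state_a != state_b)
  if (ok_a && ok_b) {
    if (n_diff == 2L) "CBC" else "hCBC"
  } else {
    "Nst"
  }
}

#' Classify a change at an unpaired column
#'
#' @param base_a,base_b Single bases. Identical bases are silent, different
#'   bases Nst. Gaps are not events of this kind (indels are logged
#'   separately); passing a gap returns `"indel"`.
#' @return `"silent"`, `"Nst"` or `"indel"`.
#' @export
classify_unpaired_change <- function(base_a, base_b) {
  if (is.na(base_a) || is.na(base_b) || base_a == "-" || base_b == "-") {
    return("indel")
  }
  if (base_a == base_b) "silent" else "Nst"
}

# Group state per column under a unanimity-style threshold: the state shared
# by >= group_threshold of the group's ungapped members, else NA
# ("polymorphic", excluded and listed as an exception).
group_column_state <- function(states_col, group_threshold = 1) {
  ng <- states_col[states_col != 0L]
  if (length(ng) == 0L) return(NA_integer_)
  tab <- table(ng)
  best <- as.integer(names(tab)[which.max(tab)])
  if (max(tab) >= group_threshold * length(ng)) best else NA_integer_
}

#' Tabulate CBC/hCBC/Nst events across an alignment
#'
#' In `taxon_pairwise` mode every pair of taxa is compared; in `group_level`
#' mode a single state per group and column is derived (state shared by at
#' least `group_threshold` of ungapped members, default unanimity) and group
#' pairs are compared; polymorphic columns are excluded and listed in the
#' `exceptions` component. Paired columns are classified with
#' [classify_pair_change()], unpaired columns with
#' [classify_unpaired_change()]; any gap involvement is logged as an indel
#' event, never as an Nst.
#'
#' @param aln A `SeqStructAlignment`.
#' @param groups Named character vector mapping every taxon to a group
#'   (required for `group_level`; optional otherwise).
#' @param helix_labels Optional character vector, one label per aligned
#'   column (e.g. from [column_helix_labels()]); unpaired columns default to
#'   `"loop"`.
#' @param mode `"taxon_pairwise"` or `"group_level"`.
#' @param group_threshold Fraction of ungapped members that must share a
#'   state in `group_level` mode (default 1 = unanimity).
#' @param lenient Passed to [classify_pair_change()].
#' @return List with `events` (data frame: a, b, aligned_col, partner_col,
#'   pos_a, pos_b, helix, state_a, state_b, class), `counts_by_pair`,
#'   `counts_by_helix` (class-count tables) and `exceptions` (group_level
#'   polymorphic columns).
#' @export
tabulate_events <- function(aln, groups = NULL, helix_labels = NULL,
                            mode = c("taxon_pairwise", "group_level"),
                            group_threshold = 1, lenient = FALSE) {
  mode <- match.arg(mode)
  states <- aln$states
  L <- ncol(states)
  pc <- aln$paired_cols
  paired_p <- if (is.null(pc) || nrow(pc) == 0L) integer(0) else pc[, 1L]
  partner_of <- rep(NA_integer_, L)
  if (length(paired_p) > 0L) {
    partner_of[pc[, 1L]] <- pc[, 2L]
    partner_of[pc[, 2L]] <- pc[, 1L]
  }
  if (is.null(helix_labels)) {
    helix_labels <- ifelse(is.na(partner_of), "loop", "helix")
  }
  stopifnot(length(helix_labels) == L)

  exceptions <- NULL
  if (mode == "group_level") {
    if (is.null(groups)) stop("group_level mode requires a group map")
    unmapped <- setdiff(aln$taxa, names(groups))
    if (length(unmapped) > 0L) {
      stop(sprintf("taxon not mapped to a group: %s", unmapped[1L]))
    }
    glabels <- sort(unique(unname(groups[aln$taxa])))
    gstates <- matrix(NA_integer_, length(glabels), L,
                      dimnames = list(glabels, NULL))
    for (g in glabels) {
      rows <- which(unname(groups[aln$taxa]) == g)
      sub <- states[rows, , drop = FALSE]
      gstates[g, ] <- apply(sub, 2L, group_column_state,
                            group_threshold = group_threshold)
      poly <- which(is.na(gstates[g, ]) & colSums(sub != 0L) > 0L)
      if (length(poly) > 0L) {
        exceptions <- rbind(exceptions,
                            data.frame(group = g, aligned_col = poly))
      }
    }
    units <- glabels
    unit_states <- gstates
    # gaps: a group column where all members are gapped stays 0
    unit_states[is.na(unit_states) &
                  t(vapply(glabels, function(g) {
                    rows <- which(unname(groups[aln$taxa]) == g)
                    colSums(states[rows, , drop = FALSE] != 0L) == 0L
                  }, logical(L)))] <- 0L
  } else {
    units <- aln$taxa
    unit_states <- states
  }

  n <- length(units)
  ev <- list()
  add_event <- function(a, b, col, pcol, sa, sb, klass) {
    ev[[length(ev) + 1L]] <<- data.frame(
      a = a, b = b, aligned_col = col,
      partner_col = if (is.na(pcol)) NA_integer_ else pcol,
      helix = helix_labels[col],
      state_a = sa, state_b = sb, class = klass,
      stringsAsFactors = FALSE)
  }
  base_of <- function(st) if (is.na(st) || st == 0L) "-" else state_base(st)
  for (x in seq_len(n - 1L)) {
    for (y in (x + 1L):n) {
      sa <- unit_states[x, ]; sb <- unit_states[y, ]
      handled <- logical(L)
      # paired columns: classify the (p, q) states jointly
      for (k in seq_along(paired_p)) {
        p <- pc[k, 1L]; q <- pc[k, 2L]
        handled[c(p, q)] <- TRUE
        if (anyNA(c(sa[p], sa[q], sb[p], sb[q]))) next  # polymorphic: skip
        ba <- c(base_of(sa[p]), base_of(sa[q]))
        bb <- c(base_of(sb[p]), base_of(sb[q]))
        if (any(c(ba, bb) == "-")) {
          if (!identical(ba, bb)) {
            add_event(units[x], units[y], p, q,
                      paste(ba, collapse = ":"), paste(bb, collapse = ":"),
                      "indel")
          }
          next
        }
        klass <- classify_pair_change(ba, bb, lenient = lenient)
        if (klass != "silent") {
          add_event(units[x], units[y], p, q,
                    paste(ba, collapse = ":"), paste(bb, collapse = ":"),
                    klass)
        }
      }
      # unpaired columns
      for (col in which(!handled)) {
        if (is.na(sa[col]) || is.na(sb[col])) next
        ba <- base_of(sa[col]); bb <- base_of(sb[col])
        if (ba == "-" && bb == "-") next
        klass <- classify_unpaired_change(
          if (ba == "-") NA else ba, if (bb == "-") NA else bb)
        if (klass != "silent") {
          add_event(units[x], units[y], col, NA_integer_, ba, bb, klass)
        }
      }
    }
  }
  events <- if (length(ev) == 0L) {
    data.frame(a = character(0), b = character(0),
               aligned_col = integer(0), partner_col = integer(0),
               helix = character(0), state_a = character(0),
               state_b = character(0), class = character(0))
  } else {
    do.call(rbind, ev)
  }
  # per-taxon original coordinates ("not-aligned" positions)
  if (mode == "taxon_pairwise" && nrow(events) > 0L) {
    events$pos_a <- mapply(function(a, col) aln$col_map[[a]][col],
                           events$a, events$aligned_col)
    events$pos_b <- mapply(function(b, col) aln$col_map[[b]][col],
                           events$b, events$aligned_col)
  } else {
    events$pos_a <- rep(NA_integer_, nrow(events))
    events$pos_b <- rep(NA_integer_, nrow(events))
  }
  classes <- c("CBC", "hCBC", "Nst", "indel")
  counts_by_pair <- as.data.frame.matrix(
    table(factor(paste(events$a, events$b, sep = "|"),
                 levels = unique(paste(events$a, events$b, sep = "|"))),
          factor(events$class, levels = classes)))
  counts_by_helix <- as.data.frame.matrix(
    table(factor(events$helix, levels = unique(helix_labels)),
          factor(events$class, levels = classes)))
  list(events = events, counts_by_pair = counts_by_pair,
       counts_by_helix = counts_by_helix, exceptions = exceptions)
}

#' CBC count matrix between taxa
#'
#' @param events Event data frame from [tabulate_events()] run in
#'   `taxon_pairwise` mode.
#' @param taxa Taxon ids ordering the matrix.
#' @return Symmetric integer matrix of CBC counts with zero diagonal.
#' @export
cbc_matrix <- function(events, taxa) {
  M <- matrix(0L, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  cb <- events[events$class == "CBC", , drop = FALSE]
  for (k in seq_len(nrow(cb))) {
    a <- cb$a[k]; b <- cb$b[k]
    M[a, b] <- M[a, b] + 1L
    M[b, a] <- M[b, a] + 1L
  }
  M
}

#' Write an event catalog to CSV
#'
#' Columns mirror the supplementary-table layout: the two units compared,
#' aligned and per-taxon original positions, helix, states and class.
#'
#' @param result Result of [tabulate_events()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_catalog <- function(result, path) {
  ev <- result$events
  utils::write.csv(ev[, c("a", "b", "aligned_col", "partner_col",
                          "pos_a", "pos_b", "helix",
                          "state_a", "state_b", "class")],
                   path, row.names = FALSE)
  invisible(path)
}
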