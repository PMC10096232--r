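# Motif-anchored annotation of ITS1 / 5.8S / ITS2 within a full ITS
# amplicon, and harmonization against external (e.g. database) annotations.
#
# HMM annotators (ITSx-style) are not reimplemented; conserved motif anchors
# with a mismatch budget approximate them, which matches how published
# boundary corrections are themselves motif-driven (the CAUAU boundary).

#' Default anchor set
#'
#' Two anchors locate the 5.8S gene: its start (5.8S Motif I, mismatch
#' budget 1) and its end (the `CAUAU` 5.8S/ITS2 boundary motif, budget 0 -
#' boundary anchors are exact). ITS1 is everything before the 5.8S start
#' and ITS2 everything after its end.
#'
#' @return Data frame: `name`, `pattern`, `edge`, `max_mismatches`.
#' @export
default_anchors <- function() {
  data.frame(
    name = c("5.8S_motif_I", "5.8S_ITS2_boundary"),
    pattern = c(MOTIF_5_8S_I, BOUNDARY_5_8S_ITS2),
    edge = c("FIVE_EIGHT_S_start", "FIVE_EIGHT_S_end"),
    max_mismatches = c(1L, 0L),
    stringsAsFactors = FALSE
  )
}

# Minimum plausible region lengths used to bound anchor search windows.
default_min_region_len <- function() {
  c(ITS1 = 100L, `5.8S` = 150L, ITS2 = 100L)
}

#' Annotate ITS1, 5.8S and ITS2 within a full ITS record
#'
#' Anchors are searched within plausibility windows derived from the
#' minimum region lengths; among multiple hits the leftmost within a window
#' of +/-30 nt around the expected position is used and a warning emitted.
#' An anchor absent within its mismatch budget leaves the corresponding
#' boundary unresolved (the region interval is reported as `NA`), never
#' guessed.
#'
#' @param record A [seq_struct_record()] with `region = "FULL_ITS"`.
#' @param anchors Anchor table as in [default_anchors()]; must include the
#'   5.8S start and end anchors.
#' @param min_region_len Named minimum lengths for ITS1, 5.8S, ITS2.
#' @param expected_5_8s_len Expected 5.8S length used to center the
#'   boundary-anchor window (default 160).
#' @param window Half-width of the anchor search window (default 30 nt).
#' @return List of class `RegionAnnotation`: `record_id`, `intervals`
#'   (named list of `c(start, end)`, 1-based inclusive, `NA` when
#'   unresolved), `anchors` (hit table), `unresolved` (edge names),
#'   `trims` (all zero until [harmonize_boundaries()]).
#' @export
annotate_regions <- function(record, anchors = default_anchors(),
                             min_region_len = default_min_region_len(),
                             expected_5_8s_len = 160L, window = 30L) {
  stopifnot(inherits(record, "SeqStructRecord"))
  if (record$region != "FULL_ITS") {
    stop(sprintf("%s: annotate_regions expects a FULL_ITS record", record$id))
  }
  if (!all(c("FIVE_EIGHT_S_start", "FIVE_EIGHT_S_end") %in% anchors$edge)) {
    stop("anchor set must include the 5.8S start and end anchors")
  }
  len <- nchar(record$seq)
  if (len < sum(min_region_len)) {
    stop(sprintf("%s: sequence shorter (%d) than the minimum region lengths (%d)",
                 record$id, len, sum(min_region_len)))
  }
  unresolved <- character(0)
  hits_out <- list()

  pick_hit <- function(hits, win_lo, win_hi, anchor_name) {
    if (nrow(hits) == 0L) return(NULL)
    inwin <- hits[hits$start >= win_lo & hits$start <= win_hi, , drop = FALSE]
    if (nrow(inwin) == 0L) return(NULL)
    if (nrow(inwin) > 1L) {
      warning(sprintf("%s: multiple %s anchor hits; using the leftmost",
                      record$id, anchor_name), call. = FALSE)
    }
    inwin[1L, , drop = FALSE]
  }

  # 5.8S start anchor: must leave room for ITS1 before and 5.8S+ITS2 after
  a_start <- anchors[anchors$edge == "FIVE_EIGHT_S_start", ][1L, ]
  hits <- iupac_hits(record$seq, a_start$pattern, a_start$max_mismatches)
  lo <- min_region_len[["ITS1"]] + 1L
  hi <- len - min_region_len[["5.8S"]] - min_region_len[["ITS2"]] + 1L
  start_hit <- pick_hit(hits, lo, hi, a_start$name)
  s58_start <- NA_integer_
  if (is.null(start_hit)) {
    unresolved <- c(unresolved, "FIVE_EIGHT_S_start")
  } else {
    s58_start <- start_hit$start
    hits_out[[length(hits_out) + 1L]] <-
      cbind(name = a_start$name, start_hit)
  }

  # 5.8S end anchor: window of +/- `window` around the expected position
  a_end <- anchors[anchors$edge == "FIVE_EIGHT_S_end", ][1L, ]
  hits <- iupac_hits(record$seq, a_end$pattern, a_end$max_mismatches)
  plen <- nchar(a_end$pattern)
  if (!is.na(s58_start)) {
    expected_start <- s58_start + expected_5_8s_len - plen
    win_lo <- expected_start - window
    win_hi <- expected_start + window
  } else {
    # without the start anchor, accept any position that leaves room for
    # ITS1 + 5.8S before and ITS2 after
    win_lo <- min_region_len[["ITS1"]] + min_region_len[["5.8S"]] - plen + 1L
    win_hi <- len - min_region_len[["ITS2"]] - plen + 1L
  }
  end_hit <- pick_hit(hits, win_lo, win_hi, a_end$name)
  s58_end <- NA_integer_
  if (is.null(end_hit)) {
    unresolved <- c(unresolved, "FIVE_EIGHT_S_end")
  } else {
    s58_end <- end_hit$end
    hits_out[[length(hits_out) + 1L]] <- cbind(name = a_end$name, end_hit)
  }

  if (is.na(s58_start) && is.na(s58_end)) {
    stop(sprintf("%s: unannotatable (no anchor found)", record$id))
  }

  intervals <- list(
    ITS1 = if (is.na(s58_start)) c(NA_integer_, NA_integer_) else
      c(1L, s58_start - 1L),
    `5.8S` = c(s58_start, s58_end),
    ITS2 = if (is.na(s58_end)) c(NA_integer_, NA_integer_) else
      c(s58_end + 1L, len)
  )
  if (!anyNA(intervals$`5.8S`) && intervals$`5.8S`[2L] <= intervals$`5.8S`[1L]) {
    stop(sprintf("%s: inconsistent anchor order", record$id))
  }
  anchors_df <- if (length(hits_out) > 0L) {
    do.call(rbind, hits_out)
  } else {
    data.frame(name = character(0), start = integer(0), end = integer(0),
               mismatches = integer(0))
  }
  structure(list(record_id = record$id, intervals = intervals,
                 anchors = anchors_df, unresolved = unresolved,
                 trims = c(ITS1 = 0L, `5.8S` = 0L, ITS2 = 0L)),
            class = "RegionAnnotation")
}

#' @export
print.RegionAnnotation <- function(x, ...) {
  cat(sprintf("<RegionAnnotation %s>\n", x$record_id))
  for (reg in names(x$intervals)) {
    iv <- x$intervals[[reg]]
    cat(sprintf("  %-5s %s..%s%s\n", reg,
                ifelse(is.na(iv[1L]), "?", iv[1L]),
                ifelse(is.na(iv[2L]), "?", iv[2L]),
                if (x$trims[[reg]] != 0L) {
                  sprintf(" (trim %+d)", x$trims[[reg]])
                } else ""))
  }
  if (length(x$unresolved) > 0L) {
    cat("  unresolved:", paste(x$unresolved, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Harmonize anchor-based boundaries with an external annotation
#'
#' Returns the anchor-based annotation with its `trims` filled in: for each
#' region, the signed nt difference between the external convention and the
#' anchor-based one at the region's anchor-defined edge (ITS1 start, 5.8S
#' start, ITS2 end). Positive means the external annotation extends
#' upstream/earlier than the anchor-based one (nucleotides pruned); negative
#' means downstream. A full per-edge table (both edges of all regions) is
#' attached as attribute `"edge_trims"`.
#'
#' @param ann Anchor-based `RegionAnnotation`.
#' @param external_ann External `RegionAnnotation` for the same record.
#' @return `ann` with `trims` filled.
#' @export
harmonize_boundaries <- function(ann, external_ann) {
  stopifnot(inherits(ann, "RegionAnnotation"),
            inherits(external_ann, "RegionAnnotation"))
  if (ann$record_id != external_ann$record_id) {
    stop("annotations refer to different records")
  }
  edge_rows <- list()
  for (reg in names(ann$intervals)) {
    a <- ann$intervals[[reg]]
    e <- external_ann$intervals[[reg]]
    if (is.null(e)) e <- c(NA_integer_, NA_integer_)
    edge_rows[[length(edge_rows) + 1L]] <- data.frame(
      region = reg,
      edge = c("start", "end"),
      anchor = a,
      external = e,
      trim = a - e
    )
  }
  edge_trims <- do.call(rbind, edge_rows)
  pick <- c(ITS1 = "start", `5.8S` = "start", ITS2 = "end")
  trims <- ann$trims
  for (reg in names(pick)) {
    row <- edge_trims[edge_trims$region == reg &
                        edge_trims$edge == pick[[reg]], ]
    trims[[reg]] <- if (is.na(row$trim)) 0L else as.integer(row$trim)
  }
  ann$trims <- trims
  attr(ann, "edge_trims") <- edge_trims
  ann
}

#' Write region annotations to a TSV file
#'
#' Columns: record_id, region, start, end (1-based inclusive), anchor_name,
#' mismatches, trim.
#'
#' @param annotations List of `RegionAnnotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_tsv <- function(annotations, path) {
  rows <- list()
  for (ann in annotations) {
    for (reg in names(ann$intervals)) {
      iv <- ann$intervals[[reg]]
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = ann$record_id, region = reg,
        start = iv[1L], end = iv[2L],
        trim = ann$trims[[reg]])
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
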