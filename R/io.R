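# Readers and writers for the external formats the pipeline touches:
# multi-FASTA, Vienna dot-bracket files, Newick trees, TSV group maps.

#' Read a multi-FASTA file into sequence-structure records
#'
#' Sequences are read with Biostrings, transcribed to RNA (`T` to `U`) and
#' uppercased; records carry an empty pair set.
#'
#' @param path Path to a FASTA file.
#' @param alphabet_policy `"strict"` rejects any non-IUPAC character
#'   (including gaps); `"iupac"` additionally tolerates `-` by dropping it.
#' @param region Region label attached to every record.
#' @return List of [seq_struct_record()] objects.
#' @export
parse_fasta <- function(path, alphabet_policy = c("strict", "iupac"),
                        region = "FULL_ITS") {
  alphabet_policy <- match.arg(alphabet_policy)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("no FASTA records in %s", path))
  ids <- names(set)
  ids <- sub("\\s.*$", "", ids)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate FASTA id: %s", dup[1L]))
  }
  lapply(seq_along(set), function(k) {
    s <- as.character(set[[k]])
    if (alphabet_policy == "iupac") s <- gsub("-", "", s, fixed = TRUE)
    seq_struct_record(ids[k], s, region = region)
  })
}

#' Write records to a FASTA file
#'
#' @param records List of [seq_struct_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  lines <- unlist(lapply(records, function(r) c(paste0(">", r$id), r$seq)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Vienna dot-bracket file
#'
#' Three lines per record: a `>id` header, the sequence, and the structure
#' line with an optional trailing `(energy)` in kcal/mol.
#'
#' @param path Path to the Vienna file.
#' @param region Region label attached to every record.
#' @param source Structure provenance label for the records.
#' @return List of [seq_struct_record()].
#' @export
read_vienna <- function(path, region = "OTHER", source = "user_supplied") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 3L != 0L) {
    stop(sprintf("%s: not a 3-line-per-record Vienna file", path))
  }
  out <- vector("list", length(lines) %/% 3L)
  for (k in seq_along(out)) {
    hdr <- lines[3L * k - 2L]
    if (!startsWith(hdr, ">")) {
      stop(sprintf("%s: expected '>' header at line %d", path, 3L * k - 2L))
    }
    id <- sub("\\s.*$", "", sub("^>", "", hdr))
    seq <- trimws(lines[3L * k - 1L])
    sline <- trimws(lines[3L * k])
    energy <- NA_real_
    m <- regmatches(sline, regexec("^([().]+)\\s*\\((\\s*-?[0-9.]+)\\)\\s*$", sline))[[1]]
    if (length(m) == 3L) {
      db <- m[2L]
      energy <- as.numeric(m[3L])
    } else {
      db <- sline
    }
    if (nchar(db) != nchar(seq)) {
      stop(sprintf("%s: structure length differs from sequence length", id))
    }
    out[[k]] <- seq_struct_record(id, seq, pairs = dotbracket_to_pairs(db),
                                  region = region, energy = energy,
                                  source = source)
  }
  out
}

#' Write records to a Vienna dot-bracket file
#'
#' @param records List of [seq_struct_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(records, path) {
  lines <- unlist(lapply(records, function(r) {
    db <- pairs_to_dotbracket(r$pairs, nchar(r$seq))
    if (!is.na(r$energy)) db <- sprintf("%s (%.2f)", db, r$energy)
    c(paste0(">", r$id), r$seq, db)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a taxon-to-group map
#'
#' Two-column tab-separated file: taxon id, group label.
#'
#' @param path Path to the TSV file.
#' @return Named character vector mapping taxon id to group label.
#' @export
read_group_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("taxon", "group"),
                          colClasses = "character")
  if (anyDuplicated(df$taxon)) {
    stop(sprintf("duplicate taxon in group map: %s",
                 df$taxon[duplicated(df$taxon)][1L]))
  }
  if (any(!nzchar(df$group))) stop("empty group label in group map")
  stats::setNames(df$group, df$taxon)
}

#' Write a taxon-to-group map
#' @param groups Named character vector (names = taxa, values = groups).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_group_map <- function(groups, path) {
  utils::write.table(data.frame(taxon = names(groups), group = unname(groups)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a tree to a Newick file
#'
#' Branch lengths are kept to full precision; bootstrap support values, when
#' present in `tree$node.label`, are written as internal-node labels.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("write_newick: not a phylo tree")
  if (is.null(tree$tip.label) || length(tree$tip.label) == 0L) {
    stop("write_newick: empty tree")
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick file
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ape::read.tree(path)
}
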