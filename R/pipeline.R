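# End-to-end orchestration: annotate -> structures -> align -> events ->
# consensus -> motifs -> diversity -> trees, from one configuration, with
# every output re-loadable from disk.

#' Run the full sequence-structure analysis pipeline
#'
#' The configuration either simulates a family (`simulate` block, a
#' [synth_config()]) or names input files (`fasta`, optional `structs`
#' Vienna file, `groups` TSV or named vector). All stages write their
#' outputs under `out_dir` and a JSON metadata file records every parameter
#' and seed; deterministic stages are bit-identical across reruns of the
#' same configuration.
#'
#' @param config List: either `simulate = synth_config(...)` or
#'   `fasta = <path>` (plus optional `structs`, a Vienna file); `groups`
#'   (path or named vector; defaults to one group per taxon prefix for
#'   simulated data); optional `use_true_alignment` (default `TRUE` for
#'   simulated input), `bootstrap_reps` (default 1000), `seed` (default 1),
#'   `min_identity` (template modeling, default 0.75).
#' @param out_dir Output directory (created if absent).
#' @return List of class `its_pipeline_result` with the main objects and
#'   file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", generate_family(config$simulate))
    records <- sim$records
    truth <- sim$truth
    write_fasta(records, file.path(out_dir, "input.fasta"))
    write_newick(truth$tree, file.path(out_dir, "true_tree.nwk"))
    utils::write.csv(truth$events, file.path(out_dir, "truth_events.csv"),
                     row.names = FALSE)
  } else if (!is.null(config$fasta)) {
    records <- stage("input", parse_fasta(config$fasta))
  } else {
    stop("pipeline stage 'input' failed: config needs a simulate block or a fasta path")
  }
  if (length(records) == 0L) {
    stop("pipeline stage 'annotate' failed: no input records")
  }

  groups <- config$groups
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    groups <- read_group_map(groups)
  }
  if (is.null(groups)) {
    ids <- vapply(records, function(r) r$id, "")
    if (!is.null(truth)) {
      # default grouping for simulated data: the two clades of the root split
      tr <- truth$tree
      root <- length(tr$tip.label) + 1L
      first_child <- tr$edge[tr$edge[, 1L] == root, 2L][1L]
      in_a <- if (first_child <= length(tr$tip.label)) {
        tr$tip.label[first_child]
      } else {
        ape::extract.clade(tr, first_child)$tip.label
      }
      groups <- stats::setNames(ifelse(ids %in% in_a, "A", "B"), ids)
    } else {
      groups <- stats::setNames(sub("[0-9]+$", "", ids), ids)
    }
  }

  # --- annotation ---
  annotations <- stage("annotate", lapply(records, annotate_regions))
  names(annotations) <- vapply(records, function(r) r$id, "")
  write_regions_tsv(annotations, file.path(out_dir, "regions.tsv"))

  # --- structures: true structures for simulated data, template modeling
  # for user input ---
  its2_records <- stage("structures", {
    lapply(seq_along(records), function(k) {
      rec <- records[[k]]
      ann <- annotations[[rec$id]]
      iv <- ann$intervals$ITS2
      if (anyNA(iv)) stop(sprintf("%s: ITS2 unresolved", rec$id))
      its2_seq <- substr(rec$seq, iv[1L], iv[2L])
      if (!is.null(truth)) {
        # project the true structure onto the ITS2 interval
        full <- rec$pairs
        keep <- full[, 1L] >= iv[1L] & full[, 2L] <= iv[2L]
        seq_struct_record(rec$id, its2_seq,
                          pairs = full[keep, , drop = FALSE] - iv[1L] + 1L,
                          region = "ITS2", source = "user_supplied")
      } else {
        model_from_template(its2_seq, its2_template(),
                            min_identity = if (is.null(config$min_identity))
                              0.75 else config$min_identity,
                            id = rec$id)
      }
    })
  })
  write_vienna(its2_records, file.path(out_dir, "structs.db"))

  # --- alignment ---
  aln <- stage("align", {
    if (!is.null(truth) && !isFALSE(config$use_true_alignment)) {
      truth$alignment
    } else {
      align_seqstruct(its2_records)
    }
  })
  write_ssaln(aln, file.path(out_dir, "aln.ssfasta"))

  # --- helix labels from the template decomposition of the first record ---
  helix_labels <- stage("helices", {
    ref <- aln$taxa[1L]
    decomp <- enumerate_helices(aln_record(aln, ref))
    column_helix_labels(aln, ref, decomp)
  })

  # --- events ---
  ev_taxon <- stage("events", tabulate_events(aln, groups, helix_labels,
                                              mode = "taxon_pairwise"))
  write_event_catalog(ev_taxon, file.path(out_dir, "events.csv"))
  ev_group <- stage("events", tabulate_events(aln, groups, helix_labels,
                                              mode = "group_level"))
  write_event_catalog(ev_group, file.path(out_dir, "events_groups.csv"))

  # --- consensus per group with >= 2 members ---
  consensus <- stage("consensus", {
    out <- list()
    for (g in unique(unname(groups[aln$taxa]))) {
      members <- aln$taxa[unname(groups[aln$taxa]) == g]
      if (length(members) < 2L) next
      cm <- build_consensus(aln, members, group = g)
      write_consensus(cm,
                      vienna_path = file.path(out_dir,
                                              sprintf("consensus_%s.db", g)),
                      conservation_path = file.path(
                        out_dir, sprintf("conservation_%s.tsv", g)))
      out[[g]] <- cm
    }
    out
  })

  # --- motifs and pseudogene screen ---
  screen <- stage("motifs", {
    hits <- list(); verdicts <- list()
    for (rec in records) {
      ann <- annotations[[rec$id]]
      h <- scan_packaged_motifs(rec, ann)
      hits[[rec$id]] <- h
      verdicts[[rec$id]] <- screen_pseudogene(rec, ann, motif_results = h)
    }
    hit_df <- do.call(rbind, hits)
    utils::write.table(hit_df, file.path(out_dir, "motifs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    vdf <- data.frame(
      record_id = vapply(verdicts, `[[`, "", "record_id"),
      pass = vapply(verdicts, `[[`, TRUE, "pass"),
      reasons = vapply(verdicts, function(v) {
        paste(v$reasons, collapse = "; ")
      }, ""))
    utils::write.table(vdf, file.path(out_dir, "pseudogene_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(hits = hit_df, verdicts = verdicts)
  })

  # --- diversity and distances (on the ITS2 alignment) ---
  div <- stage("diversity",
               diversity_indices(aln, label = if (!is.null(truth) &&
                                                  !isFALSE(config$use_true_alignment))
                 "full_ITS" else "ITS2"))
  utils::write.table(div, file.path(out_dir, "diversity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dist_tab <- stage("distances", {
    group_distances(aln, groups,
                    se_reps = if (is.null(config$se_reps)) 1000L else
                      config$se_reps,
                    seed = seed)
  })
  utils::write.table(round(dist_tab$between, 6),
                     file.path(out_dir, "distances_between.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(data.frame(group = names(dist_tab$within),
                                within = round(dist_tab$within, 6)),
                     file.path(out_dir, "distances_within.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- trees ---
  reps <- if (is.null(config$bootstrap_reps)) 1000L else
    as.integer(config$bootstrap_reps)
  nj <- stage("trees", bootstrap_support(aln, nj_tree, reps = reps,
                                         seed = seed))
  write_newick(nj, file.path(out_dir, "nj_tree.nwk"))
  cbc_tree <- stage("trees", {
    M <- cbc_matrix(ev_taxon$events, aln$taxa)
    upgma_tree(M)
  })
  write_newick(cbc_tree, file.path(out_dir, "cbc_tree.nwk"))

  meta <- list(
    seed = seed,
    n_records = length(records),
    simulated = !is.null(truth),
    bootstrap_reps = reps,
    config = config[setdiff(names(config), "simulate")],
    simulate = if (!is.null(config$simulate)) {
      unclass(config$simulate)[c("n_taxa", "total_tree_len", "rates",
                                 "n_insert_slots", "seed")]
    }
  )
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  structure(list(records = records, annotations = annotations,
                 its2_records = its2_records, alignment = aln,
                 events_taxon = ev_taxon, events_group = ev_group,
                 consensus = consensus, screen = screen,
                 diversity = div, distances = dist_tab,
                 nj_tree = nj, cbc_tree = cbc_tree, truth = truth,
                 out_dir = out_dir),
            class = "its_pipeline_result")
}

#' Write a sequence-structure alignment as paired FASTA
#'
#' Two lines per taxon after the header: the gapped sequence and the gapped
#' dot-bracket structure.
#'
#' @param aln A `SeqStructAlignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ssaln <- function(aln, path) {
  lines <- character(0)
  for (r in seq_len(nrow(aln$states))) {
    st <- aln$states[r, ]
    base <- ifelse(st == 0L, "-", state_base(st))
    role <- ifelse(st == 0L, "-",
                   ROLE_CHAR[match(state_role(st), ROLES)])
    lines <- c(lines, paste0(">", aln$taxa[r]),
               paste(base, collapse = ""), paste(role, collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a paired-FASTA sequence-structure alignment
#'
#' @param path File written by [write_ssaln()].
#' @param threshold Pairing vote threshold.
#' @return A `SeqStructAlignment`.
#' @export
read_ssaln <- function(path, threshold = 0.5) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  stopifnot(length(lines) %% 3L == 0L)
  ids <- sub("^>", "", lines[seq(1L, length(lines), by = 3L)])
  seqs <- lines[seq(2L, length(lines), by = 3L)]
  dbs <- chartr("-", ".", lines[seq(3L, length(lines), by = 3L)])
  # structure line uses '-' at gap positions; convert to '.' and rely on the
  # sequence line for gap placement
  ssalignment_from_gapped(ids, seqs, dbs, threshold = threshold)
}
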