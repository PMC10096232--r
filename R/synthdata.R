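# Structure-aware simulator of ITS families: a root built from the packaged
# ITS1 / 5.8S / ITS2 templates evolves along a known tree under planted
# CBC / hCBC / Nst / indel events, yielding records, a true alignment and a
# replayable event log. Event sites are sampled without replacement globally
# across the whole tree, so every alignment site carries at most one event
# and planted counts are recoverable exactly from leaf comparisons.

#' Simulator configuration
#'
#' Rates are expected event counts per unit branch length; with the default
#' tree scaling (total branch length `total_tree_len`) the expected family-
#' wide budget is `rate * total_tree_len` events per class. The defaults
#' emulate a tribe-scale survey compressed to desk size: about 6 CBCs, 30
#' hCBCs, 90 Nsts (roughly half on helices) and a few loop indels.
#'
#' @param n_taxa Number of leaves (default 12).
#' @param tree Optional fixed tree ([ape::phylo] or Newick string); when
#'   `NULL` a random rooted tree is drawn and rescaled.
#' @param total_tree_len Total branch length after rescaling (default 5).
#' @param cbc_rate,hcbc_rate,nst_helix_rate,nst_loop_rate,indel_loop_rate
#'   Event rates per unit branch length.
#' @param pseudogene_rate Rate of motif-ablation events per unit branch
#'   length (default 0).
#' @param n_insert_slots Latent insertion slots available in loops
#'   (split between ITS1 and ITS2).
#' @param seed Random seed; fixed seed gives bit-identical output.
#' @return List of class `SynthConfig`.
#' @export
synth_config <- function(n_taxa = 12L, tree = NULL, total_tree_len = 5,
                         cbc_rate = 1.2, hcbc_rate = 6,
                         nst_helix_rate = 9, nst_loop_rate = 9,
                         indel_loop_rate = 0.8, pseudogene_rate = 0,
                         n_insert_slots = 6L, seed = 1L) {
  rates <- c(cbc = cbc_rate, hcbc = hcbc_rate, nst_helix = nst_helix_rate,
             nst_loop = nst_loop_rate, indel = indel_loop_rate,
             pseudogene = pseudogene_rate)
  stopifnot(all(rates >= 0), n_taxa >= 3L, total_tree_len > 0)
  structure(list(n_taxa = as.integer(n_taxa), tree = tree,
                 total_tree_len = total_tree_len, rates = rates,
                 n_insert_slots = as.integer(n_insert_slots),
                 seed = as.integer(seed)),
            class = "SynthConfig")
}

# Root genome in "column space": template concatenation plus latent
# insertion columns (absent at the root), with per-column region, pairing
# partner, locked flag and pool memberships.
build_root_columns <- function(n_insert_slots, extra_5_8s = 0L) {
  its1 <- its1_template()
  f58 <- rrna_5_8s_template(extra = extra_5_8s)
  its2 <- its2_template()
  lens <- c(ITS1 = nchar(its1$seq), `5.8S` = nchar(f58$seq),
            ITS2 = nchar(its2$seq))
  offs <- c(ITS1 = 0L, `5.8S` = lens[["ITS1"]],
            ITS2 = lens[["ITS1"]] + lens[["5.8S"]])
  base_chars <- c(strsplit(its1$seq, "")[[1]], strsplit(f58$seq, "")[[1]],
                  strsplit(its2$seq, "")[[1]])
  n_base <- length(base_chars)
  base_region <- rep(names(lens), lens)
  base_pairs <- rbind(its1$pairs,
                      f58$pairs + offs[["5.8S"]],
                      its2$pairs + offs[["ITS2"]])
  # locked positions: conserved motifs and anchors that evolution never hits
  locked <- rep(FALSE, n_base)
  lock_hits <- function(region, pattern, block2 = NULL,
                        spacer_range = c(0L, 0L)) {
    sub <- paste(base_chars[base_region == region], collapse = "")
    h <- scan_motif(sub, pattern, max_mismatches = 0L, block2 = block2,
                    spacer_range = spacer_range)
    for (k in seq_len(nrow(h))) {
      locked[offs[[region]] + (h$start[k]:h$end[k])] <<- TRUE
    }
  }
  lock_hits("5.8S", MOTIF_5_8S_I)
  lock_hits("5.8S", MOTIF_5_8S_II)
  lock_hits("5.8S", MOTIF_5_8S_III)
  lock_hits("5.8S", "AAGAA")
  lock_hits("5.8S", PROXIMAL_STEM_5_8S)
  lock_hits("ITS1", ITS1_CORE_BLOCK1, block2 = ITS1_CORE_BLOCK2,
            spacer_range = c(3L, 6L))
  lock_hits("ITS2", "UGGU")
  lock_hits("ITS2", "AAA")
  # latent insertion slots after evenly spaced unpaired, unlocked loop
  # positions of ITS1 and ITS2
  paired_base <- rep(FALSE, n_base)
  paired_base[as.vector(base_pairs)] <- TRUE
  pick_anchors <- function(region, k) {
    elig <- which(base_region == region & !paired_base & !locked)
    elig <- elig[elig > offs[[region]] + 5L]
    elig[round(seq(1L, length(elig), length.out = k + 2L))[2:(k + 1L)]]
  }
  k1 <- n_insert_slots %/% 2L
  anchors <- sort(c(pick_anchors("ITS1", k1),
                    pick_anchors("ITS2", n_insert_slots - k1)))
  # column space: base columns in order, a latent column after each anchor
  n_col <- n_base + length(anchors)
  is_latent <- rep(FALSE, n_col)
  col_of_base <- seq_len(n_base) + findInterval(seq_len(n_base) - 0.5, anchors)
  is_latent[setdiff(seq_len(n_col), col_of_base)] <- TRUE
  region <- rep(NA_character_, n_col)
  region[col_of_base] <- base_region
  region[is_latent] <- base_region[anchors]
  base_pos <- rep(NA_integer_, n_col)
  base_pos[col_of_base] <- seq_len(n_base)
  root <- rep("-", n_col)
  root[col_of_base] <- base_chars
  col_pairs <- cbind(col_of_base[base_pairs[, 1L]],
                     col_of_base[base_pairs[, 2L]])
  locked_col <- rep(FALSE, n_col)
  locked_col[col_of_base] <- locked
  pos_in_region <- rep(NA_integer_, n_col)
  pos_in_region[col_of_base] <- seq_len(n_base) - offs[match(base_region, names(offs))]
  list(root = root, region = region, base_pos = base_pos,
       pos_in_region = pos_in_region, pairs = col_pairs,
       locked = locked_col, is_latent = is_latent,
       lens = lens, offs = offs,
       motif_I_cols = col_of_base[offs[["5.8S"]] + 1:16])
}

# Single-base variants of an allowed pair, by outcome class.
pair_variants <- function(b5, b3) {
  cbc <- list(); hcbc <- list(); nst <- list()
  for (x in RNA_BASES) {
    for (y in RNA_BASES) {
      if (x == b5 && y == b3) next
      ok <- is_allowed_pair(x, y)
      nd <- (x != b5) + (y != b3)
      if (nd == 2L && ok) cbc[[length(cbc) + 1L]] <- c(x, y)
      if (nd == 1L && ok) hcbc[[length(hcbc) + 1L]] <- c(x, y)
      if (nd == 1L && !ok) nst[[length(nst) + 1L]] <- c(x, y)
    }
  }
  list(cbc = cbc, hcbc = hcbc, nst = nst)
}

#' Generate a synthetic ITS family with planted events
#'
#' Evolves the packaged ITS1+5.8S+ITS2 root along a tree, planting CBCs
#' (compensatory double substitutions at paired sites), hCBCs (single
#' substitutions preserving an allowed pair), Nsts (pair-breaking or loop
#' substitutions) and loop indels, each at a site used by no other event.
#' Motif blocks are immutable unless a pseudogene event fires, which ablates
#' 5.8S Motif I and flags the descendant leaves.
#'
#' @param cfg A [synth_config()].
#' @return List with `records` (leaf [seq_struct_record()]s, `FULL_ITS`),
#'   and `truth`: `tree`, `alignment` (a `SeqStructAlignment` over the true
#'   column space), `events` (the planted log), `intervals` (per-leaf region
#'   intervals in leaf coordinates), `pseudogene_flags`, `columns` (column
#'   metadata incl. region and helix labels), `paired_cols` (true pairs in
#'   alignment columns).
#' @export
generate_family <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "SynthConfig"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(cfg$seed)
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  tree <- cfg$tree
  if (is.null(tree)) {
    tree <- ape::rtree(cfg$n_taxa)
  } else if (is.character(tree)) {
    tree <- ape::read.tree(text = tree)
  }
  tree$edge.length <- tree$edge.length / sum(tree$edge.length) *
    cfg$total_tree_len
  # root 5.8S length drawn from the observed 160-162 nt range
  extra_5_8s <- sample(0:2, 1L)
  cols <- build_root_columns(cfg$n_insert_slots, extra_5_8s = extra_5_8s)
  n_col <- length(cols$root)
  n_tip <- length(tree$tip.label)
  root_node <- n_tip + 1L

  # global site pools (without-replacement); deletions are confined to the
  # spacers (the 5.8S gene is length-invariant at this scale)
  pool_pairs <- which(!cols$locked[cols$pairs[, 1L]] &
                        !cols$locked[cols$pairs[, 2L]])
  pool_loop <- which(!cols$locked & !cols$is_latent & cols$root != "-" &
                       !(seq_len(n_col) %in% as.vector(cols$pairs)))
  pool_latent <- which(cols$is_latent)
  deletable <- cols$region != "5.8S"

  states <- matrix(NA_character_, n_tip + tree$Nnode, n_col)
  states[root_node, ] <- cols$root
  events <- list()
  pseudo_nodes <- integer(0)

  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  edge_len <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1L]; child <- edges[e, 2L]; t <- edge_len[e]
    s <- states[parent, ]
    log_ev <- function(class, col, st_par, st_chi, partner = NA_integer_) {
      events[[length(events) + 1L]] <<- data.frame(
        parent_node = parent, child_node = child, class = class,
        col = col, partner_col = partner,
        region = cols$region[col],
        pos_in_region = cols$pos_in_region[col],
        state_parent = st_par, state_child = st_chi)
    }
    counts <- stats::rpois(6L, cfg$rates * t)
    names(counts) <- names(cfg$rates)
    # paired-site events
    for (class in c("cbc", "hcbc", "nst_helix")) {
      k <- counts[[class]]
      if (k == 0L) next
      if (length(pool_pairs) < k) {
        stop("event rates too high for the available sites; lower the rates")
      }
      picked <- if (length(pool_pairs) == 1L) pool_pairs else
        sample(pool_pairs, k)
      pool_pairs <- setdiff(pool_pairs, picked)
      for (pr in picked) {
        p <- cols$pairs[pr, 1L]; q <- cols$pairs[pr, 2L]
        vars <- pair_variants(s[p], s[q])
        choice <- switch(class, cbc = vars$cbc, hcbc = vars$hcbc,
                         nst_helix = vars$nst)
        newpair <- choice[[sample.int(length(choice), 1L)]]
        log_ev(switch(class, cbc = "CBC", hcbc = "hCBC", nst_helix = "Nst"),
               p, paste(s[p], s[q], sep = ":"),
               paste(newpair, collapse = ":"), partner = q)
        s[p] <- newpair[1L]; s[q] <- newpair[2L]
      }
    }
    # loop substitutions
    if (counts[["nst_loop"]] > 0L) {
      k <- counts[["nst_loop"]]
      if (length(pool_loop) < k) {
        stop("event rates too high for the available sites; lower the rates")
      }
      picked <- if (length(pool_loop) == 1L) pool_loop else
        sample(pool_loop, k)
      pool_loop <- setdiff(pool_loop, picked)
      for (col in picked) {
        newb <- sample(setdiff(RNA_BASES, s[col]), 1L)
        log_ev("Nst", col, s[col], newb)
        s[col] <- newb
      }
    }
    # loop indels: insertions fill latent columns, deletions gap loop sites
    if (counts[["indel"]] > 0L) {
      for (dummy in seq_len(counts[["indel"]])) {
        insert <- length(pool_latent) > 0L && stats::runif(1) < 0.5
        if (insert) {
          col <- if (length(pool_latent) == 1L) pool_latent else
            sample(pool_latent, 1L)
          pool_latent <- setdiff(pool_latent, col)
          newb <- sample(RNA_BASES, 1L)
          log_ev("indel", col, "-", newb)
          s[col] <- newb
        } else {
          del_pool <- pool_loop[deletable[pool_loop]]
          if (length(del_pool) == 0L) {
            stop("event rates too high for the available sites; lower the rates")
          }
          col <- if (length(del_pool) == 1L) del_pool else
            sample(del_pool, 1L)
          pool_loop <- setdiff(pool_loop, col)
          log_ev("indel", col, s[col], "-")
          s[col] <- "-"
        }
      }
    }
    # pseudogenization: ablate 5.8S Motif I
    if (counts[["pseudogene"]] > 0L) {
      abl <- cols$motif_I_cols[1:3]
      old <- s[abl]
      s[abl] <- vapply(old, function(b) sample(setdiff(RNA_BASES, b), 1L), "")
      log_ev("pseudogene", abl[1L], paste(old, collapse = ""),
             paste(s[abl], collapse = ""))
      pseudo_nodes <- c(pseudo_nodes, child)
    }
    states[child, ] <- s
  }

  # propagate pseudogene flags to descendant leaves
  flag <- vapply(seq_len(n_tip), function(tip) {
    anc <- c(tip, ape::nodepath(tree, root_node, tip))
    any(pseudo_nodes %in% anc)
  }, TRUE)
  names(flag) <- tree$tip.label

  events <- if (length(events) > 0L) do.call(rbind, events) else
    data.frame(parent_node = integer(0), child_node = integer(0),
               class = character(0), col = integer(0),
               partner_col = integer(0), region = character(0),
               pos_in_region = integer(0), state_parent = character(0),
               state_child = character(0))

  # leaf records and the true alignment
  leaf_states <- states[seq_len(n_tip), , drop = FALSE]
  rownames(leaf_states) <- tree$tip.label
  keep_col <- colSums(leaf_states != "-") > 0L
  aln_states <- matrix(0L, n_tip, sum(keep_col),
                       dimnames = list(tree$tip.label, NULL))
  col_ids <- which(keep_col)
  col_index <- match(seq_len(n_col), col_ids)  # column-space -> aligned col
  records <- vector("list", n_tip)
  intervals <- vector("list", n_tip)
  for (r in seq_len(n_tip)) {
    chars <- leaf_states[r, ]
    ng <- chars != "-"
    leaf_pos <- cumsum(ng)
    # leaf structure: template pairs present and allowed in this leaf
    keep_pair <- ng[cols$pairs[, 1L]] & ng[cols$pairs[, 2L]] &
      is_allowed_pair(chars[cols$pairs[, 1L]], chars[cols$pairs[, 2L]])
    lp <- cbind(leaf_pos[cols$pairs[keep_pair, 1L]],
                leaf_pos[cols$pairs[keep_pair, 2L]])
    records[[r]] <- seq_struct_record(tree$tip.label[r],
                                      paste(chars[ng], collapse = ""),
                                      pairs = lp, region = "FULL_ITS")
    role <- rep("unpaired", n_col)
    role[cols$pairs[keep_pair, 1L]] <- "open"
    role[cols$pairs[keep_pair, 2L]] <- "close"
    aln_states[r, col_index[ng]] <- state_index(chars[ng], role[ng])
    intervals[[r]] <- lapply(c("ITS1", "5.8S", "ITS2"), function(reg) {
      pos <- leaf_pos[ng & cols$region == reg]
      c(min(pos), max(pos))
    })
    names(intervals[[r]]) <- c("ITS1", "5.8S", "ITS2")
  }
  names(intervals) <- tree$tip.label
  aln <- new_ssalignment(aln_states, threshold = 0.5)
  events$aligned_col <- col_index[events$col]
  events$aligned_partner <- ifelse(is.na(events$partner_col), NA_integer_,
                                   col_index[events$partner_col])
  truth <- structure(
    list(tree = tree, alignment = aln, events = events,
         intervals = intervals, pseudogene_flags = flag,
         columns = list(region = cols$region[keep_col],
                        base_pos = cols$base_pos[keep_col],
                        is_latent = cols$is_latent[keep_col]),
         paired_cols = cbind(col_index[cols$pairs[, 1L]],
                             col_index[cols$pairs[, 2L]]),
         extra_5_8s = extra_5_8s,
         config = cfg),
    class = "SynthTruth")
  list(records = records, truth = truth)
}

#' Planted event counts along the path between two leaves
#'
#' Sums the logged events over the branches connecting `a` and `b`; because
#' sites host at most one event family-wide, these equal the class counts an
#' exact pairwise comparison of the two leaves recovers.
#'
#' @param truth `SynthTruth` from [generate_family()].
#' @param a,b Tip labels.
#' @return Named integer vector over CBC, hCBC, Nst, indel.
#' @export
truth_path_counts <- function(truth, a, b) {
  tree <- truth$tree
  ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
  if (is.na(ia) || is.na(ib)) stop("unknown tip label")
  path_nodes <- ape::nodepath(tree, ia, ib)
  # branches on the path: identified by their child node (the node of each
  # consecutive pair that is farther from the root)
  on_path <- integer(0)
  for (k in seq_len(length(path_nodes) - 1L)) {
    x <- path_nodes[k]; y <- path_nodes[k + 1L]
    child <- if (any(tree$edge[, 1L] == x & tree$edge[, 2L] == y)) y else x
    on_path <- c(on_path, child)
  }
  ev <- truth$events[truth$events$child_node %in% on_path &
                       truth$events$class %in%
                       c("CBC", "hCBC", "Nst", "indel"), , drop = FALSE]
  counts <- table(factor(ev$class, levels = c("CBC", "hCBC", "Nst", "indel")))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Replay the event log from the root to a leaf
#'
#' Reapplies every logged event along the root-to-leaf path; the result
#' must equal the emitted leaf sequence exactly (log-consistency oracle).
#'
#' @param truth `SynthTruth`.
#' @param leaf Tip label.
#' @return The reconstructed (ungapped) sequence string.
#' @export
replay_events <- function(truth, leaf) {
  tree <- truth$tree
  tip <- match(leaf, tree$tip.label)
  if (is.na(tip)) stop("unknown tip label")
  root_node <- length(tree$tip.label) + 1L
  cols <- build_root_columns(truth$config$n_insert_slots,
                             extra_5_8s = truth$extra_5_8s)
  s <- cols$root
  path_nodes <- ape::nodepath(tree, root_node, tip)
  for (k in seq_len(length(path_nodes) - 1L)) {
    child <- path_nodes[k + 1L]
    ev <- truth$events[truth$events$child_node == child, , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      if (ev$class[i] %in% c("CBC", "hCBC", "Nst") &&
          !is.na(ev$partner_col[i])) {
        newpair <- strsplit(ev$state_child[i], ":", fixed = TRUE)[[1]]
        s[ev$col[i]] <- newpair[1L]
        s[ev$partner_col[i]] <- newpair[2L]
      } else if (ev$class[i] == "pseudogene") {
        newb <- strsplit(ev$state_child[i], "", fixed = TRUE)[[1]]
        abl <- cols$motif_I_cols[seq_along(newb)]
        s[abl] <- newb
      } else {
        s[ev$col[i]] <- ev$state_child[i]
      }
    }
  }
  paste(s[s != "-"], collapse = "")
}

#' Printed-exemplar toy set for the CBC classifier
#'
#' A deterministic micro-alignment encoding the published paired-position
#' states of the tribe's ITS2 survey: five diagnostic column pairs
#' (39/70 and 47/64 in Helix I, 85/113 and 97/101 in Helix II, 148/186 in
#' Helix III, 1-based) carry the printed states of the named taxa and
#' clades; every other column is identical across rows.
#'
#' @return List with `alignment` (a gap-free `SeqStructAlignment`) and
#'   `groups` (named group map).
#' @export
make_toy_cbc_set <- function() {
  L <- 212L
  pairs <- rbind(
    # Helix I outer + inner stems (contains 39/70 and 47/64)
    cbind(35:40, 74:69), cbind(45:49, 66:62),
    # Helix II (contains 85/113 and 97/101)
    cbind(82:86, 116:112), cbind(95:97, 103:101),
    # Helix III (contains 148/186)
    cbind(144:149, 190:185),
    # Helix IV
    cbind(196:198, 206:204)
  )
  special <- list(`39` = 70L, `47` = 64L, `85` = 113L, `97` = 101L,
                  `148` = 186L)
  defaults <- list(`39` = c("U", "A"), `47` = c("A", "U"),
                   `85` = c("C", "G"), `97` = c("A", "U"),
                   `148` = c("A", "U"))
  overrides <- list(
    Alhagi = list(`148` = c("U", "G")),
    H_tibeticum = list(`148` = c("U", "G")),
    CEGO = list(),
    cladeS = list(),
    cladeH = list(),
    Taverniera = list(`39` = c("C", "G")),
    cladeM = list(`39` = c("C", "G")),
    cladeC = list(`39` = c("C", "G")),
    H_pabulare = list(`39` = c("U", "G")),
    H_papillosum = list(`39` = c("C", "A")),
    H_longigynophorum = list(`47` = c("G", "C")),
    H_macranthum = list(`39` = c("C", "G"), `47` = c("A", "U")),
    H_elymaiticum = list(`39` = c("C", "G"), `85` = c("U", "A")),
    H_astragaloides = list(`97` = c("G", "C")),
    H_praticola = list()
  )
  groups <- c(Alhagi = "Alhagi", H_tibeticum = "H", CEGO = "CEGO",
              cladeS = "S", cladeH = "H", Taverniera = "Taverniera",
              cladeM = "M", cladeC = "C", H_pabulare = "M",
              H_papillosum = "C", H_longigynophorum = "H",
              H_macranthum = "C", H_elymaiticum = "M",
              H_astragaloides = "H", H_praticola = "H")
  backbone <- strsplit(paste(rep("AUCG", ceiling(L / 4)), collapse = ""),
                       "")[[1]][seq_len(L)]
  # default pair states: G:C except the five printed positions
  base_chars <- backbone
  for (k in seq_len(nrow(pairs))) {
    key <- as.character(pairs[k, 1L])
    st <- if (key %in% names(defaults)) defaults[[key]] else c("G", "C")
    base_chars[pairs[k, 1L]] <- st[1L]
    base_chars[pairs[k, 2L]] <- st[2L]
  }
  taxa <- names(overrides)
  states <- matrix(0L, length(taxa), L, dimnames = list(taxa, NULL))
  for (r in seq_along(taxa)) {
    chars <- base_chars
    for (key in names(overrides[[r]])) {
      p <- as.integer(key); q <- special[[key]]
      chars[p] <- overrides[[r]][[key]][1L]
      chars[q] <- overrides[[r]][[key]][2L]
    }
    keep <- is_allowed_pair(chars[pairs[, 1L]], chars[pairs[, 2L]])
    rec <- seq_struct_record(taxa[r], paste(chars, collapse = ""),
                             pairs = pairs[keep, , drop = FALSE],
                             region = "ITS2")
    states[r, ] <- encode12(rec)
  }
  list(alignment = new_ssalignment(states, threshold = 0.5),
       groups = groups)
}
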