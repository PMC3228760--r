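#' Per-taxon copy numbers of an orthologous group
#'
#' @param group data frame with columns `gene_id` and `taxon_id` (one row per
#'   member gene); extra columns are ignored.
#' @param universe character vector of taxa over which to count; taxa absent
#'   from the group get 0, members outside the universe are ignored.
#' @return named integer vector over `universe`.
#' @export
copy_numbers <- function(group, universe) {
  stopifnot(is.data.frame(group), all(c("gene_id", "taxon_id") %in% names(group)))
  tab <- table(factor(group$taxon_id, levels = universe))
  stats::setNames(as.integer(tab), universe)
}

#' Classify the orthology relationship of a copy-number vector
#'
#' `one_to_one` when no taxon has more than one copy, `one_to_many` when
#' exactly one taxon has duplications, `many_to_many` when several do.
#' Absent taxa (count 0) do not affect the label: spanning of the full taxon
#' set is a separate criterion, enforced by [taxon_count_call()].
#'
#' @param counts named integer vector from [copy_numbers()].
#' @return one of `"one_to_one"`, `"one_to_many"`, `"many_to_many"`.
#' @export
classify_relationship <- function(counts) {
  n_multi <- sum(counts > 1L)
  if (n_multi == 0L) "one_to_one"
  else if (n_multi == 1L) "one_to_many"
  else "many_to_many"
}

new_single_copy_call <- function(group_id, genes, mode, category,
                                 allowed_events, guide_ids = NA_character_,
                                 focal = NA_character_) {
  structure(list(group_id = group_id,
                 genes = genes,
                 mode = mode,
                 category = category,
                 allowed_events = allowed_events,
                 guide_ids = guide_ids,
                 focal = focal),
            class = "single_copy_call")
}

#' @export
print.single_copy_call <- function(x, ...) {
  cat("single-copy call:", x$group_id,
      sprintf("[%s/%s]", x$mode, x$category),
      length(x$genes), "genes")
  if (nrow(x$allowed_events)) {
    ev <- paste(x$allowed_events$kind, x$allowed_events$taxon, sep = ":")
    cat("  allowed:", paste(ev, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Taxon-count single-copy call with per-genome tolerance
#'
#' The classical baseline: a group is called single-copy when every taxon of
#' the universe has exactly one member, allowing at most `tolerance` taxa to
#' deviate (a missing copy, typically an annotation gap, or a duplicate,
#' typically an unannotated pseudogene). With the default tolerance of 1 the
#' categories are `exact` (no deviation), `one_duplication` (one taxon with
#' two or more copies) and `one_loss` (one taxon with none).
#'
#' @inheritParams copy_numbers
#' @param tolerance maximum number of deviating taxa (default 1).
#' @param group_id identifier recorded on the call.
#' @return a `single_copy_call`, or `NULL` when the group does not qualify.
#' @export
taxon_count_call <- function(group, universe, tolerance = 1L, group_id = NA_character_) {
  stopifnot(tolerance >= 0L)
  counts <- copy_numbers(group, universe)
  deviating <- universe[counts != 1L]
  if (length(deviating) > tolerance) return(NULL)
  kinds <- ifelse(counts[deviating] >= 2L, "duplication", "loss")
  category <- if (length(deviating) == 0L) "exact"
    else if (all(kinds == "duplication")) "one_duplication"
    else if (all(kinds == "loss")) "one_loss"
    else "mixed"
  genes <- group$gene_id[group$taxon_id %in% universe]
  new_single_copy_call(group_id = group_id,
                       genes = sort(genes),
                       mode = "taxon_count",
                       category = category,
                       allowed_events = data.frame(kind = unname(kinds),
                                                   taxon = deviating,
                                                   stringsAsFactors = FALSE,
                                                   row.names = NULL))
}

#' Extract single-copy sub-trees from a reconciled gene tree
#'
#' Scans a reconciled (rooted, binary) gene tree for maximal sub-trees that
#' have been in single copy since the focal species-tree node: the sub-tree
#' root must map exactly to the focal node, every internal node must be a
#' speciation except duplications confined to a single terminal genome
#' (mapping to a species tip), every loss charged inside the sub-tree must be
#' of a single terminal taxon, and the number of distinct taxa carrying such
#' species-specific events must not exceed `budget`. Sub-trees whose topology
#' explicitly conflicts with the species tree are thereby excluded, and
#' families whose root maps below the focal node are not called.
#'
#' @param rec a `reconciliation` (from [reconcile_rooted()] or
#'   [best_rooting()]).
#' @param focal focal clade: a species-tree node id, a character vector of
#'   taxa (their MRCA is used), or `NULL` for the species-tree root.
#' @param budget maximum number of distinct taxa with species-specific events
#'   per sub-tree (default 1, mirroring the taxon-count tolerance).
#' @param group_id identifier recorded on the calls.
#' @param guide_id identifier of the guide species tree.
#' @return list of `single_copy_call` objects (possibly empty).
#' @export
find_single_copy_subtrees <- function(rec, focal = NULL, budget = 1L,
                                      group_id = NA_character_,
                                      guide_id = NA_character_) {
  stopifnot(inherits(rec, "reconciliation"))
  index <- rec$index
  focal_node <- resolve_focal(index, focal)
  gt <- rec$gene_tree
  n <- length(gt$tip.label)
  M <- rec$mapping
  kids <- phylo_children(gt)
  parent <- phylo_parent(gt)
  is_dup <- rep(FALSE, length(M))
  is_dup[rec$duplication_nodes] <- TRUE

  # species subtrees lost along the embedding of edge (v, c)
  lost_roots <- function(v, c) {
    out <- integer(0)
    x <- M[c]
    while (x != M[v]) {
      p <- index$parent[x]
      sib <- setdiff(index$children[[p]], x)
      if (p != M[v] || is_dup[v]) out <- c(out, sib)
      x <- p
    }
    out
  }
  sp_tip_label <- function(s) index$tree$tip.label[s]

  # postorder accumulation of admissibility per subtree
  info <- vector("list", length(M))
  for (v in phylo_postorder(gt)) {
    if (v <= n) {
      info[[v]] <- list(ok = TRUE, dup_taxa = character(0),
                        loss_taxa = character(0), leaves = v)
      next
    }
    ok <- TRUE
    dup_taxa <- character(0); loss_taxa <- character(0); leaves <- integer(0)
    if (is_dup[v]) {
      if (M[v] <= index$n_tip) dup_taxa <- sp_tip_label(M[v]) else ok <- FALSE
    }
    for (c in kids[[v]]) {
      ci <- info[[c]]
      ok <- ok && ci$ok
      dup_taxa <- union(dup_taxa, ci$dup_taxa)
      loss_taxa <- union(loss_taxa, ci$loss_taxa)
      leaves <- c(leaves, ci$leaves)
      if (ok) {
        for (s in lost_roots(v, c)) {
          if (s <= index$n_tip) loss_taxa <- union(loss_taxa, sp_tip_label(s))
          else ok <- FALSE
        }
      }
    }
    info[[v]] <- list(ok = ok, dup_taxa = dup_taxa, loss_taxa = loss_taxa,
                      leaves = leaves)
  }

  candidates <- which(M == focal_node & vapply(info, `[[`, logical(1), "ok"))
  candidates <- candidates[vapply(candidates, function(v) {
    length(union(info[[v]]$dup_taxa, info[[v]]$loss_taxa)) <= budget
  }, logical(1))]
  # maximality: drop candidates nested inside another candidate
  keep <- vapply(candidates, function(v) {
    p <- parent[v]
    while (!is.na(p)) {
      if (p %in% candidates) return(FALSE)
      p <- parent[p]
    }
    TRUE
  }, logical(1))
  candidates <- candidates[keep]

  focal_label <- if (focal_node <= index$n_tip) sp_tip_label(focal_node) else
    paste0("node", focal_node)
  lapply(candidates, function(v) {
    inf <- info[[v]]
    ev <- rbind(
      if (length(inf$dup_taxa)) data.frame(kind = "duplication",
                                           taxon = inf$dup_taxa,
                                           stringsAsFactors = FALSE),
      if (length(inf$loss_taxa)) data.frame(kind = "loss",
                                            taxon = inf$loss_taxa,
                                            stringsAsFactors = FALSE))
    if (is.null(ev)) ev <- data.frame(kind = character(0), taxon = character(0),
                                      stringsAsFactors = FALSE)
    new_single_copy_call(group_id = group_id,
                         genes = sort(gt$tip.label[inf$leaves]),
                         mode = "subtree",
                         category = "subtree",
                         allowed_events = ev,
                         guide_ids = guide_id,
                         focal = focal_label)
  })
}

resolve_focal <- function(index, focal) {
  if (is.null(focal)) return(index$root)
  if (is.numeric(focal)) {
    stopifnot(length(focal) == 1L, focal >= 1L,
              focal <= index$n_tip + index$tree$Nnode)
    return(as.integer(focal))
  }
  species_mrca(index, focal)
}

#' Pool single-copy calls across guide trees
#'
#' Calls identical in (group, gene set) are merged, recording every
#' supporting guide tree; distinct gene sets from the same group are all
#' kept. Pooling is idempotent and order-insensitive.
#'
#' @param calls list of `single_copy_call` objects.
#' @return deduplicated list of `single_copy_call` objects, sorted by group
#'   and gene set.
#' @export
pool_calls <- function(calls) {
  if (length(calls) == 0L) return(list())
  keys <- vapply(calls, function(x) {
    paste(x$group_id, paste(sort(x$genes), collapse = ","), sep = "\r")
  }, character(1))
  pooled <- lapply(split(seq_along(calls), keys), function(ix) {
    out <- calls[[ix[1]]]
    gids <- unlist(lapply(calls[ix], `[[`, "guide_ids"))
    out$guide_ids <- sort(unique(gids[!is.na(gids)]))
    if (length(out$guide_ids) == 0L) out$guide_ids <- NA_character_
    out
  })
  unname(pooled[order(names(pooled))])
}

#' Run the full single-copy discovery pipeline
#'
#' Two passes over the orthologous groups. First the taxon-count rule with
#' the per-genome tolerance is applied to every group. Groups not called that
#' have a gene tree then go through the phylogenetic rescue: collapse of
#' branches below the support threshold into soft polytomies, the
#' most-parsimonious rooting against each guide species tree, extraction of
#' single-copy sub-trees at the focal clade, and pooling of calls across
#' guide trees (and across co-optimal rootings, whose calls are unioned).
#'
#' @param groups data frame with columns `group_id`, `gene_id`, `taxon_id`.
#' @param gene_trees named list (by group id) of `phylo` objects or paths to
#'   Newick files, for the multigene groups.
#' @param guide_trees a `phylo` or named list of rooted binary guide trees.
#' @param focal character vector of taxa defining the focal clade (their MRCA
#'   in each guide tree); `NULL` uses all tips of the first guide tree.
#' @param support_threshold bootstrap collapse threshold (default 80).
#' @param tolerance taxon-count tolerance (default 1).
#' @param budget per-sub-tree species-specific event budget (default 1).
#' @param taxon_map optional named vector gene label -> taxon for gene-tree
#'   leaves; default uses the `"TAXON|gene"` convention.
#' @return `list(report, calls, taxon_count_calls, subtree_calls)`; `report`
#'   is a `pipeline_report` with the category tallies and
#'   `percent_increase = 100 * n_subtree_rescued / n_taxon_count_total`.
#' @export
run_pipeline <- function(groups, gene_trees = list(), guide_trees,
                         focal = NULL, support_threshold = 80,
                         tolerance = 1L, budget = 1L, taxon_map = NULL) {
  stopifnot(is.data.frame(groups),
            all(c("group_id", "gene_id", "taxon_id") %in% names(groups)))
  if (inherits(guide_trees, "phylo")) guide_trees <- list(guide_trees)
  if (is.null(names(guide_trees)) || any(!nzchar(names(guide_trees)))) {
    names(guide_trees) <- paste0("guide", seq_along(guide_trees))
  }
  indices <- lapply(guide_trees, build_lca_index)
  universe <- if (is.null(focal)) guide_trees[[1]]$tip.label else focal

  by_group <- split(groups, groups$group_id)
  tc_calls <- list()
  for (gid in names(by_group)) {
    call <- taxon_count_call(by_group[[gid]], universe,
                             tolerance = tolerance, group_id = gid)
    if (!is.null(call)) tc_calls[[gid]] <- call
  }

  remaining <- setdiff(names(by_group), names(tc_calls))
  sub_calls <- list()
  skipped <- character(0)
  for (gid in remaining) {
    if (!gid %in% names(gene_trees)) {
      if (nrow(by_group[[gid]]) > length(universe) ||
          length(unique(by_group[[gid]]$taxon_id)) < nrow(by_group[[gid]])) {
        skipped <- c(skipped, gid)
      }
      next
    }
    gt <- gene_trees[[gid]]
    if (is.character(gt)) gt <- read_newick(gt)
    for (guide_id in names(guide_trees)) {
      idx <- indices[[guide_id]]
      gtaxa <- leaf_taxa(gt, taxon_map = taxon_map)
      in_guide <- gt$tip.label[gtaxa %in% names(idx$tip_id)]
      if (length(in_guide) < 3L) next
      gtp <- if (length(in_guide) < length(gt$tip.label)) {
        prune_to_taxa(gt, unique(gtaxa[in_guide]), taxon_map = taxon_map)
      } else gt
      gtc <- collapse_low_support(gtp, support_threshold)
      if (length(gtc$tip.label) < 3L) next
      br <- best_rooting(gtc, taxon_map = taxon_map, index = idx)
      focal_node <- resolve_focal(idx, if (is.null(focal)) NULL else focal)
      for (e in br$co_optimal_roots$edge) {
        rec <- if (e == br$root_edge) br else
          reconcile_rooted(root_at_edge(gtc, e), taxon_map = taxon_map,
                           index = idx)
        calls <- find_single_copy_subtrees(rec, focal = focal_node,
                                           budget = budget, group_id = gid,
                                           guide_id = guide_id)
        sub_calls <- c(sub_calls, calls)
      }
    }
  }
  if (length(skipped)) {
    warning("skipped ", length(skipped),
            " multigene group(s) without a gene tree: ",
            paste(utils::head(skipped, 5), collapse = ", "), call. = FALSE)
  }
  sub_calls <- pool_calls(sub_calls)

  tc_cats <- vapply(tc_calls, `[[`, character(1), "category")
  rescued_groups <- unique(vapply(sub_calls, `[[`, character(1), "group_id"))
  n_tc <- length(tc_calls)
  report <- structure(list(
    n_taxon_count_exact = sum(tc_cats == "exact"),
    n_taxon_count_one_dup = sum(tc_cats == "one_duplication"),
    n_taxon_count_one_loss = sum(tc_cats == "one_loss"),
    n_taxon_count_total = n_tc,
    n_subtree_rescued = length(rescued_groups),
    n_total_unique = length(unique(c(names(tc_calls), rescued_groups))),
    percent_increase = if (n_tc > 0L) 100 * length(rescued_groups) / n_tc
                       else if (length(rescued_groups) == 0L) 0 else NA_real_),
    class = "pipeline_report")
  list(report = report,
       calls = c(unname(tc_calls), sub_calls),
       taxon_count_calls = unname(tc_calls),
       subtree_calls = sub_calls)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Single-copy ortholog pipeline report\n")
  cat("  taxon-count: ", x$n_taxon_count_total,
      " (exact ", x$n_taxon_count_exact,
      ", one duplication ", x$n_taxon_count_one_dup,
      ", one loss ", x$n_taxon_count_one_loss, ")\n", sep = "")
  cat("  sub-tree rescued groups:", x$n_subtree_rescued, "\n")
  cat("  total unique groups:", x$n_total_unique, "\n")
  cat(sprintf("  increase over taxon-count: %.1f%%\n", x$percent_increase))
  invisible(x)
}

#' Tabulate single-copy calls
#'
#' @param calls list of `single_copy_call` objects.
#' @return data frame with one row per call: group, mode, category, guides,
#'   allowed events and comma-joined gene ids.
#' @export
calls_to_table <- function(calls) {
  if (length(calls) == 0L) {
    return(data.frame(group_id = character(0), mode = character(0),
                      category = character(0), guides = character(0),
                      allowed_events = character(0), genes = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(calls, function(x) {
    data.frame(group_id = x$group_id,
               mode = x$mode,
               category = x$category,
               guides = paste(x$guide_ids[!is.na(x$guide_ids)], collapse = ","),
               allowed_events = paste(paste(x$allowed_events$kind,
                                            x$allowed_events$taxon, sep = ":"),
                                      collapse = ","),
               genes = paste(x$genes, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}
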