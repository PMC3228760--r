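#' Simulation configuration
#'
#' The stated world for the synthetic benchmarks: gene families evolve along
#' a species tree of unit height under a birth-death duplication-loss model,
#' with duplications arising per lineage as a Poisson process along each
#' branch (rate per unit branch length) and each copy surviving a branch of
#' length t with probability exp(-loss_rate * t). Annotation incompleteness
#' is emulated by independent per-gene dropout; the default dropout of 0.08
#' reflects the ~8% of genes observed missing per genome in curated
#' metazoan-scale datasets.
#'
#' @param n_taxa number of taxa (default 18, a typical curated genome set).
#' @param n_families number of gene families.
#' @param dup_rate duplication rate per unit branch length.
#' @param loss_rate loss rate per unit branch length.
#' @param dropout_prob per-gene annotation dropout probability.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_taxa = 18L, n_families = 100L, dup_rate = 0.2,
                       loss_rate = 0.2, dropout_prob = 0.08, seed = 1L) {
  stopifnot(n_taxa >= 2L, n_families >= 1L,
            is.finite(dup_rate), dup_rate >= 0,
            is.finite(loss_rate), loss_rate >= 0,
            dropout_prob >= 0, dropout_prob <= 1)
  structure(list(n_taxa = as.integer(n_taxa),
                 n_families = as.integer(n_families),
                 dup_rate = dup_rate, loss_rate = loss_rate,
                 dropout_prob = dropout_prob, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a species tree
#'
#' Yule (pure-birth) topology with branch lengths rescaled to unit root
#' height; tips are labelled `T01, T02, ...`. Deterministic per seed.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed.
#' @return rooted binary `phylo` with branch lengths.
#' @export
simulate_species_tree <- function(n_taxa, seed = 1L) {
  stopifnot(n_taxa >= 2L)
  set.seed(seed)
  phy <- ape::rphylo(n_taxa, birth = 1, death = 0)
  phy$tip.label <- sprintf("T%02d", seq_len(n_taxa))
  h <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length / h
  phy$node.label <- NULL
  phy
}

#' Simulate one gene family along the species tree
#'
#' One lineage enters the species-tree root; along every branch of length t
#' each incoming copy acquires `rpois(dup_rate * t)` duplicates and every
#' resulting copy independently survives with probability
#' `exp(-loss_rate * t)` (survival thinning; duplicates created on a branch
#' do not themselves re-duplicate within that branch - a documented model
#' simplification). Surviving copies split at every species node and emit
#' genes at the tips, labelled `"TAXON|<fam>_g<k>"`. The complete event log
#' and truth labels are returned for benchmarking.
#'
#' @param species_tree rooted binary `phylo` with branch lengths.
#' @param config a [sim_config()].
#' @param fam_id family identifier used in gene names.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return `list(gene_tree, group, events, truth)`. `gene_tree` is `NULL`
#'   when fewer than 2 copies survive; `group` is a data frame
#'   (`group_id, gene_id, taxon_id`); `events` logs every duplication and
#'   loss with its species branch and time; `truth` holds `is_single_copy`
#'   (no events at all), event totals and the clean subclade gene sets.
#' @export
simulate_family <- function(species_tree, config, fam_id = "fam1", seed = NULL) {
  stopifnot(inherits(species_tree, "phylo"))
  if (!is.null(seed)) set.seed(seed)
  lam <- config$dup_rate
  mu <- config$loss_rate
  sp <- species_tree
  sp$node.label <- paste0("n", length(sp$tip.label) + seq_len(sp$Nnode))
  cl <- phylo_to_clist(sp)

  gene_counter <- 0L
  lineage_counter <- 1L
  ev_kind <- character(0); ev_branch <- character(0)
  ev_time <- numeric(0); ev_lineage <- integer(0)
  log_event <- function(kind, branch, time, lineage) {
    ev_kind <<- c(ev_kind, kind); ev_branch <<- c(ev_branch, branch)
    ev_time <<- c(ev_time, time); ev_lineage <<- c(ev_lineage, lineage)
  }
  branch_name <- function(s) if (cl_is_leaf(s)) s$label else s$label

  at_node <- function(s) {
    if (cl_is_leaf(s)) {
      gene_counter <<- gene_counter + 1L
      return(cl_node(label = paste0(s$label, "|", fam_id, "_g", gene_counter)))
    }
    kids <- lapply(s$kids, through_branch)
    kids <- kids[!vapply(kids, is.null, logical(1))]
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) return(kids[[1]])
    cl_node(kids = kids)
  }
  through_branch <- function(s) {
    L <- if (is.na(s$len)) 0 else s$len
    n_dup <- stats::rpois(1L, lam * L)
    ids <- lineage_counter + seq_len(1L + n_dup) - 1L
    lineage_counter <<- lineage_counter + 1L + n_dup
    if (n_dup > 0L) {
      for (tm in sort(stats::runif(n_dup, 0, L))) {
        log_event("duplication", branch_name(s), tm, ids[1])
      }
    }
    alive <- stats::runif(1L + n_dup) < exp(-mu * L)
    for (i in which(!alive)) log_event("loss", branch_name(s), NA_real_, ids[i])
    surv <- list()
    for (i in which(alive)) {
      res <- at_node(s)
      if (!is.null(res)) surv[[length(surv) + 1L]] <- res
    }
    if (length(surv) == 0L) return(NULL)
    out <- surv[[1]]
    for (i in seq_along(surv)[-1]) {
      out <- cl_node(kids = list(out, surv[[i]]))  # duplication node
    }
    out$len <- s$len
    out
  }

  root_res <- at_node(cl)
  events <- data.frame(kind = ev_kind, branch = ev_branch, time = ev_time,
                       lineage = ev_lineage, stringsAsFactors = FALSE)
  genes <- if (is.null(root_res)) character(0) else cl_leaf_labels(root_res)
  group <- data.frame(group_id = fam_id,
                      gene_id = genes,
                      taxon_id = taxon_map_from_labels(genes),
                      stringsAsFactors = FALSE, row.names = NULL)
  gene_tree <- if (length(genes) >= 2L) clist_to_phylo(root_res) else NULL
  clean <- nrow(events) == 0L
  truth <- list(is_single_copy = clean,
                n_dups = sum(events$kind == "duplication"),
                n_losses = sum(events$kind == "loss"),
                subclades = if (clean) list(sort(genes)) else list())
  list(gene_tree = gene_tree, group = group, events = events, truth = truth)
}

#' Plant a family of clean paralog clades
#'
#' Builds a multigene family with `n_clades` ancient duplications at the
#' species-tree root: each clade is a clean one-copy-per-taxon image of the
#' species tree. Ground truth for sub-tree rescue: exactly `n_clades`
#' single-copy subclades, none detectable by the taxon-count rule.
#'
#' @inheritParams simulate_family
#' @param n_clades number of clean paralog clades (>= 2).
#' @return same structure as [simulate_family()].
#' @export
plant_paralog_family <- function(species_tree, fam_id = "fam1", n_clades = 2L) {
  stopifnot(n_clades >= 2L)
  cl <- phylo_to_clist(species_tree)
  gene_counter <- 0L
  copy_of <- function(s) {
    if (cl_is_leaf(s)) {
      gene_counter <<- gene_counter + 1L
      return(cl_node(label = paste0(s$label, "|", fam_id, "_g", gene_counter),
                     len = s$len))
    }
    cl_node(len = s$len, kids = lapply(s$kids, copy_of))
  }
  clades <- lapply(seq_len(n_clades), function(i) copy_of(cl))
  root <- clades[[1]]
  for (i in seq_along(clades)[-1]) root <- cl_node(kids = list(root, clades[[i]]))
  genes <- cl_leaf_labels(root)
  events <- data.frame(kind = rep("duplication", n_clades - 1L),
                       branch = "root", time = 0,
                       lineage = seq_len(n_clades - 1L),
                       stringsAsFactors = FALSE)
  list(gene_tree = clist_to_phylo(root),
       group = data.frame(group_id = fam_id, gene_id = genes,
                          taxon_id = taxon_map_from_labels(genes),
                          stringsAsFactors = FALSE, row.names = NULL),
       events = events,
       truth = list(is_single_copy = FALSE,
                    n_dups = n_clades - 1L, n_losses = 0L,
                    subclades = lapply(clades, function(x) sort(cl_leaf_labels(x)))))
}

#' Simulate a full benchmark dataset
#'
#' Species tree plus `n_families` independent families; deterministic per
#' `config$seed`. Empty families (all lineages lost) are retained in the
#' truth table but excluded from the group table.
#'
#' @param config a [sim_config()].
#' @return `list(species_tree, families, groups, gene_trees, truth)`;
#'   `truth` is a data frame with one row per family (`family_id,
#'   is_single_copy, n_dups, n_losses, subclades` with gene sets
#'   `;`-separated and genes comma-joined).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  species_tree <- simulate_species_tree(config$n_taxa, seed = config$seed)
  set.seed(config$seed + 1L)
  fam_ids <- sprintf("fam%04d", seq_len(config$n_families))
  families <- lapply(fam_ids, function(fid) {
    simulate_family(species_tree, config, fam_id = fid)
  })
  names(families) <- fam_ids
  groups <- do.call(rbind, lapply(families, `[[`, "group"))
  groups <- groups[nzchar(groups$gene_id), , drop = FALSE]
  rownames(groups) <- NULL
  gene_trees <- lapply(families, `[[`, "gene_tree")
  gene_trees <- gene_trees[!vapply(gene_trees, is.null, logical(1))]
  truth <- do.call(rbind, lapply(fam_ids, function(fid) {
    tr <- families[[fid]]$truth
    data.frame(family_id = fid,
               is_single_copy = tr$is_single_copy,
               n_dups = tr$n_dups, n_losses = tr$n_losses,
               subclades = paste(vapply(tr$subclades, paste,
                                        character(1), collapse = ","),
                                 collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  list(species_tree = species_tree, families = families, groups = groups,
       gene_trees = gene_trees, truth = truth)
}

#' Remove genes to emulate annotation dropout
#'
#' Each gene is removed independently with probability `dropout_prob`; gene
#' trees are pruned accordingly (trees left with fewer than 2 leaves are
#' dropped). Truth labels are left untouched: they describe the unperturbed
#' families.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dropout_prob per-gene removal probability in `[0, 1]`.
#' @param seed integer seed.
#' @return the dataset with `groups`/`gene_trees` thinned and a `removals`
#'   data frame appended.
#' @export
perturb_annotation <- function(dataset, dropout_prob, seed = 1L) {
  stopifnot(dropout_prob >= 0, dropout_prob <= 1)
  set.seed(seed)
  g <- dataset$groups
  drop <- stats::runif(nrow(g)) < dropout_prob
  dataset$removals <- g[drop, , drop = FALSE]
  rownames(dataset$removals) <- NULL
  dataset$groups <- g[!drop, , drop = FALSE]
  rownames(dataset$groups) <- NULL
  kept_by_group <- split(dataset$groups$gene_id, dataset$groups$group_id)
  dataset$gene_trees <- Filter(Negate(is.null),
    lapply(stats::setNames(names(dataset$gene_trees),
                           names(dataset$gene_trees)), function(fid) {
      gt <- dataset$gene_trees[[fid]]
      keep <- intersect(gt$tip.label, kept_by_group[[fid]])
      if (length(keep) < 2L) return(NULL)
      if (length(keep) == length(gt$tip.label)) return(gt)
      ape::keep.tip(gt, keep)
    }))
  dataset
}

#' Write a benchmark dataset to disk
#'
#' Emits the exact plain-text formats the command-line interface consumes:
#' `species.nwk`, one Newick per family under `genetrees/`, `groups.tsv`
#' (group_id, gene_id, taxon_id), `manifest.tsv` (group_id, newick path) and
#' `truth.tsv`. Deterministic per `config$seed`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the list of files written.
#' @export
generate_benchmark <- function(config, out_dir) {
  ds <- simulate_dataset(config)
  if (config$dropout_prob > 0) {
    ds <- perturb_annotation(ds, config$dropout_prob, seed = config$seed + 2L)
  }
  dir.create(file.path(out_dir, "genetrees"), recursive = TRUE,
             showWarnings = FALSE)
  sp_file <- file.path(out_dir, "species.nwk")
  write_newick(ds$species_tree, sp_file)
  tree_files <- character(0)
  for (fid in names(ds$gene_trees)) {
    f <- file.path(out_dir, "genetrees", paste0(fid, ".nwk"))
    write_newick(ds$gene_trees[[fid]], f)
    tree_files[fid] <- f
  }
  groups_file <- file.path(out_dir, "groups.tsv")
  utils::write.table(ds$groups, groups_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  manifest_file <- file.path(out_dir, "manifest.tsv")
  utils::write.table(data.frame(group_id = names(tree_files),
                                path = file.path("genetrees",
                                                 paste0(names(tree_files), ".nwk")),
                                stringsAsFactors = FALSE),
                     manifest_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  truth_file <- file.path(out_dir, "truth.tsv")
  utils::write.table(ds$truth, truth_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(c(species = sp_file, groups = groups_file,
              manifest = manifest_file, truth = truth_file, tree_files))
}
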