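#' Build an LCA index for a rooted species tree
#'
#' Precomputes parent pointers and depths on the guide species tree so that
#' lowest-common-ancestor and path-length queries used by the reconciliation
#' are cheap. The species tree must be rooted and fully binary; polytomous
#' guide trees are rejected because the duplication/loss counts below are
#' only defined against a resolved organismal phylogeny.
#'
#' @param species_tree rooted, binary `phylo` with unique tip labels.
#' @return an object of class `lca_index`.
#' @export
build_lca_index <- function(species_tree) {
  stopifnot(inherits(species_tree, "phylo"))
  if (!ape::is.rooted(species_tree)) {
    stop("species tree must be rooted", call. = FALSE)
  }
  if (!ape::is.binary(species_tree)) {
    stop("species tree must be fully binary (resolve polytomies first)",
         call. = FALSE)
  }
  if (anyDuplicated(species_tree$tip.label)) {
    stop("species tree has duplicate tip labels", call. = FALSE)
  }
  n <- length(species_tree$tip.label)
  parent <- phylo_parent(species_tree)
  kids <- phylo_children(species_tree)
  depth <- rep(NA_integer_, n + species_tree$Nnode)
  root <- phylo_root(species_tree)
  depth[root] <- 0L
  walk <- function(node) {
    for (k in kids[[node]]) {
      depth[k] <<- depth[node] + 1L
      walk(k)
    }
  }
  walk(root)
  structure(list(tree = species_tree,
                 n_tip = n,
                 root = root,
                 parent = parent,
                 children = kids,
                 depth = depth,
                 tip_id = stats::setNames(seq_len(n), species_tree$tip.label)),
            class = "lca_index")
}

#' Lowest common ancestor of two species-tree nodes
#'
#' @param index an `lca_index`.
#' @param u,v node ids in the species tree.
#' @return the node id of the LCA.
#' @export
lca_pair <- function(index, u, v) {
  while (u != v) {
    if (index$depth[u] > index$depth[v]) {
      u <- index$parent[u]
    } else if (index$depth[v] > index$depth[u]) {
      v <- index$parent[v]
    } else {
      u <- index$parent[u]
      v <- index$parent[v]
    }
  }
  u
}

lca_many <- function(index, nodes) {
  Reduce(function(a, b) lca_pair(index, a, b), nodes)
}

#' Path length between an ancestor and a descendant
#'
#' Number of species-tree edges from `u` down to `v`; `v` must be a
#' descendant of (or equal to) `u`.
#'
#' @inheritParams lca_pair
#' @return integer edge count.
#' @export
lca_depth_diff <- function(index, u, v) {
  d <- index$depth[v] - index$depth[u]
  if (d < 0L || lca_pair(index, u, v) != u) {
    stop("v is not a descendant of u", call. = FALSE)
  }
  d
}

# species node for the MRCA of a taxon set
species_mrca <- function(index, taxa) {
  unknown <- setdiff(taxa, names(index$tip_id))
  if (length(unknown)) {
    stop("taxa not in species tree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  lca_many(index, index$tip_id[taxa])
}

#' LCA mapping of a rooted gene tree into the species tree
#'
#' Maps every gene-tree node to a species-tree node: a leaf maps to its
#' taxon's tip, an internal node to the lowest common ancestor of its
#' children's images. This is the mapping that minimises the implied
#' duplication + loss count.
#'
#' @param gene_tree rooted `phylo` (polytomies allowed).
#' @param taxon_map named vector gene label -> taxon, or `NULL` for the
#'   `"TAXON|gene"` label convention.
#' @param index an `lca_index` for the species tree.
#' @return integer vector over gene-tree node ids giving species-tree node ids.
#' @export
map_gene_tree <- function(gene_tree, taxon_map = NULL, index) {
  stopifnot(inherits(index, "lca_index"))
  taxa <- leaf_taxa(gene_tree, taxon_map = taxon_map)
  bad <- !(taxa %in% names(index$tip_id))
  if (any(bad)) {
    stop("gene(s) mapped to taxa absent from the species tree: ",
         paste(utils::head(names(taxa)[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  n <- length(gene_tree$tip.label)
  M <- rep(NA_integer_, n + gene_tree$Nnode)
  M[seq_len(n)] <- index$tip_id[taxa]
  kids <- phylo_children(gene_tree)
  for (v in phylo_postorder(gene_tree)) {
    if (v > n) M[v] <- lca_many(index, M[kids[[v]]])
  }
  M
}

#' Classify gene-tree nodes as duplications
#'
#' Under LCA mapping, an internal node is a duplication if and only if it
#' maps to the same species node as at least one of its children; all other
#' internal nodes are speciations.
#'
#' @param gene_tree rooted `phylo`.
#' @param mapping integer vector from [map_gene_tree()].
#' @return integer vector of duplication node ids.
#' @export
classify_duplications <- function(gene_tree, mapping) {
  n <- length(gene_tree$tip.label)
  kids <- phylo_children(gene_tree)
  internal <- n + seq_len(gene_tree$Nnode)
  internal[vapply(internal, function(v) {
    any(mapping[kids[[v]]] == mapping[v])
  }, logical(1))]
}

#' Count losses per gene-tree edge
#'
#' For gene edge (v, c) with species images M(v), M(c) at path distance d:
#' a speciation parent implies d - 1 losses (one per species branching passed
#' without a sister lineage), a duplication parent implies d (the extra copy
#' also misses the branching at M(v) itself).
#'
#' @inheritParams classify_duplications
#' @param duplications integer vector of duplication node ids.
#' @param index an `lca_index`.
#' @return integer vector of losses, one per row of `gene_tree$edge`.
#' @export
count_losses <- function(gene_tree, mapping, duplications, index) {
  is_dup <- rep(FALSE, length(mapping))
  is_dup[duplications] <- TRUE
  apply_edge <- function(i) {
    v <- gene_tree$edge[i, 1]
    c <- gene_tree$edge[i, 2]
    d <- index$depth[mapping[c]] - index$depth[mapping[v]]
    if (is_dup[v]) d else d - 1L
  }
  vapply(seq_len(nrow(gene_tree$edge)), apply_edge, integer(1))
}

#' Duplication-loss parsimony reconciliation of a rooted gene tree
#'
#' Embeds the gene tree into the species tree by LCA mapping and reports the
#' duplications and losses required to explain the gene-tree topology given
#' the species tree. Multifurcations in the gene tree are treated as soft
#' polytomies: they are first refined into the binary resolution of minimal
#' duplication + loss cost (see [resolve_soft_polytomies()]), so genuine
#' conflict is never charged to lack of resolution.
#'
#' @param gene_tree rooted `phylo`; polytomies allowed.
#' @param species_tree rooted binary `phylo`, or `NULL` when `index` is given.
#' @param taxon_map named vector gene label -> taxon, or `NULL` for the
#'   `"TAXON|gene"` convention.
#' @param index optional prebuilt `lca_index`.
#' @param resolve_polytomies refine multifurcations first (default TRUE).
#' @return an object of class `reconciliation`: the (refined) rooted gene
#'   tree, the node mapping, duplication node ids, per-edge losses, totals
#'   and `total_cost = n_duplications + n_losses`.
#' @export
#' @examples
#' sp <- parse_newick("((A,B),C);")
#' gt <- parse_newick("((A|a1,B|b1),(A|a2,B|b2));")
#' reconcile_rooted(gt, sp)
reconcile_rooted <- function(gene_tree, species_tree = NULL, taxon_map = NULL,
                             index = NULL, resolve_polytomies = TRUE) {
  if (is.null(index)) index <- build_lca_index(species_tree)
  stopifnot(inherits(index, "lca_index"))
  inferred <- NULL
  has_polytomy <- any(tabulate(gene_tree$edge[, 1]) > 2L)
  if (resolve_polytomies && has_polytomy) {
    rs <- resolve_soft_polytomies(gene_tree, index, taxon_map = taxon_map)
    gene_tree <- rs$tree
    inferred <- rs$inferred
  }
  M <- map_gene_tree(gene_tree, taxon_map = taxon_map, index = index)
  dups <- classify_duplications(gene_tree, M)
  losses <- count_losses(gene_tree, M, dups, index)
  structure(list(gene_tree = gene_tree,
                 index = index,
                 taxa = leaf_taxa(gene_tree, taxon_map = taxon_map),
                 mapping = M,
                 duplication_nodes = dups,
                 losses_per_edge = losses,
                 n_duplications = length(dups),
                 n_losses = sum(losses),
                 total_cost = length(dups) + sum(losses),
                 root_edge = attr(gene_tree, "root_edge_index"),
                 root_split = NULL,
                 co_optimal_roots = NULL,
                 inferred_nodes = inferred),
            class = "reconciliation")
}

#' Most parsimonious rooting of an unrooted gene tree
#'
#' Roots the gene tree at every edge, reconciles each rooting against the
#' species tree and returns the reconciliation of minimal duplication + loss
#' cost. All co-optimal root edges are reported; the representative returned
#' is the co-optimal edge whose root bipartition key (sorted leaf labels,
#' smaller side first) is lexicographically smallest, so the result is
#' deterministic without hiding ambiguity.
#'
#' @param gene_tree unrooted `phylo` with at least 3 leaves (a rooted input
#'   is unrooted first).
#' @inheritParams reconcile_rooted
#' @return a `reconciliation` with `root_edge`, `root_split`,
#'   `co_optimal_roots` (data frame of edge, split, cost) and `all_costs`.
#' @export
best_rooting <- function(gene_tree, species_tree = NULL, taxon_map = NULL,
                         index = NULL) {
  if (is.null(index)) index <- build_lca_index(species_tree)
  rootings <- enumerate_rootings(gene_tree)
  recs <- lapply(rootings, function(r) {
    reconcile_rooted(r$tree, taxon_map = taxon_map, index = index)
  })
  costs <- vapply(recs, function(r) r$total_cost, numeric(1))
  splits <- vapply(rootings, function(r) r$split, character(1))
  best <- which(costs == min(costs))
  pick <- best[order(splits[best])][1]
  out <- recs[[pick]]
  out$root_edge <- rootings[[pick]]$edge
  out$root_split <- splits[pick]
  out$co_optimal_roots <- data.frame(edge = vapply(rootings[best], `[[`,
                                                  integer(1), "edge"),
                                     split = splits[best],
                                     cost = costs[best],
                                     stringsAsFactors = FALSE)
  out$all_costs <- costs
  out
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("Duplication-loss reconciliation\n")
  cat("  gene tree leaves:", length(x$gene_tree$tip.label), "\n")
  cat("  duplications:", x$n_duplications,
      " losses:", x$n_losses,
      " total cost:", x$total_cost, "\n")
  if (!is.null(x$root_split)) {
    cat("  root:", x$root_split, "\n")
    if (nrow(x$co_optimal_roots) > 1L) {
      cat("  co-optimal roots:", nrow(x$co_optimal_roots), "\n")
    }
  }
  invisible(x)
}

#' Annotate a reconciled gene tree for output
#'
#' Returns the rooted gene tree with duplication nodes tagged with a `[D]`
#' suffix in the internal labels, for export with [write_newick()].
#'
#' @param rec a `reconciliation`.
#' @return a `phylo`.
#' @export
annotate_duplications <- function(rec) {
  gt <- rec$gene_tree
  n <- length(gt$tip.label)
  labs <- if (is.null(gt$node.label)) rep("", gt$Nnode) else gt$node.label
  for (v in rec$duplication_nodes) {
    labs[v - n] <- paste0(labs[v - n], "[D]")
  }
  gt$node.label <- labs
  gt
}
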