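# Independent oracles and fixture builders.  Every oracle here deliberately
# avoids the code path it checks: LCA queries by ancestor-set intersection,
# reconciliation cost by exhaustive dynamic programming over all
# event-consistent embeddings, polytomy refinement by enumeration of all
# binary resolutions.

canonical_topology <- function(phy) {
  scortho:::cl_canonical(scortho:::phylo_to_clist(phy))
}

# Unrooted topology comparison by bipartition sets, computed with a plain
# traversal (independent of the package's rooting machinery).  Two unrooted
# trees are isomorphic iff they share tip sets and internal splits.
unrooted_splits <- function(phy) {
  phy <- ape::unroot(phy)
  n <- length(phy$tip.label)
  kids <- scortho:::phylo_children(phy)
  tips_below <- function(v) {
    if (v <= n) return(phy$tip.label[v])
    unlist(lapply(kids[[v]], tips_below), use.names = FALSE)
  }
  anchor <- min(phy$tip.label)
  keys <- character(0)
  for (i in seq_len(nrow(phy$edge))) {
    child <- phy$edge[i, 2]
    if (child <= n) next
    side <- sort(tips_below(child))
    if (!(anchor %in% side)) side <- sort(setdiff(phy$tip.label, side))
    keys <- c(keys, paste(side, collapse = ","))
  }
  sort(unique(keys))
}

expect_same_unrooted <- function(a, b) {
  expect_setequal(a$tip.label, b$tip.label)
  expect_identical(unrooted_splits(a), unrooted_splits(b))
}

# ancestors of a node (including itself), by parent walk
oracle_ancestors <- function(phy, v) {
  par <- scortho:::phylo_parent(phy)
  out <- v
  while (!is.na(par[v])) {
    v <- par[v]
    out <- c(out, v)
  }
  out
}

# naive LCA: deepest common element of the two ancestor paths
oracle_lca <- function(phy, u, v) {
  au <- oracle_ancestors(phy, u)
  av <- oracle_ancestors(phy, v)
  common <- intersect(au, av)
  common[1]  # ancestor paths are ordered from the node up
}

# --- exhaustive reconciliation oracle -------------------------------------
# Minimal duplication+loss cost over ALL event-consistent embeddings of a
# rooted binary gene tree into the species tree: each gene node may map to
# any species node; a speciation at s sends its children into distinct
# children of s, a duplication keeps both at or below s and costs 1; each
# edge pays the number of species branchings passed without a partner
# (d - 1 below a speciation, d below a duplication).  O(V_g * V_s^3) by
# dynamic programming over assignments - no LCA shortcut involved.
oracle_reconcile_cost <- function(gene_tree, species_tree, taxon_map = NULL) {
  sp <- species_tree
  ns <- length(sp$tip.label) + sp$Nnode
  spar <- scortho:::phylo_parent(sp)
  skids <- scortho:::phylo_children(sp)
  sdepth <- integer(ns)
  for (v in rev(scortho:::phylo_postorder(sp))) {
    if (!is.na(spar[v])) sdepth[v] <- sdepth[spar[v]] + 1L
  }
  desc <- vector("list", ns)   # descendants-or-self per species node
  for (v in scortho:::phylo_postorder(sp)) {
    desc[[v]] <- c(v, unlist(lapply(skids[[v]], function(k) desc[[k]])))
  }
  taxa <- leaf_taxa(gene_tree, taxon_map = taxon_map)
  tipid <- stats::setNames(seq_along(sp$tip.label), sp$tip.label)
  ng <- length(gene_tree$tip.label)
  gkids <- scortho:::phylo_children(gene_tree)
  INF <- 1e9
  cost <- matrix(INF, nrow = ng + gene_tree$Nnode, ncol = ns)
  for (v in scortho:::phylo_postorder(gene_tree)) {
    if (v <= ng) {
      cost[v, tipid[taxa[v]]] <- 0
      next
    }
    ch <- gkids[[v]]
    stopifnot(length(ch) == 2L)
    for (s in seq_len(ns)) {
      best <- INF
      # duplication at s
      for (x in desc[[s]]) {
        cx <- cost[ch[1], x]
        if (cx >= INF) next
        for (y in desc[[s]]) {
          cy <- cost[ch[2], y]
          if (cy >= INF) next
          val <- 1 + cx + cy + (sdepth[x] - sdepth[s]) + (sdepth[y] - sdepth[s])
          if (val < best) best <- val
        }
      }
      # speciation at s: children into distinct species children
      if (length(skids[[s]]) == 2L) {
        sl <- skids[[s]][1]; sr <- skids[[s]][2]
        for (ord in list(c(sl, sr), c(sr, sl))) {
          for (x in desc[[ord[1]]]) {
            cx <- cost[ch[1], x]
            if (cx >= INF) next
            for (y in desc[[ord[2]]]) {
              cy <- cost[ch[2], y]
              if (cy >= INF) next
              val <- cx + cy + (sdepth[x] - sdepth[s] - 1) +
                (sdepth[y] - sdepth[s] - 1)
              if (val < best) best <- val
            }
          }
        }
      }
      cost[v, s] <- best
    }
  }
  root <- ng + 1L
  min(cost[root, ])
}

# --- exhaustive enumeration of rooted binary topologies --------------------
# All rooted binary trees over the given leaf clists (1, 1, 3, 15, 105, 945
# for 1..6 leaves), by inserting each leaf into every branch incl. a new root.
all_binary_resolutions <- function(leaves) {
  stopifnot(length(leaves) >= 1L)
  insert_everywhere <- function(tree, leaf) {
    out <- list(scortho:::cl_node(kids = list(tree, leaf)))
    if (!scortho:::cl_is_leaf(tree)) {
      for (i in seq_along(tree$kids)) {
        for (sub in insert_everywhere(tree$kids[[i]], leaf)) {
          t2 <- tree
          t2$kids[[i]] <- sub
          out <- c(out, list(t2))
        }
      }
    }
    out
  }
  trees <- list(leaves[[1]])
  for (i in seq_along(leaves)[-1]) {
    trees <- do.call(c, lapply(trees, insert_everywhere, leaf = leaves[[i]]))
  }
  trees
}

# minimal reconciliation cost over all binary resolutions of a multifurcating
# rooted gene tree given as a newick string whose root is the only polytomy
oracle_polytomy_min_cost <- function(poly_tree, species_tree) {
  cl <- scortho:::phylo_to_clist(poly_tree)
  stopifnot(length(cl$kids) >= 3L)
  res <- all_binary_resolutions(cl$kids)
  idx <- build_lca_index(species_tree)
  min(vapply(res, function(r) {
    reconcile_rooted(scortho:::clist_to_phylo(r), index = idx)$total_cost
  }, numeric(1)))
}

# --- random fixtures -------------------------------------------------------

# random rooted binary gene tree over the taxa of a species tree; each leaf
# gets a uniformly random taxon (with replacement)
random_gene_tree <- function(n_leaves, taxa, prefix = "g") {
  topo <- ape::rtree(n_leaves, rooted = TRUE)
  topo$edge.length <- NULL
  topo$tip.label <- paste0(sample(taxa, n_leaves, replace = TRUE), "|",
                           prefix, seq_len(n_leaves))
  topo
}

random_pair <- function(n_sp, n_leaves, seed) {
  set.seed(seed)
  sp <- ape::rtree(n_sp, rooted = TRUE)
  sp$edge.length <- NULL
  sp$tip.label <- sprintf("S%02d", seq_len(n_sp))
  list(species = sp, gene = random_gene_tree(n_leaves, sp$tip.label))
}

expect_isomorphic <- function(a, b) {
  expect_identical(canonical_topology(a), canonical_topology(b))
}
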