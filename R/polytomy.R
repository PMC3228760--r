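#' Refine soft polytomies at minimal duplication-loss cost
#'
#' Multifurcations in gene trees represent lack of resolution (typically
#' after collapsing poorly supported branches), not simultaneous divergence.
#' They are therefore refined into the binary resolution that minimises the
#' implied duplication + loss count against the species tree, so that an
#' unresolved branch never contributes conflict cost. When the polytomy's
#' children are topologically compatible with the species tree the refinement
#' adds zero duplications and zero losses; otherwise the unavoidable minimum
#' (e.g. duplications among same-species copies) is added.
#'
#' The minimum is found exactly by a dynamic programme over the species
#' subtree spanned by the polytomy's children: `f(s, k)` is the minimal cost
#' of accommodating all children mapping at or below species node `s` with
#' `k` gene lineages crossing into `s`. Duplications are charged where
#' lineage counts increase, and one loss is charged for every species
#' branching a lineage passes one-sided. An optimal binary refinement is then
#' reconstructed by backtracking; nodes created this way are flagged as
#' inferred (the polytomy node itself is observed and keeps its annotation).
#'
#' @param gene_tree rooted `phylo`, possibly multifurcating (including a
#'   multifurcating root).
#' @param index an `lca_index` for the guide species tree.
#' @param taxon_map named vector gene label -> taxon, or `NULL` for the
#'   `"TAXON|gene"` convention.
#' @return `list(tree, inferred, added_cost, n_polytomies)` where `tree` is
#'   the binary `phylo`, `inferred` a logical vector over its node ids
#'   flagging refinement-created internal nodes, and `added_cost` the total
#'   minimal cost contributed by all refinements.
#' @export
#' @examples
#' sp <- parse_newick("((A,B),C);")
#' gt <- parse_newick("(A|a,B|b,C|c);")
#' rs <- resolve_soft_polytomies(gt, build_lca_index(sp))
#' rs$added_cost  # 0: compatible polytomy
resolve_soft_polytomies <- function(gene_tree, index, taxon_map = NULL) {
  stopifnot(inherits(gene_tree, "phylo"), inherits(index, "lca_index"))
  taxa <- leaf_taxa(gene_tree, taxon_map = taxon_map)
  bad <- !(taxa %in% names(index$tip_id))
  if (any(bad)) {
    stop("gene(s) mapped to taxa absent from the species tree: ",
         paste(utils::head(names(taxa)[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  cl <- phylo_to_clist(gene_tree)
  added <- 0
  n_poly <- 0L
  walk <- function(node) {
    if (cl_is_leaf(node)) {
      return(list(node = node, M = unname(index$tip_id[taxa[node$label]])))
    }
    done <- lapply(node$kids, walk)
    node$kids <- lapply(done, `[[`, "node")
    kid_maps <- vapply(done, `[[`, integer(1), "M")
    M <- lca_many(index, kid_maps)
    if (length(node$kids) > 2L) {
      rf <- polytomy_refine(node$kids, kid_maps, index)
      added <<- added + rf$cost
      n_poly <<- n_poly + 1L
      new_node <- rf$node
      new_node$len <- node$len
      new_node$sup <- node$sup
      new_node$label <- node$label
      new_node$inferred <- FALSE
      node <- new_node
    }
    list(node = node, M = M)
  }
  out <- walk(cl)
  tree <- clist_to_phylo(out$node)
  attr(tree, "supports") <- attr(gene_tree, "supports")
  attr(tree, "root_edge_index") <- attr(gene_tree, "root_edge_index")
  list(tree = tree,
       inferred = clist_flag_vector(out$node),
       added_cost = added,
       n_polytomies = n_poly)
}

# Logical vector over phylo node ids (as assigned by clist_to_phylo) marking
# nodes carrying inferred = TRUE.
clist_flag_vector <- function(cl) {
  n_tip <- cl_n_leaves(cl)
  n_all <- cl_count_nodes(cl)
  flags <- logical(n_all)   # tips stay FALSE
  next_internal <- n_tip + 2L
  # preorder identical to clist_to_phylo: internal ids assigned on first
  # encounter, subtree walked immediately
  walk <- function(node, my_id) {
    flags[my_id] <<- isTRUE(node$inferred)
    for (k in node$kids) {
      if (!cl_is_leaf(k)) {
        kid_id <- next_internal; next_internal <<- next_internal + 1L
        walk(k, kid_id)
      }
    }
  }
  walk(cl, n_tip + 1L)
  flags
}

# Exact minimal-cost refinement of one polytomy.
#
# kid_nodes: list of clist subtrees (the polytomy's children)
# kid_maps:  species node id each child maps to (LCA mapping)
# Returns list(node = clist of the refinement root, cost = added dup+loss).
polytomy_refine <- function(kid_nodes, kid_maps, index) {
  m <- length(kid_maps)
  r0 <- lca_many(index, kid_maps)
  nsp <- index$n_tip + index$tree$Nnode
  mult <- integer(nsp)
  for (s in kid_maps) mult[s] <- mult[s] + 1L
  item_kids <- vector("list", nsp)
  for (i in seq_len(m)) {
    s <- kid_maps[i]
    item_kids[[s]] <- c(item_kids[[s]], list(kid_nodes[[i]]))
  }
  # items at or below each species node (within subtree of r0)
  below <- integer(nsp)
  fill_below <- function(s) {
    tot <- mult[s]
    for (k in index$children[[s]]) tot <- tot + fill_below(k)
    below[s] <<- tot
    tot
  }
  fill_below(r0)

  INF <- .Machine$integer.max / 4
  fmemo <- new.env(parent = emptyenv())
  cmemo <- new.env(parent = emptyenv())
  fk <- function(s, k) {
    key <- paste0(s, ",", k)
    if (!is.null(fmemo[[key]])) return(fmemo[[key]])
    val <- local({
      if (k == 0L) return(if (below[s] == 0L) 0 else INF)
      if (k > below[s]) return(INF)
      ch <- index$children[[s]]
      if (length(ch) == 0L) return(mult[s] - k)   # species tip
      l <- ch[1]; r <- ch[2]
      best <- INF; best_ch <- NULL
      for (kl in 0:min(below[l], m)) {
        fl <- fk(l, kl)
        if (fl >= INF) next
        for (kr in 0:min(below[r], m)) {
          fr <- fk(r, kr)
          if (fr >= INF) next
          navail <- mult[s] + kl + kr
          if (navail < k) next
          a <- min(kl, kr, navail - k)
          cost <- (navail - a - k) + (kl + kr - 2 * a) + fl + fr
          if (cost < best) {
            best <- cost
            best_ch <- c(kl, kr, a)
          }
        }
      }
      if (best < INF) cmemo[[key]] <- best_ch
      best
    })
    fmemo[[key]] <- val
    val
  }
  cost <- fk(r0, 1L)
  if (cost >= INF) stop("internal error: infeasible polytomy refinement")

  join <- function(x, y) cl_node(kids = list(x, y), inferred = TRUE)
  # chain units (all mapping to s, or seeded by an s-mapped unit) into groups
  group_units <- function(units_s, units_g, k) {
    n_all <- length(units_s) + length(units_g)
    stopifnot(n_all >= k)
    if (length(units_s) == 0L) {
      stopifnot(n_all == k)
      return(units_g)
    }
    j <- min(length(units_s), k)
    chains <- units_s[seq_len(j)]
    extra_s <- units_s[-seq_len(j)]
    for (u in extra_s) chains[[1]] <- join(chains[[1]], u)
    n_singleton <- k - j
    stopifnot(length(units_g) >= n_singleton)
    singles <- if (n_singleton > 0L) units_g[seq_len(n_singleton)] else list()
    rest <- if (n_singleton > 0L) units_g[-seq_len(n_singleton)] else units_g
    if (length(rest)) {
      slot <- rep(seq_len(j), length.out = length(rest))
      for (i in seq_along(rest)) {
        chains[[slot[i]]] <- join(chains[[slot[i]]], rest[[i]])
      }
    }
    c(chains, singles)
  }
  realize <- function(s, k) {
    if (k == 0L) return(list())
    items <- if (is.null(item_kids[[s]])) list() else item_kids[[s]]
    ch <- index$children[[s]]
    if (length(ch) == 0L) {
      return(group_units(items, list(), k))
    }
    pick <- cmemo[[paste0(s, ",", k)]]
    kl <- pick[1]; kr <- pick[2]; a <- pick[3]
    L <- realize(ch[1], kl)
    R <- realize(ch[2], kr)
    pairs <- lapply(seq_len(a), function(i) join(L[[i]], R[[i]]))
    Lg <- if (kl > a) L[(a + 1):kl] else list()
    Rg <- if (kr > a) R[(a + 1):kr] else list()
    group_units(c(items, pairs), c(Lg, Rg), k)
  }
  root <- realize(r0, 1L)[[1]]
  list(node = root, cost = cost)
}
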