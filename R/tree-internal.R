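# Internal recursive tree representation ("clist") used for tree surgery.
#
# A clist node is a plain list:
#   label    character(1) or NA  (tip label, or internal node name)
#   len      numeric(1), NA when the branch above has no length
#   sup      numeric(1), NA when the branch above carries no support
#   kids     list of clist nodes (empty for tips)
#   inferred logical(1), TRUE for nodes created by polytomy refinement
#
# Public functions exchange ape "phylo" objects; the converters below keep
# branch lengths and supports (stored in phylo$node.label) in sync.

cl_node <- function(label = NA_character_, len = NA_real_, sup = NA_real_,
                    kids = list(), inferred = FALSE) {
  list(label = label, len = len, sup = sup, kids = kids, inferred = inferred)
}

cl_is_leaf <- function(cl) length(cl$kids) == 0L

cl_leaf_labels <- function(cl) {
  if (cl_is_leaf(cl)) return(cl$label)
  unlist(lapply(cl$kids, cl_leaf_labels), use.names = FALSE)
}

cl_n_leaves <- function(cl) length(cl_leaf_labels(cl))

cl_count_nodes <- function(cl) {
  1L + sum(vapply(cl$kids, cl_count_nodes, integer(1)))
}

# Canonical form used as the tree-isomorphism oracle in tests and for
# deterministic tie-breaking: a parenthesised string with children sorted
# lexicographically at every level.  Ignores lengths and supports.
cl_canonical <- function(cl) {
  if (cl_is_leaf(cl)) return(cl$label)
  paste0("(", paste(sort(vapply(cl$kids, cl_canonical, character(1))),
                    collapse = ","), ")")
}

phylo_to_clist <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  n <- length(phy$tip.label)
  nn <- phy$Nnode
  kids_of <- split(phy$edge[, 2], factor(phy$edge[, 1], levels = seq_len(n + nn)))
  len_of <- rep(NA_real_, n + nn)
  if (!is.null(phy$edge.length)) len_of[phy$edge[, 2]] <- phy$edge.length
  lab_of <- rep(NA_character_, n + nn)
  if (!is.null(phy$node.label)) {
    nl <- as.character(phy$node.label)
    nl[!nzchar(nl)] <- NA_character_
    lab_of[n + seq_len(nn)] <- nl
  }
  build <- function(node) {
    if (node <= n) {
      return(cl_node(label = phy$tip.label[node], len = len_of[node]))
    }
    raw <- lab_of[node]
    sup <- suppressWarnings(as.numeric(raw))
    cl_node(label = if (is.na(sup)) raw else NA_character_,
            len = len_of[node], sup = sup,
            kids = lapply(kids_of[[node]], build))
  }
  root <- n + 1L
  build(root)
}

clist_to_phylo <- function(cl) {
  if (cl_is_leaf(cl)) stop("cannot convert a single leaf to a phylo object")
  tips <- character(0)
  parents <- integer(0); children <- integer(0)
  lens <- numeric(0); nlabs <- character(0)
  n_tip <- cl_n_leaves(cl)
  next_internal <- n_tip + 1L
  next_tip <- 1L
  internal_label <- function(node) {
    if (!is.na(node$sup)) format(node$sup, trim = TRUE)
    else if (!is.na(node$label)) node$label
    else ""
  }
  # preorder walk emitting edges parent-first (ape "cladewise" order)
  walk <- function(node, my_id) {
    for (k in node$kids) {
      if (cl_is_leaf(k)) {
        kid_id <- next_tip; next_tip <<- next_tip + 1L
        tips[kid_id] <<- k$label
      } else {
        kid_id <- next_internal; next_internal <<- next_internal + 1L
        nlabs[kid_id - n_tip] <<- internal_label(k)
      }
      parents <<- c(parents, my_id)
      children <<- c(children, kid_id)
      lens <<- c(lens, if (is.null(k$len)) NA_real_ else k$len)
      if (!cl_is_leaf(k)) walk(k, kid_id)
    }
  }
  root_id <- n_tip + 1L
  next_internal <- root_id + 1L
  nlabs[1L] <- internal_label(cl)
  walk(cl, root_id)
  phy <- list(edge = cbind(parents, children),
              tip.label = tips,
              Nnode = next_internal - n_tip - 1L)
  dimnames(phy$edge) <- NULL
  if (any(!is.na(lens))) {
    lens[is.na(lens)] <- 0
    phy$edge.length <- lens
  }
  if (any(nzchar(nlabs))) phy$node.label <- nlabs
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  phy
}

# children lists / parent vector helpers on phylo objects
phylo_children <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  out <- vector("list", n)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    out[[p]] <- c(out[[p]], phy$edge[i, 2])
  }
  out
}

phylo_parent <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  par <- rep(NA_integer_, n)
  par[phy$edge[, 2]] <- phy$edge[, 1]
  par
}

phylo_root <- function(phy) length(phy$tip.label) + 1L

# postorder sequence of node ids
phylo_postorder <- function(phy) {
  ord <- integer(0)
  kids <- phylo_children(phy)
  walk <- function(node) {
    for (k in kids[[node]]) walk(k)
    ord <<- c(ord, node)
  }
  walk(phylo_root(phy))
  ord
}
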