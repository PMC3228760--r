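#' Parse a Newick string
#'
#' Trees are represented as [ape::read.tree()] `phylo` objects throughout the
#' package. By the convention of most tree-building pipelines, internal node
#' labels are interpreted as bootstrap support values (in percent) for the
#' branch above the node; set `supports = FALSE` to treat them as plain node
#' names instead. Multifurcations are preserved. Gene-tree leaf labels are
#' expected to follow the `"TAXON|geneid"` convention (see
#' [taxon_map_from_labels()]), but any labels are accepted.
#'
#' @param text a Newick string (terminated by `;`).
#' @param supports interpret internal labels as support values (default TRUE).
#' @return an object of class `phylo`. The attribute `"supports"` records the
#'   dialect used at parse time.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1)90:1,C:2);")
#' tr$node.label
parse_newick <- function(text, supports = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("malformed Newick: ", conditionMessage(e),
                                           call. = FALSE))
  if (is.null(phy)) stop("malformed Newick: could not parse tree text", call. = FALSE)
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  attr(phy, "supports") <- isTRUE(supports)
  phy
}

# Cheap syntactic pre-check that reports a character offset for the common
# failure modes (unbalanced parentheses, missing terminator).
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("malformed Newick: unbalanced ')' at character ", i, call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop("malformed Newick: ", depth, " unclosed '(' at character ",
         length(chars), call. = FALSE)
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop("malformed Newick: missing ';' terminator at character ",
         nchar(text), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a Newick tree from a file
#'
#' @param file path to a Newick file (first tree is returned).
#' @inheritParams parse_newick
#' @return a `phylo` object.
#' @export
read_newick <- function(file, supports = TRUE) {
  txt <- paste(readLines(file, warn = FALSE), collapse = "")
  parse_newick(txt, supports = supports)
}

#' Write a tree as Newick
#'
#' Internal node labels (supports, under the default dialect) are emitted as
#' internal labels so that `parse_newick(write_newick(t))` round-trips.
#'
#' @param tree a `phylo` object.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @param digits number of digits for branch lengths.
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Collapse poorly supported branches into soft polytomies
#'
#' Contracts every internal branch whose support value is strictly below
#' `threshold`, promoting its children to the grandparent node; promoted
#' children keep their own branch lengths and the contracted branch length is
#' discarded (the convention of [ape::di2multi()]; reconciliation ignores
#' lengths). Branches carrying no support value at all are treated as
#' resolved and kept: absence of a value is not failure of the criterion.
#' The leaf set is never changed.
#'
#' The conventional threshold for this procedure is 80 (percent bootstrap
#' support), with the boundary kept: a branch with support exactly equal to
#' `threshold` is retained.
#'
#' @param tree a `phylo` with supports as internal node labels.
#' @param threshold support threshold in `[0, 100]`.
#' @return a `phylo`, possibly multifurcating.
#' @export
#' @examples
#' write_newick(collapse_low_support(parse_newick("((A,B)79,C);"), 80))
collapse_low_support <- function(tree, threshold = 80) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 100) {
    stop("threshold must be a single value in [0, 100]", call. = FALSE)
  }
  cl <- phylo_to_clist(tree)
  walk <- function(node) {
    if (cl_is_leaf(node)) return(node)
    node$kids <- lapply(node$kids, walk)
    out <- list()
    for (k in node$kids) {
      if (!cl_is_leaf(k) && !is.na(k$sup) && k$sup < threshold) {
        for (g in k$kids) {
          out[[length(out) + 1L]] <- g
        }
      } else {
        out[[length(out) + 1L]] <- k
      }
    }
    node$kids <- out
    node
  }
  res <- clist_to_phylo(walk(cl))
  attr(res, "supports") <- attr(tree, "supports")
  res
}

#' Prune a tree down to a taxon set
#'
#' Removes every leaf whose taxon is not in `keep`; unary internal nodes are
#' suppressed with branch lengths summed. For a species tree `keep` is matched
#' against leaf labels directly; for a gene tree supply a taxon map (or rely
#' on the `"TAXON|gene"` label convention).
#'
#' @param tree a `phylo`.
#' @param keep non-empty character vector of taxa to retain.
#' @param taxon_map optional named vector mapping leaf label to taxon
#'   (see [taxon_map_from_labels()]); `NULL` derives taxa from labels.
#' @param delim delimiter for the label convention when `taxon_map` is `NULL`.
#' @return a `phylo`. When fewer than 2 leaves remain a degenerate one-tip
#'   tree is returned with attribute `"degenerate"` set to `TRUE`.
#' @export
prune_to_taxa <- function(tree, keep, taxon_map = NULL, delim = "|") {
  stopifnot(inherits(tree, "phylo"))
  if (length(keep) == 0L) stop("keep must be a non-empty taxon set", call. = FALSE)
  taxa <- leaf_taxa(tree, taxon_map = taxon_map, delim = delim)
  hold <- tree$tip.label[taxa %in% keep]
  if (length(hold) == 0L) {
    stop("no leaves left after pruning: taxon set is disjoint from the tree",
         call. = FALSE)
  }
  if (length(hold) == 1L) {
    deg <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                          tip.label = hold, Nnode = 1L),
                     class = "phylo")
    attr(deg, "degenerate") <- TRUE
    return(deg)
  }
  res <- ape::keep.tip(tree, hold)
  attr(res, "supports") <- attr(tree, "supports")
  res
}

#' Unroot a tree
#'
#' Stored per the usual convention as a basal multifurcation.
#'
#' @param tree a `phylo`.
#' @return an unrooted `phylo`.
#' @export
unroot_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) return(tree)
  res <- ape::unroot(tree)
  attr(res, "supports") <- attr(tree, "supports")
  res
}

# Edge table of an unrooted tree: one row per edge with endpoint ids, length
# and the support of the corresponding bipartition.
unrooted_edge_table <- function(utree) {
  n <- length(utree$tip.label)
  sup <- rep(NA_real_, nrow(utree$edge))
  if (!is.null(utree$node.label)) {
    internal <- utree$edge[, 2] > n
    sup[internal] <- suppressWarnings(
      as.numeric(utree$node.label[utree$edge[internal, 2] - n]))
  }
  len <- if (is.null(utree$edge.length)) rep(NA_real_, nrow(utree$edge)) else
    utree$edge.length
  data.frame(a = utree$edge[, 1], b = utree$edge[, 2], len = len, sup = sup)
}

#' Root an unrooted tree at one of its edges
#'
#' Places a new root node on the chosen edge (at its midpoint when branch
#' lengths are present, else with lengths left absent); the edge's support is
#' carried onto both root-adjacent branches, which represent the same
#' bipartition. Reconciliation ignores branch lengths, so midpoint placement
#' is cosmetic.
#'
#' @param tree an unrooted `phylo` (a rooted tree is unrooted first).
#' @param edge integer index into the rows of the unrooted tree's edge matrix.
#' @return a rooted `phylo` with a binary root.
#' @export
root_at_edge <- function(tree, edge) {
  utree <- unroot_tree(tree)
  et <- unrooted_edge_table(utree)
  stopifnot(length(edge) == 1L, edge >= 1L, edge <= nrow(et))
  n <- length(utree$tip.label)
  # adjacency: per node, incident edge indices
  inc <- vector("list", n + utree$Nnode)
  for (i in seq_len(nrow(et))) {
    inc[[et$a[i]]] <- c(inc[[et$a[i]]], i)
    inc[[et$b[i]]] <- c(inc[[et$b[i]]], i)
  }
  orient <- function(node, via_edge, len, sup) {
    kid_edges <- setdiff(inc[[node]], via_edge)
    if (node <= n) {
      return(cl_node(label = utree$tip.label[node], len = len, sup = sup))
    }
    kids <- lapply(kid_edges, function(i) {
      other <- if (et$a[i] == node) et$b[i] else et$a[i]
      orient(other, i, et$len[i], et$sup[i])
    })
    cl_node(len = len, sup = sup, kids = kids)
  }
  half <- if (is.na(et$len[edge])) NA_real_ else et$len[edge] / 2
  root <- cl_node(kids = list(
    orient(et$b[edge], edge, half, et$sup[edge]),
    orient(et$a[edge], edge, half, et$sup[edge])))
  res <- clist_to_phylo(root)
  attr(res, "supports") <- attr(tree, "supports")
  attr(res, "root_edge_index") <- as.integer(edge)
  res
}

#' Enumerate all rootings of an unrooted tree
#'
#' One rooted tree per edge of the unrooted tree: `2n - 3` rootings for a
#' fully binary unrooted tree on `n` leaves. Used by [best_rooting()], which
#' scans all of them for the duplication-loss minimum.
#'
#' @param tree an unrooted `phylo` with at least 3 leaves (a rooted input is
#'   unrooted first).
#' @return a list with one element per edge: `list(edge = <index>,
#'   split = <bipartition key>, tree = <rooted phylo>)`.
#' @export
enumerate_rootings <- function(tree) {
  if (length(tree$tip.label) < 3L) {
    stop("rooting enumeration needs at least 3 leaves", call. = FALSE)
  }
  utree <- unroot_tree(tree)
  et <- unrooted_edge_table(utree)
  lapply(seq_len(nrow(et)), function(i) {
    list(edge = i,
         split = edge_bipartition_key(utree, i),
         tree = root_at_edge(utree, i))
  })
}

# Canonical key for the bipartition induced by edge i of an unrooted tree:
# both sides' sorted, comma-joined leaf labels, lexicographically smaller
# side first.  Deterministic tie-break for co-optimal rootings.
edge_bipartition_key <- function(utree, i) {
  n <- length(utree$tip.label)
  kids <- phylo_children(utree)
  below <- function(node) {
    if (node <= n) return(utree$tip.label[node])
    unlist(lapply(kids[[node]], below), use.names = FALSE)
  }
  side1 <- sort(below(utree$edge[i, 2]))
  side2 <- sort(setdiff(utree$tip.label, side1))
  s1 <- paste(side1, collapse = ",")
  s2 <- paste(side2, collapse = ",")
  paste(min(s1, s2), max(s1, s2), sep = " | ")
}

#' Derive a gene-to-taxon map from leaf labels
#'
#' Default convention: the leaf label is `"TAXON|geneid"`; the taxon is the
#' part before the first delimiter. Labels without the delimiter map to
#' themselves (the identity convention used for species trees).
#'
#' @param labels character vector of leaf labels.
#' @param delim delimiter, default `"|"`.
#' @return named character vector: `labels -> taxon`.
#' @export
taxon_map_from_labels <- function(labels, delim = "|") {
  taxa <- vapply(strsplit(labels, delim, fixed = TRUE),
                 function(x) x[[1]], character(1))
  stats::setNames(taxa, labels)
}

#' Read a gene-to-taxon map from a two-column TSV
#'
#' Columns: `gene_id <TAB> taxon_id`, no header.
#'
#' @param file path to the TSV.
#' @return named character vector: gene id -> taxon id.
#' @export
read_taxon_map <- function(file) {
  df <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("taxon map must have two columns", call. = FALSE)
  stats::setNames(df[[2]], df[[1]])
}

#' Taxa of a tree's leaves
#'
#' @inheritParams prune_to_taxa
#' @return character vector of taxa, named by leaf label.
#' @export
leaf_taxa <- function(tree, taxon_map = NULL, delim = "|") {
  labs <- tree$tip.label
  if (is.null(taxon_map)) return(taxon_map_from_labels(labs, delim = delim))
  missing <- setdiff(labs, names(taxon_map))
  if (length(missing)) {
    stop("taxon map is missing entries for: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  stats::setNames(unname(taxon_map[labs]), labs)
}
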