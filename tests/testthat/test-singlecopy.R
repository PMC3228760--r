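mk_group <- function(taxa, gid = "g1") {
  data.frame(group_id = gid,
             gene_id = paste0(taxa, "|", gid, "_", seq_along(taxa)),
             taxon_id = taxa, stringsAsFactors = FALSE)
}

test_that("copy_numbers counts per taxon over the declared universe", {
  uni <- sprintf("T%02d", 1:18)
  g <- mk_group(uni)
  expect_identical(copy_numbers(g, uni), stats::setNames(rep(1L, 18), uni))
  g2 <- mk_group(c("A", "A"))
  expect_identical(copy_numbers(g2, c("A", "B")), c(A = 2L, B = 0L))
  # sum equals the number of members inside the universe
  g3 <- mk_group(c("A", "B", "B", "Z"))
  expect_equal(sum(copy_numbers(g3, c("A", "B"))), 3L)
})

test_that("classify_relationship ignores zeros and counts duplicated taxa", {
  expect_equal(classify_relationship(c(A = 1L, B = 0L, C = 1L)), "one_to_one")
  expect_equal(classify_relationship(c(A = 3L, B = 1L, C = 1L)), "one_to_many")
  expect_equal(classify_relationship(c(A = 2L, B = 2L, C = 1L)), "many_to_many")
})

test_that("taxon_count_call applies the tolerance and labels categories", {
  uni <- sprintf("T%02d", 1:18)
  expect_equal(taxon_count_call(mk_group(uni), uni)$category, "exact")
  dup <- taxon_count_call(mk_group(c(uni, "T05")), uni)
  expect_equal(dup$category, "one_duplication")
  expect_identical(dup$allowed_events$taxon, "T05")
  loss <- taxon_count_call(mk_group(uni[-3]), uni)
  expect_equal(loss$category, "one_loss")
  expect_identical(loss$allowed_events$taxon, "T03")
  # two deviations exceed the default tolerance
  expect_null(taxon_count_call(mk_group(uni[-c(3, 4)]), uni))
  expect_null(taxon_count_call(mk_group(c(uni, "T05", "T07")), uni))
  # ... but pass with tolerance 2
  expect_equal(taxon_count_call(mk_group(uni[-c(3, 4)]), uni,
                                tolerance = 2)$category, "one_loss")
  # genes outside the universe are not certified
  g <- mk_group(c(uni, "OUT"))
  call <- taxon_count_call(g, uni)
  expect_equal(call$category, "exact")
  expect_length(call$genes, 18L)
})

test_that("a cost-0 congruent family yields one whole-tree call", {
  sp <- parse_newick("((A,B),C);")
  rec <- reconcile_rooted(parse_newick("((A|a,B|b),C|c);"), sp)
  calls <- find_single_copy_subtrees(rec, group_id = "g0")
  expect_length(calls, 1L)
  expect_setequal(calls[[1]]$genes, c("A|a", "B|b", "C|c"))
  expect_equal(nrow(calls[[1]]$allowed_events), 0L)
})

test_that("species-specific events are tolerated within the budget", {
  sp <- parse_newick("((A,B),(C,D));")
  # species-specific duplication in A
  gt <- parse_newick("(((A|a1,A|a2),B|b),(C|c,D|d));")
  rec <- reconcile_rooted(gt, sp)
  calls <- find_single_copy_subtrees(rec, group_id = "gd")
  expect_length(calls, 1L)
  expect_identical(calls[[1]]$allowed_events,
                   data.frame(kind = "duplication", taxon = "A",
                              stringsAsFactors = FALSE))
  # species-specific loss of D
  gt2 <- parse_newick("((A|a,B|b),C|c);")
  rec2 <- reconcile_rooted(gt2, sp)
  calls2 <- find_single_copy_subtrees(rec2, group_id = "gl")
  expect_length(calls2, 1L)
  expect_identical(calls2[[1]]$allowed_events$kind, "loss")
  expect_identical(calls2[[1]]$allowed_events$taxon, "D")
  # with budget 0 neither family is called
  expect_length(find_single_copy_subtrees(rec, budget = 0), 0L)
  expect_length(find_single_copy_subtrees(rec2, budget = 0), 0L)
  # dup + loss together exceed budget 1 but fit budget 2
  gt3 <- parse_newick("(((A|a1,A|a2),B|b),C|c);")
  rec3 <- reconcile_rooted(gt3, sp)
  expect_length(find_single_copy_subtrees(rec3, budget = 1), 0L)
  calls3 <- find_single_copy_subtrees(rec3, budget = 2)
  expect_length(calls3, 1L)
  expect_setequal(calls3[[1]]$allowed_events$taxon, c("A", "D"))
})

test_that("conflicting topologies and deep events disqualify sub-trees", {
  sp <- parse_newick("((A,B),(C,D));")
  # non-species-specific duplication (two full clades): two calls, not one
  planted <- parse_newick(
    "(((A|a1,B|b1),(C|c1,D|d1)),((A|a2,B|b2),(C|c2,D|d2)));")
  rec <- reconcile_rooted(planted, sp)
  calls <- find_single_copy_subtrees(rec, group_id = "gp")
  expect_length(calls, 2L)
  # a topology conflicting with the species tree is never called at the
  # default budget: the root duplication maps to an internal species node
  # and each half would need two loss events
  conflict <- parse_newick("((A|a,C|c),(B|b,D|d));")
  recc <- reconcile_rooted(conflict, sp)
  expect_length(find_single_copy_subtrees(recc, budget = 1), 0L)
  # family whose root maps below the focal node is not called at focal
  sub <- reconcile_rooted(parse_newick("(A|a,B|b);"), sp)
  expect_length(find_single_copy_subtrees(sub), 0L)
  # ... but is called at its own level
  ab_node <- scortho:::species_mrca(sub$index, c("A", "B"))
  expect_length(find_single_copy_subtrees(sub, focal = ab_node), 1L)
})

test_that("sub-tree calls are invariant to child order and budget-monotone", {
  sp <- parse_newick("((A,B),(C,D));")
  gt <- parse_newick("(((A|a1,A|a2),B|b),(C|c,D|d));")
  gt_rot <- parse_newick("((D|d,C|c),(B|b,(A|a2,A|a1)));")
  for (budget in 0:3) {
    c1 <- find_single_copy_subtrees(reconcile_rooted(gt, sp), budget = budget)
    c2 <- find_single_copy_subtrees(reconcile_rooted(gt_rot, sp), budget = budget)
    expect_equal(length(c1), length(c2))
    if (length(c1)) {
      expect_setequal(c1[[1]]$genes, c2[[1]]$genes)
    }
  }
  counts <- vapply(0:3, function(b) {
    length(find_single_copy_subtrees(reconcile_rooted(gt, sp), budget = b))
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("budget-0 calls equal maximal cost-0 congruent sub-trees (oracle)", {
  # exhaustive sub-tree check on random reconciled families
  set.seed(31)
  for (i in 1:20) {
    sp <- simulate_species_tree(sample(4:6, 1), seed = 600 + i)
    sp$edge.length <- NULL
    idx <- build_lca_index(sp)
    gt <- random_gene_tree(sample(5:10, 1), sp$tip.label)
    rec <- reconcile_rooted(gt, index = idx)
    calls <- find_single_copy_subtrees(rec, budget = 0)
    # oracle: for every gene node, test directly whether its subtree is a
    # clean one-copy image of the whole species tree
    gt2 <- rec$gene_tree
    n <- length(gt2$tip.label)
    kids <- scortho:::phylo_children(gt2)
    tips_below <- function(v) {
      if (v <= n) return(v)
      unlist(lapply(kids[[v]], tips_below))
    }
    clean <- Filter(function(v) {
      tl <- gt2$tip.label[tips_below(v)]
      taxa <- taxon_map_from_labels(tl)
      if (!setequal(taxa, sp$tip.label) || anyDuplicated(taxa)) return(FALSE)
      sub <- ape::keep.tip(gt2, tl)
      reconcile_rooted(sub, index = idx)$total_cost == 0
    }, seq_len(n + gt2$Nnode))
    # maximal ones only
    par <- scortho:::phylo_parent(gt2)
    clean <- Filter(function(v) {
      p <- par[v]
      while (!is.na(p)) {
        if (p %in% clean) return(FALSE)
        p <- par[p]
      }
      TRUE
    }, clean)
    expect_equal(length(calls), length(clean))
    expect_setequal(
      vapply(calls, function(x) paste(sort(x$genes), collapse = ","), character(1)),
      vapply(clean, function(v) paste(sort(gt2$tip.label[tips_below(v)]),
                                      collapse = ","), character(1)))
  }
})

test_that("pool_calls merges identical gene sets and keeps distinct ones", {
  a <- scortho:::new_single_copy_call("g1", c("A|a", "B|b"), "subtree",
                                      "subtree", data.frame(), "coelomata")
  b <- scortho:::new_single_copy_call("g1", c("A|a", "B|b"), "subtree",
                                      "subtree", data.frame(), "ecdysozoa")
  d <- scortho:::new_single_copy_call("g1", c("A|a2", "B|b2"), "subtree",
                                      "subtree", data.frame(), "coelomata")
  pooled <- pool_calls(list(a, b, d))
  expect_length(pooled, 2L)
  merged <- pooled[[which(vapply(pooled, function(x)
    "ecdysozoa" %in% x$guide_ids, logical(1)))[1]]]
  expect_setequal(merged$guide_ids, c("coelomata", "ecdysozoa"))
  # idempotent and order-insensitive
  again <- pool_calls(pooled)
  expect_equal(length(again), 2L)
  rev_pool <- pool_calls(list(d, b, a))
  expect_equal(vapply(rev_pool, function(x) paste(x$genes, collapse = ","),
                      character(1)),
               vapply(pooled, function(x) paste(x$genes, collapse = ","),
                      character(1)))
  expect_length(pool_calls(list()), 0L)
})

test_that("run_pipeline combines both passes and reports the increase", {
  sp <- simulate_species_tree(6, seed = 77)
  uni <- sp$tip.label
  groups <- rbind(mk_group(uni, "fam_exact"),
                  mk_group(uni[-2], "fam_loss"),
                  mk_group(c(uni, "T03"), "fam_dup"),
                  plant_paralog_family(sp, "fam_planted")$group,
                  mk_group(c(uni, "T01", "T04"), "fam_messy"))
  trees <- list(fam_planted = plant_paralog_family(sp, "fam_planted")$gene_tree)
  res <- suppressWarnings(run_pipeline(groups, trees, sp))
  rep <- res$report
  expect_equal(rep$n_taxon_count_exact, 1L)
  expect_equal(rep$n_taxon_count_one_dup, 1L)
  expect_equal(rep$n_taxon_count_one_loss, 1L)
  expect_equal(rep$n_subtree_rescued, 1L)
  expect_equal(rep$n_total_unique, 4L)
  expect_equal(rep$percent_increase, 100 * 1 / 3)
  # the planted family contributes two sub-tree calls (one per clade)
  expect_length(res$subtree_calls, 2L)
  # a multigene group without a tree is skipped with a warning
  expect_warning(run_pipeline(groups, trees["nope"], sp), "without a gene tree")
  # identical guide trees pool to the same calls as one guide
  res2 <- suppressWarnings(run_pipeline(groups, trees, list(g1 = sp, g2 = sp)))
  expect_equal(length(res2$subtree_calls), length(res$subtree_calls))
  expect_equal(res2$report$n_total_unique, rep$n_total_unique)
})

test_that("calls_to_table serialises calls", {
  sp <- parse_newick("((A,B),C);")
  rec <- reconcile_rooted(parse_newick("((A|a,B|b),C|c);"), sp)
  tab <- calls_to_table(find_single_copy_subtrees(rec, group_id = "g0",
                                                  guide_id = "gd"))
  expect_equal(tab$genes, "A|a,B|b,C|c")
  expect_equal(tab$mode, "subtree")
  expect_equal(nrow(calls_to_table(list())), 0L)
})
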