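# Unrooted reconciliation: directed edge labeling, star types, optimal
# edge set and cost, against hand-derived quartets and the brute-force
# rooting-every-edge oracle.

quartet_S <- species_tree("((a,b),(c,d));")

test_that("edge labeling of the congruent and swapped quartets", {
  g <- unrooted_gene_tree("((a,b),(c,d));")
  r <- unrooted_reconcile(g, quartet_S)
  top <- r$top
  center <- which(!g$is_leaf[g$ends[, 1]] & !g$is_leaf[g$ends[, 2]])
  # center carries the two cherry labels ab / cd, hence is symmetric non-top
  expect_setequal(r$S$cluster[r$labels[center, ]], c("ab", "cd"))
  # every leaf out-edge carries the leaf's species label
  for (e in seq_len(g$n_edge)) {
    for (j in 1:2) {
      v <- g$ends[e, j]
      if (g$is_leaf[v]) {
        expect_equal(r$S$cluster[r$labels[e, j]], g$labels[v])
      }
    }
  }
  # the complement label of each leaf of a cherry is the species root
  leafe <- setdiff(seq_len(g$n_edge), center)
  compl <- vapply(leafe, function(e) {
    j <- if (g$is_leaf[g$ends[e, 1]]) 2L else 1L
    r$labels[e, j]
  }, integer(1))
  expect_true(all(compl == top))
  # swapped quartet: both center labels are top
  g2 <- unrooted_gene_tree("((b,c),(a,d));")
  r2 <- unrooted_reconcile(g2, quartet_S)
  center2 <- which(!g2$is_leaf[g2$ends[, 1]] & !g2$is_leaf[g2$ends[, 2]])
  expect_true(all(r2$labels[center2, ] == r2$top))
})

test_that("star types of the quartet configurations", {
  r <- unrooted_reconcile(unrooted_gene_tree("((a,b),(c,d));"), quartet_S)
  expect_setequal(unname(star_types(r)), "S2")
  r2 <- unrooted_reconcile(unrooted_gene_tree("((b,c),(a,d));"), quartet_S)
  expect_setequal(unname(star_types(r2)), "S3")
  # same-species cherries on a restricted tree still classify (totality)
  r3 <- unrooted_reconcile(unrooted_gene_tree("((a,b),(a,b));"), quartet_S)
  expect_true(all(unname(star_types(r3)) %in% paste0("S", 1:5)))
})

test_that("optimal edges and costs on the worked quartets", {
  g <- unrooted_gene_tree("((a,b),(c,d));")
  r <- unrooted_reconcile(g, quartet_S)
  center <- which(!g$is_leaf[g$ends[, 1]] & !g$is_leaf[g$ends[, 2]])
  expect_equal(r$cost, 0)
  expect_equal(r$min_edges, center)
  expect_equal(sort(r$edge_costs), c(0, 4, 4, 4, 4))
  g2 <- unrooted_gene_tree("((b,c),(a,d));")
  r2 <- unrooted_reconcile(g2, quartet_S)
  center2 <- which(!g2$is_leaf[g2$ends[, 1]] & !g2$is_leaf[g2$ends[, 2]])
  expect_equal(r2$cost, 5)
  expect_equal(r2$min_edges, center2)
  expect_equal(sort(r2$edge_costs), c(5, 8, 8, 8, 8))
  # two-leaf gene tree: the single edge is trivially optimal
  r3 <- unrooted_reconcile(unrooted_gene_tree("(a,b);"), quartet_S)
  expect_equal(r3$min_edges, 1L)
  expect_equal(r3$cost, 0) # speciation at the restricted root, no events
})

test_that("linear-time optimal edges match brute force on random instances", {
  set.seed(31)
  weights <- list(c(1, 1), c(1, 2), c(3, 1), c(0.5, 0.5))
  for (i in 1:60) {
    S <- rand_species(sample(4:16, 1))
    G <- rand_gene(S, sample(4:24, 1))
    w <- weights[[sample(4, 1)]]
    r <- unrooted_reconcile(G, S, w[1], w[2])
    b <- brute_force_optimal(G, S, w[1], w[2])
    expect_equal(r$cost, b$cost)
    expect_equal(sort(r$min_edges), sort(b$min_edges))
    expect_equal(r$edge_costs, b$edge_costs)
    expect_true(dlrecon:::.check_min_structure(G, r))
  }
})

test_that("rooting cost is invariant under endpoint order", {
  set.seed(32)
  for (i in 1:10) {
    S <- rand_species(6)
    G <- rand_gene(S, 8)
    for (e in seq_len(G$n_edge)) {
      H <- G
      H$ends[e, ] <- rev(H$ends[e, ])
      expect_equal(dlrecon:::.rooted_dl(root_at_edge(G, e), S),
                   dlrecon:::.rooted_dl(root_at_edge(H, e), S))
    }
  }
})

test_that("single-species families make every edge optimal", {
  g <- unrooted_gene_tree("((a,a),(a,a));")
  r <- unrooted_reconcile(g, quartet_S)
  expect_equal(sort(r$min_edges), seq_len(g$n_edge))
  expect_equal(r$cost, 3) # three internal nodes of the rooting, all dups
})
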