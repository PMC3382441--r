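# k-NNI error correction: weak edges, neighborhood search semantics,
# aggregate totals and mu-filtering.

quartet_S <- species_tree("((a,b),(c,d));")

test_that("weak edges are the measured edges strictly below omega", {
  g <- unrooted_gene_tree("((a:1,b:2):0.05,(c:1,d:1):0.06);")
  center <- which(!g$is_leaf[g$ends[, 1]] & !g$is_leaf[g$ends[, 2]])
  expect_length(weak_edges(g, 0), 0)      # strict: nothing is < 0
  expect_equal(weak_edges(g, 0.2), center)
  expect_length(weak_edges(g, Inf), 5)
  g2 <- unrooted_gene_tree("((a,b),(c,d));") # no lengths: never weak
  expect_length(weak_edges(g2, 10), 0)
})

test_that("the swapped quartet is corrected in one NNI", {
  g_ok <- unrooted_gene_tree("((a,b),(c,d));")
  r0 <- correct_gene_tree(g_ok, quartet_S, k = 0)
  expect_equal(r0$cost, 0)
  expect_false(r0$errors_found)
  g_bad <- unrooted_gene_tree("((b,c),(a,d));")
  r1 <- correct_gene_tree(g_bad, quartet_S, k = 0)
  expect_equal(r1$cost, 5)
  r2 <- correct_gene_tree(g_bad, quartet_S, k = 1)
  expect_equal(r2$cost, 0)
  expect_true(r2$errors_found)
  expect_length(r2$moves, 1)
  expect_identical(topology_key(r2$corrected), topology_key(g_ok))
  # the 1-NNI neighborhood of bc|ad is {bc|ad, ab|cd, ac|bd}: costs 5,0,5
  nb <- materialize_neighborhood(g_bad, 1)
  expect_setequal(sapply(nb, function(h) brute_force_optimal(h, quartet_S)$cost),
                  c(5, 0, 5))
  # no further improvement at k = 2
  expect_equal(correct_gene_tree(g_bad, quartet_S, k = 2)$cost, 0)
})

test_that("corrected cost equals brute force over the materialized neighborhood", {
  set.seed(51)
  for (i in 1:10) {
    S <- rand_species(sample(4:8, 1))
    G <- rand_gene(S, sample(5:12, 1))
    costs <- vapply(0:2, function(k)
      correct_gene_tree(G, S, k = k)$cost, numeric(1))
    expect_true(all(diff(costs) <= 1e-9)) # monotone in k
    for (k in 1:2) {
      nb <- materialize_neighborhood(G, k)
      ref <- min(vapply(nb, function(h) brute_force_optimal(h, S)$cost,
                        numeric(1)))
      expect_equal(costs[k + 1], ref)
    }
  }
})

test_that("k = 0 reproduces plain unrooted reconciliation exactly", {
  set.seed(52)
  for (i in 1:10) {
    S <- rand_species(6)
    G <- rand_gene(S, 10)
    r <- correct_gene_tree(G, S, k = 0)
    u <- unrooted_reconcile(G, S)
    expect_equal(r$cost, u$cost)
    expect_identical(sort(r$recon$min_edges), sort(u$min_edges))
    expect_identical(r$recon$canonical_split, u$canonical_split)
  }
})

test_that("omega restricts the search to weak input edges", {
  g_bad <- unrooted_gene_tree("((b:1,c:1):0.02,(a:1,d:1):0.03);")
  # center is the only internal edge and it is weak at omega = 0.1
  expect_equal(correct_gene_tree(g_bad, quartet_S, k = 1, omega = 0.1)$cost, 0)
  # omega = 0.01 leaves no weak edges: no correction possible
  r <- correct_gene_tree(g_bad, quartet_S, k = 1, omega = 0.01)
  expect_equal(r$cost, 5)
  expect_false(r$errors_found)
  # omega on a lengthless tree warns and corrects nothing
  g_nolen <- unrooted_gene_tree("((b,c),(a,d));")
  expect_warning(r2 <- correct_gene_tree(g_nolen, quartet_S, k = 1, omega = 0.1),
                 "no weak edges")
  expect_equal(r2$cost, 5)
})

test_that("knnic totals add up and report per-tree corrections", {
  trees <- list(unrooted_gene_tree("((a,b),(c,d));"),
                unrooted_gene_tree("((b,c),(a,d));"))
  expect_equal(knnic_total(trees, quartet_S, k = 1)$total, 0)
  expect_equal(knnic_total(trees, quartet_S, k = 0)$total, 5)
  expect_equal(knnic_total(list(), quartet_S, k = 0)$total, 0)
  expect_error(knnic_total(list(unrooted_gene_tree("(a,zz);")), quartet_S),
               "gene tree 1")
})

test_that("mu-filtering rejects trees with too many weak edges, monotonely", {
  mk <- function(lens) { # center length is lens[3] + lens[6] (root merge)
    unrooted_gene_tree(sprintf("((a:%f,b:%f):%f,(c:%f,d:%f):%f);",
                               lens[1], lens[2], lens[3], lens[4], lens[5],
                               lens[6]))
  }
  t0 <- mk(c(1, 1, 1, 1, 1, 1))          # 0 weak edges at omega=0.5
  t3 <- mk(c(0.1, 0.1, 0.1, 1, 1, 0.1))  # 3 weak edges (a, b, center)
  flt <- filter_by_mu(list(t0, t3), omega = 0.5, mu = 2)
  expect_equal(flt$accepted_idx, 1L)
  expect_equal(flt$rejected_idx, 2L)
  expect_equal(filter_by_mu(list(t0, t3), omega = 0.5, mu = 3)$rejected_idx,
               integer(0))
  set.seed(53)
  S <- rand_species(6)
  trees <- replicate(30, rand_gene(S, 8, lengths = TRUE), simplify = FALSE)
  sizes <- vapply(1:6, function(mu)
    length(filter_by_mu(trees, omega = 0.5, mu = mu)$accepted_idx), integer(1))
  expect_true(all(diff(sizes) >= 0)) # accepted set grows with mu
})
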