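# Tree structures, newick round-trips, and the species-tree order/metric
# primitives (lca, comparability, path distance, sibling sets, loss counts).

test_that("species tree parsing exposes the expected clusters", {
  S <- species_tree("(a,(b,c));")
  expect_equal(S$n_node, 5L)
  expect_setequal(S$cluster, c("a", "b", "c", "bc", "abc"))
  expect_error(species_tree("(a,(b,c),(d,e));"), "rooted|binary")
  expect_error(species_tree("((a,b),(c,d),e);"), "rooted|binary")
  expect_error(species_tree("(a,(b,a));"), "unique")
  expect_error(species_tree("((a,b"), "malformed")
})

test_that("gene tree parsing suppresses a degree-2 root, merging lengths", {
  g <- unrooted_gene_tree("((a:1,b:2):0.05,(c:1,d:1):0.06);")
  expect_equal(sum(g$is_leaf), 4L)
  expect_equal(g$n_edge, 5L)
  center <- which(!g$is_leaf[g$ends[, 1]] & !g$is_leaf[g$ends[, 2]])
  expect_equal(g$elen[center], 0.11)
  # two-leaf tree: one edge
  g2 <- unrooted_gene_tree("(a,b);")
  expect_equal(g2$n_edge, 1L)
  expect_true(all(g2$is_leaf))
  # trifurcating input accepted as-is
  g3 <- unrooted_gene_tree("(a,b,(c,d));")
  expect_equal(g3$n_edge, 5L)
})

test_that("newick round-trips preserve topology, labels and lengths", {
  set.seed(11)
  for (i in 1:20) {
    S <- rand_species(sample(3:12, 1))
    expect_identical(unrooted_key_of_species(species_tree(write_newick(S))),
                     unrooted_key_of_species(S))
    G <- rand_gene(S, sample(4:14, 1), lengths = TRUE)
    G2 <- unrooted_gene_tree(write_newick(G))
    expect_identical(topology_key(G2), topology_key(G))
    expect_equal(sort(G2$elen), sort(G$elen), tolerance = 1e-9)
  }
  # a rooting of the quartet at the center edge is ((a,b),(c,d))
  g <- unrooted_gene_tree("((a,b),(c,d));")
  center <- which(!g$is_leaf[g$ends[, 1]] & !g$is_leaf[g$ends[, 2]])
  expect_identical(write_newick(root_at_edge(g, center)), "((a,b),(c,d));")
})

test_that("lca index agrees with the naive upward walk on all pairs", {
  set.seed(12)
  for (i in 1:10) {
    S <- rand_species(sample(3:32, 1))
    pairs <- expand.grid(a = seq_len(S$n_node), b = seq_len(S$n_node))
    got <- lca_node(S, pairs$a, pairs$b)
    want <- mapply(function(a, b) naive_lca(S, a, b), pairs$a, pairs$b)
    expect_equal(got, want)
  }
  S <- species_tree("(a,(b,c));")
  expect_equal(S$cluster[lca_node(S, "b", "c")], "bc")
  expect_equal(S$cluster[lca_node(S, "a", "b")], "abc")
  expect_equal(lca_node(S, 4L, 4L), 4L)
})

test_that("comparability, distance and sibling sets follow the definitions", {
  S <- species_tree("(a,(b,c));")
  expect_equal(comparable(S, "b", "bc"), 1L)
  expect_equal(comparable(S, "a", "bc"), 0L)
  expect_equal(comparable(S, "a", "a"), 1L)
  expect_equal(node_distance(S, "a", "b"), 3L)
  expect_equal(node_distance(S, "b", "b"), 0L)
  S4 <- species_tree("((a,b),(c,d));")
  expect_equal(node_distance(S4, "a", "d"), 4L)
  expect_length(sibling_set(S, "b", "c"), 0)      # siblings
  expect_length(sibling_set(S, "bc", "bc"), 0)    # equal
  expect_equal(names(sibling_set(S, "a", "b")), "c")
  expect_equal(loss_count(S, "a", "b"), 1L)
  expect_equal(loss_count(S4, "a", "d"), 2L)
  expect_equal(loss_count(S, "c", "c"), 0L)
})

test_that("loss count equals the sibling-set size on random trees", {
  set.seed(13)
  for (i in 1:25) {
    S <- rand_species(sample(3:32, 1))
    pairs <- expand.grid(a = seq_len(S$n_node), b = seq_len(S$n_node))
    sb_size <- mapply(function(a, b) length(sibling_set(S, a, b)),
                      pairs$a, pairs$b)
    expect_equal(loss_count(S, pairs$a, pairs$b), sb_size)
    # distance is symmetric and zero only on the diagonal
    expect_equal(node_distance(S, pairs$a, pairs$b),
                 node_distance(S, pairs$b, pairs$a))
    expect_identical(node_distance(S, pairs$a, pairs$b) == 0L,
                     pairs$a == pairs$b)
  }
})

test_that("species restriction keeps clusters and is identity on full sets", {
  S <- species_tree("((a,(b,c)),(d,e));")
  Sr <- restrict_species(S, c("b", "c", "a"))
  expect_s3_class(Sr, "species_tree")
  expect_setequal(Sr$tip_label, c("a", "b", "c"))
  expect_setequal(Sr$cluster, c("a", "b", "c", "bc", "abc"))
  expect_identical(restrict_species(S, c("a", "b", "c", "d", "e")), S)
  expect_s3_class(restrict_species(S, "d"), "species_leaf")
  expect_error(restrict_species(S, "zz"), "not in species tree")
})
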