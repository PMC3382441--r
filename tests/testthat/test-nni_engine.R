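# NNI engine: frame enumeration, label locality, the closed-form cost
# differences, and the constant-time maintenance of Min_G and the optimal
# cost along random NNI walks.

test_that("frame enumeration yields two variants per internal edge", {
  g4 <- unrooted_gene_tree("((a,b),(c,d));")
  expect_length(enumerate_nni(g4), 2L)
  g5 <- unrooted_gene_tree("(((a,b),c),(d,e));")
  expect_length(enumerate_nni(g5), 4L)
  expect_length(enumerate_nni(g5, edges = integer(0)), 0L)
  expect_length(enumerate_nni(unrooted_gene_tree("(a,b);")), 0L)
})

test_that("delta3 and delta4 match their worked values and symmetries", {
  S3 <- species_tree("(a,(b,c));")
  expect_equal(delta3(S3, "a", "b", "c"), -4)
  expect_equal(delta3(S3, "c", "b", "a"), 4)
  expect_equal(delta3(S3, "b", "b", "b"), 0)
  # cross-check: cost(((a,b),c)) - cost((a,(b,c))) under S3
  d <- reconciliation_cost(rooted_gene_tree("(a,(b,c));"), S3)$cost -
    reconciliation_cost(rooted_gene_tree("((a,b),c);"), S3)$cost
  expect_equal(delta3(S3, "a", "b", "c"), d)
  S4 <- species_tree("((a,b),(c,d));")
  expect_equal(delta4(S4, "a", "b", "c", "d"), 5)
  expect_equal(delta4(S4, "a", "a", "a", "a"), 0)
  expect_equal(delta4(S4, "a", "b", "a", "b"), 0)
  # cross-check: cost(((b,c),(a,d))) - cost(((a,b),(c,d)))
  d4 <- reconciliation_cost(rooted_gene_tree("((b,c),(a,d));"), S4)$cost -
    reconciliation_cost(rooted_gene_tree("((a,b),(c,d));"), S4)$cost
  expect_equal(delta4(S4, "a", "b", "c", "d"), d4)
})

test_that("an NNI changes only the center-edge labels", {
  set.seed(41)
  for (i in 1:20) {
    S <- rand_species(sample(4:10, 1))
    G <- rand_gene(S, sample(5:14, 1))
    st <- recon_state(G, S)
    if (is.null(st$lab)) next
    frames <- enumerate_nni(st)
    if (!length(frames)) next
    fr <- frames[[sample(length(frames), 1)]]
    lab_before <- st$lab
    apply_nni(st, fr)
    changed <- which(st$lab[, 1] != lab_before[, 1] |
                     st$lab[, 2] != lab_before[, 2])
    expect_true(all(changed %in% fr$e0))
  }
})

test_that("apply followed by undo restores the exact state", {
  set.seed(42)
  S <- rand_species(8)
  G <- rand_gene(S, 12)
  st <- recon_state(G, S)
  snap <- list(adj = st$adj, ends = st$ends, lab = st$lab,
               min = st$min_edges, sigma = st$sigma)
  tokens <- list()
  for (step in 1:8) {
    frames <- enumerate_nni(st)
    tokens[[step]] <- apply_nni(st, frames[[sample(length(frames), 1)]])
  }
  for (step in 8:1) undo_nni(st, tokens[[step]])
  expect_identical(st$adj, snap$adj)
  expect_identical(st$ends, snap$ends)
  expect_identical(st$lab, snap$lab)
  expect_identical(st$min_edges, snap$min)
  expect_identical(st$sigma, snap$sigma)
})

test_that("a frame's swap is reversed by the matching frame on the new tree", {
  g <- unrooted_gene_tree("((a,b),(c,d));")
  key0 <- topology_key(g)
  h <- dlrecon:::apply_nni_topology(g, which(!g$is_leaf[g$ends[, 1]] &
                                             !g$is_leaf[g$ends[, 2]]), 1L)
  expect_false(identical(topology_key(h), key0))
  center_h <- which(!h$is_leaf[h$ends[, 1]] & !h$is_leaf[h$ends[, 2]])
  back <- vapply(1:2, function(v) {
    topology_key(dlrecon:::apply_nni_topology(h, center_h, v))
  }, character(1))
  expect_true(key0 %in% back)
})

test_that("incremental state equals from-scratch recomputation along walks", {
  set.seed(43)
  weights <- list(c(1, 1), c(1, 2), c(3, 1))
  for (i in 1:12) {
    S <- rand_species(sample(4:12, 1))
    G <- rand_gene(S, sample(5:16, 1))
    w <- weights[[sample(3, 1)]]
    st <- recon_state(G, S, w[1], w[2])
    for (step in 1:20) {
      frames <- enumerate_nni(st)
      if (!length(frames)) break
      apply_nni(st, frames[[sample(length(frames), 1)]])
      cur <- dlrecon:::state_tree(st)
      ref <- unrooted_reconcile(cur, S, w[1], w[2])
      expect_equal(st$sigma, ref$cost)
      expect_identical(st$min_edges, sort(ref$min_edges))
    }
    expect_identical(st$n_fallback, 0L)
  }
})

test_that("maintained cost matches a from-scratch rooting at a surviving edge", {
  set.seed(44)
  S <- rand_species(8)
  G <- rand_gene(S, 14)
  st <- recon_state(G, S)
  for (step in 1:25) {
    frames <- enumerate_nni(st)
    apply_nni(st, frames[[sample(length(frames), 1)]])
    cur <- dlrecon:::state_tree(st)
    e <- st$min_edges[1]
    dl <- dlrecon:::.rooted_dl(root_at_edge(cur, e), S)
    expect_equal(st$sigma, dl[1] + dl[2])
  }
})
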