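# Random fixtures and independent oracles shared across the suite.
# Random trees are drawn via ape (independent of the package's own
# generators) so that structural properties are not tested against the
# code that produced the fixture.

rand_species <- function(n, labels = paste0("s", seq_len(n))) {
  phy <- ape::rtree(n, tip.label = labels)
  phy$edge.length <- NULL
  species_tree(phy)
}

rand_gene <- function(S, n_leaves, lengths = FALSE) {
  phy <- ape::rtree(n_leaves, rooted = FALSE)
  phy$tip.label <- sample(S$tip_label, n_leaves, replace = TRUE)
  if (!lengths) phy$edge.length <- NULL
  unrooted_gene_tree(phy)
}

rand_rooted_gene <- function(S, n_leaves) {
  phy <- ape::rtree(n_leaves)
  phy$tip.label <- sample(S$tip_label, n_leaves, replace = TRUE)
  phy$edge.length <- NULL
  rooted_gene_tree(phy)
}

# Naive LCA by upward walks: the definitional oracle for the indexed query.
naive_lca <- function(S, a, b) {
  anc <- function(v) {
    out <- v
    while (!is.na(S$parent[v])) {
      v <- S$parent[v]
      out <- c(out, v)
    }
    out
  }
  aa <- anc(a)
  bb <- anc(b)
  common <- intersect(aa, bb)
  common[which.max(S$depth[common])]
}

# Direct xi-sum duplication/loss contributions per internal node: iterate
# over all species nodes a, applying the pointwise cost-function
# definitions (duplication: M(v) = M(w_i) = a; loss: a in Sb of the
# children's images).
xi_sum_costs <- function(G, S) {
  m <- lca_mapping(G, S)
  internal <- G$postorder[!G$is_leaf[G$postorder]]
  t(vapply(internal, function(v) {
    w <- G$children[v, ]
    kd <- 0L
    kl <- 0L
    sb <- sibling_set(S, m[w[1]], m[w[2]])
    for (a in seq_len(S$n_node)) {
      if (m[v] == a && (m[w[1]] == a || m[w[2]] == a)) kd <- kd + 1L
      if (a %in% sb) kl <- kl + 1L
    }
    c(dup = kd, loss = kl)
  }, c(dup = 0L, loss = 0L)))
}

# Materialized <=k-NNI neighborhood by breadth-first tree copies,
# deduplicated by canonical topology; independent of the DFS-with-undo
# search path.
materialize_neighborhood <- function(G, k, eligible = NULL) {
  seen <- new.env(parent = emptyenv())
  out <- list(G)
  seen[[topology_key(G)]] <- TRUE
  frontier <- list(G)
  for (d in seq_len(k)) {
    nxt <- list()
    for (g in frontier) {
      internal <- which(!g$is_leaf[g$ends[, 1]] & !g$is_leaf[g$ends[, 2]])
      cand <- if (is.null(eligible)) internal else intersect(internal, eligible)
      for (e in cand) {
        for (v in 1:2) {
          h <- dlrecon:::apply_nni_topology(g, e, v)
          kk <- topology_key(h)
          if (is.null(seen[[kk]])) {
            seen[[kk]] <- TRUE
            out <- c(out, list(h))
            nxt <- c(nxt, list(h))
          }
        }
      }
    }
    frontier <- nxt
  }
  out
}

unrooted_key_of_species <- function(nwk_or_S) {
  nwk <- if (inherits(nwk_or_S, "species_tree")) write_newick(nwk_or_S) else nwk_or_S
  topology_key(unrooted_gene_tree(nwk))
}
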