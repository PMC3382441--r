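#' LCA mapping of a rooted gene tree into a species tree
#'
#' Maps each leaf to the species-tree leaf carrying its label and each
#' internal node to the least common ancestor of its children's images.
#' Runs in linear time after the species-tree index build.
#'
#' @param G An `rgene_tree`.
#' @param S A `species_tree` containing every leaf label of `G`.
#' @return Integer vector: species-tree node id per gene-tree node.
#' @export
lca_mapping <- function(G, S) {
  m <- integer(G$n_node)
  for (v in G$postorder) {
    if (G$is_leaf[v]) {
      id <- S$label2node[G$labels[v]]
      if (is.na(id)) stop("gene leaf label not in species tree: ", G$labels[v])
      m[v] <- id
    } else {
      m[v] <- .lca1(S, m[G$children[v, 1L]], m[G$children[v, 2L]])
    }
  }
  m
}

#' Per-node duplication and loss contributions
#'
#' For an internal node `v` with children `w1, w2`, the duplication
#' contribution is `D(M(w1), M(w2))` (1 iff the children's images are
#' comparable, i.e. `v` is a duplication) and the loss contribution is
#' `L(M(w1), M(w2))`. Leaves contribute 0.
#'
#' @inheritParams lca_mapping
#' @param mapping Optional precomputed [lca_mapping()].
#' @return A data frame with one row per node in postorder: `node`,
#'   `cluster` (image of the node), `dup`, `loss`, `is_duplication`.
#' @export
node_costs <- function(G, S, mapping = NULL) {
  m <- if (is.null(mapping)) lca_mapping(G, S) else mapping
  nodes <- G$postorder
  dup <- integer(length(nodes))
  loss <- integer(length(nodes))
  int <- !G$is_leaf[nodes]
  if (any(int)) {
    w1 <- G$children[nodes[int], 1L]
    w2 <- G$children[nodes[int], 2L]
    l <- .lca(S, m[w1], m[w2])
    d <- as.integer(l == m[w1] | l == m[w2])
    rho <- S$depth[m[w1]] + S$depth[m[w2]] - 2L * S$depth[l]
    dup[int] <- d
    loss[int] <- rho - 2L * (1L - d)
  }
  data.frame(node = nodes,
             cluster = S$cluster[m[nodes]],
             dup = dup, loss = loss,
             is_duplication = dup == 1L,
             stringsAsFactors = FALSE)
}

#' Weighted duplication-loss reconciliation cost
#'
#' Total mutation cost `alpha * duplications + beta * losses` of embedding a
#' rooted gene tree into a species tree, with the minimal event counts.
#'
#' @inheritParams node_costs
#' @param alpha,beta Positive event weights (duplication, loss).
#' @return List with integer `duplications`, `losses` and numeric `cost`.
#' @examples
#' S <- species_tree("(a,(b,c));")
#' G <- rooted_gene_tree("((a,b),(a,c));")
#' reconciliation_cost(G, S)   # 1 duplication, 2 losses, cost 3
#' @export
reconciliation_cost <- function(G, S, alpha = 1, beta = 1) {
  stopifnot(alpha > 0, beta > 0)
  nc <- node_costs(G, S)
  d <- sum(nc$dup)
  l <- sum(nc$loss)
  list(duplications = d, losses = l, cost = alpha * d + beta * l)
}

# Fast internal rooted cost: duplication and loss sums for a rooting of an
# unrooted tree, given arrays (used by the brute-force oracle).
.rooted_dl <- function(G, S) {
  m <- integer(G$n_node)
  dups <- 0L
  losses <- 0L
  for (v in G$postorder) {
    if (G$is_leaf[v]) {
      m[v] <- S$label2node[G$labels[v]]
    } else {
      a <- m[G$children[v, 1L]]
      b <- m[G$children[v, 2L]]
      l <- .lca1(S, a, b)
      d <- (l == a || l == b)
      rho <- S$depth[a] + S$depth[b] - 2L * S$depth[l]
      dups <- dups + d
      losses <- losses + rho - 2L * (1L - d)
      m[v] <- l
    }
  }
  c(dups, losses)
}
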