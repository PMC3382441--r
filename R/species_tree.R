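#' Build a species tree with a constant-time LCA index
#'
#' A species tree is a rooted binary tree whose leaves are uniquely labeled
#' by the species identifiers. Internal nodes are identified by their
#' *cluster*, the set of descendant leaf labels; reports write clusters as
#' the concatenation of the sorted labels (so the parent of leaves `b` and
#' `c` is written `bc`). The returned object carries an Euler-tour + sparse
#' table index so that least-common-ancestor queries run in constant time
#' after the linearithmic build.
#'
#' @param x A newick string, a file containing one newick tree, or an
#'   `ape::phylo` object. The tree must be rooted and binary with unique
#'   tip labels.
#' @return An object of class `species_tree` with fields `n_tip`, `n_node`
#'   (total node count), `parent`, `children`, `depth` (edge distance from
#'   the root), `brlen` (branch length above each node, `NA` when absent),
#'   `cluster` (display name per node) and the LCA index tables. Nodes are
#'   numbered as in `ape`: tips `1..n_tip`, root `n_tip + 1`.
#' @examples
#' S <- species_tree("(a,(b,c));")
#' S$cluster                     # "a" "b" "c" "abc" "bc"
#' lca_node(S, "b", "c")         # node with cluster "bc"
#' @export
species_tree <- function(x) {
  phy <- .as_phylo(x)
  if (!ape::is.rooted(phy)) stop("species tree must be rooted")
  if (!ape::is.binary(phy)) stop("species tree must be binary")
  if (anyDuplicated(phy$tip.label)) {
    stop("species tree leaf labels must be unique")
  }
  if (length(phy$tip.label) < 2L) stop("species tree needs at least 2 leaves")
  n_tip <- length(phy$tip.label)
  m <- n_tip + phy$Nnode
  parent <- rep(NA_integer_, m)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  children <- matrix(NA_integer_, m, 2L)
  slot <- integer(m)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]
    slot[p] <- slot[p] + 1L
    children[p, slot[p]] <- phy$edge[i, 2L]
  }
  brlen <- rep(NA_real_, m)
  if (!is.null(phy$edge.length)) brlen[phy$edge[, 2L]] <- phy$edge.length
  root <- n_tip + 1L
  .species_tree_from_arrays(parent, children, root, phy$tip.label, brlen)
}

# Assemble a species_tree object from parent/children arrays (shared by the
# newick path and by structural restriction).
.species_tree_from_arrays <- function(parent, children, root, tip_label,
                                      brlen = NULL) {
  m <- length(parent)
  n_tip <- length(tip_label)
  is_leaf <- is.na(children[, 1L])
  # breadth-first order from the root; reversing it gives a bottom-up order
  ord <- integer(m)
  ord[1L] <- root
  depth <- rep(NA_integer_, m)
  depth[root] <- 0L
  k <- 1L
  i <- 1L
  while (i <= k) {
    v <- ord[i]
    if (!is_leaf[v]) {
      c1 <- children[v, 1L]; c2 <- children[v, 2L]
      depth[c1] <- depth[v] + 1L
      depth[c2] <- depth[v] + 1L
      ord[k + 1L] <- c1
      ord[k + 2L] <- c2
      k <- k + 2L
    }
    i <- i + 1L
  }
  # clusters: sorted concatenated leaf labels ("bc", "abc", ...)
  sep <- if (all(nchar(tip_label) == 1L)) "" else "+"
  cl_set <- vector("list", m)
  cluster <- character(m)
  for (v in rev(ord)) {
    if (is_leaf[v]) {
      cl_set[[v]] <- tip_label[v]
    } else {
      cl_set[[v]] <- sort(c(cl_set[[children[v, 1L]]], cl_set[[children[v, 2L]]]))
    }
    cluster[v] <- paste(cl_set[[v]], collapse = sep)
  }
  idx <- .build_lca_index(children, root, m, is_leaf)
  S <- list(
    n_tip = n_tip, n_node = m, root = root,
    parent = parent, children = children, is_leaf = is_leaf,
    depth = depth, brlen = if (is.null(brlen)) rep(NA_real_, m) else brlen,
    tip_label = tip_label,
    label2node = stats::setNames(seq_len(n_tip), tip_label),
    cluster = cluster,
    tour = idx$tour, tdep = idx$tdep, first = idx$first,
    sp = idx$sp, logt = idx$logt, pow2 = idx$pow2
  )
  class(S) <- "species_tree"
  S
}

# Euler tour + sparse table for range-minimum LCA queries.
.build_lca_index <- function(children, root, m, is_leaf) {
  len <- 2L * m - 1L
  tour <- integer(len)
  # iterative Euler tour
  stk_node <- integer(m + 1L)
  stk_state <- integer(m + 1L)
  top <- 1L
  stk_node[1L] <- root
  stk_state[1L] <- 0L
  pos <- 0L
  while (top > 0L) {
    v <- stk_node[top]
    st <- stk_state[top]
    pos <- pos + 1L
    tour[pos] <- v
    if (is_leaf[v] || st == 2L) {
      top <- top - 1L
    } else {
      stk_state[top] <- st + 1L
      top <- top + 1L
      stk_node[top] <- children[v, st + 1L]
      stk_state[top] <- 0L
    }
  }
  # a node visited k times contributes k tour entries; depth per entry
  first <- integer(m)
  for (i in rev(seq_len(len))) first[tour[i]] <- i
  logt <- floor(log2(seq_len(len)))
  nlev <- logt[len] + 1L
  pow2 <- as.integer(2^(0:(nlev)))
  sp <- matrix(0L, nlev + 1L, len) # row k+1 = window size 2^k, values: tour pos
  sp[1L, ] <- seq_len(len)
  tdep <- integer(len)
  # tdep filled after depth known by caller; compute from tour via stack depth:
  # recompute depths here from children structure
  dep <- integer(m)
  dep[root] <- 0L
  ordq <- integer(m); ordq[1L] <- root; k <- 1L; i <- 1L
  while (i <= k) {
    v <- ordq[i]
    if (!is_leaf[v]) {
      c1 <- children[v, 1L]; c2 <- children[v, 2L]
      dep[c1] <- dep[v] + 1L; dep[c2] <- dep[v] + 1L
      ordq[k + 1L] <- c1; ordq[k + 2L] <- c2; k <- k + 2L
    }
    i <- i + 1L
  }
  tdep <- dep[tour]
  if (nlev >= 1L) {
    for (kk in seq_len(nlev)) {
      w <- pow2[kk] # half-window size 2^(kk-1)
      nmax <- len - 2L * w + 1L
      if (nmax < 1L) { sp[kk + 1L, ] <- sp[kk, ]; next }
      i1 <- seq_len(nmax)
      a <- sp[kk, i1]
      b <- sp[kk, i1 + w]
      pick <- tdep[a] <= tdep[b]
      sp[kk + 1L, i1] <- ifelse(pick, a, b)
      if (nmax < len) sp[kk + 1L, (nmax + 1L):len] <- sp[kk, (nmax + 1L):len]
    }
  }
  list(tour = tour, tdep = tdep, first = first, sp = sp, logt = logt,
       pow2 = pow2)
}

# Vectorized constant-time LCA query on node-id vectors.
.lca <- function(S, a, b) {
  ia <- S$first[a]
  ib <- S$first[b]
  lo <- pmin(ia, ib)
  hi <- pmax(ia, ib)
  k <- S$logt[hi - lo + 1L]
  w <- S$pow2[k + 1L]
  p1 <- S$sp[cbind(k + 1L, lo)]
  p2 <- S$sp[cbind(k + 1L, hi - w + 1L)]
  S$tour[ifelse(S$tdep[p1] <= S$tdep[p2], p1, p2)]
}

# Scalar fast path used in tight traversal loops.
.lca1 <- function(S, a, b) {
  ia <- S$first[a]
  ib <- S$first[b]
  if (ia > ib) { t <- ia; ia <- ib; ib <- t }
  k <- S$logt[ib - ia + 1L]
  p1 <- S$sp[k + 1L, ia]
  p2 <- S$sp[k + 1L, ib - S$pow2[k + 1L] + 1L]
  if (S$tdep[p1] <= S$tdep[p2]) S$tour[p1] else S$tour[p2]
}

.resolve_node <- function(S, x) {
  if (is.character(x)) {
    id <- match(x, S$cluster)
    if (anyNA(id)) stop("unknown cluster name: ", paste(x[is.na(id)], collapse = ", "))
    return(id)
  }
  x <- as.integer(x)
  if (any(x < 1L | x > S$n_node)) stop("node id out of range")
  x
}

#' Least common ancestor of two species-tree nodes
#'
#' The binary least-upper-bound operation of the species-tree semilattice.
#' Nodes may be given as integer ids or cluster names; vectors are
#' recycled elementwise.
#'
#' @param S A `species_tree`.
#' @param a,b Node ids or cluster names.
#' @return Integer node id(s) of the least common ancestor.
#' @export
lca_node <- function(S, a, b) {
  .lca(S, .resolve_node(S, a), .resolve_node(S, b))
}

#' Comparability predicate on species-tree nodes
#'
#' Returns 1 when one node is an ancestor of (or equal to) the other and 0
#' when the two nodes are incomparable, i.e. lie in disjoint clusters.
#'
#' @inheritParams lca_node
#' @return Integer vector of 0/1.
#' @export
comparable <- function(S, a, b) {
  a <- .resolve_node(S, a); b <- .resolve_node(S, b)
  l <- .lca(S, a, b)
  as.integer(l == a | l == b)
}

#' Path distance between species-tree nodes
#'
#' Number of edges on the unique undirected path connecting the two nodes.
#'
#' @inheritParams lca_node
#' @return Non-negative integer vector.
#' @export
node_distance <- function(S, a, b) {
  a <- .resolve_node(S, a); b <- .resolve_node(S, b)
  l <- .lca(S, a, b)
  S$depth[a] + S$depth[b] - 2L * S$depth[l]
}

#' Sibling set along the path between two nodes
#'
#' The set Sb(a, b) of species-tree lineages branching off the path between
#' `a` and `b`, by the three-case recurrence: empty when `a = b` or the two
#' nodes are siblings; otherwise the sibling of the lower node is collected
#' and the recursion climbs one step. Its size is the loss count, see
#' [loss_count()].
#'
#' @inheritParams lca_node
#' @return Integer vector of node ids, named by cluster.
#' @export
sibling_set <- function(S, a, b) {
  a <- .resolve_node(S, a); b <- .resolve_node(S, b)
  out <- .sb(S, a, b)
  stats::setNames(out, S$cluster[out])
}

.sb <- function(S, a, b) {
  if (a == b) return(integer(0))
  pa <- S$parent[a]
  pb <- S$parent[b]
  if (!is.na(pa) && !is.na(pb) && pa == pb) return(integer(0)) # siblings
  if (!is.na(pa)) {
    l <- .lca1(S, a, b)
    # case (ii): a < b, or a+c (= parent of a) < a+b
    if ((l == b && a != b) || (S$depth[pa] > S$depth[l])) {
      sib <- S$children[pa, ]
      cc <- sib[sib != a]
      return(c(cc, .sb(S, pa, b)))
    }
  }
  .sb(S, b, a) # case (iii)
}

#' Loss count between two species-tree nodes
#'
#' `L(a, b) = rho(a, b) - 2 (1 - D(a, b))`: the number of lineages implied
#' lost along the path between `a` and `b`; equals the size of the sibling
#' set [sibling_set()].
#'
#' @inheritParams lca_node
#' @return Non-negative integer vector.
#' @export
loss_count <- function(S, a, b) {
  a <- .resolve_node(S, a); b <- .resolve_node(S, b)
  l <- .lca(S, a, b)
  d <- as.integer(l == a | l == b)
  S$depth[a] + S$depth[b] - 2L * S$depth[l] - 2L * (1L - d)
}

#' Resolve cluster names to node ids
#' @inheritParams lca_node
#' @param cluster Character vector of cluster names (e.g. `"bc"`).
#' @return Integer node ids.
#' @export
node_id <- function(S, cluster) .resolve_node(S, cluster)

# Weighted duplication-loss contribution alpha*D(a,b) + beta*L(a,b),
# vectorized over node-id vectors.
.dl <- function(S, a, b, alpha, beta) {
  l <- .lca(S, a, b)
  d <- l == a | l == b
  rho <- S$depth[a] + S$depth[b] - 2L * S$depth[l]
  alpha * as.numeric(d) + beta * (rho - 2 * (1 - as.numeric(d)))
}

.dl1 <- function(S, a, b, alpha, beta) {
  l <- .lca1(S, a, b)
  d <- (l == a || l == b)
  rho <- S$depth[a] + S$depth[b] - 2L * S$depth[l]
  alpha * d + beta * (rho - 2 * (1 - d))
}

#' Restrict a species tree to the subtree spanned by a label set
#'
#' Returns the subtree of `S` rooted at the least common ancestor of the
#' given leaf labels. Reconciling a gene tree against this subtree gives the
#' same cost as against the full tree, while making the gene-tree root map
#' to the subtree root; the unrooted machinery relies on that normalization.
#'
#' @param S A `species_tree`.
#' @param labels Character vector of species labels present in `S`.
#' @return A `species_tree` on the restricted leaf set (possibly `S` itself).
#' @export
restrict_species <- function(S, labels) {
  labels <- unique(labels)
  ids <- S$label2node[labels]
  if (anyNA(ids)) {
    stop("labels not in species tree: ",
         paste(labels[is.na(ids)], collapse = ", "))
  }
  top <- ids[1L]
  for (i in seq_along(ids)[-1L]) top <- .lca1(S, top, ids[i])
  if (top == S$root) return(S)
  if (S$is_leaf[top]) {
    # single-species gene family: a one-leaf "tree" is not a valid species
    # tree; callers handle this degenerate case explicitly
    return(structure(list(single = TRUE, leaf = top,
                          label = S$tip_label[top]),
                     class = "species_leaf"))
  }
  # collect subtree nodes and rebuild arrays with compact ids
  keep <- integer(0)
  stack <- top
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    keep <- c(keep, v)
    if (!S$is_leaf[v]) stack <- c(stack, S$children[v, ])
  }
  keep_leaves <- keep[S$is_leaf[keep]]
  keep_int <- keep[!S$is_leaf[keep]]
  old <- c(sort(keep_leaves), top, setdiff(keep_int, top))
  newid <- integer(S$n_node)
  newid[old] <- seq_along(old)
  parent <- rep(NA_integer_, length(old))
  children <- matrix(NA_integer_, length(old), 2L)
  for (v in old) {
    if (!S$is_leaf[v]) {
      children[newid[v], ] <- newid[S$children[v, ]]
      parent[newid[S$children[v, 1L]]] <- newid[v]
      parent[newid[S$children[v, 2L]]] <- newid[v]
    }
  }
  .species_tree_from_arrays(parent, children, newid[top],
                            S$tip_label[sort(keep_leaves)],
                            S$brlen[old])
}

.as_phylo <- function(x) {
  if (inherits(x, "phylo")) return(x)
  if (!is.character(x) || length(x) != 1L) {
    stop("expected a newick string, file path, or phylo object")
  }
  txt <- if (!grepl("\\(", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else x
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("malformed newick: ", substr(txt, 1, 60))
  phy
}

#' @export
print.species_tree <- function(x, ...) {
  cat("Species tree:", x$n_tip, "species,", x$n_node, "nodes\n")
  cat(" ", write_newick(x), "\n")
  invisible(x)
}
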