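#' Parse an unrooted gene tree
#'
#' Gene trees come from ML or parsimony programs as rooted-binary or
#' top-level-trifurcating newick; both dialects are accepted. A degree-2
#' root is suppressed and the two root-adjacent branch lengths merge
#' additively. Leaf labels are species identifiers and may repeat
#' (paralogs). Branch lengths are optional; an edge without a length is
#' treated as having no length (it can never be weak), not as length 0.
#'
#' @param x A newick string, file path, or `ape::phylo` object.
#' @return An object of class `ugene_tree`: fields `n` (nodes), `n_edge`,
#'   `ends` (edge endpoint matrix), `adj` (node x 3 incident-edge matrix),
#'   `labels` (species label per leaf, `NA` internal), `is_leaf`, `elen`
#'   (edge lengths, `NA` when absent).
#' @examples
#' g <- unrooted_gene_tree("((a:1,b:2):0.05,(c:1,d:1):0.06);")
#' g$elen   # quartet: center edge length 0.11
#' @export
unrooted_gene_tree <- function(x) {
  phy <- .as_phylo(x)
  n_tip <- length(phy$tip.label)
  if (n_tip < 2L) stop("gene tree needs at least 2 leaves")
  m <- n_tip + phy$Nnode
  deg <- tabulate(c(phy$edge[, 1L], phy$edge[, 2L]), nbins = m)
  root <- n_tip + 1L
  edges <- phy$edge
  elen <- if (is.null(phy$edge.length)) rep(NA_real_, nrow(edges)) else phy$edge.length
  keep_node <- rep(TRUE, m)
  if (deg[root] == 2L) {
    # suppress the degree-2 root, merging its two incident lengths
    ri <- which(edges[, 1L] == root)
    a <- edges[ri[1L], 2L]; b <- edges[ri[2L], 2L]
    la <- elen[ri[1L]]; lb <- elen[ri[2L]]
    merged <- if (is.na(la) && is.na(lb)) NA_real_ else sum(la, lb, na.rm = TRUE)
    edges <- edges[-ri, , drop = FALSE]
    elen <- elen[-ri]
    edges <- rbind(edges, c(a, b))
    elen <- c(elen, merged)
    keep_node[root] <- FALSE
  }
  newid <- cumsum(keep_node)
  newid[!keep_node] <- NA_integer_
  ends <- cbind(newid[edges[, 1L]], newid[edges[, 2L]])
  n <- sum(keep_node)
  labels <- rep(NA_character_, n)
  labels[newid[seq_len(n_tip)]] <- phy$tip.label
  .ugene_from_edges(n, ends, elen, labels)
}

.ugene_from_edges <- function(n, ends, elen, labels) {
  deg <- tabulate(c(ends[, 1L], ends[, 2L]), nbins = n)
  if (n > 2L && !all(deg %in% c(1L, 3L))) {
    stop("gene tree must be binary: every node of degree 1 or 3")
  }
  adj <- matrix(NA_integer_, n, 3L)
  slot <- integer(n)
  for (e in seq_len(nrow(ends))) {
    for (v in ends[e, ]) {
      slot[v] <- slot[v] + 1L
      adj[v, slot[v]] <- e
    }
  }
  is_leaf <- deg == 1L
  if (any(is_leaf & is.na(labels))) stop("unlabeled gene-tree leaf")
  G <- list(n = n, n_edge = nrow(ends), ends = ends, adj = adj,
            labels = labels, is_leaf = is_leaf, elen = as.numeric(elen))
  class(G) <- "ugene_tree"
  G
}

#' Parse a rooted binary gene tree
#'
#' @param x A newick string, file path, or `ape::phylo` object; must be
#'   rooted and binary.
#' @return An object of class `rgene_tree` with `parent`, `children`,
#'   `labels`, `root` and a `postorder` traversal vector.
#' @export
rooted_gene_tree <- function(x) {
  phy <- .as_phylo(x)
  if (!ape::is.rooted(phy) || !ape::is.binary(phy)) {
    stop("expected a rooted binary gene tree")
  }
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
  labels <- rep(NA_character_, m)
  labels[seq_len(n_tip)] <- phy$tip.label
  .rgene(parent, children, n_tip + 1L, labels)
}

.rgene <- function(parent, children, root, labels) {
  m <- length(parent)
  ord <- integer(m)
  ord[1L] <- root
  k <- 1L; i <- 1L
  while (i <= k) {
    v <- ord[i]
    if (!is.na(children[v, 1L])) {
      ord[k + 1L] <- children[v, 1L]
      ord[k + 2L] <- children[v, 2L]
      k <- k + 2L
    }
    i <- i + 1L
  }
  G <- list(n_node = m, root = root, parent = parent, children = children,
            labels = labels, is_leaf = is.na(children[, 1L]),
            postorder = rev(ord))
  class(G) <- "rgene_tree"
  G
}

#' Root an unrooted gene tree at an edge
#'
#' Subdivides edge `e` with a new root node, yielding the rooting `G_e`
#' with `n + 1` nodes.
#'
#' @param G A `ugene_tree`.
#' @param e Edge id (row of `G$ends`).
#' @return An `rgene_tree`; node ids `1..G$n` are carried over, the root is
#'   node `G$n + 1`.
#' @export
root_at_edge <- function(G, e) {
  e <- as.integer(e)
  if (e < 1L || e > G$n_edge) stop("edge id out of range")
  m <- G$n + 1L
  parent <- rep(NA_integer_, m)
  children <- matrix(NA_integer_, m, 2L)
  root <- m
  children[root, ] <- G$ends[e, ]
  parent[G$ends[e, ]] <- root
  # orient remaining edges away from the root by BFS
  queue <- G$ends[e, ]
  qi <- 1L
  blocked <- c(e)
  while (qi <= length(queue)) {
    v <- queue[qi]; qi <- qi + 1L
    inc <- G$adj[v, ]
    inc <- inc[!is.na(inc)]
    kids <- integer(0)
    for (f in inc) {
      w <- G$ends[f, 1L] + G$ends[f, 2L] - v
      if (is.na(parent[w]) && w != root && !(f %in% blocked) && parent[v] != w) {
        kids <- c(kids, w)
        parent[w] <- v
        queue <- c(queue, w)
      }
    }
    if (length(kids) == 2L) children[v, ] <- kids
    else if (length(kids) != 0L) stop("internal error: bad degree while rooting")
  }
  .rgene(parent, children, root, c(G$labels, NA_character_))
}

#' Write a tree as newick
#'
#' Unrooted gene trees are emitted with a top-level trifurcation anchored at
#' a canonical internal node (the internal neighbor of the
#' smallest-labeled leaf); rooted trees are emitted as rooted binary
#' newick. Round-trips with the parsers up to label-preserving isomorphism.
#'
#' @param x A `species_tree`, `ugene_tree`, or `rgene_tree`.
#' @param digits Significant digits for branch lengths.
#' @return A newick string (terminated by `;`).
#' @export
write_newick <- function(x, digits = 10) UseMethod("write_newick")

#' @export
write_newick.species_tree <- function(x, digits = 10) {
  rec <- function(v) {
    if (x$is_leaf[v]) return(x$tip_label[v])
    paste0("(", rec(x$children[v, 1L]), ",", rec(x$children[v, 2L]), ")")
  }
  paste0(rec(x$root), ";")
}

#' @export
write_newick.rgene_tree <- function(x, digits = 10) {
  rec <- function(v) {
    if (x$is_leaf[v]) return(x$labels[v])
    paste0("(", rec(x$children[v, 1L]), ",", rec(x$children[v, 2L]), ")")
  }
  paste0(rec(x$root), ";")
}

#' @export
write_newick.ugene_tree <- function(x, digits = 10) {
  fmt <- function(l) {
    if (is.na(l)) "" else paste0(":", format(l, digits = digits, trim = TRUE,
                                             scientific = FALSE))
  }
  rec <- function(v, from_edge) {
    inc <- x$adj[v, ]
    inc <- inc[!is.na(inc)]
    if (!is.na(from_edge)) inc <- inc[inc != from_edge]
    if (x$is_leaf[v]) return(x$labels[v])
    parts <- vapply(inc, function(f) {
      w <- x$ends[f, 1L] + x$ends[f, 2L] - v
      paste0(rec(w, f), fmt(x$elen[f]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  if (!any(!x$is_leaf)) {
    # two-leaf tree: single edge, put its length on the second leaf
    l <- x$elen[1L]
    return(paste0("(", x$labels[1L], ",", x$labels[2L], fmt(l), ");"))
  }
  leaves <- which(x$is_leaf)
  anchor_leaf <- leaves[order(x$labels[leaves])][1L]
  f0 <- x$adj[anchor_leaf, 1L]
  anchor <- x$ends[f0, 1L] + x$ends[f0, 2L] - anchor_leaf
  paste0(rec(anchor, NA_integer_), ";")
}

#' Canonical topology key of an unrooted gene tree
#'
#' A string invariant under relabeling-free isomorphism: two unrooted trees
#' get the same key iff they have the same leaf-labeled topology (branch
#' lengths ignored). Supports duplicate leaf labels.
#'
#' @param G A `ugene_tree`.
#' @return A character scalar.
#' @export
topology_key <- function(G) {
  if (!any(!G$is_leaf)) return(paste0("(", paste(sort(G$labels), collapse = ","), ")"))
  key_from <- function(v, from_edge) {
    if (G$is_leaf[v]) return(G$labels[v])
    inc <- G$adj[v, ]
    inc <- inc[!is.na(inc) & inc != from_edge]
    parts <- sort(vapply(inc, function(f) {
      key_from(G$ends[f, 1L] + G$ends[f, 2L] - v, f)
    }, character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  if (!anyDuplicated(stats::na.omit(G$labels))) {
    leaves <- which(G$is_leaf)
    a <- leaves[order(G$labels[leaves])][1L]
    f <- G$adj[a, 1L]
    o <- G$ends[f, 1L] + G$ends[f, 2L] - a
    return(paste0(G$labels[a], "|", key_from(o, f)))
  }
  # duplicate labels: minimize over all edge-rootings
  keys <- vapply(seq_len(G$n_edge), function(e) {
    u <- G$ends[e, 1L]; v <- G$ends[e, 2L]
    parts <- sort(c(key_from(u, e), key_from(v, e)))
    paste0("(", parts[1L], ",", parts[2L], ")")
  }, character(1))
  min(keys)
}

# Canonical rooted-topology key (children sorted recursively).
.rooted_key <- function(parent, children, root, labels) {
  rec <- function(v) {
    if (is.na(children[v, 1L])) return(labels[v])
    ks <- sort(c(rec(children[v, 1L]), rec(children[v, 2L])))
    paste0("(", ks[1L], ",", ks[2L], ")")
  }
  rec(root)
}

#' Bipartition of an edge as a leaf-label split
#'
#' Reports the split induced by an edge as `"x,y|z,w"` with each side's
#' labels sorted and the lexicographically smaller side first; used to name
#' optimal rooting edges deterministically.
#'
#' @param G A `ugene_tree`.
#' @param e Edge id.
#' @return Character scalar.
#' @export
edge_split <- function(G, e) {
  side <- function(v, from_edge) {
    if (G$is_leaf[v]) return(G$labels[v])
    inc <- G$adj[v, ]
    inc <- inc[!is.na(inc) & inc != from_edge]
    unlist(lapply(inc, function(f) side(G$ends[f, 1L] + G$ends[f, 2L] - v, f)))
  }
  s1 <- paste(sort(side(G$ends[e, 1L], e)), collapse = ",")
  s2 <- paste(sort(side(G$ends[e, 2L], e)), collapse = ",")
  if (s1 <= s2) paste0(s1, "|", s2) else paste0(s2, "|", s1)
}

#' Read a collection of gene trees
#'
#' @param path File with one newick tree per line (blank lines skipped).
#' @return List of `ugene_tree` objects.
#' @export
read_gene_trees <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lapply(lines, unrooted_gene_tree)
}

#' @export
print.ugene_tree <- function(x, ...) {
  cat("Unrooted gene tree:", sum(x$is_leaf), "leaves,", x$n_edge, "edges\n")
  cat(" ", write_newick(x), "\n")
  invisible(x)
}

#' @export
print.rgene_tree <- function(x, ...) {
  cat("Rooted gene tree:", sum(x$is_leaf), "leaves\n")
  cat(" ", write_newick(x), "\n")
  invisible(x)
}
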