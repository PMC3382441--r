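# k-NNI error correction: optimal weighted mutation cost over all trees
# reachable from a gene tree by at most k NNI operations, optionally
# restricted to weak (short) edges. The search is a depth-first enumeration
# of NNI sequences on a single mutable state with undo (no tree copying);
# every step updates the cost in constant time via the lemma machinery.

#' Weak edges of a gene tree
#'
#' An edge is weak when its branch length is strictly smaller than the
#' threshold `omega`; edges without a length are never weak. Weak edges are
#' where topological error is suspected and NNI correction is allowed in
#' the omega-restricted variants.
#'
#' @param G A `ugene_tree` with (possibly partial) branch lengths.
#' @param omega Non-negative threshold; `Inf` marks every measured edge.
#' @return Integer vector of weak edge ids.
#' @export
weak_edges <- function(G, omega) {
  stopifnot(omega >= 0)
  which(!is.na(G$elen) & G$elen < omega)
}

#' Error-correct and root a gene tree
#'
#' Computes the minimum of the unrooted reconciliation cost over every tree
#' reachable from `G` by at most `k` NNI operations whose center edge is
#' eligible: all internal edges by default, or only the weak internal edges
#' of the input tree when `omega` is given (edge identity persists through
#' rewiring, so an eligible edge stays eligible across steps). `k = 0`
#' reduces to [unrooted_reconcile()]. Ties prefer the shorter NNI sequence,
#' then the lexicographically smallest canonical topology.
#'
#' @param G A `ugene_tree`.
#' @param S A `species_tree`.
#' @param k Non-negative integer: maximum number of NNIs.
#' @param omega Optional non-negative weak-edge threshold. When given but
#'   no internal edge carries a length, a warning is emitted and the tree
#'   is treated as having no weak edges.
#' @param alpha,beta Positive duplication and loss weights.
#' @param dedup Memoize visited topologies by canonical form (useful for
#'   `k >= 3`; duplicates are otherwise revisited, which only costs time).
#' @return An object of class `correction`: list with `cost` (best over
#'   the neighborhood), `cost_uncorrected` (`k = 0` cost of the input),
#'   `errors_found` (`TRUE` iff a strictly better NNI variant exists),
#'   `moves` (list of `(edge, variant)` pairs of the best sequence),
#'   `corrected` (the best `ugene_tree`), `recon` (the
#'   [unrooted_reconcile()] result for the corrected tree: optimal cost,
#'   `Min` set, canonical rooting), and `eligible_edges`.
#' @examples
#' S <- species_tree("((a,b),(c,d));")
#' g <- unrooted_gene_tree("((b,c),(a,d));") # quartet bc|ad, cost 5
#' correct_gene_tree(g, S, k = 1)$cost      # 0: corrected to ab|cd
#' @export
correct_gene_tree <- function(G, S, k = 0, omega = NULL, alpha = 1, beta = 1,
                              dedup = FALSE) {
  stopifnot(k >= 0)
  internal <- which(!G$is_leaf[G$ends[, 1L]] & !G$is_leaf[G$ends[, 2L]])
  if (is.null(omega) || is.infinite(omega)) {
    eligible <- internal
  } else {
    if (length(internal) > 0L && all(is.na(G$elen[internal]))) {
      warning("omega given but no internal edge has a length; ",
              "treating the tree as having no weak edges")
      eligible <- integer(0)
    } else {
      eligible <- intersect(weak_edges(G, omega), internal)
    }
  }
  st <- recon_state(G, S, alpha, beta)
  cost0 <- st$sigma
  best <- new.env(parent = emptyenv())
  best$cost <- cost0
  best$moves <- list()
  best$len <- 0L
  best$key <- NULL
  memo <- if (dedup) new.env(parent = emptyenv()) else NULL
  tol <- 1e-9
  moves <- vector("list", k)
  consider <- function(depth) {
    if (st$sigma < best$cost - tol) {
      best$cost <- st$sigma
      best$moves <- moves[seq_len(depth)]
      best$len <- depth
      best$key <- NULL
      return()
    }
    if (st$sigma <= best$cost + tol && depth <= best$len && best$len > 0L) {
      key <- topology_key(state_tree(st))
      if (is.null(best$key)) {
        bt <- .replay_moves(G, best$moves)
        best$key <- topology_key(bt)
      }
      if (depth < best$len || key < best$key) {
        best$cost <- min(best$cost, st$sigma)
        best$moves <- moves[seq_len(depth)]
        best$len <- depth
        best$key <- key
      }
    }
  }
  dfs <- function(depth) {
    if (depth >= k) return()
    frames <- enumerate_nni(st, edges = eligible)
    for (fi in seq_along(frames)) {
      fr <- frames[[fi]]
      tok <- apply_nni(st, fr)
      if (!is.null(memo)) {
        kk <- topology_key(state_tree(st))
        if (!is.null(memo[[kk]])) {
          undo_nni(st, tok)
          next
        }
        memo[[kk]] <- TRUE
      }
      moves[[depth + 1L]] <<- c(edge = fr$e0,
                                variant = if (fi %% 2L == 1L) 1L else 2L)
      consider(depth + 1L)
      dfs(depth + 1L)
      undo_nni(st, tok)
    }
  }
  if (k > 0L && length(eligible) > 0L) dfs(0L)
  corrected <- .replay_moves(G, best$moves)
  recon <- unrooted_reconcile(corrected, S, alpha, beta)
  out <- list(cost = recon$cost,
              cost_uncorrected = cost0,
              errors_found = recon$cost < cost0 - tol,
              moves = best$moves,
              corrected = corrected,
              recon = recon,
              eligible_edges = eligible,
              n_fallback = st$n_fallback,
              case_log = st$case_log,
              k = k, omega = omega, alpha = alpha, beta = beta)
  class(out) <- "correction"
  out
}

# Rebuild the corrected tree by replaying a move list on the input tree.
.replay_moves <- function(G, moves) {
  for (mv in moves) G <- apply_nni_topology(G, mv[["edge"]], mv[["variant"]])
  G
}

#' @export
print.correction <- function(x, ...) {
  cat(sprintf("k-NNI correction (k = %d): cost %g -> %g\n", x$k,
              x$cost_uncorrected, x$cost))
  if (x$errors_found) {
    cat("  errors found; corrected with", length(x$moves), "NNI(s)\n")
  } else {
    cat("  no correction required\n")
  }
  cat("  optimal rooting:", x$recon$canonical_split, "\n")
  invisible(x)
}

#' Total corrected cost of a gene-tree set
#'
#' Sums the k-NNI-corrected reconciliation cost of every gene tree against
#' a fixed species tree and keeps the per-tree correction results,
#' including each tree's optimal rooting and corrected topology.
#'
#' @param gene_trees List of `ugene_tree` objects (or newick strings).
#' @inheritParams correct_gene_tree
#' @return List with numeric `total` and `per_tree` (list of `correction`
#'   objects).
#' @export
knnic_total <- function(gene_trees, S, k = 0, omega = NULL,
                        alpha = 1, beta = 1) {
  gene_trees <- .as_gene_tree_list(gene_trees)
  per <- vector("list", length(gene_trees))
  for (i in seq_along(gene_trees)) {
    per[[i]] <- tryCatch(
      correct_gene_tree(gene_trees[[i]], S, k = k, omega = omega,
                        alpha = alpha, beta = beta),
      error = function(e) stop("gene tree ", i, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  list(total = sum(vapply(per, function(p) p$cost, numeric(1))),
       per_tree = per)
}

#' Filter gene trees by their weak-edge count
#'
#' A tree is rejected iff its number of weak edges (length strictly below
#' `omega`) exceeds `mu`; heavily uncertain trees are thereby excluded from
#' supertree inference and flagged for manual curation.
#'
#' @param gene_trees List of `ugene_tree` objects (or newick strings).
#' @param omega Non-negative weak-edge threshold.
#' @param mu Positive integer: maximum allowed weak edges per tree.
#' @return List with `accepted` and `rejected` tree lists and the
#'   corresponding index vectors `accepted_idx`, `rejected_idx`.
#' @export
filter_by_mu <- function(gene_trees, omega, mu) {
  stopifnot(mu >= 1)
  gene_trees <- .as_gene_tree_list(gene_trees)
  nw <- vapply(gene_trees, function(g) length(weak_edges(g, omega)),
               integer(1))
  acc <- which(nw <= mu)
  rej <- which(nw > mu)
  list(accepted = gene_trees[acc], rejected = gene_trees[rej],
       accepted_idx = acc, rejected_idx = rej, weak_counts = nw)
}

.as_gene_tree_list <- function(x) {
  if (inherits(x, "ugene_tree")) return(list(x))
  lapply(x, function(g) {
    if (inherits(g, "ugene_tree")) g else unrooted_gene_tree(g)
  })
}
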