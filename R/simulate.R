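# Fixture generator: random species trees, birth-death gene families
# evolving along them (duplication and loss at constant per-lineage rates),
# branch lengths with a distinct short-edge regime, and NNI error injection
# restricted to short edges - the statistical situation the weak-edge
# correction machinery assumes.

#' Uniform random rooted species tree
#'
#' Sequential leaf addition with a uniform attachment position at each
#' step, which draws uniformly from all rooted binary labeled topologies.
#' Every branch gets length 1, the time unit of the simulator's event
#' rates.
#'
#' @param n_taxa Number of species (at least 2).
#' @param seed Optional integer seed.
#' @param labels Optional character vector of species labels (default
#'   `t01, t02, ...`).
#' @return A `species_tree` with unit branch lengths.
#' @export
random_species_tree <- function(n_taxa, seed = NULL, labels = NULL) {
  stopifnot(n_taxa >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels)) labels <- sprintf("t%02d", seq_len(n_taxa))
  stopifnot(length(labels) == n_taxa)
  S <- species_tree(.random_rooted_newick(labels))
  S$brlen[] <- 1
  S$brlen[S$root] <- NA_real_
  S
}

#' Simulate a gene family along a species tree
#'
#' A constant-rate birth-death walk down the species tree: each gene
#' lineage on a branch duplicates (rate `dup_rate`) or dies (rate
#' `loss_rate`) per unit branch length; at speciations every surviving
#' lineage enters both child branches; lineages reaching the leaves become
#' gene-tree leaves labeled by their species. Unary nodes left by losses
#' are suppressed. Branch lengths of the resulting gene tree are drawn from
#' a log-normal body, except that a chosen fraction of *internal* edges is
#' drawn from a separate short regime - the weak edges where topological
#' error will be injected and where omega-thresholding has a crisp signal.
#'
#' @param S A `species_tree` with branch lengths (see
#'   [random_species_tree()]).
#' @param dup_rate,loss_rate Non-negative per-lineage event rates.
#' @param short_fraction Expected fraction of internal edges in the short
#'   regime.
#' @param min_short Minimum number of short internal edges (when the tree
#'   has any internal edge); set to 1 when errors will be injected.
#' @param short_range Length range of short edges.
#' @param meanlog,sdlog Log-normal parameters of the body regime.
#' @param min_leaves Resample until the surviving family has at least this
#'   many leaves.
#' @param max_retries Resampling bound; exceeded means the loss rate kills
#'   essentially every family.
#' @return List: `tree` (`ugene_tree` with lengths), `rooted_newick` (the
#'   true rooted topology before unrooting), `short_edges` (ids of
#'   short-regime edges in `tree`).
#' @export
evolve_gene_tree <- function(S, dup_rate = 0.15, loss_rate = 0.15,
                             short_fraction = 0.3, min_short = 0L,
                             short_range = c(0.01, 0.05),
                             meanlog = -0.7, sdlog = 0.6,
                             min_leaves = 4L, max_retries = 100L) {
  stopifnot(dup_rate >= 0, loss_rate >= 0)
  rate <- dup_rate + loss_rate
  sim_branch <- function(v, t_left) {
    if (rate > 0) {
      dt <- stats::rexp(1L, rate)
      if (dt < t_left) {
        if (stats::runif(1L) < loss_rate / rate) return(NULL) # loss
        a <- sim_branch(v, t_left - dt)                       # duplication
        b <- sim_branch(v, t_left - dt)
        if (is.null(a)) return(b)
        if (is.null(b)) return(a)
        return(list(a, b))
      }
    }
    if (S$is_leaf[v]) return(S$tip_label[v])
    at_speciation(v)
  }
  at_speciation <- function(v) {
    c1 <- S$children[v, 1L]; c2 <- S$children[v, 2L]
    a <- sim_branch(c1, if (is.na(S$brlen[c1])) 1 else S$brlen[c1])
    b <- sim_branch(c2, if (is.na(S$brlen[c2])) 1 else S$brlen[c2])
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    list(a, b)
  }
  for (try in seq_len(max_retries)) {
    res <- at_speciation(S$root)
    n_leaves <- length(unlist(res))
    if (!is.null(res) && n_leaves >= min_leaves) break
    res <- NULL
  }
  if (is.null(res)) {
    stop("no surviving gene family in ", max_retries,
         " attempts; loss rate too high for min_leaves = ", min_leaves)
  }
  to_nwk <- function(t) {
    if (is.character(t)) t
    else paste0("(", to_nwk(t[[1L]]), ",", to_nwk(t[[2L]]), ")")
  }
  rooted_newick <- paste0(to_nwk(res), ";")
  G <- unrooted_gene_tree(rooted_newick)
  internal <- which(!G$is_leaf[G$ends[, 1L]] & !G$is_leaf[G$ends[, 2L]])
  n_short <- 0L
  short <- integer(0)
  if (length(internal) > 0L) {
    short_mask <- stats::runif(length(internal)) < short_fraction
    n_short <- max(sum(short_mask), min(min_short, length(internal)))
    if (n_short > 0L) {
      short <- if (sum(short_mask) >= n_short) internal[short_mask]
               else internal[sample.int(length(internal), n_short)]
    }
  }
  len <- stats::rlnorm(G$n_edge, meanlog, sdlog)
  if (length(short)) {
    len[short] <- stats::runif(length(short), short_range[1L], short_range[2L])
  }
  G$elen <- len
  list(tree = G, rooted_newick = rooted_newick, short_edges = short)
}

#' Inject NNI errors on short edges
#'
#' Applies `n_errors` random NNI operations whose center edges are internal
#' edges with length strictly below `threshold`, emulating topological
#' error concentrated on weak edges. The applied moves are returned so that
#' recovery can be verified.
#'
#' @param G A `ugene_tree` with branch lengths.
#' @param n_errors Number of NNIs to inject.
#' @param threshold Only internal edges shorter than this are corrupted.
#' @return List: `corrupted` (`ugene_tree`), `moves` (list of
#'   `(edge, variant)` pairs).
#' @export
inject_errors <- function(G, n_errors = 1L, threshold = 0.1) {
  moves <- list()
  if (n_errors > 0L) {
    internal <- which(!G$is_leaf[G$ends[, 1L]] & !G$is_leaf[G$ends[, 2L]])
    eligible <- intersect(which(!is.na(G$elen) & G$elen < threshold), internal)
    if (length(eligible) == 0L) {
      stop("no internal edge below the threshold; cannot inject errors")
    }
    for (i in seq_len(n_errors)) {
      e <- eligible[sample.int(length(eligible), 1L)]
      variant <- sample.int(2L, 1L)
      G <- apply_nni_topology(G, e, variant)
      moves[[i]] <- c(edge = e, variant = variant)
    }
  }
  list(corrupted = G, moves = moves)
}

#' Simulate a full correction benchmark data set
#'
#' Convenience wrapper: draws a species tree, evolves `n_trees` gene
#' families with short internal edges, and injects `n_errors` NNI errors
#' per tree on short edges.
#'
#' @inheritParams evolve_gene_tree
#' @param n_taxa Number of species.
#' @param n_trees Number of gene families.
#' @param n_errors NNIs injected per tree (on short edges only).
#' @param error_threshold Length bound defining the short/corruptible edges.
#' @param seed Optional integer seed.
#' @param ... Passed to [evolve_gene_tree()].
#' @return List: `species` (the true `species_tree`), `true_trees`,
#'   `corrupted_trees` (lists of `ugene_tree`), `moves` (per-tree injected
#'   NNIs).
#' @export
simulate_dataset <- function(n_taxa = 8L, n_trees = 30L, n_errors = 0L,
                             error_threshold = 0.1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  S <- random_species_tree(n_taxa)
  true_trees <- vector("list", n_trees)
  corrupted <- vector("list", n_trees)
  moves <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    sim <- evolve_gene_tree(S, min_short = if (n_errors > 0L) 1L else 0L, ...)
    true_trees[[i]] <- sim$tree
    if (n_errors > 0L) {
      inj <- inject_errors(sim$tree, n_errors, error_threshold)
      corrupted[[i]] <- inj$corrupted
      moves[[i]] <- inj$moves
    } else {
      corrupted[[i]] <- sim$tree
      moves[[i]] <- list()
    }
  }
  list(species = S, true_trees = true_trees, corrupted_trees = corrupted,
       moves = moves)
}
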