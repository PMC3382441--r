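# Hill-climbing heuristic for the error-corrected gene-duplication
# supertree problem: find a rooted species tree minimizing the total
# k-NNI-corrected reconciliation cost of a set of unrooted gene trees.
# The local move set is rooted NNI plus rerooting (the objective depends on
# the species-tree root, so rerooting moves are required to explore it).

#' Total corrected cost of a candidate species tree
#'
#' The supertree objective: sum over gene trees of the k-NNI-corrected
#' optimal reconciliation cost against the candidate.
#'
#' @param candidate A `species_tree` or newick string.
#' @param gene_trees List of `ugene_tree` objects (or newick strings).
#' @inheritParams correct_gene_tree
#' @return Numeric total cost.
#' @export
total_cost_of_tree <- function(candidate, gene_trees, k = 0, omega = NULL,
                               alpha = 1, beta = 1) {
  S <- if (inherits(candidate, "species_tree")) candidate else species_tree(candidate)
  gene_trees <- .as_gene_tree_list(gene_trees)
  tot <- 0
  for (g in gene_trees) {
    tot <- tot + .corrected_cost_value(g, S, k, omega, alpha, beta)
  }
  tot
}

# Cost-only correction: the DFS of correct_gene_tree without snapshots,
# tie-breaking or result assembly. Used in the hill-climb inner loop.
.corrected_cost_value <- function(G, S, k, omega, alpha, beta) {
  if (k == 0L) return(.unrooted_core(G, S, alpha, beta)$cost)
  st <- recon_state(G, S, alpha, beta)
  internal <- which(!G$is_leaf[G$ends[, 1L]] & !G$is_leaf[G$ends[, 2L]])
  eligible <- if (is.null(omega) || is.infinite(omega)) internal
              else intersect(weak_edges(G, omega), internal)
  if (length(eligible) == 0L) return(st$sigma)
  best <- st$sigma
  dfs <- function(depth) {
    if (depth >= k) return()
    frames <- enumerate_nni(st, edges = eligible)
    for (fr in frames) {
      tok <- apply_nni(st, fr)
      if (st$sigma < best) best <<- st$sigma
      dfs(depth + 1L)
      undo_nni(st, tok)
    }
  }
  dfs(0L)
  best
}

# Uniform random rooted binary topology by sequential leaf addition: a tree
# on i leaves has 2i - 1 attachment positions (every edge plus a new root
# above the old one), and each (tree, position) pair yields a distinct tree
# on i + 1 leaves, so uniform choices give the uniform distribution over
# rooted labeled topologies.
.random_rooted_newick <- function(labels) {
  n <- length(labels)
  if (n == 1L) return(paste0(labels, ";"))
  ord <- sample.int(n)
  # nested-list tree; attach by walking a random edge index
  tree <- list(labels[ord[1L]])
  tree <- labels[ord[1L]]
  count_edges <- function(t) if (is.character(t)) 1L else 1L + count_edges(t[[1L]]) + count_edges(t[[2L]])
  attach_at <- function(t, pos, leaf) {
    # pos in 1..count_edges(t): 1 = edge above t's root
    if (pos == 1L) return(list(t, leaf))
    left <- t[[1L]]
    nl <- count_edges(left)
    if (pos - 1L <= nl) list(attach_at(left, pos - 1L, leaf), t[[2L]])
    else list(left, attach_at(t[[2L]], pos - 1L - nl, leaf))
  }
  for (i in 2:n) {
    ne <- count_edges(tree)
    pos <- sample.int(ne, 1L)
    tree <- attach_at(tree, pos, labels[ord[i]])
  }
  to_nwk <- function(t) {
    if (is.character(t)) t
    else paste0("(", to_nwk(t[[1L]]), ",", to_nwk(t[[2L]]), ")")
  }
  paste0(to_nwk(tree), ";")
}

# All rooted-NNI rearrangements of a species tree, as newick strings.
.rooted_nni_neighbors <- function(S) {
  out <- character(0)
  for (u in which(!S$is_leaf)) {
    p <- S$parent[u]
    if (is.na(p)) next
    sib <- S$children[p, ]
    sib <- sib[sib != u]
    for (ci in 1:2) {
      ch <- S$children
      moved <- ch[u, ci]
      ch[u, ci] <- sib
      ch[p, ][S$children[p, ] == sib] <- moved
      parent <- S$parent
      parent[sib] <- u
      parent[moved] <- p
      out <- c(out, .write_rooted_arrays(parent, ch, S$root, S$tip_label,
                                         S$is_leaf))
    }
  }
  out
}

.write_rooted_arrays <- function(parent, children, root, tip_label, is_leaf) {
  rec <- function(v) {
    if (is_leaf[v]) return(tip_label[v])
    paste0("(", rec(children[v, 1L]), ",", rec(children[v, 2L]), ")")
  }
  paste0(rec(root), ";")
}

# All rerootings of a species tree (same unrooted topology, different
# root edge), as newick strings; excludes the input rooting.
.reroot_neighbors <- function(S) {
  ug <- unrooted_gene_tree(write_newick(S))
  self_key <- .species_key(write_newick(S))
  out <- character(0)
  for (e in seq_len(ug$n_edge)) {
    nwk <- write_newick(root_at_edge(ug, e))
    if (.species_key(nwk) != self_key) out <- c(out, nwk)
  }
  out
}

# Canonical key of a rooted species topology: sort children recursively,
# working directly on the (lengthless) newick string.
.species_key <- function(nwk) {
  s <- sub(";\\s*$", "", nwk)
  pos <- 1L
  n <- nchar(s)
  parse1 <- function() {
    if (substr(s, pos, pos) == "(") {
      pos <<- pos + 1L
      a <- parse1()
      stopifnot(substr(s, pos, pos) == ",")
      pos <<- pos + 1L
      b <- parse1()
      stopifnot(substr(s, pos, pos) == ")")
      pos <<- pos + 1L
      ks <- sort(c(a, b))
      paste0("(", ks[1L], ",", ks[2L], ")")
    } else {
      start <- pos
      while (pos <= n && !(substr(s, pos, pos) %in% c(",", ")", "("))) {
        pos <<- pos + 1L
      }
      substr(s, start, pos - 1L)
    }
  }
  parse1()
}

#' Hill-climbing search for the error-corrected supertree
#'
#' Repeated steepest-descent local search for a rooted species tree
#' minimizing [total_cost_of_tree()]. Each run starts from an independent
#' uniform random rooted topology and moves to the best strictly-improving
#' neighbor (rooted NNIs plus rerootings) until a local optimum. All
#' distinct final trees are ranked by cost; co-optimal trees are all
#' reported. With `mu` set, gene trees with more than `mu` weak edges are
#' rejected before the search.
#'
#' @param gene_trees List of `ugene_tree` objects (or newick strings).
#' @param species Character vector of species labels; defaults to the union
#'   of the gene-tree labels.
#' @param k,omega,alpha,beta Correction parameters, as in
#'   [correct_gene_tree()].
#' @param mu Optional positive integer: reject gene trees with more than
#'   `mu` weak edges (requires `omega`).
#' @param runs Number of random restarts.
#' @param seed Optional integer seed for reproducible searches.
#' @return List with `best_trees` (newicks of all co-optimal final trees),
#'   `best_cost`, `ranking` (data frame: tree, cost, runs reaching it),
#'   `runs` (per-run trajectories: start, steps, final cost),
#'   `n_accepted`/`n_rejected` gene-tree counts.
#' @examples
#' trees <- list(unrooted_gene_tree("((a,b),(c,d));"))
#' fit <- hill_climb(trees, runs = 3, seed = 1)
#' fit$best_cost   # 0
#' @export
hill_climb <- function(gene_trees, species = NULL, k = 0, omega = NULL,
                       alpha = 1, beta = 1, mu = NULL, runs = 20,
                       seed = NULL) {
  stopifnot(runs >= 1)
  if (!is.null(seed)) set.seed(seed)
  gene_trees <- .as_gene_tree_list(gene_trees)
  n_rejected <- 0L
  if (!is.null(mu)) {
    if (is.null(omega)) stop("mu filtering requires omega")
    flt <- filter_by_mu(gene_trees, omega, mu)
    n_rejected <- length(flt$rejected_idx)
    gene_trees <- flt$accepted
  }
  if (is.null(species)) {
    species <- sort(unique(unlist(lapply(gene_trees, function(g)
      g$labels[g$is_leaf]))))
  }
  if (length(species) < 2L) stop("need at least 2 species")
  cache <- new.env(parent = emptyenv())
  eval_tree <- function(nwk) {
    key <- .species_key(nwk)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- total_cost_of_tree(species_tree(nwk), gene_trees, k = k,
                              omega = omega, alpha = alpha, beta = beta)
    cache[[key]] <- val
    val
  }
  run_rec <- vector("list", runs)
  for (r in seq_len(runs)) {
    cur <- .random_rooted_newick(species)
    cur_cost <- eval_tree(cur)
    steps <- 0L
    start <- cur
    repeat {
      S <- species_tree(cur)
      nbr <- c(.rooted_nni_neighbors(S), .reroot_neighbors(S))
      costs <- vapply(nbr, eval_tree, numeric(1), USE.NAMES = FALSE)
      imp <- which(costs < cur_cost - 1e-9)
      if (length(imp) == 0L) break
      pick <- imp[which.min(costs[imp])]
      cur <- nbr[pick]
      cur_cost <- costs[pick]
      steps <- steps + 1L
    }
    run_rec[[r]] <- list(start = start, final = cur, final_key = .species_key(cur),
                         cost = cur_cost, steps = steps)
  }
  finals <- vapply(run_rec, `[[`, character(1), "final_key")
  costs <- vapply(run_rec, `[[`, numeric(1), "cost")
  nwks <- vapply(run_rec, `[[`, character(1), "final")
  uk <- !duplicated(finals)
  ranking <- data.frame(tree = nwks[uk],
                        cost = costs[uk],
                        runs = as.integer(table(finals)[finals[uk]]),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(ranking$cost), , drop = FALSE]
  rownames(ranking) <- NULL
  best_cost <- min(costs)
  best_trees <- ranking$tree[ranking$cost <= best_cost + 1e-9]
  list(best_trees = best_trees, best_cost = best_cost, ranking = ranking,
       runs = run_rec, n_accepted = length(gene_trees),
       n_rejected = n_rejected)
}
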