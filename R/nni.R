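# NNI engine: mutable reconciliation state with constant-time maintenance
# of the directed labeling (only the center edge's two labels change), the
# optimal-edge set Min_G (nine-case analysis EQ1-EQ4 / NE1-NE5) and the
# optimal cost (closed-form differences Delta3/Delta4 evaluated at a
# surviving optimal edge).
#
# A frame fixes the orientation of an NNI: center edge e0 = {x, y}, side
# edges in slots 1..4 with slots 1,2 at x and 3,4 at y, subtree roots w_i
# and subtree labels a_i = label<w_i, center>. Applying a frame always
# swaps the subtrees in slots 1 and 3; the two distinct NNI neighbors of an
# edge are obtained from the two frames that differ in which of x's edges
# sits in slot 1.

#' Build a mutable reconciliation state
#'
#' Wraps a gene tree, the restricted species tree, the directed labeling
#' and the optimal-edge set into an environment that [apply_nni()] updates
#' in place in constant time.
#'
#' @inheritParams unrooted_reconcile
#' @return An environment of class `recon_state` with fields `adj`, `ends`,
#'   `elen`, `labels`, `lab`, `top`, `S`, `alpha`, `beta`, `sigma` (optimal
#'   cost), `min_edges`, `n_fallback` (count of case-analysis failures that
#'   forced a full recompute) and `case_log` (case-tag frequency table).
#' @export
recon_state <- function(G, S, alpha = 1, beta = 1) {
  st <- new.env(parent = emptyenv())
  st$n <- G$n
  st$n_edge <- G$n_edge
  st$adj <- G$adj
  st$ends <- G$ends
  st$elen <- G$elen
  st$labels <- G$labels
  st$is_leaf <- G$is_leaf
  st$alpha <- alpha
  st$beta <- beta
  res <- .unrooted_core(G, S, alpha, beta)
  st$degenerate_species <- inherits(res$S, "species_leaf")
  st$S <- res$S
  st$sigma <- res$cost
  st$min_edges <- sort(res$min_edges)
  st$lab <- res$labels
  st$top <- res$top
  st$n_fallback <- 0L
  st$case_log <- integer(0)
  st$last_case <- NA_character_
  class(st) <- "recon_state"
  st
}

#' @export
print.recon_state <- function(x, ...) {
  cat("Reconciliation state:", sum(x$is_leaf), "leaves | optimal cost",
      x$sigma, "|", length(x$min_edges), "optimal edge(s)\n")
  invisible(x)
}

# Current tree snapshot of a state as an immutable ugene_tree.
state_tree <- function(st) {
  .ugene_from_edges(st$n, st$ends, st$elen, st$labels)
}

#' Enumerate NNI frames
#'
#' Yields both NNI variants for every internal edge (an edge whose two
#' endpoints are internal), optionally restricted to a subset of edges.
#'
#' @param x A `ugene_tree` or `recon_state`.
#' @param edges Optional integer vector of candidate center edges; the
#'   default considers every internal edge.
#' @return List of frames; each frame is a list with `e0`, `x`, `y`,
#'   `slots` (four side-edge ids, slots 1,2 at `x`), `w` (subtree roots).
#' @export
enumerate_nni <- function(x, edges = NULL) {
  adj <- x$adj; ends <- x$ends; is_leaf <- x$is_leaf
  ne <- if (inherits(x, "recon_state")) x$n_edge else x$n_edge
  cand <- if (is.null(edges)) seq_len(ne) else as.integer(edges)
  internal <- cand[!is_leaf[ends[cand, 1L]] & !is_leaf[ends[cand, 2L]]]
  frames <- vector("list", 2L * length(internal))
  k <- 0L
  for (e0 in internal) {
    xx <- ends[e0, 1L]; yy <- ends[e0, 2L]
    ex <- adj[xx, ]; ex <- ex[ex != e0]
    ey <- adj[yy, ]; ey <- ey[ey != e0]
    for (variant in 1:2) {
      s <- if (variant == 1L) c(ex[1L], ex[2L], ey[1L], ey[2L])
           else c(ex[2L], ex[1L], ey[1L], ey[2L])
      w <- c(ends[s[1L], 1L] + ends[s[1L], 2L] - xx,
             ends[s[2L], 1L] + ends[s[2L], 2L] - xx,
             ends[s[3L], 1L] + ends[s[3L], 2L] - yy,
             ends[s[4L], 1L] + ends[s[4L], 2L] - yy)
      k <- k + 1L
      frames[[k]] <- list(e0 = e0, x = xx, y = yy, slots = s, w = w)
    }
  }
  frames[seq_len(k)]
}

#' Cost-difference primitive for a three-subtree rearrangement
#'
#' `phi(a, b, c) = alpha (D(a,b) + D(a+b,c)) + beta (L(a,b) + L(a+b,c))` is
#' the partial mutation-cost contribution of a rooted subtree `((x,y),z)`
#' whose parts map to `a, b, c`. `delta3(a,b,c) = phi(c,b,a) - phi(a,b,c)`
#' is the cost change when the NNI turns `((x,y),z)` into `(x,(y,z))`.
#'
#' @param S A `species_tree`.
#' @param a,b,c Species-tree node ids or cluster names.
#' @param alpha,beta Positive event weights.
#' @return Numeric cost difference.
#' @export
delta3 <- function(S, a, b, c, alpha = 1, beta = 1) {
  a <- .resolve_node(S, a); b <- .resolve_node(S, b); c <- .resolve_node(S, c)
  .phi(S, c, b, a, alpha, beta) - .phi(S, a, b, c, alpha, beta)
}

.phi <- function(S, a, b, c, alpha, beta) {
  .dl1(S, a, b, alpha, beta) + .dl1(S, .lca1(S, a, b), c, alpha, beta)
}

.phi4 <- function(S, a, b, c, d, alpha, beta) {
  .phi(S, a, b, .lca1(S, c, d), alpha, beta) + .dl1(S, c, d, alpha, beta)
}

#' Cost-difference primitive for a four-subtree rearrangement
#'
#' With `phi'(a,b,c,d) = phi(a, b, c+d) + alpha D(c,d) + beta L(c,d)`,
#' `delta4(a,b,c,d) = phi'(a,d,b,c) - phi'(a,b,c,d)` is the cost change of
#' an NNI `((x,y),(z,v)) -> ((x,v),(y,z))` evaluated at the center rooting,
#' with the four subtrees mapping to `a, b, c, d`.
#'
#' @inheritParams delta3
#' @param d Species-tree node id or cluster name.
#' @return Numeric cost difference.
#' @export
delta4 <- function(S, a, b, c, d, alpha = 1, beta = 1) {
  a <- .resolve_node(S, a); b <- .resolve_node(S, b)
  c <- .resolve_node(S, c); d <- .resolve_node(S, d)
  .phi4(S, a, d, b, c, alpha, beta) - .phi4(S, a, b, c, d, alpha, beta)
}

# Lemma-7 Delta3 argument order per surviving-subtree index i.
.delta3_by_index <- function(S, a, i, alpha, beta) {
  if (i == 1L) delta3(S, a[4L], a[3L], a[2L], alpha, beta)
  else if (i == 2L) delta3(S, a[3L], a[4L], a[1L], alpha, beta)
  else if (i == 3L) delta3(S, a[2L], a[1L], a[4L], alpha, beta)
  else delta3(S, a[1L], a[2L], a[3L], alpha, beta)
}

# Follow the direction of non-top outgoing labels from the center to find
# the subtree slot holding Min_G (EQ1: both center stars are S1).
.follow_min_direction <- function(st, fr) {
  out_of <- function(e, v) st$lab[e, if (st$ends[e, 1L] == v) 1L else 2L]
  ox <- c(out_of(fr$slots[1L], fr$x), out_of(fr$slots[2L], fr$x),
          out_of(fr$e0, fr$x))
  nt <- which(ox != st$top)
  if (length(nt) != 1L) return(NA_integer_)
  if (nt == 1L) return(1L)
  if (nt == 2L) return(2L)
  oy <- c(out_of(fr$slots[3L], fr$y), out_of(fr$slots[4L], fr$y))
  nty <- which(oy != st$top)
  if (length(nty) != 1L) return(NA_integer_)
  nty + 2L
}

#' Apply an NNI to a reconciliation state
#'
#' Rewires the tree according to the frame (swapping the subtrees in slots
#' 1 and 3), recomputes the two directed labels of the center edge (the
#' only labels an NNI changes), and updates the optimal-edge set and the
#' optimal cost in constant time by the case analysis on how `Min_G` meets
#' the five frame edges. If an internal consistency check fails the state
#' is recomputed from scratch and `n_fallback` is incremented.
#'
#' @param st A `recon_state`.
#' @param frame A frame from [enumerate_nni()], valid for the current tree.
#' @return Invisibly, an undo token for [undo_nni()]. The state is modified
#'   in place; its `last_case` field records the case tag.
#' @export
apply_nni <- function(st, frame) {
  e0 <- frame$e0
  s <- frame$slots
  xx <- frame$x; yy <- frame$y
  # stale-frame validation
  if (!((st$ends[e0, 1L] == xx && st$ends[e0, 2L] == yy) ||
        (st$ends[e0, 1L] == yy && st$ends[e0, 2L] == xx)) ||
      !all(s[1:2] %in% st$adj[xx, ]) || !all(s[3:4] %in% st$adj[yy, ])) {
    stop("stale NNI frame: tree changed since enumeration")
  }
  side_of <- function(e, v) if (st$ends[e, 1L] == v) 1L else 2L
  if (isTRUE(st$degenerate_species)) {
    # single-species family: every rooting of every NNI variant costs the
    # same (all internal nodes are duplications); only rewire
    token <- list(e0 = e0, s1 = s[1L], s3 = s[3L], x = xx, y = yy,
                  adj_x = st$adj[xx, ], adj_y = st$adj[yy, ],
                  ends_s1 = st$ends[s[1L], ], ends_s3 = st$ends[s[3L], ],
                  lab_e0 = NULL,
                  min_edges = st$min_edges, sigma = st$sigma,
                  last_case = st$last_case)
    st$adj[xx, ][st$adj[xx, ] == s[1L]] <- s[3L]
    st$adj[yy, ][st$adj[yy, ] == s[3L]] <- s[1L]
    st$ends[s[1L], ][st$ends[s[1L], ] == xx] <- yy
    st$ends[s[3L], ][st$ends[s[3L], ] == yy] <- xx
    st$last_case <- "DEGEN"
    return(invisible(token))
  }
  a <- c(st$lab[s[1L], side_of(s[1L], frame$w[1L])],
         st$lab[s[2L], side_of(s[2L], frame$w[2L])],
         st$lab[s[3L], side_of(s[3L], frame$w[3L])],
         st$lab[s[4L], side_of(s[4L], frame$w[4L])])
  token <- list(
    e0 = e0, s1 = s[1L], s3 = s[3L], x = xx, y = yy,
    adj_x = st$adj[xx, ], adj_y = st$adj[yy, ],
    ends_s1 = st$ends[s[1L], ], ends_s3 = st$ends[s[3L], ],
    lab_e0 = st$lab[e0, ],
    min_edges = st$min_edges, sigma = st$sigma, last_case = st$last_case
  )
  top <- st$top
  sym_pre <- !xor(st$lab[e0, 1L] == top, st$lab[e0, 2L] == top)
  side_sym <- vapply(1:4, function(i) {
    !xor(st$lab[s[i], 1L] == top, st$lab[s[i], 2L] == top)
  }, logical(1))
  # new center labels: after the swap x holds slots 3,2 and y holds 1,4
  new_x <- .lca1(st$S, a[3L], a[2L])
  new_y <- .lca1(st$S, a[1L], a[4L])
  sym_post <- !xor(new_x == top, new_y == top)
  # case analysis (before mutating, so the EQ1 direction-following and the
  # pre-NNI symmetries read consistent labels)
  upd <- .nni_min_update(st, frame, a, sym_pre, sym_post, side_sym)
  # --- rewire topology ---
  st$adj[xx, ][st$adj[xx, ] == s[1L]] <- s[3L]
  st$adj[yy, ][st$adj[yy, ] == s[3L]] <- s[1L]
  st$ends[s[1L], ][st$ends[s[1L], ] == xx] <- yy
  st$ends[s[3L], ][st$ends[s[3L], ] == yy] <- xx
  st$lab[e0, side_of(e0, xx)] <- new_x
  st$lab[e0, 3L - side_of(e0, xx)] <- new_y
  if (is.null(upd)) {
    # consistency fallback: recompute labeling, costs and Min from scratch
    st$n_fallback <- st$n_fallback + 1L
    G <- state_tree(st)
    res <- .unrooted_core(G, st$S, st$alpha, st$beta)
    st$sigma <- res$cost
    st$min_edges <- sort(res$min_edges)
    st$lab <- res$labels
    st$last_case <- "FALLBACK"
  } else {
    st$min_edges <- sort(upd$min_new)
    st$sigma <- st$sigma + upd$delta
    st$last_case <- upd$tag
  }
  st$case_log[st$last_case] <- (if (is.na(st$case_log[st$last_case])) 0L
                                else st$case_log[st$last_case]) + 1L
  invisible(token)
}

# Decide the update case and the cost difference. Returns NULL when no case
# applies (triggers the logged fallback in apply_nni).
.nni_min_update <- function(st, frame, a, sym_pre, sym_post, side_sym) {
  S <- st$S; alpha <- st$alpha; beta <- st$beta
  e0 <- frame$e0
  s <- frame$slots
  C <- c(e0, s)
  mg <- st$min_edges
  ic <- intersect(mg, C)
  d4 <- function() delta4(S, a[1L], a[2L], a[3L], a[4L], alpha, beta)
  d3 <- function(i) .delta3_by_index(S, a, i, alpha, beta)
  partner <- c(4L, 3L, 2L, 1L)
  if (length(ic) == 0L) {
    i <- .follow_min_direction(st, frame)
    if (is.na(i)) return(NULL)
    return(list(tag = "EQ1", min_new = mg, delta = d3(i)))
  }
  if (length(ic) == 1L && ic == e0) {
    if (length(mg) > 1L) return(NULL) # M1 would put the whole star in Min
    return(list(tag = "EQ3", min_new = mg, delta = d4()))
  }
  if (length(ic) == 1L) {
    i <- match(ic, s)
    if (!sym_post) {
      return(list(tag = "EQ4", min_new = mg, delta = d3(i)))
    }
    star <- c(e0, s[i], s[partner[i]])
    return(list(tag = "NE2",
                min_new = union(setdiff(mg, ic), star),
                delta = d3(i)))
  }
  if (length(ic) == 5L) {
    pair14_asym <- !side_sym[1L] && !side_sym[4L]
    pair23_asym <- !side_sym[2L] && !side_sym[3L]
    if (pair14_asym && pair23_asym) return(NULL)
    if (pair14_asym) {
      return(list(tag = "NE1",
                  min_new = union(setdiff(mg, C), c(e0, s[2L], s[3L])),
                  delta = d4()))
    }
    if (pair23_asym) {
      return(list(tag = "NE1",
                  min_new = union(setdiff(mg, C), c(e0, s[1L], s[4L])),
                  delta = d4()))
    }
    return(list(tag = "EQ2", min_new = mg, delta = d4()))
  }
  if (length(ic) == 3L && e0 %in% ic) {
    ij <- match(setdiff(ic, e0), s)
    # {e0, ei, ej} must be one star: both side slots at x or both at y
    if (!(all(ij %in% 1:2) || all(ij %in% 3:4))) return(NULL)
    si <- side_sym[ij]
    if (all(si)) {
      return(list(tag = "NE3", min_new = union(setdiff(mg, C), C),
                  delta = d4()))
    }
    if (sum(si) != 1L) return(NULL)
    i <- ij[si]      # symmetric one: the lemma's e_i
    if (sym_post) {
      star <- c(e0, s[i], s[partner[i]])
      return(list(tag = "NE4", min_new = union(setdiff(mg, C), star),
                  delta = d3(i)))
    }
    return(list(tag = "NE5", min_new = union(setdiff(mg, C), s[i]),
                delta = d3(i)))
  }
  NULL
}

#' Undo an NNI
#'
#' Restores the exact state (topology, labels, optimal set, cost) recorded
#' in the token returned by [apply_nni()]. Tokens must be undone in
#' reverse order of application.
#'
#' @param st A `recon_state`.
#' @param token Undo token from [apply_nni()].
#' @return The state, invisibly.
#' @export
undo_nni <- function(st, token) {
  st$adj[token$x, ] <- token$adj_x
  st$adj[token$y, ] <- token$adj_y
  st$ends[token$s1, ] <- token$ends_s1
  st$ends[token$s3, ] <- token$ends_s3
  if (!is.null(token$lab_e0)) st$lab[token$e0, ] <- token$lab_e0
  st$min_edges <- token$min_edges
  st$sigma <- token$sigma
  st$last_case <- token$last_case
  invisible(st)
}

# Pure-topology NNI on an immutable ugene_tree (no reconciliation state);
# used by the simulator and by neighborhood materialization in tests.
apply_nni_topology <- function(G, e0, variant = 1L) {
  frames <- enumerate_nni(G, edges = e0)
  if (length(frames) == 0L) stop("edge ", e0, " is not an internal edge")
  fr <- frames[[variant]]
  ends <- G$ends
  adj <- G$adj
  s1 <- fr$slots[1L]; s3 <- fr$slots[3L]
  adj[fr$x, ][adj[fr$x, ] == s1] <- s3
  adj[fr$y, ][adj[fr$y, ] == s3] <- s1
  ends[s1, ][ends[s1, ] == fr$x] <- fr$y
  ends[s3, ][ends[s3, ] == fr$y] <- fr$x
  G$ends <- ends
  G$adj <- adj
  G
}
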