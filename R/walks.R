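#' Second-order walk bias factor
#'
#' The distance-based factor of the biased second-order random walk: a
#' candidate next node `k` is scored by `1/p` when it is the previous node
#' itself (distance 0, the "return" case), `1` when it is adjacent to the
#' previous node (distance 1), and `1/q` when it is two steps away
#' (distance 2, the "in-out" case). `p` is the return parameter and `q` the
#' in-out parameter.
#'
#' @param d_ku integer distance in `{0, 1, 2}` between the candidate and the
#'   previously traversed node.
#' @param p return parameter, positive.
#' @param q in-out parameter, positive.
#' @return Positive scalar bias.
#' @export
alpha_factor <- function(d_ku, p, q) {
  stopifnot(is_prob(p), is_prob(q))
  if (!d_ku %in% c(0L, 1L, 2L)) stop2("d_ku must be 0, 1 or 2, got ", d_ku)
  switch(as.character(d_ku), "0" = 1 / p, "1" = 1, "2" = 1 / q)
}

## Flatten a hetero_graph to the 0-based CSR arrays the C++ walker expects.
## Incident edge order matches g$adj, so R and C++ enumerate candidates
## identically.
graph_csr <- function(g) {
  deg <- lengths(g$adj)
  ptr <- c(0L, cumsum(deg))
  idx <- unlist(g$adj, use.names = FALSE)
  if (is.null(idx)) idx <- integer(0)
  e <- g$edges
  this_end <- rep.int(seq_along(g$adj), deg)
  nbr <- ifelse(e$from[idx] == this_end, e$to[idx], e$from[idx])
  list(ptr = as.integer(ptr),
       nbr = as.integer(nbr - 1L),
       type = as.integer(e$type[idx] - 1L),
       weight = as.numeric(e$weight[idx]))
}

#' Next-step transition distribution of the biased walk
#'
#' Given that the walk moved from `prev` to `cur` along an edge of type
#' `prev_type`, each incident edge of `cur` leading to a candidate `n` with
#' type `t` is scored as `weight * M[prev_type, t] * alpha`, where `alpha`
#' is the distance factor of [alpha_factor()], and scores are normalized to
#' a probability vector. Candidates are incident *edges*, so parallel edges
#' of different types receive separate probabilities.
#'
#' This pure-R routine is the reference against which the compiled walker
#' is cross-checked; it is practical for enumeration on small graphs.
#'
#' @param g a `hetero_graph`.
#' @param prev,cur node ids; `prev` must be a neighbor of `cur`.
#' @param prev_type integer edge-type id of the edge used to reach `cur`.
#' @param M m-by-m transition matrix.
#' @param p,q walk bias parameters.
#' @return data frame with columns `neighbor`, `type`, `weight`, `score`,
#'   `prob` (summing to 1), one row per incident edge of `cur`.
#' @export
next_step_distribution <- function(g, prev, cur, prev_type, M,
                                   p = 0.25, q = 0.25) {
  iu <- node_index(g, prev)
  iv <- node_index(g, cur)
  nb <- graph_neighbors(g, cur)
  if (nrow(nb) == 0L) stop2("dead end: node ", cur, " has no incident edges")
  u_nbrs <- graph_neighbors(g, prev)$neighbor
  k_idx <- node_index(g, nb$neighbor)
  d <- ifelse(k_idx == iu, 0L, ifelse(nb$neighbor %in% u_nbrs, 1L, 2L))
  a <- vapply(d, alpha_factor, 0, p = p, q = q)
  score <- nb$weight * M[prev_type, nb$type] * a
  tot <- sum(score)
  if (tot <= 0) stop2("all candidate scores are zero at node ", cur)
  data.frame(neighbor = nb$neighbor, type = nb$type, weight = nb$weight,
             d = d, score = score, prob = score / tot, row.names = NULL)
}

new_walk_corpus <- function(nodes, types, g) {
  structure(list(nodes = nodes, types = types,
                 node_ids = g$nodes, edge_types = g$edge_types),
            class = "walk_corpus")
}

#' @export
print.walk_corpus <- function(x, ...) {
  len <- lengths(x$nodes)
  cat(sprintf("Walk corpus: %d walks over %d nodes (lengths %d..%d)\n",
              length(x$nodes), length(x$node_ids),
              if (length(len)) min(len) else 0L,
              if (length(len)) max(len) else 0L))
  invisible(x)
}

#' @export
length.walk_corpus <- function(x) length(x$nodes)

#' Generate a corpus of biased heterogeneous random walks
#'
#' Runs `walks_per_node` truncated random walks of at most `walk_length`
#' nodes from every node in `nodes` (default: all nodes of the graph). The
#' first step has no previous edge, so it is sampled proportional to edge
#' weight alone; subsequent steps follow [next_step_distribution()] under
#' the transition matrix `M`. Walks truncate early at dead ends; an isolated
#' start node yields a length-1 walk.
#'
#' @param g a `hetero_graph`.
#' @param M m-by-m edge-type transition matrix (default all ones, the
#'   uninformative initialization under which the walk reduces to the
#'   homogeneous p/q-biased walk).
#' @param nodes node ids to start from; default all nodes.
#' @param walks_per_node number of walks per start node (r).
#' @param walk_length maximum walk length in nodes (w), at least 2.
#' @param p,q return and in-out parameters.
#' @param seed integer seed; identical seeds and inputs give identical
#'   corpora.
#' @return A `walk_corpus`: parallel lists of node-index sequences and
#'   edge-type-id sequences (each type sequence one shorter than its walk).
#' @export
generate_walks <- function(g, M = NULL, nodes = NULL, walks_per_node = 1,
                           walk_length = 50, p = 0.25, q = 0.25, seed = 1L) {
  m <- n_edge_types(g)
  M <- M %||% matrix(1, m, m)
  stopifnot(nrow(M) == m, ncol(M) == m)
  stopifnot(is_count(walks_per_node), is_count(walk_length), walk_length >= 2,
            is_prob(p), is_prob(q))
  starts <- if (is.null(nodes)) seq_along(g$nodes) else node_index(g, nodes)
  if (!length(starts)) stop2("empty start-node subset")
  starts <- rep(starts, times = walks_per_node)
  csr <- graph_csr(g)
  res <- cpp_generate_walks(csr$ptr, csr$nbr, csr$type, csr$weight,
                            M, as.integer(starts - 1L),
                            as.integer(walk_length), p, q,
                            as.integer(seed))
  new_walk_corpus(res$nodes, res$types, g)
}

#' Single biased random walk
#'
#' Convenience wrapper around [generate_walks()] for one start node.
#'
#' @inheritParams generate_walks
#' @param start a node id.
#' @return list with `nodes` (character node ids) and `types` (integer
#'   edge-type ids, one shorter).
#' @export
random_walk <- function(g, M = NULL, start, walk_length = 50,
                        p = 0.25, q = 0.25, seed = 1L) {
  corp <- generate_walks(g, M, nodes = start, walks_per_node = 1,
                         walk_length = walk_length, p = p, q = q, seed = seed)
  list(nodes = g$nodes[corp$nodes[[1]]], types = corp$types[[1]])
}

#' Fraction of consecutive same-type steps in a corpus
#'
#' Diagnostic for the same-type preference a trained transition matrix
#' induces: among all consecutive edge pairs in all walks, the fraction
#' whose two edges share an edge type.
#'
#' @param corpus a `walk_corpus`.
#' @return Scalar in `[0, 1]`, or `NaN` when no walk has two edges.
#' @export
same_type_fraction <- function(corpus) {
  num <- 0; den <- 0
  for (tt in corpus$types) {
    if (length(tt) >= 2L) {
      num <- num + sum(tt[-1] == tt[-length(tt)])
      den <- den + length(tt) - 1L
    }
  }
  if (den == 0) return(NaN)
  num / den
}
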