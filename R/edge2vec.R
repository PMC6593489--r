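#' Fit edge-semantics-aware node embeddings (edge2vec)
#'
#' Fits the full model on a heterogeneous graph: an m-by-m edge-type
#' transition matrix is trained by an expectation-maximization loop over
#' biased second-order random walks ([train_transition_matrix()]), a full
#' walk corpus is generated under the trained matrix, and node embeddings
#' are learned from that corpus by skip-gram with negative sampling
#' ([train_embeddings()]).
#'
#' Setting `em_iterations = 0` keeps the transition matrix at its all-ones
#' initialization, in which case the walks are exactly the homogeneous
#' p/q-biased (node2vec-style) walks — the natural ablation for measuring
#' what edge semantics contribute.
#'
#' @param graph a [hetero_graph()].
#' @param dimensions embedding dimension d (default 128).
#' @param p,q walk return and in-out parameters (default 0.25 each).
#' @param walks_per_node walks started per node, r (default 1).
#' @param walk_length maximum nodes per walk, w (default 50).
#' @param em_iterations EM iterations N for the transition matrix (default
#'   10; 0 = ablation).
#' @param sample_ratio fraction of nodes sampled per EM iteration (default
#'   0.01).
#' @param damping optional convex blend of successive transition matrices
#'   (default 0 = full replacement).
#' @param window,negative,epochs,lr,neg_dist skip-gram training
#'   parameters; see [train_embeddings()].
#' @param seed master integer seed controlling every random choice.
#' @return An object of class `edge2vec`: a list with components
#'   `embedding` (|V|-by-d matrix, node ids as row names), `transition`
#'   (trained m-by-m matrix), `history` (per-EM-iteration snapshots),
#'   `corpus` (the final walk corpus), `graph`, `config` and `call`.
#' @examples
#' g <- generate_typed_sbm(n_per_class = 20, n_classes = 2, seed = 1)$graph
#' fit <- edge2vec(g, dimensions = 8, epochs = 1, seed = 1)
#' fit
#' head(coef(fit), 2)
#' @export
edge2vec <- function(graph, dimensions = 128, p = 0.25, q = 0.25,
                     walks_per_node = 1, walk_length = 50,
                     em_iterations = 10, sample_ratio = 0.01, damping = 0,
                     window = 10, negative = 5, epochs = 5, lr = 0.025,
                     neg_dist = c("uniform", "unigram75"), seed = 1L) {
  stopifnot(inherits(graph, "hetero_graph"))
  neg_dist <- match.arg(neg_dist)
  em <- train_transition_matrix(graph, walks_per_node = walks_per_node,
                                walk_length = walk_length, p = p, q = q,
                                sample_ratio = sample_ratio,
                                iterations = em_iterations,
                                damping = damping, final_corpus = TRUE,
                                seed = seed)
  emb <- train_embeddings(em$corpus, dimensions = dimensions,
                          window = window, negative = negative,
                          epochs = epochs, lr = lr, neg_dist = neg_dist,
                          seed = derive_seed(seed, 999L))
  structure(list(
    embedding = emb,
    transition = em$transition,
    history = em$history,
    corpus = em$corpus,
    graph = graph,
    config = list(dimensions = dimensions, p = p, q = q,
                  walks_per_node = walks_per_node,
                  walk_length = walk_length,
                  em_iterations = em_iterations,
                  sample_ratio = sample_ratio, damping = damping,
                  window = window, negative = negative, epochs = epochs,
                  lr = lr, neg_dist = neg_dist, seed = seed),
    call = match.call()
  ), class = "edge2vec")
}

#' @export
print.edge2vec <- function(x, ...) {
  cat("edge2vec fit\n")
  cat(sprintf("  graph: %d nodes, %d edges, %d edge types\n",
              n_nodes(x$graph), n_edges(x$graph), n_edge_types(x$graph)))
  cat(sprintf("  embedding: %d x %d\n", nrow(x$embedding), ncol(x$embedding)))
  cat(sprintf("  EM iterations: %d (p = %g, q = %g, r = %d, w = %d)\n",
              x$config$em_iterations, x$config$p, x$config$q,
              x$config$walks_per_node, x$config$walk_length))
  invisible(x)
}

#' @export
summary.edge2vec <- function(object, ...) {
  M <- object$transition
  off <- M[row(M) != col(M)]
  stf <- same_type_fraction(object$corpus)
  out <- list(
    config = object$config,
    n_nodes = n_nodes(object$graph),
    n_edges = n_edges(object$graph),
    edge_types = object$graph$edge_types,
    transition = M,
    diag_mean = mean(diag(M)),
    offdiag_mean = if (length(off)) mean(off) else NA_real_,
    same_type_fraction = stf
  )
  class(out) <- "summary.edge2vec"
  out
}

#' @export
print.summary.edge2vec <- function(x, ...) {
  cat(sprintf("edge2vec fit on %d nodes / %d edges, %d edge types\n",
              x$n_nodes, x$n_edges, length(x$edge_types)))
  cat("Trained edge-type transition matrix:\n")
  print(round(x$transition, 4))
  cat(sprintf("  mean diagonal %.4f, mean off-diagonal %.4f\n",
              x$diag_mean, x$offdiag_mean))
  cat(sprintf("  same-type consecutive-step fraction in corpus: %.4f\n",
              x$same_type_fraction))
  invisible(x)
}

#' @export
coef.edge2vec <- function(object, ...) object$embedding

#' Predict pairwise similarity or ranked neighbors from a fit
#'
#' With `type = "similarity"`, `newdata` is a two-column data frame of node
#' id pairs and the cosine similarity of their embeddings is returned —
#' the score the search-ranking protocol uses to reproduce known links.
#' With `type = "rank"`, `newdata` is a vector of query node ids and the
#' `top_k` most cosine-similar other nodes are returned per query.
#'
#' @param object an `edge2vec` fit.
#' @param newdata pairs data frame or query node vector (see above).
#' @param type `"similarity"` or `"rank"`.
#' @param top_k ranking depth for `type = "rank"`.
#' @param ... unused.
#' @return Numeric vector of similarities, or a named list of ranked data
#'   frames (`node`, `score`).
#' @export
predict.edge2vec <- function(object, newdata,
                             type = c("similarity", "rank"), top_k = 100,
                             ...) {
  type <- match.arg(type)
  emb <- object$embedding
  if (type == "similarity") {
    stopifnot(is.data.frame(newdata), ncol(newdata) >= 2)
    a <- as.character(newdata[[1]]); b <- as.character(newdata[[2]])
    ia <- match(a, rownames(emb)); ib <- match(b, rownames(emb))
    if (anyNA(ia) || anyNA(ib)) stop2("pair contains unknown node ids")
    va <- emb[ia, , drop = FALSE]; vb <- emb[ib, , drop = FALSE]
    rowSums(va * vb) / (sqrt(rowSums(va^2)) * sqrt(rowSums(vb^2)))
  } else {
    queries <- as.character(newdata)
    rank_by_cosine(emb, queries, top_k = top_k)
  }
}

#' Simulate walks from a fitted model
#'
#' Generates new biased random walks on the fitted graph under the trained
#' transition matrix, mirroring [stats::simulate()] semantics: `nsim`
#' corpora are produced with seeds derived from `seed`.
#'
#' @param object an `edge2vec` fit.
#' @param nsim number of corpora.
#' @param seed integer seed.
#' @param nodes optional start-node subset.
#' @param ... unused.
#' @return list of `walk_corpus` objects of length `nsim`.
#' @export
simulate.edge2vec <- function(object, nsim = 1, seed = 1L, nodes = NULL,
                              ...) {
  cfg <- object$config
  lapply(seq_len(nsim), function(i) {
    generate_walks(object$graph, object$transition, nodes = nodes,
                   walks_per_node = cfg$walks_per_node,
                   walk_length = cfg$walk_length, p = cfg$p, q = cfg$q,
                   seed = derive_seed(seed, i))
  })
}

#' Plot the trained transition matrix
#'
#' Image of the m-by-m edge-type transition matrix, diagonal running from
#' bottom-left to top-right; darker cells are stronger transitions.
#'
#' @param x an `edge2vec` fit.
#' @param ... passed to [graphics::image()].
#' @export
plot.edge2vec <- function(x, ...) {
  M <- x$transition
  m <- nrow(M)
  graphics::image(seq_len(m), seq_len(m), t(M[m:1, , drop = FALSE]),
                  axes = FALSE, xlab = "to edge type",
                  ylab = "from edge type",
                  col = grDevices::hcl.colors(24, "Blues 3", rev = TRUE),
                  ...)
  graphics::axis(1, at = seq_len(m), labels = colnames(M), las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, at = seq_len(m), labels = rev(rownames(M)), las = 2,
                 cex.axis = 0.8)
  graphics::box()
  invisible(x)
}

## Cosine ranking shared by predict() and the search-ranking task.
## Ties are broken by node-id order so rankings are deterministic.
rank_by_cosine <- function(emb, queries, top_k = 100) {
  norms <- sqrt(rowSums(emb^2))
  norms[norms == 0] <- 1
  unit <- emb / norms
  out <- lapply(queries, function(qn) {
    iq <- match(qn, rownames(emb))
    if (is.na(iq)) return(NULL)
    score <- as.numeric(unit %*% unit[iq, ])
    cand <- setdiff(seq_len(nrow(emb)), iq)
    ids <- rownames(emb)[cand]
    ord <- order(-score[cand], ids)
    keep <- utils::head(ord, top_k)
    data.frame(node = ids[keep], score = score[cand][keep],
               row.names = NULL)
  })
  names(out) <- queries
  out
}
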