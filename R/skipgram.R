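#' Enumerate (center, context) pairs from a walk corpus
#'
#' Treats walks as sentences: for every position `i` of every walk, emits a
#' pair for each position `j` with `0 < |i - j| <= window`. Length-1 walks
#' contribute no pairs.
#'
#' @param corpus a `walk_corpus`.
#' @param window context window size, at least 1.
#' @return data frame with integer columns `center` and `context` (node
#'   indices into `corpus$node_ids`).
#' @export
build_context_pairs <- function(corpus, window = 10) {
  if (!is_count(window)) stop2("window must be a positive integer")
  if (!length(corpus$nodes)) stop2("empty walk corpus")
  centers <- vector("list", length(corpus$nodes))
  contexts <- vector("list", length(corpus$nodes))
  for (w in seq_along(corpus$nodes)) {
    walk <- corpus$nodes[[w]]
    L <- length(walk)
    if (L < 2L) next
    cc <- vector("list", L)
    xx <- vector("list", L)
    for (i in seq_len(L)) {
      j <- max(1L, i - window):min(L, i + window)
      j <- j[j != i]
      cc[[i]] <- rep.int(walk[i], length(j))
      xx[[i]] <- walk[j]
    }
    centers[[w]] <- unlist(cc, use.names = FALSE)
    contexts[[w]] <- unlist(xx, use.names = FALSE)
  }
  data.frame(center = unlist(centers, use.names = FALSE) %||% integer(0),
             context = unlist(contexts, use.names = FALSE) %||% integer(0))
}

#' Draw negative samples
#'
#' Draws `k` node indices from the negative-sampling distribution,
#' rejecting (and redrawing) any draw equal to the true context node.
#' The default distribution is uniform over nodes; `"unigram75"` uses
#' corpus frequencies raised to the 3/4 power, the word2vec convention.
#'
#' @param context integer index of the true context node, excluded from the
#'   sample.
#' @param k number of negatives, at least 1 and less than `n`.
#' @param n number of nodes.
#' @param probs optional per-node probability weights (length `n`);
#'   overrides the uniform default.
#' @param seed optional integer seed.
#' @return Integer vector of `k` node indices, none equal to `context`.
#' @export
sample_negatives <- function(context, k, n, probs = NULL, seed = NULL) {
  if (!is_count(k)) stop2("k must be a positive integer")
  if (k >= n) stop2("k must be smaller than the number of nodes")
  with_seed(seed, {
    out <- integer(k)
    filled <- 0L
    while (filled < k) {
      draw <- sample.int(n, k - filled, replace = TRUE, prob = probs)
      draw <- draw[draw != context]
      if (length(draw)) {
        out[(filled + 1L):(filled + length(draw))] <- draw
        filled <- filled + length(draw)
      }
    }
    out
  })
}

#' Skip-gram negative-sampling objective and gradient
#'
#' The per-pair objective maximized by the trainer:
#' `log sigmoid(f_t . f_v) + sum_i log sigmoid(-f_{u_i} . f_v)`,
#' where `f_v` is the center node's input vector, `f_t` the true context
#' node's output vector and `f_{u_i}` the output vectors of the `k`
#' negative nodes. `sgns_gradient` returns the exact analytic gradient
#' with respect to every involved row.
#'
#' @param f_v numeric center (input) vector.
#' @param f_t numeric context (output) vector.
#' @param F_neg matrix of negative (output) vectors, one per row.
#' @return `sgns_objective`: scalar log-objective. `sgns_gradient`: list
#'   with components `v`, `t` and `neg` (matrix, one gradient per row).
#' @export
sgns_objective <- function(f_v, f_t, F_neg) {
  pos <- log(sigmoid(sum(f_t * f_v)))
  neg <- sum(log(sigmoid(-as.numeric(F_neg %*% f_v))))
  pos + neg
}

#' @rdname sgns_objective
#' @export
sgns_gradient <- function(f_v, f_t, F_neg) {
  g_pos <- 1 - sigmoid(sum(f_t * f_v))
  s_neg <- sigmoid(as.numeric(F_neg %*% f_v))
  list(
    v = g_pos * f_t - as.numeric(crossprod(F_neg, s_neg)),
    t = g_pos * f_v,
    neg = -outer(s_neg, f_v)
  )
}

#' One stochastic-gradient ascent step on the negative-sampling objective
#'
#' Applies the analytic gradient of [sgns_objective()] scaled by `lr` to a
#' two-matrix skip-gram model: the center row of the input matrix, the
#' context row of the output matrix and each negative row of the output
#' matrix are updated in a single step. `lr = 0` leaves the model
#' unchanged. This is the reference implementation of the update performed
#' by the compiled trainer.
#'
#' @param model list with numeric matrices `input` and `output` of equal
#'   shape (nodes by dimensions).
#' @param center,context integer row indices of the center and true context
#'   node.
#' @param negatives integer row indices of the negative nodes.
#' @param lr learning rate, non-negative.
#' @return The updated model (invisibly usable; R copy semantics).
#' @export
sgd_step <- function(model, center, context, negatives, lr) {
  stopifnot(lr >= 0)
  g <- sgns_gradient(model$input[center, ], model$output[context, ],
                     model$output[negatives, , drop = FALSE])
  model$input[center, ] <- model$input[center, ] + lr * g$v
  model$output[context, ] <- model$output[context, ] + lr * g$t
  model$output[negatives, ] <- model$output[negatives, , drop = FALSE] +
    lr * g$neg
  model
}

#' Train node embeddings by skip-gram with negative sampling
#'
#' Runs the compiled single-threaded SGD trainer over the walk corpus:
#' context pairs are enumerated with a sliding window, shuffled each epoch,
#' and for each pair one positive and `negative` negative updates are
#' applied with a learning rate decaying linearly from `lr` to `1e-4 * lr`.
#' Input vectors are initialized uniformly in `[-0.5/d, 0.5/d]`, output
#' vectors at zero. Nodes absent from the corpus keep their random
#' initialization (a message reports how many).
#'
#' @param corpus a `walk_corpus` covering the nodes to embed.
#' @param dimensions embedding dimension d; default 128.
#' @param window context window size; default 10.
#' @param negative number of negative samples k per positive pair; default
#'   5.
#' @param epochs passes over the shuffled pair stream; default 5.
#' @param lr initial learning rate; default 0.025.
#' @param neg_dist negative-sampling distribution: `"uniform"` (default)
#'   or `"unigram75"` (corpus frequency to the 3/4 power).
#' @param seed integer seed; fixed seeds give bitwise-identical embeddings.
#' @return numeric |V|-by-d matrix of input vectors, row names the node
#'   ids.
#' @export
train_embeddings <- function(corpus, dimensions = 128, window = 10,
                             negative = 5, epochs = 5, lr = 0.025,
                             neg_dist = c("uniform", "unigram75"),
                             seed = 1L) {
  neg_dist <- match.arg(neg_dist)
  if (!length(corpus$nodes)) stop2("empty walk corpus")
  stopifnot(is_count(dimensions), is_count(window), is_count(negative),
            is_count(epochs), lr > 0)
  n <- length(corpus$node_ids)
  if (negative >= n) stop2("negative sample count must be below |V|")
  probs <- if (neg_dist == "unigram75") {
    freq <- tabulate(unlist(corpus$nodes, use.names = FALSE), nbins = n)
    w <- freq^0.75
    w / sum(w)
  } else numeric(0)
  covered <- unique(unlist(corpus$nodes, use.names = FALSE))
  n_missing <- n - length(covered)
  if (n_missing > 0)
    message(n_missing,
            " node(s) absent from the corpus keep their random initialization")
  emb <- cpp_train_sgns(corpus$nodes, as.integer(n), as.integer(dimensions),
                        as.integer(window), as.integer(negative),
                        as.numeric(lr), as.integer(epochs), probs,
                        as.integer(seed))
  rownames(emb) <- corpus$node_ids
  emb
}

#' Softmax co-occurrence probability from embeddings
#'
#' Diagnostic for tiny graphs: the probability of context `c` given node
#' `v` under a full softmax over all nodes,
#' `exp(f_v . f_c) / sum_u exp(f_u . f_c)`. Ranking candidates `v` by this
#' probability is equivalent to ranking by inner product.
#'
#' @param emb embedding matrix with node ids as row names.
#' @param c,v node ids or row indices.
#' @return Scalar probability.
#' @export
softmax_probability <- function(emb, c, v) {
  ic <- if (is.character(c)) match(c, rownames(emb)) else c
  iv <- if (is.character(v)) match(v, rownames(emb)) else v
  if (is.na(ic) || is.na(iv)) stop2("unknown node id")
  scores <- as.numeric(emb %*% emb[ic, ])
  scores <- scores - max(scores)
  exp(scores[iv]) / sum(exp(scores))
}

#' Write / read embeddings in word2vec text format
#'
#' First line `<count> <dim>`, then one `<node_id> v1 ... vd` line per
#' node.
#'
#' @param emb embedding matrix with node ids as row names.
#' @param path file path.
#' @return `read_embeddings` returns the matrix.
#' @export
write_embeddings <- function(emb, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(emb), ncol(emb)), con)
  ids <- rownames(emb) %||% as.character(seq_len(nrow(emb)))
  body <- vapply(seq_len(nrow(emb)), function(i) {
    paste(c(ids[i], sprintf("%.17g", emb[i, ])), collapse = " ")
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) stop2("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  parts <- strsplit(trimws(lines[-1]), "\\s+")
  emb <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  rownames(emb) <- vapply(parts, `[`, "", 1L)
  if (nrow(emb) != hdr[1]) stop2("embedding file row count mismatch")
  emb
}
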