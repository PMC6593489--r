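#' Per-walk edge-type count matrix
#'
#' For each edge type `e_j` and each walk `p_i`, counts how many times an
#' edge of type `e_j` is traversed in `p_i`. Row `j` is the count vector
#' v_j whose pairwise correlations drive the transition-matrix update.
#'
#' @param corpus a `walk_corpus`.
#' @param m number of edge types; defaults to the corpus vocabulary size.
#' @return m-by-n_walks integer matrix; column sums equal per-walk edge
#'   counts (walk length minus 1 for full-length walks).
#' @export
edge_type_counts <- function(corpus, m = length(corpus$edge_types)) {
  stopifnot(is_count(m))
  nw <- length(corpus$types)
  counts <- matrix(0L, nrow = m, ncol = nw)
  for (i in seq_len(nw)) {
    tt <- corpus$types[[i]]
    if (length(tt)) {
      if (any(tt > m)) stop2("edge-type id exceeds vocabulary size m = ", m)
      counts[, i] <- tabulate(tt, nbins = m)
    }
  }
  labs <- corpus$edge_types
  length(labs) <- m
  rownames(counts) <- labs
  counts
}

#' Sigmoid (logistic) function
#'
#' `1 / (1 + exp(-x))`, with the argument clipped to `|x| <= 35` so the
#' result never under- or overflows. Maps correlations in `[-1, 1]` to
#' transition weights in `[0.269, 0.731]` and is the link used in the
#' negative-sampling objective.
#'
#' @param x numeric vector.
#' @return Values in (0, 1); `sigmoid(x) + sigmoid(-x) == 1`.
#' @export
sigmoid <- function(x) {
  x <- pmin(pmax(x, -35), 35)
  1 / (1 + exp(-x))
}

#' Update the edge-type transition matrix from walk counts
#'
#' Re-estimates the m-by-m transition matrix as the sigmoid-transformed
#' Pearson correlation between per-walk count vectors: `M[i, j] =
#' sigmoid(cor(v_i, v_j))`. The update replaces the previous matrix (no
#' damping by default). Because self-correlation of any non-constant count
#' vector is +1, the diagonal entry of such a type is always the maximum of
#' its row, which is what makes trained walks prefer staying on the same
#' edge type.
#'
#' Degenerate count vectors are handled without producing `NaN`:
#' a type absent from the corpus (all-zero counts) keeps its entries from
#' `prev` when supplied (else the neutral 0.5); a constant non-zero vector
#' has undefined correlation, defined here as 0, giving the neutral weight
#' `sigmoid(0) = 0.5`.
#'
#' @param counts m-by-n_walks count matrix from [edge_type_counts()], with
#'   at least 2 walks.
#' @param prev optional previous m-by-m matrix used for types absent from
#'   the corpus.
#' @param damping optional damping coefficient in `[0, 1)`: the returned
#'   matrix is `(1 - damping) * new + damping * prev`. Default 0 (full
#'   replacement).
#' @return Symmetric m-by-m matrix with entries in
#'   `[sigmoid(-1), sigmoid(1)]`.
#' @export
update_transition_matrix <- function(counts, prev = NULL, damping = 0) {
  stopifnot(is.matrix(counts))
  m <- nrow(counts)
  if (ncol(counts) < 2L)
    stop2("need at least 2 walks to estimate correlations, got ",
          ncol(counts))
  stopifnot(damping >= 0, damping < 1)
  sds <- apply(counts, 1L, stats::sd)
  C <- suppressWarnings(stats::cor(t(counts)))
  C[!is.finite(C)] <- 0
  # constant vectors: neutral correlation 0 everywhere, including diagonal
  degen <- sds == 0
  C[degen, ] <- 0
  C[, degen] <- 0
  M <- sigmoid(C)
  absent <- rowSums(counts != 0) == 0L
  if (any(absent)) {
    keep <- if (is.null(prev)) matrix(0.5, m, m) else prev
    M[absent, ] <- keep[absent, ]
    M[, absent] <- keep[, absent]
  }
  if (damping > 0 && !is.null(prev)) M <- (1 - damping) * M + damping * prev
  dimnames(M) <- list(rownames(counts), rownames(counts))
  M
}

#' EM training of the edge-type transition matrix
#'
#' Alternates, for `iterations` rounds, between (a) generating a walk
#' corpus from a uniform random sample of `ceiling(sample_ratio * |V|)`
#' nodes under the current matrix and (b) re-estimating the matrix from the
#' per-walk edge-type count correlations via [update_transition_matrix()].
#' The matrix is initialized to all ones (all transitions equally
#' probable). After the loop a final corpus is generated over *all* nodes
#' with the trained matrix, suitable as the skip-gram training corpus.
#'
#' Each iteration's node sample is drawn without replacement with a seed
#' derived deterministically from `seed` and the iteration index, so runs
#' are exactly reproducible.
#'
#' @param g a `hetero_graph` with at least one edge.
#' @param walks_per_node,walk_length,p,q walk parameters; see
#'   [generate_walks()]. Defaults r = 1, w = 50, p = q = 0.25.
#' @param sample_ratio fraction of nodes sampled per EM iteration, in
#'   (0, 1]. Default 0.01.
#' @param iterations number of EM iterations N; default 10. `iterations =
#'   0` skips EM and returns the all-ones matrix (homogeneous-walk
#'   ablation).
#' @param damping optional convex blend with the previous matrix; default 0.
#' @param final_corpus logical; generate the full-graph corpus after
#'   training (default `TRUE`).
#' @param seed master integer seed.
#' @return list with components `transition` (the trained matrix, with
#'   edge-type labels as dimnames), `corpus` (the final full
#'   `walk_corpus`, or `NULL`), and `history` (per-iteration matrix
#'   snapshots).
#' @export
train_transition_matrix <- function(g, walks_per_node = 1, walk_length = 50,
                                    p = 0.25, q = 0.25, sample_ratio = 0.01,
                                    iterations = 10, damping = 0,
                                    final_corpus = TRUE, seed = 1L) {
  if (n_edges(g) < 1L) stop2("graph has no edges")
  stopifnot(sample_ratio > 0, sample_ratio <= 1,
            iterations >= 0, iterations == floor(iterations))
  m <- n_edge_types(g)
  M <- matrix(1, m, m, dimnames = list(g$edge_types, g$edge_types))
  history <- vector("list", iterations)
  n_sample <- max(2L, ceiling(sample_ratio * n_nodes(g)))
  n_sample <- min(n_sample, n_nodes(g))
  for (it in seq_len(iterations)) {
    it_seed <- derive_seed(seed, it)
    subset <- with_seed(it_seed,
                        sample(g$nodes, n_sample, replace = FALSE))
    corp <- generate_walks(g, M, nodes = subset,
                           walks_per_node = walks_per_node,
                           walk_length = walk_length, p = p, q = q,
                           seed = it_seed)
    if (length(corp) < 2L)
      stop2("sampled corpus has fewer than 2 walks; increase sample_ratio")
    counts <- edge_type_counts(corp, m)
    M <- update_transition_matrix(counts, prev = M, damping = damping)
    history[[it]] <- M
  }
  corpus <- NULL
  if (final_corpus) {
    corpus <- generate_walks(g, M, nodes = NULL,
                             walks_per_node = walks_per_node,
                             walk_length = walk_length, p = p, q = q,
                             seed = derive_seed(seed, iterations + 1L))
  }
  list(transition = M, corpus = corpus, history = history)
}

#' Write / read a transition matrix as TSV
#'
#' Serializes with edge-type labels as header row and first column, values
#' at 17 significant digits so the decimal round-trip is bit exact.
#'
#' @param M matrix with dimnames.
#' @param path file path.
#' @return `read_transition_matrix` returns the matrix.
#' @export
write_transition_matrix <- function(M, path) {
  labels <- rownames(M) %||% as.character(seq_len(nrow(M)))
  header <- paste(c("edge_type", labels), collapse = "\t")
  rows <- vapply(seq_len(nrow(M)), function(i) {
    paste(c(labels[i], sprintf("%.17g", M[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_transition_matrix
#' @export
read_transition_matrix <- function(path) {
  if (!file.exists(path)) stop2("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  M <- t(vapply(body, function(r) as.numeric(r[-1]), numeric(length(header))))
  dimnames(M) <- list(vapply(body, `[`, "", 1L), header)
  M
}
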