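#' Typed stochastic block model with planted edge-type structure
#'
#' Generates a heterogeneous graph whose nodes fall into `n_classes`
#' communities (stochastic block model topology) and whose edge types are
#' drawn from a distribution conditioned on the endpoint-class pair:
#' within-class edges carry that class's own "signature" type with
#' probability `signal`, between-class edges carry a shared background
#' type with probability `signal` (the remainder is spread uniformly over
#' the other types). Edge semantics therefore carry the community signal,
#' and the induced edge-type co-occurrence structure is known exactly —
#' the planted ground truth for transition-matrix recovery tests. A
#' `skew` exponent > 1 power-law-reweights the type-assignment rows,
#' mimicking the highly skewed type frequencies of real biomedical
#' knowledge graphs.
#'
#' @param n_per_class nodes per class (default 100).
#' @param n_classes number of classes C (default 5).
#' @param p_within,p_between edge probabilities inside / across classes
#'   (defaults 0.10 and 0.02).
#' @param types_per_class number of signature types per class (default 1).
#'   With 2 or more, the signature types of a class are co-planted: they
#'   are mixed evenly on that class's within-class edges, so their
#'   per-walk counts rise and fall together — the positive co-occurrence
#'   a transition-matrix estimate should recover, while types of
#'   different classes are anti-planted.
#' @param signal probability mass on the designated type(s) for each class
#'   pair (default 0.9).
#' @param skew power-law exponent reweighting each type-assignment row
#'   (default 1 = none).
#' @param type_table optional custom assignment table: one row per
#'   unordered class pair in the order (1,1), (1,2), ..., (C,C), rows
#'   summing to 1; overrides `signal`/`skew`.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return list with `graph` (a [hetero_graph()] whose edge types are
#'   `t1..t(C+1)`), `labels` (named character vector of node classes) and
#'   `cooccurrence` (the planted type-by-type co-occurrence matrix,
#'   expected co-occurrence mass of type pairs within a class
#'   neighborhood).
#' @export
generate_typed_sbm <- function(n_per_class = 100, n_classes = 5,
                               p_within = 0.10, p_between = 0.02,
                               types_per_class = 1, signal = 0.9, skew = 1,
                               type_table = NULL, seed = 1L) {
  stopifnot(is_count(n_per_class), is_count(n_classes),
            is_count(types_per_class),
            p_within >= 0, p_within <= 1, p_between >= 0, p_between <= 1,
            signal > 0, signal <= 1, skew > 0)
  C <- n_classes
  n <- n_per_class * C
  # signature type(s) per class plus a shared background type
  m <- C * types_per_class + 1L
  cls <- rep(seq_len(C), each = n_per_class)
  ids <- sprintf("n%04d", seq_len(n))

  # type-assignment table: one distribution per unordered class pair
  pair_idx <- function(i, j) {
    a <- min(i, j); b <- max(i, j)
    (a - 1L) * C - (a - 1L) * a / 2L + b  # row index in upper-triangle order
  }
  n_pairs <- C * (C + 1L) / 2L
  if (is.null(type_table)) {
    type_table <- matrix(0, n_pairs, m)
    for (i in seq_len(C)) for (j in i:C) {
      row <- numeric(m)
      # signature types within class, background type across classes
      target <- if (i == j) (i - 1L) * types_per_class + seq_len(types_per_class)
                else m
      row[target] <- signal / length(target)
      row[-target] <- (1 - signal) / (m - length(target))
      if (skew != 1) row <- row^skew / sum(row^skew)
      type_table[pair_idx(i, j), ] <- row
    }
  } else {
    stopifnot(nrow(type_table) == n_pairs, ncol(type_table) >= 2)
    m <- ncol(type_table)
    if (any(abs(rowSums(type_table) - 1) > 1e-8))
      stop2("type_table rows must sum to 1")
  }

  res <- with_seed(seed, {
    from <- integer(0); to <- integer(0); ty <- integer(0)
    for (i in seq_len(C)) for (j in i:C) {
      a_nodes <- which(cls == i)
      if (i == j) {
        if (n_per_class >= 2 && p_within > 0) {
          cmb <- utils::combn(a_nodes, 2L)
          keep <- stats::runif(ncol(cmb)) < p_within
          f <- cmb[1L, keep]; t <- cmb[2L, keep]
        } else { f <- integer(0); t <- integer(0) }
      } else {
        b_nodes <- which(cls == j)
        grid_f <- rep(a_nodes, times = length(b_nodes))
        grid_t <- rep(b_nodes, each = length(a_nodes))
        keep <- stats::runif(length(grid_f)) < p_between
        f <- grid_f[keep]; t <- grid_t[keep]
      }
      if (length(f)) {
        probs <- type_table[pair_idx(i, j), ]
        tt <- sample.int(m, length(f), replace = TRUE, prob = probs)
        from <- c(from, f); to <- c(to, t); ty <- c(ty, tt)
      }
    }
    list(from = from, to = to, ty = ty)
  })

  type_labels <- paste0("t", seq_len(m))
  labels <- stats::setNames(paste0("class", cls), ids)
  if (!length(res$from)) {
    g <- hetero_graph(data.frame(from = character(0), to = character(0),
                                 type = character(0)),
                      nodes = ids, node_type = labels)
  } else {
    g <- hetero_graph(data.frame(from = ids[res$from], to = ids[res$to],
                                 type = type_labels[res$ty]),
                      nodes = ids, node_type = labels)
    # register the full vocabulary even if some type never appeared
    if (length(g$edge_types) < m) {
      seen <- g$edge_types
      g$edge_types <- c(seen, setdiff(type_labels, seen))
    }
  }

  # planted co-occurrence: mass of type pairs expected within one class
  # neighborhood, summed over class pairs weighted by expected edge count
  cooc <- matrix(0, m, m, dimnames = list(type_labels, type_labels))
  for (i in seq_len(C)) for (j in i:C) {
    w <- if (i == j) choose(n_per_class, 2) * p_within
         else n_per_class^2 * p_between
    pr <- type_table[pair_idx(i, j), ]
    cooc <- cooc + w * outer(pr, pr)
  }
  cooc <- cooc / sum(cooc)

  list(graph = g, labels = labels, cooccurrence = cooc)
}

#' Latent-factor bipartite bioactivity benchmark
#'
#' Emulates a compound-gene bioactivity layer with known ground truth.
#' Compounds and genes get latent factors; the noisy latent inner product
#' ranks all cross pairs. The strongest pairs become "bind" edges in the
#' graph; the next strongest are *held out* as labeled positives (never
#' placed in the graph, mirroring benchmark pairs absent from the training
#' network), and an equal number of the weakest pairs become labeled
#' negatives. Same-layer similarity edges ("similar" between compounds,
#' "interact" between genes, from latent cosine proximity) and uniformly
#' random cross-layer "spurious" edges give the walk several edge types of
#' very different informativeness.
#'
#' @param n_compounds,n_genes layer sizes (defaults 200 and 200).
#' @param latent_dim latent factor dimension (default 8).
#' @param bind_rate fraction of cross pairs that become bind edges
#'   (default 0.02).
#' @param holdout_rate fraction of cross pairs held out as labeled
#'   positives (default 0.01).
#' @param noise standard deviation of Gaussian noise added to latent
#'   scores before ranking (default 0.1); at `noise = 0` held-out
#'   positives have strictly higher latent scores than negatives by
#'   construction.
#' @param sim_degree average number of same-layer similarity edges per
#'   node (default 2).
#' @param spurious_rate fraction of cross pairs added as uniformly random
#'   "spurious" edges (default 0.005).
#' @param seed integer seed.
#' @return list with `graph` (node types `compound`/`gene`), `pairs`
#'   (held-out data frame `a, b, label`) and `latent_scores` (named list
#'   of positive/negative mean latent inner products).
#' @export
generate_bioactivity <- function(n_compounds = 200, n_genes = 200,
                                 latent_dim = 8, bind_rate = 0.02,
                                 holdout_rate = 0.01, noise = 0.1,
                                 sim_degree = 2, spurious_rate = 0.005,
                                 seed = 1L) {
  stopifnot(is_count(n_compounds), is_count(n_genes), is_count(latent_dim),
            bind_rate > 0, bind_rate < 1, holdout_rate > 0, holdout_rate < 1,
            noise >= 0, sim_degree >= 0, spurious_rate >= 0)
  comp <- sprintf("c%04d", seq_len(n_compounds))
  gene <- sprintf("g%04d", seq_len(n_genes))

  with_seed(seed, {
    U <- matrix(stats::rnorm(n_compounds * latent_dim), n_compounds) /
      sqrt(latent_dim)
    V <- matrix(stats::rnorm(n_genes * latent_dim), n_genes) /
      sqrt(latent_dim)
    S <- U %*% t(V)
    Snoisy <- S + noise * matrix(stats::rnorm(length(S)), nrow(S))

    np <- n_compounds * n_genes
    ord <- order(Snoisy, decreasing = TRUE)
    n_bind <- max(1L, round(bind_rate * np))
    n_hold <- max(1L, round(holdout_rate * np))
    if (n_bind + n_hold >= np) stop2("bind_rate + holdout_rate too large")
    bind_idx <- ord[seq_len(n_bind)]
    pos_idx <- ord[n_bind + seq_len(n_hold)]
    neg_idx <- ord[np - seq_len(n_hold) + 1L]

    idx_pair <- function(idx) {
      i <- ((idx - 1L) %% n_compounds) + 1L
      j <- ((idx - 1L) %/% n_compounds) + 1L
      list(c = comp[i], g = gene[j], ci = i, gi = j)
    }
    bp <- idx_pair(bind_idx); pp <- idx_pair(pos_idx); npair <- idx_pair(neg_idx)

    edges <- data.frame(from = bp$c, to = bp$g, type = "bind")

    knn_edges <- function(X, ids, k, type) {
      if (k < 1) return(NULL)
      D <- X %*% t(X)
      out_f <- character(0); out_t <- character(0)
      for (i in seq_along(ids)) {
        o <- order(D[i, ], decreasing = TRUE)
        o <- setdiff(o, i)[seq_len(k)]
        out_f <- c(out_f, rep(ids[i], k)); out_t <- c(out_t, ids[o])
      }
      # dedupe unordered duplicates
      key <- paste(pmin(out_f, out_t), pmax(out_f, out_t))
      keep <- !duplicated(key)
      data.frame(from = out_f[keep], to = out_t[keep], type = type)
    }
    k_sim <- max(1L, round(sim_degree / 2))
    edges <- rbind(edges,
                   knn_edges(U, comp, k_sim, "similar"),
                   knn_edges(V, gene, k_sim, "interact"))

    n_spur <- round(spurious_rate * np)
    if (n_spur > 0) {
      avail <- setdiff(seq_len(np), c(bind_idx, pos_idx, neg_idx))
      sp <- idx_pair(sample(avail, min(n_spur, length(avail))))
      edges <- rbind(edges, data.frame(from = sp$c, to = sp$g,
                                       type = "spurious"))
    }

    node_type <- stats::setNames(c(rep("compound", n_compounds),
                                   rep("gene", n_genes)),
                                 c(comp, gene))
    g <- hetero_graph(edges, nodes = c(comp, gene), node_type = node_type)
    pairs <- data.frame(a = c(pp$c, npair$c), b = c(pp$g, npair$g),
                        label = rep(c(1L, 0L), each = n_hold))
    list(graph = g, pairs = pairs,
         latent_scores = list(positive = mean(S[pos_idx]),
                              negative = mean(S[neg_idx])))
  })
}

#' Hold out within-class edges as a labeled pair set
#'
#' Builds a link-prediction benchmark from a node-labeled graph: a random
#' fraction of within-class edges is removed from the graph and returned
#' as positive pairs, together with an equal number of cross-class
#' non-adjacent node pairs as negatives. The held-out pairs are absent
#' from the returned graph, mirroring bioactivity ground-truth pairs that
#' do not occur in the training network.
#'
#' @param g a `hetero_graph`.
#' @param labels named character vector of node class labels.
#' @param frac fraction of within-class edges to hold out (default 0.15).
#' @param seed integer seed.
#' @return list with `graph` (the reduced graph, same node set and
#'   vocabulary) and `pairs` (data frame `a`, `b`, `label`).
#' @export
holdout_within_edges <- function(g, labels, frac = 0.15, seed = 1L) {
  stopifnot(frac > 0, frac < 1)
  e <- g$edges
  cls <- labels[g$nodes]
  within <- which(cls[e$from] == cls[e$to])
  if (length(within) < 2L) stop2("graph has too few within-class edges")
  with_seed(seed, {
    hold <- sample(within, max(1L, round(frac * length(within))))
    keep <- setdiff(seq_len(nrow(e)), hold)
    g2 <- hetero_graph(
      data.frame(from = g$nodes[e$from[keep]], to = g$nodes[e$to[keep]],
                 type = g$edge_types[e$type[keep]], weight = e$weight[keep]),
      nodes = g$nodes, node_type = g$node_type)
    if (length(g2$edge_types) < length(g$edge_types))
      g2$edge_types <- c(g2$edge_types,
                         setdiff(g$edge_types, g2$edge_types))
    neg <- t(vapply(seq_along(hold), function(i) {
      repeat {
        x <- sample(g$nodes, 2L)
        if (cls[x[1]] != cls[x[2]]) return(x)
      }
    }, character(2)))
    pairs <- data.frame(a = c(g$nodes[e$from[hold]], neg[, 1]),
                        b = c(g$nodes[e$to[hold]], neg[, 2]),
                        label = rep(c(1L, 0L), each = length(hold)))
    list(graph = g2, pairs = pairs)
  })
}
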