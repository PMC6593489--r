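#' Macro-averaged classification metrics
#'
#' Precision, recall and F1 are computed per class and macro-averaged; a
#' class never predicted has per-class precision 0 (and F1 0). Hamming
#' loss for single-label classification is the fraction of incorrectly
#' predicted labels, i.e. `1 - accuracy`.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param levels class labels to average over; defaults to the union of
#'   labels seen.
#' @return list with `precision`, `recall`, `f1`, `hamming_loss`.
#' @export
classification_metrics <- function(y_true, y_pred, levels = NULL) {
  if (!length(y_true)) stop2("empty input")
  if (length(y_true) != length(y_pred)) stop2("label vectors differ in length")
  levels <- levels %||% sort(unique(c(as.character(y_true),
                                      as.character(y_pred))))
  yt <- factor(as.character(y_true), levels = levels)
  yp <- factor(as.character(y_pred), levels = levels)
  cm <- table(truth = yt, pred = yp)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(precision = mean(prec), recall = mean(rec), f1 = mean(f1),
       hamming_loss = mean(yt != yp))
}

make_folds <- function(n, folds, seed) {
  with_seed(seed, sample(rep_len(seq_len(folds), n)))
}

#' Node multi-class classification evaluation
#'
#' The entity-classification protocol: nodes with known type labels are
#' balanced by downsampling every class to the size of the smallest, a
#' linear support-vector machine is cross-validated on the embedding
#' features, and macro precision/recall/F1 plus Hamming loss are reported.
#' For a balanced task with C classes a random classifier scores precision
#' 1/C (0.1 for the ten-type knowledge-graph benchmark).
#'
#' @param emb embedding matrix, node ids as row names.
#' @param labels named character/factor vector mapping node ids to class
#'   labels (or a two-column data frame `node`, `class`).
#' @param folds cross-validation folds (default 10).
#' @param balance downsample classes to equal size (default `TRUE`).
#' @param degree_features optional matrix of per-edge-type degree counts
#'   (node ids as row names) concatenated to the features — the
#'   augmentation used for homogeneous baselines, off by default.
#' @param seed integer seed for balancing and fold assignment.
#' @return An `eval_report` list: the metrics of
#'   [classification_metrics()] plus `n` and `folds`.
#' @export
node_classification_task <- function(emb, labels, folds = 10,
                                     balance = TRUE, degree_features = NULL,
                                     seed = 1L) {
  if (is.data.frame(labels))
    labels <- stats::setNames(as.character(labels[[2]]),
                              as.character(labels[[1]]))
  labels <- labels[names(labels) %in% rownames(emb)]
  if (!length(labels)) stop2("no labeled node has an embedding")
  if (balance) {
    counts <- table(labels)
    k <- min(counts)
    keep <- with_seed(seed, unlist(lapply(names(counts), function(cl) {
      ids <- names(labels)[labels == cl]
      sample(ids, k)
    })))
    labels <- labels[keep]
  }
  y <- factor(as.character(labels))
  if (any(table(y) < folds))
    stop2("every class needs at least `folds` members")
  X <- emb[names(labels), , drop = FALSE]
  if (!is.null(degree_features))
    X <- cbind(X, degree_features[names(labels), , drop = FALSE])
  fold <- make_folds(length(y), folds, derive_seed(seed, 17L))
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- e1071::svm(x = X[tr, , drop = FALSE], y = y[tr],
                      kernel = "linear", scale = FALSE)
    pred[!tr] <- stats::predict(fit, X[!tr, , drop = FALSE])
  }
  met <- classification_metrics(y, pred, levels = levels(y))
  structure(c(met, list(n = length(y), folds = folds, task = "classify")),
            class = "eval_report")
}

#' Pairwise link (bioactivity) prediction evaluation
#'
#' The compound-gene bioactivity protocol: each labeled pair is featurized
#' as the element-wise difference of the two node embeddings, a logistic
#' regression classifier is cross-validated, pairs scoring above
#' `threshold` are called positive, and macro classification metrics plus
#' AUROC are reported. Balanced random scores give accuracy 0.5.
#'
#' @param emb embedding matrix, node ids as row names.
#' @param pairs data frame with columns `a`, `b` (node ids) and `label`
#'   (0/1 or "negative"/"positive"); both classes must be present.
#' @param feature `"difference"` for the signed difference `f_a - f_b`
#'   (default) or `"absdiff"` for its absolute value (order-invariant).
#' @param folds cross-validation folds (default 10).
#' @param threshold positive-call threshold on the predicted probability
#'   (default 0.5).
#' @param seed integer seed for fold assignment.
#' @return An `eval_report` with `precision`, `recall`, `f1`,
#'   `hamming_loss`, `AUROC`, `roc` (curve points) and `scores`.
#' @export
link_prediction_task <- function(emb, pairs, feature = c("difference",
                                                         "absdiff"),
                                 folds = 10, threshold = 0.5, seed = 1L) {
  feature <- match.arg(feature)
  stopifnot(is.data.frame(pairs), ncol(pairs) >= 3)
  a <- as.character(pairs[[1]]); b <- as.character(pairs[[2]])
  lab <- pairs[[3]]
  if (!is.numeric(lab)) lab <- as.integer(as.character(lab) %in%
                                            c("1", "positive", "pos", "TRUE"))
  lab <- as.integer(lab)
  if (length(unique(lab)) < 2L) stop2("pairs contain a single class")
  ok <- a %in% rownames(emb) & b %in% rownames(emb)
  if (!all(ok)) {
    warning(sum(!ok), " pair(s) dropped: missing embeddings")
    a <- a[ok]; b <- b[ok]; lab <- lab[ok]
  }
  X <- emb[a, , drop = FALSE] - emb[b, , drop = FALSE]
  if (feature == "absdiff") X <- abs(X)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  fold <- make_folds(length(lab), folds, derive_seed(seed, 29L))
  score <- numeric(length(lab))
  df <- as.data.frame(X)
  df$y <- lab
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- suppressWarnings(stats::glm(y ~ ., data = df[tr, ],
                                       family = stats::binomial()))
    score[!tr] <- suppressWarnings(
      stats::predict(fit, df[!tr, , drop = FALSE], type = "response"))
  }
  pred <- as.integer(score > threshold)
  met <- classification_metrics(lab, pred, levels = c("0", "1"))
  roc <- pROC::roc(response = lab, predictor = score, quiet = TRUE,
                   levels = c(0, 1), direction = "<")
  structure(c(met, list(AUROC = as.numeric(pROC::auc(roc)),
                        roc = data.frame(fpr = 1 - roc$specificities,
                                         tpr = roc$sensitivities),
                        scores = score, n = length(lab),
                        task = "linkpred")),
            class = "eval_report")
}

#' Ranking-quality metrics
#'
#' Information-retrieval metrics over a set of ranked queries with binary
#' relevance: precision and recall at each cutoff in `K`, mean average
#' precision (MAP), normalized discounted cumulative gain (NDCG, binary
#' gains, log2 discount from rank 2, normalized by the ideal ranking) and
#' mean reciprocal rank (MRR, inverse rank of the first relevant hit).
#'
#' @param queries list; each element a list with `ranking` (character
#'   vector of candidate ids, best first) and `relevant` (non-empty
#'   character vector).
#' @param K integer cutoffs (default `c(10, 100)`). A cutoff beyond the
#'   ranking length is computed over the available prefix with a warning.
#' @return named list: `P@K`/`R@K` per cutoff, `MAP`, `NDCG`, `MRR`.
#' @export
ranking_metrics <- function(queries, K = c(10, 100)) {
  if (!length(queries)) stop2("no queries")
  per_q <- lapply(queries, function(q) {
    rk <- as.character(q$ranking)
    rel <- unique(as.character(q$relevant))
    if (!length(rk)) stop2("empty ranking")
    if (!length(rel)) stop2("empty relevant set")
    hit <- rk %in% rel
    pk <- vapply(K, function(k) {
      if (k > length(rk)) {
        warning("cutoff ", k, " exceeds ranking length ", length(rk),
                "; using full ranking")
        k <- length(rk)
      }
      mean(hit[seq_len(k)])
    }, 0)
    rkk <- vapply(K, function(k) {
      k <- min(k, length(rk))
      sum(hit[seq_len(k)]) / length(rel)
    }, 0)
    # average precision over the relevant items (denominator = |relevant|)
    cum_hits <- cumsum(hit)
    ap <- if (any(hit))
      sum((cum_hits / seq_along(hit))[hit]) / length(rel)
    else 0
    dcg <- sum(hit / log2(seq_along(hit) + 1))
    n_ideal <- min(length(rel), length(rk))
    idcg <- sum(1 / log2(seq_len(n_ideal) + 1))
    ndcg <- if (idcg > 0) dcg / idcg else 0
    rr <- if (any(hit)) 1 / which(hit)[1] else 0
    c(pk, rkk, ap = ap, ndcg = ndcg, rr = rr)
  })
  agg <- Reduce(`+`, per_q) / length(per_q)
  nk <- length(K)
  out <- c(as.list(agg[seq_len(nk)]), as.list(agg[nk + seq_len(nk)]),
           list(agg[["ap"]], agg[["ndcg"]], agg[["rr"]]))
  names(out) <- c(paste0("P@", K), paste0("R@", K), "MAP", "NDCG", "MRR")
  out
}

#' Cosine-similarity search-ranking evaluation
#'
#' The compound-gene search protocol: for each query node the `top_k` most
#' cosine-similar other nodes are retrieved (ties broken by node-id order)
#' and scored against its relevant set with [ranking_metrics()]. Queries
#' without an embedding are skipped with a warning and reported.
#'
#' @param emb embedding matrix, node ids as row names.
#' @param query_nodes character vector of query node ids.
#' @param relevant_map named list mapping each query id to its non-empty
#'   relevant node-id set.
#' @param top_k ranking depth (default 100).
#' @param K metric cutoffs (default `c(10, 100)`), capped at `top_k`.
#' @return An `eval_report` with the ranking metrics, `n_queries` and
#'   `skipped`.
#' @export
search_ranking_task <- function(emb, query_nodes, relevant_map,
                                top_k = 100, K = c(10, 100)) {
  query_nodes <- as.character(query_nodes)
  missing <- setdiff(query_nodes, rownames(emb))
  if (length(missing)) {
    warning("skipping ", length(missing), " query node(s) without embeddings")
    query_nodes <- setdiff(query_nodes, missing)
  }
  if (!length(query_nodes)) stop2("no usable query nodes")
  K <- pmin(K, top_k)
  ranked <- rank_by_cosine(emb, query_nodes, top_k = top_k)
  queries <- lapply(query_nodes, function(qn) {
    rel <- relevant_map[[qn]]
    if (is.null(rel) || !length(rel)) stop2("query ", qn,
                                            " has an empty relevant set")
    list(ranking = ranked[[qn]]$node, relevant = rel)
  })
  met <- ranking_metrics(queries, K = K)
  structure(c(met, list(n_queries = length(query_nodes),
                        skipped = missing, task = "rank")),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation report (", x$task %||% "metrics", ")\n", sep = "")
  skip <- c("roc", "scores", "task", "skipped")
  for (nm in setdiff(names(x), skip)) {
    v <- x[[nm]]
    if (is.numeric(v) && length(v) == 1)
      cat(sprintf("  %-14s %.4f\n", nm, v))
  }
  invisible(x)
}

#' Read node labels / labeled pairs; write a metric report
#'
#' `read_node_labels` reads a TSV of `node_id<TAB>class`;
#' `read_pair_labels` reads `node_a<TAB>node_b<TAB>label` with label in
#' `{0, 1}` (the positive/negative ground-truth pair dialect);
#' `write_eval_report` serializes an `eval_report` to JSON with the metric
#' names as keys.
#'
#' @param path file path.
#' @return labels as a named character vector; pairs as a data frame
#'   `a, b, label`.
#' @export
read_node_labels <- function(path) {
  if (!file.exists(path)) stop2("file does not exist: ", path)
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("node", "class"),
                         colClasses = "character", quote = "")
  stats::setNames(d$class, d$node)
}

#' @rdname read_node_labels
#' @export
read_pair_labels <- function(path) {
  if (!file.exists(path)) stop2("file does not exist: ", path)
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("a", "b", "label"), quote = "",
                         colClasses = c("character", "character", "integer"))
  d
}

#' @rdname read_node_labels
#' @param report an `eval_report`.
#' @export
write_eval_report <- function(report, path) {
  keep <- vapply(report, function(v) is.numeric(v) && length(v) == 1,
                 logical(1))
  jsonlite::write_json(as.list(report[keep]), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
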