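test_that("macro classification metrics match hand-computed confusion matrix", {
  # confusion matrix (rows truth, cols pred): [[2,1,0],[0,2,0],[0,0,2]]
  y_true <- c("A", "A", "A", "B", "B", "C", "C")
  y_pred <- c("A", "A", "B", "B", "B", "C", "C")
  m <- classification_metrics(y_true, y_pred)
  expect_equal(m$precision, mean(c(2 / 2, 2 / 3, 2 / 2)))
  expect_equal(m$recall, mean(c(2 / 3, 2 / 2, 2 / 2)))
  f1A <- 2 * 1 * (2 / 3) / (1 + 2 / 3)
  expect_equal(m$f1, mean(c(f1A, f1A, 1)))
  expect_equal(m$hamming_loss, 1 / 7)
})

test_that("perfect and degenerate predictions hit the metric boundaries", {
  y <- rep(c("x", "y"), 5)
  perfect <- classification_metrics(y, y)
  expect_equal(unlist(perfect[c("precision", "recall", "f1")]),
               c(precision = 1, recall = 1, f1 = 1))
  expect_equal(perfect$hamming_loss, 0)
  # 2 wrong out of 10 -> hamming 0.2; hamming = 1 - accuracy
  y_pred <- y; y_pred[c(1, 4)] <- c("y", "x")
  m <- classification_metrics(y, y_pred)
  expect_equal(m$hamming_loss, 0.2)
  # class never predicted gets precision 0, not NaN
  m2 <- classification_metrics(c("a", "b"), c("a", "a"))
  expect_equal(m2$precision, mean(c(1 / 2, 0)))
  expect_error(classification_metrics(character(0), character(0)), "empty")
})

test_that("all classification metrics stay within [0, 1]", {
  set.seed(21)
  for (rep in 1:10) {
    y1 <- sample(letters[1:4], 40, replace = TRUE)
    y2 <- sample(letters[1:4], 40, replace = TRUE)
    m <- unlist(classification_metrics(y1, y2))
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("one-hot class embeddings classify perfectly", {
  classes <- rep(c("c1", "c2", "c3"), each = 12)
  ids <- paste0("n", seq_along(classes))
  emb <- diag(3)[match(classes, c("c1", "c2", "c3")), ]
  rownames(emb) <- ids
  rep <- node_classification_task(emb, stats::setNames(classes, ids),
                                  folds = 3, seed = 1)
  expect_equal(rep$f1, 1)
  expect_equal(rep$hamming_loss, 0)
})

test_that("classification task enforces fold feasibility and balance", {
  ids <- paste0("n", 1:12)
  emb <- matrix(stats::rnorm(24), 12, dimnames = list(ids, NULL))
  labels <- stats::setNames(rep(c("a", "b"), c(9, 3)), ids)
  expect_error(node_classification_task(emb, labels, folds = 10), "folds")
  rep <- node_classification_task(emb, labels, folds = 3, seed = 1)
  expect_equal(rep$n, 6L)  # balanced to 3 per class
})

test_that("degree features can augment the classifier input", {
  classes <- rep(c("u", "v"), each = 10)
  ids <- paste0("n", 1:20)
  emb <- matrix(0, 20, 2, dimnames = list(ids, NULL))  # useless embedding
  deg <- matrix(rep(c(5, 0), each = 10), 20,
                dimnames = list(ids, NULL))             # informative degrees
  rep <- node_classification_task(emb + stats::rnorm(40, sd = 1e-3),
                                  stats::setNames(classes, ids),
                                  folds = 5, degree_features = deg,
                                  seed = 2)
  expect_equal(rep$f1, 1)
})

test_that("link prediction achieves AUROC 1 on separable difference features", {
  n <- 30
  emb <- rbind(matrix(1, n, 4), matrix(0, 2 * n, 4),
               matrix(-1, n, 4))
  rownames(emb) <- paste0("n", seq_len(nrow(emb)))
  pairs <- data.frame(a = paste0("n", c(1:n, (3 * n + 1):(4 * n))),
                      b = paste0("n", c((n + 1):(2 * n), (2 * n + 1):(3 * n))),
                      label = rep(c(1L, 0L), each = n))
  rep <- link_prediction_task(emb, pairs, folds = 5, seed = 1)
  expect_equal(rep$AUROC, 1)
  expect_equal(rep$f1, 1)
  expect_true(all(rep$roc$tpr >= 0 & rep$roc$tpr <= 1))
})

test_that("random difference features give chance-level link prediction", {
  set.seed(31)
  emb <- matrix(stats::rnorm(400 * 8), 400,
                dimnames = list(paste0("n", 1:400), NULL))
  pairs <- data.frame(a = paste0("n", 1:200),
                      b = paste0("n", 201:400),
                      label = rep(c(1L, 0L), 100))
  rep <- link_prediction_task(emb, pairs, folds = 5, seed = 2)
  expect_lt(abs(rep$AUROC - 0.5), 0.12)
  expect_lt(abs(rep$hamming_loss - 0.5), 0.12)
  expect_error(link_prediction_task(emb, transform(pairs, label = 1L)),
               "single class")
})

test_that("ranking metrics reproduce direct arithmetic on a worked example", {
  # ranking [rel, non, rel] with 2 relevant items
  q <- list(list(ranking = c("r1", "x", "r2"), relevant = c("r1", "r2")))
  m <- ranking_metrics(q, K = c(3))
  expect_equal(m$MAP, (1 / 1 + 2 / 3) / 2)
  expect_equal(m$NDCG, (1 + 1 / log2(4)) / (1 + 1 / log2(3)))
  expect_equal(round(m$MAP, 4), 0.8333)
  expect_equal(round(m$NDCG, 4), 0.9197)
  expect_equal(m$MRR, 1)
  expect_equal(m$`P@3`, 2 / 3)
  expect_equal(m$`R@3`, 1)
})

test_that("ranking metrics match brute-force definitions on random cases", {
  brute <- function(rk, rel, k) {
    hit <- rk %in% rel
    ap <- 0; seen <- 0
    for (i in seq_along(rk)) if (hit[i]) {
      seen <- seen + 1; ap <- ap + seen / i
    }
    ap <- ap / length(rel)
    dcg <- 0
    for (i in seq_along(rk)) if (hit[i]) dcg <- dcg + 1 / log2(i + 1)
    idcg <- sum(1 / log2(seq_len(min(length(rel), length(rk))) + 1))
    rr <- 0
    for (i in seq_along(rk)) if (hit[i]) { rr <- 1 / i; break }
    c(p = sum(hit[seq_len(k)]) / k, r = sum(hit[seq_len(k)]) / length(rel),
      map = ap, ndcg = dcg / idcg, mrr = rr)
  }
  set.seed(17)
  for (rep in 1:20) {
    items <- paste0("i", 1:10)
    rk <- sample(items, sample(4:10, 1))
    rel <- sample(items, sample(1:5, 1))
    k <- sample(2:4, 1)
    m <- ranking_metrics(list(list(ranking = rk, relevant = rel)), K = k)
    b <- brute(rk, rel, k)
    expect_equal(m[[paste0("P@", k)]], unname(b["p"]))
    expect_equal(m[[paste0("R@", k)]], unname(b["r"]))
    expect_equal(m$MAP, unname(b["map"]))
    expect_equal(m$NDCG, unname(b["ndcg"]))
    expect_equal(m$MRR, unname(b["mrr"]))
  }
})

test_that("ranking metrics respect invariances and demotion monotonicity", {
  q1 <- list(list(ranking = c("a", "b", "c", "d"), relevant = c("b")))
  relab <- list(list(ranking = c("z9", "z1", "z5", "z2"), relevant = "z1"))
  expect_equal(ranking_metrics(q1, K = 2), ranking_metrics(relab, K = 2))
  demoted <- list(list(ranking = c("a", "c", "b", "d"), relevant = "b"))
  for (metric in c("MAP", "NDCG", "MRR"))
    expect_gte(ranking_metrics(q1, K = 2)[[metric]],
               ranking_metrics(demoted, K = 2)[[metric]])
  # first relevant at rank 1 for every query -> MRR 1; 3 of top 10 -> P@10
  q2 <- list(list(ranking = paste0("i", 1:10),
                  relevant = c("i1", "i5", "i9")))
  m <- ranking_metrics(q2, K = 10)
  expect_equal(m$MRR, 1)
  expect_equal(m$`P@10`, 0.3)
  expect_warning(ranking_metrics(q2, K = 50), "exceeds")
})

test_that("cosine search ranking finds planted nearest neighbors", {
  base <- diag(4)
  emb <- rbind(q = base[1, ], hit = base[1, ] * 2,
               far1 = base[2, ], far2 = base[3, ], far3 = base[4, ])
  rep <- search_ranking_task(emb, "q", list(q = "hit"), top_k = 4)
  expect_equal(rep$MRR, 1)  # nearest by cosine is the relevant node
  expect_warning(
    rep2 <- search_ranking_task(emb, c("q", "ghost"), list(q = "hit"),
                                top_k = 4),
    "skipping")
  expect_equal(rep2$skipped, "ghost")
})

test_that("tied cosine scores break deterministically by node id", {
  emb <- matrix(1, 5, 3, dimnames = list(c("e", "c", "a", "d", "b"), NULL))
  r1 <- rank_by_cosine <- predict(
    structure(list(embedding = emb), class = "edge2vec"),
    newdata = "c", type = "rank", top_k = 4)
  expect_equal(r1$c$node, c("a", "b", "d", "e"))
  rep1 <- search_ranking_task(emb, "c", list(c = "b"), top_k = 4)
  rep2 <- search_ranking_task(emb, "c", list(c = "b"), top_k = 4)
  expect_identical(rep1[c("MAP", "NDCG", "MRR")],
                   rep2[c("MAP", "NDCG", "MRR")])
})

test_that("label and pair files read back and reports serialize to JSON", {
  lf <- write_tmp(c("n1\tgene", "n2\tcompound"))
  labs <- read_node_labels(lf)
  expect_equal(labs, c(n1 = "gene", n2 = "compound"))
  pf <- write_tmp(c("c1\tg1\t1", "c2\tg2\t0"))
  pr <- read_pair_labels(pf)
  expect_equal(pr$label, c(1L, 0L))
  rep <- structure(list(precision = 0.5, f1 = 0.25, task = "classify"),
                   class = "eval_report")
  out <- tempfile(fileext = ".json")
  write_eval_report(rep, out)
  got <- jsonlite::read_json(out)
  expect_equal(got$precision, 0.5)
  expect_null(got$task)
})
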