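test_that("context pairs enumerate the sliding window", {
  corp <- structure(list(nodes = list(c(5L, 7L, 9L)),
                         types = list(c(1L, 1L)),
                         node_ids = paste0("n", 1:9),
                         edge_types = "a"),
                    class = "walk_corpus")
  p1 <- build_context_pairs(corp, window = 1)
  got <- paste(p1$center, p1$context)
  expect_setequal(got, c("5 7", "7 5", "7 9", "9 7"))
  expect_equal(nrow(build_context_pairs(corp, window = 2)), 6L)
  # length-1 walks contribute nothing
  corp$nodes <- list(3L); corp$types <- list(integer(0))
  expect_equal(nrow(build_context_pairs(corp, window = 2)), 0L)
  expect_error(build_context_pairs(corp, window = 0), "window")
})

test_that("sigmoid is a proper logistic with overflow protection", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(1), 0.7310586, tolerance = 1e-7)
  x <- c(-3.2, 0.7, 12)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, 3), tolerance = 1e-12)
  expect_true(is.finite(sigmoid(1e6)) && is.finite(sigmoid(-1e6)))
  expect_true(all(diff(sigmoid(seq(-10, 10, 0.5))) > 0))
})

test_that("negative sampling excludes the context and matches the uniform law", {
  draws <- unlist(lapply(1:3500, function(i)
    sample_negatives(context = 1L, k = 3, n = 4, seed = i)))
  expect_false(any(draws == 1L))
  p <- 1 / 3
  se <- sqrt(p * (1 - p) / length(draws))
  for (node in 2:4)
    expect_lt(abs(mean(draws == node) - p), 3 * se)
  expect_error(sample_negatives(1L, k = 0, n = 5), "positive integer")
  expect_error(sample_negatives(1L, k = 5, n = 5), "smaller")
  expect_identical(sample_negatives(2L, 4, 50, seed = 3),
                   sample_negatives(2L, 4, 50, seed = 3))
})

test_that("analytic gradient matches central differences", {
  # the core correctness property of the trainer's update rule
  set.seed(99)
  h <- 1e-5
  for (rep in 1:100) {
    d <- sample(2:8, 1)
    k <- sample(1:5, 1)
    f_v <- stats::rnorm(d); f_t <- stats::rnorm(d)
    F_neg <- matrix(stats::rnorm(k * d), k)
    g <- sgns_gradient(f_v, f_t, F_neg)
    num <- function(fn) {
      vapply(seq_len(d), function(i) {
        e <- numeric(d); e[i] <- h
        (fn(e) - fn(-e)) / (2 * h)
      }, 0)
    }
    gv <- num(function(e) sgns_objective(f_v + e, f_t, F_neg))
    gt <- num(function(e) sgns_objective(f_v, f_t + e, F_neg))
    expect_lt(max(abs(gv - g$v)) / max(abs(g$v), 1e-8), 1e-5)
    expect_lt(max(abs(gt - g$t)) / max(abs(g$t), 1e-8), 1e-5)
    for (j in seq_len(k)) {
      gn <- num(function(e) {
        Fp <- F_neg; Fp[j, ] <- Fp[j, ] + e
        sgns_objective(f_v, f_t, Fp)
      })
      expect_lt(max(abs(gn - g$neg[j, ])) / max(abs(g$neg[j, ]), 1e-8),
                1e-5)
    }
  }
})

test_that("a small-step update does not decrease the objective", {
  set.seed(3)
  model <- list(input = matrix(stats::rnorm(10 * 4), 10),
                output = matrix(stats::rnorm(10 * 4), 10))
  obj <- function(m) sgns_objective(m$input[2, ], m$output[5, ],
                                    m$output[c(7, 9), , drop = FALSE])
  before <- obj(model)
  after <- obj(sgd_step(model, 2L, 5L, c(7L, 9L), lr = 1e-3))
  expect_gte(after, before)
  # lr = 0 leaves the model unchanged
  expect_identical(sgd_step(model, 2L, 5L, c(7L, 9L), lr = 0), model)
})

test_that("training separates disjoint cliques and is seed-reproducible", {
  g <- two_cliques(8)
  corp <- generate_walks(g, walks_per_node = 5, walk_length = 15,
                         p = 1, q = 1, seed = 2)
  emb <- train_embeddings(corp, dimensions = 16, epochs = 3, seed = 4)
  expect_equal(dim(emb), c(16L, 16L))
  expect_identical(emb,
                   train_embeddings(corp, dimensions = 16, epochs = 3,
                                    seed = 4))
  unit <- emb / sqrt(rowSums(emb^2))
  S <- unit %*% t(unit)
  grp <- substr(rownames(emb), 1, 1)
  same <- outer(grp, grp, "==") & row(S) != col(S)
  expect_gt(mean(S[same]), mean(S[!same & row(S) != col(S)]))
})

test_that("barbell hubs end up farther apart than within-bell pairs", {
  gaps <- vapply(1:5, function(s) {
    g <- barbell_graph(6)
    corp <- generate_walks(g, walks_per_node = 8, walk_length = 12,
                           p = 1, q = 1, seed = s)
    emb <- train_embeddings(corp, dimensions = 12, epochs = 3, seed = s)
    dist_ab <- sqrt(sum((emb["a1", ] - emb["b1", ])^2))
    within <- utils::combn(paste0("a", 1:6), 2)
    d_within <- mean(apply(within, 2, function(pr)
      sqrt(sum((emb[pr[1], ] - emb[pr[2], ])^2))))
    dist_ab - d_within
  }, 0)
  expect_gt(mean(gaps), 0)
})

test_that("tiny embedding jobs run end to end", {
  g <- path_graph(6)
  corp <- generate_walks(g, walks_per_node = 2, walk_length = 5, seed = 1)
  emb <- train_embeddings(corp, dimensions = 2, epochs = 1, seed = 1)
  expect_equal(dim(emb), c(6L, 2L))
  expect_true(all(is.finite(emb)))
  expect_error(train_embeddings(structure(list(nodes = list(),
                                               types = list(),
                                               node_ids = "a",
                                               edge_types = "e"),
                                          class = "walk_corpus"),
                                dimensions = 2), "empty")
})

test_that("softmax probability is a proper distribution monotone in inner product", {
  set.seed(5)
  emb <- matrix(stats::rnorm(5 * 3), 5,
                dimnames = list(paste0("n", 1:5), NULL))
  probs <- vapply(1:5, function(v) softmax_probability(emb, 2L, v), 0)
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  ip <- as.numeric(emb %*% emb[2, ])
  expect_equal(order(probs), order(ip))
  zero <- matrix(0, 4, 2, dimnames = list(letters[1:4], NULL))
  expect_equal(softmax_probability(zero, "a", "c"), 0.25)
})

test_that("embeddings round-trip through word2vec text format", {
  set.seed(6)
  emb <- matrix(stats::rnorm(12), 4,
                dimnames = list(c("g1", "c2", "x3", "y4"), NULL))
  f <- tempfile()
  write_embeddings(emb, f)
  got <- read_embeddings(f)
  expect_equal(got, emb, tolerance = 1e-15)
  expect_equal(readLines(f)[1], "4 3")
})

test_that("unigram negative distribution follows corpus frequency", {
  corp <- structure(list(nodes = list(rep(1:3, c(8, 3, 1))),
                         types = list(integer(11)),
                         node_ids = paste0("n", 1:4), edge_types = "a"),
                    class = "walk_corpus")
  emb <- train_embeddings(corp, dimensions = 4, epochs = 1,
                          neg_dist = "unigram75", negative = 2, seed = 1)
  expect_equal(dim(emb), c(4L, 4L))  # smoke: runs with weighted sampler
})
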