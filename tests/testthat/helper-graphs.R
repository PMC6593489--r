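# Shared fixture builders. All fixtures are constructed in code.

path_graph <- function(n = 3, type = "e") {
  ids <- paste0("p", seq_len(n))
  hetero_graph(data.frame(from = ids[-n], to = ids[-1], type = type))
}

# Star around v with a typed side edge: u--v (a), v--x (b), v--y (a),
# y--u (a). From prev = u at cur = v the three candidates sit at
# distances 0 (u), 2 (x) and 1 (y) from u.
star_graph <- function() {
  hetero_graph(data.frame(
    from = c("v", "v", "v", "y"),
    to = c("u", "x", "y", "u"),
    type = c("a", "b", "a", "a")
  ))
}

clique_edges <- function(members, type = "e") {
  cmb <- t(utils::combn(members, 2))
  data.frame(from = cmb[, 1], to = cmb[, 2], type = type)
}

two_cliques <- function(size = 10) {
  a <- paste0("a", seq_len(size))
  b <- paste0("b", seq_len(size))
  hetero_graph(rbind(clique_edges(a), clique_edges(b)))
}

# Two cliques joined by a single bridge edge between their first members.
barbell_graph <- function(size = 6) {
  a <- paste0("a", seq_len(size))
  b <- paste0("b", seq_len(size))
  hetero_graph(rbind(clique_edges(a), clique_edges(b),
                     data.frame(from = a[1], to = b[1], type = "e")))
}

# Random connected-ish weighted homogeneous graph for enumeration tests.
random_small_graph <- function(n = 8, p_edge = 0.5, seed = 1) {
  set.seed(seed)
  repeat {
    cmb <- t(utils::combn(seq_len(n), 2))
    keep <- stats::runif(nrow(cmb)) < p_edge
    if (sum(keep) >= n) break
  }
  ids <- paste0("r", seq_len(n))
  hetero_graph(data.frame(from = ids[cmb[keep, 1]], to = ids[cmb[keep, 2]],
                          type = "e",
                          weight = round(stats::runif(sum(keep), 0.5, 3), 2)),
               nodes = ids)
}

write_tmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

# Walk-corpus validity: every consecutive node pair must be joined by an
# edge of the recorded type.
expect_valid_corpus <- function(corpus, g) {
  e <- g$edges
  key <- c(paste(e$from, e$to, e$type), paste(e$to, e$from, e$type))
  for (i in seq_along(corpus$nodes)) {
    w <- corpus$nodes[[i]]
    tt <- corpus$types[[i]]
    expect_equal(length(tt), length(w) - 1L)
    if (length(tt))
      expect_true(all(paste(w[-length(w)], w[-1], tt) %in% key))
  }
  invisible(TRUE)
}
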