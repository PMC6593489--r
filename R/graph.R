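#' Construct a heterogeneous graph
#'
#' A heterogeneous graph is a set of nodes joined by typed, weighted edges.
#' Edge types come from a finite vocabulary of `m` labels mapped to the
#' contiguous integer ids `1..m`; parallel edges between the same node pair
#' with different (or equal) types are retained as distinct records. This is
#' the data model for knowledge graphs such as drug-discovery networks in
#' which, say, genes and compounds are linked by "bind", "expression" or
#' "has pathway" relations.
#'
#' @param edges data frame with columns `from`, `to` (character node ids),
#'   `type` (character edge-type label) and optionally `weight` (positive
#'   numeric, default 1).
#' @param nodes optional character vector of node ids; defaults to all ids
#'   appearing in `edges`. Extra ids create isolated nodes.
#' @param node_type optional named character vector mapping node ids to node
#'   type labels (used by evaluation tasks, never by the walk itself).
#' @param directed logical; undirected by default, in which case every edge
#'   is traversable from both endpoints and counted once in edge totals.
#' @return An object of class `hetero_graph` with components `nodes`,
#'   `node_type`, `edges` (integer-indexed), `edge_types` (the vocabulary)
#'   and `adj` (per-node incident edge index lists).
#' @examples
#' g <- hetero_graph(data.frame(from = c("a", "b"), to = c("b", "c"),
#'                              type = c("binds", "regulates")))
#' g
#' @export
hetero_graph <- function(edges, nodes = NULL, node_type = NULL,
                         directed = FALSE) {
  stopifnot(is.data.frame(edges))
  need <- c("from", "to", "type")
  if (!all(need %in% names(edges)))
    stop2("`edges` must have columns from, to, type")
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  type <- as.character(edges$type)
  weight <- if ("weight" %in% names(edges)) as.numeric(edges$weight)
            else rep(1, nrow(edges))
  weight[is.na(weight)] <- 1
  if (any(!is.finite(weight) | weight <= 0))
    stop2("edge weights must be positive: offending rows ",
          paste(utils::head(which(!is.finite(weight) | weight <= 0), 5),
                collapse = ", "))

  node_ids <- nodes %||% unique(c(from, to))
  node_ids <- as.character(node_ids)
  if (anyDuplicated(node_ids)) node_ids <- unique(node_ids)
  missing <- setdiff(unique(c(from, to)), node_ids)
  if (length(missing))
    stop2("edge endpoints not in node set: ", paste(missing, collapse = ", "))

  # vocabulary in order of first appearance
  labels <- unique(type)
  e <- data.frame(
    from = match(from, node_ids),
    to = match(to, node_ids),
    type = match(type, labels),
    weight = weight
  )

  adj <- build_adjacency(nrow(e), e$from, e$to, length(node_ids), directed)

  structure(list(
    nodes = node_ids,
    node_type = node_type,
    edges = e,
    edge_types = labels,
    directed = isTRUE(directed),
    adj = adj
  ), class = "hetero_graph")
}

build_adjacency <- function(n_edges, from, to, n_nodes, directed) {
  adj <- vector("list", n_nodes)
  if (n_edges > 0) {
    if (directed) {
      adj_idx <- split(seq_len(n_edges), factor(from, levels = seq_len(n_nodes)))
    } else {
      adj_idx <- split(c(seq_len(n_edges), seq_len(n_edges)),
                       factor(c(from, to), levels = seq_len(n_nodes)))
    }
    for (i in seq_len(n_nodes)) adj[[i]] <- as.integer(adj_idx[[i]])
  } else {
    for (i in seq_len(n_nodes)) adj[[i]] <- integer(0)
  }
  adj
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat(sprintf("Heterogeneous graph: %d nodes, %d edges, %d edge types (%s)\n",
              length(x$nodes), nrow(x$edges), length(x$edge_types),
              if (x$directed) "directed" else "undirected"))
  cat("Edge types:", paste(x$edge_types, collapse = ", "), "\n")
  if (!is.null(x$node_type))
    cat("Node types:", paste(sort(unique(x$node_type)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of nodes / edges / edge types
#'
#' @param g a `hetero_graph`.
#' @return Integer count.
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

#' @rdname n_nodes
#' @export
n_edge_types <- function(g) length(g$edge_types)

node_index <- function(g, v) {
  i <- match(as.character(v), g$nodes)
  if (anyNA(i)) stop2("unknown node id: ", paste(v[is.na(i)], collapse = ", "))
  i
}

#' Incident edges of a node
#'
#' Returns every edge incident to `v` (both orientations when the graph is
#' undirected), in stable insertion order. The neighborhood N(v) over which
#' walk transition probabilities are normalized.
#'
#' @param g a `hetero_graph`.
#' @param v a node id (character) or internal integer index.
#' @return data frame with columns `edge` (edge index), `neighbor` (node id),
#'   `type` (integer edge-type id), `type_label`, `weight`.
#' @export
graph_neighbors <- function(g, v) {
  i <- if (is.character(v)) node_index(g, v) else as.integer(v)
  if (is.na(i) || i < 1L || i > length(g$nodes)) stop2("unknown node: ", v)
  idx <- g$adj[[i]]
  e <- g$edges[idx, , drop = FALSE]
  nb <- ifelse(e$from == i, e$to, e$from)
  data.frame(
    edge = idx,
    neighbor = g$nodes[nb],
    type = e$type,
    type_label = g$edge_types[e$type],
    weight = e$weight,
    row.names = NULL
  )
}

#' Read a typed edge list
#'
#' Reads a CSV/TSV file with columns `source,target,edge_type[,weight]`.
#' Lines starting with `#` are comments. A missing weight column defaults to
#' 1. The edge-type vocabulary is built in file order of first appearance.
#'
#' @param path file path.
#' @param directed logical.
#' @param has_header logical; whether the first non-comment line is a header.
#' @param sep field separator; `","` for CSV (default) or `"\t"` for TSV.
#' @return A [hetero_graph()].
#' @export
read_edge_list <- function(path, directed = FALSE, has_header = FALSE,
                           sep = ",") {
  if (!file.exists(path)) stop2("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (has_header && length(lines)) {
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  if (!length(lines)) stop2("empty edge list: ", path)
  parts <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 3L)
  if (length(bad))
    stop2("malformed row (need >= 3 fields) at line ", lineno[bad[1]],
          " of ", path)
  from <- trimws(vapply(parts, `[`, "", 1L))
  to <- trimws(vapply(parts, `[`, "", 2L))
  type <- trimws(vapply(parts, `[`, "", 3L))
  weight <- rep(1, length(parts))
  has_w <- nf >= 4L
  if (any(has_w)) {
    w <- suppressWarnings(as.numeric(vapply(parts[has_w], `[`, "", 4L)))
    bad <- which(!is.finite(w) | w <= 0)
    if (length(bad))
      stop2("non-positive or unreadable weight at line ",
            lineno[has_w][bad[1]], " of ", path)
    weight[has_w] <- w
  }
  hetero_graph(data.frame(from = from, to = to, type = type, weight = weight),
               directed = directed)
}

#' Write a typed edge list
#'
#' Inverse of [read_edge_list()]; round-trips node count, edge count,
#' vocabulary and weights exactly.
#'
#' @param g a `hetero_graph`.
#' @param path output file path.
#' @param sep field separator.
#' @export
write_edge_list <- function(g, path, sep = ",") {
  e <- g$edges
  lines <- paste(g$nodes[e$from], g$nodes[e$to], g$edge_types[e$type],
                 format(e$weight, digits = 17, scientific = FALSE, trim = TRUE),
                 sep = sep)
  writeLines(lines, path)
  invisible(path)
}

#' Read an RDF-style triple file
#'
#' Parses whitespace-separated `subject predicate object` lines, the dialect
#' used by integrated drug-discovery knowledge graphs distributed as flat
#' triple dumps. Subject and object URIs become nodes, the predicate string
#' becomes the edge-type label. Node types are inferred from a URI path
#' component; edge-type labels are reduced to the final path component.
#'
#' @param path file path.
#' @param directed logical.
#' @param dedup logical; when `TRUE`, duplicate identical triples are
#'   collapsed to a single edge. Default keeps them as parallel edges.
#' @param type_extractor function mapping a URI string to a node-type label;
#'   the default takes the penultimate `/`-separated path component.
#' @return A [hetero_graph()] with `node_type` filled in.
#' @examples
#' f <- tempfile()
#' writeLines("ns/gene/EGFR ns/bind ns/compound/C1", f)
#' g <- read_rdf_triples(f)
#' g$edge_types  # "bind"
#' @export
read_rdf_triples <- function(path, directed = FALSE, dedup = FALSE,
                             type_extractor = uri_penultimate) {
  if (!file.exists(path)) stop2("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop2("empty triple file: ", path)
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop2("triple with ", lengths(parts)[bad[1]], " fields at line ",
          lineno[bad[1]], " of ", path)
  subj <- vapply(parts, `[`, "", 1L)
  pred <- vapply(parts, `[`, "", 2L)
  obj <- vapply(parts, `[`, "", 3L)
  if (dedup) {
    key <- paste(subj, pred, obj, sep = "\r")
    first <- !duplicated(key)
    subj <- subj[first]; pred <- pred[first]; obj <- obj[first]
  }
  pred_label <- vapply(strsplit(pred, "/", fixed = TRUE),
                       function(p) p[length(p)], "")
  nodes <- unique(c(subj, obj))
  ntype <- vapply(nodes, type_extractor, "")
  hetero_graph(data.frame(from = subj, to = obj, type = pred_label),
               nodes = nodes,
               node_type = stats::setNames(ntype, nodes),
               directed = directed)
}

#' @rdname read_rdf_triples
#' @param uri a URI string.
#' @export
uri_penultimate <- function(uri) {
  p <- strsplit(uri, "/", fixed = TRUE)[[1]]
  if (length(p) >= 2L) p[length(p) - 1L] else "unknown"
}
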