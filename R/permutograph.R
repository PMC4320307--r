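#' Permutographs
#'
#' The permutograph of an n-valued system is the graph whose vertices are
#' the n! permutations (identified by lexicographic rank) and whose edges
#' join permutations differing by a single negation operator. It is the
#' Cayley graph of the symmetric group S_n with adjacent-transposition
#' generators: (n-1)-regular, connected, and bipartite by permutation
#' parity. Edges are stored undirected with an operator label; gap
#' junctions, which the operators model, conduct bidirectionally, so
#' direction is a traversal concern, not a storage concern.
#'
#' @name permutograph
NULL

#' Build the permutograph of an n-valued system
#'
#' @param n valuedness, 2..7.
#' @param semantics operator semantics, `"value"` (default) or `"position"`.
#' @return an object of class `permutograph`: a list with `n`, `semantics`,
#'   `perms` (the n! x n lexicographic permutation matrix), `adj` (an
#'   n! x (n-1) matrix; `adj[v, i]` is the rank reached from `v` by
#'   operator i) and `edges` (a data.frame `source_rank`, `target_rank`,
#'   `operator` with `source_rank < target_rank`).
#' @examples
#' g <- build_permutograph(4)
#' nrow(g$edges)  # 36 = 24 * 3 / 2
#' @export
build_permutograph <- function(n, semantics = c("value", "position")) {
  n <- .check_n(n, min_n = 2L, max_n = 7L)
  semantics <- match.arg(semantics)
  perms <- all_permutations(n)
  size <- nrow(perms)
  adj <- matrix(NA_integer_, size, n - 1L)
  for (v in seq_len(size)) {
    for (i in seq_len(n - 1L)) {
      adj[v, i] <- lex_rank(apply_negation(perms[v, ], i, semantics))
    }
  }
  src <- rep(seq_len(size), n - 1L)
  tgt <- as.vector(adj)
  op <- rep(seq_len(n - 1L), each = size)
  keep <- src < tgt
  edges <- data.frame(source_rank = src[keep], target_rank = tgt[keep],
                      operator = op[keep])
  edges <- edges[order(edges$source_rank, edges$target_rank), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(n = n, semantics = semantics, perms = perms, adj = adj,
         edges = edges),
    class = "permutograph"
  )
}

#' @export
print.permutograph <- function(x, ...) {
  cat(sprintf("<permutograph> n = %d (%s-swap): %d vertices, %d labeled edges\n",
              x$n, x$semantics, nrow(x$perms), nrow(x$edges)))
  invisible(x)
}

#' Operator-labeled neighbors of a vertex
#'
#' @param g a `permutograph`.
#' @param v vertex rank in 1..n!.
#' @return a named integer vector of length n-1; entry `"N<i>"` is the rank
#'   reached from `v` by negation operator i.
#' @examples
#' g <- build_permutograph(4)
#' neighbors(g, 1)  # N1 = 7, N2 = 3, N3 = 2
#' @export
neighbors <- function(g, v) UseMethod("neighbors")

#' @export
neighbors.permutograph <- function(g, v) {
  size <- nrow(g$perms)
  if (length(v) != 1L || is.na(v) || v != as.integer(v) || v < 1L || v > size)
    stop(sprintf("unknown vertex rank %s (graph has ranks 1..%d)",
                 format(v), size), call. = FALSE)
  out <- g$adj[as.integer(v), ]
  names(out) <- paste0("N", seq_along(out))
  out
}

#' Convert a permutograph to an igraph object
#'
#' Vertices carry `rank` and `perm` (digit-string) attributes; edges carry
#' the `operator` label.
#'
#' @param g a `permutograph`.
#' @return an undirected [igraph::igraph] graph.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "permutograph"))
  size <- nrow(g$perms)
  ig <- igraph::graph_from_data_frame(
    d = data.frame(from = g$edges$source_rank, to = g$edges$target_rank,
                   operator = g$edges$operator),
    directed = FALSE,
    vertices = data.frame(
      name = as.character(seq_len(size)),
      rank = seq_len(size),
      perm = apply(g$perms, 1L, perm_to_string)
    )
  )
  ig
}

#' Export a permutograph
#'
#' Serializes the graph with permutation strings on vertices and operator
#' labels on edges. GraphML and DOT go through igraph; the CSV edge list
#' has columns `source_rank`, `target_rank`, `operator`.
#'
#' @param g a `permutograph`.
#' @param path output file path.
#' @param format `"graphml"`, `"dot"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("graphml", "dot", "csv")) {
  stopifnot(inherits(g, "permutograph"))
  if (length(format) != 1L || !format %in% c("graphml", "dot", "csv"))
    stop("unknown export format: ", paste(format, collapse = ", "),
         " (supported: graphml, dot, csv)", call. = FALSE)
  if (format == "csv") {
    utils::write.csv(g$edges, path, row.names = FALSE, quote = FALSE)
  } else {
    igraph::write_graph(as_igraph(g), path, format = format)
  }
  invisible(path)
}

#' Re-import an exported permutograph edge list
#'
#' Reads a GraphML file or CSV edge list back into the `(source_rank,
#' target_rank, operator)` edge table, for roundtrip checks.
#'
#' @param path file written by [export_graph()].
#' @param format `"graphml"` or `"csv"`.
#' @return a data.frame with columns `source_rank`, `target_rank`, `operator`.
#' @export
import_edges <- function(path, format = c("graphml", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path)
  } else {
    ig <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_edgelist(ig, names = FALSE)
    rank <- igraph::vertex_attr(ig, "rank")
    df <- data.frame(source_rank = rank[el[, 1L]],
                     target_rank = rank[el[, 2L]],
                     operator = igraph::edge_attr(ig, "operator"))
  }
  df[c("source_rank", "target_rank")] <-
    list(pmin(df$source_rank, df$target_rank),
         pmax(df$source_rank, df$target_rank))
  df <- df[order(df$source_rank, df$target_rank), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Permutation parity
#'
#' Sign of a permutation (+1 even, -1 odd); every permutograph edge joins
#' permutations of opposite parity.
#'
#' @param p a permutation of 1..n.
#' @return +1 or -1.
#' @export
perm_parity <- function(p) {
  p <- validate_permutation(p)
  n <- length(p)
  inv <- 0L
  for (j in seq_len(n - 1L)) inv <- inv + sum(p[(j + 1L):n] < p[j])
  if (inv %% 2L == 0L) 1L else -1L
}
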