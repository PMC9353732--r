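#' Build a weighted, undirected gene-interaction graph
#'
#' Constructs the interaction network used by the graph-convolutional encoder
#' from a table of weighted gene pairs (e.g. functional-association links with
#' log-likelihood-score weights). The graph is undirected: `(a, b, w)` and
#' `(b, a, w)` describe the same edge, and duplicate records for a pair are
#' collapsed to the record with the maximum weight. Node order is
#' first-appearance order in the input, and is preserved in every matrix and
#' report derived from the graph.
#'
#' @param edges A data frame whose first three columns are gene A, gene B and a
#'   strictly positive numeric weight (columns `gene_a`, `gene_b`, `weight` as
#'   returned by [read_edge_list()], or any 3+ column table in that order).
#' @param rescale_weights If `TRUE`, min-max rescale edge weights to (0, 1]
#'   after duplicate collapsing. Raw weights are used by default.
#'
#' @return A `gene_graph` object: a list with `node_ids` (character, in
#'   first-appearance order), `edges` (a tibble with `gene_a`, `gene_b`,
#'   `weight`) and `adjacency` (symmetric numeric matrix with zero diagonal,
#'   dimnames = node ids).
#'
#' @examples
#' g <- build_graph(tibble::tibble(
#'   gene_a = c("g1", "g2"), gene_b = c("g2", "g3"), weight = c(1.5, 2)
#' ))
#' g$adjacency
#' @seealso [prune_isolated()], [normalized_operator()], [graph_laplacian()]
#' @export
build_graph <- function(edges, rescale_weights = FALSE) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 3L || nrow(edges) == 0L) {
    rlang::abort("`edges` needs at least one record with 3 columns (gene_a, gene_b, weight)",
                 class = "gcnprio_shape_error")
  }
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  w <- edges[[3]]
  if (!is.numeric(w)) {
    rlang::abort("edge weights must be numeric", class = "gcnprio_weight_domain_error")
  }
  w <- as.double(w)
  if (any(is.na(a) | is.na(b) | !nzchar(a) | !nzchar(b))) {
    rlang::abort("gene identifiers must be nonempty strings",
                 class = "gcnprio_rejected_record_error")
  }
  bad_w <- !is.finite(w) | w <= 0
  if (any(bad_w)) {
    rlang::abort(
      sprintf("edge weights must be strictly positive; offending record(s): %s",
              paste(which(bad_w), collapse = ", ")),
      class = "gcnprio_weight_domain_error"
    )
  }
  self <- a == b
  if (any(self)) {
    rlang::abort(
      sprintf("self-interaction records are not allowed (gene %s at record %s)",
              a[which(self)[1]], which(self)[1]),
      class = "gcnprio_rejected_record_error"
    )
  }

  # node order: first appearance scanning each record's two endpoints in turn
  node_ids <- unique(as.vector(rbind(a, b)))
  n <- length(node_ids)

  # collapse duplicate (a,b)/(b,a) records to the maximum weight
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  w_max <- tapply(w, key, max)
  first <- !duplicated(key)
  edge_tbl <- tibble::tibble(
    gene_a = a[first], gene_b = b[first],
    weight = as.double(w_max[key[first]])
  )
  if (rescale_weights) {
    rng <- range(edge_tbl$weight)
    edge_tbl$weight <- if (rng[1] == rng[2]) {
      rep(1, nrow(edge_tbl))
    } else {
      (edge_tbl$weight - rng[1]) / (rng[2] - rng[1]) * (1 - 1e-6) + 1e-6
    }
  }

  adj <- matrix(0, n, n, dimnames = list(node_ids, node_ids))
  ia <- match(edge_tbl$gene_a, node_ids)
  ib <- match(edge_tbl$gene_b, node_ids)
  adj[cbind(ia, ib)] <- edge_tbl$weight
  adj[cbind(ib, ia)] <- edge_tbl$weight

  structure(
    list(node_ids = node_ids, edges = edge_tbl, adjacency = adj),
    class = "gene_graph"
  )
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("<gene_graph> %d nodes, %d edges\n",
              length(x$node_ids), nrow(x$edges)))
  removed <- attr(x, "removed")
  if (!is.null(removed) && length(removed)) {
    cat(sprintf("  removed isolated: %s\n", paste(removed, collapse = ", ")))
  }
  invisible(x)
}

#' Drop candidate genes with no interactions
#'
#' Restricts the graph to the candidate genes (typically the labelled gene
#' universe) that participate in at least one interaction; genes with no edge
#' carry no network information and are removed before encoding. The removed
#' identifiers are recorded in the `removed` attribute of the result.
#'
#' @param graph A `gene_graph`.
#' @param listed_nodes Character vector: the candidate gene universe. May
#'   include genes absent from every edge.
#' @return A pruned `gene_graph` containing exactly the listed nodes that have
#'   degree >= 1, with attribute `removed` (character vector of dropped ids).
#' @export
prune_isolated <- function(graph, listed_nodes) {
  stopifnot(inherits(graph, "gene_graph"))
  listed_nodes <- unique(as.character(listed_nodes))
  deg <- rowSums(graph$adjacency)
  connected <- graph$node_ids[deg > 0]
  keep <- graph$node_ids[graph$node_ids %in% intersect(listed_nodes, connected)]
  removed <- setdiff(listed_nodes, keep)
  if (length(keep) == 0L) {
    rlang::abort("no listed gene has any interaction: the pruned graph would be empty",
                 class = "gcnprio_empty_graph_error")
  }
  adj <- graph$adjacency[keep, keep, drop = FALSE]
  # edges internal to the kept set only
  e <- graph$edges[graph$edges$gene_a %in% keep & graph$edges$gene_b %in% keep, ]
  out <- structure(
    list(node_ids = keep, edges = e, adjacency = adj),
    class = "gene_graph"
  )
  attr(out, "removed") <- removed
  out
}

#' Graph Laplacian L = D - A
#'
#' The combinatorial Laplacian of the (un-augmented) weighted graph, with
#' `D[i,i]` the weighted degree. Symmetric, rows sum to zero, positive
#' semi-definite; exposed as a structural descriptor and for testing — the
#' encoder's forward pass uses the normalized operator, not L.
#'
#' @param graph A nonempty `gene_graph`.
#' @return A symmetric numeric matrix.
#' @export
graph_laplacian <- function(graph) {
  stopifnot(inherits(graph, "gene_graph"))
  if (length(graph$node_ids) == 0L) {
    rlang::abort("graph is empty", class = "gcnprio_empty_graph_error")
  }
  a <- graph$adjacency
  diag(rowSums(a), nrow = nrow(a)) - a
}

#' Self-loop-augmented, symmetrically normalized propagation operator
#'
#' Builds the operator applied to node features by every graph-convolution
#' layer: `A' = A + I` (each gene keeps its own features via a unit
#' self-loop), `D'` the diagonal degree matrix of `A'`, and
#' `Ahat = D'^(-1/2) A' D'^(-1/2)`. `Ahat` is symmetric with spectrum in
#' `[-1, 1]`, so repeated propagation neither explodes nor changes sign
#' structure.
#'
#' @param graph A nonempty `gene_graph` (isolated nodes already pruned).
#' @return A `propagation_operator`: list with `a_hat`, `a_aug` (= A + I),
#'   `d_aug` (vector of augmented degrees), `laplacian` (of the un-augmented
#'   graph) and `node_ids`.
#' @export
normalized_operator <- function(graph) {
  stopifnot(inherits(graph, "gene_graph"))
  if (length(graph$node_ids) == 0L) {
    rlang::abort("graph is empty", class = "gcnprio_empty_graph_error")
  }
  a_aug <- graph$adjacency
  diag(a_aug) <- diag(a_aug) + 1
  d_aug <- rowSums(a_aug)
  s <- 1 / sqrt(d_aug)
  a_hat <- a_aug * tcrossprod(s) # s_i * a'_ij * s_j
  structure(
    list(
      a_hat = a_hat,
      a_aug = a_aug,
      d_aug = d_aug,
      laplacian = graph_laplacian(graph),
      node_ids = graph$node_ids
    ),
    class = "propagation_operator"
  )
}

#' @export
print.propagation_operator <- function(x, ...) {
  cat(sprintf("<propagation_operator> %d nodes (symmetric normalized adjacency with self-loops)\n",
              length(x$node_ids)))
  invisible(x)
}

#' Propagate node features across the network
#'
#' Applies the normalized operator to a feature matrix: `Ahat %*% X`. This is
#' the linear part of a graph-convolution layer — each gene's features become
#' a degree-normalized weighted average of its own and its neighbours'
#' features. Linear in `X` and permutation-equivariant.
#'
#' @param op A `propagation_operator` from [normalized_operator()].
#' @param x Numeric matrix with one row per node (graph node order), or a data
#'   frame with a `gene` column and numeric feature columns.
#' @return A numeric matrix of the same shape as `x` (rows in node order).
#' @export
propagate <- function(op, x) {
  stopifnot(inherits(op, "propagation_operator"))
  if (is.data.frame(x)) {
    x <- features_to_matrix(x, op$node_ids)$x
  }
  x <- as.matrix(x)
  if (nrow(x) != length(op$node_ids)) {
    rlang::abort(
      sprintf("feature matrix has %d rows but the operator has %d nodes",
              nrow(x), length(op$node_ids)),
      class = "gcnprio_shape_error"
    )
  }
  op$a_hat %*% x
}
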