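split_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE), lineno = which(keep))
}

#' Read a 3-column edge list
#'
#' Tab-separated file with columns gene A, gene B, numeric weight; lines
#' starting with `#` and blank lines are skipped. Records are returned in file
#' order with their source line numbers. Malformed lines are rejected, never
#' coerced.
#'
#' @param path Path to the edge-list file.
#' @return A tibble with columns `gene_a`, `gene_b`, `weight`, `line`.
#' @export
read_edge_list <- function(path) {
  sp <- split_tsv_lines(path)
  if (length(sp$fields) == 0L) {
    rlang::abort(sprintf("'%s' contains no edge records", path),
                 class = "gcnprio_parse_error")
  }
  nf <- lengths(sp$fields)
  if (any(nf != 3L)) {
    bad <- sp$lineno[which(nf != 3L)[1L]]
    rlang::abort(sprintf("line %d of '%s' does not have 3 tab-separated fields",
                         bad, path),
                 class = "gcnprio_parse_error")
  }
  m <- do.call(rbind, sp$fields)
  w <- suppressWarnings(as.numeric(m[, 3L]))
  if (anyNA(w)) {
    bad <- sp$lineno[which(is.na(w))[1L]]
    rlang::abort(sprintf("non-numeric weight at line %d of '%s'", bad, path),
                 class = "gcnprio_parse_error")
  }
  tibble::tibble(gene_a = m[, 1L], gene_b = m[, 2L], weight = w, line = sp$lineno)
}

#' Read a gene-by-feature expression matrix
#'
#' Tab-separated file with a header row of feature names and a first column of
#' gene identifiers. Ragged rows, non-numeric values and duplicate gene rows
#' are errors.
#'
#' @param path Path to the matrix file.
#' @return A tibble with a `gene` column followed by numeric feature columns.
#' @export
read_expression_matrix <- function(path) {
  sp <- split_tsv_lines(path)
  if (length(sp$fields) < 2L) {
    rlang::abort(sprintf("'%s' needs a header row and at least one gene row", path),
                 class = "gcnprio_parse_error")
  }
  header <- sp$fields[[1L]]
  body <- sp$fields[-1L]
  lineno <- sp$lineno[-1L]
  nf <- lengths(body)
  if (any(nf != length(header))) {
    bad <- lineno[which(nf != length(header))[1L]]
    rlang::abort(sprintf("ragged row at line %d of '%s' (expected %d fields)",
                         bad, path, length(header)),
                 class = "gcnprio_parse_error")
  }
  m <- do.call(rbind, body)
  genes <- m[, 1L]
  if (anyDuplicated(genes)) {
    rlang::abort(
      sprintf("duplicate gene row(s) in '%s': %s", path,
              paste(unique(genes[duplicated(genes)]), collapse = ", ")),
      class = "gcnprio_duplicate_id_error"
    )
  }
  vals <- suppressWarnings(apply(m[, -1L, drop = FALSE], 2L, as.numeric))
  vals <- matrix(vals, nrow = length(genes))
  if (anyNA(vals)) {
    bad <- lineno[which(rowSums(is.na(vals)) > 0)[1L]]
    rlang::abort(sprintf("non-numeric expression value at line %d of '%s'", bad, path),
                 class = "gcnprio_parse_error")
  }
  out <- tibble::as_tibble(as.data.frame(vals))
  names(out) <- header[-1L]
  dplyr::bind_cols(tibble::tibble(gene = genes), out)
}

#' Read positive and negative gene lists
#'
#' One gene identifier per line (blank and `#` lines skipped). A gene present
#' in both lists is a labelling conflict and an error.
#'
#' @param pos_path,neg_path Paths to the positive and negative gene lists.
#' @return A tibble with columns `gene`, `label` (1 = positive, 0 = negative).
#' @export
read_label_lists <- function(pos_path, neg_path) {
  read_list <- function(p) {
    x <- readLines(p, warn = FALSE)
    x <- trimws(x)
    unique(x[!grepl("^(#|$)", x)])
  }
  pos <- read_list(pos_path)
  neg <- read_list(neg_path)
  both <- intersect(pos, neg)
  if (length(both)) {
    rlang::abort(
      sprintf("gene(s) listed as both positive and negative: %s",
              paste(both, collapse = ", ")),
      class = "gcnprio_label_conflict_error"
    )
  }
  tibble::tibble(gene = c(pos, neg), label = rep(c(1L, 0L), c(length(pos), length(neg))))
}

#' Write a graph summary as JSON
#'
#' Records node count, edge count, the node ordering (for cross-file
#' alignment) and any isolated genes removed by [prune_isolated()].
#'
#' @param graph A `gene_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graph_summary <- function(graph, path) {
  jsonlite::write_json(
    list(
      n_nodes = length(graph$node_ids),
      n_edges = nrow(graph$edges),
      node_order = graph$node_ids,
      removed_isolated = attr(graph, "removed") %||% character(0)
    ),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}

#' Write a cross-validation report as JSON
#'
#' @param report An `eval_report` from [run_cv()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  jsonlite::write_json(
    list(
      method = report$method,
      depth = report$depth,
      k = report$k,
      seed = report$seed,
      auc = report$mean_auc,
      aupr = report$mean_aupr,
      pooled_auc = report$pooled_auc,
      pooled_aupr = report$pooled_aupr,
      per_fold = report$per_fold
    ),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}

# reproducibility manifest written by every CLI run
write_manifest <- function(out_dir, config_list, inputs = character(0)) {
  sums <- if (length(inputs)) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else {
    stats::setNames(list(), character(0))
  }
  jsonlite::write_json(
    list(config = config_list, input_md5 = sums,
         package_version = as.character(utils::packageVersion("gcnprio"))),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(file.path(out_dir, "manifest.json"))
}
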