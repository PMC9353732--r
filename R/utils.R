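# internal helpers shared across modules

`%||%` <- rlang::`%||%`

# deterministic child seeds for per-fold / per-repeat RNG streams; always
# strictly below .Machine$integer.max so they are valid set.seed() inputs
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    rlang::abort(
      sprintf("`%s` must be a single finite number in [%s, %s].", name, lower, upper),
      class = "gcnprio_config_error"
    )
  }
  invisible(x)
}

# coerce a features table (gene column + numeric columns) to a numeric matrix
# aligned with `node_ids`; genes missing from the table are reported back
features_to_matrix <- function(features, node_ids) {
  if (is.matrix(features)) {
    if (is.null(rownames(features))) {
      if (nrow(features) != length(node_ids)) {
        rlang::abort(
          sprintf("feature matrix has %d rows but the graph has %d nodes",
                  nrow(features), length(node_ids)),
          class = "gcnprio_shape_error"
        )
      }
      rownames(features) <- node_ids
    }
    tab <- features
    genes <- rownames(features)
  } else {
    features <- tibble::as_tibble(features)
    gene_col <- intersect(c("gene", "gene_id"), names(features))[1]
    if (is.na(gene_col)) {
      rlang::abort("features must contain a `gene` column", class = "gcnprio_shape_error")
    }
    genes <- as.character(features[[gene_col]])
    if (anyDuplicated(genes)) {
      rlang::abort(
        sprintf("duplicate gene rows in features: %s",
                paste(unique(genes[duplicated(genes)]), collapse = ", ")),
        class = "gcnprio_duplicate_id_error"
      )
    }
    tab <- as.matrix(features[setdiff(names(features), gene_col)])
    rownames(tab) <- genes
  }
  missing <- setdiff(node_ids, genes)
  keep <- intersect(node_ids, genes)
  x <- tab[keep, , drop = FALSE]
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) {
    rlang::abort("features contain non-finite values", class = "gcnprio_shape_error")
  }
  list(x = x, missing = missing)
}

labels_to_vector <- function(labels) {
  labels <- tibble::as_tibble(labels)
  gene_col <- intersect(c("gene", "gene_id"), names(labels))[1]
  if (is.na(gene_col) || !"label" %in% names(labels)) {
    rlang::abort("labels must contain `gene` and `label` columns",
                 class = "gcnprio_shape_error")
  }
  y <- as.integer(labels$label)
  if (!all(y %in% c(0L, 1L))) {
    rlang::abort("labels must be 0/1", class = "gcnprio_shape_error")
  }
  stats::setNames(y, as.character(labels[[gene_col]]))
}
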