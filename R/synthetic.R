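#' Synthetic benchmark configuration
#'
#' Describes a planted two-class benchmark with the statistical structure the
#' classifier assumes: an assortative interaction network (two-block
#' stochastic graph, denser within classes than between), log-normal positive
#' edge weights mimicking right-skewed log-likelihood association scores, and
#' Gaussian per-gene features whose class means are separated by a configured
#' effect size. Defaults mirror the scale of a curated disease-gene study: 284
#' genes, balanced classes (142 + 142), 32 tissue-expression-like features,
#' class-mean separation of 2 feature standard deviations and a 4:1
#' within/between edge-density ratio.
#'
#' @param n_genes Number of genes (default 284).
#' @param frac_positive Fraction of disease-related genes (default 0.5).
#' @param n_features Number of features per gene (default 32).
#' @param effect_size Difference of class feature means in units of the
#'   feature standard deviation (default 2).
#' @param p_within Edge probability inside a class (default 0.3).
#' @param p_between Edge probability across classes (default 0.075).
#' @param weight_meanlog,weight_sdlog Log-normal edge-weight parameters
#'   (defaults 0.5 and 0.5).
#' @param seed Integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 284, frac_positive = 0.5, n_features = 32,
                             effect_size = 2, p_within = 0.3, p_between = 0.075,
                             weight_meanlog = 0.5, weight_sdlog = 0.5, seed = 1) {
  assert_scalar_number(n_genes, "n_genes", lower = 4)
  assert_scalar_number(n_features, "n_features", lower = 1)
  assert_scalar_number(effect_size, "effect_size", lower = 0)
  assert_scalar_number(weight_sdlog, "weight_sdlog", lower = 0)
  if (frac_positive <= 0 || frac_positive >= 1) {
    rlang::abort("`frac_positive` must lie strictly between 0 and 1",
                 class = "gcnprio_config_error")
  }
  if (p_between < 0 || p_within > 1 || p_between > p_within) {
    rlang::abort("need 0 <= p_between <= p_within <= 1",
                 class = "gcnprio_config_error")
  }
  structure(
    list(n_genes = as.integer(n_genes), frac_positive = frac_positive,
         n_features = as.integer(n_features), effect_size = effect_size,
         p_within = p_within, p_between = p_between,
         weight_meanlog = weight_meanlog, weight_sdlog = weight_sdlog,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate a planted-signal benchmark instance
#'
#' Draws a two-block stochastic graph (Bernoulli edges at `p_within` /
#' `p_between`, strictly positive log-normal weights), class-separated
#' Gaussian features, and balanced label lists. Genes left isolated by chance
#' are kept in the feature/label tables and simply absent from the edge list —
#' pruning them is the pipeline's job ([prune_isolated()]). Deterministic
#' given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A `gene_benchmark` list: `graph` (a `gene_graph` over the connected
#'   genes), `features` (tibble: `gene` + `f1..fK`, all genes), `labels`
#'   (tibble: `gene`, `label`, all genes) and `config`.
#' @export
generate_benchmark <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_genes
  withr::with_seed(config$seed, {
    gene_ids <- sprintf("g%0*d", nchar(n), seq_len(n))
    n_pos <- round(config$frac_positive * n)
    y <- integer(n)
    y[sample.int(n, n_pos)] <- 1L

    pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    same <- y[pairs[, 1L]] == y[pairs[, 2L]]
    p_edge <- ifelse(same, config$p_within, config$p_between)
    keep <- stats::runif(nrow(pairs)) < p_edge
    i <- pairs[keep, 1L]
    j <- pairs[keep, 2L]
    w <- stats::rlnorm(length(i), config$weight_meanlog, config$weight_sdlog)
    edges <- tibble::tibble(gene_a = gene_ids[i], gene_b = gene_ids[j], weight = w)

    x <- matrix(stats::rnorm(n * config$n_features), n, config$n_features) +
      config$effect_size * y
    features <- tibble::as_tibble(as.data.frame(x))
    names(features) <- paste0("f", seq_len(config$n_features))
    features <- dplyr::bind_cols(tibble::tibble(gene = gene_ids), features)

    structure(
      list(
        graph = build_graph(edges),
        features = features,
        labels = tibble::tibble(gene = gene_ids, label = y),
        config = config
      ),
      class = "gene_benchmark"
    )
  })
}

#' @export
print.gene_benchmark <- function(x, ...) {
  cat(sprintf("<gene_benchmark> %d genes (%d positive), %d features, %d edges\n",
              x$config$n_genes, sum(x$labels$label), x$config$n_features,
              nrow(x$graph$edges)))
  invisible(x)
}

#' Write a benchmark instance as the three external file formats
#'
#' Produces `edges.tsv` (3-column tab-separated edge list), `expression.tsv`
#' (gene-by-feature matrix with a header row) and `positives.txt` /
#' `negatives.txt` (one gene identifier per line). The files round-trip
#' losslessly through [read_edge_list()], [read_expression_matrix()] and
#' [read_label_lists()].
#'
#' @param instance A `gene_benchmark` from [generate_benchmark()].
#' @param directory Output directory (created if absent).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_fixture <- function(instance, directory) {
  stopifnot(inherits(instance, "gene_benchmark"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) {
      rlang::abort(sprintf("cannot create directory '%s'", directory),
                   class = "gcnprio_io_error")
    }
  }
  paths <- c(
    edges = file.path(directory, "edges.tsv"),
    expression = file.path(directory, "expression.tsv"),
    positives = file.path(directory, "positives.txt"),
    negatives = file.path(directory, "negatives.txt")
  )
  ed <- instance$graph$edges
  writeLines(
    c("# gene_a\tgene_b\tweight",
      sprintf("%s\t%s\t%.17g", ed$gene_a, ed$gene_b, ed$weight)),
    paths[["edges"]]
  )
  ex <- as.data.frame(instance$features)
  num <- vapply(ex, is.numeric, logical(1))
  ex[num] <- lapply(ex[num], function(v) sprintf("%.17g", v))
  utils::write.table(ex, paths[["expression"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(instance$labels$gene[instance$labels$label == 1L], paths[["positives"]])
  writeLines(instance$labels$gene[instance$labels$label == 0L], paths[["negatives"]])
  invisible(paths)
}
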