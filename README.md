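# gcnprio

Disease-gene prioritization on weighted gene-interaction networks with a
graph-convolutional encoder and a small 1-D convolutional decoder.

## The problem

Candidate disease genes are routinely ranked from two complementary sources of
evidence: per-gene measurements (e.g. tissue expression profiles) and the
gene-interaction network, whose weighted edges (log-likelihood-style
association scores) encode functional relationships that single-gene analyses
ignore. `gcnprio` treats the task as semi-supervised binary node
classification on the interaction graph: given a small set of genes known to
be disease-related (positives) and a matched set of unrelated genes
(negatives), score every gene's probability of being disease-related.

The model is a two-stage neural network trained end to end:

1. **Encoder** — a stack of 1–4 graph-convolution layers. Each layer
   propagates features with the self-loop-augmented, symmetrically
   degree-normalized adjacency and mixes them with a trainable weight matrix:

   ```
   Â = D'^(-1/2) (A + I) D'^(-1/2),      D' = diag(rowSums(A + I))
   X_{l+1} = ReLU( Â X_l W_l )
   ```

   A depth-`N` stack summarizes each gene's `N`-hop network neighbourhood.

2. **Decoder** — each gene's embedding is read as a one-channel 1-D signal by
   four convolutional blocks (kernel size 3; 32, 64, 32, 16 filters; each
   followed by batch normalization and ReLU; same-padding, stride 1), then
   flattened through dropout (rate 0.5) and a fully connected layer to two
   softmax logits.

Training minimizes binary cross-entropy over the labelled genes with
full-batch Adam: 50 epochs, learning rate 0.01 dropped to 0.001 after epoch
40. Evaluation is stratified 10-fold cross-validation, transductive (the graph
stays whole; held-out labels are masked), reporting fold-averaged AUC and
AUPR. The package also ships the evaluation harness around the model: an
encoder-depth ablation, comparisons against GCN-only, CNN-only, random-forest
and k-nearest-neighbour baselines, and a planted-partition synthetic benchmark
generator so the whole pipeline runs with no external downloads.

## Worked example

```r
library(gcnprio)

# a study-scale planted benchmark: 284 genes (142 positive), 32 features,
# class-mean separation of 2 sd, within/between edge densities 0.30 / 0.075
bench <- generate_benchmark(synthetic_config(seed = 1))
#> <gene_benchmark> 284 genes (142 positive), 32 features, 7570 edges

graph <- prune_isolated(bench$graph, bench$labels$gene)
model <- train_gcnn(graph, bench$features, bench$labels, depth = 3,
                    config = train_config(seed = 1))
glance(model)
#> # A tibble: 1 × 9
#>   method  depth hidden_dim epochs initial_loss final_loss n_nodes n_train  seed
#>   <chr>   <int>      <int>  <int>        <dbl>      <dbl>   <int>   <int> <int>
#> 1 gcn_cnn     3         32     50         1.03 0.00000224     284     284     1

report <- run_cv(graph, bench$features, bench$labels, depth = 3,
                 config = train_config(seed = 1), k = 10)
report
#> <eval_report> gcn_cnn | 10-fold CV | mean AUC 1.0000 | mean AUPR 1.0000

head(tidy(report), 3)
#> # A tibble: 3 × 4
#>    fold n_test   auc  aupr
#>   <int>  <int> <dbl> <dbl>
#> 1     1     29     1     1
#> 2     2     29     1     1
#> 3     3     29     1     1
```

`glance(model)` shows the training loss falling from 1.03 to ~2e-6 over the 50
epochs; the cross-validated AUC/AUPR of 1.0 reflects that the default
benchmark plants a strong, fully recoverable signal in both the features and
the network (on a null benchmark with no planted signal the same pipeline
stays at chance, ~0.5). `predict(model)` returns a tibble of per-gene
disease-relatedness probabilities — a ranked candidate list.

`autoplot()` methods draw ROC/PR curves (`roc_points()`, `pr_points()`),
per-fold CV metrics, the depth ablation (`ablate_depth()`) and the method
comparison (`run_baselines()`).

## Command line

A thin wrapper over the same functions lives at `inst/cli/gcnprio`:

```sh
Rscript inst/cli/gcnprio simulate --n-genes 284 --seed 1 --out fixture/
Rscript inst/cli/gcnprio evaluate --edges fixture/edges.tsv \
    --expression fixture/expression.tsv --positives fixture/positives.txt \
    --negatives fixture/negatives.txt --out results/
```

Subcommands: `simulate`, `build-graph`, `train`, `evaluate`, `ablate-layers`,
`compare`. Inputs are a 3-column tab-separated edge list, a gene-by-feature
expression matrix with a header row, and one-gene-per-line positive/negative
lists; every run writes a `manifest.json` with the configuration, seed and
input checksums.

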