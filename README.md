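# guidegraph

Editing-efficiency prediction for CRISPR guide RNAs from **sequence and
secondary structure**, modeled as graphs.

Most on-target efficiency models read the 20-nt spacer as a flat string
and ignore how the guide folds. `guidegraph` represents each guide as a
graph G = (V, E): one node per nucleotide, *sequential* edges along the
phosphodiester backbone, and *structural* edges between the base pairs of
the RNA secondary structure. A graph-attention regression network —
per-node MLP, multi-head graph attention (incoming weights
softmax-normalized per node), graph convolution, global pooling and a
feed-forward head — maps each graph to a predicted editing efficiency on
the 0–100 percent scale. The attention weights double as an
interpretability readout: per-position received/emitted/hub importance
scores along the spacer.

The package is aimed at computational biologists who want to

* fold guides with a self-contained Nussinov-style base-pair maximization
  predictor (or plug in external predictions as Vienna dot-bracket files),
* build guide graphs from one-hot or per-nucleotide embedding features
  (embedding matrices from RNA language models load from a plain-text
  block format),
* train, fine-tune (transfer learning across editing systems) and
  checkpoint the graph regressor,
* evaluate with Spearman/Pearson/MSE, seeded cross-validation folds,
  sequence-similarity redundancy filtering (global alignment identity,
  threshold 0.9) and a label-permutation significance test, and
* generate fully synthetic guide datasets with a *planted* efficiency
  function, so every claim above is testable end-to-end without any
  external download.

Everything is seeded and bit-reproducible: identical configuration and
seeds give byte-identical datasets, loss histories, predictions and
reports.

## Worked example

```r
library(guidegraph)

spec    <- synthetic_spec(n = 400, seed = 42)   # planted efficiency function
records <- generate_dataset(spec)
records[[1]]
#> <guide_record> synthetic_0001  AAAACUCCAUGUGUAACUCC  efficiency=38.1369  structure=..((.....)((...))).. 

graphs <- build_dataset(records)
graphs[[1]]
#> <guide_graph> synthetic_0001: 20 nodes, 38 sequential + 8 structural arcs, label=38.1369

split <- holdout_split(length(graphs), fraction = 0.2, seed = 42)
cfg   <- model_config(hidden_dim = 32, attention_heads = 4, learning_rate = 3e-3,
                      batch_size = 32, max_epochs = 20, seed = 42)
fit   <- train_model(init_model(cfg, feature_dim = 4),
                     graphs[split$train_idx][1:280],    # train
                     graphs[split$train_idx][281:320])  # validation
#> <gg_model> feature_dim=4, hidden=32, 1 attention layer(s) x 4 head(s), 1 conv layer(s),
#>            mean pooling, 4225 parameters, trained (best epoch 20)

test_g <- graphs[split$test_idx]
preds  <- predict(fit, test_g)
labels <- vapply(test_g, `[[`, numeric(1), "label")
metric_report(unname(preds), labels)
#> <metric_report> n=80  Spearman=0.7962  Pearson=0.7972  MSE=169.657

permutation_test(unname(preds), labels, B = 999, seed = 42)
#> <permutation_result> observed Spearman=0.7962, B=999, p=0.001

prof <- position_importance(extract_attention(fit, test_g), length = 20)
head(rank_positions(prof)$combined, 8)
#> [1] 18  3  4  9  2  5 16  6
```

The held-out Spearman of 0.80 shows the network recovering the planted
signal from 320 training guides; the permutation p of 0.001 is the
smallest attainable at B = 999. The top-ranked hub positions (18, 3, 4,
9, 2, 5, 16, 6) concentrate in the generator's "important" regions —
spacer positions 2–6 (5' seed) and 15–19 (3' near-PAM), 0-based — which
is exactly the directional behavior the interpretability module is meant
to surface.

## Command line

An `exec/guidegraph` Rscript wrapper exposes the same workflows:

```sh
guidegraph simulate --n 200 --seed 7 --out guides.tsv
guidegraph train    --guides guides.tsv --checkpoint model.rds --seed 7
guidegraph evaluate --guides guides.tsv --checkpoint model.rds --out metrics.tsv
guidegraph explain  --guides guides.tsv --checkpoint model.rds --out profile.tsv
```

Other commands: `build-graphs`, `predict`, `filter-similar`, `permtest`,
`search`. Every run writes a JSON provenance sidecar (config echo, seeds,
package version) next to its output.

## Documentation

See the methods vignette (`vignettes/guidegraph-methods.Rmd`) for the
model, the planted synthetic world, numerical choices and limitations.
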