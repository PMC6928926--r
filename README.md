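# hetgo

Most mature human miRNAs have no experimentally supported Gene Ontology
annotation. `hetgo` predicts miRNA GO functions by exploiting the networks a
miRNA is embedded in: it integrates a miRNA co-expression network (Pearson
correlation of expression profiles, negative correlations screened out), a
protein–protein interaction network and a disease phenotype similarity
network — linked by miRNA–target, miRNA–disease and protein–disease
associations — into one weighted heterogeneous graph G = (V, E); learns a
d-dimensional representation per node with LINE (first- plus second-order
proximity, negative sampling, d = 64 split 32/32 between the orders); trains
a hierarchical multi-label classifier on GO-annotated proteins (one shared
dense layer, a sigmoid head per term, and a maximum-merge layer per
non-leaf term so that score(parent) ≥ score(child) across the DAG); and
transfers the model to miRNAs through the shared embedding space.

Predictions are scored protein-centrically: for threshold t, with P_i(t)
the terms scoring ≥ t for entity i and R_i its propagated truth set,

    Pre(t) = (1/m(t)) Σ_i |P_i(t) ∩ R_i| / |P_i(t)|     (over entities with predictions)
    Rec(t) = (1/N)    Σ_i |P_i(t) ∩ R_i| / |R_i|        (over all N entities)
    Fmax   = max_t  2·Pre(t)·Rec(t) / (Pre(t) + Rec(t))

A seeded synthetic benchmark generator (planted functional modules coupled
across expression, graph structure, associations and annotations) makes the
whole pipeline runnable and testable at desk scale with no external
databases.

## Worked example

```r
library(hetgo)

run <- run_pipeline(pipeline_config(synth = synth_config(), seed = 1L),
                    out_dir = "run1")
glance(run$eval)
#> # A tibble: 1 × 6
#>    fmax t_max precision recall     n coverage
#>   <dbl> <dbl>     <dbl>  <dbl> <int>    <int>
#> 1 0.867  0.52     0.894  0.842   120      120
```

Reading: on the default synthetic benchmark (120 miRNAs, 120 proteins, 60
diseases in 4 planted modules, a 60-term ontology), the model trained on
the 120 annotated proteins and transferred to the 120 miRNAs attains its
best F-measure 0.867 at score threshold 0.52, where averaged precision is
0.894 and averaged recall 0.842; all 120 miRNAs receive at least one
predicted term at that threshold. `autoplot(run$eval)` draws the
precision–recall curve, `tidy(run$eval)` returns the full threshold sweep,
and `tidy(run$prediction)` the per-miRNA term scores. The run directory
contains every artifact (merged network, embedding in word2vec text format,
model, predictions, evaluation, config) and is byte-reproducible from the
seed.

Individual stages are exposed as plain functions
(`coexpression_edges()`, `build_global_network()`, `line_embedding()`,
`propagate_annotations()`, `select_terms()`, `train_hmc()`,
`evaluate_predictions()`, ...) and as a shell front-end:

```sh
Rscript inst/scripts/hetgo.R run --out myrun --seed 7
Rscript inst/scripts/hetgo.R simulate --out data --seed 7   # stage by stage
```

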