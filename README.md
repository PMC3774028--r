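# netsam

Differential network analysis for prioritizing disease-associated genes
from case/control gene-expression data.

Single-gene differential expression ranks genes by how much their mean
level changes, but many disease genes act by *rewiring* their regulatory
neighborhood. netsam targets those genes: it infers one gene regulatory
network per condition, subtracts the two networks so that interactions
common to health and disease cancel, and prioritizes the hubs of what
remains. It is aimed at analysts working with two-group expression
matrices (microarray intensities or comparable log-scale data) who want a
network-level candidate gene list with a fully reproducible, seeded
synthetic benchmark behind it.

## Method

Five stages, each exposed as a pipe-friendly function:

1. **Differential expression** — per-gene two-sample Student's t-test and
   symmetric fold change FC = 2^|Δ log2 mean|; genes with FC > 2 and
   p < 0.01 form the analysis panel (`differential_expression()`,
   `filter_de_genes()`).
2. **Network inference per condition** — with standardized profiles
   (x_j^T x_i is then the Pearson correlation), componentwise boosting
   selects, per target gene i, the coefficient update
   β_ij += ν x_j^T r_i that maximizes the posterior score

   score_i = −log(RSS_i + ε) + log C²,

   where RSS is the regression's residual sum of squares and C is the
   Pearson correlation between log degree-bin frequency and log degree of
   the current coefficient matrix — a scale-free prior that is maximal
   (log C² = 0) when the degree distribution follows a power law
   π(d) ~ d^−λ exactly (`boosting_fit()`). An edge i–j is kept when
   sgn(β_ij β_ji) ≠ 0 (`build_network()`).
3. **Network subtraction** — the differential network is the symmetric
   difference of the case and control edge sets; case-only edges are
   *positive* (inducible), control-only edges *negative* (suppressive)
   (`subtract_networks()`).
4. **Hub detection** — genes with differential degree ≥ 5 and DE p-value
   ≤ 0.01, both inclusive (`identify_hubs()`).
5. **Prioritization** — GeneRank (PageRank with damping 0.5, biased by
   |log2 FC|) and plain differential degree; the candidate signature is
   the intersection of the two top-10 hub lists (`generank()`,
   `degree_ranking()`, `prioritize_hubs()`).

A synthetic benchmark generator (`simulation_config()`,
`generate_case_control()`) produces scale-free topologies (~500 edges over
200 genes), linear-Gaussian expression (σ = 0.5, 100 samples per
condition), planted differential edges and DE genes with full ground
truth; `edge_recovery_metrics()`, `benchmark_methods()` and
`robustness_curve()` compute ROC/AUC/PPV/FDR and compare against t-test
and lasso baselines. See the methods vignette
(`vignettes/differential-network-analysis.Rmd`) for the model details and
design rationale.

## Worked example

```r
library(netsam)

sim <- generate_case_control(simulation_config(
  n_genes = 60, n_samples = 60, target_edges = 120,
  rewire_fraction = 0.15, n_de_genes = 20, seed = 5))
expr <- cbind_expression(sim$case, sim$control)

res <- netsam(expr, sim$labels,
              boosting = boosting_config(n_iterations = 60), min_degree = 3)
res
#> netsam_result
#>   DE genes: 20 of 60
#>   case/control edges: 61 / 60
#>   differential edges: 69 (35 positive, 34 negative)
#>   hubs: 20; signature: g026, g058, g023, g049, g005, g040, g060, g055, g027, g014
```

The 20 planted DE genes are recovered exactly; the pipeline then infers a
network per condition on that panel, keeps the 69 interactions present in
only one condition (35 case-specific, 34 control-specific), and all 20
panel genes clear the hub thresholds, of which the two top-10 rankings
agree on a 10-gene signature.

Edge recovery against the known control-condition network, using the
continuous per-pair scores min(|β_ij|, |β_ji|):

```r
fit <- boosting_fit(standardize_expression(sim$control),
                    boosting_config(n_iterations = 60))
ev <- edge_recovery_metrics(edge_scores(fit), sim$truth$control_network)
ev
#> edge_eval: AUC = 0.8411 (120 true edges, 1650 non-edges)
```

Recall of the planted differential edges (inferring both conditions on all
genes), against a degree-matched random baseline:

```r
case_fit <- boosting_fit(standardize_expression(sim$case),
                         boosting_config(n_iterations = 60))
dn <- subtract_networks(build_network(case_fit), build_network(fit))
differential_edge_recall(dn, sim$truth$differential_edges, seed = 5)
#> # A tibble: 1 × 4
#>   recall random_recall n_true n_predicted
#>    <dbl>         <dbl>  <int>       <int>
#> 1  0.611         0.124     36         223
```

61% of the 36 planted rewired edges appear in the predicted differential
network, five times the rate of a degree-matched random edge set.

Results carry broom-style `tidy()`/`glance()` methods and `autoplot()`
figures (volcano plot, ROC curve, log-log degree distribution, benchmark
box plots). A thin command-line front end with subcommands
`simulate`/`de`/`infer`/`diff`/`rank`/`eval` is installed at
`system.file("cli", "netsam", package = "netsam")`.

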