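# kddn — knowledge-fused differential dependency networks

`kddn` infers how a gene network *rewires* between two biological
conditions. Given two expression matrices over the same genes (for
example treated vs. untreated, or recurring vs. non-recurring tumors),
it jointly estimates two condition-specific sparse dependency graphs,
labels every edge as common or condition-specific, and — its
distinguishing feature — incorporates an imperfect prior-knowledge
network (a pathway-database rendering, say) with a weight calibrated so
that even completely wrong knowledge cannot degrade the result beyond a
user-set budget.

## The model

Both conditions are Gaussian Markov random fields over the same `p`
genes; structure is learned by neighborhood selection with the two
conditions coupled per node:

$$
\min_{\beta^{(1)},\beta^{(2)}}\;
\tfrac12\bigl\lVert y_i - X\beta_i\bigr\rVert_2^2
+\lambda_1\sum_j (1-W_{ji}\theta)\bigl(|\beta^{(1)}_{ji}|+|\beta^{(2)}_{ji}|\bigr)
+\lambda_2\sum_j\bigl|\beta^{(1)}_{ji}-\beta^{(2)}_{ji}\bigr|
$$

subject to `β_ii = 0`, solved exactly per node by block coordinate
descent with a closed-form update for each coefficient pair (compiled
with Rcpp). `W` is the 0/1 prior-knowledge adjacency; `θ ∈ [0, 1]`
relaxes the sparsity penalty on knowledge-supported pairs; the fusion
term `λ2` drives conserved edges to identical coefficients, so edges
present in exactly one condition's graph — the differential dependency
network — reflect real structural change rather than noise.

All three penalties are selected from the data:

- `λ1 = (2σ̂/√N)·Φ⁻¹(1 − α₁/(2p²))` controls the probability of falsely
  joining two distinct connectivity components;
- `λ2` is calibrated by permutation (pool, re-split, refit) so that
  differential edges under the null occur at a chosen significance
  level;
- `θ` is the largest weight for which the expected relative graph edit
  distance between the data-only network and networks refit under
  *random* knowledge stays within the degradation budget `δ` — the
  worst-case guarantee: at `δ = 0.1`, even pure-noise knowledge costs at
  most 10% degradation, while genuinely informative knowledge is free to
  help.

Differential edges get permutation p-values (condition-label re-splits)
and Benjamini–Hochberg q-values. A simulation suite (GMRF ground truths
with 10% rewiring, controlled-error priors) and a scoring layer
(precision/recall/F per scope, labeled graph edit distance, naive
union baseline, false-positive-rate sweeps) support benchmarking. See
`vignettes/kddn-methods.Rmd` for assumptions, parameter meanings and
numerical choices.

## Worked example

```r
library(kddn)

# ground truth: p = 50 GMRF, 10% of edges rewired between conditions,
# 150 samples per condition, prior knowledge with 30% false positives
truth <- perturb_network(simulate_gmrf_truth(50, seed = 11),
                         rewire_fraction = 0.1, seed = 12)
data  <- sample_condition_data(truth, n1 = 150, seed = 13)
prior <- make_prior_knowledge(truth, fp_rate = 0.3, seed = 14)

fit <- kddn(data, knowledge = prior,
            config = kddn_config(seed = 5, delta = 0.1),
            significance = TRUE)
fit
#> <kddn_fit> 50 genes; |E1| = 12, |E2| = 12; common = 12, differential = 0
#>   lambda1 = 0.6965, lambda2 = 0.3366, theta = 0.1

glance(attr(fit, "theta_calibration"))
#> # A tibble: 1 × 7
#>   theta_hat delta     M     R n_edges_gx lambda1 lambda2
#>       <dbl> <dbl> <int> <dbl>      <int>   <dbl>   <dbl>
#> 1       0.1   0.1    51   100         12   0.696   0.337

tidy(fit)   # edge table: nodes, condition, 4 directed coefficients, p/q
#> # A tibble: 12 × 9
#>   node_a node_b condition beta1_ab beta2_ab beta1_ba beta2_ba pvalue qvalue
#> 1 g004   g019   both      -0.00468 -0.00468 -0.0136   -0.0136     NA     NA
#> ...

score_network(fit, truth, scope = "overall")
#> # A tibble: 1 × 7
#>   scope      tp    fp    fn precision recall fscore
#> 1 overall    24     0    90         1  0.211  0.348
```

Reading the numbers: `λ1 ≈ 0.70` is the false-join level at
`p = 50, N = 150` — deliberately strict, so the fit makes no false
edges (precision 1). The `θ` calibration settled on `θ̂ = 0.1`, the
largest weight whose worst-case (random-knowledge) perturbation of the
data-only network stays within `δ = 0.1`. At that weight the
70%-correct prior doubles recall over the purely data-driven fit (0.211
vs. 0.105, 12 edges vs. 6) without admitting a single false positive.
No edge is called differential here: the fusion penalty, calibrated to
a 5% null rate, found no rewiring evidence strong enough at these
sample sizes — so no permutation p-values are filled.

The same pipeline is scriptable from a shell via the thin CLI wrapper
(`inst/cli/kddn.R`; subcommands `simulate`, `fit`, `calibrate`,
`sweep`), which writes edge tables, calibration reports, a resolved
config and a seed-stamped log — see `?kddn_cli`.

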