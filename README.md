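# regcap

Multilayer regulatory-capacity models for subtype-specific gene
regulation: fit a thermodynamic model of TF→target control per molecular
subtype, mine subtype-specific ("repurposed") regulatory edges, simulate
TF knockdowns through the network, score protein signaling activity on a
signed interactome, and predict per-sample gene essentiality from the
resulting activity changes.

The package is aimed at computational biologists who have (i) a
gene-expression cohort with subtype labels, (ii) a candidate TF→gene
backbone (from binding scores and/or tissue networks), and optionally
(iii) a signed protein-interaction network and gene-essentiality screens
— and who want a mechanistically interpretable bridge from regulatory
parameters to predicted vulnerabilities. Everything is also runnable
end-to-end on built-in synthetic cohorts with known ground truth.

## The model

Each target gene *i* is modeled as independently and saturably controlled
by its candidate regulators *j*:

    log2 y_i = log2 x_i0 + Σ_j log2( (1 + F_ji x_j) / (1 + x_j) )

`F_ji > 0` is the **regulatory capacity** — the maximum fold change TF *j*
can induce on gene *i* (`F > 1` activation, `F < 1` repression, `F = 1`
none) — and `x_i0` the basal level. Capacities are fitted per subtype by
L-BFGS-B on the penalized least-squares objective

    Σ_k Σ_j (log2 ŷ_ik − log2 y_ik)² + λ Σ_j (log2 F_ji)²,    λ = 0.1 by default.

On top of the fitted capacities the package provides:

- **Backbone assembly** — binding-score thresholding (top fraction by
  rank), closest-gene assignment within a ±10 kb TSS window, network
  union, expression filtering.
- **Subtype signatures** — label-permutation null (30 shuffles), 5-SD
  edge calling, TF participation scores, hypergeometric enrichment,
  TF–target correlation shifts.
- **Co-regulation** — robust (consensus/RANSAC-style) correlation of
  capacity profiles, benchmarked by Fisher enrichment and PR-AUC against
  known interactions.
- **Knockdown propagation (`h_perturb`)** — recursive steady-state
  updates with feedback-loop protection; each TF perturbed at most once.
- **Exponential Ranking** — signed-network protein activity,
  `p ← exp(Aᵀp/μ)/‖·‖₁` with `μ = max(A) − min(A)`, tolerance 1e-6.
- **Essentiality models** — per-TF elastic nets from activity deltas to
  depletion scores (24/8 line split, 4-fold CV), plus subtype-specificity
  summaries.
- **Synthetic cohorts** — generators for ground-truth regulatory systems,
  signed protein nets and sparse essentiality truths, so every stage is
  testable without external data.

## Worked example

```r
library(regcap)

truth  <- generate_regulatory_truth(n_tfs = 5, n_genes = 20,
                                    subtypes = c("Classical", "Mesenchymal"),
                                    edge_density = 0.4,
                                    frac_signature_edges = 0.3,
                                    noise_sd = 0.1, seed = 7)
cohort <- simulate_cohort(truth, samples_per_subtype = 120, seed = 8)
truth
#> <ground_truth> 5 TFs -> 20 genes, 40 edges, 2 subtype(s), 12 signature edges
cohort
#> <expression_set> 25 genes x 240 samples
#>   subtypes: Classical=120, Mesenchymal=120

backbone <- candidate_network(truth$backbone$tf, truth$backbone$gene)
fit <- fit_subtype_model(backbone, cohort, "Classical",
                         fit_config(lambda = 0.1))
fit$fvals
#> <f_matrix> subtype=Classical: 40 edges, 20 target genes, lambda=0.1
head(fit$fvals$edges, 3)
#>     tf gene      log2f
#> 1 TF02 G001  0.2406088
#> 2 TF03 G001 -1.7045203
#> 3 TF01 G002 -0.9588163
```

The fitted `log2f` column is the estimated log2 regulatory capacity:
TF03 represses G001 about 3.3-fold at saturation, TF02 weakly activates
it. Against the generating truth these estimates correlate at r = 0.999
(`cor(fit$fvals$edges$log2f, truth log2 F)`).

Knocking out TF01 and propagating:

```r
kd  <- h_perturb(fit$fvals, cohort, tf = "TF01", knockdown_factor = 0)
kd$updated_genes
#>  [1] "TF01" "G002" "G003" "G004" "G006" "G008" "G011" "G012" "G015" "G016" "G020"
lfc <- perturbation_log2fc(kd, cohort)
round(sort(rowMeans(lfc[setdiff(rownames(lfc), "TF01"), ]))[1:3], 2)
#>  G008  G011  G006
#> -0.78 -0.73 -0.52
```

Only TF01's targets change; G008 drops ~1.7-fold on average, consistent
with its fitted capacity. The per-sample expression after knockdown feeds
`build_transition_matrix()` / `exponential_ranking()` for activity deltas
and `train_essentiality_model()` for essentiality prediction;
`run_pipeline()` chains all stages with one seed and writes a hashed
manifest. A command-line wrapper with per-stage subcommands is installed
at `inst/cli/regcap`.

## Package layout

| Path | Contents |
| --- | --- |
| `R/synthetic.R` | ground-truth and cohort generators |
| `R/backbone.R` | binding-score → candidate-network assembly |
| `R/model.R` | thermodynamic regression, sMAPE, CV, cross-prediction |
| `R/cohort.R` | nearest-centroid classification, batch correction |
| `R/coregulation.R` | robust correlation, enrichment, PR-AUC |
| `R/signatures.R` | permutation null, signature edges, participation |
| `R/perturbation.R` | hPerturb knockdown propagation |
| `R/protein-activity.R` | Exponential Ranking, signed-log transform |
| `R/essentiality.R` | elastic-net essentiality models |
| `R/pipeline.R` | seeded end-to-end orchestration with manifests |

See `vignettes/regcap-methods.Rmd` for the model, its assumptions, and
the reasoning behind every numerical default.
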