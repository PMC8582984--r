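# perceptrisk

Socio-mathematical modeling of pandemic risk perception from categorical
survey data.

During an epidemic, how strongly people perceive the risk shapes whether
they follow protective recommendations — and that perception is far from
uniform even inside a single community. `perceptrisk` implements a complete
pipeline for quantifying that heterogeneity from an ordinary categorical
survey, for epidemiologists and social scientists analysing
risk-perception instruments:

1. **Signed dummy encoding** — a validated codebook maps every response
   category to a sign `s ∈ {-1, 0, +1}` according to whether the answer
   aligns with expected protective knowledge/behaviour; each respondent
   becomes a signed *risk vector* `v ∈ {-1, 0, 1}^m`.
2. **Additive risk score and quartiles** — the risk-perception score is
   `r = Σ_j v_j`, split at empirical quartiles into groups QR1 (lowest
   perception) … QR4 (highest), with descriptive tables: quartile × gender
   / age contingency tables with Pearson chi-square tests, score
   histograms with a mixture-based bimodality check, and per-group
   emotion/media frequency profiles.
3. **Optimal-scaling categorical PCA** (princals-style alternating least
   squares): category quantifications and components are estimated jointly
   by minimizing `Σ_j ‖h_j − X a_j‖²` under nominal/ordinal/numeric
   scaling restrictions; the leading components reaching 80% cumulative
   variance accounted for are retained.
4. **Similarity network, layout, clusters** — respondents are connected
   when the cosine similarity of their component scores exceeds 0.5, the
   network is embedded with a ForceAtlas2 force-directed layout (linear
   edge attraction, degree-weighted `k_r(d_i+1)(d_j+1)/d` repulsion,
   gravity, adaptive speed; exact or Barnes–Hut), and DBSCAN extracts
   density-based respondent clusters whose demographic/emotion/media
   profiles are compared against the population.

A synthetic survey generator (latent bimodal risk trait, logistic item
responses, heterogeneous low-risk "archetypes", trait-linked emotion and
media flags) provides ground truth, so every stage is testable without
access to any study's raw data. The pipeline equally accepts an external
responses CSV + codebook YAML.

## Worked example

```r
library(perceptrisk)

res <- run_pipeline(pipeline_config(seed = 0))  # synthetic preset, n = 2000
#> dropping 86 constant dummy columns before CAT-PCA
print(res)
#> <pipeline_result> 2000 respondents
#>   score range: -28 .. 40 | bimodal: TRUE
#>   reduced to 26 components | 671932 edges | 5 clusters
```

The risk scores are bimodal (fitted component means −12.1 and +36.5): a
low-perception and a high-perception subpopulation. The additive score
tracks the generator's latent trait closely
(`res$recovery$score_correlation` = 0.963). The quartile × gender table
shows the female excess in the upper quartiles, dependent by the Pearson
test (χ² = 74.8, df = 3, p = 4e-16):

```r
res$tables$gender_by_quartile
#>         cols
#> rows       1   2   3   4 Total
#>   female 289 332 271 353  1245
#>   male   252 129 238 136   755
#>   Total  541 461 509 489  2000
```

And the cluster-dispersion summary quantifies the study design's central
qualitative claim — high-risk respondents are homogeneous, low-risk
respondents heterogeneous:

```r
res$heterogeneity
#>   quartile   n n_clustered n_clusters_5pct   entropy top_cluster_share
#> 1        1 541         485               3 0.8285584         0.3814433
#> 2        2 461         451               3 0.9963852         0.3614191
#> 3        3 509         499               1 0.0000000         1.0000000
#> 4        4 489         488               1 0.0000000         1.0000000
```

QR4 sits in a single cluster (top-cluster share 1.00, entropy 0); QR1
spreads over three clusters (entropy 0.83) — the archetype structure the
generator planted, recovered by the full encode → score → CAT-PCA →
network → layout → DBSCAN chain.

To analyse real files instead:

```r
cfg <- pipeline_config(responses_path = "responses.csv",
                       codebook_path = "codebook.yml",
                       out_dir = "artifacts")
res <- run_pipeline(cfg)
```

Every artifact (scores, tables, component scores, GraphML/edge-list
network, layout, clusters, profiles) is written as plain CSV/XML plus a
JSON manifest of stages, parameters, seeds and checksums. A thin CLI lives
in `inst/scripts/perceptrisk.R` (`simulate` and `run` subcommands).

See the vignette `vignettes/risk-perception-pipeline.Rmd` for the model,
its assumptions, parameter meanings and numerical choices.

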