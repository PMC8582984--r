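---
title: "Modeling the heterogeneity of survey-based risk perception"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the heterogeneity of survey-based risk perception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`perceptrisk` operationalizes a socio-mathematical model of how a population
perceives an epidemic risk. The raw material is an ordinary categorical
survey: single-choice items spanning three dimensions of risk — knowledge
about the disease, perceived severity/probability, and preventive practice —
plus demographics, binary emotion flags and binary media-use flags.

The pipeline has four stages.

**1. Signed dummy encoding and the additive risk score.** A codebook maps
every response category of every item to a sign: `+1` if the answer lines up
with the protective knowledge and behaviour expected during the epidemic,
`-1` if it runs against it, `0` if it is uninformative. A respondent's *risk
vector* is the concatenation of these signed dummies (one column per
(item, category) pair; the chosen category's column carries its sign, the
rest of the item's block is zero), and the *risk score* is simply the sum of
the vector's elements. Scores are split at the empirical 25/50/75
percentiles into quartile groups QR1 (lowest perceived risk) to QR4
(highest). Ties never straddle a boundary and a score exactly on a boundary
goes to the lower group, so group sizes are only approximately equal — the
same behaviour that produces unequal quartile counts in real survey data.

**2. Optimal-scaling categorical PCA.** The signed dummy matrix is
high-dimensional and categorical, so plain PCA is not appropriate. We use
categorical principal component analysis in the Gifi tradition
(princals-style): each variable `j` is replaced by a quantified version
`h_j = G_j y_j` (indicator matrix times category quantifications,
standardized to mean 0 / variance 1), and alternating least squares
minimizes

    loss = sum_j || h_j - X a_j ||^2 / (n m)

over the quantifications, the object scores `X` (normalized `X'X = n I`)
and the loadings `A`. One half-step re-quantifies every variable (the
optimal unrestricted quantification is the vector of category means of the
variable's fitted values, to which the scaling-level restriction is
applied); the other half-step is a rank-`p` SVD of the quantified data
matrix, which also leaves the solution in principal-axes orientation so
per-component variance shares (VAF) are well defined. Both half-steps
minimize the same loss, so the loss sequence is non-increasing — a property
the tests check directly.

Scaling levels: `nominal` leaves quantifications free; `ordinal` (the
default for signed dummies, which carry the order -1 < 0 < +1) restricts
them to be monotone in the category order via weighted
pool-adjacent-violators, in either direction since the loading sign is
free; `numeric` fixes them to the standardized category values, in which
case the quantified matrix *is* the standardized data and the VAF shares
equal classical PCA eigenvalue shares — the module's oracle.

Components are retained by the cumulative-VAF rule: the smallest `k` whose
cumulative share reaches the threshold (80% by default, inclusive).

**3. Cosine-similarity network.** Each respondent's retained component
scores form a vector; every pair with cosine similarity strictly greater
than the cutoff (0.5 by default) is connected. Similarities are computed in
fixed-size row blocks so memory stays bounded for five-digit populations.
The network is embedded in 2-D with a ForceAtlas2-style force-directed
layout: linear attraction along edges, degree-weighted `k_r (d_i+1)(d_j+1)/d`
repulsion between all pairs (exact, or Barnes-Hut-approximated), classic
gravity `g (d_i+1)` toward the origin, and the adaptive global/local speed
scheme that slows swinging nodes. Respondents with similar response
patterns end up close together; dissimilar ones are pushed apart.

**4. Density clustering and profiles.** DBSCAN over the layout coordinates
extracts density-connected groups (core point: at least `min_pts`
neighbours within `eps`, counting itself), leaving sparse respondents as
noise. Each cluster is profiled against the population: prevalence of
gender, age band, quartile membership, and every emotion/media flag, with
deltas against both the full population and the clustered (non-noise)
subset — the two baselines differ and published tables are ambiguous about
which is meant, so both are reported and labelled.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `variance_threshold` | 0.80 | cumulative VAF kept after CAT-PCA (fraction) |
| `scaling_level` | `"ordinal"` | quantification restriction per dummy variable |
| `similarity_cutoff` | 0.5 | cosine threshold for an edge (strict `>`) |
| `layout$k_r` | 2 | repulsion scaling (layout units²) |
| `layout$gravity` | 1 | pull toward the origin |
| `layout$iterations` | 2000 (pipeline) / 1000 (`run_layout`) | fixed iteration count |
| `eps` | from `suggest_eps()` | DBSCAN radius in layout units |
| `min_pts` | 10 | DBSCAN core threshold (includes the point) |
| `top_k` | 13 | clusters profiled |

Every stochastic stage derives its seed deterministically from the single
pipeline seed, so a config reruns to byte-identical artifacts.

## The synthetic generator

Real survey deposits cannot ship with a package, so `simulate_survey()`
generates data with the statistical structure the analysis assumes:

* a latent risk-perception trait `theta` drawn from a two-component normal
  mixture (defaults: means ±1.5, sd 0.6, equal weights) — the source of the
  bimodal score distribution;
* additive trait shifts for women (+0.3) and per age band (+0.06), giving
  the gender/age gradients across quartiles that descriptive tables show;
* graded logistic item responses: the risk-consistent (+1) category is
  chosen with probability `plogis(a_j (theta - b_j))` with discriminations
  `a_j ∈ [1, 2]`; otherwise the risk-inconsistent (-1) category is chosen
  with a probability that *falls* with `theta` (scaled by `minus_tilt`),
  else an unsigned middle category;
* *archetypes*: low-component respondents are assigned one of `A = 3`
  archetypes, each owning a disjoint 12-item block answered with the
  risk-inconsistent category (override probability 0.95). High-trait
  respondents answer homogeneously, low-trait respondents split into
  distinct patterns — exactly the "homogeneous high-risk blob, heterogeneous
  low-risk blobs" geometry the network stage is meant to reveal;
* emotion/media flags drawn as `Bernoulli(plogis(c_f theta + d_f + ...))`
  with slopes mirroring reported trends (alertness/worry strongly positive,
  boredom negative, plus gender/age terms on a few flags).

The generator writes a `responses.csv` / `codebook.yml` / `truth.csv`
triple; the codebook has 40 items and 166 signed dummy columns, matching
the scale of the instrument it emulates.

What the generator does *not* emulate: item nonresponse patterns,
acquiescence and other response styles, correlated item blocks beyond the
archetype structure, or any calibration to the original study's deposited
data. Passing recovery tests therefore show that the pipeline recovers the
structure *this* generative model plants — evidence of correctness of the
machinery, not a replication of the study's field results.

## Numerical choices

* **Constant dummy columns.** A category mapped to sign 0 produces a
  structurally constant (all-zero) dummy column — choosing it is
  indistinguishable from a missing answer under the signed encoding. CAT-PCA
  rejects constant variables, so the pipeline drops them (with a message)
  before fitting; with the reference codebook 86 of 166 columns carry no
  variance.
* **CAT-PCA dimensionality.** `fit_princals()` defaults to a modest
  `ndim`, but the pipeline fits `ndim = min(n - 1, m_active)` so the 80%
  cumulative-VAF cutoff is always reachable; a fixed cap can make the
  selection rule undefined on weakly structured data.
* **Component scaling for similarity.** `select_components()` returns the
  retained components in *principal coordinates* (column variance equal to
  the component's eigenvalue) rather than sphered object scores. Cosine
  similarity on sphered scores weights a noise component as heavily as the
  dominant one; on the synthetic preset that erases the low-risk archetype
  separation entirely, while principal coordinates preserve it. With
  numeric scaling, principal coordinates coincide with classical PCA
  scores. `scaling = "uniform"` restores the sphered scores.
* **Missing responses** contribute a zero block, i.e. 0 to the score — the
  additive score tolerates partial response and no imputation is attempted.
* **Strict cutoff.** An edge requires similarity strictly greater than the
  cutoff; a pair at exactly the cutoff is not connected.
* **Layout iterations.** The pipeline runs a fixed 2000 iterations: dense
  paper-scale networks are still drifting apart at 1000, which can leave
  two genuinely distinct blobs touching and merged by DBSCAN. Fixed counts
  (rather than an early-stopping rule) keep runs deterministic; per-iteration
  swinging/traction are recorded for inspection.
* **Coincident layout points** receive a small deterministic, index-based
  displacement instead of a random jitter, preserving reproducibility.
* **`suggest_eps()`** returns the k-nearest-neighbour distance at the
  elbow (maximum deviation below the chord of the sorted curve), with the
  top 1% of k-distances trimmed before drawing the chord — isolated points
  otherwise drag the chord endpoint up and push the "elbow" into the tail.
* **Bimodality.** `detect_bimodality()` compares one- against two-component
  Gaussian mixtures by BIC and additionally requires (i) component means
  separated by more than the pooled within-component sd and (ii) the fitted
  two-component density to have two local maxima. Condition (ii) matters:
  a *skewed* unimodal score distribution reliably earns a second component
  by BIC without ever producing a second mode.
* **DBSCAN determinism.** Core points are expanded in ascending point
  order and a border point reachable from several clusters joins the
  cluster of its lowest-index core neighbour; clusters are renumbered by
  decreasing size (ties by smallest member index).

## Worked example

```{r example}
library(perceptrisk)

cfg <- pipeline_config(seed = 0)      # synthetic paper-like preset, n = 2000
res <- run_pipeline(cfg)

res$bimodality$is_bimodal             # two modes in the risk scores?
attr(res$reduced, "k")                # components kept at 80% variance
res$recovery$score_correlation       # latent trait vs additive score
res$heterogeneity                     # per-quartile cluster dispersion
```

To analyse a real deposit instead, point the config at files:

```{r files}
cfg <- pipeline_config(responses_path = "responses.csv",
                       codebook_path = "codebook.yml",
                       out_dir = "artifacts")
res <- run_pipeline(cfg)
```

## Problem sizes used by the test suite

The tests exercise the synthetic preset at n = 2000 for the end-to-end
structural checks and n = 60–1500 for unit-level properties; oracle
comparisons (classical PCA, quadratic DBSCAN reference, pair-loop edge
oracle) run at 100–200 observations, where the reference implementations
are exact and fast. These sizes are the package's own choice of a
desk-scale replica of the study design: the original deposit is an order of
magnitude larger, and nothing in the implementation is specific to the
smaller sizes (the similarity pass is blocked, the layout supports
Barnes-Hut repulsion).

## Known limitations

* The instrument itself (item wording, validated sign allocations) is not
  part of the package; the shipped codebook is synthetic and any real
  analysis needs the study's own codebook.
* Quantitative replication of the original study's numbers (166→80
  components, cluster sizes, figure percentages) additionally depends on
  princals, layout and DBSCAN settings the study did not report; the
  pipeline exposes all of them but cannot guess them.
* CAT-PCA treats missing data by zero blocks only (no passive/active
  missing treatments); no rotation options or biplots.
* The layout implements the core ForceAtlas2 forces and adaptive speed,
  not the LinLog / no-overlap / dissuade-hubs variants.
* Clustering operates on the 2-D embedding, as in the modelled study —
  clusters are conditional on the layout, not on the 80-dimensional scores.
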