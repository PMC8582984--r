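Package: perceptrisk
Title: Socio-Mathematical Modeling of Risk Perception from Categorical Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for modeling the heterogeneity of pandemic risk
    perception from categorical survey data. Survey responses are encoded
    as signed dummy variables via a validated codebook, summed into an
    additive risk-perception score with quartile grouping and descriptive
    tables, reduced by optimal-scaling categorical principal component
    analysis (princals-style alternating least squares), and turned into a
    cosine-similarity respondent network that is embedded with a
    ForceAtlas2 force-directed layout and clustered with DBSCAN. Cluster
    profiles compare demographic, emotion and media-use prevalences
    against the population. A synthetic latent-trait survey generator with
    a bimodal trait and low-risk response archetypes makes every stage
    testable without access to the original study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    mclust,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
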