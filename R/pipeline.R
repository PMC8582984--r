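#' Pipeline configuration
#'
#' One object drives the whole analysis: either paths to a responses CSV and
#' a codebook YAML, or the synthetic "paper-like" preset. A single global
#' seed is fanned out deterministically to every stochastic stage.
#'
#' @param responses_path,codebook_path input files (both or neither)
#' @param simulate a [simulation_config()] used when no input files are
#'   given; defaults to the paper-like preset at the configured `seed`
#' @param variance_threshold cumulative-VAF cutoff for component selection
#' @param ndim number of CAT-PCA dimensions; `NULL` = min(n - 1, m) after
#'   dropping constant dummy columns, so the threshold is always reachable
#' @param scaling_level CAT-PCA scaling level ("ordinal", "nominal",
#'   "numeric")
#' @param similarity_cutoff cosine-similarity edge threshold
#' @param block_size row-block size for the pairwise similarity pass
#' @param layout list of [run_layout()] arguments (iterations, k_r, gravity,
#'   tolerance, barnes_hut, theta)
#' @param eps DBSCAN radius; `NULL` = take it from [suggest_eps()]
#' @param min_pts DBSCAN minimum neighbourhood size
#' @param top_k number of clusters to profile
#' @param bin_width risk-histogram bin width
#' @param seed global seed
#' @param out_dir artifact directory; `NULL` = no files written
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(responses_path = NULL, codebook_path = NULL,
                            simulate = NULL, variance_threshold = 0.8,
                            ndim = NULL, scaling_level = "ordinal",
                            similarity_cutoff = 0.5, block_size = 1024L,
                            layout = list(), eps = NULL, min_pts = 10L,
                            top_k = 13L, bin_width = 1L, seed = 0L,
                            out_dir = NULL) {
  .assert(is.null(responses_path) == is.null(codebook_path),
          "give both `responses_path` and `codebook_path`, or neither")
  if (is.null(responses_path) && is.null(simulate))
    simulate <- simulation_config(seed = seed)
  structure(as.list(environment()), class = "pipeline_config")
}

stage_seed <- function(seed, offset) as.integer(seed) + offset

#' Run the full risk-perception pipeline
#'
#' Executes encode -> score/quartiles/describe -> CAT-PCA reduce -> cosine
#' network -> ForceAtlas2 layout -> DBSCAN cluster -> profile, plus a
#' ground-truth recovery report when the input is synthetic. When
#' `config$out_dir` is set, every intermediate artifact is written as CSV
#' (plus GraphML for the network) together with a JSON run manifest listing
#' each stage, its parameters, seed and artifact checksums.
#'
#' @param config a [pipeline_config()]
#' @param verbose print a line per stage
#' @return list of class `pipeline_result` with elements `responses`,
#'   `codebook`, `risk_matrix`, `scores`, `quartiles`, `histogram`,
#'   `bimodality`, `tables` (contingency + frequency profiles), `princals`,
#'   `reduced`, `graph`, `layout`, `clustering`, `profile`, `heterogeneity`,
#'   `recovery` (when truth available), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  .assert(inherits(config, "pipeline_config"),
          "`config` must come from pipeline_config()")
  t0 <- Sys.time()
  manifest <- list(created = format(t0, "%Y-%m-%dT%H:%M:%S"),
                   package_version = as.character(utils::packageVersion("perceptrisk")),
                   seed = config$seed, stages = list())
  say <- function(...) if (verbose) message(sprintf(...))
  note_stage <- function(name, params) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(stage = name, params = params)
  }
  fail <- function(stage, e) stop("pipeline stage '", stage, "' failed: ",
                                  conditionMessage(e), call. = FALSE)

  # -- stage 1: input -------------------------------------------------------
  truth <- NULL
  tryCatch({
    if (!is.null(config$responses_path)) {
      codebook <- load_codebook(config$codebook_path)
      responses <- load_responses(config$responses_path, codebook)
      note_stage("input", list(responses = config$responses_path,
                               codebook = config$codebook_path,
                               n = n_respondents(responses)))
    } else {
      sim <- simulate_survey(config$simulate)
      responses <- sim$responses
      codebook <- sim$codebook
      truth <- sim$truth
      note_stage("input", list(simulate = "synthetic",
                               seed = config$simulate$seed,
                               n = n_respondents(responses)))
    }
  }, error = function(e) fail("input", e))
  say("input: %d respondents, %d items", n_respondents(responses),
      length(codebook$items))

  # -- stage 2: encode ------------------------------------------------------
  risk_matrix <- tryCatch(encode_risk_matrix(responses, codebook),
                          error = function(e) fail("encode", e))
  note_stage("encode", list(m = ncol(risk_matrix)))
  say("encode: %d x %d signed dummy matrix", nrow(risk_matrix), ncol(risk_matrix))

  # -- stage 3: score + describe -------------------------------------------
  tryCatch({
    scores <- risk_score(risk_matrix)
    quartiles <- assign_quartiles(scores)
    histogram <- risk_histogram(scores, config$bin_width)
    bimodality <- detect_bimodality(scores)
    bands <- age_band(responses$demographics$age)
    tables <- list(
      gender_by_quartile = contingency_table(responses$demographics$gender,
                                             quartiles),
      age_by_quartile = contingency_table(bands, quartiles),
      emotions_by_quartile_gender = frequency_profile(
        data.frame(quartile = quartiles, gender = responses$demographics$gender),
        responses$emotions),
      media_by_quartile_gender = frequency_profile(
        data.frame(quartile = quartiles, gender = responses$demographics$gender),
        responses$media),
      emotions_by_quartile_age = frequency_profile(
        data.frame(quartile = quartiles, age_band = bands),
        responses$emotions))
    tables$chi_square_gender <- chi_square_test(tables$gender_by_quartile)
  }, error = function(e) fail("score", e))
  note_stage("score", list(bin_width = config$bin_width,
                           bimodal = bimodality$is_bimodal))
  say("score: range [%d, %d], bimodal = %s", min(scores), max(scores),
      bimodality$is_bimodal)

  # -- stage 4: reduce (CAT-PCA) -------------------------------------------
  tryCatch({
    keep <- apply(risk_matrix, 2, function(col) length(unique(col)) > 1)
    if (any(!keep))
      message("dropping ", sum(!keep),
              " constant dummy columns before CAT-PCA")
    active <- risk_matrix[, keep, drop = FALSE]
    ndim <- config$ndim %||% min(nrow(active) - 1L, ncol(active))
    princals <- fit_princals(active, ndim = ndim,
                             level = config$scaling_level,
                             seed = stage_seed(config$seed, 1L))
    reduced <- select_components(princals, config$variance_threshold)
  }, error = function(e) fail("reduce", e))
  note_stage("reduce", list(ndim = ndim, level = config$scaling_level,
                            threshold = config$variance_threshold,
                            k = attr(reduced, "k"),
                            seed = stage_seed(config$seed, 1L)))
  say("reduce: %d active columns -> %d components (%.1f%% variance)",
      ncol(active), attr(reduced, "k"), 100 * attr(reduced, "cumulative_vaf"))

  # -- stage 5: network -----------------------------------------------------
  tryCatch({
    node_attrs <- data.frame(quartile = paste0("QR", quartiles),
                             gender = responses$demographics$gender,
                             age_band = as.character(age_band(responses$demographics$age)),
                             stringsAsFactors = FALSE)
    graph <- build_graph(reduced, cutoff = config$similarity_cutoff,
                         block_size = config$block_size,
                         node_attrs = node_attrs)
  }, error = function(e) fail("network", e))
  note_stage("network", list(cutoff = config$similarity_cutoff,
                             block_size = config$block_size,
                             n_edges = graph$n_edges))
  say("network: %d edges above cutoff %.2f", graph$n_edges,
      config$similarity_cutoff)

  # -- stage 6: layout ------------------------------------------------------
  tryCatch({
    # 2000 iterations by default: the dense paper-scale networks are still
    # drifting apart at 1000, which can leave distinct blobs touching
    layout_args <- utils::modifyList(
      list(iterations = 2000L, k_r = 2, gravity = 1, tolerance = 1,
           barnes_hut = NULL, theta = 0.9), config$layout)
    layout <- do.call(run_layout,
                      c(list(graph = graph,
                             seed = stage_seed(config$seed, 2L)), layout_args))
  }, error = function(e) fail("layout", e))
  note_stage("layout", c(layout_args, list(seed = stage_seed(config$seed, 2L))))
  say("layout: %d iterations done", layout_args$iterations)

  # -- stage 7: cluster + profile ------------------------------------------
  tryCatch({
    pts <- as.matrix(layout$coords[, c("x", "y")])
    eps <- config$eps %||% suggest_eps(pts, k = config$min_pts)$eps
    clustering <- dbscan(pts, eps = eps, min_pts = config$min_pts)
    profile <- suppressWarnings(
      profile_clusters(clustering, responses, quartiles,
                       top_k = config$top_k))
    heterogeneity <- if (length(clustering$sizes) >= 2)
      heterogeneity_summary(clustering, quartiles) else NULL
  }, error = function(e) fail("cluster", e))
  note_stage("cluster", list(eps = eps, min_pts = config$min_pts,
                             top_k = config$top_k,
                             n_clusters = length(clustering$sizes),
                             coverage = profile$coverage))
  say("cluster: %d clusters (eps = %.3f), coverage %.1f%%",
      length(clustering$sizes), eps, 100 * profile$coverage)

  recovery <- if (!is.null(truth))
    recovery_report(truth, scores, quartiles, clustering) else NULL

  result <- list(responses = responses, codebook = codebook,
                 risk_matrix = risk_matrix, scores = scores,
                 quartiles = quartiles, histogram = histogram,
                 bimodality = bimodality, tables = tables,
                 princals = princals, reduced = reduced, graph = graph,
                 layout = layout, clustering = clustering, profile = profile,
                 heterogeneity = heterogeneity, recovery = recovery,
                 truth = truth, manifest = manifest)

  if (!is.null(config$out_dir)) {
    result$manifest <- write_artifacts(result, config)
  }
  class(result) <- "pipeline_result"
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", length(x$scores), "respondents\n")
  cat("  score range:", min(x$scores), "..", max(x$scores),
      "| bimodal:", x$bimodality$is_bimodal, "\n")
  cat("  reduced to", attr(x$reduced, "k"), "components |", x$graph$n_edges,
      "edges |", length(x$clustering$sizes), "clusters\n")
  invisible(x)
}

write_artifacts <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  wcsv <- function(df, f) { utils::write.csv(df, p(f), row.names = FALSE); f }
  files <- character(0)
  files <- c(files, wcsv(data.frame(respondent_id = names(result$scores),
                                    score = as.integer(result$scores),
                                    quartile = as.integer(result$quartiles)),
                         "scores.csv"))
  files <- c(files, wcsv(result$histogram, "histogram.csv"))
  xt <- result$tables$gender_by_quartile$counts_with_margins
  files <- c(files, wcsv(cbind(gender = rownames(xt), as.data.frame(xt)),
                         "gender_by_quartile.csv"))
  files <- c(files, wcsv(result$tables$emotions_by_quartile_gender,
                         "emotions_by_quartile_gender.csv"))
  files <- c(files, wcsv(result$tables$media_by_quartile_gender,
                         "media_by_quartile_gender.csv"))
  files <- c(files, wcsv(data.frame(component = seq_along(result$princals$vaf),
                                    vaf = result$princals$vaf,
                                    cumulative = cumsum(result$princals$vaf)),
                         "vaf.csv"))
  red <- as.data.frame(result$reduced)
  files <- c(files, wcsv(cbind(respondent_id = names(result$scores), red),
                         "components.csv"))
  export_graph(result$graph, p("network.graphml"), "graphml")
  export_graph(result$graph, p("network_edges.csv"), "edgelist")
  files <- c(files, "network.graphml", "network_edges.csv")
  files <- c(files, wcsv(result$layout$coords, "layout.csv"))
  files <- c(files, wcsv(data.frame(respondent_id = names(result$scores),
                                    cluster = result$clustering$cluster),
                         "clusters.csv"))
  files <- c(files, wcsv(result$profile$profile, "cluster_profiles.csv"))
  if (!is.null(result$heterogeneity))
    files <- c(files, wcsv(result$heterogeneity, "heterogeneity.csv"))
  manifest <- result$manifest
  sums <- tools::md5sum(file.path(config$out_dir, files))
  manifest$artifacts <- lapply(seq_along(files), function(i)
    list(file = files[i], md5 = unname(sums[i])))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest
}
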