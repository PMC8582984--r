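#' Reference synthetic codebook
#'
#' Deterministic codebook shaped like the study instrument: 40 single-choice
#' items spread over the three risk dimensions (knowledge,
#' perception/severity, preventive practice), with 34 four-category and 6
#' five-category items for a total of 166 signed dummy columns. In every
#' item the first category is the risk-consistent answer (+1), the last the
#' risk-inconsistent one (-1), and the middle categories carry no sign.
#'
#' @param n_items number of items (default 40); the first
#'   `min(6, n_items)` items get 5 categories, the rest 4
#' @return a `perceptrisk_codebook`
#' @export
default_codebook <- function(n_items = 40L) {
  .assert(n_items >= 1, "`n_items` must be >= 1")
  dims <- rep(RISK_DIMENSIONS, length.out = n_items)
  dims <- sort(dims)  # contiguous dimension blocks, like a questionnaire
  items <- lapply(seq_len(n_items), function(j) {
    k <- if (j <= min(6L, n_items)) 5L else 4L
    cats <- if (k == 5L) c("always", "often", "sometimes", "rarely", "never")
            else c("always", "often", "rarely", "never")
    list(item_id = sprintf("Q%02d", j), dimension = dims[j],
         categories = cats,
         signs = c(1L, rep(0L, k - 2L), -1L))
  })
  codebook(items)
}

#' Configuration for the synthetic survey generator
#'
#' The generator emulates the statistical structure the analysis assumes: a
#' latent risk-perception trait theta drawn from a two-component (bimodal)
#' normal mixture, shifted upward for women and for older age bands; graded
#' logistic item responses whose risk-consistent probability increases with
#' theta; a set of disjoint low-risk response archetypes that make the
#' low-perception population heterogeneous while the high-perception
#' population answers homogeneously; and emotion/media flags that are
#' Bernoulli with logistic probabilities monotone in theta (boredom runs the
#' other way, and a few flags carry gender/age terms).
#'
#' @param n number of respondents
#' @param seed integer RNG seed; the whole dataset is reproducible from it
#' @param mixture_weights length-2 weights (low, high), summing to 1
#' @param mixture_means,mixture_sds length-2 trait means / sds (low, high)
#' @param gender_effect additive trait shift for women
#' @param age_effect additive trait shift per age band above the first
#' @param age_band_probs sampling probabilities of the eight age bands
#' @param female_prob probability of gender female
#' @param n_items number of items passed to [default_codebook()]
#' @param discrimination_range range of the per-item logistic slopes a_j
#' @param difficulty_range range of the per-item logistic locations b_j
#' @param n_archetypes number of low-risk archetypes A >= 1
#' @param archetype_items items per archetype block (disjoint blocks)
#' @param archetype_strength per-item probability that an archetype member's
#'   response is overridden by the archetype's fixed pattern
#' @param minus_tilt scale of the risk-inconsistent choice probability among
#'   non-consistent answers (lower = more weight on unsigned categories)
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n = 2000L, seed = 0L,
                              mixture_weights = c(0.5, 0.5),
                              mixture_means = c(-1.5, 1.5),
                              mixture_sds = c(0.6, 0.6),
                              gender_effect = 0.3,
                              age_effect = 0.06,
                              age_band_probs = c(0.43, 0.205, 0.134, 0.111,
                                                 0.08, 0.0345, 0.0045, 0.0005),
                              female_prob = 0.62,
                              n_items = 40L,
                              discrimination_range = c(1, 2),
                              difficulty_range = c(-0.5, 0.5),
                              n_archetypes = 3L,
                              archetype_items = 12L,
                              archetype_strength = 0.95,
                              minus_tilt = 0.35) {
  .assert(abs(sum(mixture_weights) - 1) < 1e-9, "mixture weights must sum to 1")
  .assert(all(mixture_sds > 0), "mixture sds must be positive")
  .assert(n_archetypes >= 1, "need at least one archetype")
  .assert(length(age_band_probs) == length(DEFAULT_AGE_BANDS),
          "need one probability per age band")
  if (n_archetypes * archetype_items > n_items)
    stop("archetype blocks (", n_archetypes, " x ", archetype_items,
         " items) exceed the ", n_items, " available items", call. = FALSE)
  structure(as.list(environment()), class = "simulation_config")
}

#' Generate a synthetic survey dataset
#'
#' Draws a full respondent table plus ground truth from a
#' [simulation_config()]; see that help page for the generative model. When
#' `dir` is given, also writes `responses.csv`, `codebook.yml`,
#' `truth.csv` and a `config.yml` echo, which round-trip through
#' [load_responses()] without warnings.
#'
#' @param config a `simulation_config`
#' @param dir optional output directory (created if needed)
#' @return list of class `synthetic_survey`: `responses`
#'   (`perceptrisk_responses`), `codebook`, `truth` (data frame with
#'   `respondent_id`, `theta`, `component`, `archetype`), `config`, and
#'   `paths` when files were written.
#' @export
simulate_survey <- function(config = simulation_config(), dir = NULL) {
  .assert(inherits(config, "simulation_config"),
          "`config` must come from simulation_config()")
  cb <- default_codebook(config$n_items)
  n <- config$n
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(config$seed)

  gender <- ifelse(stats::runif(n) < config$female_prob, "female", "male")
  band_idx <- sample.int(length(config$age_band_probs), n, replace = TRUE,
                         prob = config$age_band_probs)
  band_lo <- DEFAULT_AGE_BANDS[band_idx]
  band_hi <- c(DEFAULT_AGE_BANDS[-1] - 1, 95)[band_idx]
  age <- band_lo + floor(stats::runif(n) * (band_hi - band_lo + 1))

  comp <- ifelse(stats::runif(n) < config$mixture_weights[1], 1L, 2L)
  theta <- stats::rnorm(n, config$mixture_means[comp], config$mixture_sds[comp]) +
    config$gender_effect * (gender == "female") +
    config$age_effect * (band_idx - 1L)

  m_items <- config$n_items
  a <- stats::runif(m_items, config$discrimination_range[1],
                    config$discrimination_range[2])
  b <- stats::runif(m_items, config$difficulty_range[1],
                    config$difficulty_range[2])

  # archetypes: disjoint item blocks; members answer their block with the
  # risk-inconsistent category, which makes low-trait response patterns
  # heterogeneous across archetypes but homogeneous within one
  A <- config$n_archetypes
  arch_blocks <- split(seq_len(A * config$archetype_items),
                       rep(seq_len(A), each = config$archetype_items))
  archetype <- ifelse(comp == 1L, sample.int(A, n, replace = TRUE), NA_integer_)

  items <- as.data.frame(matrix(NA_character_, n, m_items), optional = TRUE)
  names(items) <- names(cb$items)
  for (j in seq_len(m_items)) {
    cats <- cb$items[[j]]$categories
    k <- length(cats)
    eta <- a[j] * (theta - b[j])
    u <- stats::runif(n)
    p_plus <- stats::plogis(eta)
    choice <- integer(n)
    plus <- u < p_plus
    choice[plus] <- 1L
    rest <- which(!plus)
    p_minus <- config$minus_tilt * stats::plogis(-eta[rest])
    u2 <- stats::runif(length(rest))
    minus <- u2 < p_minus
    choice[rest[minus]] <- k
    zeros <- rest[!minus]
    choice[zeros] <- if (k > 2L)
      1L + sample.int(k - 2L, length(zeros), replace = TRUE) else k
    items[[j]] <- cats[choice]
  }
  for (aidx in seq_len(A)) {
    members <- which(!is.na(archetype) & archetype == aidx)
    for (j in arch_blocks[[aidx]]) {
      cats <- cb$items[[j]]$categories
      hit <- members[stats::runif(length(members)) < config$archetype_strength]
      items[[j]][hit] <- cats[length(cats)]  # the -1 category
    }
  }

  flag_prob <- function(slope, intercept, extra = 0)
    stats::plogis(slope * theta + intercept + extra)
  emotion_spec <- list(  # slopes/intercepts chosen to mirror the reported trends
    alertness  = flag_prob(0.6, 0.7),
    worry      = flag_prob(0.5, 0.5),
    isolation  = flag_prob(0.3, 0.1, 0.25 * (gender == "female")),
    anxiety    = flag_prob(0.3, -0.3, 0.6 * (gender == "female") -
                             0.05 * (band_idx - 1L)),
    alarm      = flag_prob(0.4, -0.6, 0.2 * (gender == "female")),
    boredom    = flag_prob(-0.25, -0.5, -0.12 * (band_idx - 1L) + 0.35),
    confusion  = flag_prob(-0.1, -0.7, -0.1 * (band_idx - 1L) +
                             0.15 * (gender == "female")),
    fear       = flag_prob(0.35, -0.9, 0.2 * (gender == "female")),
    depression = flag_prob(-0.05, -1.0, 0.15 * (gender == "female") -
                             0.1 * (band_idx - 1L)))
  media_spec <- list(
    social_media = flag_prob(0.25, 0.7, -0.18 * (band_idx - 1L)),
    ministry_announcements = flag_prob(0.45, 0.4, 0.3 * (gender == "female")),
    television = flag_prob(0.2, 0.2),
    websites = flag_prob(0.3, 0.2, -0.2 * (gender == "female")),
    official_websites = flag_prob(0.35, -0.2),
    newspapers = flag_prob(0.3, -0.4, 0.12 * (band_idx - 1L)))
  draw_flags <- function(spec) as.data.frame(
    lapply(spec, function(p) stats::runif(n) < p), optional = TRUE)
  emotions <- draw_flags(emotion_spec)
  media <- draw_flags(media_spec)

  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)

  id <- sprintf("R%05d", seq_len(n))
  raw <- data.frame(respondent_id = id, age = age, gender = gender,
                    civil_status = ifelse(theta > stats::median(theta),
                                          "partner", "no_partner"),
                    education = "university",
                    position = ifelse(band_idx == 1L, "student", "staff"),
                    stringsAsFactors = FALSE)
  raw <- cbind(raw, items,
               as.data.frame(lapply(emotions, as.integer), optional = TRUE),
               as.data.frame(lapply(media, as.integer), optional = TRUE))
  responses <- as_responses(raw, cb)
  truth <- data.frame(respondent_id = id, theta = theta,
                      component = c("low", "high")[comp],
                      archetype = archetype, stringsAsFactors = FALSE)

  out <- list(responses = responses, codebook = cb, truth = truth,
              config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(responses = file.path(dir, "responses.csv"),
                  codebook = file.path(dir, "codebook.yml"),
                  truth = file.path(dir, "truth.csv"),
                  config = file.path(dir, "config.yml"))
    utils::write.csv(raw, paths$responses, row.names = FALSE)
    write_codebook(cb, paths$codebook)
    utils::write.csv(truth, paths$truth, row.names = FALSE)
    cfg <- unclass(config)
    yaml::write_yaml(cfg[order(names(cfg))], paths$config)
    out$paths <- paths
  }
  structure(out, class = "synthetic_survey")
}

#' @export
print.synthetic_survey <- function(x, ...) {
  cat("<synthetic_survey>", x$config$n, "respondents, seed", x$config$seed,
      "\n")
  invisible(x)
}

#' Ground-truth recovery metrics for a pipeline run
#'
#' Measures how well the analysis recovers the generator's ground truth:
#' the correlation between the latent trait and the additive risk score, the
#' fraction of high-component respondents placed in the upper two quartiles,
#' the cluster-entropy contrast between the lowest and highest quartile, and
#' the adjusted Rand agreement between low-trait archetypes and cluster
#' labels.
#'
#' @param truth the `truth` data frame of a [simulate_survey()] result
#' @param scores named risk scores (names = respondent ids)
#' @param quartiles named quartile labels
#' @param assignment a `dbscan_clustering` or integer labels aligned with
#'   `scores`
#' @return list with `score_correlation`, `high_in_upper_quartiles`,
#'   `qr1_entropy`, `qr4_entropy`, `qr1_clusters_5pct`,
#'   `qr4_top_cluster_share`, `archetype_ari`.
#' @export
recovery_report <- function(truth, scores, quartiles, assignment = NULL) {
  ids <- names(scores)
  .assert(!is.null(ids) && setequal(ids, truth$respondent_id) &&
            length(ids) == nrow(truth),
          "score names and truth respondent ids are misaligned")
  theta <- truth$theta[match(ids, truth$respondent_id)]
  out <- list(score_correlation = stats::cor(theta, as.numeric(scores)),
              high_in_upper_quartiles = mean(
                quartiles[truth$component[match(ids, truth$respondent_id)] ==
                            "high"] >= 3L))
  if (!is.null(assignment)) {
    labels <- if (inherits(assignment, "dbscan_clustering")) assignment$cluster
              else as.integer(assignment)
    het <- heterogeneity_summary(labels, quartiles)
    out$qr1_entropy <- het$entropy[het$quartile == 1]
    out$qr4_entropy <- het$entropy[het$quartile == max(het$quartile)]
    out$qr1_clusters_5pct <- het$n_clusters_5pct[het$quartile == 1]
    out$qr4_top_cluster_share <- het$top_cluster_share[het$quartile == max(het$quartile)]
    arch <- truth$archetype[match(ids, truth$respondent_id)]
    low_clustered <- which(!is.na(arch) & labels > 0L)
    out$archetype_ari <- if (length(low_clustered) > 1)
      mclust::adjustedRandIndex(arch[low_clustered], labels[low_clustered])
    else NA_real_
  }
  out
}
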