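#' Additive risk-perception score
#'
#' The risk score of a respondent is the sum of all elements of their signed
#' dummy risk vector; higher scores mean a higher perception of risk. With m
#' dummy columns the score is bounded by \[-m, +m\].
#'
#' @param matrix risk matrix from [encode_risk_matrix()]
#' @return named integer vector of row sums.
#' @export
risk_score <- function(matrix) {
  .assert(is.matrix(matrix), "`matrix` must be a matrix")
  s <- rowSums(matrix)
  storage.mode(s) <- "integer"
  s
}

#' Quartile grouping of risk scores
#'
#' Respondents are split at the empirical 25/50/75 percentiles of the score
#' distribution: group 1 holds the lowest perception of risk, group 4 the
#' highest. A score value never straddles two groups (all ties share one
#' label), and a score exactly on a boundary goes to the lower group, so
#' group sizes are only approximately equal.
#'
#' @param scores integer vector from [risk_score()]
#' @return integer vector of labels in 1..4, named like `scores`.
#' @export
assign_quartiles <- function(scores) {
  n <- length(scores)
  .assert(n >= 4, "need at least 4 respondents to form quartiles")
  if (length(unique(scores)) == 1L) {
    warning("all risk scores are equal; every respondent placed in group 1")
    return(setNames(rep(1L, n), names(scores)))
  }
  cuts <- stats::quantile(scores, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  lab <- 1L + (scores > cuts[1]) + (scores > cuts[2]) + (scores > cuts[3])
  setNames(as.integer(lab), names(scores))
}

#' Histogram of risk scores
#'
#' @param scores integer score vector
#' @param bin_width positive integer bin width
#' @return data frame with `bin_left`, `bin_right`, `count`; contiguous
#'   half-open bins `[left, right)` covering the score range (the last bin is
#'   closed). Empty input gives a zero-row frame.
#' @export
risk_histogram <- function(scores, bin_width = 1L) {
  .assert(bin_width >= 1, "`bin_width` must be >= 1")
  if (length(scores) == 0)
    return(data.frame(bin_left = numeric(0), bin_right = numeric(0),
                      count = integer(0)))
  lo <- min(scores)
  breaks <- seq(lo, max(scores) + bin_width, by = bin_width)
  idx <- pmin(findInterval(scores, breaks), length(breaks) - 1L)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  data.frame(bin_left = breaks[-length(breaks)], bin_right = breaks[-1],
             count = as.integer(counts))
}

#' Test the score distribution for bimodality
#'
#' Fits one- and two-component univariate Gaussian mixtures (unequal
#' variances, via \pkg{mclust}) and flags the distribution bimodal when the
#' two-component model wins on BIC, the component means are separated by
#' more than the pooled within-component standard deviation, *and* the
#' fitted two-component density actually has two local maxima. The extra
#' conditions guard against well-supported but overlapping components and
#' against skewed unimodal distributions, both of which earn a second
#' component without producing a second mode.
#'
#' @param scores numeric score vector, length >= 50
#' @return list with `is_bimodal` (logical), `component_means` (length-2
#'   numeric, NA when degenerate), `bic` (named numeric, G=1 and G=2).
#' @export
detect_bimodality <- function(scores) {
  .assert(length(scores) >= 50, "need at least 50 scores")
  if (stats::sd(scores) < .Machine$double.eps^0.5) {
    warning("degenerate (constant) score distribution; not bimodal")
    return(list(is_bimodal = FALSE, component_means = c(NA_real_, NA_real_),
                bic = c(`1` = NA_real_, `2` = NA_real_)))
  }
  x <- as.numeric(scores)
  fit1 <- Mclust(x, G = 1, modelNames = "V", verbose = FALSE)
  fit2 <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit2)) {
    warning("two-component mixture fit failed; reporting unimodal")
    return(list(is_bimodal = FALSE, component_means = c(NA_real_, NA_real_),
                bic = c(`1` = fit1$bic, `2` = NA_real_)))
  }
  mu <- as.numeric(fit2$parameters$mean)
  vars <- fit2$parameters$variance$sigmasq
  if (length(vars) == 1) vars <- rep(vars, 2)
  w <- fit2$parameters$pro
  pooled_sd <- sqrt(sum(w * vars))
  separated <- abs(diff(mu)) > pooled_sd
  # count modes of the fitted mixture density on a fine grid
  grid <- seq(min(x), max(x), length.out = 512)
  dens <- w[1] * stats::dnorm(grid, mu[1], sqrt(vars[1])) +
    w[2] * stats::dnorm(grid, mu[2], sqrt(vars[2]))
  n_modes <- sum(diff(sign(diff(dens))) == -2) +
    (dens[1] > dens[2]) + (dens[512] > dens[511])
  list(is_bimodal = isTRUE(fit2$bic > fit1$bic) && separated && n_modes >= 2,
       component_means = sort(mu),
       bic = c(`1` = fit1$bic, `2` = fit2$bic))
}

#' Contingency table with margins and grand-total percentages
#'
#' Lays out counts the way the study's population-distribution table does:
#' one row per `rows` level, one column per `cols` level, row/column/grand
#' totals, and each cell also expressed as a percentage of the grand total.
#'
#' @param rows,cols equal-length categorical label vectors
#' @return list of class `perceptrisk_xtab`: `counts` (matrix without
#'   margins), `counts_with_margins`, `percent` (of grand total), `n`.
#' @export
contingency_table <- function(rows, cols) {
  .assert(length(rows) == length(cols),
          "`rows` and `cols` must have the same length")
  counts <- unclass(table(rows, cols))
  wm <- stats::addmargins(as.table(counts))
  dimnames(wm) <- lapply(dimnames(wm), function(d) sub("^Sum$", "Total", d))
  n <- length(rows)
  structure(list(counts = counts,
                 counts_with_margins = unclass(wm),
                 percent = if (n > 0) 100 * unclass(wm) / n else unclass(wm) * NA,
                 n = n),
            class = "perceptrisk_xtab")
}

#' @export
print.perceptrisk_xtab <- function(x, ...) {
  cat("<perceptrisk_xtab> n =", x$n, "\n")
  print(x$counts_with_margins)
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson statistic sum((O-E)^2/E) on a counts matrix with
#' df = (r-1)(c-1) and an upper-tail p value; no continuity correction.
#'
#' @param table integer counts matrix (no margins), or a `perceptrisk_xtab`
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(table) {
  if (inherits(table, "perceptrisk_xtab")) table <- table$counts
  .assert(is.matrix(table) && all(table >= 0), "`table` must be a counts matrix")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column marginal; expected counts undefined", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  .assert(all(ht$expected > 0), "expected counts must all be positive")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Cut ages into the study's descriptive bands
#'
#' @param age integer ages
#' @param bands increasing vector of band lower bounds (default 15, 25, ...,
#'   85; the last band is open-ended)
#' @return factor with labels like `"15-24"`, ..., `"85+"`.
#' @export
age_band <- function(age, bands = DEFAULT_AGE_BANDS) {
  .assert(all(diff(bands) > 0), "`bands` must be strictly increasing")
  labels <- c(paste0(bands[-length(bands)], "-", bands[-1] - 1),
              paste0(bands[length(bands)], "+"))
  cut(age, breaks = c(bands, Inf), labels = labels, right = FALSE)
}

#' Per-group frequency profile of binary flags
#'
#' For every combination of the grouping variables (e.g. risk quartile x
#' gender) and every flag (emotion or media use), reports how many group
#' members carry the flag and what percentage of the group that is — the
#' long-format equivalent of the study's heatmap figures.
#'
#' @param groups data frame of grouping variables (factors or labels), one
#'   row per respondent
#' @param flags logical data frame, row-aligned with `groups`
#' @return long data frame: grouping columns, `flag`, `n_group`, `count`,
#'   `percent` (NA for empty groups).
#' @export
frequency_profile <- function(groups, flags) {
  .assert(is.data.frame(groups) && ncol(groups) >= 1, "`groups` must be a data frame")
  .assert(nrow(groups) == nrow(flags), "`groups` and `flags` must be row-aligned")
  .assert(nrow(groups) > 0, "`groups` must be nonempty")
  gf <- lapply(groups, function(g) if (is.factor(g)) g else factor(g))
  key <- do.call(interaction, c(gf, list(drop = FALSE, sep = "\r")))
  levels_df <- as.data.frame(do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE)),
                             stringsAsFactors = FALSE)
  names(levels_df) <- names(groups)
  n_group <- as.integer(table(key))
  out <- do.call(rbind, lapply(names(flags), function(f) {
    cnt <- tapply(as.integer(flags[[f]]), key, sum)
    cnt <- as.integer(ifelse(is.na(cnt), 0L, cnt))
    cbind(levels_df,
          data.frame(flag = f, n_group = n_group, count = cnt,
                     percent = ifelse(n_group > 0, 100 * cnt / n_group, NA_real_),
                     stringsAsFactors = FALSE))
  }))
  rownames(out) <- NULL
  out
}
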