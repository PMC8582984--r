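test_that("risk scores are row sums and conserve the matrix total", {
  m <- rbind(c(0L, 0L, 0L), c(1L, 1L, -1L), c(-1L, -1L, -1L))
  rownames(m) <- c("a", "b", "c")
  s <- risk_score(m)
  expect_identical(unname(s), c(0L, 1L, -3L))
  expect_identical(names(s), rownames(m))

  set.seed(9)
  r <- matrix(sample(c(-1L, 0L, 1L), 300, TRUE), 30)
  expect_equal(sum(risk_score(r)), sum(r))
  expect_true(all(abs(risk_score(r)) <= ncol(r)))
})

test_that("quartile labels follow the percentile rule and are monotone", {
  expect_equal(unname(assign_quartiles(1:8)), c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_error(assign_quartiles(1:3), "at least 4")
  expect_warning(q <- assign_quartiles(rep(5L, 10)), "all risk scores")
  expect_true(all(q == 1L))

  set.seed(21)
  for (rep in 1:5) {
    s <- sample(-20:20, 50, replace = TRUE)
    q <- assign_quartiles(s)
    # monotone in the score, ties share a label
    expect_true(all(diff(q[order(s)]) >= 0))
    expect_equal(length(unique(tapply(q, s, function(x) length(unique(x))))), 1L)
    expect_true(all(tapply(q, s, function(x) length(unique(x))) == 1L))
  }
})

test_that("histograms cover the range and conserve counts", {
  expect_equal(nrow(risk_histogram(integer(0))), 0L)
  h <- risk_histogram(c(0L, 0L, 1L), bin_width = 1L)
  expect_equal(h$count, c(2L, 1L))
  expect_equal(h$bin_left, c(0, 1))

  set.seed(3)
  s <- sample(-15:25, 200, TRUE)
  for (w in c(1L, 3L, 5L)) {
    h <- risk_histogram(s, w)
    expect_equal(sum(h$count), 200L)
    expect_true(all(diff(h$bin_left) == w))
  }
})

test_that("bimodality detection separates mixtures from single normals", {
  set.seed(5)
  two <- c(rnorm(250, -20, 5), rnorm(250, 20, 5))
  res <- detect_bimodality(two)
  expect_true(res$is_bimodal)
  expect_equal(res$component_means, c(-20, 20), tolerance = 0.15)

  expect_warning(flat <- detect_bimodality(rep(3, 60)), "degenerate")
  expect_false(flat$is_bimodal)

  # under a single normal the two-component model should rarely win
  hits <- vapply(1:20, function(seed) {
    set.seed(seed)
    detect_bimodality(rnorm(500))$is_bimodal
  }, logical(1))
  expect_lte(sum(hits), 1L)
})

test_that("contingency tables reproduce the study's marginal layout", {
  xt <- contingency_table("female", "1")
  expect_equal(unname(xt$counts_with_margins["Total", "Total"]), 1)

  # rebuild respondent-level labels from the printed gender x quartile counts
  counts <- rbind(male = c(1395, 1422, 1015, 976),
                  female = c(1785, 1992, 1932, 2132))
  gender <- rep(rep(rownames(counts), each = 4), times = as.vector(t(counts)))
  quart <- rep(rep(1:4, times = 2), times = as.vector(t(counts)))
  xt <- contingency_table(gender, quart)
  expect_equal(unname(xt$counts["female", ]), c(1785, 1992, 1932, 2132))
  expect_equal(unname(xt$counts_with_margins["female", "Total"]), 7841)
  expect_equal(xt$n, 12649)

  set.seed(12)
  a <- sample(letters[1:3], 100, TRUE); b <- sample(LETTERS[1:4], 100, TRUE)
  xt <- contingency_table(a, b)
  expect_equal(unname(xt$counts_with_margins["Total", "Total"]), 100)
  expect_equal(unname(rowSums(xt$counts)),
               unname(xt$counts_with_margins[seq_len(3), "Total"]))
})

test_that("chi-square matches the direct Pearson formula", {
  prop <- outer(c(10, 20), c(3, 7)) / 10  # exactly proportional to margins
  res <- chi_square_test(prop)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  tab <- rbind(c(10, 20), c(20, 10))
  res <- chi_square_test(tab)
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - exp_counts)^2 / exp_counts),
               tolerance = 1e-12)
  expect_equal(res$df, 1)

  set.seed(8)
  for (rep in 1:10) {
    t2 <- matrix(sample(1:30, 6), 2)
    res <- chi_square_test(t2)
    e <- outer(rowSums(t2), colSums(t2)) / sum(t2)
    expect_equal(res$statistic, sum((t2 - e)^2 / e), tolerance = 1e-9)
  }

  expect_error(chi_square_test(rbind(c(0, 0), c(2, 3))), "zero row or column")
})

test_that("frequency profiles report per-group flag percentages", {
  groups <- data.frame(g = rep("all", 4))
  flags <- data.frame(worry = c(TRUE, TRUE, TRUE, TRUE))
  fp <- frequency_profile(groups, flags)
  expect_equal(fp$percent, 100)
  expect_equal(fp$count, 4L)

  # counts partition over groups
  groups <- data.frame(q = c(1, 1, 2, 2, 2), sex = c("f", "m", "f", "f", "m"))
  flags <- data.frame(alert = c(TRUE, FALSE, TRUE, TRUE, FALSE),
                      fear = c(FALSE, FALSE, TRUE, FALSE, TRUE))
  fp <- frequency_profile(groups, flags)
  expect_equal(sum(fp$count[fp$flag == "alert"]), 3L)
  expect_equal(sum(fp$count[fp$flag == "fear"]), 2L)
  empty <- fp[fp$q == 1 & fp$sex == "m" & fp$flag == "alert", ]
  expect_equal(empty$percent, 0)

  # emotion prevalence rises with the quartile under the generator
  sim <- simulate_survey(simulation_config(n = 600, seed = 6))
  rm <- encode_risk_matrix(sim$responses, sim$codebook)
  q <- assign_quartiles(risk_score(rm))
  fp <- frequency_profile(data.frame(quartile = q), sim$responses$emotions)
  alert <- fp[fp$flag == "alertness", ]
  expect_gt(alert$percent[alert$quartile == 4],
            alert$percent[alert$quartile == 1])
})

test_that("age bands follow the descriptive table's limits", {
  b <- age_band(c(15, 24, 25, 84, 85, 99))
  expect_equal(as.character(b),
               c("15-24", "15-24", "25-34", "75-84", "85+", "85+"))
})
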