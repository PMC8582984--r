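test_that("well-separated blobs form two clusters with no noise", {
  set.seed(1)
  pts <- rbind(matrix(rnorm(40, 0, 0.3), 20), matrix(rnorm(40, 50, 0.3), 20))
  cl <- dbscan(pts, eps = 2, min_pts = 5)
  expect_equal(length(cl$sizes), 2)
  expect_equal(sum(cl$cluster == 0), 0)
  expect_equal(unname(as.integer(cl$sizes)), c(20, 20))

  lonely <- rbind(pts, c(500, 500))
  cl2 <- dbscan(lonely, eps = 2, min_pts = 2)
  expect_equal(cl2$cluster[41], 0L)
})

test_that("labels match the independent quadratic reference", {
  set.seed(202)
  pts <- matrix(runif(400, 0, 10), 200, 2)
  settings <- list(c(0.5, 3), c(0.8, 5), c(1.0, 8), c(1.5, 10), c(0.3, 2),
                   c(2.5, 4))
  for (s in settings) {
    mine <- dbscan(pts, eps = s[1], min_pts = s[2])
    ref <- reference_dbscan(pts, eps = s[1], min_pts = s[2])
    expect_true(same_partition(mine$cluster, ref),
                label = sprintf("partition equal (eps=%.1f, min_pts=%d)",
                                s[1], s[2]))
    # partition property: cluster sizes + noise = n
    expect_equal(sum(mine$sizes) + sum(mine$cluster == 0), 200)
    # ids ordered by decreasing size
    expect_true(all(diff(as.integer(mine$sizes)) <= 0))
  }
})

test_that("permuting the points permutes only the numbering", {
  set.seed(77)
  pts <- matrix(runif(240, 0, 8), 120, 2)
  base <- dbscan(pts, eps = 0.9, min_pts = 4)
  perm <- sample(120)
  shuffled <- dbscan(pts[perm, ], eps = 0.9, min_pts = 4)
  expect_true(same_partition(base$cluster[perm], shuffled$cluster))
})

test_that("eps suggestion finds the k-distance elbow", {
  grid <- as.matrix(expand.grid(x = 1:10, y = 1:10))
  est <- suggest_eps(grid, k = 4)
  expect_equal(est$eps, 1, tolerance = 0.1)
  expect_equal(nrow(est$curve), 100)
  expect_true(all(diff(est$curve$kdist) >= 0))

  set.seed(3)
  blobs <- rbind(matrix(rnorm(100, 0, 0.5), ncol = 2),
                 matrix(rnorm(100, 30, 0.5), ncol = 2))
  expect_lt(suggest_eps(blobs, k = 4)$eps, 30)
  expect_error(suggest_eps(grid[1:3, ], k = 4), "more points")
})

test_that("cluster profiles measure prevalence deltas against baselines", {
  cb <- toy_codebook()
  n <- 10
  items <- data.frame(A = rep("cat1", n), B = rep("cat1", n),
                      C = rep("cat2", n), stringsAsFactors = FALSE)
  raw <- make_raw(cb, items, gender = c(rep("female", 7), rep("male", 3)))
  raw$gender <- c(rep("female", 7), rep("male", 3))
  resp <- as_responses(raw, cb)
  quart <- rep(c(1L, 4L), 5)

  # everyone in one cluster: zero deltas, full coverage
  one <- profile_clusters(rep(1L, n), resp, quart, top_k = 1)
  expect_equal(one$coverage, 1)
  full <- one$profile[one$profile$cluster != "noise", ]
  expect_true(all(abs(full$delta_population) < 1e-12))
  # the empty noise row reports undefined percentages as missing
  expect_true(all(is.na(one$profile$percent[one$profile$cluster == "noise"])))

  # 10-person cluster with 7 females in a 50% female population
  raw2 <- make_raw(cb, items[rep(1, 20), ],
                   gender = c(rep("female", 7), rep("male", 3),
                              rep("female", 3), rep("male", 7)))
  resp2 <- as_responses(raw2, cb)
  expect_warning(
    pr <- profile_clusters(c(rep(1L, 10), rep(2L, 10)), resp2,
                           rep(1:4, 5), top_k = 5),
    "exceeds")
  row <- pr$profile[pr$profile$cluster == "cluster_1" &
                      pr$profile$attribute == "gender" &
                      pr$profile$level == "female", ]
  expect_equal(row$percent, 70)
  expect_equal(row$delta_population, 20)
})

test_that("profile prevalences aggregate back to the population", {
  sim <- simulate_survey(simulation_config(n = 300, seed = 13))
  rm <- encode_risk_matrix(sim$responses, sim$codebook)
  q <- assign_quartiles(risk_score(rm))
  set.seed(5)
  labels <- sample(0:3, 300, TRUE)
  pr <- suppressWarnings(profile_clusters(labels, sim$responses, q, top_k = 3))
  prof <- pr$profile
  pop <- prof[prof$cluster == "population", ]
  groups <- setdiff(unique(prof$cluster), "population")
  for (lv in c("gender|female", "flag|worry")) {
    key <- strsplit(lv, "|", fixed = TRUE)[[1]]
    rows <- prof[prof$attribute == key[1] & prof$level == key[2] &
                   prof$cluster %in% groups, ]
    weighted <- sum(rows$percent * rows$size) / sum(rows$size)
    expect_equal(weighted,
                 pop$percent[pop$attribute == key[1] & pop$level == key[2]],
                 tolerance = 1e-9)
  }
})

test_that("heterogeneity entropy is 0 when concentrated, 1 when uniform", {
  quart <- c(rep(4L, 8), rep(1L, 8))
  labels <- c(rep(1L, 8), rep(1:4, 2))
  het <- heterogeneity_summary(labels, quart)
  expect_equal(het$entropy[het$quartile == 4], 0)
  expect_equal(het$entropy[het$quartile == 1], 1)
  expect_equal(het$n_clusters_5pct[het$quartile == 1], 4L)
  expect_error(heterogeneity_summary(rep(1L, 16), quart), "at least 2")
})
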