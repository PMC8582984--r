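test_that("codebook dummy-column layout follows item then category order", {
  cb <- codebook(list(
    list(item_id = "X", dimension = "knowledge",
         categories = c("yes", "no"), signs = c(1L, -1L)),
    list(item_id = "Y", dimension = "preventive_practice",
         categories = c("always", "never"), signs = c(1L, -1L))))
  expect_equal(n_dummy_columns(cb), 4L)
  expect_equal(cb$dummy_columns$item_id, c("X", "X", "Y", "Y"))
  expect_equal(cb$dummy_columns$category, c("yes", "no", "always", "never"))

  # reference synthetic codebook reproduces the study's 166 dummy columns
  expect_equal(n_dummy_columns(default_codebook()), 166L)
})

test_that("invalid codebooks are rejected with informative errors", {
  base <- list(item_id = "X", dimension = "knowledge",
               categories = c("a", "b"), signs = c(1L, -1L))
  expect_error(codebook(list(modifyList(base, list(signs = c(0L, 0L))))),
               "at least one must be signed")
  expect_error(codebook(list(modifyList(base, list(signs = c(2L, -1L))))),
               "signs must be")
  expect_error(codebook(list(base, base)), "duplicate item_id")
  expect_error(codebook(list(modifyList(base, list(dimension = "mood")))),
               "dimension must be")
})

test_that("codebook YAML round-trip is lossless and order-stable", {
  cb <- default_codebook(10)
  path <- withr::local_tempfile(fileext = ".yml")
  write_codebook(cb, path)
  cb2 <- load_codebook(path)
  expect_identical(cb2$dummy_columns, cb$dummy_columns)
  expect_identical(lapply(cb2$items, `[[`, "signs"),
                   lapply(cb$items, `[[`, "signs"))
  # reloading yields an identical encoding for identical data
  sim <- simulate_survey(simulation_config(n = 20, seed = 4, n_items = 10,
                                           n_archetypes = 1,
                                           archetype_items = 3))
  expect_identical(encode_risk_matrix(sim$responses, cb2),
                   encode_risk_matrix(sim$responses, cb))
})

test_that("response loading validates ids, ages, genders and categories", {
  cb <- toy_codebook()
  items <- data.frame(A = "cat1", B = "cat2", C = "cat1",
                      stringsAsFactors = FALSE)
  raw <- make_raw(cb, items[rep(1, 3), ])

  expect_silent(as_responses(raw, cb))

  bad <- raw; bad$respondent_id[2] <- bad$respondent_id[1]
  expect_error(as_responses(bad, cb), "duplicate respondent_id")
  bad <- raw; bad$age[3] <- "unknown"
  expect_error(as_responses(bad, cb), "unparseable age.*3")
  bad <- raw; bad$age[1] <- 12
  expect_error(as_responses(bad, cb), "below 15")
  bad <- raw; bad$B[2] <- "Often"
  expect_error(as_responses(bad, cb), "item B.*Often.*row.* 2")
})

test_that("a header-only CSV yields an empty validated table", {
  cb <- toy_codebook()
  raw <- make_raw(cb, data.frame(A = character(0), B = character(0),
                                 C = character(0)), n = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(raw, path, row.names = FALSE)
  resp <- load_responses(path, cb)
  expect_s3_class(resp, "perceptrisk_responses")
  expect_equal(n_respondents(resp), 0L)
})

test_that("signed dummy encoding places signs in the chosen category column", {
  cb <- toy_codebook()
  items <- data.frame(A = c("cat1", NA), B = c("cat2", NA), C = c("cat1", NA),
                      stringsAsFactors = FALSE)
  resp <- as_responses(make_raw(cb, items), cb)
  rm <- encode_risk_matrix(resp, cb)
  # hand enumeration of the sign map under the documented column order
  expect_equal(unname(rm[1, ]), c(1L, 0L, 0L, 0L, -1L, 0L))
  # all-missing respondent encodes to an all-zero row
  expect_equal(unname(rm[2, ]), rep(0L, 6))
  expect_equal(dim(rm), c(2L, 6L))
})

test_that("encoding satisfies block exclusivity and signed invertibility", {
  sim <- simulate_survey(simulation_config(n = 60, seed = 11))
  rm <- encode_risk_matrix(sim$responses, sim$codebook)
  expect_true(all(rm %in% c(-1L, 0L, 1L)))
  # at most one nonzero per item block and per respondent
  for (id in names(sim$codebook$items)) {
    block <- rm[, sim$codebook$dummy_columns$item_id == id, drop = FALSE]
    expect_true(all(rowSums(block != 0L) <= 1L))
  }
  # decoding recovers every choice of a signed (+1/-1) category
  dec <- decode_risk_matrix(rm, sim$codebook)
  for (id in names(sim$codebook$items)) {
    it <- sim$codebook$items[[id]]
    signed <- it$categories[it$signs != 0L]
    chosen <- sim$responses$items[[id]]
    idx <- !is.na(chosen) & chosen %in% signed
    expect_identical(dec[[id]][idx], chosen[idx])
  }
})

test_that("generated survey files round-trip through the loader cleanly", {
  dir <- withr::local_tempdir()
  sim <- simulate_survey(simulation_config(n = 100, seed = 2), dir = dir)
  cb <- load_codebook(sim$paths$codebook)
  expect_warning(resp <- load_responses(sim$paths$responses, cb), NA)
  expect_equal(n_respondents(resp), 100L)
  expect_identical(encode_risk_matrix(resp, cb),
                   encode_risk_matrix(sim$responses, sim$codebook))
})
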