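test_that("cosine similarity follows the direct formula", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2), c(-1, -2)), -1)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), sqrt(0.5),
               tolerance = 1e-12)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero-norm")

  set.seed(14)
  for (rep in 1:20) {
    u <- rnorm(6); v <- rnorm(6); c <- runif(1, 0.1, 10)
    expect_equal(cosine_similarity(u, v), cosine_similarity(v, u),
                 tolerance = 1e-12)
    expect_equal(cosine_similarity(c * u, v), cosine_similarity(u, v),
                 tolerance = 1e-12)
    expect_true(abs(cosine_similarity(u, v)) <= 1)
  }
})

test_that("identical rows form a complete graph above the cutoff", {
  scores <- matrix(rep(c(1, 2, 0.5), each = 4), 4)
  g <- build_graph(scores, cutoff = 0.5)
  expect_equal(g$n_edges, 6)
})

test_that("a pair at exactly the cutoff similarity is not connected", {
  # exact ties representable in floating point: similarity 0 at cutoff 0,
  # similarity 1 at cutoff 1 — strict ">" must exclude both
  orth <- rbind(c(1, 0), c(0, 1))
  expect_identical(cosine_similarity(orth[1, ], orth[2, ]), 0)
  expect_equal(build_graph(orth, cutoff = 0)$n_edges, 0)

  anti <- rbind(c(1, 0), c(-1, 0))
  expect_identical(cosine_similarity(anti[1, ], anti[2, ]), -1)
  expect_equal(build_graph(anti, cutoff = -1)$n_edges, 0)

  # ... while anything strictly above the cutoff is connected
  tilted <- rbind(c(1, 0), c(1, 0.01))
  expect_equal(build_graph(tilted, cutoff = 0)$n_edges, 1)
})

test_that("blocked edge construction equals the double-loop oracle", {
  set.seed(42)
  scores <- matrix(rnorm(200 * 5), 200, 5)
  ref <- naive_edges(scores, 0.5)
  for (bs in c(7L, 64L, 1024L)) {
    g <- build_graph(scores, cutoff = 0.5, block_size = bs)
    el <- igraph::as_edgelist(g$graph, names = FALSE)
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
    expect_equal(nrow(el), nrow(ref))
    expect_equal(unname(el), unname(ref))
  }
})

test_that("edge counts shrink as the cutoff rises and isolates survive", {
  set.seed(4)
  scores <- matrix(rnorm(60 * 3), 60, 3)
  counts <- vapply(c(-0.5, 0, 0.3, 0.5, 0.8, 0.95), function(ct)
    build_graph(scores, cutoff = ct)$n_edges, numeric(1))
  expect_true(all(diff(counts) <= 0))

  g <- build_graph(scores, cutoff = 0.999)
  expect_equal(igraph::vcount(g$graph), 60)  # isolated nodes kept

  bad <- scores; bad[5, ] <- 0
  rownames(bad) <- sprintf("r%02d", 1:60)
  expect_error(build_graph(bad), "zero-norm.*r05")
})

test_that("graph export round-trips and serializes valid files", {
  set.seed(2)
  scores <- matrix(rnorm(30), 10, 3,
                   dimnames = list(sprintf("n%02d", 1:10), NULL))
  g <- build_graph(scores, cutoff = 0.2,
                   node_attrs = data.frame(quartile = rep(c("QR1", "QR4"), 5)))

  gm <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, gm, "graphml")
  back <- import_graph(gm, "graphml")
  expect_setequal(igraph::V(back)$name, igraph::V(g$graph)$name)
  expect_equal(igraph::ecount(back), g$n_edges)

  el <- withr::local_tempfile(fileext = ".csv")
  export_graph(g, el, "edgelist")
  df <- read.csv(el)
  expect_named(df, c("source", "target", "weight"))
  expect_equal(nrow(df), g$n_edges)
  back2 <- import_graph(el, "edgelist")
  expect_equal(igraph::ecount(back2), g$n_edges)

  gx <- withr::local_tempfile(fileext = ".gexf")
  export_graph(g, gx, "gexf")
  doc <- xml2::read_xml(gx)
  ns <- xml2::xml_ns(doc)
  expect_length(xml2::xml_find_all(doc, ".//d1:node", ns), 10)
  expect_length(xml2::xml_find_all(doc, ".//d1:edge", ns), g$n_edges)

  # a 3-node path graph exports exactly 2 edge rows
  path3 <- build_graph(rbind(c(1, 0.2), c(1, 1), c(0.2, 1)), cutoff = 0.8)
  expect_equal(path3$n_edges, 2)
  el3 <- withr::local_tempfile(fileext = ".csv")
  export_graph(path3, el3, "edgelist")
  expect_equal(nrow(read.csv(el3)), 2)

  # empty graph: files still valid
  empty <- build_graph(rbind(c(1, 0), c(0, 1)), cutoff = 0.9)
  gx2 <- withr::local_tempfile(fileext = ".gexf")
  export_graph(empty, gx2, "gexf")
  expect_length(xml2::xml_find_all(xml2::read_xml(gx2), ".//d1:edge",
                                   xml2::xml_ns(xml2::read_xml(gx2))), 0)
})
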