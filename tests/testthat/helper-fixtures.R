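# Shared fixtures and independent oracle implementations.

# 3-item toy codebook with signs (+1/-1), (+1/0), (-1/0)
toy_codebook <- function() {
  codebook(list(
    list(item_id = "A", dimension = "knowledge",
         categories = c("cat1", "cat2"), signs = c(1L, -1L)),
    list(item_id = "B", dimension = "perception_severity",
         categories = c("cat1", "cat2"), signs = c(1L, 0L)),
    list(item_id = "C", dimension = "preventive_practice",
         categories = c("cat1", "cat2"), signs = c(-1L, 0L))))
}

# raw data frame with the full column set expected by as_responses()
make_raw <- function(cb, items_df, n = nrow(items_df), age = 30L,
                     gender = "female") {
  raw <- data.frame(respondent_id = sprintf("P%03d", seq_len(n)),
                    age = rep_len(age, n), gender = rep_len(gender, n),
                    civil_status = rep_len("partner", n),
                    education = rep_len("university", n),
                    position = rep_len("student", n),
                    stringsAsFactors = FALSE)
  raw <- cbind(raw, items_df)
  for (f in c(emotion_flags(), media_flags())) raw[[f]] <- rep_len(0L, n)
  raw
}

# brute-force double-loop edge oracle over cosine_similarity()
naive_edges <- function(scores, cutoff) {
  n <- nrow(scores)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- cosine_similarity(scores[i, ], scores[j, ])
      if (s > cutoff) out[[length(out) + 1L]] <- c(i, j)
    }
  }
  if (length(out) == 0) matrix(integer(0), 0, 2) else do.call(rbind, out)
}

# independent DBSCAN reference: full distance matrix, core adjacency
# components via igraph, borders to the lowest-index core neighbour
reference_dbscan <- function(points, eps, min_pts) {
  D <- as.matrix(stats::dist(points))
  n <- nrow(D)
  within <- D <= eps + 1e-12
  core <- rowSums(within) >= min_pts
  labels <- integer(n)
  if (any(core)) {
    A <- within & outer(core, core, "&")
    diag(A) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(A[core, core, drop = FALSE],
                                             mode = "undirected")
    labels[core] <- igraph::components(g)$membership
    for (i in which(!core)) {
      cs <- which(within[i, ] & core)
      if (length(cs) > 0) labels[i] <- labels[cs[1]]
    }
  }
  labels
}

# do two labelings define the same partition (incl. identical noise set)?
same_partition <- function(a, b) {
  if (!identical(a == 0L, b == 0L)) return(FALSE)
  keep <- a != 0L
  if (!any(keep)) return(TRUE)
  tab <- table(a[keep], b[keep])
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# two dense cliques joined by a single edge, for layout benchmarks
two_clique_graph <- function(size = 12) {
  g <- igraph::disjoint_union(igraph::make_full_graph(size),
                              igraph::make_full_graph(size))
  igraph::add_edges(g, c(1, size + 1))
}
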