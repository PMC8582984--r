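#' Density-based clustering of the 2-D layout (DBSCAN)
#'
#' Classic core/border/noise semantics: a core point has at least `min_pts`
#' neighbours within `eps` (counting itself); clusters are the
#' density-connected components of core points together with the border
#' points reachable from them; everything else is noise. Deterministic: core
#' points are expanded in ascending point order, so a border point reachable
#' from several clusters joins the cluster whose core was reached first in
#' that scan order. Clusters are renumbered by decreasing size (ties broken
#' by smallest member index).
#'
#' @param points n x 2 (or n x d) coordinate matrix, finite values
#' @param eps neighbourhood radius > 0
#' @param min_pts minimum neighbourhood size (including the point itself)
#' @return object of class `dbscan_clustering`: `cluster` (integer per
#'   point; 0 = noise), `is_core` (logical), `sizes` (named, decreasing),
#'   `eps`, `min_pts`.
#' @export
dbscan <- function(points, eps, min_pts = 10L) {
  points <- as.matrix(points)
  .assert(all(is.finite(points)), "`points` must be finite")
  .assert(eps > 0, "`eps` must be positive")
  .assert(min_pts >= 1, "`min_pts` must be >= 1")
  n <- nrow(points)
  nb <- neighbour_lists(points, eps)
  is_core <- lengths(nb) >= min_pts
  labels <- integer(n)  # 0 = unassigned/noise
  # density-connect the core points (scan in ascending point order)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is_core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- i
    qpos <- 1L
    while (qpos <= length(frontier)) {
      j <- frontier[qpos]
      qpos <- qpos + 1L
      cand <- nb[[j]]
      cand <- cand[is_core[cand] & labels[cand] == 0L]
      if (length(cand) > 0) {
        labels[cand] <- cl
        frontier <- c(frontier, cand)
      }
    }
  }
  # border points: non-core within eps of a core; ties go to the cluster of
  # the lowest-index core neighbour (nb lists are ascending)
  for (i in seq_len(n)) {
    if (is_core[i] || labels[i] != 0L) next
    cores <- nb[[i]][is_core[nb[[i]]]]
    if (length(cores) > 0) labels[i] <- labels[cores[1]]
  }
  labels <- renumber_by_size(labels)
  sizes <- table(labels[labels > 0])
  structure(list(cluster = labels, is_core = is_core,
                 sizes = sizes[order(-as.integer(sizes), as.integer(names(sizes)))],
                 eps = eps, min_pts = as.integer(min_pts)),
            class = "dbscan_clustering")
}

# eps-neighbour lists (self included), computed in row blocks to bound memory
neighbour_lists <- function(points, eps, block = 512L) {
  n <- nrow(points)
  sq <- rowSums(points^2)
  out <- vector("list", n)
  eps2 <- eps^2
  start <- 1L
  while (start <= n) {
    end <- min(start + block - 1L, n)
    d2 <- outer(sq[start:end], sq, "+") -
      2 * points[start:end, , drop = FALSE] %*% t(points)
    for (bi in seq_len(end - start + 1L))
      out[[start + bi - 1L]] <- which(d2[bi, ] <= eps2 + 1e-12)
    start <- end + 1L
  }
  out
}

# renumber cluster ids by decreasing size; ties by smallest member index
renumber_by_size <- function(labels) {
  ids <- setdiff(unique(labels), 0L)
  if (length(ids) == 0) return(labels)
  size <- vapply(ids, function(c) sum(labels == c), integer(1))
  first <- vapply(ids, function(c) which(labels == c)[1], integer(1))
  new_order <- ids[order(-size, first)]
  map <- integer(max(labels))
  map[new_order] <- seq_along(new_order)
  out <- labels
  pos <- labels > 0L
  out[pos] <- map[labels[pos]]
  out
}

#' @export
print.dbscan_clustering <- function(x, ...) {
  cat("<dbscan_clustering>", length(x$sizes), "clusters,",
      sum(x$cluster == 0), "noise points (eps =", x$eps,
      ", min_pts =", x$min_pts, ")\n")
  invisible(x)
}

#' Suggest an eps radius from the k-nearest-neighbour distance curve
#'
#' Computes every point's distance to its k-th nearest neighbour, sorts the
#' curve, and returns the distance at the elbow: the point of maximum
#' vertical deviation below the chord joining the curve's endpoints. The
#' full curve is returned for inspection.
#'
#' @param points coordinate matrix, n > k rows
#' @param k neighbour rank (conventionally `min_pts`), >= 1
#' @return list with `eps` (the suggested radius) and `curve` (data frame
#'   with `rank`, `kdist` sorted ascending).
#' @export
suggest_eps <- function(points, k = 10L) {
  points <- as.matrix(points)
  n <- nrow(points)
  .assert(k >= 1, "`k` must be >= 1")
  .assert(n > k, "need more points than `k`")
  sq <- rowSums(points^2)
  kd <- numeric(n)
  block <- 512L
  start <- 1L
  while (start <= n) {
    end <- min(start + block - 1L, n)
    d2 <- outer(sq[start:end], sq, "+") -
      2 * points[start:end, , drop = FALSE] %*% t(points)
    for (bi in seq_len(end - start + 1L)) {
      v <- sort(d2[bi, ])
      kd[start + bi - 1L] <- sqrt(max(v[k + 1L], 0))  # v[1] is self
    }
    start <- end + 1L
  }
  kd <- sort(kd)
  # elbow: max deviation below the chord over the curve, trimming the top 1%
  # (outlying k-distances of isolated points otherwise drag the chord up)
  ntrim <- max(2L, floor(0.99 * n))
  x <- seq_len(ntrim)
  chord <- kd[1] + (kd[ntrim] - kd[1]) * (x - 1) / (ntrim - 1)
  idx <- which.max(chord - kd[x])
  list(eps = kd[idx], curve = data.frame(rank = seq_len(n), kdist = kd))
}

#' Profile clusters against the population
#'
#' For the `top_k` largest clusters (plus a noise row and a population row),
#' tabulates prevalence of gender, age band, risk-quartile membership and
#' every emotion/media flag, and the delta of each prevalence against two
#' baselines: the full population and the clustered (non-noise) subset.
#'
#' @param assignment a `dbscan_clustering` (or integer labels, 0 = noise)
#' @param responses a `perceptrisk_responses`, point-aligned with the
#'   assignment
#' @param quartiles integer quartile labels from [assign_quartiles()]
#' @param top_k number of largest clusters to profile (default 13)
#' @return list of class `cluster_profile`: `profile` (long data frame with
#'   `cluster`, `size`, `attribute`, `level`, `percent`,
#'   `delta_population`, `delta_clustered`), `coverage` (fraction of the
#'   population inside the profiled clusters), `top_k`.
#' @export
profile_clusters <- function(assignment, responses, quartiles, top_k = 13L) {
  labels <- if (inherits(assignment, "dbscan_clustering")) assignment$cluster
            else as.integer(assignment)
  n <- length(labels)
  .assert(n == n_respondents(responses),
          "assignment and responses are not aligned")
  .assert(n == length(quartiles), "assignment and quartiles are not aligned")

  n_clusters <- length(setdiff(unique(labels), 0L))
  if (top_k > n_clusters) {
    warning("top_k = ", top_k, " exceeds the ", n_clusters,
            " clusters found; profiling all of them")
    top_k <- n_clusters
  }
  keep <- seq_len(top_k)  # ids are already ordered by decreasing size

  attrs <- data.frame(
    gender = responses$demographics$gender,
    age_band = as.character(age_band(responses$demographics$age)),
    quartile = paste0("QR", quartiles),
    stringsAsFactors = FALSE)
  flags <- cbind(responses$emotions, responses$media)

  prevalences <- function(rows) {
    # empty group: percentages are undefined, reported as missing
    denom <- if (length(rows) > 0) length(rows) else NA_real_
    part <- unlist(lapply(names(attrs), function(a) {
      tab <- table(factor(attrs[[a]][rows],
                          levels = sort(unique(attrs[[a]]))))
      p <- 100 * as.numeric(tab) / denom
      setNames(p, paste0(a, "|", names(tab)))
    }))
    flg <- vapply(names(flags), function(f)
      100 * sum(flags[[f]][rows]) / denom, numeric(1))
    c(part, setNames(flg, paste0("flag|", names(flags))))
  }

  pop <- prevalences(seq_len(n))
  clustered_rows <- which(labels > 0L)
  clustered <- prevalences(clustered_rows)

  groups <- c(list(population = seq_len(n)),
              setNames(lapply(keep, function(c) which(labels == c)),
                       paste0("cluster_", keep)),
              list(noise = which(labels == 0L)))
  profile <- do.call(rbind, lapply(names(groups), function(gname) {
    rows <- groups[[gname]]
    p <- prevalences(rows)
    key <- strsplit(names(p), "|", fixed = TRUE)
    data.frame(cluster = gname, size = length(rows),
               attribute = vapply(key, `[`, character(1), 1),
               level = vapply(key, `[`, character(1), 2),
               percent = as.numeric(p),
               delta_population = as.numeric(p - pop),
               delta_clustered = as.numeric(p - clustered),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  coverage <- sum(labels %in% keep) / n
  structure(list(profile = profile, coverage = coverage,
                 top_k = as.integer(top_k)),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat("<cluster_profile>", x$top_k, "clusters profiled; coverage",
      sprintf("%.1f%%", 100 * x$coverage), "of the population\n")
  invisible(x)
}

#' Per-quartile cluster-dispersion summary
#'
#' Quantifies how concentrated each risk quartile is across the clusters:
#' the number of clusters holding at least 5% of the quartile's members, the
#' normalized entropy of its cluster-membership distribution (0 = all in one
#' cluster, 1 = spread evenly over the clusters it occupies; noise
#' excluded), and the share of its members in its single largest cluster.
#'
#' @param assignment a `dbscan_clustering` or integer labels (0 = noise)
#' @param quartiles integer quartile labels, aligned with the assignment
#' @return data frame with `quartile`, `n`, `n_clustered`,
#'   `n_clusters_5pct`, `entropy`, `top_cluster_share`.
#' @export
heterogeneity_summary <- function(assignment, quartiles) {
  labels <- if (inherits(assignment, "dbscan_clustering")) assignment$cluster
            else as.integer(assignment)
  .assert(length(labels) == length(quartiles),
          "assignment and quartiles are not aligned")
  .assert(length(setdiff(unique(labels), 0L)) >= 2,
          "need at least 2 non-noise clusters")
  out <- do.call(rbind, lapply(sort(unique(quartiles)), function(q) {
    rows <- which(quartiles == q)
    lab <- labels[rows]
    clustered <- lab[lab > 0L]
    counts <- table(clustered)
    p <- as.numeric(counts) / sum(counts)
    entropy <- if (length(p) <= 1) 0 else
      -sum(p * log(p)) / log(length(p))
    data.frame(quartile = q, n = length(rows), n_clustered = length(clustered),
               n_clusters_5pct = sum(counts >= 0.05 * length(rows)),
               entropy = entropy,
               top_cluster_share = if (length(p) > 0) max(p) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
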