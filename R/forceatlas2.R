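#' Linear attraction force magnitude
#'
#' Edge attraction in the layout model is linear in distance.
#'
#' @param d non-negative distance
#' @return force magnitude `d`, directed inward along the edge.
#' @export
attraction_force <- function(d) {
  .assert(all(d >= 0), "`d` must be non-negative")
  d
}

#' Degree-weighted repulsion force magnitude
#'
#' Every pair of nodes repels with magnitude
#' `k_r * (deg_i + 1) * (deg_j + 1) / d`, so hubs push harder and the force
#' decays with distance.
#'
#' @param deg_i,deg_j node degrees
#' @param d positive distance
#' @param k_r repulsion scaling > 0
#' @return force magnitude, directed outward.
#' @export
repulsion_force <- function(deg_i, deg_j, d, k_r = 2) {
  .assert(all(d > 0), "`d` must be positive")
  .assert(k_r > 0, "`k_r` must be positive")
  k_r * (deg_i + 1) * (deg_j + 1) / d
}

#' ForceAtlas2 force-directed layout of a similarity graph
#'
#' Iterates force accumulation — linear attraction along edges,
#' degree-weighted `1/d` repulsion between all pairs (exact, or Barnes-Hut
#' approximated for large graphs), and classic gravity of magnitude
#' `gravity * (deg + 1)` toward the origin — with the adaptive global/local
#' speed scheme: a node that swings (force direction flipping between
#' iterations) is slowed down, and the global speed follows the
#' traction/swinging ratio. Runs a fixed number of iterations; per-iteration
#' total swinging and traction are recorded as convergence diagnostics.
#' Identical seed, parameters and graph give identical coordinates.
#'
#' @param graph a `similarity_graph` (or bare \pkg{igraph} graph)
#' @param iterations number of iterations T >= 1
#' @param k_r repulsion scaling (> 0)
#' @param gravity gravity strength (>= 0)
#' @param tolerance jitter tolerance of the adaptive speed (> 0)
#' @param barnes_hut `TRUE`/`FALSE`, or `NULL` (default) to enable the
#'   Barnes-Hut approximation automatically for graphs of 2000+ nodes
#' @param theta Barnes-Hut accuracy parameter in (0, 1]
#' @param seed integer seed for the initial positions (uniform in a disc)
#' @param init optional n x 2 matrix of starting coordinates (overrides
#'   `seed`)
#' @return object of class `fa2_layout`: `coords` (data frame with `id`,
#'   `x`, `y`), `diagnostics` (data frame with `iteration`, `swinging`,
#'   `traction`), `params`.
#' @export
run_layout <- function(graph, iterations = 1000L, k_r = 2, gravity = 1,
                       tolerance = 1, barnes_hut = NULL, theta = 0.9,
                       seed = 0L, init = NULL) {
  g <- if (inherits(graph, "similarity_graph")) graph$graph else graph
  .assert(inherits(g, "igraph"), "`graph` must be a similarity_graph or igraph")
  n <- igraph::vcount(g)
  .assert(n >= 1, "graph must be nonempty")
  .assert(iterations >= 1, "`iterations` must be >= 1")
  .assert(k_r > 0 && gravity >= 0 && tolerance > 0,
          "`k_r`, `tolerance` must be > 0 and `gravity` >= 0")
  .assert(theta > 0 && theta <= 1, "`theta` must be in (0, 1]")
  if (is.null(barnes_hut)) barnes_hut <- n >= 2000

  ids <- igraph::V(g)$name %||% as.character(seq_len(n))
  edges <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(edges) <- "integer"
  edges <- edges - 1L  # 0-based for the compiled core
  mass <- igraph::degree(g) + 1

  if (is.null(init)) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    r <- sqrt(stats::runif(n)) * 10 * sqrt(n)  # uniform in a disc
    ang <- stats::runif(n, 0, 2 * pi)
    init <- cbind(r * cos(ang), r * sin(ang))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  } else {
    init <- as.matrix(init)
    .assert(nrow(init) == n && ncol(init) == 2, "`init` must be n x 2")
  }

  res <- .fa2_run(init, edges, mass, k_r, gravity, as.integer(iterations),
                  tolerance, barnes_hut, theta)
  coords <- data.frame(id = ids, x = res$positions[, 1], y = res$positions[, 2],
                       stringsAsFactors = FALSE)
  structure(list(coords = coords,
                 diagnostics = data.frame(iteration = seq_len(iterations),
                                          swinging = res$swinging,
                                          traction = res$traction),
                 params = list(iterations = iterations, k_r = k_r,
                               gravity = gravity, tolerance = tolerance,
                               barnes_hut = barnes_hut, theta = theta,
                               seed = seed)),
            class = "fa2_layout")
}

#' @export
print.fa2_layout <- function(x, ...) {
  cat("<fa2_layout>", nrow(x$coords), "nodes,", x$params$iterations,
      "iterations,", if (x$params$barnes_hut) "Barnes-Hut" else "exact",
      "repulsion\n")
  invisible(x)
}

#' Pairwise layout forces for one configuration
#'
#' Computes the net force on every node at the given positions (one force
#' accumulation, no movement). Useful for checking force-balance properties
#' and equilibria.
#'
#' @param positions n x 2 coordinate matrix
#' @param graph a `similarity_graph` or igraph with n nodes
#' @param k_r,gravity,barnes_hut,theta as in [run_layout()]
#' @return n x 2 matrix of force vectors.
#' @export
layout_forces <- function(positions, graph, k_r = 2, gravity = 1,
                          barnes_hut = FALSE, theta = 0.9) {
  g <- if (inherits(graph, "similarity_graph")) graph$graph else graph
  positions <- as.matrix(positions)
  n <- igraph::vcount(g)
  .assert(nrow(positions) == n && ncol(positions) == 2,
          "`positions` must be n x 2")
  edges <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(edges) <- "integer"
  .fa2_forces(positions, edges - 1L, igraph::degree(g) + 1, k_r, gravity,
              barnes_hut, theta)
}
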