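#' Cosine similarity of two score vectors
#'
#' `dot(u, v) / (|u| |v|)`: similarity of orientation regardless of
#' magnitude, in \[-1, 1\]; negative values indicate dissimilarity.
#'
#' @param u,v numeric vectors of equal length and nonzero norm
#' @return numeric scalar in \[-1, 1\].
#' @export
cosine_similarity <- function(u, v) {
  .assert(length(u) == length(v), "`u` and `v` must have the same length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine similarity undefined for zero-norm vectors", call. = FALSE)
  max(-1, min(1, sum(u * v) / (nu * nv)))
}

#' Build the thresholded cosine-similarity respondent network
#'
#' Respondents are nodes; an undirected edge joins every pair whose cosine
#' similarity is strictly greater than `cutoff` (a pair at exactly the
#' cutoff is not connected). Similarities are computed in fixed-size row
#' blocks so transient storage is bounded by `block_size * n` rather than
#' n^2. Isolated respondents stay in the graph as nodes without edges.
#'
#' @param scores n x k numeric matrix of (reduced) score vectors; rownames
#'   are used as respondent ids
#' @param cutoff similarity threshold, default 0.5
#' @param block_size rows per block, default 1024
#' @param node_attrs optional data frame of per-node attributes (e.g.
#'   quartile, gender, age band), row-aligned with `scores`
#' @return object of class `similarity_graph`: `graph` (an \pkg{igraph}
#'   undirected graph with edge attribute `weight` = similarity), `cutoff`,
#'   `n`, `n_edges`.
#' @export
build_graph <- function(scores, cutoff = 0.5, block_size = 1024L,
                        node_attrs = NULL) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  .assert(n >= 2, "need at least 2 respondents")
  .assert(block_size >= 1, "`block_size` must be >= 1")
  norms <- sqrt(rowSums(scores^2))
  zero <- which(norms == 0)
  if (length(zero) > 0) {
    ids <- rownames(scores)[zero] %||% as.character(zero)
    stop("zero-norm score vectors (similarity undefined) for: ",
         paste(utils::head(ids, 10), collapse = ", "), call. = FALSE)
  }
  xn <- scores / norms
  ids <- rownames(scores) %||% as.character(seq_len(n))

  from <- list(); to <- list(); w <- list(); nb <- 0L
  start <- 1L
  while (start <= n) {
    end <- min(start + block_size - 1L, n)
    s <- xn[start:end, , drop = FALSE] %*% t(xn)
    for (bi in seq_len(end - start + 1L)) {
      i <- start + bi - 1L
      if (i == n) next
      js <- which(s[bi, (i + 1L):n] > cutoff) + i
      if (length(js) > 0) {
        nb <- nb + 1L
        from[[nb]] <- rep.int(i, length(js))
        to[[nb]] <- js
        w[[nb]] <- s[bi, js]
      }
    }
    start <- end + 1L
  }
  edges <- data.frame(from = ids[unlist(from)], to = ids[unlist(to)],
                      weight = as.numeric(unlist(w)), stringsAsFactors = FALSE)
  vertices <- data.frame(name = ids, stringsAsFactors = FALSE)
  if (!is.null(node_attrs)) {
    .assert(nrow(node_attrs) == n, "`node_attrs` must be row-aligned with `scores`")
    vertices <- cbind(vertices, node_attrs)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
  structure(list(graph = g, cutoff = cutoff, n = n,
                 n_edges = igraph::ecount(g)),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("<similarity_graph>", x$n, "nodes,", x$n_edges,
      "edges (cosine similarity >", x$cutoff, ")\n")
  invisible(x)
}

#' Export a similarity graph
#'
#' Writes GraphML or GEXF (both Gephi-compatible, with node attributes) or a
#' plain edge-list CSV with columns `source`, `target`, `weight`.
#'
#' @param graph a `similarity_graph`
#' @param path output file path
#' @param format `"graphml"`, `"gexf"` or `"edgelist"`
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "gexf", "edgelist")) {
  .assert(inherits(graph, "similarity_graph"), "`graph` must be a similarity_graph")
  format <- match.arg(format)
  g <- graph$graph
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "edgelist") {
    el <- igraph::as_data_frame(g, what = "edges")
    names(el)[1:2] <- c("source", "target")
    utils::write.csv(el, path, row.names = FALSE)
  } else {
    write_gexf(g, path)
  }
  invisible(path)
}

#' Re-import an exported graph
#' @param path file written by [export_graph()]
#' @param format `"graphml"` or `"edgelist"`
#' @return an \pkg{igraph} graph.
#' @export
import_graph <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") return(igraph::read_graph(path, format = "graphml"))
  el <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(source = "character", target = "character"))
  igraph::graph_from_data_frame(el, directed = FALSE)
}

# Minimal GEXF 1.2 writer: node ids/labels, string node attributes, and
# float edge weights. Enough for inspection in Gephi.
write_gexf <- function(g, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  ids <- igraph::V(g)$name
  attrs <- setdiff(igraph::vertex_attr_names(g), "name")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
               '<graph mode="static" defaultedgetype="undirected">'), con)
  if (length(attrs) > 0) {
    writeLines('<attributes class="node">', con)
    for (k in seq_along(attrs))
      writeLines(sprintf('<attribute id="%d" title="%s" type="string"/>',
                         k - 1L, esc(attrs[k])), con)
    writeLines('</attributes>', con)
  }
  writeLines("<nodes>", con)
  for (i in seq_along(ids)) {
    if (length(attrs) == 0) {
      writeLines(sprintf('<node id="%s" label="%s"/>', esc(ids[i]), esc(ids[i])), con)
    } else {
      vals <- vapply(attrs, function(a)
        sprintf('<attvalue for="%d" value="%s"/>', match(a, attrs) - 1L,
                esc(as.character(igraph::vertex_attr(g, a)[i]))), character(1))
      writeLines(c(sprintf('<node id="%s" label="%s"><attvalues>',
                           esc(ids[i]), esc(ids[i])),
                   vals, "</attvalues></node>"), con)
    }
  }
  writeLines("</nodes>", con)
  el <- igraph::as_data_frame(g, what = "edges")
  writeLines("<edges>", con)
  if (nrow(el) > 0) {
    wgt <- if ("weight" %in% names(el)) el$weight else rep(1, nrow(el))
    writeLines(sprintf('<edge id="%d" source="%s" target="%s" weight="%.10g"/>',
                       seq_len(nrow(el)) - 1L, esc(el$from), esc(el$to), wgt), con)
  }
  writeLines(c("</edges>", "</graph>", "</gexf>"), con)
  invisible(path)
}
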