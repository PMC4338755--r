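#' Efferent edges of a node set
#'
#' Lists every unordered connected pair with at least one endpoint in
#' `node_set` (the "bookmarked" edges emanating from a region of interest,
#' e.g. a lesioned area), deduplicated and sorted by `(node_a, node_b)`
#' with `node_a < node_b`.
#'
#' @param conn a `connectome`.
#' @param node_set 1-based node IDs.
#' @return Data frame with columns `node_a`, `node_b`, `weight`.
#' @export
efferent_edges <- function(conn, node_set) {
  node_set <- unique(as.integer(node_set))
  n <- conn$n_nodes
  if (length(node_set) > 0 && (min(node_set) < 1 || max(node_set) > n)) {
    stop("node IDs must lie in 1..", n)
  }
  ut <- which(upper.tri(conn$weights) & conn$weights != 0, arr.ind = TRUE)
  keep <- ut[, 1] %in% node_set | ut[, 2] %in% node_set
  ut <- ut[keep, , drop = FALSE]
  ord <- order(ut[, 1], ut[, 2])
  ut <- ut[ord, , drop = FALSE]
  data.frame(node_a = as.integer(ut[, 1]), node_b = as.integer(ut[, 2]),
             weight = conn$weights[ut])
}

.edge_lengths <- function(w, mode) {
  if (mode == "inverse") 1 / w else -log(w / max(w))
}

.conn_igraph <- function(conn, length_mode) {
  ut <- which(upper.tri(conn$weights) & conn$weights != 0, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = conn$n_nodes, directed = FALSE)
  g <- igraph::add_edges(g, rbind(ut[, 1], ut[, 2]))
  igraph::E(g)$length <- .edge_lengths(conn$weights[ut], length_mode)
  g
}

#' Weighted shortest path between two nodes
#'
#' Dijkstra shortest path under one of two length transforms of the fiber
#' weights: `"inverse"` (default, length `1/w`, the usual convention for
#' fiber-density matrices where strong connections are short) or
#' `"neglog"` (length `-log(w / w_max)`, additive along paths in relative
#' weight). Among equal-length shortest paths the lexicographically
#' smallest node sequence is returned, so results are reproducible across
#' platforms.
#'
#' @param conn a `connectome`.
#' @param source,target distinct 1-based node IDs.
#' @param length_mode `"inverse"` or `"neglog"`.
#' @return A `path_result`: list with `nodes` (1-based ID sequence),
#'   `length` (sum of edge lengths; `Inf` if disconnected), `edge_weights`
#'   (original weights along the path), `mode` and `found`.
#' @export
shortest_path <- function(conn, source, target,
                          length_mode = c("inverse", "neglog")) {
  length_mode <- match.arg(length_mode)
  n <- conn$n_nodes
  source <- as.integer(source); target <- as.integer(target)
  if (source == target) stop("source and target must differ")
  if (min(source, target) < 1 || max(source, target) > n) {
    stop("node IDs must lie in 1..", n)
  }
  g <- .conn_igraph(conn, length_mode)
  d_src <- as.numeric(igraph::distances(g, v = source,
                                        weights = igraph::E(g)$length))
  d_tgt <- as.numeric(igraph::distances(g, v = target,
                                        weights = igraph::E(g)$length))
  total <- d_src[target]
  if (!is.finite(total)) {
    return(structure(list(nodes = integer(0), length = Inf,
                          edge_weights = numeric(0), mode = length_mode,
                          found = FALSE),
                     class = "path_result"))
  }
  # reconstruction: depth-first search over nodes that stay on some
  # shortest path to the target, trying smaller IDs first, so the first
  # complete simple path found is the lexicographically smallest shortest
  # path. Zero-length edges (the max-weight edge under "neglog") can make
  # a greedy walk dead-end, hence the backtracking.
  lens <- .edge_lengths(conn$weights, length_mode)
  tol <- 1e-9 * max(1, abs(total))
  candidates_from <- function(cur, visited) {
    nbrs <- which(conn$weights[cur, ] != 0 & !visited)
    nbrs[abs(d_src[cur] + lens[cur, nbrs] + d_tgt[nbrs] - total) <= tol]
  }
  visited <- rep(FALSE, n)
  visited[source] <- TRUE
  path <- source
  options <- list(candidates_from(source, visited))
  repeat {
    depth <- length(path)
    cur <- path[depth]
    if (cur == target) break
    opts <- options[[depth]]
    if (length(opts) == 0) {
      # dead end: backtrack
      visited[cur] <- FALSE
      path <- path[-depth]
      options[[depth]] <- NULL
      if (length(path) == 0) {
        stop("shortest-path reconstruction failed between ", source,
             " and ", target)
      }
      next
    }
    nxt <- opts[1]
    options[[depth]] <- opts[-1]
    visited[nxt] <- TRUE
    path <- c(path, nxt)
    options[[depth + 1L]] <- sort(candidates_from(nxt, visited))
  }
  ew <- conn$weights[cbind(path[-length(path)], path[-1])]
  structure(
    list(nodes = path, length = sum(lens[cbind(path[-length(path)],
                                               path[-1])]),
         edge_weights = ew, mode = length_mode, found = TRUE),
    class = "path_result"
  )
}

#' @export
print.path_result <- function(x, ...) {
  if (!x$found) {
    cat("path_result: no path\n")
  } else {
    cat("path_result (", x$mode, "): ",
        paste(x$nodes, collapse = " - "),
        ", length ", format(x$length, digits = 6), "\n", sep = "")
  }
  invisible(x)
}

#' Regions reached in one hop from a node set
#'
#' Tabulates, per atlas region, how many efferent edge endpoints outside
#' `node_set` fall in that region -- i.e. which regions a node set reaches
#' directly through its bookmarked efferent connections.
#'
#' @param conn an atlas-linked `connectome`.
#' @param atlas the `brain_atlas` the connectome is labeled with.
#' @param node_set 1-based node IDs.
#' @return Data frame with columns `region` and `count`, sorted by
#'   decreasing count; zero rows if the set has no outside efferents.
#' @export
region_span <- function(conn, atlas, node_set) {
  ee <- efferent_edges(conn, node_set)
  outside <- c(ee$node_a[!(ee$node_a %in% node_set)],
               ee$node_b[!(ee$node_b %in% node_set)])
  if (length(outside) == 0) {
    return(data.frame(region = character(0), count = integer(0)))
  }
  tab <- table(region_of_nodes(atlas, outside))
  out <- data.frame(region = names(tab), count = as.integer(tab))
  out[order(-out$count, out$region), , drop = FALSE]
}
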