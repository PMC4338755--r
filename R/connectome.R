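#' Construct a connectome
#'
#' A connectome couples `n` nodes through a symmetric, zero-diagonal,
#' non-negative weight matrix (normalized fiber-tract counts, dimensionless),
#' and carries per-node 3D coordinates (Talairach mm), region labels and
#' 1-based external node IDs.
#'
#' @param weights n x n numeric matrix; symmetric, zero diagonal, all
#'   entries >= 0 and finite.
#' @param coordinates n x 3 numeric matrix of node coordinates (mm). Defaults
#'   to zeros.
#' @param region_label character vector of per-node region labels, or `NULL`.
#' @param node_id integer vector of external 1-based node IDs; defaults to
#'   `1:n`.
#' @param symmetry_tol tolerance on `max |W - t(W)|` before the matrix is
#'   rejected as asymmetric.
#' @return An object of class `connectome`: a list with elements `n_nodes`,
#'   `weights`, `coordinates`, `region_label`, `node_id` and an optional
#'   logical `lesion_mask`.
#' @seealso [read_graphml()], [write_graphml()], [synthetic_connectome()]
#' @export
connectome <- function(weights, coordinates = NULL, region_label = NULL,
                       node_id = NULL, symmetry_tol = 1e-9) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (n != ncol(weights)) stop("weight matrix must be square")
  if (is.null(coordinates)) coordinates <- matrix(0, n, 3)
  coordinates <- as.matrix(coordinates)
  if (is.null(node_id)) node_id <- seq_len(n)
  obj <- structure(
    list(n_nodes = n, weights = weights, coordinates = coordinates,
         region_label = region_label, node_id = as.integer(node_id),
         lesion_mask = NULL),
    class = "connectome"
  )
  validate_connectome(obj, symmetry_tol = symmetry_tol)
  obj
}

#' Validate connectome invariants
#'
#' Checks symmetry (to `symmetry_tol`), zero diagonal, non-negative finite
#' weights, finite coordinates of the right shape and consistent label/id
#' lengths. Called by every constructor; exported so generated or modified
#' objects can be re-checked.
#'
#' @param x a `connectome`.
#' @param symmetry_tol tolerance on `max |W - t(W)|`.
#' @param atlas optional `brain_atlas`; when given, region labels must be
#'   drawn from its label set.
#' @return `x`, invisibly.
#' @export
validate_connectome <- function(x, symmetry_tol = 1e-9, atlas = NULL) {
  w <- x$weights
  n <- x$n_nodes
  if (nrow(w) != n || ncol(w) != n) stop("weights must be ", n, " x ", n)
  if (n > 0) {
    if (!all(is.finite(w))) stop("weights must be finite")
    if (any(w < 0)) stop("weights must be non-negative")
    if (any(diag(w) != 0)) stop("weight matrix must have a zero diagonal")
    asym <- max(abs(w - t(w)))
    if (asym > symmetry_tol) {
      stop("weight matrix asymmetric: max |W - t(W)| = ",
           format(asym), " exceeds tolerance ", format(symmetry_tol))
    }
    if (!all(is.finite(x$coordinates))) stop("coordinates must be finite")
  }
  if (nrow(x$coordinates) != n || ncol(x$coordinates) != 3) {
    stop("coordinates must be ", n, " x 3")
  }
  if (!is.null(x$region_label) && length(x$region_label) != n) {
    stop("region_label must have one entry per node")
  }
  if (length(x$node_id) != n) stop("node_id must have one entry per node")
  if (!is.null(atlas) && !is.null(x$region_label)) {
    bad <- setdiff(unique(x$region_label), atlas_region_labels(atlas))
    if (length(bad) > 0) {
      stop("region labels not in atlas: ", paste(bad, collapse = ", "))
    }
  }
  invisible(x)
}

#' @export
print.connectome <- function(x, ...) {
  np <- n_edge_pairs(x)
  cat("connectome:", x$n_nodes, "nodes,", np, "unordered weighted pairs\n")
  if (!is.null(x$lesion_mask) && any(x$lesion_mask)) {
    cat("  lesioned nodes:", sum(x$lesion_mask), "\n")
  }
  invisible(x)
}

#' Number of unordered connected node pairs
#'
#' Counts unordered pairs `{i, j}`, `i < j`, with nonzero weight: each
#' undirected ("bidirectional") link is counted once.
#'
#' @param x a `connectome`.
#' @return Integer pair count.
#' @export
n_edge_pairs <- function(x) {
  sum(x$weights[upper.tri(x$weights)] != 0)
}

.fmt_num <- function(x) {
  # full round-trip precision for doubles
  formatC(x, digits = 17, format = "g")
}

#' Write a connectome to GraphML
#'
#' Emits an undirected GraphML file with node attributes `x`, `y`, `z`
#' (double, mm), `region` (string) and `id` (int, 1-based external ID), and
#' edge attribute `weight` (double). Each unordered connected pair appears
#' exactly once. Weights are printed at full double precision so that
#' [read_graphml()] inverts the file bit-exactly.
#'
#' @param conn a `connectome`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(conn, path) {
  validate_connectome(conn)
  n <- conn$n_nodes
  keys <- paste0(
    '  <key id="d_x" for="node" attr.name="x" attr.type="double"/>\n',
    '  <key id="d_y" for="node" attr.name="y" attr.type="double"/>\n',
    '  <key id="d_z" for="node" attr.name="z" attr.type="double"/>\n',
    '  <key id="d_region" for="node" attr.name="region" attr.type="string"/>\n',
    '  <key id="d_id" for="node" attr.name="id" attr.type="int"/>\n',
    '  <key id="d_weight" for="edge" attr.name="weight" attr.type="double"/>\n'
  )
  lab <- conn$region_label
  if (is.null(lab)) lab <- rep("", n)
  node_lines <- character(0)
  if (n > 0) {
    node_lines <- sprintf(
      paste0('    <node id="n%d"><data key="d_x">%s</data>',
             '<data key="d_y">%s</data><data key="d_z">%s</data>',
             '<data key="d_region">%s</data><data key="d_id">%d</data></node>'),
      seq_len(n),
      .fmt_num(conn$coordinates[, 1]), .fmt_num(conn$coordinates[, 2]),
      .fmt_num(conn$coordinates[, 3]),
      vapply(lab, .xml_escape, character(1), USE.NAMES = FALSE),
      conn$node_id
    )
  }
  ut <- which(upper.tri(conn$weights) & conn$weights != 0, arr.ind = TRUE)
  edge_lines <- character(0)
  if (nrow(ut) > 0) {
    ord <- order(ut[, 1], ut[, 2])
    ut <- ut[ord, , drop = FALSE]
    edge_lines <- sprintf(
      '    <edge source="n%d" target="n%d"><data key="d_weight">%s</data></edge>',
      ut[, 1], ut[, 2], .fmt_num(conn$weights[ut])
    )
  }
  txt <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">\n',
    keys,
    '  <graph id="G" edgedefault="undirected">\n',
    paste(c(node_lines, edge_lines), collapse = "\n"),
    if (n > 0 || length(edge_lines) > 0) "\n" else "",
    "  </graph>\n</graphml>\n"
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(txt), con)
  invisible(path)
}

.xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

#' Read a connectome from GraphML
#'
#' Parses the GraphML dialect written by [write_graphml()]: node attributes
#' `x`, `y`, `z`, `region`, `id` and edge attribute `weight`, matched by
#' `attr.name` so foreign key ids are accepted. Edges may appear in either
#' orientation; if both orientations of a pair are present with conflicting
#' weights, `symmetrize_policy` decides:
#'
#' * `"strict"` (default): a discrepancy beyond `1e-9` is a validation error;
#' * `"average"`: the two directed weights are replaced by their mean.
#'
#' @param path GraphML file path.
#' @param symmetrize_policy `"strict"` or `"average"`.
#' @return A validated `connectome`.
#' @export
read_graphml <- function(path, symmetrize_policy = c("strict", "average")) {
  symmetrize_policy <- match.arg(symmetrize_policy)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  key_nodes <- xml2::xml_find_all(doc, ".//g:key", ns)
  key_map <- stats::setNames(xml2::xml_attr(key_nodes, "attr.name"),
                             xml2::xml_attr(key_nodes, "id"))
  nodes <- xml2::xml_find_all(doc, ".//g:graph/g:node", ns)
  n <- length(nodes)
  xml_ids <- xml2::xml_attr(nodes, "id")

  # vectorized attribute extraction by declared attr.name, coalescing over
  # all key ids that declare the name
  pull_attr <- function(elements, labels, attr_name, what) {
    ids <- names(key_map)[key_map == attr_name]
    if (length(ids) == 0) {
      stop("GraphML format error: no <key> declares attribute '",
           attr_name, "'")
    }
    out <- rep(NA_character_, length(elements))
    for (id in ids) {
      hit <- xml2::xml_find_first(
        elements, sprintf("./g:data[@key='%s']", id), ns)
      got <- xml2::xml_text(hit)
      out[is.na(out)] <- got[is.na(out)]
    }
    if (anyNA(out)) {
      stop("GraphML format error: ", what, " '",
           labels[which(is.na(out))[1]], "' is missing attribute '",
           attr_name, "'")
    }
    out
  }

  coords <- matrix(0, n, 3)
  region <- character(0)
  node_id <- integer(0)
  if (n > 0) {
    coords[, 1] <- as.numeric(pull_attr(nodes, xml_ids, "x", "node"))
    coords[, 2] <- as.numeric(pull_attr(nodes, xml_ids, "y", "node"))
    coords[, 3] <- as.numeric(pull_attr(nodes, xml_ids, "z", "node"))
    region <- pull_attr(nodes, xml_ids, "region", "node")
    node_id <- as.integer(pull_attr(nodes, xml_ids, "id", "node"))
  }
  idx <- stats::setNames(seq_len(n), xml_ids)

  edges <- xml2::xml_find_all(doc, ".//g:graph/g:edge", ns)
  w <- matrix(0, n, n)
  if (length(edges) > 0) {
    s <- idx[xml2::xml_attr(edges, "source")]
    t <- idx[xml2::xml_attr(edges, "target")]
    edge_label <- paste(xml_ids[s], "->", xml_ids[t])
    wt <- as.numeric(pull_attr(edges, edge_label, "weight", "edge"))
    # reconcile duplicate orientations of the same unordered pair
    pair <- paste(pmin(s, t), pmax(s, t))
    groups <- split(seq_along(pair), pair)
    for (g in groups) {
      vals <- wt[g]
      v <- vals[1]
      if (length(vals) > 1 && diff(range(vals)) > 1e-9) {
        if (symmetrize_policy == "strict") {
          stop("asymmetric weights for pair (", edge_label[g[1]], "): ",
               paste(format(vals), collapse = " vs "),
               "; use symmetrize_policy = 'average' to reconcile")
        }
        v <- mean(vals)
      }
      w[s[g[1]], t[g[1]]] <- v
      w[t[g[1]], s[g[1]]] <- v
    }
  }
  region_label <- if (length(region) == 0 || all(region == "")) NULL
                  else region
  connectome(w, coords, region_label, node_id)
}
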