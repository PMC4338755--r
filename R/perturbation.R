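.new_lesion <- function(node_set, kind, provenance) {
  node_set <- sort(unique(as.integer(node_set)))
  structure(list(node_set = node_set, kind = kind, provenance = provenance),
            class = "lesion")
}

#' @export
print.lesion <- function(x, ...) {
  cat("lesion (", x$kind, "): ", length(x$node_set), " nodes\n", sep = "")
  invisible(x)
}

#' Construct a focal lesion
#'
#' A focal (stroke-like) lesion disconnects every node of a set of named,
#' anatomically contiguous atlas regions.
#'
#' @param atlas a `brain_atlas`.
#' @param region_names hemisphere-prefixed region names (e.g.
#'   `c("rCUN", "rLOCC", "rPCUN")`, the occipito-parietal set studied in
#'   the stroke protocol, 52 nodes on the built-in atlas).
#' @return A `lesion` of kind `"focal"`.
#' @export
focal_lesion <- function(atlas, region_names) {
  .new_lesion(nodes_of_regions(atlas, region_names), "focal", region_names)
}

#' Construct a diffuse lesion
#'
#' A diffuse (multiple-sclerosis-like) lesion disconnects nodes sampled
#' uniformly at random, without replacement, across the whole network.
#'
#' @param conn a `connectome`.
#' @param n_nodes number of nodes to disconnect.
#' @param seed RNG seed; the same seed reproduces the same node set.
#' @param exclude node IDs excluded from sampling (e.g. an existing focal
#'   set).
#' @return A `lesion` of kind `"diffuse"` with `seed` recorded as
#'   provenance.
#' @export
diffuse_lesion <- function(conn, n_nodes, seed = 1L, exclude = integer(0)) {
  pool <- setdiff(seq_len(conn$n_nodes), as.integer(exclude))
  if (n_nodes > length(pool)) {
    stop("cannot sample ", n_nodes, " nodes from ", length(pool),
         " available")
  }
  set.seed(seed)
  .new_lesion(pool[sample.int(length(pool), n_nodes)], "diffuse",
              list(seed = seed))
}

#' Apply a lesion to a connectome
#'
#' Severs all connections of the lesioned nodes by zeroing their rows and
#' columns in the weight matrix. Nodes are retained (uncoupled, receiving
#' only the baseline current in simulations) so node indexing is unchanged;
#' a logical `lesion_mask` is attached. Applying the same lesion twice is
#' idempotent, and symmetry is preserved.
#'
#' @param conn a `connectome`.
#' @param lesion a `lesion`.
#' @return A lesioned copy of `conn`.
#' @export
apply_lesion <- function(conn, lesion) {
  stopifnot(inherits(conn, "connectome"), inherits(lesion, "lesion"))
  ns <- lesion$node_set
  if (length(ns) > 0 && (min(ns) < 1 || max(ns) > conn$n_nodes)) {
    stop("lesion node IDs must lie in 1..", conn$n_nodes)
  }
  conn$weights[ns, ] <- 0
  conn$weights[, ns] <- 0
  mask <- conn$lesion_mask
  if (is.null(mask)) mask <- rep(FALSE, conn$n_nodes)
  mask[ns] <- TRUE
  conn$lesion_mask <- mask
  validate_connectome(conn)
  conn
}

#' Fraction of connections removed by a lesion
#'
#' Proportion of the network's unordered connected pairs that have at least
#' one endpoint in the lesioned set, either by pair count (`mode =
#' "count"`) or by summed weight (`mode = "weight"`). Evaluate on the
#' pre-lesion connectome.
#'
#' @param conn a `connectome` with at least one connection.
#' @param lesion a `lesion`.
#' @param mode `"count"` or `"weight"`.
#' @return A fraction in `[0, 1]`.
#' @export
lesion_connection_fraction <- function(conn, lesion,
                                       mode = c("count", "weight")) {
  mode <- match.arg(mode)
  if (conn$n_nodes == 0) stop("empty connectome")
  ut <- upper.tri(conn$weights)
  w <- conn$weights[ut]
  nz <- w != 0
  if (!any(nz)) stop("connectome has no connections")
  n <- conn$n_nodes
  ri <- row(conn$weights)[ut]
  ci <- col(conn$weights)[ut]
  hit <- nz & (ri %in% lesion$node_set | ci %in% lesion$node_set)
  if (mode == "count") sum(hit) / sum(nz) else sum(w[hit]) / sum(w[nz])
}

#' Construct a stimulation protocol
#'
#' A constant current `amplitude` (nA; negative values are inhibitory, as
#' in the virtual TMS protocol) injected into every node of `node_set`
#' during the half-open time window `[t_on, t_off)`. Stimulations enter
#' [synaptic_input()] additively, so disjoint protocols compose.
#'
#' @param node_set 1-based node IDs.
#' @param amplitude current in nA (signed).
#' @param t_on,t_off window start and end in seconds, `t_on < t_off`.
#' @return A `stimulation`.
#' @export
make_stimulation <- function(node_set, amplitude, t_on, t_off) {
  node_set <- sort(unique(as.integer(node_set)))
  if (t_on >= t_off) stop("stimulation window inverted: t_on must be < t_off")
  if (t_on < 0) stop("t_on must be non-negative")
  structure(list(node_set = node_set, amplitude = amplitude,
                 t_on = t_on, t_off = t_off),
            class = "stimulation")
}

#' @export
print.stimulation <- function(x, ...) {
  cat("stimulation: ", length(x$node_set), " nodes, ", x$amplitude,
      " nA over [", x$t_on, ", ", x$t_off, ") s\n", sep = "")
  invisible(x)
}
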