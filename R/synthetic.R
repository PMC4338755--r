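#' Specification for an atlas-structured synthetic connectome
#'
#' Describes a random modular connectome emulating the shape of the 998-ROI
#' diffusion-imaging dataset: nodes grouped into atlas regions, a denser
#' within-region block structure, heavy-tailed weights normalized into
#' (0, 1], and region-clustered coordinates.
#'
#' Edges are drawn independently per unordered node pair with probability
#' `intra_region_density` (both endpoints in the same region) or
#' `inter_region_density` (otherwise). When `inter_region_density` is `NULL`
#' (the default) it is solved analytically from the atlas pair counts so the
#' expected unordered edge count equals `target_edge_pairs`.
#'
#' @param n_nodes node count; must equal the atlas coverage.
#' @param atlas a `brain_atlas`; defaults to the built-in 66-region atlas.
#' @param target_edge_pairs expected number of unordered connected pairs.
#' @param intra_region_density edge probability within a region.
#' @param inter_region_density edge probability across regions, or `NULL`
#'   to derive it from `target_edge_pairs`.
#' @param weight_distribution `list(kind = "lognormal", meanlog, sdlog)` or
#'   `list(kind = "uniform", lo, hi)`; sampled weights are divided by their
#'   maximum so weights lie in (0, 1].
#' @param coordinate_jitter per-axis standard deviation (mm) of node scatter
#'   around its region centroid.
#' @param seed integer RNG seed.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_nodes = 998,
                       atlas = load_builtin_atlas(),
                       target_edge_pairs = 17000,
                       intra_region_density = 0.30,
                       inter_region_density = NULL,
                       weight_distribution = list(kind = "lognormal",
                                                  meanlog = 0, sdlog = 1),
                       coordinate_jitter = 5,
                       seed = 1L) {
  if (n_nodes != atlas_total_nodes(atlas)) {
    stop("n_nodes (", n_nodes, ") must match atlas coverage (",
         atlas_total_nodes(atlas), ")")
  }
  counts <- .pair_counts(atlas)
  if (is.null(inter_region_density)) {
    inter_region_density <-
      (target_edge_pairs - intra_region_density * counts$intra) / counts$inter
  }
  if (intra_region_density < 0 || intra_region_density > 1 ||
      inter_region_density < 0 || inter_region_density > 1) {
    stop("infeasible density/edge-target combination: intra = ",
         format(intra_region_density), ", inter = ",
         format(inter_region_density), " (must lie in [0, 1])")
  }
  expected <- intra_region_density * counts$intra +
    inter_region_density * counts$inter
  if (abs(expected - target_edge_pairs) > 0.1 * target_edge_pairs) {
    stop("infeasible density/edge-target combination: expected pair count ",
         round(expected), " deviates more than 10% from target ",
         target_edge_pairs)
  }
  structure(
    list(n_nodes = as.integer(n_nodes), atlas = atlas,
         target_edge_pairs = target_edge_pairs,
         intra_region_density = intra_region_density,
         inter_region_density = inter_region_density,
         weight_distribution = weight_distribution,
         coordinate_jitter = coordinate_jitter,
         expected_edge_pairs = expected,
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

# unordered pair counts within / across atlas regions
.pair_counts <- function(atlas) {
  sizes <- atlas$node_end - atlas$node_start + 1
  n <- sum(sizes)
  intra <- sum(sizes * (sizes - 1) / 2)
  list(intra = intra, inter = n * (n - 1) / 2 - intra)
}

#' Generate a synthetic connectome
#'
#' Draws a symmetric, zero-diagonal, non-negative weighted network from a
#' [synth_spec()]: Bernoulli edges with block densities, weights from the
#' configured distribution max-normalized into (0, 1], and coordinates
#' clustered around per-region centroids. The same spec (including seed)
#' always yields a bit-identical connectome.
#'
#' @param spec a `synth_spec`.
#' @return A validated `connectome` with region labels from the atlas.
#' @examples
#' conn <- synthetic_connectome(synth_spec(seed = 7))
#' conn$n_nodes          # 998
#' @export
synthetic_connectome <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_nodes
  labels <- atlas_node_labels(spec$atlas)
  group <- match(labels, atlas_region_labels(spec$atlas))

  # upper-triangle Bernoulli draw with block-dependent probability
  ut <- which(upper.tri(matrix(0, n, n)))
  ri <- ((ut - 1) %% n) + 1          # row index of column-major position
  ci <- ((ut - 1) %/% n) + 1
  p <- ifelse(group[ri] == group[ci],
              spec$intra_region_density, spec$inter_region_density)
  on <- stats::runif(length(ut)) < p
  sel <- ut[on]

  wd <- spec$weight_distribution
  m <- length(sel)
  wvals <- switch(wd$kind,
    lognormal = stats::rlnorm(m, meanlog = wd$meanlog, sdlog = wd$sdlog),
    uniform = stats::runif(m, min = wd$lo, max = wd$hi),
    stop("unknown weight distribution kind: ", wd$kind)
  )
  if (m > 0) wvals <- wvals / max(wvals)
  w <- matrix(0, n, n)
  w[sel] <- wvals
  w <- w + t(w)

  centroids <- .region_centroids(spec$atlas)
  coords <- centroids[group, , drop = FALSE] +
    matrix(stats::rnorm(3 * n, sd = spec$coordinate_jitter), n, 3)

  conn <- connectome(w, coords, labels)
  validate_connectome(conn, atlas = spec$atlas)
  conn
}

# Deterministic region centroids: regions spread in a Talairach-sized box,
# hemispheres mirrored in x. Layout is fixed (independent of spec seed) so
# coordinates are comparable across generated connectomes.
.region_centroids <- function(atlas) {
  k <- nrow(atlas)
  ids <- atlas$id
  per_hemi <- max(ids)
  ang <- 2 * pi * (ids - 1) / per_hemi
  x <- ifelse(atlas$hemisphere == "R", 45, -45) + 10 * cos(3 * ang)
  y <- 70 * sin(ang)
  z <- 30 * cos(2 * ang) + 15
  cbind(x = x, y = y, z = z)
}

#' Mirror the right hemisphere onto the left
#'
#' Replaces the left-hemisphere block of the weight matrix with a relabeled
#' copy of the right-hemisphere block (node `i` maps to node `n/2 + i`) and
#' replaces inter-hemispheric coupling with `n_homotopic` weak random
#' homotopic links connecting mirrored node pairs. Coordinates of the left
#' half become the x-mirrored right-half coordinates; labels swap their
#' hemisphere prefix. Requires an even node count with equal-sized
#' hemisphere halves and atlas-derived region labels.
#'
#' @param conn a `connectome` whose first half is the right hemisphere.
#' @param n_homotopic number of homotopic links to create.
#' @param homotopic_weight length-2 range of uniform weights for the links.
#' @param seed RNG seed for link placement.
#' @return A new symmetric `connectome`.
#' @export
mirror_hemispheres <- function(conn, n_homotopic = 66,
                               homotopic_weight = c(0.01, 0.1), seed = 1L) {
  if (is.null(conn$region_label)) {
    stop("mirror_hemispheres requires atlas-derived region labels")
  }
  n <- conn$n_nodes
  if (n %% 2 != 0) stop("mirror_hemispheres requires an even node count")
  h <- n / 2
  pre <- substr(conn$region_label, 1, 1)
  if (!all(pre[seq_len(h)] == "r") || !all(pre[h + seq_len(h)] == "l")) {
    stop("hemisphere halves are not equal-sized (right block must be ",
         "nodes 1..n/2, left block n/2+1..n)")
  }
  if (n_homotopic > h) stop("n_homotopic exceeds nodes per hemisphere")
  set.seed(seed)
  w <- conn$weights
  rr <- w[seq_len(h), seq_len(h)]
  w[h + seq_len(h), h + seq_len(h)] <- rr
  w[seq_len(h), h + seq_len(h)] <- 0
  w[h + seq_len(h), seq_len(h)] <- 0
  picks <- sort(sample.int(h, n_homotopic))
  link_w <- stats::runif(n_homotopic, homotopic_weight[1], homotopic_weight[2])
  for (k in seq_along(picks)) {
    i <- picks[k]
    w[i, h + i] <- link_w[k]
    w[h + i, i] <- link_w[k]
  }
  coords <- conn$coordinates
  coords[h + seq_len(h), ] <- coords[seq_len(h), ] %*% diag(c(-1, 1, 1))
  labels <- conn$region_label
  labels[h + seq_len(h)] <- sub("^r", "l", labels[seq_len(h)])
  connectome(w, coords, labels, conn$node_id)
}
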