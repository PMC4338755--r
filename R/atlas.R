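# Built-in cortical atlas: 33 regions per hemisphere, 998 ROIs total.
# Columns: region id (1..33), abbreviation, anatomical name, node ranges on
# the right (1..500) and left (501..998) hemispheres. Node IDs are 1-based.
.atlas_table <- function() {
  raw <- c(
    "1|BSTS|Bank of the superior temporal sulcus|463|469|961|965",
    "2|CAC|Caudal anterior cingulate cortex|191|194|692|695",
    "3|CMF|Caudal middle frontal cortex|126|138|628|640",
    "4|CUN|Cuneus|335|344|835|842",
    "5|ENT|Entorhinal cortex|419|420|918|920",
    "6|FP|Frontal pole|26|27|527|528",
    "7|FUS|Fusiform gyrus|391|412|890|911",
    "8|IP|Inferior parietal cortex|284|311|787|811",
    "9|IT|Inferior temporal cortex|424|442|925|941",
    "10|ISTC|Isthmus of the cingulate cortex|202|209|703|710",
    "11|LOCC|Lateral occipital cortex|355|373|852|873",
    "12|LOF|Lateral orbitofrontal cortex|1|19|501|520",
    "13|LING|Lingual gyrus|374|390|874|889",
    "14|MOF|Medial orbitofrontal cortex|28|39|529|540",
    "15|MT|Middle temporal cortex|443|462|942|960",
    "16|PARC|Paracentral lobule|175|186|677|687",
    "17|PARH|Parahippocampal cortex|413|418|912|917",
    "18|POPE|Pars opercularis|48|57|548|558",
    "19|PORB|Pars orbitalis|20|25|521|526",
    "20|PTRI|Pars triangularis|40|47|541|547",
    "21|PCAL|Pericalcarine cortex|345|354|843|851",
    "22|PSTC|Postcentral gyrus|210|240|711|740",
    "23|PC|Posterior cingulate cortex|195|201|696|702",
    "24|PREC|Precentral gyrus|139|174|641|676",
    "25|PCUN|Precuneus|312|334|812|834",
    "26|RAC|Rostral anterior cingulate cortex|187|190|688|691",
    "27|RMF|Rostral middle frontal cortex|58|79|559|577",
    "28|SF|Superior frontal cortex|80|125|578|627",
    "29|SP|Superior parietal cortex|257|283|760|786",
    "30|ST|Superior temporal cortex|470|497|966|994",
    "31|SMAR|Supramarginal gyrus|241|256|741|759",
    "32|TP|Temporal pole|421|423|921|924",
    "33|TT|Transverse temporal cortex|498|500|995|998"
  )
  fields <- strsplit(raw, "|", fixed = TRUE)
  m <- do.call(rbind, fields)
  data.frame(
    id = as.integer(m[, 1]),
    abbr = m[, 2],
    name = m[, 3],
    r_start = as.integer(m[, 4]), r_end = as.integer(m[, 5]),
    l_start = as.integer(m[, 6]), l_end = as.integer(m[, 7]),
    stringsAsFactors = FALSE
  )
}

#' Construct a brain atlas
#'
#' An atlas maps named cortical regions to inclusive, 1-based node index
#' ranges. Regions must tile the node index space: ranges are pairwise
#' disjoint and their union is `1..max(node_end)` with no gaps.
#'
#' @param regions data frame with columns `id` (integer region id within
#'   hemisphere), `hemisphere` (`"R"` or `"L"`), `abbr` (abbreviation,
#'   without hemisphere prefix), `name` (full anatomical name),
#'   `node_start`, `node_end` (inclusive 1-based node range).
#' @return An object of class `brain_atlas` (a validated data frame).
#' @seealso [load_builtin_atlas()], [nodes_of_regions()]
#' @export
brain_atlas <- function(regions) {
  needed <- c("id", "hemisphere", "abbr", "name", "node_start", "node_end")
  missing_cols <- setdiff(needed, names(regions))
  if (length(missing_cols) > 0) {
    stop("atlas is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  regions <- as.data.frame(regions)[, needed]
  regions$id <- as.integer(regions$id)
  regions$node_start <- as.integer(regions$node_start)
  regions$node_end <- as.integer(regions$node_end)
  if (!all(regions$hemisphere %in% c("R", "L"))) {
    stop("hemisphere must be 'R' or 'L'")
  }
  if (any(regions$node_start > regions$node_end)) {
    stop("node_start must not exceed node_end")
  }
  key <- paste0(ifelse(regions$hemisphere == "R", "r", "l"), regions$abbr)
  if (anyDuplicated(key)) stop("duplicated region labels: ",
                               paste(key[duplicated(key)], collapse = ", "))
  idx <- unlist(mapply(seq.int, regions$node_start, regions$node_end,
                       SIMPLIFY = FALSE))
  if (anyDuplicated(idx)) stop("atlas node ranges overlap")
  n <- max(regions$node_end)
  if (length(idx) != n || !setequal(idx, seq_len(n))) {
    stop("atlas node ranges leave gaps: ", length(idx), " indices for 1..", n)
  }
  regions <- regions[order(regions$hemisphere == "L", regions$id), ]
  rownames(regions) <- NULL
  structure(regions, class = c("brain_atlas", "data.frame"))
}

#' Load the built-in 66-region cortical atlas
#'
#' Returns the packaged parcellation of 998 cortical regions of interest
#' (ROIs) into 33 anatomical regions per hemisphere (66 regions total).
#' Right-hemisphere ROIs occupy indices 1-500, left-hemisphere ROIs 501-998.
#' Region labels carry an `r`/`l` hemisphere prefix, e.g. `"rCUN"` is the
#' right cuneus.
#'
#' @return A `brain_atlas` with 66 rows covering node indices 1..998.
#' @examples
#' atl <- load_builtin_atlas()
#' nrow(atl)                          # 66
#' atlas_total_nodes(atl)             # 998
#' nodes_of_regions(atl, "rBSTS")     # 463..469
#' @export
load_builtin_atlas <- function() {
  tab <- .atlas_table()
  regions <- rbind(
    data.frame(id = tab$id, hemisphere = "R", abbr = tab$abbr, name = tab$name,
               node_start = tab$r_start, node_end = tab$r_end,
               stringsAsFactors = FALSE),
    data.frame(id = tab$id, hemisphere = "L", abbr = tab$abbr, name = tab$name,
               node_start = tab$l_start, node_end = tab$l_end,
               stringsAsFactors = FALSE)
  )
  brain_atlas(regions)
}

#' @export
print.brain_atlas <- function(x, ...) {
  cat("brain_atlas:", nrow(x), "regions,", atlas_total_nodes(x), "nodes\n")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more regions\n")
  invisible(x)
}

#' Region labels of an atlas
#'
#' @param atlas a `brain_atlas`.
#' @return Character vector of hemisphere-prefixed labels (e.g. `"rCUN"`),
#'   one per atlas row, in atlas order.
#' @export
atlas_region_labels <- function(atlas) {
  paste0(ifelse(atlas$hemisphere == "R", "r", "l"), atlas$abbr)
}

#' Total number of nodes covered by an atlas
#' @param atlas a `brain_atlas`.
#' @return Integer count of node indices covered.
#' @export
atlas_total_nodes <- function(atlas) {
  sum(atlas$node_end - atlas$node_start + 1L)
}

#' Per-node region labels
#'
#' @param atlas a `brain_atlas`.
#' @return Character vector of length `atlas_total_nodes(atlas)` giving the
#'   hemisphere-prefixed region label of every node.
#' @export
atlas_node_labels <- function(atlas) {
  lab <- atlas_region_labels(atlas)
  out <- character(atlas_total_nodes(atlas))
  for (i in seq_len(nrow(atlas))) {
    out[atlas$node_start[i]:atlas$node_end[i]] <- lab[i]
  }
  out
}

#' Nodes belonging to named regions
#'
#' Resolves hemisphere-prefixed region names (`r`/`l` + abbreviation, e.g.
#' `"rPCUN"`) to the union of their node index ranges. Ranges are disjoint by
#' atlas construction, so the result has no duplicates.
#'
#' @param atlas a `brain_atlas`.
#' @param region_names character vector of prefixed region names; may be
#'   empty.
#' @return Sorted integer vector of 1-based node IDs.
#' @examples
#' atl <- load_builtin_atlas()
#' length(nodes_of_regions(atl, c("rCUN", "rLOCC", "rPCUN")))  # 52
#' @export
nodes_of_regions <- function(atlas, region_names) {
  if (length(region_names) == 0) return(integer(0))
  lab <- atlas_region_labels(atlas)
  hit <- match(region_names, lab)
  if (anyNA(hit)) {
    stop("unknown region name(s): ",
         paste(region_names[is.na(hit)], collapse = ", "),
         "\nvalid names are: ", paste(sort(lab), collapse = ", "))
  }
  sort(unlist(mapply(seq.int, atlas$node_start[hit], atlas$node_end[hit],
                     SIMPLIFY = FALSE)))
}

#' Region label of individual nodes
#'
#' @param atlas a `brain_atlas`.
#' @param nodes integer vector of 1-based node IDs.
#' @return Character vector of hemisphere-prefixed region labels.
#' @examples
#' region_of_nodes(load_builtin_atlas(), 193)  # "rCAC"
#' @export
region_of_nodes <- function(atlas, nodes) {
  n <- atlas_total_nodes(atlas)
  nodes <- as.integer(nodes)
  if (any(nodes < 1L | nodes > n)) {
    stop("node IDs must lie in 1..", n)
  }
  atlas_node_labels(atlas)[nodes]
}

#' Export an atlas as CSV
#'
#' Writes columns `id,abbr,name,hemisphere,node_start,node_end`.
#'
#' @param atlas a `brain_atlas`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_atlas_csv <- function(atlas, path) {
  out <- as.data.frame(atlas)[, c("id", "abbr", "name", "hemisphere",
                                  "node_start", "node_end")]
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
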