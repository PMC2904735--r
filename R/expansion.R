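#' Diameter of an induced subgraph
#'
#' Breadth-first all-pairs shortest paths on the subgraph induced by
#' `nodes`.  When the induced subgraph is disconnected the diameter of the
#' largest connected component is reported, together with the fraction of
#' nodes that component holds.
#'
#' @param net an undirected simple igraph.
#' @param nodes nonempty character vector of node names.
#' @return list `diameter` (integer; 0 for a single node), `lccFraction`
#'   (1 when connected), `lccSize`.
#' @examples
#' p5 <- igraph::make_ring(5, circular = FALSE)
#' igraph::V(p5)$name <- letters[1:5]
#' subgraphDiameter(p5, letters[1:5])$diameter  # 4
#' @export
subgraphDiameter <- function(net, nodes) {
  .checkNetwork(net)
  if (length(nodes) == 0L) stop("empty node set")
  unknown <- setdiff(nodes, igraph::V(net)$name)
  if (length(unknown)) stop("unknown node(s): ", paste(unknown, collapse = ", "))
  sub <- igraph::induced_subgraph(net, nodes)
  comp <- igraph::components(sub)
  lcc <- which.max(comp$csize)
  lccNodes <- igraph::V(sub)$name[comp$membership == lcc]
  d <- if (length(lccNodes) == 1L) 0L else {
    core <- igraph::induced_subgraph(sub, lccNodes)
    as.integer(max(igraph::distances(core)))
  }
  list(diameter = d,
       lccFraction = max(comp$csize) / length(nodes),
       lccSize = as.integer(max(comp$csize)))
}

#' Expand a cluster to its neighbourhood network
#'
#' The expanded network holds the cluster (core) plus every direct neighbour
#' of a core node (periphery), with all interactions of the parent network
#' among those nodes -- the construction used to recover a connected pathway
#' subnetwork around a signature cluster, which on its own is typically
#' disconnected.
#'
#' @param net an undirected simple igraph.
#' @param core nonempty character vector of cluster member names.
#' @param labels optional data.frame from [labelSPRs()], used to annotate
#'   nodes as KPR / SPR / other.
#' @return list `core`, `periphery`, `nodes`, `subgraph` (igraph with vertex
#'   attributes `role` in core/periphery and, when labels are given, `label`
#'   in KPR/SPR/other), `diameter`, `lccFraction`.
#' @export
expandCluster <- function(net, core, labels = NULL) {
  .checkNetwork(net)
  if (length(core) == 0L) stop("empty core")
  unknown <- setdiff(core, igraph::V(net)$name)
  if (length(unknown)) stop("unknown node(s): ", paste(unknown, collapse = ", "))
  nb <- unlist(lapply(igraph::adjacent_vertices(net, core), names))
  periphery <- sort(setdiff(nb, core))
  nodes <- c(sort(core), periphery)
  sub <- igraph::induced_subgraph(net, nodes)
  role <- ifelse(igraph::V(sub)$name %in% core, "core", "periphery")
  sub <- igraph::set_vertex_attr(sub, "role", value = role)
  if (!is.null(labels)) {
    m <- match(igraph::V(sub)$name, labels$id)
    lab <- ifelse(!is.na(m) & labels$is_kpr[m], "KPR",
                  ifelse(!is.na(m) & labels$is_spr[m], "SPR", "other"))
    sub <- igraph::set_vertex_attr(sub, "label", value = lab)
  }
  dm <- subgraphDiameter(net, nodes)
  list(core = sort(core), periphery = periphery, nodes = nodes,
       subgraph = sub, diameter = dm$diameter, lccFraction = dm$lccFraction)
}

#' Direct-neighbourhood cluster around a seed
#'
#' The seed plus its direct neighbours.  Because every pair of members is
#' joined through the seed, the induced subgraph is connected with diameter
#' at most 2 (0 for an isolated seed, 1 for a clique neighbourhood) -- the
#' structural ceiling that makes direct neighbourhoods a poor stand-in for
#' biological pathways, whose mapped diameters are typically much larger.
#'
#' @param net an undirected simple igraph.
#' @param seed a node name.
#' @return Character vector: seed and its neighbours.
#' @export
directNeighborhoodCluster <- function(net, seed) {
  .checkNetwork(net)
  if (!seed %in% igraph::V(net)$name) stop("unknown seed: ", seed)
  sort(unique(c(seed, names(igraph::neighbors(net, seed)))))
}

#' Two-step neighbourhood of a seed
#'
#' All nodes within distance 2 of the seed.  The induced subgraph has
#' diameter at most 4 (any two members reach each other through the seed).
#'
#' @param net an undirected simple igraph.
#' @param seed a node name.
#' @return Character vector of node names.
#' @export
twoStepNeighborhood <- function(net, seed) {
  .checkNetwork(net)
  if (!seed %in% igraph::V(net)$name) stop("unknown seed: ", seed)
  sort(names(igraph::ego(net, order = 2, nodes = seed)[[1L]]))
}

#' Survey pathway gene-set diameters on a network
#'
#' Maps each gene set onto the network (dropping identifiers the network
#' does not contain, counted in the report), excludes sets that map too
#' sparsely to be meaningful, and computes the induced-subgraph diameter of
#' each surviving set (largest-component convention).  Exclusion rule,
#' operationalizing "consists mainly of isolated edges": fewer than
#' `minMapped` mapped nodes, or a largest connected component holding less
#' than `lccMinFraction` of the mapped nodes, or a largest component of at
#' most `lccMinSize` nodes.
#'
#' @param net an undirected simple igraph.
#' @param geneSets named list of identifier vectors (see [readGeneSets()]).
#' @param minMapped minimum mapped nodes (default 3).
#' @param lccMinFraction minimum fraction of mapped nodes in the largest
#'   component (default 0.5).
#' @param lccMinSize largest component must exceed this size (default 2).
#' @return list `perSet` (data.frame `name`, `n_set`, `n_mapped`,
#'   `lcc_fraction`, `diameter`, `excluded`, `reason`) and `summary` (list
#'   `n_surveyed`, `fraction_gt2`, `mean`, `sd`, `excluded_sets`).
#' @export
pathwayDiameterSurvey <- function(net, geneSets, minMapped = 3L,
                                  lccMinFraction = 0.5, lccMinSize = 2L) {
  .checkNetwork(net)
  vs <- igraph::V(net)$name
  rows <- lapply(names(geneSets), function(nm) {
    ids <- unique(geneSets[[nm]])
    mapped <- intersect(ids, vs)
    if (length(mapped) < minMapped)
      return(data.frame(name = nm, n_set = length(ids), n_mapped = length(mapped),
                        lcc_fraction = NA_real_, diameter = NA_integer_,
                        excluded = TRUE, reason = "too few mapped nodes"))
    dm <- subgraphDiameter(net, mapped)
    excl <- dm$lccFraction < lccMinFraction || dm$lccSize <= lccMinSize
    data.frame(name = nm, n_set = length(ids), n_mapped = length(mapped),
               lcc_fraction = dm$lccFraction, diameter = dm$diameter,
               excluded = excl,
               reason = if (excl) "mainly isolated edges" else "")
  })
  perSet <- do.call(rbind, rows)
  keep <- perSet[!perSet$excluded, , drop = FALSE]
  summary <- list(
    n_surveyed = nrow(keep),
    fraction_gt2 = if (nrow(keep)) mean(keep$diameter > 2) else NA_real_,
    mean = if (nrow(keep)) mean(keep$diameter) else NA_real_,
    sd = if (nrow(keep) > 1L) stats::sd(keep$diameter) else NA_real_,
    excluded_sets = perSet$name[perSet$excluded])
  list(perSet = perSet, summary = summary)
}

#' Write a diameter survey as TSV
#'
#' Per-set rows plus a trailing summary comment line.
#'
#' @param survey result of [pathwayDiameterSurvey()].
#' @param path output file path.
#' @export
writeSurveyReport <- function(survey, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(survey$perSet, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  s <- survey$summary
  writeLines(sprintf("# surveyed=%d fraction_gt2=%.4f mean=%.4f sd=%.4f excluded=%d",
                     s$n_surveyed, s$fraction_gt2, s$mean,
                     ifelse(is.na(s$sd), 0, s$sd), length(s$excluded_sets)), con)
  invisible(path)
}
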