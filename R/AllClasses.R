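#' Graphlet and orbit catalog
#'
#' Holds the 30 connected 2-5-node graphlets, their 73 automorphism orbits,
#' per-mask orbit lookup tables used by the counting engine, and the orbit
#' dependency counts / similarity weights.
#'
#' @slot graphlets list of 30 adjacency matrices in canonical order G0..G29.
#' @slot orbits data.frame with one row per orbit (columns `orbit`,
#'   `graphlet`, `nodes`, `edges`, `degree`, `multiplicity`, `o`, `weight`).
#' @slot orbitOfNode list parallel to `graphlets`: 0-based global orbit id of
#'   each node of each graphlet.
#' @slot maskOrbit list of 4 integer matrices (k = 2..5); row = edge-mask of
#'   a labelled k-node graph, column = node position, entry = global orbit id
#'   or -1 when the mask is disconnected.
#' @slot depCounts integer vector of 73 dependency counts \eqn{o_i}.
#' @slot weights numeric vector of 73 weights \eqn{w_i}.
#' @aliases GraphletCatalog
#' @export
setClass("GraphletCatalog",
  representation(graphlets = "list", orbits = "data.frame",
                 orbitOfNode = "list", maskOrbit = "list",
                 depCounts = "integer", weights = "numeric"))

setValidity("GraphletCatalog", function(object) {
  msg <- character()
  if (length(object@graphlets) != 30L) msg <- c(msg, "expected 30 graphlets")
  if (nrow(object@orbits) != 73L) msg <- c(msg, "expected 73 orbits")
  small <- object@orbits$nodes <= 4L
  if (sum(small) != 15L) msg <- c(msg, "expected 15 orbits on <=4-node graphlets")
  if (length(unique(object@orbits$graphlet[small])) != 9L)
    msg <- c(msg, "expected 9 graphlets on <=4 nodes")
  if (length(object@depCounts) != 73L || object@depCounts[1L] != 1L)
    msg <- c(msg, "o_0 must be 1 (the edge depends only on itself)")
  if (any(object@weights < 0 | object@weights > 1))
    msg <- c(msg, "weights must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Seed-centric signature clusters
#'
#' The result of the adaptive-threshold cluster search run over a set of
#' screen-positive seeds.  One record per seed; `status` is `"formed"`
#' (seed plus at least two signature-similar nodes), `"singleton"` (seed plus
#' exactly one other node) or `"unformed"` (nothing within reach at the
#' threshold floor).  Only formed clusters (size >= 3) enter enrichment
#' analysis.
#'
#' @slot table data.frame with columns `seed`, `status`, `threshold`, `size`.
#' @slot members named list (by seed) of member identifier vectors, seed
#'   included.
#' @slot grid numeric vector, the descending threshold grid that was scanned.
#' @aliases SignatureClusterSet
#' @export
setClass("SignatureClusterSet",
  representation(table = "data.frame", members = "list", grid = "numeric"))

setValidity("SignatureClusterSet", function(object) {
  msg <- character()
  tb <- object@table
  need <- c("seed", "status", "threshold", "size")
  if (!all(need %in% names(tb))) return("cluster table missing columns")
  if (!all(tb$status %in% c("formed", "singleton", "unformed")))
    msg <- c(msg, "unknown cluster status")
  if (!all(tb$seed %in% names(object@members)))
    msg <- c(msg, "every seed needs a member record")
  for (s in tb$seed) if (!(s %in% object@members[[s]]))
    msg <- c(msg, sprintf("seed %s missing from its own cluster", s))
  if (length(msg)) msg else TRUE
})

#' Random-cluster null model summary
#'
#' Distribution of the number of significant clusters when clusters of the
#' observed sizes are redrawn uniformly at random from the eligible node set,
#' with the observed count standardized against it.
#'
#' @slot observed integer, significant clusters in the real data.
#' @slot runs integer, number of randomization runs.
#' @slot nullCounts integer vector of per-run significant-cluster counts.
#' @slot mu,sigma numeric, mean and standard deviation of `nullCounts`.
#' @slot empiricalP numeric, fraction of runs with count >= observed.
#' @slot z,normalP numeric, Z-score of the observation and its upper-tail
#'   normal p-value (NA when sigma is 0).
#' @aliases NullModelSummary
#' @export
setClass("NullModelSummary",
  representation(observed = "integer", runs = "integer", nullCounts = "integer",
                 mu = "numeric", sigma = "numeric", empiricalP = "numeric",
                 z = "numeric", normalP = "numeric"))

setValidity("NullModelSummary", function(object) {
  msg <- character()
  if (length(object@nullCounts) != object@runs)
    msg <- c(msg, "nullCounts length must equal runs")
  if (object@empiricalP < 0 || object@empiricalP > 1)
    msg <- c(msg, "empiricalP outside [0,1]")
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic screen-plus-network study
#'
#' A generated PPI-like network with planted pathway modules, per-node screen
#' Z-scores and known-regulator flags, plus the ground truth needed for
#' parameter-recovery evaluation.
#'
#' @slot network an igraph, undirected and simple, with named vertices.
#' @slot annotations data.frame `id`, `z_score`, `is_kpr` covering all nodes.
#' @slot pathways named list of planted member identifier vectors.
#' @slot planted named logical vector over all nodes.
#' @slot config list, the generator configuration (including the seed).
#' @aliases SyntheticStudy
#' @export
setClass("SyntheticStudy",
  representation(network = "ANY", annotations = "data.frame",
                 pathways = "list", planted = "logical", config = "list"))

setValidity("SyntheticStudy", function(object) {
  msg <- character()
  if (!igraph::is_igraph(object@network)) return("network must be an igraph")
  nodes <- igraph::V(object@network)$name
  if (!all(unlist(object@pathways) %in% nodes))
    msg <- c(msg, "planted members must be network nodes")
  if (!setequal(object@annotations$id, nodes))
    msg <- c(msg, "annotations must cover exactly the network nodes")
  if (igraph::any_loop(object@network) || igraph::any_multiple(object@network))
    msg <- c(msg, "network must be simple")
  if (length(msg)) msg else TRUE
})

## ---- accessors and show methods -----------------------------------------

#' @describeIn GraphletCatalog number of graphlets (30)
#' @param catalog,object a `GraphletCatalog`
#' @export
nGraphlets <- function(catalog) length(catalog@graphlets)

#' @describeIn GraphletCatalog number of orbits (73)
#' @export
nOrbits <- function(catalog) nrow(catalog@orbits)

#' @describeIn GraphletCatalog the per-orbit metadata table
#' @export
orbitTable <- function(catalog) catalog@orbits

#' @describeIn GraphletCatalog adjacency matrices of the graphlets
#' @export
graphletAdjacency <- function(catalog) catalog@graphlets

setMethod("show", "GraphletCatalog", function(object) {
  cat("GraphletCatalog: ", nGraphlets(object), " graphlets (2-5 nodes), ",
      nOrbits(object), " automorphism orbits\n", sep = "")
  cat("  weights: w_i = 1 - log(o_i)/log(73); w_0 = 1\n")
})

#' @describeIn SignatureClusterSet per-seed summary table
#' @param x a `SignatureClusterSet`
#' @export
clusterTable <- function(x) x@table

#' @describeIn SignatureClusterSet member lists (seed included); `seeds`
#'   restricts to a subset of seeds
#' @param seeds optional character vector of seeds
#' @export
clusterMembers <- function(x, seeds = NULL) {
  if (is.null(seeds)) x@members else x@members[seeds]
}

#' @describeIn SignatureClusterSet seeds whose clusters reached size >= 3
#' @export
formedSeeds <- function(x) x@table$seed[x@table$status == "formed"]

setMethod("show", "SignatureClusterSet", function(object) {
  tb <- table(factor(object@table$status,
                     levels = c("formed", "singleton", "unformed")))
  cat("SignatureClusterSet: ", nrow(object@table), " seeds (",
      tb[["formed"]], " formed, ", tb[["singleton"]], " singleton, ",
      tb[["unformed"]], " unformed)\n", sep = "")
  cat("  threshold grid: ", paste(format(object@grid), collapse = " "), "\n", sep = "")
})

setMethod("show", "NullModelSummary", function(object) {
  cat("NullModelSummary: observed =", object@observed,
      "significant clusters over", object@runs, "randomization runs\n")
  cat(sprintf("  null mean = %.2f, sd = %.2f, empirical p = %.4g, Z = %.2f, normal-tail p = %.4g\n",
              object@mu, object@sigma, object@empiricalP, object@z, object@normalP))
})

setMethod("show", "SyntheticStudy", function(object) {
  cat("SyntheticStudy:", igraph::vcount(object@network), "nodes,",
      igraph::ecount(object@network), "edges;",
      length(object@pathways), "planted pathways of sizes",
      paste(vapply(object@pathways, length, integer(1L)), collapse = ", "), "\n")
  cat("  seed:", object@config$seed, "\n")
})

#' @describeIn SyntheticStudy the generated network (igraph)
#' @param study a `SyntheticStudy`
#' @export
studyNetwork <- function(study) study@network

#' @describeIn SyntheticStudy the node annotation table
#' @export
studyAnnotations <- function(study) study@annotations

#' @describeIn SyntheticStudy named list of planted pathway member sets
#' @export
plantedPathways <- function(study) study@pathways
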