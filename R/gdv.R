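#' Graphlet degree vectors for every node of a network
#'
#' Computes, for each node, the 73-coordinate graphlet degree vector (GDV):
#' coordinate i counts how many times the node is touched by automorphism
#' orbit i over all connected induced subgraphs on 2-5 nodes.  Coordinate 0
#' is the node degree.  Counting always uses the full network (every node and
#' edge), regardless of any eligibility filtering applied downstream.
#'
#' Connected induced subgraphs are enumerated exactly once each with the ESU
#' neighbourhood-expansion scheme and classified through the catalog's
#' canonical-form lookup tables; the exhaustive [countGDVOracle()] guards the
#' implementation on small graphs.
#'
#' @param net an undirected simple igraph with named vertices.
#' @param catalog a [GraphletCatalog-class].
#' @return Numeric matrix, one row per node (in `V(net)` order, rownames set
#'   to vertex names), 73 columns `orbit_0` .. `orbit_72`.
#' @examples
#' tri <- igraph::make_ring(3)
#' igraph::V(tri)$name <- c("a", "b", "c")
#' gdvMatrix(tri)[, 1:4]  # each node: degree 2, one triangle
#' @export
gdvMatrix <- function(net, catalog = buildOrbitCatalog()) {
  .checkNetwork(net)
  adj <- lapply(igraph::as_adj_list(net, mode = "all"), function(v) as.integer(v) - 1L)
  counts <- esu_gdv_counts(igraph::vcount(net), adj, catalog@maskOrbit)
  dimnames(counts) <- list(igraph::V(net)$name, paste0("orbit_", 0:72))
  counts
}

#' Graphlet degree vector of one node
#'
#' @param net an undirected simple igraph with named vertices.
#' @param node a vertex name present in `net`.
#' @param catalog a [GraphletCatalog-class].
#' @return Named numeric vector of 73 orbit counts.
#' @export
countGDV <- function(net, node, catalog = buildOrbitCatalog()) {
  .checkNetwork(net)
  if (!node %in% igraph::V(net)$name)
    stop("unknown node: ", node)
  gdvMatrix(net, catalog)[node, ]
}

## ---- exhaustive oracle ---------------------------------------------------

## per-catalog classification aids, cached alongside the catalog
.oracleIndex <- function(catalog) {
  if (!is.null(.catalogEnv$oracleIndex)) return(.catalogEnv$oracleIndex)
  glets <- catalog@graphlets
  key <- vapply(seq_along(glets), function(g) {
    a <- glets[[g]]
    paste(nrow(a), sum(a) / 2L,
          paste(sort(rowSums(a), decreasing = TRUE), collapse = ""), sep = "/")
  }, character(1L))
  igs <- lapply(glets, function(a)
    igraph::graph_from_adjacency_matrix(a, mode = "undirected"))
  ## per graphlet: node signature (degree | sorted neighbour degrees) -> orbit,
  ## NA when the signature does not pin the orbit uniquely
  sig2orbit <- lapply(seq_along(glets), function(g) {
    a <- glets[[g]]
    deg <- rowSums(a)
    sig <- vapply(seq_len(nrow(a)), function(v)
      paste(c(deg[v], sort(deg[a[v, ] == 1L])), collapse = "."), character(1L))
    orb <- catalog@orbitOfNode[[g]]
    out <- tapply(orb, sig, function(x) if (length(unique(x)) == 1L) x[1L] else NA_integer_)
    out
  })
  idx <- list(key = key, igs = igs, sig2orbit = sig2orbit)
  .catalogEnv$oracleIndex <- idx
  idx
}

.classifySubset <- function(a, catalog, idx) {
  k <- nrow(a)
  key <- paste(k, sum(a) / 2L,
               paste(sort(rowSums(a), decreasing = TRUE), collapse = ""), sep = "/")
  cand <- which(idx$key == key)
  if (length(cand) == 0L) stop("no catalog match for subset")  # cannot happen
  sg <- NULL
  if (length(cand) > 1L) {
    sg <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    cand <- cand[vapply(cand, function(g) igraph::isomorphic(sg, idx$igs[[g]]),
                        logical(1L))]
  }
  g <- cand[1L]
  deg <- rowSums(a)
  sig <- vapply(seq_len(k), function(v)
    paste(c(deg[v], sort(deg[a[v, ] == 1L])), collapse = "."), character(1L))
  orbs <- idx$sig2orbit[[g]][sig]
  if (anyNA(orbs)) {
    ## degree profile is ambiguous within this graphlet: resolve through an
    ## explicit isomorphism onto the catalog representative
    if (is.null(sg)) sg <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    maps <- igraph::isomorphisms(sg, idx$igs[[g]])
    map <- as.integer(maps[[1L]])
    orbs <- catalog@orbitOfNode[[g]][map]
  }
  as.integer(orbs)
}

#' Exhaustive brute-force graphlet degree vectors (validation oracle)
#'
#' Enumerates every 2-5-node subset of the vertex set directly, keeps the
#' connected ones, and classifies each by isomorphism against the catalog
#' representatives.  Entirely independent of the optimized ESU path; intended
#' as its correctness oracle on small graphs.
#'
#' @param net an undirected simple igraph with named vertices, at most
#'   `maxNodes` of them.
#' @param catalog a [GraphletCatalog-class].
#' @param maxNodes guard against accidentally running the exhaustive path on
#'   a large network (use [gdvMatrix()] there).
#' @return Numeric node-by-orbit matrix like [gdvMatrix()].
#' @export
gdvMatrixOracle <- function(net, catalog = buildOrbitCatalog(), maxNodes = 30L) {
  .checkNetwork(net)
  n <- igraph::vcount(net)
  if (n > maxNodes)
    stop("exhaustive oracle limited to ", maxNodes,
         " nodes; use gdvMatrix() for larger networks")
  idx <- .oracleIndex(catalog)
  A <- as.matrix(igraph::as_adjacency_matrix(net, type = "both"))
  diag(A) <- 0L
  counts <- matrix(0, n, 73,
                   dimnames = list(igraph::V(net)$name, paste0("orbit_", 0:72)))
  for (k in 2:min(5L, n)) {
    sets <- utils::combn(n, k)
    for (ci in seq_len(ncol(sets))) {
      s <- sets[, ci]
      a <- A[s, s, drop = FALSE]
      if (!.isConnectedAdj(a)) next
      orbs <- .classifySubset(a, catalog, idx)
      for (p in seq_len(k)) counts[s[p], orbs[p] + 1L] <- counts[s[p], orbs[p] + 1L] + 1
    }
  }
  counts
}

#' @rdname gdvMatrixOracle
#' @param node a vertex name present in `net`.
#' @export
countGDVOracle <- function(net, node, catalog = buildOrbitCatalog(), maxNodes = 30L) {
  if (!node %in% igraph::V(net)$name) stop("unknown node: ", node)
  gdvMatrixOracle(net, catalog, maxNodes)[node, ]
}

#' Write a GDV table as TSV
#'
#' One row per node with an `id` column followed by the 73 orbit-count
#' columns `orbit_0` .. `orbit_72`; rows in lexicographic node order.
#'
#' @param gdv matrix from [gdvMatrix()].
#' @param path output file path.
#' @export
writeGDVTable <- function(gdv, path) {
  df <- data.frame(id = rownames(gdv), gdv, check.names = FALSE)
  df <- df[order(df$id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
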