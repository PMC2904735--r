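#' Signature similarity between two graphlet degree vectors
#'
#' The per-orbit distance between signatures u and v is
#' \deqn{D_i = w_i \frac{|\log(u_i + 1) - \log(v_i + 1)|}{\log(\max(u_i, v_i) + 2)}}
#' with \eqn{w_i = 1 - \log(o_i)/\log(73)} down-weighting orbits that are
#' redundant with many others.  The total distance is
#' \eqn{D = \sum_i D_i / \sum_i w_i} and the similarity \eqn{S = 1 - D}.
#' The log scale keeps a one-graphlet difference on a rare orbit from being
#' drowned out by huge counts on common orbits; the denominator bounds each
#' term by \eqn{w_i}, so \eqn{S \in [0, 1]}, with \eqn{S = 1} exactly for
#' identical vectors (two all-zero vectors are identical, hence similarity
#' 1; in practice clustering only ever compares nodes of degree > 3).
#'
#' @param u,v numeric vectors of 73 orbit counts.
#' @param catalog a [GraphletCatalog-class].
#' @param uniformWeights use \eqn{w_i = 1} for all orbits (sensitivity
#'   analysis of the weighting scheme).
#' @return Similarity in `[0, 1]`.
#' @examples
#' cat73 <- buildOrbitCatalog()
#' g <- igraph::make_full_graph(4)
#' igraph::V(g)$name <- letters[1:4]
#' gdv <- gdvMatrix(g)
#' signatureSimilarity(gdv["a", ], gdv["b", ], cat73)  # identical signatures: 1
#' @export
signatureSimilarity <- function(u, v, catalog = buildOrbitCatalog(),
                                uniformWeights = FALSE) {
  if (length(u) != 73L || length(v) != 73L)
    stop("signature vectors must have 73 coordinates")
  w <- orbitWeights(catalog, uniform = uniformWeights)
  di <- w * abs(log(u + 1) - log(v + 1)) / log(pmax(u, v) + 2)
  1 - sum(di) / sum(w)
}

#' Pairwise signature-similarity matrix
#'
#' Computes GDVs on the full network, then all pairwise similarities for the
#' requested node subset (typically the eligible, degree > 3 set).
#'
#' @param net an undirected simple igraph; GDVs always use the whole network.
#' @param nodes node names to compare (default: all); output order is
#'   lexicographic regardless of input order.
#' @param catalog a [GraphletCatalog-class].
#' @param gdv optional precomputed matrix from [gdvMatrix()] covering at
#'   least `nodes`, to avoid recounting.
#' @param uniformWeights see [signatureSimilarity()].
#' @return Symmetric numeric matrix with unit diagonal, dimnames = nodes.
#' @export
similarityMatrix <- function(net, nodes = NULL, catalog = buildOrbitCatalog(),
                             gdv = NULL, uniformWeights = FALSE) {
  if (is.null(gdv)) {
    .checkNetwork(net)
    gdv <- gdvMatrix(net, catalog)
  }
  if (is.null(nodes)) nodes <- rownames(gdv)
  missing <- setdiff(nodes, rownames(gdv))
  if (length(missing))
    stop("nodes not in GDV matrix: ", paste(missing, collapse = ", "))
  nodes <- sort(nodes)
  g <- gdv[nodes, , drop = FALSE]
  n <- nrow(g)
  w <- orbitWeights(catalog, uniform = uniformWeights)
  D <- matrix(0, n, n)
  for (i in seq_len(73L)) {
    if (w[i] == 0) next
    ci <- g[, i]
    L <- log(ci + 1)
    num <- abs(outer(L, L, "-"))
    mx <- pmax(matrix(ci, n, n), matrix(ci, n, n, byrow = TRUE))
    D <- D + w[i] * num / log(mx + 2)
  }
  S <- 1 - D / sum(w)
  dimnames(S) <- list(nodes, nodes)
  S
}

#' Write a similarity matrix as TSV
#'
#' Node identifiers as header row and first column.
#'
#' @param sims matrix from [similarityMatrix()].
#' @param path output file path.
#' @param digits significant digits written.
#' @export
writeSimilarityMatrix <- function(sims, path, digits = 10L) {
  df <- data.frame(id = rownames(sims),
                   signif(sims, digits), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
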