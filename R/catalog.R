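#' @include AllClasses.R
NULL

## ---- internal combinatorics helpers -------------------------------------

## all permutations of 1..k, in lexicographic order
.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(k - 1L)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    rest <- seq_len(k)[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), k - 1L))
  }
  do.call(rbind, out)
}

## index of unordered pair (i,j), i<j, in the fixed bit order
## (1,2),(1,3),(2,3),(1,4),(2,4),(3,4),(1,5),...  -- node j contributes the
## block of pairs with all smaller nodes, which lets an edge mask grow
## incrementally as nodes are appended
.pairIndex <- function(i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  (hi - 1L) * (hi - 2L) / 2L + lo
}

.maskToAdj <- function(mask, k) {
  a <- matrix(0L, k, k)
  b <- 1L
  for (j in seq_len(k)[-1L]) for (i in seq_len(j - 1L)) {
    if (bitwAnd(mask, bitwShiftL(1L, b - 1L)) != 0L) { a[i, j] <- 1L; a[j, i] <- 1L }
    b <- b + 1L
  }
  a
}

.isConnectedAdj <- function(a) {
  k <- nrow(a)
  seen <- logical(k); seen[1L] <- TRUE; front <- 1L
  while (length(front)) {
    nxt <- which(colSums(a[front, , drop = FALSE]) > 0L & !seen)
    seen[nxt] <- TRUE
    front <- nxt
  }
  all(seen)
}

## Canonicalize every mask on k nodes: canonical code = minimum edge mask over
## all relabelings; also record one permutation achieving it (old -> canonical
## labels) so node positions can be mapped onto the representative.
.canonicalizeMasks <- function(k) {
  m <- k * (k - 1L) / 2L
  nm <- bitwShiftL(1L, m)
  masks <- 0:(nm - 1L)
  bits <- matrix(0L, nm, m)
  for (b in seq_len(m)) bits[, b] <- bitwAnd(bitwShiftR(masks, b - 1L), 1L)
  perms <- .permutations(k)
  np <- nrow(perms)
  ## bitMap[p, b]: bit position that original pair b lands on under perm p
  pairI <- matrix(0L, k, k)
  for (j in seq_len(k)[-1L]) for (i in seq_len(j - 1L)) pairI[i, j] <- pairI[j, i] <- .pairIndex(i, j)
  bitMap <- matrix(0L, np, m)
  for (p in seq_len(np)) {
    pp <- perms[p, ]
    b <- 1L
    for (j in seq_len(k)[-1L]) for (i in seq_len(j - 1L)) {
      bitMap[p, b] <- pairI[pp[i], pp[j]]
      b <- b + 1L
    }
  }
  pow <- 2^(0:(m - 1L))
  canon <- masks
  argPerm <- rep(1L, nm)
  for (p in seq_len(np)) {
    img <- as.integer(bits %*% pow[bitMap[p, ]])
    better <- img < canon
    canon[better] <- img[better]
    argPerm[better] <- p
  }
  list(masks = masks, canon = canon, argPerm = argPerm, perms = perms, bitMap = bitMap)
}

## automorphism orbits of the representative mask, ordered by
## (degree, sorted neighbour-degree profile, smallest node index)
.orbitPartition <- function(adj) {
  k <- nrow(adj)
  perms <- .permutations(k)
  cls <- seq_len(k)
  for (p in seq_len(nrow(perms))) {
    pp <- perms[p, ]
    if (all(adj[pp, pp] == adj)) {
      for (v in seq_len(k)) {
        a <- min(cls[v], cls[pp[v]]); b <- max(cls[v], cls[pp[v]])
        if (a != b) cls[cls == b] <- a
      }
    }
  }
  reps <- sort(unique(cls))
  deg <- rowSums(adj)
  key <- vapply(reps, function(r) {
    v <- which(cls == r)[1L]
    nb <- sort(deg[adj[v, ] == 1L])
    paste(sprintf("%02d", c(deg[v], nb)), collapse = ".")
  }, character(1L))
  ord <- order(key, reps)
  ranked <- integer(k)
  for (i in seq_along(ord)) ranked[cls == reps[ord[i]]] <- i
  ranked
}

## ---- catalog construction ------------------------------------------------

.catalogEnv <- new.env(parent = emptyenv())

#' Build the 2-5-node graphlet and automorphism-orbit catalog
#'
#' Enumerates, by exhaustive generation and isomorphism rejection, the 30
#' connected non-isomorphic graphs ("graphlets") on 2 to 5 nodes and
#' partitions the nodes of each into its 73 automorphism orbits.  Orbit 0 is
#' the edge; the 3-node path contributes orbits 1 (end) and 2 (middle); the
#' triangle is orbit 3; the 5-clique carries orbit 72.  The catalog also
#' carries, per orbit, the dependency count \eqn{o_i} (how many orbits affect
#' orbit i under anchored subgraph containment, itself included) and the
#' similarity weight \eqn{w_i = 1 - \log(o_i)/\log(73)}.
#'
#' Graphlets are ordered by node count, then edge count, then degree
#' sequence; orbits within a graphlet by node degree and neighbour-degree
#' profile.  This reproduces the standard published numbering on all 2-4-node
#' graphlets (orbits 0-14) and on the 5-path and 5-clique endpoints.
#'
#' The catalog is deterministic, built once per session and cached.
#'
#' @param force logical; rebuild even if a cached catalog exists.
#' @return A [GraphletCatalog-class] object.
#' @examples
#' cat73 <- buildOrbitCatalog()
#' nGraphlets(cat73)  # 30
#' nOrbits(cat73)     # 73
#' @export
buildOrbitCatalog <- function(force = FALSE) {
  if (!force && !is.null(.catalogEnv$catalog)) return(.catalogEnv$catalog)

  graphlets <- list()     # adjacency matrices
  orbitRows <- list()     # per-orbit metadata
  maskGraphlet <- list()  # per k: mask -> graphlet id (0-based) or -1
  maskOrbit <- list()     # per k: (mask, position) -> global orbit id or -1
  orbitOfNode <- list()   # per graphlet: node -> global orbit id
  nextGraphlet <- 0L
  nextOrbit <- 0L

  for (k in 2:5) {
    cz <- .canonicalizeMasks(k)
    connected <- vapply(cz$masks, function(ms) {
      ms > 0L && .isConnectedAdj(.maskToAdj(ms, k))
    }, logical(1L))
    repsMask <- sort(unique(cz$canon[connected]))
    ## order graphlets deterministically: edge count, then degree sequence
    ## (descending within each graph, ascending lexicographic across graphs),
    ## then canonical code
    info <- lapply(repsMask, function(ms) {
      a <- .maskToAdj(ms, k)
      d <- sort(rowSums(a), decreasing = TRUE)
      list(mask = ms, adj = a, edges = sum(a) / 2L, degseq = d)
    })
    ord <- order(vapply(info, `[[`, numeric(1L), "edges"),
                 vapply(info, function(x) paste(sprintf("%02d", x$degseq), collapse = "."),
                        character(1L)),
                 repsMask)
    info <- info[ord]
    repsMask <- repsMask[ord]

    gIdOfCanon <- integer(max(cz$canon) + 1L)  # canonical mask -> graphlet id + 1
    orbitBase <- integer(length(info))
    for (gi in seq_along(info)) {
      a <- info[[gi]]$adj
      part <- .orbitPartition(a)
      nOrb <- max(part)
      glob <- nextOrbit + part - 1L            # 0-based global orbit ids
      graphlets[[nextGraphlet + 1L]] <- a
      orbitOfNode[[nextGraphlet + 1L]] <- glob
      deg <- rowSums(a)
      for (oo in seq_len(nOrb)) {
        v <- which(part == oo)[1L]
        orbitRows[[nextOrbit + oo]] <- data.frame(
          orbit = nextOrbit + oo - 1L, graphlet = nextGraphlet,
          nodes = k, edges = info[[gi]]$edges, degree = deg[v],
          multiplicity = sum(part == oo))
      }
      gIdOfCanon[info[[gi]]$mask + 1L] <- nextGraphlet + 1L
      orbitBase[gi] <- nextOrbit
      nextGraphlet <- nextGraphlet + 1L
      nextOrbit <- nextOrbit + nOrb
    }

    ## lookup tables over all masks
    m <- k * (k - 1L) / 2L
    lookG <- rep(-1L, bitwShiftL(1L, m))
    lookO <- matrix(-1L, bitwShiftL(1L, m), k)
    for (ms in cz$masks[connected]) {
      cm <- cz$canon[ms + 1L]
      gid <- gIdOfCanon[cm + 1L]
      lookG[ms + 1L] <- gid - 1L
      sigma <- cz$perms[cz$argPerm[ms + 1L], ]   # node v -> canonical label
      lookO[ms + 1L, ] <- orbitOfNode[[gid]][sigma]
    }
    maskGraphlet[[k - 1L]] <- lookG
    maskOrbit[[k - 1L]] <- lookO
  }

  orbits <- do.call(rbind, orbitRows)
  rownames(orbits) <- NULL
  dep <- .computeOrbitDependencies(graphlets, orbitOfNode, orbits)
  if (!identical(dep, .ORBIT_DEPENDENCY_COUNTS))
    stop("orbit dependency recomputation disagrees with the shipped constant table; ",
         "the catalog numbering has drifted")
  orbits$o <- dep
  orbits$weight <- 1 - log(dep) / log(73)

  cat73 <- new("GraphletCatalog",
               graphlets = graphlets,
               orbits = orbits,
               orbitOfNode = orbitOfNode,
               maskOrbit = maskOrbit,
               depCounts = dep,
               weights = orbits$weight)
  .catalogEnv$catalog <- cat73
  cat73
}

## o_i under anchored containment: orbit j affects orbit i iff graphlet G_j,
## anchored at an orbit-j node, maps injectively into G_i with all its edges
## preserved (not necessarily induced) and the anchor on an orbit-i node.
.computeOrbitDependencies <- function(graphlets, orbitOfNode, orbits) {
  nOrb <- nrow(orbits)
  anchor <- integer(nOrb)   # representative node of each orbit (1-based)
  for (o in seq_len(nOrb)) {
    g <- orbits$graphlet[o] + 1L
    anchor[o] <- which(orbitOfNode[[g]] == o - 1L)[1L]
  }
  edgeList <- lapply(graphlets, function(a) which(upper.tri(a) & a == 1L, arr.ind = TRUE))
  dep <- integer(nOrb)
  for (i in seq_len(nOrb)) {
    gi <- orbits$graphlet[i] + 1L
    ai <- graphlets[[gi]]
    ti <- nrow(ai)
    target <- anchor[i]
    cnt <- 0L
    for (j in seq_len(nOrb)) {
      gj <- orbits$graphlet[j] + 1L
      aj <- graphlets[[gj]]
      s <- nrow(aj)
      if (s > ti) next
      ej <- edgeList[[gj]]
      rest <- seq_len(ti)[-target]
      srcRest <- seq_len(s)[-anchor[j]]
      found <- FALSE
      if (s == 1L) {
        found <- TRUE
      } else {
        idx <- utils::combn(rest, s - 1L, simplify = FALSE)
        for (cset in idx) {
          pm <- .permutations(s - 1L)
          for (p in seq_len(nrow(pm))) {
            f <- integer(s)
            f[anchor[j]] <- target
            f[srcRest] <- cset[pm[p, ]]
            ok <- TRUE
            for (e in seq_len(nrow(ej))) {
              if (ai[f[ej[e, 1L]], f[ej[e, 2L]]] != 1L) { ok <- FALSE; break }
            }
            if (ok) { found <- TRUE; break }
          }
          if (found) break
        }
      }
      if (found) cnt <- cnt + 1L
    }
    dep[i] <- cnt
  }
  dep
}

#' Per-orbit dependency counts
#'
#' Returns the vector \eqn{o_i} (i = 0..72): the number of orbits that affect
#' orbit i, itself included, under anchored subgraph containment.  The edge
#' orbit depends only on itself (\eqn{o_0 = 1}), so its similarity weight is
#' exactly 1; the 5-clique orbit is affected by all 73 orbits.
#'
#' @param catalog a [GraphletCatalog-class].
#' @param recompute logical; if `TRUE`, recompute from the containment
#'   definition instead of returning the catalog's frozen table (used to
#'   guard against numbering drift).
#' @return Integer vector of length 73.
#' @export
orbitDependencyCounts <- function(catalog = buildOrbitCatalog(), recompute = FALSE) {
  if (recompute)
    return(.computeOrbitDependencies(catalog@graphlets, catalog@orbitOfNode, catalog@orbits))
  catalog@depCounts
}

#' Per-orbit similarity weights
#'
#' @param catalog a [GraphletCatalog-class].
#' @param uniform logical; if `TRUE` return all-ones weights (an escape hatch
#'   for sensitivity analysis of the weighting scheme).
#' @return Numeric vector of length 73, \eqn{w_i = 1 - \log(o_i)/\log(73)}.
#' @export
orbitWeights <- function(catalog = buildOrbitCatalog(), uniform = FALSE) {
  if (uniform) rep(1, nOrbits(catalog)) else catalog@weights
}

#' Write the orbit catalog as a TSV table
#'
#' One row per orbit with its graphlet index, graphlet size, edge count,
#' orbit degree, orbit multiplicity, dependency count and weight.  Used both
#' as a human-readable reference and as the golden fixture that pins the
#' canonical numbering.
#'
#' @param catalog a [GraphletCatalog-class].
#' @param path output file path.
#' @export
writeOrbitCatalog <- function(catalog, path) {
  df <- catalog@orbits
  df$weight <- sprintf("%.10f", df$weight)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
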