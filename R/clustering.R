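#' Form the signature cluster around one seed
#'
#' Scans a descending threshold grid (default 0.96, 0.95, ..., 0.90).  At the
#' first -- i.e. highest -- threshold where at least one other eligible node
#' is signature-similar to the seed (similarity >= threshold, ties included),
#' the cluster is the seed plus all such nodes and the search stops.  If
#' nothing is within reach at the 0.90 floor, no cluster is formed.  A
#' cluster whose only content is the seed plus one other node is flagged
#' `"singleton"`; only clusters of size >= 3 (`"formed"`) are analyzed for
#' enrichment.
#'
#' @param seed node name; must be a row of `sims` (i.e. eligible).
#' @param sims similarity matrix over the eligible candidate pool, from
#'   [similarityMatrix()].
#' @param start,floor,step threshold grid (defaults 0.96 down to 0.90 by
#'   0.01).
#' @return list with `seed`, `status` (`"formed"`, `"singleton"`,
#'   `"unformed"`), `threshold` (NA when unformed), `members` (seed included;
#'   seed alone when unformed).
#' @export
formCluster <- function(seed, sims, start = 0.96, floor = 0.90, step = 0.01) {
  if (!seed %in% rownames(sims))
    stop("seed ", seed, " is not in the eligible candidate pool")
  if (start < floor) stop("start must be >= floor")
  grid <- .thresholdGrid(start, floor, step)
  row <- sims[seed, ]
  row <- row[names(row) != seed]
  for (thr in grid) {
    hit <- names(row)[row >= thr]
    if (length(hit) >= 1L) {
      members <- c(seed, sort(hit))
      status <- if (length(members) >= 3L) "formed" else "singleton"
      return(list(seed = seed, status = status, threshold = thr,
                  members = members))
    }
  }
  list(seed = seed, status = "unformed", threshold = NA_real_, members = seed)
}

.thresholdGrid <- function(start, floor, step) {
  ## round to the step's precision so 0.96 - 6*0.01 lands exactly on 0.90
  g <- seq(start, floor - step / 2, by = -step)
  round(g, max(0L, ceiling(-log10(step)) + 2L))
}

#' Form clusters for every seed
#'
#' Runs [formCluster()] over a set of seeds (typically all eligible
#' screen-positive regulators) and collects the results.
#'
#' @param seeds character vector of seed node names.
#' @param sims similarity matrix over the eligible pool.
#' @param start,floor,step threshold grid, as in [formCluster()].
#' @param quiet suppress the summary message.
#' @return A [SignatureClusterSet-class].
#' @export
formAllClusters <- function(seeds, sims, start = 0.96, floor = 0.90,
                            step = 0.01, quiet = FALSE) {
  seeds <- sort(unique(seeds))
  res <- lapply(seeds, formCluster, sims = sims, start = start,
                floor = floor, step = step)
  tab <- data.frame(
    seed = seeds,
    status = vapply(res, `[[`, character(1L), "status"),
    threshold = vapply(res, `[[`, numeric(1L), "threshold"),
    size = vapply(res, function(x) length(x$members), integer(1L)),
    stringsAsFactors = FALSE)
  members <- lapply(res, `[[`, "members")
  names(members) <- seeds
  if (!quiet)
    message("formAllClusters: ", sum(tab$status == "formed"), " formed, ",
            sum(tab$status == "singleton"), " singleton, ",
            sum(tab$status == "unformed"), " unformed of ",
            length(seeds), " seeds")
  new("SignatureClusterSet", table = tab, members = members,
      grid = .thresholdGrid(start, floor, step))
}

#' Write a cluster table as TSV
#'
#' Columns `seed`, `threshold`, `size`, `status`, `members`
#' (semicolon-joined, seed first).
#'
#' @param clusters a [SignatureClusterSet-class].
#' @param path output file path.
#' @export
writeClusterTable <- function(clusters, path) {
  tab <- clusterTable(clusters)
  tab$members <- vapply(tab$seed, function(s)
    paste(clusterMembers(clusters, s)[[1L]], collapse = ";"), character(1L))
  tab <- tab[, c("seed", "threshold", "size", "status", "members")]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
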