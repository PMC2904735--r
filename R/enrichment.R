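#' Hit-rate of a cluster
#'
#' The percentage of cluster members that are screen-positive, excluding the
#' seed from both numerator and denominator: `100 * k / C` with `C` the
#' cluster size minus the seed and `k` the screen-positive members minus the
#' seed.
#'
#' @param members character vector of cluster members, seed included.
#' @param seed the seed node name.
#' @param sprs character vector of screen-positive identifiers.
#' @return Percent in `[0, 100]`.
#' @examples
#' # a 13-protein cluster whose 12 non-seed members contain 5 screen hits
#' hitRate(c("seed", paste0("m", 1:12)), "seed", paste0("m", 1:5))  # 41.67
#' @export
hitRate <- function(members, seed, sprs) {
  others <- setdiff(members, seed)
  if (length(others) == 0L) stop("cluster has no non-seed members")
  100 * sum(others %in% sprs) / length(others)
}

#' Hypergeometric upper-tail enrichment p-value
#'
#' Probability of drawing `k` or more screen-positives when `C` nodes are
#' drawn uniformly without replacement from a universe of `N` nodes of which
#' `S` are screen-positive:
#' \deqn{p = \sum_{j=k}^{\min(C,S)} \frac{\binom{S}{j}\binom{N-S}{C-j}}{\binom{N}{C}}}
#' Computed in log space via the hypergeometric distribution, so it is exact
#' for universes far larger than the ~5,000-protein eligible sets it is used
#' on.  `k = 0` gives p = 1.
#'
#' @param N universe size (eligible nodes, seed excluded).
#' @param S screen-positives in the universe (seed excluded).
#' @param C cluster size, seed excluded.
#' @param k screen-positive cluster members, seed excluded.
#' @return p-value in `(0, 1]`.
#' @export
hypergeomPValue <- function(N, S, C, k) {
  if (any(k < 0 | C < k | N < C | S > N | S < 0))
    stop("inconsistent counts: need 0 <= k <= C <= N and 0 <= S <= N")
  stats::phyper(k - 1, m = S, n = N - S, k = C, lower.tail = FALSE)
}

#' Score every formed cluster for screen-hit enrichment
#'
#' For each formed cluster (size >= 3) computes the hit-rate and the
#' hypergeometric enrichment p-value against the eligible universe, with the
#' seed excluded everywhere: the universe is `N = |eligible| - 1` and carries
#' `S = |eligible screen-positives| - 1`, matching the convention that the
#' protein the cluster was formed for never counts towards its own
#' enrichment.  Significance is `p < alpha` with no multiple-testing
#' correction by default (the cluster tests are heavily overlapping, and the
#' downstream randomization null judges the family as a whole); a
#' Benjamini-Hochberg option is available.
#'
#' @param clusters a [SignatureClusterSet-class].
#' @param labels data.frame from [labelSPRs()].
#' @param eligible character vector of eligible node names (the candidate
#'   universe the clusters were drawn from).
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame `seed`, `size` (C), `k`, `hit_rate`, `p_value`,
#'   `significant`, one row per formed cluster, ordered by seed.
#' @export
scoreAllClusters <- function(clusters, labels, eligible, alpha = 0.05,
                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  sprs <- labels$id[labels$is_spr]
  elig <- sort(unique(eligible))
  eligSprs <- intersect(elig, sprs)
  tab <- clusterTable(clusters)
  tab <- tab[tab$status == "formed", , drop = FALSE]
  out <- lapply(tab$seed, function(s) {
    members <- clusterMembers(clusters, s)[[1L]]
    others <- setdiff(members, s)
    k <- sum(others %in% sprs)
    C <- length(others)
    N <- length(elig) - 1L
    S <- length(eligSprs) - 1L * (s %in% eligSprs)
    ## seed excluded from the universe; when the seed is not an eligible SPR
    ## (possible only with hand-built label sets) S is left as is
    data.frame(seed = s, size = C, k = k,
               hit_rate = 100 * k / C,
               p_value = hypergeomPValue(N, S, C, k),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(seed = character(), size = integer(), k = integer(),
                      hit_rate = numeric(), p_value = numeric())
  if (adjust == "BH") res$p_value <- stats::p.adjust(res$p_value, "BH")
  ## significance is p < alpha; alpha >= 1 degenerates to "every cluster",
  ## including p = 1, so it is treated as a closed bound
  res$significant <- if (alpha >= 1) rep(TRUE, nrow(res)) else res$p_value < alpha
  res[order(res$seed), , drop = FALSE]
}

#' Randomization null for the number of significant clusters
#'
#' For each observed cluster, draws a uniform random node set of the same
#' size from the eligible universe excluding that cluster's seed, scores it
#' with the same hypergeometric test and significance rule, and counts the
#' significant random clusters per run.  Repeating this `runs` times yields
#' the null distribution of the significant-cluster count, from which the
#' observed count is assessed three ways: the empirical (frequency)
#' probability of seeing at least the observed count, the Z-score
#' `(x - mu)/sigma` against the null mean and standard deviation, and the
#' upper-tail normal p-value of that Z-score (the null counts are close to
#' bell-shaped).
#'
#' @param enrichment data.frame from [scoreAllClusters()] (real-data scores;
#'   its `seed` and `size` columns define the randomization layout and its
#'   `significant` count is the observation).
#' @param labels data.frame from [labelSPRs()].
#' @param eligible character vector, the eligible universe.
#' @param runs randomization runs (default 1000).
#' @param alpha significance level applied to each random cluster.
#' @param rngSeed integer master seed; all randomness derives from it.
#' @return A [NullModelSummary-class].
#' @export
randomClusterNull <- function(enrichment, labels, eligible, runs = 1000L,
                              alpha = 0.05, rngSeed = 1L) {
  elig <- sort(unique(eligible))
  sprs <- labels$id[labels$is_spr]
  eligSprFlag <- elig %in% sprs
  nClust <- nrow(enrichment)
  if (nClust == 0L) stop("no formed clusters to randomize")
  if (any(enrichment$size > length(elig) - 1L))
    stop("cluster size exceeds the eligible universe")
  observed <- sum(enrichment$significant)
  seedIdx <- match(enrichment$seed, elig)
  Nper <- length(elig) - 1L
  Sper <- sum(eligSprFlag) - ifelse(!is.na(seedIdx) & eligSprFlag[pmax(seedIdx, 1L)], 1L, 0L)
  withr::with_seed(rngSeed, {
    nullCounts <- integer(runs)
    nElig <- length(elig)
    for (r in seq_len(runs)) {
      ks <- integer(nClust)
      for (ci in seq_len(nClust)) {
        pool <- if (!is.na(seedIdx[ci])) seq_len(nElig)[-seedIdx[ci]] else seq_len(nElig)
        draw <- pool[sample.int(length(pool), enrichment$size[ci])]
        ks[ci] <- sum(eligSprFlag[draw])
      }
      p <- hypergeomPValue(Nper, Sper, enrichment$size, ks)
      nullCounts[r] <- sum(p < alpha)
    }
  })
  mu <- mean(nullCounts)
  sigma <- stats::sd(nullCounts)
  z <- if (sigma > 0) (observed - mu) / sigma else NA_real_
  new("NullModelSummary",
      observed = as.integer(observed), runs = as.integer(runs),
      nullCounts = nullCounts, mu = mu, sigma = sigma,
      empiricalP = mean(nullCounts >= observed),
      z = z,
      normalP = if (is.na(z)) NA_real_ else normalTailPValue(z))
}

#' Standardize a count against a null mean and standard deviation
#'
#' `(x - mu) / sigma`; summaries report it to two decimals.
#'
#' @param x observed value.
#' @param mu,sigma null mean and standard deviation (`sigma > 0`).
#' @return Z-score.
#' @examples
#' zscoreStandardize(26, 15.45, 4.03)  # 2.62
#' @export
zscoreStandardize <- function(x, mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  (x - mu) / sigma
}

#' Upper-tail standard normal p-value
#'
#' `P(Z >= z)` for a standard normal Z.
#'
#' @param z Z-score.
#' @return Upper-tail probability.
#' @examples
#' normalTailPValue(2.62)  # 0.0044
#' @export
normalTailPValue <- function(z) {
  stats::pnorm(z, lower.tail = FALSE)
}

#' Write an enrichment table as TSV
#'
#' Columns `seed`, `size`, `k`, `hit_rate`, `p_value`, `significant`.
#'
#' @param enrichment data.frame from [scoreAllClusters()].
#' @param path output file path.
#' @export
writeEnrichmentTable <- function(enrichment, path) {
  utils::write.table(enrichment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a null-model summary as TSV
#'
#' The per-run significant-cluster counts plus a one-line summary
#' (`observed mu sigma empirical_p z normal_p`) as a trailing comment.
#'
#' @param null a [NullModelSummary-class].
#' @param path output file path.
#' @export
writeNullSummary <- function(null, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("run\tsignificant_clusters", con)
  writeLines(paste(seq_len(null@runs), null@nullCounts, sep = "\t"), con)
  writeLines(sprintf("# observed=%d mu=%.4f sigma=%.4f empirical_p=%.6f z=%.2f normal_p=%.6g",
                     null@observed, null@mu, null@sigma, null@empiricalP,
                     null@z, null@normalP), con)
  invisible(path)
}
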