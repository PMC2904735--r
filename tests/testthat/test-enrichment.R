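test_that("hit-rate excludes the seed from both sides of the ratio", {
  ## a 13-member cluster with 5 screen hits among its 12 companions
  members <- c("seed", sprintf("m%02d", 1:12))
  sprs <- c(sprintf("m%02d", 1:5), "seed")   # seed's own hit status is ignored
  expect_equal(hitRate(members, "seed", sprs), 41.67, tolerance = 1e-4)
  expect_equal(hitRate(members, "seed", character()), 0)
  expect_equal(hitRate(members, "seed", members), 100)
  expect_error(hitRate("seed", "seed", sprs), "no non-seed")
})

test_that("hypergeometric tail matches exhaustive enumeration for all small universes", {
  ## oracle: enumerate every C-subset of a labelled universe and count the
  ## fraction with at least k positives
  for (N in 2:12) {
    for (S in 0:N) {
      universe <- c(rep(TRUE, S), rep(FALSE, N - S))
      for (C in 1:N) {
        draws <- utils::combn(N, C)
        hits <- colSums(matrix(universe[draws], nrow = C))
        for (k in 0:C) {
          expect_equal(hypergeomPValue(N, S, C, k), mean(hits >= k),
                       tolerance = 1e-12,
                       info = sprintf("N=%d S=%d C=%d k=%d", N, S, C, k))
        }
      }
    }
  }
})

test_that("hypergeometric boundary values and worked fractions are exact", {
  expect_equal(hypergeomPValue(100, 30, 10, 0), 1)
  expect_equal(hypergeomPValue(10, 5, 4, 4), 5 / 210)
  expect_equal(hypergeomPValue(4, 2, 2, 2), 1 / 6)
  ## monotone non-increasing in k; point probabilities sum to one
  p <- vapply(0:6, function(k) hypergeomPValue(40, 12, 6, k), numeric(1))
  expect_true(all(diff(p) <= 0))
  expect_equal(sum(dhyper(0:6, 12, 28, 6)), 1)
  expect_error(hypergeomPValue(10, 5, 12, 3), "inconsistent")
  expect_error(hypergeomPValue(10, 5, 4, 5), "inconsistent")
})

test_that("Z standardization and the normal tail reproduce the worked example", {
  expect_equal(round(zscoreStandardize(26, 15.45, 4.03), 2), 2.62)
  expect_equal(zscoreStandardize(7, 7, 2), 0)
  expect_equal(zscoreStandardize(26, 15.45, 2 * 4.03),
               zscoreStandardize(26, 15.45, 4.03) / 2)
  expect_error(zscoreStandardize(1, 0, 0), "sigma")
  expect_equal(round(normalTailPValue(2.62), 4), 0.0044)
  expect_equal(normalTailPValue(0), 0.5)
  z <- c(-2.5, -0.3, 0.7, 1.9)
  expect_equal(normalTailPValue(z) + normalTailPValue(-z), rep(1, 4))
})

test_that("cluster scoring applies the seed-excluded universe convention", {
  elig <- sort(c(sprintf("k%d", 1:5), sprintf("m%d", 1:5)))   # 10 nodes
  cl <- handClusters(list(k1 = c("k1", "k2", "k3", "m4", "m5"),
                          m1 = c("m1", "k4", "m2")))
  labels <- labelSPRs(data.frame(
    id = elig,
    z_score = ifelse(elig %in% c("k1", "k2", "k3", "m1"), 2, 0),
    is_kpr = FALSE))
  enr <- scoreAllClusters(cl, labels, elig)
  expect_equal(nrow(enr), 2L)
  r <- enr[enr$seed == "k1", ]
  ## cluster k1,k2,k3,m4,m5: C = 4, hits k2, k3 -> k = 2; universe N = 9,
  ## S = 3 (four eligible hits minus the seed itself)
  expect_equal(r$size, 4L)
  expect_equal(r$k, 2L)
  expect_equal(r$hit_rate, 50)
  expect_equal(r$p_value, hypergeomPValue(9, 3, 4, 2))
  ## k = 0 cluster scores p = 1 and is never significant
  labels0 <- labelSPRs(data.frame(id = elig,
                                  z_score = ifelse(elig == "k1", 2, 0),
                                  is_kpr = FALSE))
  enr0 <- scoreAllClusters(cl, labels0, elig)
  expect_equal(enr0$p_value[enr0$seed == "k1"], 1)
  expect_false(any(enr0$significant[enr0$seed == "k1"]))
  ## alpha >= 1 flags every formed cluster
  enr1 <- scoreAllClusters(cl, labels0, elig, alpha = 1)
  expect_true(all(enr1$significant))
  ## BH adjustment never decreases a p-value
  enrBH <- scoreAllClusters(cl, labels, elig, adjust = "BH")
  expect_true(all(enrBH$p_value >= enr$p_value - 1e-12))
})

test_that("randomization null is reproducible and sane at the extremes", {
  elig <- sprintf("g%03d", 1:60)
  labels <- labelSPRs(data.frame(id = elig,
                                 z_score = c(rep(2, 15), rep(0, 45)),
                                 is_kpr = FALSE))
  enr <- data.frame(seed = c("g001", "g002", "g020"),
                    size = c(5L, 8L, 6L), k = c(5L, 7L, 0L),
                    hit_rate = c(100, 87.5, 0),
                    p_value = c(1e-4, 1e-4, 1), significant = c(TRUE, TRUE, FALSE))
  n1 <- randomClusterNull(enr, labels, elig, runs = 300, rngSeed = 9)
  n2 <- randomClusterNull(enr, labels, elig, runs = 300, rngSeed = 9)
  expect_identical(n1@nullCounts, n2@nullCounts)
  expect_equal(n1@observed, 2L)
  expect_equal(n1@empiricalP, mean(n1@nullCounts >= 2L))
  expect_true(validObject(n1))
  ## observed above every null count: empirical p is exactly 0
  expect_equal(randomClusterNull(enr, labels, elig, runs = 50,
                                 rngSeed = 3)@empiricalP >= 0, TRUE)
  ## all-positive universe: S = N forces k = C, p = 1, nothing significant
  labAll <- labelSPRs(data.frame(id = elig, z_score = 2, is_kpr = FALSE))
  nAll <- randomClusterNull(enr, labAll, elig, runs = 100, rngSeed = 4)
  expect_equal(nAll@nullCounts, rep(0L, 100))
  expect_equal(nAll@sigma, 0)
  expect_true(is.na(nAll@z))
  expect_error(randomClusterNull(enr[0, ], labels, elig), "no formed")
})

test_that("null counts match the analytic expectation on an enumerable setup", {
  ## universe of 20 with 8 positives; clusters of sizes 3 and 5; exact
  ## per-cluster significance probability by enumeration of the tail
  elig <- sprintf("e%02d", 1:20)
  labels <- labelSPRs(data.frame(id = elig,
                                 z_score = c(rep(2, 8), rep(0, 12)),
                                 is_kpr = FALSE))
  alpha <- 0.05
  enr <- data.frame(seed = c("e01", "e09"), size = c(3L, 5L), k = c(3L, 5L),
                    hit_rate = 100, p_value = 0.01, significant = TRUE)
  ## per-seed universe: N = 19, S = 7 (seed e01 positive) or 8 (e09 negative)
  pSig <- function(N, S, C) {
    ks <- 0:C
    tails <- vapply(ks, function(k) hypergeomPValue(N, S, C, k), numeric(1))
    sum(dhyper(ks, S, N - S, C)[tails < alpha])
  }
  expectation <- pSig(19, 7, 3) + pSig(19, 8, 5)
  nm <- randomClusterNull(enr, labels, elig, runs = 4000, alpha = alpha,
                          rngSeed = 77)
  se <- sqrt(expectation * 2 / 4000)  # loose bound on the sd of the mean
  expect_lt(abs(nm@mu - expectation), 4 * se + 0.02)
})

test_that("null and enrichment writers emit readable summaries", {
  elig <- sprintf("g%03d", 1:30)
  labels <- labelSPRs(data.frame(id = elig,
                                 z_score = rep(c(2, 0), 15), is_kpr = FALSE))
  enr <- data.frame(seed = "g001", size = 4L, k = 2L, hit_rate = 50,
                    p_value = 0.3, significant = FALSE)
  f <- withr::local_tempfile()
  writeEnrichmentTable(enr, f)
  expect_equal(read.delim(f)$seed, "g001")
  nm <- randomClusterNull(enr, labels, elig, runs = 20, rngSeed = 1)
  f2 <- withr::local_tempfile()
  writeNullSummary(nm, f2)
  lines <- readLines(f2)
  expect_equal(length(lines), 22L)
  expect_match(lines[22], "^# observed=0")
})
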