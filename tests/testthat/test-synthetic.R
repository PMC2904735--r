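test_that("generated networks are simple, exactly sized and seed-deterministic", {
  cfg <- syntheticStudyConfig(nNodes = 300, nPathways = 2, seed = 5)
  g1 <- generateNetwork(cfg)
  g2 <- generateNetwork(cfg)
  expect_equal(igraph::vcount(g1$network), 300L)
  expect_false(igraph::any_loop(g1$network) || igraph::any_multiple(g1$network))
  expect_false(igraph::is_directed(g1$network))
  elKey <- function(x) {
    el <- igraph::as_edgelist(x)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_identical(elKey(g1$network), elKey(g2$network))
  g3 <- generateNetwork(syntheticStudyConfig(nNodes = 300, nPathways = 2,
                                             seed = 6))
  expect_false(identical(elKey(g1$network), elKey(g3$network)))
  ## no pathways: a plain background of exactly nNodes
  g0 <- generateNetwork(syntheticStudyConfig(nNodes = 150, nPathways = 0))
  expect_equal(igraph::vcount(g0$network), 150L)
  expect_equal(g0$pathways, list())
  expect_error(syntheticStudyConfig(pathwaySize = 4), ">= 6")
  expect_error(syntheticStudyConfig(nNodes = 50), "10 \\* pathwaySize")
})

test_that("planted modules keep pathway-like diameters above the neighbourhood ceiling", {
  for (s in c(5, 11, 23)) {
    st <- generateStudy(syntheticStudyConfig(nNodes = 400, nPathways = 3,
                                             seed = s))
    for (p in plantedPathways(st)) {
      d <- subgraphDiameter(studyNetwork(st), p)
      expect_equal(d$lccFraction, 1)
      expect_gt(d$diameter, 2L)   # beyond any direct-neighbourhood cluster
      expect_lte(d$diameter, 4L)  # the ring-with-chords regime
    }
  }
  ## deterministic modules when the decoration tails are switched off
  st0 <- generateStudy(syntheticStudyConfig(nNodes = 400, decorationProb = 0,
                                            seed = 1))
  expect_equal(subgraphDiameter(studyNetwork(st0),
                                plantedPathways(st0)$pathway_1)$diameter, 3L)
  ## members are well connected enough to pass the degree filter
  el <- eligibleNodes(studyNetwork(st0))
  expect_true(all(unlist(plantedPathways(st0)) %in% el))
})

test_that("background Z-scores produce the standard-normal hit rate", {
  cfg <- syntheticStudyConfig(nNodes = 2000, nPathways = 0, seed = 31)
  st <- generateStudy(cfg)
  lab <- labelSPRs(studyAnnotations(st))
  pHit <- 2 * (1 - pnorm(1))           # 0.3173
  se <- sqrt(pHit * (1 - pHit) / 2000)
  expect_lt(abs(mean(lab$is_spr) - pHit), 4 * se)
  expect_equal(sum(lab$is_kpr), 0L)    # no pathways, no known regulators
})

test_that("planted effects shift members across the labelling threshold", {
  hit <- 0; tot <- 0
  for (s in 1:3) {
    cfg <- syntheticStudyConfig(nNodes = 700, nPathways = 5, effectMu = -3,
                                seed = 50 + s)
    st <- generateStudy(cfg)
    lab <- labelSPRs(studyAnnotations(st))
    planted <- unlist(plantedPathways(st))
    hit <- hit + sum(planted %in% lab$id[lab$is_spr])
    tot <- tot + length(planted)
  }
  expect_gt(hit / tot, 0.95)           # P(Z < -1 | mean -3) = pnorm(2) = 0.977
  ## kprFraction controls the known-regulator complement
  st0 <- generateStudy(syntheticStudyConfig(nNodes = 400, kprFraction = 0,
                                            seed = 2))
  expect_equal(sum(studyAnnotations(st0)$is_kpr), 0L)
  st3 <- generateStudy(syntheticStudyConfig(nNodes = 400, kprFraction = 0.25,
                                            seed = 2))
  ann <- studyAnnotations(st3)
  expect_equal(sum(ann$is_kpr), 3L * 3L)   # round(0.25 * 12) per pathway
  expect_true(all(ann$id[ann$is_kpr] %in% unlist(plantedPathways(st3))))
})

test_that("study objects validate and serialize to the pipeline formats", {
  st <- generateStudy(syntheticStudyConfig(nNodes = 200, nPathways = 1,
                                           seed = 7))
  expect_true(validObject(st))
  expect_setequal(studyAnnotations(st)$id, igraph::V(studyNetwork(st))$name)
  d <- withr::local_tempdir()
  paths <- writeStudy(st, d)
  net <- readEdgeList(paths["network"], quiet = TRUE)
  expect_setequal(igraph::V(net)$name, igraph::V(studyNetwork(st))$name)
  expect_equal(igraph::ecount(net), igraph::ecount(studyNetwork(st)))
  ann <- readAnnotations(paths["annotations"])
  expect_equal(nrow(ann), 200L)
  truth <- readGeneSets(paths["truth"])
  expect_equal(truth, plantedPathways(st))
  cfg <- yaml::read_yaml(paths["config"])
  expect_equal(cfg$seed, 7L)
})

test_that("recovery report scores planted pathways against significant clusters", {
  pathways <- list(pw1 = c("a", "b", "c", "d"), pw2 = c("e", "f", "g", "h"))
  clusters <- handClusters(list(s1 = c("s1", "a", "b", "c", "d"),
                                s2 = c("s2", "x", "y", "z")))
  enr <- data.frame(seed = c("s1", "s2"), size = c(4L, 3L), k = 0L,
                    hit_rate = 0, p_value = c(0.01, 0.01),
                    significant = c(TRUE, TRUE))
  rep <- truthRecoveryReport(enr, clusters, pathways)
  pw1 <- rep$perPathway[rep$perPathway$pathway == "pw1", ]
  expect_equal(pw1$recall, 1)
  expect_equal(pw1$precision, 0.8)   # the seed itself is not planted
  expect_true(pw1$recovered)
  pw2 <- rep$perPathway[rep$perPathway$pathway == "pw2", ]
  expect_equal(pw2$recall, 0)
  expect_false(pw2$recovered)
  expect_equal(rep$recoveredFraction, 0.5)
  ## clusters that are not significant never count
  enr$significant <- FALSE
  rep0 <- truthRecoveryReport(enr, clusters, pathways)
  expect_equal(rep0$perPathway$recall, c(0, 0))
})
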