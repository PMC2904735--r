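test_that("induced diameters match closed forms", {
  expect_equal(subgraphDiameter(makePath(5), paste0("p", 1:5))$diameter, 4L)
  star <- makeStar(5)
  expect_equal(subgraphDiameter(star, igraph::V(star)$name)$diameter, 2L)
  expect_equal(subgraphDiameter(makeRingGraph(4), paste0("r", 1:4))$diameter, 2L)
  k6 <- makeClique(6)
  expect_equal(subgraphDiameter(k6, igraph::V(k6)$name)$diameter, 1L)
  ## disconnected set: largest-component convention
  g <- igraph::disjoint_union(makePath(4), makeClique(3))
  d <- subgraphDiameter(g, igraph::V(g)$name)
  expect_equal(d$diameter, 3L)
  expect_equal(d$lccFraction, 4 / 7)
  expect_equal(subgraphDiameter(g, "p1")$diameter, 0L)
  expect_error(subgraphDiameter(g, character()), "empty")
  expect_error(subgraphDiameter(g, "nope"), "unknown")
})

test_that("cluster expansion adds exactly the direct neighbours", {
  star <- makeStar(5)
  ex <- expandCluster(star, "hub")
  expect_setequal(ex$periphery, paste0("l", 1:5))
  expect_equal(ex$diameter, 2L)
  ## two ends of a 5-path: middle node is two steps away, stays out
  p5 <- makePath(5)
  ex <- expandCluster(p5, c("p1", "p5"))
  expect_setequal(ex$nodes, c("p1", "p2", "p4", "p5"))
  expect_lt(ex$lccFraction, 1)
  ## neighbourhood-closed cores are fixpoints; expansion never removes nodes
  k5 <- makeClique(5)
  ex <- expandCluster(k5, igraph::V(k5)$name)
  expect_equal(ex$periphery, character())
  expect_setequal(ex$nodes, igraph::V(k5)$name)
  expect_error(expandCluster(k5, character()), "empty")
  ## role / label vertex annotation
  labels <- labelSPRs(data.frame(id = igraph::V(star)$name,
                                 z_score = c(2, -2, rep(0, 3), NA),
                                 is_kpr = c(FALSE, FALSE, TRUE, rep(FALSE, 3))))
  ex <- expandCluster(star, "hub", labels)
  v <- igraph::as_data_frame(ex$subgraph, what = "vertices")
  expect_equal(v$role[v$name == "hub"], "core")
  expect_setequal(v$role[v$name != "hub"], "periphery")
  expect_equal(v$label[v$name == "hub"], "SPR")
  expect_equal(v$label[v$name == "l2"], "KPR")
})

test_that("direct neighbourhoods are bounded by diameter 2 and two-step by 4", {
  expect_equal(directNeighborhoodCluster(makeClique(4), "k1"),
               paste0("k", 1:4))
  iso <- namedGraph("a", "b", isolates = "z")
  expect_equal(directNeighborhoodCluster(iso, "z"), "z")
  expect_equal(subgraphDiameter(iso, "z")$diameter, 0L)
  expect_error(directNeighborhoodCluster(iso, "q"), "unknown")
  ## randomized sweep: the seed joins every pair within two steps
  for (s in 1:20) {
    g <- randomGnp(25, 0.12, seed = 400 + s)
    for (v in sample(igraph::V(g)$name, 5)) {
      nb <- directNeighborhoodCluster(g, v)
      expect_lte(subgraphDiameter(g, nb)$diameter, 2L)
      two <- twoStepNeighborhood(g, v)
      expect_lte(subgraphDiameter(g, two)$diameter, 4L)
      expect_true(all(nb %in% two))
    }
  }
  ## centre of a 9-path: two-step set is the middle five, an induced 4-path
  p9 <- makePath(9)
  two <- twoStepNeighborhood(p9, "p5")
  expect_setequal(two, paste0("p", 3:7))
  expect_equal(subgraphDiameter(p9, two)$diameter, 4L)
  expect_equal(twoStepNeighborhood(makeClique(4), "k2"), paste0("k", 1:4))
})

test_that("pathway survey computes per-set diameters and applies the exclusion rule", {
  ## three long induced paths and one pair of isolated edges
  g <- igraph::disjoint_union(makePath(6, "a"), makePath(8, "b"),
                              makePath(10, "c"), namedGraph("x1", "x2", "y1", "y2"))
  sets <- list(pathA = paste0("a", 1:6),
               pathB = paste0("b", 1:8),
               pathC = paste0("c", 1:10),
               frag = c("x1", "x2", "y1", "y2"),
               tiny = c("a1", "a2"),
               unmapped = c("q1", "q2", "q3"))
  sv <- pathwayDiameterSurvey(g, sets)
  keep <- sv$perSet[!sv$perSet$excluded, ]
  expect_setequal(keep$name, c("pathA", "pathB", "pathC"))
  expect_equal(sort(keep$diameter), c(5L, 7L, 9L))
  expect_equal(sv$summary$mean, 7)
  expect_equal(sv$summary$fraction_gt2, 1)
  expect_equal(sv$summary$sd, 2)
  expect_setequal(sv$summary$excluded_sets, c("frag", "tiny", "unmapped"))
  expect_equal(sv$perSet$reason[sv$perSet$name == "frag"],
               "mainly isolated edges")
  expect_equal(sv$perSet$lcc_fraction[sv$perSet$name == "frag"], 0.5)
  ## writer round-trip of the per-set table
  f <- withr::local_tempfile()
  writeSurveyReport(sv, f)
  lines <- readLines(f)
  expect_match(lines[length(lines)], "^# surveyed=3")
})
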