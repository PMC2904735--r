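test_that("edge-list reader simplifies and reports", {
  f <- withr::local_tempfile()
  writeLines(c("A\tB", "B\tA", "C\tC"), f)
  expect_message(net <- readEdgeList(f), "1 self-loop.*1 duplicate")
  expect_setequal(igraph::V(net)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(net), 1L)

  writeLines(c("a\tb", "b\tc"), f)
  net <- readEdgeList(f, quiet = TRUE)
  expect_equal(igraph::vcount(net), 3L)
  expect_equal(igraph::ecount(net), 2L)

  ## extra columns ignored; header skipped; comments skipped
  writeLines(c("source\ttarget", "# a comment", "x\ty\t0.7\tdb1"), f)
  net <- readEdgeList(f, quiet = TRUE)
  expect_setequal(igraph::V(net)$name, c("x", "y"))

  writeLines(character(), f)
  expect_error(readEdgeList(f), "empty")
  writeLines("onlyonetoken another extra", f)
  net <- readEdgeList(f, quiet = TRUE)  # whitespace-separated two columns
  expect_equal(igraph::ecount(net), 1L)
  expect_error(readEdgeList(tempfile()), "not found")
})

test_that("SIF reader fans out multi-target lines", {
  f <- withr::local_tempfile()
  writeLines(c("A pp B C", "D pp A", "E"), f)
  net <- readEdgeList(f, format = "sif", quiet = TRUE)
  expect_setequal(igraph::V(net)$name, c("A", "B", "C", "D", "E"))
  el <- igraph::as_edgelist(net)
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  expect_setequal(key, c("A B", "A C", "A D"))
  expect_equal(igraph::degree(net)[["E"]], 0L)
  writeLines("A pp", f)
  expect_error(readEdgeList(f, format = "sif"), "line 1")
})

test_that("annotation reader validates and admits missing Z-scores", {
  f <- withr::local_tempfile()
  writeLines(c("id\tz_score\tis_kpr",
               "EDNRB\t-1.1\tTRUE",
               "EDN3\t0.2\tTRUE",
               "XYZ\t\tFALSE"), f)
  ann <- readAnnotations(f)
  expect_equal(ann$z_score[ann$id == "EDNRB"], -1.1)
  expect_true(ann$is_kpr[ann$id == "EDN3"])
  expect_true(is.na(ann$z_score[ann$id == "XYZ"]))

  writeLines(c("id\tz_score\tis_kpr", "A\t1\tTRUE", "A\t2\tFALSE"), f)
  expect_error(readAnnotations(f), "duplicate")
  writeLines(c("id\tz_score\tis_kpr", "A\tbad\tTRUE"), f)
  expect_error(readAnnotations(f), "non-numeric")
})

test_that("eligibility keeps exactly the nodes above the degree cutoff", {
  star <- makeStar(4)
  expect_equal(eligibleNodes(star), "hub")
  tri <- makeClique(3)
  expect_equal(eligibleNodes(tri), character())
  k6 <- makeClique(6)
  expect_equal(eligibleNodes(k6), sort(igraph::V(k6)$name))
  ## degree is computed on the full network and cutoff is strict
  expect_equal(eligibleNodes(star, degreeCutoff = 4L), character())
  expect_setequal(eligibleNodes(star, degreeCutoff = 0L),
                  igraph::V(star)$name)
  expect_error(eligibleNodes(star, degreeCutoff = -1L), ">= 0")
  ## monotone: raising the cutoff never adds members
  g <- randomGnp(40, 0.15, seed = 3)
  prev <- eligibleNodes(g, 0L)
  for (cut in 1:6) {
    cur <- eligibleNodes(g, cut)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("subnetwork writers round-trip through the reader", {
  g <- randomGnp(25, 0.12, seed = 9)
  for (fmt in c("tsv", "sif")) {
    f <- withr::local_tempfile()
    writeSubnetwork(g, igraph::V(g)$name, f, format = fmt)
    back <- readEdgeList(f, format = fmt, quiet = TRUE)
    expect_setequal(igraph::V(back)$name, igraph::V(g)$name)
    elKey <- function(x) {
      el <- igraph::as_edgelist(x)
      sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
    }
    expect_equal(elKey(back), elKey(g))
  }
  ## induced subgraph on two triangle corners keeps one edge
  tri <- makeClique(3)
  f <- withr::local_tempfile()
  writeSubnetwork(tri, c("k1", "k2"), f, format = "tsv")
  sub <- readEdgeList(f, quiet = TRUE)
  expect_equal(igraph::ecount(sub), 1L)
  ## empty node set: header only, readable as an error (no content)
  writeSubnetwork(tri, character(), f, format = "tsv")
  expect_equal(readLines(f), "source\ttarget")
  expect_error(writeSubnetwork(tri, "nope", f), "unknown")
  ## graphml carries node attributes
  f2 <- withr::local_tempfile(fileext = ".graphml")
  writeSubnetwork(tri, igraph::V(tri)$name, f2, format = "graphml",
                  nodeAttrs = data.frame(id = c("k1", "k2", "k3"),
                                         role = c("core", "core", "periphery")))
  back <- igraph::read_graph(f2, format = "graphml")
  expect_setequal(igraph::V(back)$role, c("core", "core", "periphery"))
})

test_that("induced subgraphs never gain edges and GMT sets round-trip", {
  g <- randomGnp(30, 0.2, seed = 4)
  withr::with_seed(11, {
    for (i in 1:10) {
      sub <- sample(igraph::V(g)$name, sample(2:20, 1))
      f <- withr::local_tempfile()
      writeSubnetwork(g, sub, f, format = "tsv")
      back <- readEdgeList(f, quiet = TRUE)
      expect_lte(igraph::ecount(back), igraph::ecount(g))
    }
  })
  sets <- list(a = c("x", "y", "z"), b = c("p", "q", "r", "s"))
  f <- withr::local_tempfile()
  writeGeneSets(sets, f)
  expect_equal(readGeneSets(f), sets)
  writeLines("bad\tline", f)
  expect_error(readGeneSets(f), "malformed")
})
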