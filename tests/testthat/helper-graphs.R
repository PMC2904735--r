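## small named-graph builders used across the suite

namedGraph <- function(..., isolates = character()) {
  edges <- c(...)
  g <- igraph::make_graph(edges, directed = FALSE)
  if (length(isolates))
    g <- igraph::add_vertices(g, length(isolates), name = isolates)
  g
}

makePath <- function(n, prefix = "p") {
  g <- igraph::make_ring(n, circular = FALSE)
  igraph::V(g)$name <- paste0(prefix, seq_len(n))
  g
}

makeRingGraph <- function(n, prefix = "r") {
  g <- igraph::make_ring(n)
  igraph::V(g)$name <- paste0(prefix, seq_len(n))
  g
}

makeStar <- function(nLeaves, center = "hub", prefix = "l") {
  g <- igraph::make_star(nLeaves + 1L, mode = "undirected", center = 1)
  igraph::V(g)$name <- c(center, paste0(prefix, seq_len(nLeaves)))
  g
}

makeClique <- function(n, prefix = "k") {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- paste0(prefix, seq_len(n))
  g
}

randomGnp <- function(n, p, seed) {
  withr::with_seed(seed, {
    g <- igraph::sample_gnp(n, p)
  })
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  g
}

toyFile <- function(name) {
  system.file("extdata", name, package = "graphletsig", mustWork = TRUE)
}

## a tiny SignatureClusterSet built by hand (for recovery-report tests)
handClusters <- function(members) {
  tab <- data.frame(seed = names(members),
                    status = "formed",
                    threshold = 0.96,
                    size = lengths(members),
                    stringsAsFactors = FALSE)
  methods::new("SignatureClusterSet", table = tab, members = members,
               grid = seq(0.96, 0.90, by = -0.01))
}
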