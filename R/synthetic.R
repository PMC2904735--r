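#' Configuration for a synthetic screen-plus-network study
#'
#' Collects and validates the generator parameters.  Defaults define the
#' package's reference study: a 600-node network whose background has
#' heavy-tailed preferential-attachment degrees, three planted 12-member
#' pathway modules, planted screen effects of mean -2 on the Z-score scale
#' against a standard-normal background, and 30% of planted members
#' catalogued as known regulators.
#'
#' Each planted module is a closed chain (ring) of its members with a
#' pathway-specific chord pattern, so different pathways are topologically
#' distinguishable, and every member carries a private decoration chain (a
#' pendant interactor plus a tail of variable length) that individualizes
#' its graphlet signature without destroying within-module coherence.  The
#' modules tie into the background through bridge edges attached at pendant
#' nodes, keeping the perturbation of member signatures gentle.
#'
#' @param nNodes total nodes, background plus members plus decorations
#'   (default 600; exact, the background absorbs the remainder).
#' @param attachment edges per new node in the preferential-attachment
#'   background (default 3; controls density and the heavy degree tail).
#' @param nPathways planted pathway modules (default 3).
#' @param pathwaySize members per module, the ring circumference (default
#'   12; at least 6).
#' @param decorationProb tail-length parameter: each member's decoration
#'   tail is Binomial(2, `decorationProb`) nodes long (default 0.5); 0 makes
#'   modules fully deterministic.
#' @param nBridges bridge edges tying each module into the background,
#'   attached at pendant nodes (default 2).
#' @param effectMu mean Z-score shift of planted members (default -2;
#'   `|effectMu|` should exceed the labelling threshold of 1 for the screen
#'   to see the planted signal).
#' @param kprFraction fraction of each module catalogued as a known
#'   regulator (default 0.3).
#' @param seed integer master seed; every random choice derives from it.
#' @return Named list of validated parameters.
#' @export
syntheticStudyConfig <- function(nNodes = 600L, attachment = 3L,
                                 nPathways = 3L, pathwaySize = 12L,
                                 decorationProb = 0.5,
                                 nBridges = 2L, effectMu = -2,
                                 kprFraction = 0.3, seed = 42L) {
  cfg <- list(nNodes = as.integer(nNodes), attachment = as.integer(attachment),
              nPathways = as.integer(nPathways),
              pathwaySize = as.integer(pathwaySize),
              decorationProb = decorationProb,
              nBridges = as.integer(nBridges), effectMu = effectMu,
              kprFraction = kprFraction, seed = as.integer(seed))
  if (cfg$nPathways > 0L) {
    if (cfg$pathwaySize < 6L) stop("pathwaySize must be >= 6")
    if (cfg$nNodes < 10L * cfg$pathwaySize)
      stop("nNodes must be at least 10 * pathwaySize")
    if (cfg$nBridges > cfg$pathwaySize)
      stop("nBridges must not exceed pathwaySize")
  }
  if (cfg$decorationProb < 0 || cfg$decorationProb > 1 ||
      cfg$kprFraction < 0 || cfg$kprFraction > 1)
    stop("probabilities must lie in [0, 1]")
  cfg
}

## chord distance of module p: 2, 3, 4, ... cycling within what the ring
## circumference admits
.moduleChord <- function(p, pathwaySize) {
  maxd <- max(2L, pathwaySize %/% 2L - 1L)
  2L + (p - 1L) %% (maxd - 1L)
}

#' Generate the synthetic network
#'
#' The background is a preferential-attachment graph (heavy-tailed degrees,
#' the regime typical of protein-interaction data).  Planted module `p` is a
#' ring of `pathwaySize` members with chords at ring distance
#' `2 + (p - 1)`, giving each pathway its own local texture (triangles for
#' chord 2, squares and pentagons for longer chords); every member carries a
#' pendant interactor whose tail length is Binomial(2, `decorationProb`),
#' individualizing member signatures; `nBridges` bridge edges run from
#' distinct pendants to uniformly chosen background nodes.  The background
#' is sized so the total node count is exactly `nNodes`.  Deterministic for
#' a fixed `config$seed`.
#'
#' @param config list from [syntheticStudyConfig()].
#' @return list `network` (igraph, simple, named nodes), `pathways` (named
#'   list of planted member names; decorations are not members).
#' @export
generateNetwork <- function(config = syntheticStudyConfig()) {
  withr::with_seed(config$seed, {
    modules <- list()
    pathways <- list()
    nDecor <- 0L
    for (p in seq_len(config$nPathways)) {
      k <- config$pathwaySize
      ids <- sprintf("P%d_%02d", p, seq_len(k))
      edges <- cbind(ids, ids[seq_len(k) %% k + 1L])             # ring
      d <- .moduleChord(p, k)
      edges <- rbind(edges, cbind(ids, ids[(seq_len(k) + d - 1L) %% k + 1L]))
      pend <- sprintf("%s_d1", ids)
      edges <- rbind(edges, cbind(ids, pend))
      tailLen <- stats::rbinom(k, 2L, config$decorationProb)
      for (i in seq_len(k)) {
        if (tailLen[i] >= 1L)
          edges <- rbind(edges, cbind(pend[i], sprintf("%s_d2", ids[i])))
        if (tailLen[i] == 2L)
          edges <- rbind(edges, cbind(sprintf("%s_d2", ids[i]),
                                      sprintf("%s_d3", ids[i])))
      }
      modules[[p]] <- list(edges = edges, pendants = pend)
      pathways[[paste0("pathway_", p)]] <- ids
      nDecor <- nDecor + k + sum(tailLen)
    }
    nBg <- config$nNodes - config$nPathways * config$pathwaySize - nDecor
    if (nBg < 10L) stop("config leaves too few background nodes")
    bg <- igraph::sample_pa(nBg, power = 1, m = config$attachment,
                            directed = FALSE)
    igraph::V(bg)$name <- sprintf("B%04d", seq_len(nBg))
    net <- bg
    for (p in seq_len(config$nPathways)) {
      m <- igraph::graph_from_edgelist(modules[[p]]$edges, directed = FALSE)
      net <- igraph::disjoint_union(net, m)
      if (config$nBridges > 0L) {
        from <- sample(modules[[p]]$pendants, config$nBridges)
        to <- sample(igraph::V(bg)$name, config$nBridges)
        net <- igraph::add_edges(net, rbind(from, to))
      }
    }
    net <- igraph::simplify(net)
  })
  list(network = net, pathways = pathways)
}

#' Generate screen annotations for a network with planted truth
#'
#' Background and decoration nodes draw Z ~ Normal(0, 1) -- so about 31.7%
#' of them land outside (-1, 1) and get labelled screen-positive, the base
#' rate a genome-wide screen with this labelling rule produces.  Planted
#' members draw Z ~ Normal(`effectMu`, 1).  A random `kprFraction` of each
#' module is flagged as a known regulator.
#'
#' @param net igraph with named vertices.
#' @param pathways named list of planted member name vectors.
#' @param config list from [syntheticStudyConfig()].
#' @return data.frame `id`, `z_score`, `is_kpr` covering all nodes.
#' @export
generateAnnotations <- function(net, pathways, config = syntheticStudyConfig()) {
  ids <- igraph::V(net)$name
  planted <- ids %in% unlist(pathways)
  withr::with_seed(config$seed + 1L, {
    z <- stats::rnorm(length(ids), mean = ifelse(planted, config$effectMu, 0), sd = 1)
    kpr <- logical(length(ids))
    for (p in pathways) {
      nk <- round(config$kprFraction * length(p))
      if (nk > 0L) kpr[ids %in% sample(p, nk)] <- TRUE
    }
  })
  data.frame(id = ids, z_score = z, is_kpr = kpr, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: network, annotations and truth labels in one
#' [SyntheticStudy-class] object.
#'
#' @param config list from [syntheticStudyConfig()].
#' @return A [SyntheticStudy-class].
#' @examples
#' study <- generateStudy(syntheticStudyConfig(nNodes = 200, nPathways = 1,
#'                                             seed = 7))
#' study
#' @export
generateStudy <- function(config = syntheticStudyConfig()) {
  gen <- generateNetwork(config)
  ann <- generateAnnotations(gen$network, gen$pathways, config)
  planted <- ann$id %in% unlist(gen$pathways)
  names(planted) <- ann$id
  new("SyntheticStudy", network = gen$network, annotations = ann,
      pathways = gen$pathways, planted = planted, config = config)
}

#' Write a synthetic study to the pipeline's input formats
#'
#' Emits exactly what the readers consume: a TSV edge list, an annotation
#' TSV and a GMT truth file, plus a sidecar YAML echoing the generator
#' configuration and seed.
#'
#' @param study a [SyntheticStudy-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(network = file.path(dir, "network.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             truth = file.path(dir, "truth.gmt"),
             config = file.path(dir, "config.yaml"))
  writeSubnetwork(study@network, igraph::V(study@network)$name,
                  paths["network"], format = "tsv")
  ann <- study@annotations[order(study@annotations$id), ]
  utils::write.table(ann, paths["annotations"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeGeneSets(study@pathways, paths["truth"], description = "planted")
  yaml::write_yaml(study@config, paths["config"])
  invisible(paths)
}

#' Recovery of planted pathways by significant clusters
#'
#' For each planted pathway, finds the significant cluster that best covers
#' it and reports that cluster's precision (planted fraction of the cluster)
#' and recall (fraction of planted members in the cluster); a pathway counts
#' as recovered when its best recall reaches `recallThreshold`.
#'
#' @param enrichment data.frame from [scoreAllClusters()].
#' @param clusters a [SignatureClusterSet-class].
#' @param pathways named list of planted member vectors.
#' @param recallThreshold recall needed to call a pathway recovered
#'   (default 0.5).
#' @return list `perPathway` (data.frame `pathway`, `size`, `best_seed`,
#'   `precision`, `recall`, `recovered`) and `recoveredFraction`.
#' @export
truthRecoveryReport <- function(enrichment, clusters, pathways,
                                recallThreshold = 0.5) {
  sig <- enrichment$seed[enrichment$significant]
  rows <- lapply(names(pathways), function(nm) {
    truth <- pathways[[nm]]
    best <- data.frame(pathway = nm, size = length(truth),
                       best_seed = NA_character_, precision = 0,
                       recall = 0, stringsAsFactors = FALSE)
    for (s in sig) {
      members <- clusterMembers(clusters, s)[[1L]]
      ov <- length(intersect(members, truth))
      rec <- ov / length(truth)
      if (rec > best$recall ||
          (rec == best$recall && ov / length(members) > best$precision)) {
        best$best_seed <- s
        best$recall <- rec
        best$precision <- ov / length(members)
      }
    }
    best
  })
  perPathway <- do.call(rbind, rows)
  perPathway$recovered <- perPathway$recall >= recallThreshold
  list(perPathway = perPathway,
       recoveredFraction = mean(perPathway$recovered))
}
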