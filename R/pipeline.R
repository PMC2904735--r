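#' Pipeline configuration
#'
#' Assembles, with validation, the configuration for [runPipeline()].  All
#' analysis defaults are the reference parameters of the method: degree
#' cutoff 3, Z-score threshold 1, similarity threshold grid 0.96 down to
#' 0.90 in steps of 0.01, significance level 0.05, 1000 randomization runs.
#'
#' @param network path to an edge-list file, or an igraph object.
#' @param annotations path to an annotation TSV, or a data.frame.
#' @param geneSets optional path to a GMT file (or named list) for the
#'   pathway diameter survey.
#' @param outDir output directory for the stage tables.
#' @param degreeCutoff,zThreshold,thresholdStart,thresholdFloor,thresholdStep
#'   analysis parameters (see the stage functions).
#' @param alpha significance level for cluster enrichment.
#' @param nullRuns randomization runs for the null model.
#' @param seed integer master RNG seed.
#' @param networkFormat `"tsv"` or `"sif"`, when `network` is a path.
#' @return Named list of class-checked settings.
#' @export
pipelineConfig <- function(network, annotations, geneSets = NULL,
                           outDir = "graphletsig-out",
                           degreeCutoff = 3L, zThreshold = 1.0,
                           thresholdStart = 0.96, thresholdFloor = 0.90,
                           thresholdStep = 0.01, alpha = 0.05,
                           nullRuns = 1000L, seed = 1L,
                           networkFormat = "tsv") {
  if (thresholdStart < thresholdFloor) stop("thresholdStart must be >= thresholdFloor")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  list(network = network, annotations = annotations, geneSets = geneSets,
       outDir = outDir, degreeCutoff = as.integer(degreeCutoff),
       zThreshold = zThreshold, thresholdStart = thresholdStart,
       thresholdFloor = thresholdFloor, thresholdStep = thresholdStep,
       alpha = alpha, nullRuns = as.integer(nullRuns),
       seed = as.integer(seed), networkFormat = networkFormat)
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value YAML mirroring the arguments of [pipelineConfig()];
#' relative input paths are resolved against the file's directory.
#'
#' @param path YAML file path.
#' @param ... overrides applied after reading (e.g. `seed = 7`).
#' @return Configuration list, as from [pipelineConfig()].
#' @export
readPipelineConfig <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  base <- dirname(normalizePath(path))
  for (f in c("network", "annotations", "geneSets"))
    if (is.character(vals[[f]]) && !grepl("^(/|[A-Za-z]:)", vals[[f]]))
      vals[[f]] <- file.path(base, vals[[f]])
  do.call(pipelineConfig, vals)
}

#' Run the full signature-clustering analysis
#'
#' Executes the stages in order -- screen labelling, eligibility filter, GDV
#' counting on the full network, similarity matrix over the eligible pool,
#' adaptive cluster formation around every eligible screen-positive seed,
#' hypergeometric enrichment scoring, the random-cluster null model, and
#' neighbourhood expansion of every significant cluster -- writing each
#' stage's table into `config$outDir` and returning a run report.  With
#' `config$geneSets` set, a pathway diameter survey is appended.  Fully
#' reproducible from the configuration and its seed.
#'
#' @param config list from [pipelineConfig()] or [readPipelineConfig()].
#' @param catalog a [GraphletCatalog-class] (built on demand by default).
#' @param quiet suppress stage progress messages.
#' @return list with `counts` (eligible / SPR / KPR / overlap / cluster-fate
#'   / significant tallies), `clusters` ([SignatureClusterSet-class]),
#'   `enrichment` (data.frame), `null` ([NullModelSummary-class]),
#'   `expansion` (per-significant-cluster diameters), `survey` (or NULL),
#'   `labels`, `eligible`, `config`, `files`.
#' @export
runPipeline <- function(config, catalog = buildOrbitCatalog(), quiet = FALSE) {
  say <- function(...) if (!quiet) message("[graphletsig] ", ...)
  net <- if (igraph::is_igraph(config$network)) config$network
         else readEdgeList(config$network, config$networkFormat, quiet = quiet)
  ann <- if (is.data.frame(config$annotations)) config$annotations
         else readAnnotations(config$annotations)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outDir, f)
  files <- character(0)

  say("labelling screen hits (|Z| > ", config$zThreshold, ")")
  missing <- setdiff(igraph::V(net)$name, ann$id)
  if (length(missing))
    ann <- rbind(ann, data.frame(id = missing, z_score = NA_real_,
                                 is_kpr = FALSE))
  labels <- labelSPRs(ann, config$zThreshold)
  writeScreenLabels(labels, files["labels"] <- out("labels.tsv"))

  say("eligibility filter (degree > ", config$degreeCutoff, ")")
  eligible <- eligibleNodes(net, config$degreeCutoff)

  say("counting graphlet degree vectors on the full network (",
      igraph::vcount(net), " nodes, ", igraph::ecount(net), " edges)")
  gdv <- gdvMatrix(net, catalog)
  writeGDVTable(gdv, files["gdv"] <- out("gdv.tsv"))

  say("similarity matrix over ", length(eligible), " eligible nodes")
  sims <- similarityMatrix(net, eligible, catalog, gdv = gdv)
  writeSimilarityMatrix(sims, files["sims"] <- out("similarity.tsv"))

  sprs <- labels$id[labels$is_spr]
  seeds <- intersect(eligible, sprs)
  say("forming clusters around ", length(seeds), " eligible screen-positive seeds")
  clusters <- formAllClusters(seeds, sims, start = config$thresholdStart,
                              floor = config$thresholdFloor,
                              step = config$thresholdStep, quiet = quiet)
  writeClusterTable(clusters, files["clusters"] <- out("clusters.tsv"))

  say("scoring cluster enrichment (alpha = ", config$alpha, ")")
  enr <- scoreAllClusters(clusters, labels, eligible, alpha = config$alpha)
  writeEnrichmentTable(enr, files["enrichment"] <- out("enrichment.tsv"))

  nullModel <- NULL
  if (nrow(enr)) {
    say("random-cluster null model (", config$nullRuns, " runs)")
    nullModel <- randomClusterNull(enr, labels, eligible,
                                   runs = config$nullRuns,
                                   alpha = config$alpha,
                                   rngSeed = config$seed)
    writeNullSummary(nullModel, files["null"] <- out("null_model.tsv"))
  }

  say("expanding significant clusters")
  sigSeeds <- enr$seed[enr$significant]
  expansion <- lapply(sigSeeds, function(s) {
    ex <- expandCluster(net, clusterMembers(clusters, s)[[1L]], labels)
    data.frame(seed = s, n_core = length(ex$core),
               n_periphery = length(ex$periphery),
               diameter = ex$diameter, lcc_fraction = ex$lccFraction)
  })
  expansion <- if (length(expansion)) do.call(rbind, expansion)
               else data.frame(seed = character(), n_core = integer(),
                               n_periphery = integer(), diameter = integer(),
                               lcc_fraction = numeric())
  utils::write.table(expansion, files["expansion"] <- out("expansion.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  survey <- NULL
  if (!is.null(config$geneSets)) {
    sets <- if (is.list(config$geneSets)) config$geneSets
            else readGeneSets(config$geneSets)
    say("pathway diameter survey over ", length(sets), " gene sets")
    survey <- pathwayDiameterSurvey(net, sets)
    writeSurveyReport(survey, files["survey"] <- out("survey.tsv"))
  }

  counts <- list(
    nodes = igraph::vcount(net), edges = igraph::ecount(net),
    eligible = length(eligible),
    sprs = length(attr(labels, "sprs")),
    kprs = length(attr(labels, "kprs")),
    spr_kpr_overlap = length(attr(labels, "overlap")),
    eligible_sprs = length(seeds),
    formed = sum(clusterTable(clusters)$status == "formed"),
    singleton = sum(clusterTable(clusters)$status == "singleton"),
    unformed = sum(clusterTable(clusters)$status == "unformed"),
    significant = sum(enr$significant))
  report <- list(counts = counts, clusters = clusters, enrichment = enr,
                 null = nullModel, expansion = expansion, survey = survey,
                 labels = labels, eligible = eligible, config = config,
                 files = files)
  reportLines <- c(
    sprintf("%s\t%s", names(unlist(counts)), unlist(counts)),
    if (!is.null(nullModel))
      sprintf("null\tmu=%.4f sigma=%.4f empirical_p=%.6f z=%.2f normal_p=%.6g",
              nullModel@mu, nullModel@sigma, nullModel@empiricalP,
              nullModel@z, nullModel@normalP))
  writeLines(reportLines, out("report.tsv"))
  say("done; tables in ", config$outDir)
  invisible(report)
}
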