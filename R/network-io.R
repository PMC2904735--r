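## shared guard for user-supplied networks
.checkNetwork <- function(net) {
  if (!igraph::is_igraph(net)) stop("expected an igraph object")
  if (igraph::is_directed(net)) stop("expected an undirected network")
  if (is.null(igraph::V(net)$name)) stop("network vertices must be named")
  if (igraph::any_loop(net) || igraph::any_multiple(net))
    stop("network must be simple (no self-loops or parallel edges); ",
         "readEdgeList() simplifies on input")
  invisible(TRUE)
}

#' Read an undirected interaction network from an edge-list or SIF file
#'
#' TSV dialect: the first two whitespace/tab-separated columns of each line
#' are the interacting node identifiers; extra columns are ignored.  SIF
#' dialect: `source relation target [target ...]`, fanning one line out to
#' one edge per target.  Identifiers are case-sensitive opaque strings.
#' Self-loops and duplicate edges (in either orientation) are removed, with
#' the removed counts reported via `message()` -- a union of interaction
#' databases routinely carries both.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"sif"`.
#' @param quiet suppress the simplification message.
#' @return An undirected simple igraph with named vertices.
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB", "B\tA", "C\tC", "B\tC"), f)
#' g <- readEdgeList(f)   # 3 nodes, 2 edges: the duplicate and loop are dropped
#' @export
readEdgeList <- function(path, format = c("tsv", "sif"), quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  ## drop comments and the writer's header line, keep original numbering
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#") &
    !(tolower(trimws(lines)) %in% c("source\ttarget", "source target"))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty network file: ", path)
  pairs <- vector("list", length(lines))
  for (ii in seq_along(lines)) {
    i <- lineNo[ii]
    f <- strsplit(trimws(lines[ii]), "[ \t]+")[[1L]]
    if (format == "tsv") {
      if (length(f) == 1L) {            # isolated node
        pairs[[ii]] <- matrix(character(), 0L, 2L)
        attr(pairs[[ii]], "lone") <- f[1L]
        next
      }
      pairs[[ii]] <- matrix(f[1:2], 1L, 2L)
    } else {
      if (length(f) == 1L) {
        pairs[[ii]] <- matrix(character(), 0L, 2L)   # isolated node line
        attr(pairs[[ii]], "lone") <- f[1L]
      } else if (length(f) < 3L) {
        stop("malformed SIF line ", i, " in ", path,
             ": need source, relation, target(s)")
      } else {
        pairs[[ii]] <- cbind(f[1L], f[-(1:2)])
      }
    }
  }
  lone <- unlist(lapply(pairs, attr, "lone"))
  em <- do.call(rbind, pairs)
  loops <- em[, 1L] == em[, 2L]
  lone <- c(lone, em[loops, 1L])   # a self-loop still names its node
  em2 <- em[!loops, , drop = FALSE]
  keyed <- paste(pmin(em2[, 1L], em2[, 2L]), pmax(em2[, 1L], em2[, 2L]), sep = "\r")
  dup <- duplicated(keyed)
  if (!quiet && (sum(loops) || sum(dup)))
    message("readEdgeList: dropped ", sum(loops), " self-loop(s) and ",
            sum(dup), " duplicate edge(s)")
  em2 <- em2[!dup, , drop = FALSE]
  nodes <- sort(unique(c(as.vector(em2), lone)))
  igraph::graph_from_data_frame(as.data.frame(em2, stringsAsFactors = FALSE),
                                directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Read a node annotation table
#'
#' A TSV with header columns `id`, `z_score`, `is_kpr`: the screen Z-score
#' (blank when the gene was not screened) and the known-pathway-regulator
#' flag.  Nodes in the network but absent from the table are treated
#' downstream as unscreened non-regulators.
#'
#' @param path file path.
#' @return data.frame with columns `id` (character), `z_score` (numeric, NA
#'   allowed), `is_kpr` (logical).
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = TRUE)
  need <- c("id", "z_score", "is_kpr")
  if (!all(need %in% names(df)))
    stop("annotation file needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$id))
    stop("duplicate identifiers in annotation file: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  z <- trimws(df$z_score)
  z[is.na(z)] <- ""
  zn <- suppressWarnings(as.numeric(z))
  bad <- nzchar(z) & !toupper(z) %in% c("NA", "NAN") & is.na(zn)
  if (any(bad))
    stop("non-numeric z_score for: ", paste(df$id[bad], collapse = ", "))
  kpr <- toupper(trimws(df$is_kpr)) %in% c("TRUE", "T", "1", "YES")
  data.frame(id = df$id, z_score = zn, is_kpr = kpr, stringsAsFactors = FALSE)
}

#' Nodes passing the connectivity (degree) filter
#'
#' Signature clustering is restricted to well-connected proteins: nodes whose
#' degree in the full, unfiltered network is strictly greater than the
#' cutoff.  Poorly connected nodes tend to sit in incompletely mapped regions
#' of interaction data, so they are excluded from clustering (but still
#' contribute to every GDV computation).
#'
#' @param net an undirected simple igraph.
#' @param degreeCutoff non-negative integer; membership requires degree
#'   strictly greater than this (default 3).
#' @return Character vector of eligible node names, lexicographically sorted.
#' @export
eligibleNodes <- function(net, degreeCutoff = 3L) {
  .checkNetwork(net)
  if (degreeCutoff < 0L) stop("degreeCutoff must be >= 0")
  deg <- igraph::degree(net)
  sort(names(deg)[deg > degreeCutoff])
}

#' Write an induced subnetwork
#'
#' Writes the subgraph induced by `nodes` (all edges of `net` with both ends
#' in `nodes`).  TSV and SIF outputs round-trip through [readEdgeList()];
#' GraphML is for external viewers.  Writers are deterministic: edges are
#' emitted in lexicographic order, and isolated nodes of the induced
#' subgraph are listed as bare single-identifier lines (both dialects), so
#' the node set round-trips exactly.
#'
#' @param net an undirected simple igraph.
#' @param nodes character vector, a subset of the network's nodes.
#' @param path output file path.
#' @param format `"tsv"`, `"sif"` or `"graphml"`.
#' @param nodeAttrs optional data.frame (`id` plus attribute columns) carried
#'   into GraphML output as vertex attributes.
#' @export
writeSubnetwork <- function(net, nodes, path, format = c("tsv", "sif", "graphml"),
                            nodeAttrs = NULL) {
  format <- match.arg(format)
  .checkNetwork(net)
  unknown <- setdiff(nodes, igraph::V(net)$name)
  if (length(unknown))
    stop("unknown node(s): ", paste(unknown, collapse = ", "))
  sub <- igraph::induced_subgraph(net, nodes)
  el <- igraph::as_edgelist(sub)
  if (nrow(el)) {
    el <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
    el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  }
  iso <- sort(setdiff(nodes, as.vector(el)))
  if (format == "tsv") {
    lines <- c("source\ttarget",
               if (nrow(el)) paste(el[, 1L], el[, 2L], sep = "\t"),
               iso)
    writeLines(lines, path)
  } else if (format == "sif") {
    lines <- c(if (nrow(el)) paste(el[, 1L], "pp", el[, 2L], sep = "\t"), iso)
    writeLines(lines, path)
  } else {
    if (!is.null(nodeAttrs)) {
      m <- match(igraph::V(sub)$name, nodeAttrs$id)
      for (col in setdiff(names(nodeAttrs), "id"))
        sub <- igraph::set_vertex_attr(sub, col, value = nodeAttrs[[col]][m])
    }
    igraph::write_graph(sub, path, format = "graphml")
  }
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member identifiers, all
#' tab-separated.
#'
#' @param path file path.
#' @return Named list of character vectors.
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": need name, description, members")
    sets[[f[1L]]] <- unique(f[-(1:2)])
  }
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output file path.
#' @param description description field written for every set.
#' @export
writeGeneSets <- function(sets, path, description = "synthetic") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}
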