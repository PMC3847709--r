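# Sequence-similarity networks: nodes are sequences, edges are similarity
# hits passing an E-value ceiling; connected components approximate
# families.

#' Build a sequence-similarity graph from a hit table
#'
#' Collapses directional hits to undirected edges: an edge `(u, v)` is kept
#' iff the minimum E-value over the two directions is `<= threshold` and
#' `u != v`. Classic thresholds are 1e-10 for a panel-wide toxin network
#' and 1e-20 for a within-family network.
#'
#' @param hits hit [S4Vectors::DataFrame] from [searchAllVsAll()] over the
#'   node universe.
#' @param threshold E-value ceiling for edge connection.
#' @param nodes optional character vector of node ids (defaults to the ids
#'   present in `hits`); nodes without qualifying edges become singletons.
#' @param origin optional named character vector tagging each node
#'   (`"panel"` or `"query"`); stored as a vertex attribute.
#' @return an [igraph::igraph] with vertex attributes `name`, `origin` and
#'   edge attributes `evalue`, `minusLog10E`; the threshold is stored as a
#'   graph attribute.
#' @export
buildSimilarityGraph <- function(hits, threshold, nodes = NULL,
                                 origin = NULL) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be a positive E-value ceiling")
  nodes <- nodes %||% sort(unique(c(hits$query, hits$subject)))
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(hits)) {
    u <- pmin(hits$query, hits$subject)
    v <- pmax(hits$query, hits$subject)
    key <- paste(u, v, sep = "\r")
    ev <- tapply(hits$evalue, key, min)
    keep <- ev <= threshold
    if (any(keep)) {
      pairs <- do.call(rbind, strsplit(names(ev)[keep], "\r", fixed = TRUE))
      sel <- pairs[, 1] != pairs[, 2]
      pairs <- pairs[sel, , drop = FALSE]
      evk <- as.numeric(ev[keep])[sel]
      if (nrow(pairs)) {
        g <- igraph::add_edges(g, as.vector(t(pairs)),
                               evalue = evk,
                               minusLog10E = -log10(evk))
      }
    }
  }
  if (!is.null(origin))
    igraph::V(g)$origin <- unname(origin[igraph::V(g)$name])
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

#' Connected components of a similarity graph
#'
#' Standard undirected connected components with deterministic ordering:
#' components (>= 2 nodes) sorted by decreasing size, ties by smallest
#' member id; degree-0 nodes are reported as singletons, mirroring the
#' network-annotation convention that a sequence with no similarity edge
#' is a singleton and does not appear in the graphical representation.
#'
#' @param graph an [igraph::igraph] from [buildSimilarityGraph()].
#' @return list with `components` (list of sorted character vectors) and
#'   `singletons` (character vector).
#' @export
connectedComponentsPartition <- function(graph) {
  comp <- igraph::components(graph)
  ids <- igraph::V(graph)$name
  groups <- split(ids, comp$membership)
  sizes <- lengths(groups)
  singles <- unlist(groups[sizes == 1], use.names = FALSE)
  multi <- groups[sizes >= 2]
  multi <- lapply(multi, sort)
  if (length(multi)) {
    firstId <- vapply(multi, `[[`, character(1), 1)
    ord <- order(-lengths(multi), firstId)
    multi <- unname(multi[ord])
  } else multi <- list()
  list(components = multi, singletons = sort(singles %||% character()))
}

#' Classify query sequences into similarity groups
#'
#' Queries sharing a connected component share a group label (`G1`, `G2`,
#' ... assigned by decreasing component size, ties by smallest member id);
#' queries in no component are flagged singletons. Components containing
#' panel members inherit the panel family as an annotation (majority
#' family among panel members, ties alphabetical).
#'
#' @param partition output of [connectedComponentsPartition()].
#' @param origin named character vector: node id -> `"query"` / `"panel"`.
#' @param panelFamilies optional named character vector: panel id ->
#'   family.
#' @return [S4Vectors::DataFrame] with one row per query: `id`, `group`
#'   (NA for singletons), `singleton`, `family`.
#' @export
classifyQueryGroups <- function(partition, origin, panelFamilies = NULL) {
  queries <- names(origin)[origin == "query"]
  group <- setNames(rep(NA_character_, length(queries)), queries)
  family <- setNames(rep(NA_character_, length(queries)), queries)
  for (k in seq_along(partition$components)) {
    memb <- partition$components[[k]]
    qs <- intersect(memb, queries)
    if (!length(qs)) next
    group[qs] <- paste0("G", k)
    if (!is.null(panelFamilies)) {
      pan <- intersect(memb, names(panelFamilies))
      if (length(pan)) {
        fam <- sort(table(panelFamilies[pan]), decreasing = TRUE)
        family[qs] <- names(fam)[1]
      }
    }
  }
  DataFrame(id = queries, group = unname(group[queries]),
            singleton = queries %in% partition$singletons,
            family = unname(family[queries]))
}

#' Export a similarity graph for visualization
#'
#' Writes GraphML (full attributes) and SIF (Cytoscape-compatible;
#' one `a sim b` line per edge plus a bare line per isolated node) files,
#' and a TSV membership table (node, origin, group or singleton, family).
#'
#' @param graph an [igraph::igraph] from [buildSimilarityGraph()].
#' @param partition output of [connectedComponentsPartition()].
#' @param basePath output path prefix; `<basePath>.graphml`,
#'   `<basePath>.sif` and `<basePath>_membership.tsv` are written.
#' @param groups optional [classifyQueryGroups()] table merged into the
#'   membership TSV.
#' @return character vector of the written paths, invisibly.
#' @export
exportGraph <- function(graph, partition, basePath, groups = NULL) {
  graphml <- paste0(basePath, ".graphml")
  sif <- paste0(basePath, ".sif")
  tsv <- paste0(basePath, "_membership.tsv")
  igraph::write_graph(graph, graphml, format = "graphml")
  el <- igraph::as_edgelist(graph)
  sifLines <- if (nrow(el)) paste(el[, 1], "sim", el[, 2]) else character()
  iso <- igraph::V(graph)$name[igraph::degree(graph) == 0]
  writeLines(c(sifLines, iso), sif)
  compOf <- setNames(rep(NA_character_, length(igraph::V(graph)$name)),
                     igraph::V(graph)$name)
  for (k in seq_along(partition$components))
    compOf[partition$components[[k]]] <- paste0("C", k)
  memb <- data.frame(
    node = igraph::V(graph)$name,
    origin = igraph::V(graph)$origin %||% NA_character_,
    component = unname(compOf[igraph::V(graph)$name]),
    singleton = igraph::V(graph)$name %in% partition$singletons)
  if (!is.null(groups)) {
    g <- as.data.frame(groups)
    memb <- merge(memb, g, by.x = "node", by.y = "id", all.x = TRUE,
                  sort = FALSE)
  }
  write.table(memb, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(graphml, sif, tsv))
}
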