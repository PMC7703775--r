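.kept_adjacency <- function(network) {
  k <- keptEdges(network)
  adj <- split(c(k$nodeB, k$nodeA), c(k$nodeA, k$nodeB))
  lapply(adj, unique)
}

#' First neighbours of a network node
#'
#' Nodes adjacent to `node` via kept edges; the node itself is excluded.
#'
#' @param network a [MINetwork-class].
#' @param node a node id.
#' @return Character vector of neighbour node ids.
#' @export
firstNeighbors <- function(network, node) {
  stopifnot(is(network, "MINetwork"))
  if (!node %in% networkNodes(network)) stop("unknown node: ", node)
  k <- keptEdges(network)
  sort(unique(c(k$nodeB[k$nodeA == node], k$nodeA[k$nodeB == node])))
}

#' Mutual first neighbours of a seed set
#'
#' Nodes outside the seed set that are first neighbours of at least
#' `minLinks` seeds. With the default `minLinks = length(seeds)` this is
#' the classical mutual first neighbour: a node adjacent to every seed,
#' the pattern by which unannotated hub clusters tie the biomineralization
#' marker clusters together.
#'
#' @param network a [MINetwork-class].
#' @param seeds non-empty character vector of seed node ids.
#' @param minLinks integer in `[2, length(seeds)]`.
#' @return Character vector of hub node ids (possibly empty).
#' @export
mutualFirstNeighbors <- function(network, seeds, minLinks = length(seeds)) {
  stopifnot(is(network, "MINetwork"))
  if (!length(seeds)) stop("seeds must be non-empty")
  if (minLinks > length(seeds))
    stop("minLinks must not exceed the number of seeds")
  if (minLinks < 2) stop("minLinks must be at least 2")
  minLinks <- as.integer(minLinks)
  unknown <- setdiff(seeds, networkNodes(network))
  if (length(unknown)) stop("unknown seed(s): ", paste(unknown, collapse = ", "))
  nb <- lapply(seeds, function(s) firstNeighbors(network, s))
  counts <- table(unlist(nb))
  hubs <- names(counts)[counts >= minLinks]
  sort(setdiff(hubs, seeds))
}

#' Extract a marker-anchored module
#'
#' The module node set is the union over present seeds of breadth-first
#' neighbourhoods of depth at most `radius` over kept edges. Hubs are the
#' mutual first neighbours of all present seeds that fall inside the module;
#' anchors are the present seeds. Seeds absent from the network are
#' reported in the `absentSeeds` slot, not an error (a marker whose cluster
#' was filtered out should not abort the analysis).
#'
#' @param network a [MINetwork-class].
#' @param seeds character vector of seed (marker-bearing) node ids.
#' @param radius non-negative BFS depth (default 1: seeds, their first
#'   neighbours and shared hubs).
#' @param moduleId label for the module.
#' @return A [GRNModule-class].
#' @export
extractModule <- function(network, seeds, radius = 1L, moduleId = "module") {
  stopifnot(is(network, "MINetwork"))
  if (radius < 0) stop("radius must be non-negative")
  present <- intersect(seeds, networkNodes(network))
  absent <- setdiff(seeds, present)
  if (!length(present)) stop("all seeds are absent from the network")
  adj <- .kept_adjacency(network)
  nodes <- frontier <- unique(present)
  depth <- 0L
  while (depth < radius && length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), nodes)
    nodes <- c(nodes, nxt)
    frontier <- nxt
    depth <- depth + 1L
  }
  hubs <- if (length(present) >= 2L)
    intersect(mutualFirstNeighbors(network, present), nodes)
  else character()
  new("GRNModule", moduleId = as.character(moduleId), nodeIds = sort(nodes),
      anchorIds = sort(present), hubIds = hubs,
      absentSeeds = sort(absent))
}

#' Summarize a module's gene content
#'
#' Counts the clusters and member genes of a module, split by annotation
#' status.
#'
#' @param module a [GRNModule-class].
#' @param assignment a [SotaClustering-class] or named character vector
#'   (gene id -> cluster id) covering every module node.
#' @param annotations `NULL`, or an annotation data.frame with columns
#'   `gene_id`, `description`, `terms` (a gene is unannotated iff its
#'   description and term set are both empty).
#' @return A one-row data.frame: `module_id`, `n_clusters`, `n_genes`,
#'   `n_annotated`, `n_unannotated`.
#' @export
summarizeModule <- function(module, assignment, annotations = NULL) {
  stopifnot(is(module, "GRNModule"))
  asg <- if (is(assignment, "SotaClustering")) clusterAssignment(assignment)
         else assignment
  missing_nodes <- setdiff(moduleNodes(module), asg)
  if (length(missing_nodes))
    stop("module node(s) missing from the assignment: ",
         paste(missing_nodes, collapse = ", "))
  genes <- names(asg)[asg %in% moduleNodes(module)]
  annotated <- annotatedGenes(annotations)
  n_ann <- sum(genes %in% annotated)
  data.frame(module_id = module@moduleId,
             n_clusters = length(moduleNodes(module)),
             n_genes = length(genes), n_annotated = n_ann,
             n_unannotated = length(genes) - n_ann)
}

#' Genes with a non-empty annotation
#'
#' @param annotations `NULL` or a data.frame with columns `gene_id`,
#'   `description` and optionally `terms`.
#' @return Character vector of annotated gene ids.
#' @export
annotatedGenes <- function(annotations) {
  if (is.null(annotations) || nrow(annotations) == 0L) return(character())
  desc <- !is.na(annotations$description) &
    nzchar(trimws(annotations$description))
  trm <- if ("terms" %in% colnames(annotations))
    !is.na(annotations$terms) & nzchar(trimws(annotations$terms))
  else rep(FALSE, nrow(annotations))
  annotations$gene_id[desc | trm]
}

#' Write module membership as TSV
#'
#' Columns `module_id`, `node_id`, `role` (`anchor`, `hub` or `member`).
#'
#' @param modules list of [GRNModule-class] objects (or a single one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeModulesTable <- function(modules, path) {
  if (is(modules, "GRNModule")) modules <- list(modules)
  rows <- do.call(rbind, lapply(modules, function(m) {
    role <- ifelse(moduleNodes(m) %in% anchorNodes(m), "anchor",
                   ifelse(moduleNodes(m) %in% hubNodes(m), "hub", "member"))
    data.frame(module_id = m@moduleId, node_id = moduleNodes(m), role = role)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
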