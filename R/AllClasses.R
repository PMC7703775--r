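#' Expression matrix container with sample design
#'
#' `MantleExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment-class] with a `valueKind` slot
#' recording whether the single `"values"` assay holds raw counts or
#' log-scale expression. Sample-level factors of the damage-repair study
#' design (`time_point`, `age_category`, `treatment`) live in `colData`.
#'
#' @slot valueKind character, `"counts"` or `"log_expression"`. Counts must
#'   be non-negative integers; log expression must be finite.
#'
#' @seealso [MantleExperiment()] for the constructor, [readCountsTable()]
#' @export
setClass("MantleExperiment",
  contains = "SummarizedExperiment",
  representation(valueKind = "character")
)

.AGE_LEVELS <- c("juvenile", "adolescent", "adult")
.TREATMENT_LEVELS <- c("damaged", "control")

.validate_mantle_experiment <- function(object) {
  msg <- character()
  vk <- object@valueKind
  if (length(vk) != 1L || !vk %in% c("counts", "log_expression"))
    msg <- c(msg, "valueKind must be 'counts' or 'log_expression'")
  v <- assay(object, 1L)
  gid <- rownames(object)
  sid <- colnames(object)
  if ((is.null(gid) && nrow(v) > 0) || anyDuplicated(gid))
    msg <- c(msg, "gene ids must be present and unique")
  if ((is.null(sid) && ncol(v) > 0) || anyDuplicated(sid))
    msg <- c(msg, "sample ids must be present and unique")
  if (length(msg) == 0L && identical(vk, "counts")) {
    bad <- !is.finite(v) | v < 0 | v != round(v)
    if (any(bad)) {
      i <- which(bad, arr.ind = TRUE)[1L, ]
      msg <- c(msg, sprintf(
        "counts must be non-negative integers; first violation at gene '%s', sample '%s'",
        gid[i[1L]], sid[i[2L]]))
    }
  }
  if (length(msg) == 0L && identical(vk, "log_expression") && !all(is.finite(v)))
    msg <- c(msg, "log_expression values must all be finite")
  cd <- colData(object)
  if ("age_category" %in% colnames(cd) &&
      !all(as.character(cd$age_category) %in% .AGE_LEVELS))
    msg <- c(msg, sprintf("age_category levels must be in {%s}",
                          paste(.AGE_LEVELS, collapse = ", ")))
  if ("treatment" %in% colnames(cd) &&
      !all(as.character(cd$treatment) %in% .TREATMENT_LEVELS))
    msg <- c(msg, sprintf("treatment levels must be in {%s}",
                          paste(.TREATMENT_LEVELS, collapse = ", ")))
  if (length(msg)) msg else TRUE
}
setValidity("MantleExperiment", .validate_mantle_experiment)

#' Construct a MantleExperiment
#'
#' @param values numeric matrix, genes in rows (unique rownames) and samples
#'   in columns (unique colnames).
#' @param design `NULL`, or a data.frame with one row per sample (matched by
#'   `sample_id` column or rownames) carrying the factors `time_point`
#'   (six ordered levels), `age_category` (juvenile/adolescent/adult) and
#'   `treatment` (damaged/control).
#' @param valueKind `"counts"` (non-negative integers) or
#'   `"log_expression"` (finite values).
#'
#' @return A validated [MantleExperiment-class] object.
#' @examples
#' m <- matrix(0:5, nrow = 2, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' MantleExperiment(m, valueKind = "counts")
#' @export
MantleExperiment <- function(values, design = NULL,
                             valueKind = c("counts", "log_expression")) {
  valueKind <- match.arg(valueKind)
  values <- as.matrix(values)
  if (is.null(design)) {
    cd <- DataFrame(row.names = colnames(values))
  } else {
    design <- as.data.frame(design)
    if ("sample_id" %in% colnames(design)) {
      rownames(design) <- as.character(design$sample_id)
      design$sample_id <- NULL
    }
    missing_samples <- setdiff(colnames(values), rownames(design))
    extra_samples <- setdiff(rownames(design), colnames(values))
    if (length(missing_samples) || length(extra_samples))
      stop("metadata sample set differs from matrix sample set ",
           "(missing: ", paste(missing_samples, collapse = ","),
           "; extra: ", paste(extra_samples, collapse = ","), ")")
    cd <- DataFrame(design[colnames(values), , drop = FALSE])
  }
  se <- SummarizedExperiment(assays = list(values = values), colData = cd)
  new("MantleExperiment", se, valueKind = valueKind)
}

#' SOTA clustering result
#'
#' Binary growing tree of prototype "cells" fitted by [runSota()] together
#' with the gene-to-cell assignment. Internal nodes have exactly two
#' children; the non-empty leaves are the final expression clusters.
#'
#' @slot prototypes numeric matrix, one row per tree node (dimension = number
#'   of samples).
#' @slot tree data.frame with columns `node`, `parent`, `left`, `right`,
#'   `isCell` describing the binary tree (`NA` links where absent).
#' @slot assignment named character vector mapping each gene id to the
#'   cluster id of its cell.
#' @slot clusterIds character, ordered ids of the non-empty cells.
#' @slot totalError numeric, final sum over genes of distance to the
#'   assigned prototype.
#' @slot params list, the [sotaParams()] used.
#' @export
setClass("SotaClustering", representation(
  prototypes = "matrix", tree = "data.frame", assignment = "character",
  clusterIds = "character", totalError = "numeric", params = "list"
))

setValidity("SotaClustering", function(object) {
  msg <- character()
  tr <- object@tree
  internal <- !tr$isCell
  if (any(internal & (is.na(tr$left) | is.na(tr$right))))
    msg <- c(msg, "every internal node must have exactly two children")
  if (sum(is.na(tr$parent)) != 1L)
    msg <- c(msg, "exactly one root required")
  if (!all(is.finite(object@prototypes)))
    msg <- c(msg, "prototype vectors must be finite")
  if (is.null(names(object@assignment)) || anyDuplicated(names(object@assignment)))
    msg <- c(msg, "assignment must map each gene exactly once")
  if (!all(object@clusterIds %in% object@assignment))
    msg <- c(msg, "every cluster id must be non-empty")
  if (!all(object@assignment %in% object@clusterIds))
    msg <- c(msg, "assignment refers to unknown cluster ids")
  if (length(msg)) msg else TRUE
})

#' Mutual-information relevance network
#'
#' Undirected simple graph on cluster ids produced by [inferNetwork()].
#' Every candidate pair is recorded with its mutual information (nats) and a
#' provenance status: `kept`, `removed_by_threshold` or `removed_by_dpi`.
#'
#' @slot nodeIds character, the network nodes (cluster ids).
#' @slot edges data.frame with columns `nodeA`, `nodeB`, `mi`, `status`.
#' @slot threshold numeric, the permutation-calibrated MI threshold used
#'   (`-Inf` when none was applied).
#' @slot params list, the [aracneParams()] used.
#' @export
setClass("MINetwork", representation(
  nodeIds = "character", edges = "data.frame", threshold = "numeric",
  params = "list"
))

setValidity("MINetwork", function(object) {
  msg <- character()
  e <- object@edges
  need <- c("nodeA", "nodeB", "mi", "status")
  if (!all(need %in% colnames(e)))
    return(paste("edges must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(object@nodeIds))
    msg <- c(msg, "node ids must be unique")
  if (nrow(e)) {
    if (any(e$nodeA == e$nodeB)) msg <- c(msg, "self-loops are not allowed")
    key <- paste(pmin(e$nodeA, e$nodeB), pmax(e$nodeA, e$nodeB))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges are not allowed")
    if (!all(e$nodeA %in% object@nodeIds & e$nodeB %in% object@nodeIds))
      msg <- c(msg, "edges refer to unknown nodes")
    if (!all(e$status %in% c("kept", "removed_by_threshold", "removed_by_dpi")))
      msg <- c(msg, "unknown edge status")
    if (any(e$mi < 0)) msg <- c(msg, "MI weights must be non-negative")
    thr <- object@threshold
    if (length(thr) == 1L && is.finite(thr) &&
        any(e$status == "kept" & e$mi <= thr))
      msg <- c(msg, "kept edges must exceed the threshold")
  }
  if (length(msg)) msg else TRUE
})

#' Marker-anchored network module
#'
#' A subset of [MINetwork-class] nodes extracted by [extractModule()] around
#' marker-bearing anchor nodes, with mutual-first-neighbour hub nodes.
#'
#' @slot moduleId character scalar.
#' @slot nodeIds character, all module nodes.
#' @slot anchorIds character, marker-bearing seed nodes (subset of nodeIds).
#' @slot hubIds character, mutual-first-neighbour nodes (subset of nodeIds).
#' @slot absentSeeds character, requested seeds missing from the network.
#' @export
setClass("GRNModule", representation(
  moduleId = "character", nodeIds = "character", anchorIds = "character",
  hubIds = "character", absentSeeds = "character"
))

setValidity("GRNModule", function(object) {
  msg <- character()
  if (length(object@moduleId) != 1L) msg <- c(msg, "moduleId must be scalar")
  if (!all(object@anchorIds %in% object@nodeIds))
    msg <- c(msg, "anchors must be module nodes")
  if (!all(object@hubIds %in% object@nodeIds))
    msg <- c(msg, "hubs must be module nodes")
  if (length(msg)) msg else TRUE
})

#' Ground-truth regulator network of the synthetic generator
#'
#' The planted regulator graph behind a [SyntheticDataset-class]: two
#' disjoint marker modules ("A" and "B"), each a set of anchor regulators
#' plus one hub adjacent to all of them, embedded among background
#' regulators with sparse random edges.
#'
#' @slot nodes character, regulator ids.
#' @slot edges data.frame with columns `nodeA`, `nodeB` (undirected, simple).
#' @slot moduleLabels named character, node -> `"A"`, `"B"` or
#'   `"background"`.
#' @slot hubs named character `c(A = ..., B = ...)`.
#' @slot anchors list with character elements `A` and `B`.
#' @export
setClass("TruthNetwork", representation(
  nodes = "character", edges = "data.frame", moduleLabels = "character",
  hubs = "character", anchors = "list"
))

setValidity("TruthNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (nrow(e) && !all(c(e$nodeA, e$nodeB) %in% object@nodes))
    msg <- c(msg, "edges refer to unknown nodes")
  if (length(intersect(object@anchors$A, object@anchors$B)))
    msg <- c(msg, "modules A and B must be disjoint")
  adj <- paste(c(e$nodeA, e$nodeB), c(e$nodeB, e$nodeA))
  for (m in c("A", "B")) {
    hub <- object@hubs[[m]]
    if (!all(paste(hub, object@anchors[[m]]) %in% adj))
      msg <- c(msg, sprintf("hub of module %s must be adjacent to all its anchors", m))
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic benchmark dataset with planted truth
#'
#' Output of [simulateDataset()]: negative-binomial counts over the
#' damage-repair design, the planted [TruthNetwork-class], the true
#' gene-to-regulator map, the six planted marker genes (4 in module A, 2 in
#' module B), a partially annotated gene table and the true damage-response
#' gene set.
#'
#' @slot experiment [MantleExperiment-class] of counts with design.
#' @slot truth [TruthNetwork-class].
#' @slot geneCluster named character, gene id -> true regulator id.
#' @slot markers data.frame with columns `marker_id`, `gene_id`, `module`.
#' @slot annotations data.frame with columns `gene_id`, `description`,
#'   `terms` (';'-separated `namespace:term` tokens, possibly empty).
#' @slot damageGenes character, true damage-response gene ids.
#' @slot params list, the [simParams()] used.
#' @export
setClass("SyntheticDataset", representation(
  experiment = "MantleExperiment", truth = "TruthNetwork",
  geneCluster = "character", markers = "data.frame",
  annotations = "data.frame", damageGenes = "character", params = "list"
))

setValidity("SyntheticDataset", function(object) {
  msg <- character()
  genes <- rownames(object@experiment)
  if (!all(object@markers$gene_id %in% genes))
    msg <- c(msg, "marker genes must exist in the count matrix")
  tab <- table(object@markers$module)
  split_ok <- identical(as.integer(tab[c("A", "B")]), c(4L, 2L))
  if (!split_ok && isTRUE(object@params$marker_split_42))
    msg <- c(msg, "marker split must be 4 (module A) / 2 (module B)")
  if (!all(names(object@geneCluster) %in% genes))
    msg <- c(msg, "geneCluster refers to unknown genes")
  if (length(msg)) msg else TRUE
})
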