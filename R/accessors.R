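#' @rdname mantleGRN-accessors
#' @export
setMethod("valueKind", "MantleExperiment", function(x) x@valueKind)

#' @rdname mantleGRN-accessors
#' @export
setMethod("exprValues", "MantleExperiment", function(x) assay(x, "values"))

#' @rdname mantleGRN-accessors
#' @export
setMethod("sampleDesign", "MantleExperiment", function(x) {
  as.data.frame(colData(x))
})

#' @rdname mantleGRN-accessors
#' @export
setMethod("clusterAssignment", "SotaClustering", function(x) x@assignment)

#' @rdname mantleGRN-accessors
#' @export
setMethod("clusterIds", "SotaClustering", function(x) x@clusterIds)

#' @rdname mantleGRN-accessors
#' @export
setMethod("networkNodes", "MINetwork", function(x) x@nodeIds)

#' @rdname mantleGRN-accessors
#' @export
setMethod("networkEdges", "MINetwork", function(x) x@edges)

#' @rdname mantleGRN-accessors
#' @export
setMethod("keptEdges", "MINetwork", function(x) {
  x@edges[x@edges$status == "kept", , drop = FALSE]
})

#' @rdname mantleGRN-accessors
#' @export
setMethod("miThreshold", "MINetwork", function(x) x@threshold)

#' @rdname mantleGRN-accessors
#' @export
setMethod("moduleNodes", "GRNModule", function(x) x@nodeIds)

#' @rdname mantleGRN-accessors
#' @export
setMethod("anchorNodes", "GRNModule", function(x) x@anchorIds)

#' @rdname mantleGRN-accessors
#' @export
setMethod("hubNodes", "GRNModule", function(x) x@hubIds)

#' @rdname mantleGRN-accessors
#' @export
setMethod("truthNetwork", "SyntheticDataset", function(x) x@truth)

#' @rdname mantleGRN-accessors
#' @export
setMethod("markerGenes", "SyntheticDataset", function(x) x@markers)

#' @rdname mantleGRN-accessors
#' @export
setMethod("geneAnnotations", "SyntheticDataset", function(x) x@annotations)

#' @rdname mantleGRN-accessors
#' @export
setMethod("damageGenes", "SyntheticDataset", function(x) x@damageGenes)

#' @rdname mantleGRN-accessors
#' @export
setMethod("clusterAssignment", "SyntheticDataset", function(x) x@geneCluster)

#' @describeIn MantleExperiment-class compact display
#' @param object a `MantleExperiment`
#' @export
setMethod("show", "MantleExperiment", function(object) {
  cat(sprintf("MantleExperiment: %d genes x %d samples [%s]\n",
              nrow(object), ncol(object), object@valueKind))
  callNextMethod()
})

#' @describeIn SotaClustering-class compact display
#' @param object a `SotaClustering`
#' @export
setMethod("show", "SotaClustering", function(object) {
  cat(sprintf(
    "SotaClustering: %d genes in %d clusters (%d tree nodes, total error %.4g)\n",
    length(object@assignment), length(object@clusterIds),
    nrow(object@tree), object@totalError))
})

#' @describeIn MINetwork-class compact display
#' @param object a `MINetwork`
#' @export
setMethod("show", "MINetwork", function(object) {
  st <- table(factor(object@edges$status,
                     c("kept", "removed_by_threshold", "removed_by_dpi")))
  cat(sprintf(
    "MINetwork: %d nodes, %d kept edges (%d below threshold, %d pruned by DPI; threshold %.4g nats)\n",
    length(object@nodeIds), st[["kept"]], st[["removed_by_threshold"]],
    st[["removed_by_dpi"]], object@threshold))
})

#' @describeIn GRNModule-class compact display
#' @param object a `GRNModule`
#' @export
setMethod("show", "GRNModule", function(object) {
  cat(sprintf("GRNModule '%s': %d nodes (%d anchors, %d hubs)\n",
              object@moduleId, length(object@nodeIds),
              length(object@anchorIds), length(object@hubIds)))
  if (length(object@absentSeeds))
    cat("  absent seeds:", paste(object@absentSeeds, collapse = ", "), "\n")
})

#' @describeIn TruthNetwork-class compact display
#' @param object a `TruthNetwork`
#' @export
setMethod("show", "TruthNetwork", function(object) {
  cat(sprintf(
    "TruthNetwork: %d regulators, %d edges; module A %d+hub, module B %d+hub\n",
    length(object@nodes), nrow(object@edges),
    length(object@anchors$A), length(object@anchors$B)))
})

#' @describeIn SyntheticDataset-class compact display
#' @param object a `SyntheticDataset`
#' @export
setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf(
    "SyntheticDataset: %d genes x %d samples, %d regulators, %d markers, %d damage-response genes\n",
    nrow(object@experiment), ncol(object@experiment),
    length(object@truth@nodes), nrow(object@markers),
    length(object@damageGenes)))
})
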