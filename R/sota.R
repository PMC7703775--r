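#' Parameters for SOTA clustering
#'
#' The Self-Organizing Tree Algorithm grows a binary tree of prototype
#' "cells". Winner, mother and sister learning rates must satisfy
#' `alphaWinner > alphaMother > alphaSister > 0`, and at least one stopping
#' rule must be active (a finite `maxCells` or a positive
#' `variabilityThreshold`).
#'
#' @param distanceMetric `"pearson"` (d = (1 - r)/2, in \[0, 1\]) or
#'   `"euclidean"`.
#' @param alphaWinner,alphaMother,alphaSister learning rates in (0, 1).
#' @param cycleEpsilon relative-error convergence tolerance of a training
#'   cycle.
#' @param maxCells cap on the number of cells (`Inf` for unbounded, in which
#'   case `variabilityThreshold` must be positive).
#' @param variabilityThreshold stop growing once every cell's variability
#'   (maximum pairwise member distance) is at or below this value.
#' @param maxEpochsPerCycle cap on epochs within one cycle.
#' @param seed integer seed for the deterministic prototype jitter.
#' @return A validated list of class `"SotaParams"`.
#' @export
sotaParams <- function(distanceMetric = c("pearson", "euclidean"),
                       alphaWinner = 0.01, alphaMother = 0.005,
                       alphaSister = 0.001, cycleEpsilon = 1e-4,
                       maxCells = Inf, variabilityThreshold = 0,
                       maxEpochsPerCycle = 50L, seed = 1L) {
  distanceMetric <- match.arg(distanceMetric)
  if (!(alphaWinner > alphaMother && alphaMother > alphaSister &&
        alphaSister > 0 && alphaWinner < 1))
    stop("learning rates must satisfy 1 > alphaWinner > alphaMother > alphaSister > 0")
  if (cycleEpsilon <= 0) stop("cycleEpsilon must be positive")
  if (variabilityThreshold < 0) stop("variabilityThreshold must be non-negative")
  if (!is.finite(maxCells) && variabilityThreshold <= 0)
    stop("at least one stopping rule must be active: ",
         "bound maxCells or set variabilityThreshold > 0")
  if (is.finite(maxCells) && maxCells < 1) stop("maxCells must be positive")
  if (maxEpochsPerCycle < 1) stop("maxEpochsPerCycle must be positive")
  structure(list(distanceMetric = distanceMetric, alphaWinner = alphaWinner,
                 alphaMother = alphaMother, alphaSister = alphaSister,
                 cycleEpsilon = cycleEpsilon, maxCells = maxCells,
                 variabilityThreshold = variabilityThreshold,
                 maxEpochsPerCycle = as.integer(maxEpochsPerCycle),
                 seed = as.integer(seed)),
            class = "SotaParams")
}

#' Distance between two expression profiles
#'
#' Pearson distance `d = (1 - r)/2` maps perfect correlation to 0 and
#' perfect anticorrelation to 1 (shape-based co-expression); euclidean is
#' the standard L2 norm. Under the pearson metric a constant profile has no
#' defined correlation; its distance to anything is fixed at the
#' uninformative midpoint 0.5 (constant genes should be filtered upstream).
#'
#' @param a,b numeric vectors of equal length (>= 2).
#' @param metric `"pearson"` or `"euclidean"`.
#' @return A non-negative scalar distance.
#' @examples
#' profileDistance(c(1, 2, 3), c(3, 2, 1))  # r = -1 -> 1
#' @export
profileDistance <- function(a, b, metric = c("pearson", "euclidean")) {
  metric <- match.arg(metric)
  if (length(a) != length(b)) stop("profiles must have equal length")
  if (length(a) < 2L) stop("profiles must have dimension >= 2")
  if (metric == "euclidean") return(sqrt(sum((a - b)^2)))
  if (sd(a) == 0 || sd(b) == 0) return(0.5)
  (1 - cor(a, b)) / 2
}

#' Cluster expression profiles with the Self-Organizing Tree Algorithm
#'
#' Grows a binary tree of prototype cells: the root spawns two daughter
#' cells at the global centroid (plus seeded jitter); within a cycle every
#' profile is presented in turn, moving the winning cell's prototype toward
#' it by `alphaWinner` (and, when the winner's sibling is still a leaf, the
#' mother and sister prototypes by their rates); once the relative change in
#' total assignment error falls below `cycleEpsilon` the cell with the
#' largest resource (mean member distance) splits. Growth stops when every
#' cell's variability is at or below `variabilityThreshold` or the cell
#' count reaches `maxCells`. Deterministic given `params$seed`.
#'
#' @param x a log-expression [MantleExperiment-class] (counts are accepted
#'   with a warning and clustered as-is).
#' @param params a [sotaParams()] object.
#' @return A [SotaClustering-class]; cluster ids are `"c<node>"` labels of
#'   the non-empty cells.
#' @export
runSota <- function(x, params = sotaParams(maxCells = 16)) {
  stopifnot(is(x, "MantleExperiment"), inherits(params, "SotaParams"))
  v <- exprValues(x)
  if (nrow(v) < 1L) stop("at least one gene is required")
  if (ncol(v) < 2L) stop("at least two samples are required")
  if (valueKind(x) == "counts")
    warning("clustering raw counts; cpmLogTransform() is recommended")
  max_cells <- if (is.finite(params$maxCells)) as.integer(params$maxCells)
               else nrow(v)
  metric <- match(params$distanceMetric, c("pearson", "euclidean")) - 1L
  fit <- withr::with_seed(params$seed, .sota_fit_cpp(
    v, metric, params$alphaWinner, params$alphaMother, params$alphaSister,
    params$cycleEpsilon, max_cells, params$variabilityThreshold,
    params$maxEpochsPerCycle))
  tree <- data.frame(node = seq_along(fit$parent), parent = fit$parent,
                     left = fit$left, right = fit$right, isCell = fit$isCell)
  assignment <- setNames(paste0("c", fit$assignment), rownames(v))
  ids <- paste0("c", sort(unique(fit$assignment)))
  proto <- fit$prototypes
  dimnames(proto) <- list(paste0("c", tree$node), colnames(v))
  new("SotaClustering", prototypes = proto, tree = tree,
      assignment = assignment, clusterIds = ids,
      totalError = fit$totalError, params = unclass(params))
}

#' Mean expression profile of each cluster
#'
#' One row per cluster id, the arithmetic mean of its member genes' rows;
#' these centroid profiles are the nodes of the inferred network.
#'
#' @param clustering a [SotaClustering-class] (or a named character vector
#'   mapping gene id to cluster id).
#' @param x a [MantleExperiment-class] containing every assigned gene.
#' @return A [MantleExperiment-class] of cluster centroids (clusters x
#'   samples); centroids are continuous summaries, so `valueKind` is always
#'   `"log_expression"`.
#' @export
assignmentCentroids <- function(clustering, x) {
  asg <- if (is(clustering, "SotaClustering")) clusterAssignment(clustering)
         else clustering
  stopifnot(is(x, "MantleExperiment"))
  v <- exprValues(x)
  missing_genes <- setdiff(names(asg), rownames(v))
  if (length(missing_genes))
    stop("assignment references gene(s) absent from the matrix: ",
         paste(head(missing_genes, 5L), collapse = ", "))
  ids <- if (is(clustering, "SotaClustering")) clusterIds(clustering)
         else unique(asg)
  cent <- t(vapply(ids, function(cl) {
    colMeans(v[names(asg)[asg == cl], , drop = FALSE])
  }, numeric(ncol(v))))
  dimnames(cent) <- list(ids, colnames(v))
  MantleExperiment(cent, design = .design_or_null(x),
                   valueKind = "log_expression")
}
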