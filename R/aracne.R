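#' Parameters for relevance-network inference
#'
#' @param estimator mutual-information estimator: `"gaussian_kde"` (Gaussian
#'   product kernels on rank-transformed margins) or `"binning"`
#'   (equal-frequency discretization, plug-in MI).
#' @param bandwidthRule bandwidth rule for the kernel estimator;
#'   `"silverman"` is `h = 1.06 * sd * n^(-1/5)` per margin after the rank
#'   transform.
#' @param nBins number of equal-frequency bins for the binning estimator.
#' @param nPermutations size of the permutation null sample used to
#'   calibrate the MI significance threshold (>= 10).
#' @param alpha significance level in (0, 1) for the threshold (the
#'   `1 - alpha` null quantile).
#' @param dpiTolerance Data Processing Inequality tolerance `epsilon` in
#'   \[0, 1\]; the weakest edge of a triangle is pruned only when its MI is
#'   below `(1 - epsilon)` times the smaller of the other two.
#' @param seed integer seed governing permutations.
#' @return A validated list of class `"AracneParams"`.
#' @export
aracneParams <- function(estimator = c("gaussian_kde", "binning"),
                         bandwidthRule = "silverman", nBins = 8L,
                         nPermutations = 1000L, alpha = 0.05,
                         dpiTolerance = 0.15, seed = 1L) {
  estimator <- match.arg(estimator)
  if (!identical(bandwidthRule, "silverman"))
    stop("unknown bandwidthRule: ", bandwidthRule)
  if (dpiTolerance < 0 || dpiTolerance > 1)
    stop("dpiTolerance must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (nPermutations < 10) stop("nPermutations must be >= 10")
  if (nBins < 2) stop("nBins must be >= 2")
  structure(list(estimator = estimator, bandwidthRule = bandwidthRule,
                 nBins = as.integer(nBins),
                 nPermutations = as.integer(nPermutations), alpha = alpha,
                 dpiTolerance = dpiTolerance, seed = as.integer(seed)),
            class = "AracneParams")
}

.rank_unit <- function(x) (rank(x, ties.method = "average") - 0.5) / length(x)

#' Estimate mutual information between two profiles
#'
#' Both margins are first rank-transformed to `(rank - 0.5)/n`, which makes
#' the estimate invariant to strictly monotone transforms of either input.
#' The kernel estimator averages `log f(u_i, v_i) / (fu(u_i) fv(v_i))` over
#' the sample with Gaussian product kernels; the binning estimator computes
#' plug-in MI from an equal-frequency contingency table. Estimates are in
#' nats, clipped below at zero, and symmetric in `(x, y)`.
#'
#' @param x,y numeric vectors of equal length `n >= 8` with finite values.
#' @param params an [aracneParams()] object.
#' @return Non-negative MI estimate in nats.
#' @examples
#' set.seed(1)
#' x <- rnorm(200); y <- x + rnorm(200, sd = 0.5)
#' estimateMI(x, y, aracneParams())
#' @export
estimateMI <- function(x, y, params = aracneParams()) {
  stopifnot(inherits(params, "AracneParams"))
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 8L) stop("at least 8 paired observations are required")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("x and y must be finite")
  u <- .rank_unit(x)
  v <- .rank_unit(y)
  if (params$estimator == "gaussian_kde") {
    hu <- 1.06 * sd(u) * n^(-1 / 5)
    hv <- 1.06 * sd(v) * n^(-1 / 5)
    return(.kde_mi_cpp(u, v, hu, hv))
  }
  b <- params$nBins
  bu <- ceiling(u * b)
  bv <- ceiling(v * b)
  tab <- table(bu, bv) / n
  pu <- rowSums(tab)
  pv <- colSums(tab)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(pu, pv)[nz]))
  max(0, mi)
}

#' Permutation-calibrated MI significance threshold
#'
#' Builds a null MI sample by repeatedly drawing two node profiles,
#' permuting each independently, and estimating their MI; returns the
#' `1 - alpha` empirical quantile. Deterministic given `params$seed`.
#'
#' @param centroids a [MantleExperiment-class] of node profiles (>= 2 rows).
#' @param params an [aracneParams()] object.
#' @return The MI threshold (nats).
#' @export
calibrateMIThreshold <- function(centroids, params = aracneParams()) {
  stopifnot(is(centroids, "MantleExperiment"),
            inherits(params, "AracneParams"))
  v <- exprValues(centroids)
  if (nrow(v) < 2L) stop("at least two node profiles are required")
  null_mi <- withr::with_seed(params$seed, vapply(
    seq_len(params$nPermutations), function(b) {
      ij <- sample.int(nrow(v), 2L)
      estimateMI(sample(v[ij[1L], ]), sample(v[ij[2L], ]), params)
    }, numeric(1L)))
  unname(quantile(null_mi, probs = 1 - params$alpha))
}

.edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Prune indirect edges with the Data Processing Inequality
#'
#' For every triangle of kept edges in the input network, the edge with the
#' smallest MI is marked for removal when its MI is below `(1 - tolerance)`
#' times the smaller of the other two; all marks are evaluated against the
#' input graph and applied simultaneously. An exact tie for the smallest
#' edge removes none of the tied edges.
#'
#' @param network a [MINetwork-class].
#' @param tolerance DPI tolerance in \[0, 1\] (1 disables pruning).
#' @return The network with pruned edges re-flagged `removed_by_dpi`.
#' @export
applyDPI <- function(network, tolerance = 0.15) {
  stopifnot(is(network, "MINetwork"))
  if (tolerance < 0 || tolerance > 1) stop("tolerance must lie in [0, 1]")
  e <- networkEdges(network)
  kept <- e[e$status == "kept", , drop = FALSE]
  if (nrow(kept) < 3L) return(network)
  g <- igraph::graph_from_data_frame(kept[, c("nodeA", "nodeB")],
                                     directed = FALSE,
                                     vertices = networkNodes(network))
  mi_of <- setNames(kept$mi, .edge_key(kept$nodeA, kept$nodeB))
  tri <- igraph::triangles(g)
  drop_keys <- character()
  if (length(tri)) {
    tri <- matrix(igraph::V(g)$name[tri], nrow = 3L)
    for (t in seq_len(ncol(tri))) {
      nd <- tri[, t]
      keys <- .edge_key(nd[c(1L, 1L, 2L)], nd[c(2L, 3L, 3L)])
      mis <- mi_of[keys]
      lo <- which.min(mis)
      if (sum(mis == mis[lo]) > 1L) next
      if (mis[lo] < (1 - tolerance) * min(mis[-lo]))
        drop_keys <- c(drop_keys, keys[lo])
    }
  }
  if (length(drop_keys)) {
    all_keys <- .edge_key(e$nodeA, e$nodeB)
    e$status[all_keys %in% drop_keys & e$status == "kept"] <- "removed_by_dpi"
  }
  initialize(network, edges = e)
}

#' Infer a mutual-information relevance network on cluster centroids
#'
#' Computes MI for all `N(N-1)/2` node pairs, removes edges at or below the
#' permutation-calibrated threshold, then prunes indirect edges with the
#' Data Processing Inequality. Every candidate pair is retained in the edge
#' table with a provenance status. Deterministic given `params$seed`.
#'
#' @param centroids a [MantleExperiment-class] of node profiles (rows), e.g.
#'   from [assignmentCentroids()].
#' @param params an [aracneParams()] object.
#' @return A [MINetwork-class].
#' @export
inferNetwork <- function(centroids, params = aracneParams()) {
  stopifnot(is(centroids, "MantleExperiment"),
            inherits(params, "AracneParams"))
  v <- exprValues(centroids)
  if (nrow(v) < 2L) stop("at least two nodes are required")
  ids <- rownames(v)
  pairs <- utils::combn(length(ids), 2L)
  mi <- vapply(seq_len(ncol(pairs)), function(k) {
    estimateMI(v[pairs[1L, k], ], v[pairs[2L, k], ], params)
  }, numeric(1L))
  threshold <- calibrateMIThreshold(centroids, params)
  edges <- data.frame(nodeA = ids[pairs[1L, ]], nodeB = ids[pairs[2L, ]],
                      mi = mi,
                      status = ifelse(mi > threshold, "kept",
                                      "removed_by_threshold"),
                      stringsAsFactors = FALSE)
  net <- new("MINetwork", nodeIds = ids, edges = edges,
             threshold = threshold, params = unclass(params))
  applyDPI(net, params$dpiTolerance)
}

#' Write the full edge table as TSV
#'
#' Columns `node_a`, `node_b`, `mi`, `status`.
#'
#' @param network a [MINetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(network, path) {
  e <- networkEdges(network)
  write.table(data.frame(node_a = e$nodeA, node_b = e$nodeB, mi = e$mi,
                         status = e$status),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write kept edges in SIF format
#'
#' One line per kept edge: `node_a <TAB> mi <TAB> node_b`.
#'
#' @param network a [MINetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSIF <- function(network, path) {
  k <- keptEdges(network)
  writeLines(sprintf("%s\t%.6g\t%s", k$nodeA, k$mi, k$nodeB), path)
  invisible(path)
}
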