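#' Parameters for damage-response differential expression
#'
#' This module is a deliberately minimal negative-binomial exact test for
#' two-group count comparisons within each time x age stratum: a common
#' moment-based dispersion, a conditional exact test on group totals and
#' Benjamini-Hochberg control within strata.
#'
#' @param alphaFdr FDR level in (0, 1) used to call significance on
#'   adjusted p-values.
#' @param dispersionMethod currently only `"moments_common"`.
#' @param minCountFilter genes whose mean scaled count is at or below this
#'   value are excluded from the common-dispersion median.
#' @param minStrata a gene is a damage-response gene when significant in at
#'   least this many strata (default 1).
#' @return A validated list of class `"DEParams"`.
#' @export
deParams <- function(alphaFdr = 0.05, dispersionMethod = "moments_common",
                     minCountFilter = 5, minStrata = 1L) {
  if (alphaFdr <= 0 || alphaFdr >= 1) stop("alphaFdr must lie in (0, 1)")
  if (!identical(dispersionMethod, "moments_common"))
    stop("unknown dispersionMethod: ", dispersionMethod)
  if (minCountFilter < 0) stop("minCountFilter must be non-negative")
  if (minStrata < 1) stop("minStrata must be >= 1")
  structure(list(alphaFdr = alphaFdr, dispersionMethod = dispersionMethod,
                 minCountFilter = minCountFilter,
                 minStrata = as.integer(minStrata)),
            class = "DEParams")
}

.cpm_scale <- function(counts) {
  libs <- colSums(counts)
  if (any(libs == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[libs == 0], collapse = ", "))
  sweep(counts, 2L, 1e6 / libs, "*")
}

#' Moment estimate of the common negative-binomial dispersion
#'
#' Counts are CPM-scaled, then for each gene the within-group variance is
#' pooled over the two groups and the moment estimate
#' `phi = max(0, (s^2 - mu) / mu^2)` is formed from the pooled variance and
#' the grand mean. The common dispersion is the median over genes whose
#' mean exceeds `minCountFilter` (all-zero genes therefore never
#' contribute).
#'
#' @param x a counts [MantleExperiment-class] or count matrix.
#' @param groups two-level factor over the samples, each level with >= 2
#'   samples.
#' @param minCountFilter scaled-mean cutoff for inclusion in the median.
#' @return Common dispersion estimate `phi >= 0`.
#' @export
estimateCommonDispersion <- function(x, groups, minCountFilter = 5) {
  counts <- if (is(x, "MantleExperiment")) exprValues(x) else as.matrix(x)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L)
    stop("groups must have exactly two levels")
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 samples")
  y <- .cpm_scale(counts)
  idx <- split(seq_along(groups), groups)
  n1 <- length(idx[[1L]]); n2 <- length(idx[[2L]])
  v1 <- apply(y[, idx[[1L]], drop = FALSE], 1L, var)
  v2 <- apply(y[, idx[[2L]], drop = FALSE], 1L, var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mu <- rowMeans(y)
  phi_g <- pmax(0, (s2 - mu) / mu^2)
  usable <- mu > minCountFilter
  if (!any(usable)) return(0)
  median(phi_g[usable])
}

#' Negative-binomial exact test on two count vectors
#'
#' Conditions on the total `s` of both groups. Group totals are modelled as
#' negative binomial with means proportional to group size and dispersion
#' `phi / n` per group (the dispersion of a sum of `n` i.i.d. NB
#' variables); the two-sided p-value sums the probabilities of all splits
#' of `s` no more probable than the observed one. At `phi = 0` this reduces
#' to the exact binomial test of the group-A total against proportion
#' `nA / (nA + nB)`. Equal effective library sizes are assumed: rescale
#' counts first (see [callDamageResponseGenes()]).
#'
#' @param countsA,countsB non-negative integer vectors (the two groups).
#' @param phi common dispersion `>= 0`.
#' @return Two-sided p-value in (0, 1\].
#' @examples
#' nbExactTest(c(1, 2, 3), c(3, 2, 1), phi = 0.1)  # symmetric split -> 1
#' @export
nbExactTest <- function(countsA, countsB, phi) {
  if (any(countsA < 0) || any(countsB < 0)) stop("counts must be non-negative")
  if (any(countsA != round(countsA)) || any(countsB != round(countsB)))
    stop("counts must be integers")
  if (phi < 0) stop("phi must be non-negative")
  sa <- sum(countsA); sb <- sum(countsB); s <- sa + sb
  if (s == 0) return(1)
  na <- length(countsA); nb <- length(countsB)
  k <- 0:s
  if (phi == 0) {
    logp <- dpois(k, lambda = s * na / (na + nb), log = TRUE) +
      dpois(s - k, lambda = s * nb / (na + nb), log = TRUE)
  } else {
    logp <- dnbinom(k, size = na / phi, mu = s * na / (na + nb), log = TRUE) +
      dnbinom(s - k, size = nb / phi, mu = s * nb / (na + nb), log = TRUE)
  }
  logp <- logp - max(logp)
  pr <- exp(logp)
  pr <- pr / sum(pr)
  p_obs <- pr[sa + 1L]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-10)]))
}

#' Benjamini-Hochberg adjustment
#'
#' Validates the inputs and applies the step-up procedure
#' (`stats::p.adjust(method = "BH")`); the mapping is order-preserving.
#'
#' @param pValues numeric vector of p-values in \[0, 1\].
#' @return q-values in \[0, 1\], same order as the input.
#' @export
bhAdjust <- function(pValues) {
  if (any(!is.finite(pValues) | pValues < 0 | pValues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pValues, method = "BH")
}

#' Call time-dependent damage-response genes
#'
#' Within every time x age stratum that has both treatments with at least
#' two replicates each, counts are rescaled to the geometric-mean library
#' size and rounded, a common dispersion is estimated from the two
#' treatment groups, each gene is tested with [nbExactTest()] and
#' Benjamini-Hochberg adjusted within the stratum. A gene is a
#' damage-response gene when significant (`q < alphaFdr`) in at least
#' `params$minStrata` strata.
#'
#' @param x a counts [MantleExperiment-class] whose design has
#'   `time_point`, `age_category` and `treatment` columns.
#' @param params a [deParams()] object.
#' @return A list with `table` (one row per gene x tested stratum:
#'   `gene_id`, `time_point`, `age_category`, `log2FC`, `p`, `q`,
#'   `significant`) and `genes` (the flagged damage-response gene ids).
#' @export
callDamageResponseGenes <- function(x, params = deParams()) {
  stopifnot(is(x, "MantleExperiment"), inherits(params, "DEParams"))
  if (valueKind(x) != "counts") stop("counts are required")
  design <- sampleDesign(x)
  need <- c("time_point", "age_category", "treatment")
  if (!all(need %in% colnames(design)))
    stop("design lacks column(s): ",
         paste(setdiff(need, colnames(design)), collapse = ", "))
  counts <- exprValues(x)
  strata <- interaction(design$time_point, design$age_category, drop = TRUE)
  out <- list()
  for (st in levels(strata)) {
    sel <- strata == st
    trt <- as.character(design$treatment[sel])
    if (sum(trt == "damaged") < 2L || sum(trt == "control") < 2L) next
    cs <- counts[, sel, drop = FALSE]
    libs <- colSums(cs)
    if (any(libs == 0)) next
    target <- exp(mean(log(libs)))
    scaled <- round(sweep(cs, 2L, target / libs, "*"))
    a_idx <- which(trt == "damaged"); b_idx <- which(trt == "control")
    phi <- estimateCommonDispersion(scaled, factor(trt),
                                    minCountFilter = params$minCountFilter)
    pv <- vapply(seq_len(nrow(scaled)), function(g) {
      nbExactTest(scaled[g, a_idx], scaled[g, b_idx], phi)
    }, numeric(1L))
    qv <- bhAdjust(pv)
    lfc <- log2((rowMeans(scaled[, a_idx, drop = FALSE]) + 0.5) /
                  (rowMeans(scaled[, b_idx, drop = FALSE]) + 0.5))
    out[[st]] <- data.frame(
      gene_id = rownames(counts),
      time_point = as.character(design$time_point[sel][1L]),
      age_category = as.character(design$age_category[sel][1L]),
      log2FC = lfc, p = pv, q = qv,
      significant = qv < params$alphaFdr, row.names = NULL)
  }
  if (!length(out)) stop("no testable stratum (need both treatments with >= 2 replicates)")
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  hits <- table(tab$gene_id[tab$significant])
  list(table = tab,
       genes = sort(names(hits)[hits >= params$minStrata]))
}

#' Map differential-expression status onto network nodes
#'
#' A node is flagged when at least one member gene of its cluster is in the
#' damage-response gene set. DE genes not covered by the assignment are
#' ignored with a warning.
#'
#' @param network a [MINetwork-class].
#' @param assignment a [SotaClustering-class] or named character vector
#'   (gene id -> cluster id).
#' @param deGenes character vector of damage-response gene ids.
#' @return data.frame with columns `node_id`, `de_flag`, `n_de_members`.
#' @export
mapDEToNetwork <- function(network, assignment, deGenes) {
  stopifnot(is(network, "MINetwork"))
  asg <- if (is(assignment, "SotaClustering")) clusterAssignment(assignment)
         else assignment
  unknown <- setdiff(deGenes, names(asg))
  if (length(unknown))
    warning(length(unknown), " DE gene(s) not covered by the assignment; ignored")
  de_in <- intersect(deGenes, names(asg))
  cnt <- table(asg[de_in])
  nodes <- networkNodes(network)
  n_de <- as.integer(cnt[nodes])
  n_de[is.na(n_de)] <- 0L
  data.frame(node_id = nodes, de_flag = n_de > 0L, n_de_members = n_de,
             row.names = NULL)
}
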