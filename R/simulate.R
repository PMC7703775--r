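#' Study design of the damage-repair time course
#'
#' Default design: six post-perturbation time points, three age categories
#' and two treatments. Per-cell replicate counts are 2, raised to 3 at the
#' first time point (the acute damage response is the phase of interest),
#' which totals 78 sampled animals. The total is the anchored constraint;
#' the per-cell breakdown is this generator's explicit assumption.
#'
#' @param timePoints character vector of ordered time point labels.
#' @param ageCategories subset of juvenile/adolescent/adult.
#' @param treatments subset of damaged/control.
#' @param allocation `NULL` for the default allocation, or a data.frame
#'   with columns `time_point`, `age_category`, `treatment`, `n`.
#' @return A list of class `"DesignSpec"` with the factors and the
#'   allocation table (`sum(allocation$n)` samples in total).
#' @examples
#' sum(designSpec()$allocation$n)  # 78
#' @export
designSpec <- function(timePoints = paste0("t", 1:6),
                       ageCategories = .AGE_LEVELS,
                       treatments = .TREATMENT_LEVELS,
                       allocation = NULL) {
  if (!all(ageCategories %in% .AGE_LEVELS))
    stop("ageCategories must be drawn from ", paste(.AGE_LEVELS, collapse = "/"))
  if (!all(treatments %in% .TREATMENT_LEVELS))
    stop("treatments must be drawn from ", paste(.TREATMENT_LEVELS, collapse = "/"))
  if (is.null(allocation)) {
    allocation <- expand.grid(time_point = timePoints,
                              age_category = ageCategories,
                              treatment = treatments,
                              stringsAsFactors = FALSE)
    allocation$n <- ifelse(allocation$time_point == timePoints[1L], 3L, 2L)
  } else {
    need <- c("time_point", "age_category", "treatment", "n")
    if (!all(need %in% colnames(allocation)))
      stop("allocation needs columns ", paste(need, collapse = ", "))
    if (any(allocation$n < 0)) stop("allocation counts must be non-negative")
  }
  structure(list(timePoints = timePoints, ageCategories = ageCategories,
                 treatments = treatments, allocation = allocation),
            class = "DesignSpec")
}

#' Parameters of the synthetic expression generator
#'
#' A linear-Gaussian latent regulator network with a negative-binomial
#' observation layer: each regulator's activity is its own unit Gaussian
#' root signal plus `edgeEffect` times the root signals of its network
#' neighbours; genes load on their regulator's activity with additive
#' Gaussian noise on the log2 scale, and counts are drawn NB with
#' dispersion `phi`. Shell damage perturbs the module-A hub's root signal
#' by `damageLog2FC` scaled by a decaying time profile, so the damage
#' response propagates through the planted network.
#'
#' @param nRegulators number of regulator nodes (>= 10).
#' @param genesPerCluster genes emitted per regulator.
#' @param loading gene loading on the regulator activity (log2 units per
#'   activity unit).
#' @param geneNoiseSd per-gene log2-scale noise standard deviation.
#' @param edgeEffect propagation weight along true edges (within-cluster
#'   correlation and edge-detectability dial).
#' @param damageLog2FC peak log2 fold change injected into the module-A
#'   hub's root signal in damaged samples.
#' @param damageTimeProfile multiplier per time point (recycled/truncated
#'   to the design's time points).
#' @param phi negative-binomial dispersion (0 gives Poisson counts).
#' @param unannotatedFraction fraction of genes left without annotation
#'   (default 0.54, the unannotated share of module genes in mantle
#'   transcriptomes this generator emulates).
#' @param anchorsA,anchorsB anchor counts of the two planted marker
#'   modules (markers split 4/2 by default).
#' @param intraModuleEdgeProb probability of an extra anchor-anchor edge
#'   inside a module (beyond the hub star).
#' @param backgroundEdgeProb edge probability among background regulators.
#' @param baselineLog2Range range of per-gene baseline log2 expression.
#' @param seed integer seed; every generator output is reproducible from
#'   (design, params, seed).
#' @return A validated list of class `"SimParams"`.
#' @export
simParams <- function(nRegulators = 60L, genesPerCluster = 10L,
                      loading = 1.4, geneNoiseSd = 0.4, edgeEffect = 0.45,
                      damageLog2FC = 2.0,
                      damageTimeProfile = c(1, 0.8, 0.6, 0.4, 0.2, 0.1),
                      phi = 0.2, unannotatedFraction = 0.54,
                      anchorsA = 4L, anchorsB = 2L,
                      intraModuleEdgeProb = 0.0,
                      backgroundEdgeProb = 0.03,
                      baselineLog2Range = c(5, 9), seed = 1L) {
  if (nRegulators < 10) stop("nRegulators must be >= 10")
  if (genesPerCluster < 1) stop("genesPerCluster must be >= 1")
  if (geneNoiseSd <= 0 || loading <= 0) stop("variances must be positive")
  if (phi < 0) stop("phi must be non-negative")
  if (unannotatedFraction < 0 || unannotatedFraction > 1)
    stop("unannotatedFraction must lie in [0, 1]")
  if (anchorsA + anchorsB + 2 > nRegulators)
    stop("module sizes exceed nRegulators")
  if (intraModuleEdgeProb < 0 || intraModuleEdgeProb > 1 ||
      backgroundEdgeProb < 0 || backgroundEdgeProb > 1)
    stop("edge probabilities must lie in [0, 1]")
  structure(list(nRegulators = as.integer(nRegulators),
                 genesPerCluster = as.integer(genesPerCluster),
                 loading = loading, geneNoiseSd = geneNoiseSd,
                 edgeEffect = edgeEffect, damageLog2FC = damageLog2FC,
                 damageTimeProfile = damageTimeProfile, phi = phi,
                 unannotatedFraction = unannotatedFraction,
                 anchorsA = as.integer(anchorsA),
                 anchorsB = as.integer(anchorsB),
                 intraModuleEdgeProb = intraModuleEdgeProb,
                 backgroundEdgeProb = backgroundEdgeProb,
                 baselineLog2Range = baselineLog2Range,
                 seed = as.integer(seed),
                 marker_split_42 = (anchorsA == 4L && anchorsB == 2L)),
            class = "SimParams")
}

#' Simulate the planted ground-truth regulator network
#'
#' Two disjoint marker modules, each a hub adjacent to all of its anchors
#' (plus optional sparse anchor-anchor edges), embedded among background
#' regulators carrying sparse random edges. No edges connect module A to
#' module B. Reproducible from `params$seed`.
#'
#' @param params a [simParams()] object.
#' @return A [TruthNetwork-class].
#' @export
simulateTruthNetwork <- function(params = simParams()) {
  stopifnot(inherits(params, "SimParams"))
  n <- params$nRegulators
  nodes <- sprintf("r%02d", seq_len(n))
  hubA <- nodes[1L]
  anchA <- nodes[1L + seq_len(params$anchorsA)]
  hubB <- nodes[1L + params$anchorsA + 1L]
  anchB <- nodes[2L + params$anchorsA + seq_len(params$anchorsB)]
  background <- setdiff(nodes, c(hubA, anchA, hubB, anchB))
  withr::with_seed(params$seed, {
    edges <- rbind(data.frame(nodeA = hubA, nodeB = anchA),
                   data.frame(nodeA = hubB, nodeB = anchB))
    for (mod in list(anchA, anchB)) {
      if (length(mod) >= 2L) {
        prs <- utils::combn(mod, 2L)
        pick <- runif(ncol(prs)) < params$intraModuleEdgeProb
        if (any(pick))
          edges <- rbind(edges, data.frame(nodeA = prs[1L, pick],
                                           nodeB = prs[2L, pick]))
      }
    }
    if (length(background) >= 2L) {
      prs <- utils::combn(background, 2L)
      pick <- runif(ncol(prs)) < params$backgroundEdgeProb
      if (any(pick))
        edges <- rbind(edges, data.frame(nodeA = prs[1L, pick],
                                         nodeB = prs[2L, pick]))
    }
    labels <- setNames(rep("background", n), nodes)
    labels[c(hubA, anchA)] <- "A"
    labels[c(hubB, anchB)] <- "B"
    new("TruthNetwork", nodes = nodes, edges = edges, moduleLabels = labels,
        hubs = c(A = hubA, B = hubB), anchors = list(A = anchA, B = anchB))
  })
}

.MARKER_IDS <- list(A = c("pif", "mytilin", "tyrA", "chitin_binding"),
                    B = c("tyrB", "contig01043"))

.ANNOT_POOL <- list(
  "Receptor and signal transduction" = c(
    "Toll-like receptor 2", "Toll-like receptor 4", "Notch 2",
    "FGF receptor 3", "Forkhead box protein J1",
    "Thioredoxin domain-containing protein 11", "Akirin-1"),
  "Ion transport" = c(
    "Solute carrier family 23 member 1", "Sodium/calcium exchanger 3",
    "Pendrin", "Regucalcin", "Sodium/glucose cotransporter 4"),
  "Shell matrix" = c(
    "Insoluble matrix shell protein 1", "PIF-like isoform X1",
    "cartilage matrix protein-like"),
  "Biomineralization enzyme" = c(
    "Carbonic anhydrase 2-like isoform X3", "Tyrosinase",
    "Alkaline phosphatase, tissue-nonspecific"),
  "Protein folding/chaperoning" = c(
    "HSP70 12B", "HSP 90A", "Heat shock factor-binding protein 1"),
  "Protein transport" = c("Protein transport protein Sec61 alpha-2"),
  "other" = c(
    "ATP synthase subunit beta", "Elongation factor 1-alpha",
    "Ubiquitin-conjugating enzyme E2", "Histone H3", "Ferritin",
    "Actin, cytoplasmic", "Tubulin alpha chain", "Cytochrome c oxidase"))

.TERM_POOL <- c("KEGG:ko03010_ribosome", "KEGG:ko04141_protein_processing",
                "GO_MF:GO:0005509_calcium_ion_binding",
                "GO_MF:GO:0004089_carbonate_dehydratase_activity",
                "GO_BP:GO:0006412_translation",
                "GO_BP:GO:0006811_ion_transport",
                "GO_BP:GO:0015031_protein_transport",
                "GO_CC:GO:0005576_extracellular_region",
                "GO_CC:GO:0005840_ribosome")

#' Simulate a benchmark dataset with planted modular structure
#'
#' Draws the latent regulator activities over the planted network, injects
#' the treatment x time damage perturbation into the module-A hub, emits
#' `genesPerCluster` genes per regulator with NB(mean, phi) counts, places
#' the six marker genes (four in module-A anchor clusters, two in
#' module-B anchor clusters), and plants a partially empty annotation
#' table whose descriptions match the default lexicon. The true
#' damage-response genes are exactly the members of the damage-affected
#' (module A) clusters.
#'
#' @param design a [designSpec()] object.
#' @param params a [simParams()] object.
#' @return A [SyntheticDataset-class].
#' @export
simulateDataset <- function(design = designSpec(), params = simParams()) {
  stopifnot(inherits(design, "DesignSpec"), inherits(params, "SimParams"))
  truth <- simulateTruthNetwork(params)
  alloc <- design$allocation
  alloc <- alloc[rep(seq_len(nrow(alloc)), alloc$n), , drop = FALSE]
  n_samp <- nrow(alloc)
  samples <- data.frame(
    sample_id = sprintf("s%03d", seq_len(n_samp)),
    time_point = as.character(alloc$time_point),
    age_category = as.character(alloc$age_category),
    treatment = as.character(alloc$treatment), row.names = NULL)
  regs <- truth@nodes
  n_reg <- length(regs)
  genes <- sprintf("g%04d", seq_len(n_reg * params$genesPerCluster))
  gene_cluster <- setNames(rep(regs, each = params$genesPerCluster), genes)

  adj <- matrix(0, n_reg, n_reg, dimnames = list(regs, regs))
  e <- truth@edges
  adj[cbind(e$nodeA, e$nodeB)] <- 1
  adj[cbind(e$nodeB, e$nodeA)] <- 1

  tprof <- rep_len(params$damageTimeProfile, length(design$timePoints))
  names(tprof) <- design$timePoints

  withr::with_seed(params$seed + 1L, {
    root <- matrix(rnorm(n_reg * n_samp), n_reg, n_samp,
                   dimnames = list(regs, samples$sample_id))
    shift <- params$damageLog2FC * tprof[samples$time_point] *
      (samples$treatment == "damaged")
    root[truth@hubs[["A"]], ] <- root[truth@hubs[["A"]], ] + shift
    activity <- root + params$edgeEffect * (adj %*% root)

    baseline <- runif(length(genes), params$baselineLog2Range[1L],
                      params$baselineLog2Range[2L])
    log2mean <- baseline +
      params$loading * activity[gene_cluster, , drop = FALSE] +
      matrix(rnorm(length(genes) * n_samp, sd = params$geneNoiseSd),
             length(genes), n_samp)
    mu <- 2^log2mean
    counts <- if (params$phi > 0)
      matrix(rnbinom(length(mu), mu = mu, size = 1 / params$phi),
             nrow(mu), ncol(mu))
    else matrix(rpois(length(mu), lambda = mu), nrow(mu), ncol(mu))
    dimnames(counts) <- list(genes, samples$sample_id)

    marker_gene <- function(anchor_nodes, ids, label) {
      g <- vapply(anchor_nodes, function(a) {
        names(gene_cluster)[gene_cluster == a][1L]
      }, character(1L))
      data.frame(marker_id = ids, gene_id = unname(g), module = label)
    }
    markers <- rbind(marker_gene(truth@anchors$A, .MARKER_IDS$A, "A"),
                     marker_gene(truth@anchors$B, .MARKER_IDS$B, "B"))

    annotated <- runif(length(genes)) >= params$unannotatedFraction
    cat_pick <- sample(names(.ANNOT_POOL), length(genes), replace = TRUE,
                       prob = c(rep(1, length(.ANNOT_POOL) - 1L), 3))
    desc <- vapply(seq_along(genes), function(i) {
      if (!annotated[i]) return("")
      pool <- .ANNOT_POOL[[cat_pick[i]]]
      pool[sample.int(length(pool), 1L)]
    }, character(1L))
    terms <- vapply(seq_along(genes), function(i) {
      if (!annotated[i]) return("")
      k <- sample.int(3L, 1L)
      paste(sample(.TERM_POOL, k), collapse = ";")
    }, character(1L))
    annotations <- data.frame(gene_id = genes, description = desc,
                              terms = terms, row.names = NULL)

    damage_nodes <- c(truth@hubs[["A"]], truth@anchors$A)
    damage_genes <- names(gene_cluster)[gene_cluster %in% damage_nodes]

    expt <- MantleExperiment(counts, design = samples, valueKind = "counts")
    new("SyntheticDataset", experiment = expt, truth = truth,
        geneCluster = gene_cluster, markers = markers,
        annotations = annotations, damageGenes = sort(damage_genes),
        params = unclass(params))
  })
}

#' Adjusted Rand Index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items
#' (1 = identical, about 0 = random), computed with
#' [mclust::adjustedRandIndex()].
#'
#' @param labelsA,labelsB vectors of equal length.
#' @return ARI scalar.
#' @export
adjustedRand <- function(labelsA, labelsB) {
  stopifnot(length(labelsA) == length(labelsB))
  mclust::adjustedRandIndex(labelsA, labelsB)
}

.dominant_map <- function(inferred_assignment, true_assignment) {
  shared <- intersect(names(inferred_assignment), names(true_assignment))
  vapply(split(true_assignment[shared], inferred_assignment[shared]),
         function(tl) names(sort(table(tl), decreasing = TRUE))[1L],
         character(1L))
}

#' Score recovery of the planted structure
#'
#' Compares a clustering, an inferred network and the extracted marker
#' modules against the generator's truth: (i) Adjusted Rand Index of the
#' gene clustering versus the true gene-to-regulator map; (ii) precision
#' and recall of kept edges after mapping each inferred node to its
#' dominant true regulator (edges collapsing to a single regulator are
#' dropped from both sets); (iii) whether the four module-A markers fall in
#' one extracted module and the two module-B markers in a distinct one,
#' with no cross-contamination of marker nodes; (iv) whether each planted
#' hub is returned among the mutual first neighbours (hub slot) of its
#' module.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param clustering a [SotaClustering-class] (or named gene -> cluster
#'   character vector).
#' @param network the inferred [MINetwork-class].
#' @param modules named list of [GRNModule-class] objects with elements
#'   `A` and `B`.
#' @return A list: `ari`, `edge_precision`, `edge_recall`,
#'   `marker_modules_recovered`, `hub_recovered` (named logical for A and
#'   B), `node_map` (inferred node -> dominant true regulator).
#' @export
evaluateRecovery <- function(dataset, clustering, network, modules) {
  stopifnot(is(dataset, "SyntheticDataset"), is(network, "MINetwork"))
  asg <- if (is(clustering, "SotaClustering")) clusterAssignment(clustering)
         else clustering
  truth <- truthNetwork(dataset)
  true_map <- dataset@geneCluster
  shared <- intersect(names(asg), names(true_map))
  if (!length(shared)) stop("no shared gene ids between assignment and truth")
  ari <- adjustedRand(asg[shared], true_map[shared])

  node_map <- .dominant_map(asg, true_map)
  k <- keptEdges(network)
  mapA <- node_map[k$nodeA]; mapB <- node_map[k$nodeB]
  ok <- !is.na(mapA) & !is.na(mapB) & mapA != mapB
  inferred_pairs <- unique(.edge_key(mapA[ok], mapB[ok]))
  true_pairs <- unique(.edge_key(truth@edges$nodeA, truth@edges$nodeB))
  tp <- length(intersect(inferred_pairs, true_pairs))
  precision <- if (length(inferred_pairs)) tp / length(inferred_pairs) else NA_real_
  recall <- if (length(true_pairs)) tp / length(true_pairs) else NA_real_

  mk <- markerGenes(dataset)
  marker_nodes <- split(unname(asg[mk$gene_id]), mk$module)
  marker_ok <- FALSE
  hub_ok <- c(A = FALSE, B = FALSE)
  if (all(c("A", "B") %in% names(modules))) {
    nodesA <- moduleNodes(modules[["A"]]); nodesB <- moduleNodes(modules[["B"]])
    marker_ok <- all(marker_nodes$A %in% nodesA) &&
      all(marker_nodes$B %in% nodesB) &&
      !any(marker_nodes$B %in% nodesA) && !any(marker_nodes$A %in% nodesB)
    for (m in c("A", "B")) {
      hubs <- hubNodes(modules[[m]])
      hub_ok[m] <- length(hubs) > 0 &&
        truth@hubs[[m]] %in% node_map[hubs]
    }
  }
  list(ari = ari, edge_precision = precision, edge_recall = recall,
       marker_modules_recovered = marker_ok, hub_recovered = hub_ok,
       node_map = node_map)
}

#' Run the full pipeline on a simulated dataset and score recovery
#'
#' Convenience benchmark: simulate counts, CPM-log transform, SOTA
#' clustering (cell cap at 1.2x the number of true regulators, leaving
#' headroom to resolve strongly correlated neighbouring clusters), network
#' inference at `alpha = 0.01` (with ~1800 candidate pairs a 0.05 per-pair
#' level would admit ~90 false edges), marker-seeded module extraction for
#' both marker groups, and recovery scoring. All stage seeds derive from
#' `seed`.
#'
#' @param seed integer master seed.
#' @param design a [designSpec()].
#' @param params a [simParams()] (its `seed` is overridden by `seed`).
#' @param sota a [sotaParams()] or `NULL` for the benchmark default.
#' @param aracne an [aracneParams()] or `NULL` for the default.
#' @return The [evaluateRecovery()] list, plus `dataset`, `clustering`,
#'   `network`, `modules`.
#' @export
benchmarkRecovery <- function(seed = 1L, design = designSpec(),
                              params = simParams(), sota = NULL,
                              aracne = NULL) {
  params$seed <- as.integer(seed)
  if (is.null(sota))
    sota <- sotaParams(maxCells = ceiling(1.2 * params$nRegulators),
                       seed = seed + 101L)
  if (is.null(aracne)) aracne <- aracneParams(alpha = 0.01, seed = seed + 202L)
  ds <- simulateDataset(design, params)
  logx <- cpmLogTransform(ds@experiment)
  cl <- runSota(logx, sota)
  cent <- assignmentCentroids(cl, logx)
  net <- inferNetwork(cent, aracne)
  asg <- clusterAssignment(cl)
  mk <- markerGenes(ds)
  seedsA <- unique(unname(asg[mk$gene_id[mk$module == "A"]]))
  seedsB <- unique(unname(asg[mk$gene_id[mk$module == "B"]]))
  modules <- list(
    A = extractModule(net, seedsA, radius = 1L, moduleId = "A"),
    B = extractModule(net, seedsB, radius = 1L, moduleId = "B"))
  out <- evaluateRecovery(ds, cl, net, modules)
  out$dataset <- ds
  out$clustering <- cl
  out$network <- net
  out$modules <- modules
  out
}
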