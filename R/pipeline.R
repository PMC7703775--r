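.CONFIG_KEYS <- list(
  top = c("seed", "outdir", "log_level", "io", "simulate", "normalize",
          "sota", "aracne", "modules", "de", "characterization"),
  io = c("counts", "metadata", "annotations"),
  simulate = c("n_regulators", "genes_per_cluster", "phi", "damage_log2fc",
               "edge_effect", "unannotated_fraction", "gene_noise_sd",
               "loading"),
  normalize = c("min_cpm", "min_samples", "pseudocount"),
  sota = c("distance_metric", "alpha_winner", "alpha_mother", "alpha_sister",
           "cycle_epsilon", "max_cells", "variability_threshold",
           "max_epochs_per_cycle"),
  aracne = c("estimator", "n_bins", "n_permutations", "alpha",
             "dpi_tolerance"),
  modules = c("radius", "marker_genes"),
  de = c("alpha_fdr", "min_count_filter", "min_strata"),
  characterization = c("min_term_size", "lexicon", "min_connectivity")
)

.check_keys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown))
    stop(sprintf("unknown config key(s) in %s: %s", where,
                 paste(unknown, collapse = ", ")))
}

#' Read and validate a pipeline configuration
#'
#' YAML with a global `seed`, `outdir` and `log_level` plus per-stage
#' blocks (`io` or `simulate`, `normalize`, `sota`, `aracne`, `modules`,
#' `de`, `characterization`). Unknown keys anywhere are rejected before
#' any stage runs.
#'
#' @param path YAML config path, or a list already in that shape.
#' @return Validated config list of class `"PipelineConfig"`.
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  .check_keys(cfg, .CONFIG_KEYS$top, "top level")
  for (blk in intersect(names(cfg), setdiff(names(.CONFIG_KEYS), "top")))
    .check_keys(cfg[[blk]], .CONFIG_KEYS[[blk]], blk)
  if (is.null(cfg$io) && is.null(cfg$simulate))
    stop("config needs an 'io' or a 'simulate' block")
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg$outdir <- if (is.null(cfg$outdir)) "mantleGRN_out" else cfg$outdir
  cfg$log_level <- if (is.null(cfg$log_level)) "info" else cfg$log_level
  if (!cfg$log_level %in% c("debug", "info", "warn"))
    stop("log_level must be debug, info or warn")
  structure(cfg, class = "PipelineConfig")
}

.pipe_log <- function(cfg, level, ...) {
  rank <- c(debug = 1L, info = 2L, warn = 3L)
  if (rank[[level]] >= rank[[cfg$log_level]])
    message(sprintf("[%s] %s", level, paste0(...)))
}

.cfg_get <- function(block, key, default) {
  if (is.null(block[[key]])) default else block[[key]]
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes, in order: data input (or simulation), normalization and
#' filtering, SOTA clustering, network inference, marker-anchored module
#' extraction, damage-response differential expression, enrichment and the
#' functional screen with unannotated-gene prioritization. Each stage
#' writes its declared TSV outputs under `outdir`; a deterministic
#' manifest (inputs, parameters, derived seeds, output MD5 hashes) is
#' written as `manifest.yaml`. Rerunning with an identical config
#' reproduces identical outputs; per-stage timing goes to the log, not the
#' manifest. A failing stage aborts with its name after writing a
#' `<stage>.partial` marker.
#'
#' @param config a [readPipelineConfig()] result, a path to a YAML config,
#'   or a config list.
#' @return The manifest list, invisibly.
#' @export
runPipeline <- function(config) {
  cfg <- if (inherits(config, "PipelineConfig")) config
         else readPipelineConfig(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outdir, f)
  manifest <- list(config = unclass(cfg), seeds = list(), outputs = list())
  stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      file.create(out(paste0(name, ".partial")))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    .pipe_log(cfg, "info", sprintf("stage %s done (%.2fs)", name,
                                   as.numeric(Sys.time() - t0, "secs")))
    res
  }
  env <- new.env()

  stage("input", function() {
    if (!is.null(cfg$simulate)) {
      sb <- cfg$simulate
      sp <- simParams(
        nRegulators = .cfg_get(sb, "n_regulators", 60L),
        genesPerCluster = .cfg_get(sb, "genes_per_cluster", 10L),
        phi = .cfg_get(sb, "phi", 0.2),
        damageLog2FC = .cfg_get(sb, "damage_log2fc", 2),
        edgeEffect = .cfg_get(sb, "edge_effect", 0.45),
        geneNoiseSd = .cfg_get(sb, "gene_noise_sd", 0.4),
        loading = .cfg_get(sb, "loading", 1.4),
        unannotatedFraction = .cfg_get(sb, "unannotated_fraction", 0.54),
        seed = cfg$seed)
      ds <- simulateDataset(designSpec(), sp)
      env$dataset <- ds
      env$counts <- ds@experiment
      env$annotations <- ds@annotations
      writeCountsTable(env$counts, out("counts.tsv"), out("metadata.tsv"))
      tr <- truthNetwork(ds)
      write.table(tr@edges, out("truth_edges.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(data.frame(node = names(tr@moduleLabels),
                             module = unname(tr@moduleLabels)),
                  out("truth_labels.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      write.table(ds@annotations, out("annotations.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      manifest$seeds$simulate <<- cfg$seed
    } else {
      env$counts <- readCountsTable(cfg$io$counts, cfg$io$metadata)
      env$annotations <- if (!is.null(cfg$io$annotations))
        readAnnotationTable(cfg$io$annotations)
      else data.frame(gene_id = character(), description = character(),
                      terms = character())
    }
  })

  stage("normalize", function() {
    nb <- cfg$normalize
    filtered <- filterLowExpression(env$counts,
                                    minCpm = .cfg_get(nb, "min_cpm", 1),
                                    minSamples = .cfg_get(nb, "min_samples", 2))
    env$filtered <- filtered
    env$logx <- cpmLogTransform(filtered,
                                pseudocount = .cfg_get(nb, "pseudocount", 1))
  })

  stage("cluster", function() {
    sb <- cfg$sota
    seed <- cfg$seed + 101L
    sp <- sotaParams(
      distanceMetric = .cfg_get(sb, "distance_metric", "pearson"),
      alphaWinner = .cfg_get(sb, "alpha_winner", 0.01),
      alphaMother = .cfg_get(sb, "alpha_mother", 0.005),
      alphaSister = .cfg_get(sb, "alpha_sister", 0.001),
      cycleEpsilon = .cfg_get(sb, "cycle_epsilon", 1e-4),
      maxCells = .cfg_get(sb, "max_cells", 72L),
      variabilityThreshold = .cfg_get(sb, "variability_threshold", 0),
      maxEpochsPerCycle = .cfg_get(sb, "max_epochs_per_cycle", 50L),
      seed = seed)
    env$clustering <- runSota(env$logx, sp)
    manifest$seeds$cluster <<- seed
    asg <- clusterAssignment(env$clustering)
    write.table(data.frame(gene_id = names(asg), cluster_id = unname(asg)),
                out("assignment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    env$centroids <- assignmentCentroids(env$clustering, env$logx)
    writeCountsTable(exprValues(env$centroids), out("centroids.tsv"))
  })

  stage("infer", function() {
    ab <- cfg$aracne
    seed <- cfg$seed + 202L
    ap <- aracneParams(
      estimator = .cfg_get(ab, "estimator", "gaussian_kde"),
      nBins = .cfg_get(ab, "n_bins", 8L),
      nPermutations = .cfg_get(ab, "n_permutations", 1000L),
      alpha = .cfg_get(ab, "alpha", 0.01),
      dpiTolerance = .cfg_get(ab, "dpi_tolerance", 0.15),
      seed = seed)
    env$network <- inferNetwork(env$centroids, ap)
    manifest$seeds$infer <<- seed
    writeEdgeList(env$network, out("edges.tsv"))
    writeSIF(env$network, out("network.sif"))
  })

  stage("modules", function() {
    mb <- cfg$modules
    radius <- .cfg_get(mb, "radius", 1L)
    groups <- mb$marker_genes
    if (is.null(groups) && !is.null(env$dataset)) {
      mk <- markerGenes(env$dataset)
      groups <- split(mk$gene_id, mk$module)
    }
    if (is.null(groups)) stop("modules stage needs marker_genes")
    asg <- clusterAssignment(env$clustering)
    env$modules <- lapply(names(groups), function(gname) {
      seeds <- unique(unname(asg[intersect(groups[[gname]], names(asg))]))
      seeds <- seeds[!is.na(seeds)]
      extractModule(env$network, seeds, radius = radius, moduleId = gname)
    })
    names(env$modules) <- names(groups)
    writeModulesTable(env$modules, out("modules.tsv"))
    summ <- do.call(rbind, lapply(env$modules, summarizeModule,
                                  assignment = env$clustering,
                                  annotations = env$annotations))
    write.table(summ, out("module_summary.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  })

  stage("de", function() {
    db <- cfg$de
    dp <- deParams(alphaFdr = .cfg_get(db, "alpha_fdr", 0.05),
                   minCountFilter = .cfg_get(db, "min_count_filter", 5),
                   minStrata = .cfg_get(db, "min_strata", 1L))
    de <- callDamageResponseGenes(env$filtered, dp)
    env$de <- de
    write.table(de$table, out("de_table.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    flags <- mapDEToNetwork(env$network, env$clustering, de$genes)
    write.table(flags, out("de_nodes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  })

  stage("characterize", function() {
    cb <- cfg$characterization
    asg <- clusterAssignment(env$clustering)
    background <- names(asg)
    enr <- do.call(rbind, lapply(names(env$modules), function(m) {
      genes <- names(asg)[asg %in% moduleNodes(env$modules[[m]])]
      e <- enrichTerms(genes, background, env$annotations,
                       minTermSize = .cfg_get(cb, "min_term_size", 3L))
      if (nrow(e)) cbind(module_id = m, e) else NULL
    }))
    if (is.null(enr))
      enr <- data.frame(module_id = character(), term_id = character())
    write.table(enr, out("enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    lex <- if (!is.null(cb$lexicon)) readLexicon(cb$lexicon)
           else defaultLexicon()
    module_genes <- unique(unlist(lapply(env$modules, function(m) {
      names(asg)[asg %in% moduleNodes(m)]
    })))
    screen <- screenFunctionalCategories(env$annotations, module_genes, lex)
    write.table(screen, out("candidates.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    prio <- do.call(rbind, lapply(names(env$modules), function(m) {
      mod <- env$modules[[m]]
      if (length(anchorNodes(mod)) == 0L) return(NULL)
      p <- prioritizeUnannotated(
        env$network, mod, env$clustering, env$annotations,
        deGenes = env$de$genes,
        minConnectivity = .cfg_get(cb, "min_connectivity", 1L))
      if (nrow(p)) cbind(module_id = m, p) else NULL
    }))
    if (is.null(prio))
      prio <- data.frame(module_id = character(), gene_id = character())
    write.table(prio, out("priorities.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  })

  files <- sort(setdiff(list.files(cfg$outdir), "manifest.yaml"))
  manifest$outputs <- as.list(setNames(
    unname(tools::md5sum(file.path(cfg$outdir, files))), files))
  yaml::write_yaml(manifest, out("manifest.yaml"))
  .pipe_log(cfg, "info", "pipeline complete: ", cfg$outdir)
  invisible(manifest)
}
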