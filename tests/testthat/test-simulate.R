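test_that("the default design allocates 78 samples over the full factorial", {
  d <- designSpec()
  expect_equal(sum(d$allocation$n), 78)
  expect_equal(length(d$timePoints), 6)
  expect_equal(length(d$ageCategories), 3)
  expect_equal(length(d$treatments), 2)
  expect_equal(nrow(d$allocation), 36)
  expect_true(all(d$allocation$n >= 2))
})

test_that("the truth network is reproducible with hubs wired to all anchors", {
  p <- simParams(seed = 5)
  t1 <- simulateTruthNetwork(p)
  t2 <- simulateTruthNetwork(p)
  expect_identical(t1@edges, t2@edges)
  adj <- paste(c(t1@edges$nodeA, t1@edges$nodeB),
               c(t1@edges$nodeB, t1@edges$nodeA))
  for (m in c("A", "B")) {
    hub <- t1@hubs[[m]]
    deg <- sum(grepl(paste0("^", hub, " "), adj))
    expect_gte(deg, length(t1@anchors[[m]]))
    expect_true(all(paste(hub, t1@anchors[[m]]) %in% adj))
  }
  expect_length(intersect(t1@anchors$A, t1@anchors$B), 0)
  # no cross edges between the two marker modules by default
  lab <- t1@moduleLabels
  cross <- lab[t1@edges$nodeA] == "A" & lab[t1@edges$nodeB] == "B" |
    lab[t1@edges$nodeA] == "B" & lab[t1@edges$nodeB] == "A"
  expect_false(any(cross))
  # edge count self-consistency with the returned edge list
  expect_equal(nrow(t1@edges),
               length(unique(paste(pmin(t1@edges$nodeA, t1@edges$nodeB),
                                   pmax(t1@edges$nodeA, t1@edges$nodeB)))))
  expect_error(simParams(nRegulators = 10, anchorsA = 6, anchorsB = 4),
               "exceed")
})

test_that("simulated datasets match the design and are seed-reproducible", {
  sp <- simParams(nRegulators = 12, genesPerCluster = 4, seed = 9)
  ds1 <- simulateDataset(designSpec(), sp)
  ds2 <- simulateDataset(designSpec(), sp)
  expect_identical(exprValues(ds1@experiment), exprValues(ds2@experiment))
  expect_equal(ncol(ds1@experiment), 78)
  expect_equal(nrow(ds1@experiment), 12 * 4)
  mk <- markerGenes(ds1)
  expect_equal(sum(mk$module == "A"), 4)
  expect_equal(sum(mk$module == "B"), 2)
  expect_true(all(mk$gene_id %in% rownames(ds1@experiment)))
  # true damage-response genes are exactly the members of affected clusters
  tr <- truthNetwork(ds1)
  affected <- c(tr@hubs[["A"]], tr@anchors$A)
  expect_setequal(damageGenes(ds1),
                  names(ds1@geneCluster)[ds1@geneCluster %in% affected])
})

test_that("the planted unannotated fraction is honoured within tolerance", {
  ds <- simulateDataset(params = simParams(seed = 30))
  ann <- geneAnnotations(ds)
  frac <- 1 - length(annotatedGenes(ann)) / nrow(ann)
  expect_lte(abs(frac - 0.54), 0.05)
})

test_that("within-cluster correlation exceeds between-cluster correlation", {
  ds <- simulateDataset(params = simParams(nRegulators = 15,
                                           genesPerCluster = 6, seed = 77))
  lx <- exprValues(cpmLogTransform(ds@experiment))
  cm <- cor(t(lx))
  same <- outer(ds@geneCluster, ds@geneCluster, "==")
  diag(same) <- NA
  within <- mean(cm[same & !is.na(same)])
  between <- mean(cm[!same & !is.na(same)])
  expect_gt(within, between + 0.3)
})

test_that("recovery scoring is exact on the truth and null on noise", {
  ds <- simulateDataset(params = simParams(nRegulators = 12,
                                           genesPerCluster = 5, seed = 3))
  tr <- truthNetwork(ds)
  # perfect assignment + true edge set + ideal modules
  perfect_net <- make_network(tr@edges, nodes = tr@nodes)
  modules <- list(
    A = new("GRNModule", moduleId = "A",
            nodeIds = c(tr@hubs[["A"]], tr@anchors$A),
            anchorIds = tr@anchors$A, hubIds = tr@hubs[["A"]],
            absentSeeds = character()),
    B = new("GRNModule", moduleId = "B",
            nodeIds = c(tr@hubs[["B"]], tr@anchors$B),
            anchorIds = tr@anchors$B, hubIds = tr@hubs[["B"]],
            absentSeeds = character()))
  rec <- evaluateRecovery(ds, ds@geneCluster, perfect_net, modules)
  expect_equal(rec$ari, 1)
  expect_equal(rec$edge_precision, 1)
  expect_equal(rec$edge_recall, 1)
  expect_true(rec$marker_modules_recovered)
  expect_true(all(rec$hub_recovered))

  # a random clustering of the same genes scores ARI ~ 0
  withr::with_seed(44, {
    rand <- setNames(sample(tr@nodes, length(ds@geneCluster), TRUE),
                     names(ds@geneCluster))
    rec0 <- evaluateRecovery(ds, rand, perfect_net, modules)
    expect_lte(abs(rec0$ari), 0.05)
  })
})

test_that("ARI agrees with an independent contingency-table computation", {
  withr::with_seed(50, {
    for (i in 1:10) {
      a <- sample(1:4, 40, TRUE)
      b <- sample(1:3, 40, TRUE)
      expect_equal(adjustedRand(a, b), ari_oracle(a, b), tolerance = 1e-12)
    }
    expect_equal(adjustedRand(1:10, rep(1:5, 2) * 10), ari_oracle(1:10, rep(1:5, 2)))
  })
})
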