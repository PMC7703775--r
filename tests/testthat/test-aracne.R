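test_that("MI estimates are symmetric, non-negative and rank-invariant", {
  withr::with_seed(17, {
    x <- rnorm(200); y <- 0.7 * x + rnorm(200)
    p <- aracneParams()
    expect_equal(estimateMI(x, y, p), estimateMI(y, x, p))
    expect_gte(estimateMI(x, y, p), 0)
    # strictly monotone transforms leave the rank-based estimate unchanged
    expect_equal(estimateMI(exp(x), y, p), estimateMI(x, y, p))
    expect_equal(estimateMI(x, y^3 + 2 * y, p), estimateMI(x, y, p))
    pb <- aracneParams(estimator = "binning")
    expect_equal(estimateMI(exp(x), y, pb), estimateMI(x, y, pb))
    # dependence is ranked above independence by both estimators
    z <- rnorm(200)
    expect_gt(estimateMI(x, y, p), estimateMI(x, z, p))
    expect_gt(estimateMI(x, y, pb), estimateMI(x, z, pb))
  })
  expect_error(estimateMI(1:10, 1:9, aracneParams()), "equal length")
  expect_error(estimateMI(1:5, 1:5, aracneParams()), "at least 8")
})

test_that("permuted pairs carry near-zero estimated MI", {
  withr::with_seed(23, {
    x <- rnorm(2000)
    y <- sample(x)
    expect_lte(estimateMI(x, y, aracneParams()), 0.05)
  })
})

test_that("the permutation threshold is deterministic and calibrated", {
  withr::with_seed(41, {
    m <- matrix(rnorm(12 * 100), 12, 100,
                dimnames = list(sprintf("n%02d", 1:12), paste0("s", 1:100)))
    cent <- MantleExperiment(m, valueKind = "log_expression")
    p <- aracneParams(nPermutations = 200, alpha = 0.1, seed = 7)
    thr1 <- calibrateMIThreshold(cent, p)
    thr2 <- calibrateMIThreshold(cent, p)
    expect_identical(thr1, thr2)
    # alpha -> 1 pushes the threshold toward the null minimum
    lo <- calibrateMIThreshold(cent, aracneParams(nPermutations = 200,
                                                  alpha = 0.999, seed = 7))
    expect_lte(lo, thr1)
    # fresh null exceedances happen at rate ~ alpha (binomial 95% band)
    null_mi <- vapply(1:200, function(b) {
      ij <- sample.int(12, 2)
      estimateMI(sample(m[ij[1], ]), sample(m[ij[2], ]), p)
    }, numeric(1))
    rate <- mean(null_mi > thr1)
    band <- 1.96 * sqrt(0.1 * 0.9 / 200)
    expect_gte(rate, 0.1 - band - 0.02)
    expect_lte(rate, 0.1 + band + 0.02)
  })
  expect_error(aracneParams(nPermutations = 5), "nPermutations")
})

test_that("DPI removes the weakest edge of a clear triangle and respects ties", {
  net <- make_network(edge_df(c("A", "B", "A"), c("B", "C", "C")),
                      mi = c(0.5, 0.4, 0.1))
  out <- applyDPI(net, 0)
  st <- setNames(networkEdges(out)$status,
                 paste(networkEdges(out)$nodeA, networkEdges(out)$nodeB))
  expect_identical(unname(st[c("A B", "B C")]), c("kept", "kept"))
  expect_identical(unname(st["A C"]), "removed_by_dpi")

  # tolerance 1 disables pruning entirely
  expect_identical(networkEdges(applyDPI(net, 1))$status,
                   rep("kept", 3))

  # an exact tie for the smallest edge removes none of the tied edges
  tied <- make_network(edge_df(c("A", "B", "A"), c("B", "C", "C")),
                       mi = c(0.5, 0.1, 0.1))
  expect_identical(networkEdges(applyDPI(tied, 0))$status, rep("kept", 3))
  expect_error(applyDPI(net, 1.2), "tolerance")
})

test_that("DPI agrees with a brute-force triple loop on random graphs", {
  for (s in 1:100) {
    rk <- random_kept_network(seed = 1000 + s)
    eps <- withr::with_seed(2000 + s, sample(c(0, 0.1, 0.15, 0.3), 1))
    out <- applyDPI(rk$net, eps)
    e <- networkEdges(out)
    kept <- e[e$status == "kept", ]
    got <- sort(paste(pmin(kept$nodeA, kept$nodeB),
                      pmax(kept$nodeA, kept$nodeB)))
    want <- sort(brute_force_dpi(rk$nodes, networkEdges(rk$net), eps))
    expect_identical(got, want)
    # idempotent at eps = 0: a second pass removes nothing
    if (eps == 0) {
      again <- applyDPI(out, 0)
      expect_identical(networkEdges(again)$status, e$status)
    }
  }
})

test_that("inferNetwork scores all pairs and ranks a duplicated node first", {
  withr::with_seed(9, {
    m <- matrix(rnorm(5 * 60), 5, 60,
                dimnames = list(paste0("n", 1:5), paste0("s", 1:60)))
    m <- rbind(m, n6 = m["n1", ] )  # duplicate of n1
    cent <- MantleExperiment(m, valueKind = "log_expression")
    net <- inferNetwork(cent, aracneParams(nPermutations = 100, seed = 3))
    e <- networkEdges(net)
    expect_equal(nrow(e), choose(6, 2))
    e6 <- e[e$nodeA == "n6" | e$nodeB == "n6", ]
    other <- ifelse(e6$nodeA == "n6", e6$nodeB, e6$nodeA)
    expect_identical(other[which.max(e6$mi)], "n1")
  })
})

test_that("independent profiles yield an (almost) empty network", {
  withr::with_seed(13, {
    m <- matrix(rnorm(3 * 100), 3, 100,
                dimnames = list(paste0("n", 1:3), paste0("s", 1:100)))
    cent <- MantleExperiment(m, valueKind = "log_expression")
    net <- inferNetwork(cent, aracneParams(nPermutations = 200, alpha = 0.05,
                                           seed = 11))
    expect_lte(nrow(keptEdges(net)), 1L)
  })
})

test_that("edge list and SIF writers export kept edges faithfully", {
  net <- make_network(edge_df(c("A", "B"), c("B", "C")), mi = c(0.5, 0.2))
  f <- withr::local_tempfile(); writeEdgeList(net, f)
  tab <- read.delim(f)
  expect_identical(tab$status, c("kept", "kept"))
  f2 <- withr::local_tempfile(); writeSIF(net, f2)
  expect_identical(readLines(f2), c("A\t0.5\tB", "B\t0.2\tC"))
})
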