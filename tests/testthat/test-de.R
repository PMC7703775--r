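test_that("common dispersion recovers Poisson and NB truths", {
  withr::with_seed(8, {
    mu <- exp(runif(800, log(20), log(200)))
    grp <- rep(c("a", "b"), each = 6)
    nb <- matrix(rnbinom(800 * 12, mu = rep(mu, 12), size = 1 / 0.2), 800, 12,
                 dimnames = list(paste0("g", 1:800), paste0("s", 1:12)))
    pois <- matrix(rpois(800 * 12, rep(mu, 12)), 800, 12,
                   dimnames = dimnames(nb))
    phi_nb <- estimateCommonDispersion(nb, grp)
    phi_p <- estimateCommonDispersion(pois, grp)
    expect_gte(phi_nb, 0.1); expect_lte(phi_nb, 0.3)
    expect_gte(phi_p, 0); expect_lte(phi_p, 0.05)
    # all-zero genes cannot influence the median
    nb0 <- rbind(nb, gZ = 0L)
    expect_identical(estimateCommonDispersion(nb0, grp), phi_nb)
  })
  expect_error(estimateCommonDispersion(matrix(1:4, 2, 2,
    dimnames = list(c("a", "b"), c("x", "y"))), c("a", "b")), "2 samples")
})

test_that("nbExactTest reduces to the exact binomial at phi = 0", {
  withr::with_seed(42, {
    for (i in 1:40) {
      a <- rpois(3, 3); b <- rpois(3, 3); s <- sum(a) + sum(b)
      if (s == 0 || s > 50) next
      p1 <- nbExactTest(a, b, 0)
      pr <- dbinom(0:s, s, length(a) / (length(a) + length(b)))
      p2 <- sum(pr[pr <= pr[sum(a) + 1] * (1 + 1e-10)])
      expect_equal(p1, p2, tolerance = 1e-9)
    }
  })
})

test_that("nbExactTest is symmetric and handles degenerate input", {
  expect_equal(nbExactTest(c(1, 2, 3), c(3, 2, 1), 0.2), 1)  # modal split
  expect_equal(nbExactTest(c(9, 1), c(2, 3), 0.3),
               nbExactTest(c(2, 3), c(9, 1), 0.3))
  expect_equal(nbExactTest(c(0, 0), c(0, 0), 0.2), 1)
  expect_error(nbExactTest(c(-1, 2), c(1, 1), 0.1), "non-negative")
  expect_error(nbExactTest(c(1, 2), c(1, 1), -0.1), "phi")
})

test_that("null p-values are approximately uniform", {
  withr::with_seed(71, {
    mu <- exp(runif(1000, log(20), log(200)))
    pv <- vapply(seq_len(1000), function(g) {
      nbExactTest(rnbinom(3, mu = mu[g], size = 5),
                  rnbinom(3, mu = mu[g], size = 5), 0.2)
    }, numeric(1))
    d <- max(abs(ecdf(pv)(seq(0, 1, 0.01)) - seq(0, 1, 0.01)))
    expect_lte(d, 0.08)
  })
})

test_that("bhAdjust applies the step-up procedure", {
  expect_equal(bhAdjust(0.07), 0.07)
  expect_equal(bhAdjust(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bhAdjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  # monotone: larger p never gets a smaller q
  withr::with_seed(3, {
    p <- runif(50)
    q <- bhAdjust(p)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  })
  expect_error(bhAdjust(c(0.1, 1.2)), "0, 1")
})

test_that("injected damage effects are detected with high power", {
  withr::with_seed(55, {
    n_de <- 50; n_null <- 950; n <- n_de + n_null
    mu <- exp(runif(n, log(50), log(200)))
    gids <- sprintf("g%03d", 1:n)
    samp <- make_design(paste0("s", 1:6),
                        treatment = rep(c("damaged", "control"), each = 3))
    fold <- c(rep(4, n_de), rep(1, n_null))
    m <- vapply(seq_len(6), function(j) {
      f <- if (samp$treatment[j] == "damaged") fold else rep(1, n)
      rnbinom(n, mu = mu * f, size = 1 / 0.1)
    }, numeric(n))
    dimnames(m) <- list(gids, samp$sample_id)
    x <- MantleExperiment(m, design = samp, valueKind = "counts")
    res <- callDamageResponseGenes(x, deParams())
    power <- mean(gids[1:n_de] %in% res$genes)
    expect_gte(power, 0.8)
    # fold-change signs point the right way for the injected genes
    tab <- res$table[res$table$gene_id %in% gids[1:n_de], ]
    expect_gte(mean(tab$log2FC > 0), 0.9)
  })
})

test_that("a dataset without both treatments has no testable stratum", {
  x <- make_counts(10, 4, seed = 2)
  design <- make_design(colnames(x), treatment = rep("control", 4))
  xd <- MantleExperiment(exprValues(x), design = design, valueKind = "counts")
  expect_error(callDamageResponseGenes(xd), "no testable stratum")
})

test_that("DE status maps onto network nodes by cluster membership", {
  net <- make_network(edge_df("c1", "c2"), nodes = c("c1", "c2", "c3"))
  asg <- c(g1 = "c1", g2 = "c2", g3 = "c2", g4 = "c3")
  none <- mapDEToNetwork(net, asg, character())
  expect_false(any(none$de_flag))
  one <- mapDEToNetwork(net, asg, "g2")
  expect_identical(one$de_flag, c(FALSE, TRUE, FALSE))
  expect_identical(one$n_de_members, c(0L, 1L, 0L))
  expect_warning(mapDEToNetwork(net, asg, c("g2", "gX")), "ignored")
  # brute-force membership scan on a random instance
  withr::with_seed(12, {
    asg2 <- setNames(sample(c("c1", "c2", "c3"), 40, TRUE),
                     sprintf("g%02d", 1:40))
    de <- sample(names(asg2), 15)
    got <- mapDEToNetwork(net, asg2, de)
    for (nd in c("c1", "c2", "c3")) {
      expect_identical(got$n_de_members[got$node_id == nd],
                       length(intersect(de, names(asg2)[asg2 == nd])))
    }
  })
})
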