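test_that("firstNeighbors follows kept edges only", {
  net <- make_network(edge_df(c("a", "b"), c("b", "c")),
                      nodes = c("a", "b", "c", "iso"))
  expect_identical(firstNeighbors(net, "b"), c("a", "c"))
  expect_identical(firstNeighbors(net, "iso"), character())
  expect_error(firstNeighbors(net, "zz"), "unknown node")

  # removed edges do not count
  e <- networkEdges(net); e$status[1] <- "removed_by_dpi"
  net2 <- initialize(net, edges = e)
  expect_identical(firstNeighbors(net2, "b"), "c")

  # random graph: equals an adjacency scan
  rk <- random_kept_network(77)
  e <- networkEdges(rk$net)
  for (nd in rk$nodes[1:3]) {
    want <- sort(unique(c(e$nodeB[e$nodeA == nd], e$nodeA[e$nodeB == nd])))
    expect_identical(firstNeighbors(rk$net, nd), want)
  }
})

test_that("mutual first neighbours recover a star hub and obey minLinks", {
  seeds <- paste0("s", 1:4)
  net <- make_network(edge_df(rep("hub", 4), seeds))
  expect_identical(mutualFirstNeighbors(net, seeds), "hub")
  expect_identical(mutualFirstNeighbors(net, seeds, minLinks = 2), "hub")

  # mutually adjacent seeds with no shared outside neighbour
  net2 <- make_network(edge_df(c("s1", "s1", "s2"), c("s2", "s3", "s3")))
  expect_identical(mutualFirstNeighbors(net2, paste0("s", 1:3)), character())

  expect_error(mutualFirstNeighbors(net, seeds, minLinks = 5), "exceed")
  expect_error(mutualFirstNeighbors(net, character()), "non-empty")

  # brute-force count-over-seeds scan on random graphs
  for (s in 1:20) {
    rk <- random_kept_network(300 + s)
    sds <- withr::with_seed(400 + s, sample(rk$nodes, 3))
    for (ml in 2:3) {
      got <- mutualFirstNeighbors(rk$net, sds, minLinks = ml)
      cnt <- vapply(setdiff(rk$nodes, sds), function(nd) {
        sum(vapply(sds, function(sd)
          nd %in% firstNeighbors(rk$net, sd), logical(1)))
      }, numeric(1))
      expect_identical(got, sort(names(cnt)[cnt >= ml]))
    }
  }
})

test_that("extractModule grows BFS neighbourhoods of the seeds", {
  # path a-b-c-d
  net <- make_network(edge_df(c("a", "b", "c"), c("b", "c", "d")))
  expect_identical(moduleNodes(extractModule(net, "a", radius = 0)), "a")
  expect_identical(moduleNodes(extractModule(net, "a", radius = 1)),
                   c("a", "b"))
  expect_identical(moduleNodes(extractModule(net, "a", radius = 3)),
                   c("a", "b", "c", "d"))

  # monotone in radius; absent seeds reported, all-absent fatal
  m0 <- extractModule(net, c("a", "zz"), radius = 1)
  expect_identical(m0@absentSeeds, "zz")
  expect_error(extractModule(net, "zz"), "absent")
  for (r in 0:2) {
    expect_true(all(moduleNodes(extractModule(net, "b", radius = r)) %in%
                      moduleNodes(extractModule(net, "b", radius = r + 1))))
  }

  # random graphs vs an independent BFS oracle at radius 2
  for (s in 1:20) {
    rk <- random_kept_network(500 + s)
    sds <- withr::with_seed(600 + s, sample(rk$nodes, 2))
    got <- moduleNodes(extractModule(rk$net, sds, radius = 2))
    reach <- unique(unlist(lapply(sds, function(sd) {
      n1 <- firstNeighbors(rk$net, sd)
      n2 <- unlist(lapply(n1, firstNeighbors, network = rk$net))
      c(sd, n1, n2)
    })))
    expect_setequal(got, reach)
  }
})

test_that("module summaries count genes and annotation status", {
  net <- make_network(edge_df("c1", "c2"))
  mod <- extractModule(net, c("c1", "c2"), radius = 0, moduleId = "m1")
  asg <- c(g1 = "c1", g2 = "c1", g3 = "c1", g4 = "c2", g5 = "c2",
           g6 = "c2", g7 = "c2")
  ann <- data.frame(gene_id = c("g1", "g4"),
                    description = c("Pendrin", ""),
                    terms = c("", "KEGG:k1"))
  s <- summarizeModule(mod, asg, ann)
  expect_identical(s$n_clusters, 2L)
  expect_identical(s$n_genes, 7L)
  expect_identical(s$n_annotated, 2L)
  expect_identical(s$n_unannotated, 5L)
  # empty annotation table: everything unannotated
  s0 <- summarizeModule(mod, asg, NULL)
  expect_identical(s0$n_annotated, 0L)
  expect_identical(s0$n_unannotated + s0$n_annotated, s0$n_genes)
  expect_error(summarizeModule(mod, asg[asg != "c2"], ann), "missing")
})
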