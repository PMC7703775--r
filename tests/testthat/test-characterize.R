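make_term_annotations <- function(genes, term_sets) {
  data.frame(gene_id = genes,
             description = "",
             terms = vapply(genes, function(g) {
               paste(term_sets[[g]], collapse = ";")
             }, character(1)), row.names = NULL)
}

test_that("enrichment p-values follow the hypergeometric tail exactly", {
  # full overlap of a 5-gene term with a 5-gene module in a background of 20
  bg <- sprintf("g%02d", 1:20)
  module <- bg[1:5]
  term_sets <- setNames(rep(list(character()), 20), bg)
  for (g in bg[1:5]) term_sets[[g]] <- "KEGG:ko1"
  ann <- make_term_annotations(bg, term_sets)
  res <- enrichTerms(module, bg, ann, minTermSize = 2)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)

  # zero overlap gives p = 1
  res0 <- enrichTerms(bg[6:10], bg, ann, minTermSize = 2)
  expect_equal(res0$p_value, 1)

  expect_error(enrichTerms(c("g01", "zz"), bg, ann), "outside")
})

test_that("enrichment equals one-sided Fisher on random small instances", {
  for (s in 1:25) {
    withr::with_seed(900 + s, {
      N <- sample(20:200, 1)
      bg <- sprintf("g%03d", seq_len(N))
      module <- sample(bg, sample(5:min(40, N), 1))
      term <- sample(bg, sample(3:min(30, N), 1))
      term_sets <- setNames(rep(list(character()), N), bg)
      for (g in term) term_sets[[g]] <- "GO_BP:GO:1"
      ann <- make_term_annotations(bg, term_sets)
      res <- enrichTerms(module, bg, ann, minTermSize = 1)
      k <- length(intersect(module, term))
      tab <- matrix(c(k, length(term) - k,
                      length(module) - k,
                      N - length(term) - length(module) + k), 2, 2)
      fp <- fisher.test(tab, alternative = "greater")$p.value
      expect_equal(res$p_value, fp, tolerance = 1e-9)
    })
  }
})

test_that("q-values are adjusted within each namespace", {
  bg <- sprintf("g%02d", 1:30)
  term_sets <- setNames(rep(list(character()), 30), bg)
  for (g in bg[1:6]) term_sets[[g]] <- c("KEGG:k1", "GO_MF:m1")
  for (g in bg[7:12]) term_sets[[g]] <- "KEGG:k2"
  ann <- make_term_annotations(bg, term_sets)
  res <- enrichTerms(bg[1:6], bg, ann, minTermSize = 2)
  for (ns in unique(res$namespace)) {
    i <- res$namespace == ns
    expect_equal(res$q_value[i], bhAdjust(res$p_value[i]))
  }
})

test_that("the lexicon screen reproduces canonical category assignments", {
  ann <- data.frame(
    gene_id = paste0("g", 1:6),
    description = c("Pendrin",
                    "Carbonic anhydrase 2-like isoform X3",
                    "Toll-like receptor 2",
                    "Protein transport protein Sec61 alpha-2",
                    "Heat shock factor-binding protein 1",
                    ""),
    terms = "")
  res <- screenFunctionalCategories(ann)
  expect_identical(res$category,
                   c("Ion transport", "Biomineralization enzyme",
                     "Receptor and signal transduction", "Protein transport",
                     "Protein folding/chaperoning", "uncategorized"))
  # stable under reordering of the genes
  res2 <- screenFunctionalCategories(ann, genes = rev(ann$gene_id))
  expect_identical(res2$category, rev(res$category))
})

test_that("lexicons can be overridden from YAML and are validated", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("My category:", "  - widget", "Other:", "  - pendrin"), f)
  lex <- readLexicon(f)
  ann <- data.frame(gene_id = "g1", description = "A widget pendrin",
                    terms = "")
  # first-match-wins in declared order
  expect_identical(screenFunctionalCategories(ann, lexicon = lex)$category,
                   "My category")
  expect_error(.validate_lexicon(list(a = character())), "non-empty")
})

test_that("unannotated prioritization enforces all three filters and the rank", {
  # hub2 adjacent to both anchors, far adjacent to one
  net <- make_network(edge_df(c("a1", "a2", "a1", "c9"),
                              c("hub2", "hub2", "far", "far")),
                      mi = c(0.9, 0.8, 0.3, 0.2))
  mod <- new("GRNModule", moduleId = "m", anchorIds = c("a1", "a2"),
             nodeIds = c("a1", "a2", "hub2", "far"), hubIds = "hub2",
             absentSeeds = character())
  asg <- c(u1 = "hub2", u2 = "far", u3 = "hub2", a_g = "a1")
  ann <- data.frame(gene_id = "a_g", description = "Pendrin", terms = "")
  de <- c("u1", "u2", "a_g")
  res <- prioritizeUnannotated(net, mod, asg, ann, de,
                               anchors = c("a1", "a2"), minConnectivity = 1)
  # u3 is not DE; a_g is annotated; u1 (2 anchor links) ranks above u2 (1)
  expect_identical(res$gene_id, c("u1", "u2"))
  expect_identical(res$anchor_connectivity, c(2L, 1L))
  # raising the connectivity bar drops u2
  res2 <- prioritizeUnannotated(net, mod, asg, ann, de,
                                anchors = c("a1", "a2"), minConnectivity = 2)
  expect_identical(res2$gene_id, "u1")
  expect_error(prioritizeUnannotated(net, mod, asg, ann, de,
                                     anchors = character()), "non-empty")
  expect_error(prioritizeUnannotated(net, mod, asg, ann, de,
                                     anchors = "zz"), "not in network")

  # every returned gene is unannotated, DE and connectivity-qualified
  withr::with_seed(31, {
    rk <- random_kept_network(808)
    anchors <- sample(rk$nodes, 2)
    modall <- new("GRNModule", moduleId = "m2", nodeIds = rk$nodes,
                  anchorIds = intersect(anchors, rk$nodes),
                  hubIds = character(), absentSeeds = character())
    genes <- sprintf("q%03d", 1:120)
    asg2 <- setNames(sample(rk$nodes, 120, TRUE), genes)
    annotated <- sample(genes, 40)
    ann2 <- data.frame(gene_id = annotated, description = "Ferritin",
                       terms = "")
    de2 <- sample(genes, 60)
    res3 <- prioritizeUnannotated(rk$net, modall, asg2, ann2, de2,
                                  anchors = anchors, minConnectivity = 1)
    if (nrow(res3)) {
      expect_true(all(!res3$gene_id %in% annotated))
      expect_true(all(res3$gene_id %in% de2))
      expect_true(all(res3$anchor_connectivity >= 1))
      # independent filter-scan oracle for membership
      conn <- vapply(rk$nodes, function(nd) {
        sum(anchors %in% firstNeighbors(rk$net, nd))
      }, numeric(1))
      want <- genes[!genes %in% annotated & genes %in% de2 &
                      conn[asg2[genes]] >= 1]
      expect_setequal(res3$gene_id, want)
    }
  })
})
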