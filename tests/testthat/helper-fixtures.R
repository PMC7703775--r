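# Small in-code fixtures shared across tests.

make_counts <- function(nGenes = 6, nSamples = 4, seed = 1, lambda = 50) {
  withr::with_seed(seed, {
    m <- matrix(rpois(nGenes * nSamples, lambda), nGenes, nSamples,
                dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                                sprintf("s%02d", seq_len(nSamples))))
    MantleExperiment(m, valueKind = "counts")
  })
}

make_design <- function(sample_ids, time = "t1", age = "adult",
                        treatment = NULL) {
  n <- length(sample_ids)
  if (is.null(treatment))
    treatment <- rep(c("damaged", "control"), length.out = n)
  data.frame(sample_id = sample_ids,
             time_point = rep(time, length.out = n),
             age_category = rep(age, length.out = n),
             treatment = treatment)
}

# a MINetwork with every listed edge kept (for module/DPI tests)
make_network <- function(edges, nodes = NULL, mi = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$nodeA, edges$nodeB)))
  if (is.null(mi)) mi <- rep(1, nrow(edges))
  edges$mi <- mi
  edges$status <- "kept"
  new("MINetwork", nodeIds = nodes, edges = edges, threshold = -Inf,
      params = list())
}

edge_df <- function(a, b) data.frame(nodeA = a, nodeB = b,
                                     stringsAsFactors = FALSE)

# independent brute-force DPI: triple loop over node triples on the input
brute_force_dpi <- function(nodes, edges, eps) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  mi <- setNames(edges$mi, key(edges$nodeA, edges$nodeB))
  drop <- character()
  n <- length(nodes)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i < j && j < k) {
      ks <- c(key(nodes[i], nodes[j]), key(nodes[i], nodes[k]),
              key(nodes[j], nodes[k]))
      if (all(ks %in% names(mi))) {
        v <- mi[ks]
        lo <- which.min(v)
        if (sum(v == v[lo]) == 1L && v[lo] < (1 - eps) * min(v[-lo]))
          drop <- c(drop, ks[lo])
      }
    }
  }
  setdiff(names(mi), unique(drop))
}

random_kept_network <- function(seed, max_nodes = 15) {
  withr::with_seed(seed, {
    n <- sample(4:max_nodes, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    prs <- t(utils::combn(nodes, 2))
    pick <- runif(nrow(prs)) < 0.5
    prs <- prs[pick, , drop = FALSE]
    mi <- round(runif(nrow(prs), 0.01, 1), 3)
    list(nodes = nodes,
         net = make_network(edge_df(prs[, 1], prs[, 2]), nodes, mi))
  })
}

# independent contingency-table ARI (Hubert & Arabie)
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(as.vector(tab))
  a_c <- sum_comb(rowSums(tab)); b_c <- sum_comb(colSums(tab))
  expected <- a_c * b_c / choose(n, 2)
  mx <- (a_c + b_c) / 2
  if (mx == expected) return(0)
  (idx - expected) / (mx - expected)
}

well_separated_profiles <- function(nProfiles = 200, nCentroids = 5,
                                    nSamples = 20, noise_sd = 0.3,
                                    seed = 1) {
  withr::with_seed(seed, {
    centroids <- matrix(rnorm(nCentroids * nSamples, sd = 3),
                        nCentroids, nSamples)
    labels <- rep(seq_len(nCentroids), length.out = nProfiles)
    m <- centroids[labels, ] +
      matrix(rnorm(nProfiles * nSamples, sd = noise_sd), nProfiles, nSamples)
    dimnames(m) <- list(sprintf("g%03d", seq_len(nProfiles)),
                        sprintf("s%02d", seq_len(nSamples)))
    list(x = MantleExperiment(m, valueKind = "log_expression"),
         labels = labels)
  })
}
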