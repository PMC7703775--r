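#' Default keyword lexicon for the functional screen
#'
#' Ordered categories of the in silico screen with case-insensitive keyword
#' lists: receptors and signal transduction, ion transport, shell matrix,
#' biomineralization enzymes, protein folding/chaperoning and protein
#' transport. Assignment is first-match-wins in this order, so a
#' description matching several categories lands in the earliest one. The
#' lexicon is fully user-overridable ([readLexicon()]).
#'
#' @return A named, ordered list of keyword character vectors, class
#'   `"Lexicon"`.
#' @examples
#' names(defaultLexicon())
#' @export
defaultLexicon <- function() {
  lex <- list(
    "Receptor and signal transduction" = c(
      "receptor", "notch", "toll-like", "forkhead", "headcase", "akirin",
      "thioredoxin", "signal transduction"),
    "Ion transport" = c(
      "solute carrier", "slc", "sodium/", "sodium-", "pendrin", "regucalcin",
      "exchanger", "ion channel", "ion transport"),
    "Shell matrix" = c(
      "matrix protein", "shell protein", "pif", "mytilin", "chitin-binding",
      "shell matrix"),
    "Biomineralization enzyme" = c(
      "carbonic anhydrase", "tyrosinase", "alkaline phosphatase"),
    "Protein folding/chaperoning" = c(
      "hsp", "heat shock", "chaperon", "protein folding"),
    "Protein transport" = c("sec61", "protein transport")
  )
  .validate_lexicon(lex)
  structure(lex, class = "Lexicon")
}

.validate_lexicon <- function(lex) {
  if (!length(lex) || is.null(names(lex)) || anyDuplicated(names(lex)))
    stop("lexicon categories must be uniquely named")
  ok <- vapply(lex, function(k) length(k) > 0 && all(nzchar(k)), logical(1L))
  if (!all(ok))
    stop("every lexicon category needs non-empty keywords: ",
         paste(names(lex)[!ok], collapse = ", "))
  invisible(lex)
}

#' Read a lexicon from a YAML config file
#'
#' The file maps category names to keyword lists; category order in the
#' file is the first-match-wins screening order.
#'
#' @param path YAML file path.
#' @return A `"Lexicon"` list.
#' @export
readLexicon <- function(path) {
  lex <- yaml::read_yaml(path)
  lex <- lapply(lex, as.character)
  .validate_lexicon(lex)
  structure(lex, class = "Lexicon")
}

#' Read a gene annotation table
#'
#' TSV with columns `gene_id`, `description` and optionally `terms`
#' (`;`-separated `namespace:term` tokens; namespaces `KEGG`, `GO_MF`,
#' `GO_BP`, `GO_CC`). A gene is unannotated iff both fields are empty.
#'
#' @param path TSV path.
#' @return data.frame with columns `gene_id`, `description`, `terms`.
#' @export
readAnnotationTable <- function(path) {
  ann <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  if (!all(c("gene_id", "description") %in% colnames(ann)))
    stop("annotation table needs columns gene_id and description")
  if (!"terms" %in% colnames(ann)) ann$terms <- ""
  ann[, c("gene_id", "description", "terms")]
}

.TERM_NAMESPACES <- c("KEGG", "GO_MF", "GO_BP", "GO_CC")

.parse_terms <- function(annotations) {
  toks <- strsplit(annotations$terms, ";", fixed = TRUE)
  n <- lengths(toks)
  if (!sum(n)) return(data.frame(gene_id = character(),
                                 namespace = character(),
                                 term_id = character()))
  flat <- trimws(unlist(toks))
  gid <- rep(annotations$gene_id, n)
  keep <- nzchar(flat)
  flat <- flat[keep]; gid <- gid[keep]
  ns <- sub(":.*$", "", flat)
  term <- sub("^[^:]*:", "", flat)
  bad <- !ns %in% .TERM_NAMESPACES
  if (any(bad))
    stop("unknown term namespace(s): ", paste(unique(ns[bad]), collapse = ", "))
  unique(data.frame(gene_id = gid, namespace = ns, term_id = flat))
}

#' Hypergeometric term enrichment of a module
#'
#' For every annotation term carried by at least `minTermSize` background
#' genes, computes the upper-tail hypergeometric probability of observing
#' at least the module's overlap with the term, given the module size, term
#' size and background size (equivalent to a one-sided Fisher exact test),
#' with Benjamini-Hochberg adjustment within each namespace.
#'
#' @param moduleGenes character vector, a subset of `backgroundGenes`.
#' @param backgroundGenes character vector, the gene universe (typically
#'   all genes in clusters that survived into the network).
#' @param annotations annotation data.frame (see [readAnnotationTable()]).
#' @param minTermSize smallest background term size tested.
#' @return data.frame with columns `term_id`, `namespace`, `n_module`,
#'   `n_background`, `p_value`, `q_value`, ordered by namespace then
#'   p-value.
#' @export
enrichTerms <- function(moduleGenes, backgroundGenes, annotations,
                        minTermSize = 3L) {
  moduleGenes <- unique(moduleGenes)
  backgroundGenes <- unique(backgroundGenes)
  extra <- setdiff(moduleGenes, backgroundGenes)
  if (length(extra))
    stop("module genes outside the background: ",
         paste(head(extra, 5L), collapse = ", "))
  terms <- .parse_terms(annotations)
  terms <- terms[terms$gene_id %in% backgroundGenes, , drop = FALSE]
  if (!nrow(terms))
    return(data.frame(term_id = character(), namespace = character(),
                      n_module = integer(), n_background = integer(),
                      p_value = numeric(), q_value = numeric()))
  N <- length(backgroundGenes)
  n <- length(moduleGenes)
  res <- do.call(rbind, lapply(split(terms, terms$term_id), function(tt) {
    K <- nrow(tt)
    if (K < minTermSize) return(NULL)
    k <- sum(tt$gene_id %in% moduleGenes)
    data.frame(term_id = tt$term_id[1L], namespace = tt$namespace[1L],
               n_module = k, n_background = K,
               p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  }))
  if (is.null(res))
    return(data.frame(term_id = character(), namespace = character(),
                      n_module = integer(), n_background = integer(),
                      p_value = numeric(), q_value = numeric()))
  res$q_value <- NA_real_
  for (ns in unique(res$namespace)) {
    i <- res$namespace == ns
    res$q_value[i] <- bhAdjust(res$p_value[i])
  }
  res <- res[order(res$namespace, res$p_value, res$term_id), ]
  rownames(res) <- NULL
  res
}

#' Screen gene descriptions against the functional-category lexicon
#'
#' Each gene's description is matched case-insensitively against the
#' lexicon keywords and assigned the first matching category in lexicon
#' order; unmatched or unannotated genes are `"uncategorized"`. The
#' assignment is deterministic and independent of gene order.
#'
#' @param annotations annotation data.frame (see [readAnnotationTable()]).
#' @param genes gene ids to screen (default: all annotated genes).
#' @param lexicon a `"Lexicon"` (default [defaultLexicon()]).
#' @return data.frame with columns `gene_id`, `description`, `category`.
#' @examples
#' ann <- data.frame(gene_id = "g1", description = "Pendrin", terms = "")
#' screenFunctionalCategories(ann)
#' @export
screenFunctionalCategories <- function(annotations,
                                       genes = annotations$gene_id,
                                       lexicon = defaultLexicon()) {
  .validate_lexicon(lexicon)
  ann <- annotations[match(genes, annotations$gene_id), , drop = FALSE]
  desc <- ifelse(is.na(ann$description), "", ann$description)
  category <- rep("uncategorized", length(genes))
  remaining <- rep(TRUE, length(genes))
  for (cat_name in names(lexicon)) {
    pat <- paste(.regex_escape(tolower(lexicon[[cat_name]])), collapse = "|")
    hit <- remaining & grepl(pat, tolower(desc))
    category[hit] <- cat_name
    remaining <- remaining & !hit
  }
  data.frame(gene_id = genes, description = desc, category = category,
             row.names = NULL)
}

.regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Prioritize unannotated damage-responsive genes by marker connectivity
#'
#' Implements the screening rule for the unannotated fraction of a module:
#' keep genes that are (i) unannotated, (ii) damage-response genes, and
#' (iii) members of module clusters whose node has at least
#' `minConnectivity` kept edges to the marker-bearing anchor nodes. Ranked
#' by anchor connectivity (descending), then the cluster's summed MI to the
#' anchors (descending), then gene id.
#'
#' @param network a [MINetwork-class].
#' @param module a [GRNModule-class].
#' @param assignment a [SotaClustering-class] or named character vector.
#' @param annotations annotation data.frame.
#' @param deGenes damage-response gene ids.
#' @param anchors anchor node ids (non-empty, present in the network).
#' @param minConnectivity minimum number of kept anchor edges (>= 1).
#' @return data.frame with columns `gene_id`, `node_id`,
#'   `anchor_connectivity`, `anchor_mi_sum`, ranked.
#' @export
prioritizeUnannotated <- function(network, module, assignment, annotations,
                                  deGenes, anchors = anchorNodes(module),
                                  minConnectivity = 1L) {
  stopifnot(is(network, "MINetwork"), is(module, "GRNModule"))
  if (!length(anchors)) stop("anchor set must be non-empty")
  if (minConnectivity < 1) stop("minConnectivity must be >= 1")
  unknown <- setdiff(anchors, networkNodes(network))
  if (length(unknown))
    stop("anchor(s) not in network: ", paste(unknown, collapse = ", "))
  asg <- if (is(assignment, "SotaClustering")) clusterAssignment(assignment)
         else assignment
  k <- keptEdges(network)
  anchor_edges <- rbind(
    data.frame(node = k$nodeA, other = k$nodeB, mi = k$mi),
    data.frame(node = k$nodeB, other = k$nodeA, mi = k$mi))
  anchor_edges <- anchor_edges[anchor_edges$other %in% anchors, , drop = FALSE]
  conn <- vapply(moduleNodes(module), function(nd) {
    sum(anchor_edges$node == nd)
  }, integer(1L))
  mi_sum <- vapply(moduleNodes(module), function(nd) {
    sum(anchor_edges$mi[anchor_edges$node == nd])
  }, numeric(1L))
  ok_nodes <- moduleNodes(module)[conn >= minConnectivity]
  annotated <- annotatedGenes(annotations)
  cand <- names(asg)[asg %in% ok_nodes & !names(asg) %in% annotated &
                       names(asg) %in% deGenes]
  if (!length(cand))
    return(data.frame(gene_id = character(), node_id = character(),
                      anchor_connectivity = integer(),
                      anchor_mi_sum = numeric()))
  node <- unname(asg[cand])
  out <- data.frame(gene_id = cand, node_id = node,
                    anchor_connectivity = unname(conn[node]),
                    anchor_mi_sum = unname(mi_sum[node]))
  out <- out[order(-out$anchor_connectivity, -out$anchor_mi_sum,
                   out$gene_id), ]
  rownames(out) <- NULL
  out
}
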