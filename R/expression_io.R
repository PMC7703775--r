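#' Read a counts table and its sample metadata
#'
#' Reads a tab-separated counts table (first column gene ids, header row
#' sample ids) and a companion metadata table (columns `sample_id`,
#' `time_point`, `age_category`, `treatment`), validates both and returns a
#' counts [MantleExperiment-class]. Gene and sample order are preserved from
#' the files.
#'
#' @param path path to the counts TSV.
#' @param metadataPath path to the sample metadata TSV, or `NULL` to read a
#'   bare matrix without design factors.
#' @return A [MantleExperiment-class] with `valueKind = "counts"`.
#' @examples
#' tmp <- tempfile(); meta <- tempfile()
#' m <- matrix(0:5, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' writeCountsTable(MantleExperiment(m, valueKind = "counts"), tmp)
#' writeLines(c("sample_id\ttime_point\tage_category\ttreatment",
#'   paste(c("s1", "s2", "s3"), "t1", "adult", c("damaged", "control",
#'   "damaged"), sep = "\t")), meta)
#' readCountsTable(tmp, meta)
#' @export
readCountsTable <- function(path, metadataPath = NULL) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  gene_ids <- raw[[1L]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicated gene id(s): ", paste(dup, collapse = ", "))
  sample_ids <- colnames(raw)[-1L]
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicated sample id(s): ", paste(dup, collapse = ", "))
  values <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1L) values <- matrix(values, nrow = 1L)
  dimnames(values) <- list(gene_ids, sample_ids)
  bad <- which(!is.finite(values) | values < 0 | values != round(values),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-integer or negative count at gene '%s', sample '%s'",
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  if (all(values <= .Machine$integer.max)) storage.mode(values) <- "integer"
  design <- NULL
  if (!is.null(metadataPath)) {
    design <- read.delim(metadataPath, header = TRUE, sep = "\t",
                         check.names = FALSE, colClasses = "character",
                         quote = "")
    need <- c("sample_id", "time_point", "age_category", "treatment")
    miss <- setdiff(need, colnames(design))
    if (length(miss))
      stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(design$sample_id))
      stop("duplicated sample id in metadata")
  }
  MantleExperiment(values, design = design, valueKind = "counts")
}

#' Write a counts or expression table as TSV
#'
#' Inverse of [readCountsTable()]: tab-separated, no quoting, first header
#' cell `gene_id`. Integer counts round-trip bit-exactly.
#'
#' @param x a [MantleExperiment-class] or a matrix with dimnames.
#' @param path output file path.
#' @param metadataPath optional path for a companion metadata TSV (written
#'   only when `x` carries design columns).
#' @return `path`, invisibly.
#' @export
writeCountsTable <- function(x, path, metadataPath = NULL) {
  v <- if (is(x, "MantleExperiment")) exprValues(x) else as.matrix(x)
  df <- data.frame(gene_id = rownames(v), v, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadataPath) && is(x, "MantleExperiment")) {
    d <- sampleDesign(x)
    md <- data.frame(sample_id = colnames(v), d, check.names = FALSE)
    write.table(md, metadataPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

.library_sizes <- function(counts) colSums(counts)

#' Counts-per-million log transform
#'
#' Transforms counts to `log2(1e6 * count / librarySize + pseudocount)`,
#' where the library size is the per-sample column sum. Within a sample the
#' transform is strictly monotone in the count, and it is invariant to
#' rescaling all counts of a sample by a common factor.
#'
#' @param x a counts [MantleExperiment-class].
#' @param pseudocount positive offset added after CPM scaling (default 1, so
#'   zero counts map to 0).
#' @return A [MantleExperiment-class] with `valueKind = "log_expression"`.
#' @examples
#' m <- matrix(c(0, 100), 1, 2,
#'             dimnames = list("g1", c("s1", "s2")))
#' # s2 carries the whole library: log2(1e6 + 1)
#' exprValues(cpmLogTransform(MantleExperiment(m, valueKind = "counts")))
#' @export
cpmLogTransform <- function(x, pseudocount = 1) {
  stopifnot(is(x, "MantleExperiment"))
  if (valueKind(x) != "counts") stop("cpmLogTransform expects counts")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stop("pseudocount must be a positive number")
  counts <- exprValues(x)
  libs <- .library_sizes(counts)
  if (any(libs == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[libs == 0], collapse = ", "))
  logv <- log2(sweep(counts, 2L, 1e6 / libs, "*") + pseudocount)
  MantleExperiment(logv, design = .design_or_null(x),
                   valueKind = "log_expression")
}

.design_or_null <- function(x) {
  d <- sampleDesign(x)
  if (ncol(d) == 0L) NULL else cbind(sample_id = colnames(x), d)
}

#' Filter genes by minimum expression
#'
#' Retains exactly the genes with CPM >= `minCpm` in at least `minSamples`
#' samples. Library sizes are the column sums of the input matrix, so the
#' filter is idempotent: a second application with the library sizes of the
#' already-filtered matrix would change them, hence the retained library
#' sizes are carried in the result's metadata and reused.
#'
#' @param x a counts [MantleExperiment-class].
#' @param minCpm non-negative CPM cutoff.
#' @param minSamples non-negative integer, number of samples required at or
#'   above the cutoff (must not exceed the sample count).
#' @return The filtered [MantleExperiment-class]; gene order and the sample
#'   set are unchanged.
#' @export
filterLowExpression <- function(x, minCpm = 1, minSamples = 2) {
  stopifnot(is(x, "MantleExperiment"))
  if (valueKind(x) != "counts") stop("filterLowExpression expects counts")
  if (minCpm < 0 || minSamples < 0)
    stop("minCpm and minSamples must be non-negative")
  counts <- exprValues(x)
  if (minSamples > ncol(counts))
    stop("minSamples exceeds the number of samples")
  libs <- metadata(x)$filter_library_sizes
  if (is.null(libs)) libs <- .library_sizes(counts)
  cpm <- sweep(counts, 2L, 1e6 / libs, "*")
  keep <- rowSums(cpm >= minCpm) >= minSamples
  out <- MantleExperiment(counts[keep, , drop = FALSE],
                          design = .design_or_null(x), valueKind = "counts")
  metadata(out)$filter_library_sizes <- libs
  out
}
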