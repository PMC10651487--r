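#' Write a cohort to a directory of plain-text files
#'
#' Layout: `counts.mtx` (MatrixMarket coordinate), `genes.tsv`,
#' `barcodes.tsv`, `cells.tsv` (cell_id, sample_id, cell_type, state,
#' emb_*), `samples.tsv` and `truth_composition.tsv`. The pair
#' [read_cohort()] / `write_cohort()` round-trips exactly.
#'
#' @param cohort A `ctap_cohort`.
#' @param directory Output directory (created if missing).
#' @return `directory`, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "ctap_cohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(directory, f)
  if (!is.null(cohort$counts)) {
    Matrix::writeMM(methods::as(cohort$counts, "CsparseMatrix"), p("counts.mtx"))
    writeLines(rownames(cohort$counts), p("genes.tsv"))
    writeLines(colnames(cohort$counts), p("barcodes.tsv"))
  }
  utils::write.table(cohort$cell_table, p("cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$sample_meta, p("samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tc <- data.frame(sample_id = rownames(cohort$truth$composition),
                   unclass(cohort$truth$composition), check.names = FALSE)
  utils::write.table(tc, p("truth_composition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(directory)
}

#' Read a cohort written by [write_cohort()]
#'
#' Validates the MatrixMarket header and the agreement between matrix
#' dimensions and the gene/barcode/cell metadata files before assembling
#' the cohort object.
#'
#' @param directory Directory produced by [write_cohort()].
#' @return A `ctap_cohort` (without the original `config`).
#' @export
read_cohort <- function(directory) {
  p <- function(f) file.path(directory, f)
  if (!file.exists(p("cells.tsv"))) stop("missing cells.tsv in ", directory)
  cell_table <- utils::read.table(p("cells.tsv"), sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
  sample_meta <- utils::read.table(p("samples.tsv"), sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE)
  counts <- NULL
  gene_ids <- NULL
  if (file.exists(p("counts.mtx"))) {
    header <- readLines(p("counts.mtx"), n = 1L)
    if (!grepl("^%%MatrixMarket matrix coordinate", header))
      stop("malformed MatrixMarket header in counts.mtx: ", header)
    counts <- Matrix::readMM(p("counts.mtx"))
    gene_ids <- readLines(p("genes.tsv"))
    barcodes <- readLines(p("barcodes.tsv"))
    if (length(gene_ids) != nrow(counts))
      stop("dimension mismatch: ", length(gene_ids), " genes in genes.tsv vs ",
           nrow(counts), " matrix rows")
    if (length(barcodes) != ncol(counts))
      stop("dimension mismatch: ", length(barcodes),
           " barcodes in barcodes.tsv vs ", ncol(counts), " matrix columns")
    if (nrow(cell_table) != ncol(counts))
      stop("dimension mismatch: ", nrow(cell_table), " cells in cells.tsv vs ",
           ncol(counts), " matrix columns")
    counts <- methods::as(counts, "CsparseMatrix")
    dimnames(counts) <- list(gene_ids, barcodes)
  }
  missing_samples <- setdiff(cell_table$sample_id, sample_meta$sample_id)
  if (length(missing_samples))
    stop("cells reference samples absent from samples.tsv: ",
         paste(missing_samples, collapse = ", "))
  tc <- utils::read.table(p("truth_composition.tsv"), sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  comp <- as.matrix(tc[, -1, drop = FALSE])
  rownames(comp) <- tc$sample_id
  phenotype <- stats::setNames(sample_meta$phenotype, sample_meta$sample_id)
  structure(list(cell_table = cell_table, counts = counts,
                 sample_meta = sample_meta, gene_ids = gene_ids,
                 truth = list(phenotype = phenotype,
                              composition = as_composition(comp, tol = 1e-6)),
                 config = NULL),
            class = "ctap_cohort")
}
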