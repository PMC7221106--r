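#' Read a 10x-style MatrixMarket directory
#'
#' Reads a sparse gene-by-cell UMI count matrix stored in the plain-text
#' 10x convention: `matrix.mtx` (MatrixMarket triplet, genes as rows),
#' `genes.tsv` (one gene identifier per row, optional second name column)
#' and `barcodes.tsv` (one cell barcode per row).
#'
#' @param dirPath Directory containing `matrix.mtx`, `genes.tsv` and
#'   `barcodes.tsv`.
#' @return A [Matrix::sparseMatrix()] (class `dgCMatrix`) of nonnegative
#'   integer counts, genes as rows, with `dimnames` taken from the gene and
#'   barcode tables in file order.
#' @export
read_10x_mtx <- function(dirPath) {
  paths <- file.path(dirPath, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  for (p in paths) {
    if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
  }
  m <- as(Matrix::readMM(paths[1L]), "CsparseMatrix")
  genes <- utils::read.delim(paths[2L], header = FALSE,
                             stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(paths[3L], header = FALSE,
                                stringsAsFactors = FALSE)
  if (nrow(genes) != nrow(m)) {
    stop(sprintf(
      "gene table does not match matrix header: expected %d rows, found %d",
      nrow(m), nrow(genes)), call. = FALSE)
  }
  if (nrow(barcodes) != ncol(m)) {
    stop(sprintf(
      "barcode table does not match matrix header: expected %d rows, found %d",
      ncol(m), nrow(barcodes)), call. = FALSE)
  }
  if (any(m@x < 0)) stop("negative counts in matrix", call. = FALSE)
  dimnames(m) <- list(genes[[1L]], barcodes[[1L]])
  m
}

#' Write a count matrix in the 10x MatrixMarket layout
#'
#' Inverse of [read_10x_mtx()]: writes `matrix.mtx`, `genes.tsv` and
#' `barcodes.tsv` into `dirPath` (created if absent).
#'
#' @param counts Sparse or dense genes-by-cells count matrix with dimnames.
#' @param dirPath Output directory.
#' @return `dirPath`, invisibly.
#' @export
write_10x_mtx <- function(counts, dirPath) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and cell colnames", call. = FALSE)
  }
  dir.create(dirPath, recursive = TRUE, showWarnings = FALSE)
  m <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(m, file.path(dirPath, "matrix.mtx"))
  utils::write.table(data.frame(rownames(counts)),
                     file.path(dirPath, "genes.tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(colnames(counts)),
                     file.path(dirPath, "barcodes.tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(dirPath)
}

#' Read a GMT gene-set file
#'
#' Each line is tab-separated: set name, description, then one or more
#' member genes. Duplicate members within a set are dropped.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of unique character vectors (gene sets).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", i),
           call. = FALSE)
    }
    nms[i] <- fields[1L]
    sets[[i]] <- unique(fields[-c(1L, 2L)])
  }
  names(sets) <- nms
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
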