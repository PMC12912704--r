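#' Read an expression matrix from disk
#'
#' Three on-disk layouts are supported, all normalized to cells-in-rows,
#' genes-in-columns on read:
#' \describe{
#'   \item{`tsv`}{tab-separated matrix; header row = gene names, first column
#'     = cell names.}
#'   \item{`mtx_triplet`}{MatrixMarket sparse triplets with genes in rows and
#'     cells in columns (the usual single-cell convention), plus sidecar
#'     files `<stem>_features.txt` (gene names) and `<stem>_barcodes.txt`
#'     (cell names), one name per line.}
#'   \item{`h5_container`}{an HDF5 file with datasets `X` (cells x genes),
#'     `obs_names` (cells) and `var_names` (genes).}
#' }
#'
#' @param path file path.
#' @param format one of `"tsv"`, `"mtx_triplet"`, `"h5_container"`.
#' @param modality modality tag for the returned object.
#' @return A validated [ExpressionMatrix-class].
#' @export
readExpression <- function(path, format = c("tsv", "mtx_triplet", "h5_container"),
                           modality = c("scrna", "st")) {
  format <- match.arg(format)
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
    v <- as.matrix(df)
    return(ExpressionMatrix(v, colnames(v), rownames(df), modality))
  }
  if (format == "mtx_triplet") {
    stem <- sub("\\.mtx$", "", path)
    genes <- readLines(paste0(stem, "_features.txt"))
    cells <- readLines(paste0(stem, "_barcodes.txt"))
    sp <- Matrix::readMM(path)
    v <- t(as.matrix(sp))  # stored genes x cells
    if (nrow(v) != length(cells) || ncol(v) != length(genes)) {
      stop("sidecar name files do not match matrix dimensions")
    }
    return(ExpressionMatrix(v, genes, cells, modality))
  }
  x <- rhdf5::h5read(path, "X")
  obs <- as.character(rhdf5::h5read(path, "obs_names"))
  var <- as.character(rhdf5::h5read(path, "var_names"))
  ExpressionMatrix(as.matrix(x), var, obs, modality)
}

#' Write an expression matrix to disk
#'
#' Inverse of [readExpression()]: reading the written file reproduces the
#' gene and cell names exactly and the values to float round-trip tolerance
#' (TSV is written at full `%.17g` precision; the other formats are binary or
#' exact).
#'
#' @param x an [ExpressionMatrix-class].
#' @param path destination path.
#' @param format one of `"tsv"`, `"mtx_triplet"`, `"h5_container"`.
#' @return Invisibly, `path`.
#' @export
writeExpression <- function(x, path,
                            format = c("tsv", "mtx_triplet", "h5_container")) {
  format <- match.arg(format)
  stopifnot(is(x, "ExpressionMatrix"))
  if (length(x@geneNames) == 0L) stop("refusing to write a matrix with no genes")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("parent directory does not exist: ", dir)
  if (format == "tsv") {
    v <- x@values
    df <- data.frame(cell = x@cellNames,
                     matrix(sprintf("%.17g", v), nrow = nrow(v)),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("cell", x@geneNames)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "mtx_triplet") {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(methods::as(Matrix::Matrix(t(x@values), sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(x@geneNames, paste0(stem, "_features.txt"))
    writeLines(x@cellNames, paste0(stem, "_barcodes.txt"))
  } else {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(x@values, path, "X")
    rhdf5::h5write(x@cellNames, path, "obs_names")
    rhdf5::h5write(x@geneNames, path, "var_names")
    rhdf5::h5closeAll()
  }
  invisible(path)
}
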