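#' @import methods
NULL

#' ExpressionMatrix: labelled nonnegative expression values
#'
#' The central container of the package: a dense cells-by-genes matrix of
#' nonnegative expression values with unique gene and cell identifiers and a
#' modality tag. Both the scRNA-seq reference and the spatial (ST) matrix are
#' held in this class; the convention throughout is cells in rows, genes in
#' columns.
#'
#' @slot values numeric matrix, `n_cells x n_genes`, no negative entries.
#' @slot geneNames character vector of unique gene identifiers (columns).
#' @slot cellNames character vector of unique cell identifiers (rows).
#' @slot modality either `"scrna"` or `"st"`.
#'
#' @seealso [ExpressionMatrix()] for the constructor, [readExpression()],
#'   [buildGeneMask()].
#' @export
setClass("ExpressionMatrix",
  representation(
    values = "matrix",
    geneNames = "character",
    cellNames = "character",
    modality = "character"
  )
)

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (length(v) && any(!is.finite(v))) {
    msg <- c(msg, "values must be finite")
  } else if (length(v) && any(v < 0)) {
    msg <- c(msg, "negative expression values are not allowed")
  }
  if (ncol(v) != length(object@geneNames)) {
    msg <- c(msg, "length(geneNames) must equal ncol(values)")
  }
  if (nrow(v) != length(object@cellNames)) {
    msg <- c(msg, "length(cellNames) must equal nrow(values)")
  }
  dup <- object@geneNames[duplicated(object@geneNames)]
  if (length(dup)) {
    msg <- c(msg, paste0("duplicate gene names: ",
                         paste(unique(dup), collapse = ", ")))
  }
  if (anyDuplicated(object@cellNames)) {
    msg <- c(msg, "duplicate cell names")
  }
  if (length(object@modality) != 1L ||
      !object@modality %in% c("scrna", "st")) {
    msg <- c(msg, "modality must be one of 'scrna', 'st'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, cells in rows, genes in columns.
#' @param geneNames character vector of column (gene) identifiers; defaults
#'   to `colnames(values)`.
#' @param cellNames character vector of row (cell) identifiers; defaults to
#'   `rownames(values)`, or `cell_1..cell_n` when absent.
#' @param modality `"scrna"` or `"st"`.
#' @return A validated [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rpois(6, 4), 3, 2, dimnames = list(NULL, c("gA", "gB")))
#' ExpressionMatrix(m, modality = "scrna")
#' @export
ExpressionMatrix <- function(values, geneNames = colnames(values),
                             cellNames = rownames(values),
                             modality = c("scrna", "st")) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(geneNames)) stop("gene names are required")
  if (is.null(cellNames)) cellNames <- paste0("cell_", seq_len(nrow(values)))
  dimnames(values) <- list(cellNames, geneNames)
  new("ExpressionMatrix", values = values,
      geneNames = as.character(geneNames),
      cellNames = as.character(cellNames), modality = modality)
}

#' GeneMask: shared- vs unique-gene indicator
#'
#' Binary cells-by-genes matrix `m` over the reference gene axis: a column is
#' 1 when the gene is measured in both modalities (a "shared" gene used as
#' conditioning signal) and 0 when it is unique to the reference (the genes
#' the model imputes). Columns are constant by construction.
#'
#' @slot m binary matrix (`n_cells x n_genes`).
#' @slot sharedGenes character vector of shared gene names in reference
#'   column order.
#' @slot geneNames all reference gene names, column order of `m`.
#' @export
setClass("GeneMask",
  representation(m = "matrix", sharedGenes = "character",
                 geneNames = "character")
)

setValidity("GeneMask", function(object) {
  msg <- character()
  if (!all(object@m %in% c(0, 1))) msg <- c(msg, "mask entries must be 0/1")
  if (ncol(object@m) != length(object@geneNames)) {
    msg <- c(msg, "geneNames length must match mask columns")
  }
  cm <- colMeans(object@m)
  if (nrow(object@m) > 1L && any(cm > 0 & cm < 1)) {
    msg <- c(msg, "mask columns must be constant (gene shared for all cells or none)")
  }
  if (!all(object@sharedGenes %in% object@geneNames)) {
    msg <- c(msg, "sharedGenes must be a subset of geneNames")
  }
  if (length(msg)) msg else TRUE
})

#' NoiseSchedule: per-step and cumulative retention factors
#'
#' Holds the diffusion schedule: per-step retention factors `alpha[t]` in
#' (0,1) and their cumulative products `gamma[t]`, strictly decreasing in t.
#'
#' @slot T integer number of diffusion steps.
#' @slot alpha numeric vector of length T.
#' @slot gamma numeric vector of length T, `gamma[t] = prod(alpha[1:t])`.
#' @slot offset the small cosine-schedule offset used to build the schedule.
#' @export
setClass("NoiseSchedule",
  representation(T = "integer", alpha = "numeric", gamma = "numeric",
                 offset = "numeric")
)

setValidity("NoiseSchedule", function(object) {
  msg <- character()
  if (object@T < 1L) msg <- c(msg, "T must be >= 1")
  if (length(object@alpha) != object@T || length(object@gamma) != object@T) {
    msg <- c(msg, "alpha and gamma must have length T")
  }
  if (any(object@alpha <= 0) || any(object@alpha >= 1)) {
    msg <- c(msg, "alpha must lie strictly in (0,1)")
  }
  if (object@T > 1L && any(diff(object@gamma) >= 0)) {
    msg <- c(msg, "gamma must be strictly decreasing")
  }
  rel <- abs(object@gamma - cumprod(object@alpha)) /
    pmax(abs(cumprod(object@alpha)), 1e-300)
  if (any(rel > 1e-10)) msg <- c(msg, "gamma must equal cumprod(alpha)")
  if (length(msg)) msg else TRUE
})

#' SplitPlan: gene-holdout cross-validation assignment
#'
#' Partition of the shared genes into k folds of near-equal size. During fold
#' i, that fold's genes are relabelled "unique" (dropped from the ST
#' conditional) and scored against their measured values.
#'
#' @slot foldAssignments named integer vector mapping gene name to fold index
#'   in `0..k-1`.
#' @slot k integer fold count.
#' @export
setClass("SplitPlan",
  representation(foldAssignments = "integer", k = "integer")
)

setValidity("SplitPlan", function(object) {
  msg <- character()
  if (object@k < 2L) msg <- c(msg, "k must be >= 2")
  f <- object@foldAssignments
  if (is.null(names(f)) || anyDuplicated(names(f))) {
    msg <- c(msg, "foldAssignments must be uniquely named by gene")
  }
  if (length(f) && (min(f) < 0L || max(f) >= object@k)) {
    msg <- c(msg, "fold indices must lie in 0..k-1")
  }
  sizes <- tabulate(f + 1L, nbins = object@k)
  if (length(f) && diff(range(sizes)) > 1L) {
    msg <- c(msg, "fold sizes must differ by at most one")
  }
  if (length(msg)) msg else TRUE
})
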