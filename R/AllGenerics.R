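#' Accessors for ExpressionMatrix and GeneMask
#'
#' `exprValues()` returns the dense cells-by-genes matrix, `geneNames()` and
#' `cellNames()` the identifiers, `modality()` the modality tag,
#' `sharedGenes()` the shared-gene names of a [GeneMask-class], and
#' `maskMatrix()` its binary matrix.
#'
#' @param x an [ExpressionMatrix-class] or [GeneMask-class] object.
#' @return The slot contents as documented per accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))
#' @rdname accessors
#' @export
setGeneric("cellNames", function(x) standardGeneric("cellNames"))
#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname accessors
#' @export
setGeneric("sharedGenes", function(x) standardGeneric("sharedGenes"))
#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname accessors
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)
#' @rdname accessors
setMethod("geneNames", "ExpressionMatrix", function(x) x@geneNames)
#' @rdname accessors
setMethod("cellNames", "ExpressionMatrix", function(x) x@cellNames)
#' @rdname accessors
setMethod("modality", "ExpressionMatrix", function(x) x@modality)
#' @rdname accessors
setMethod("geneNames", "GeneMask", function(x) x@geneNames)
#' @rdname accessors
setMethod("sharedGenes", "GeneMask", function(x) x@sharedGenes)
#' @rdname accessors
setMethod("maskMatrix", "GeneMask", function(x) x@m)

setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix (%s): %d cells x %d genes\n",
              object@modality, nrow(object@values), ncol(object@values)))
  g <- object@geneNames
  cat("  genes: ", paste(utils::head(g, 5), collapse = ", "),
      if (length(g) > 5) ", ..." else "", "\n", sep = "")
  cat(sprintf("  values: min %.3g, max %.3g, %.1f%% zero\n",
              min(object@values), max(object@values),
              100 * mean(object@values == 0)))
})

setMethod("show", "GeneMask", function(object) {
  cat(sprintf("GeneMask: %d genes, %d shared / %d unique (x %d cells)\n",
              length(object@geneNames), length(object@sharedGenes),
              length(object@geneNames) - length(object@sharedGenes),
              nrow(object@m)))
})

setMethod("show", "NoiseSchedule", function(object) {
  cat(sprintf("NoiseSchedule: T = %d (cosine, offset %.4g); gamma %ss from %.4g to %.4g\n",
              object@T, object@offset, "range", object@gamma[1],
              object@gamma[object@T]))
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan: %d genes in %d folds (sizes %s)\n",
              length(object@foldAssignments), object@k,
              paste(tabulate(object@foldAssignments + 1L, object@k),
                    collapse = "/")))
})
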