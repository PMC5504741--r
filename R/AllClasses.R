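#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData assayNames
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.OMICS_LAYERS <- c("transcriptome", "metabolome", "targeted_metabolome")
.OMICS_SCALES <- c("raw", "log2")
.CONDITIONS <- c("control", "D", "H_LrH", "H_HrH", "DH_LrH", "DH_HrH")

#' Container for one omics layer
#'
#' An `OmicsExperiment` is a [SummarizedExperiment::SummarizedExperiment]
#' holding a variables-by-samples intensity matrix for one measurement layer
#' (microarray transcriptome, non-targeted metabolome, or targeted
#' metabolome), together with a logical `missing` assay marking values below
#' the instrument's detection limit. The transcriptome layer is complete by
#' contract: microarray matrices carry no missing values. The `scale` slot
#' records whether values are raw intensities or log2-transformed; the
#' transition is one-way (`raw` to `log2`).
#'
#' @slot layer one of `"transcriptome"`, `"metabolome"`,
#'   `"targeted_metabolome"`.
#' @slot scale one of `"raw"`, `"log2"`.
#' @export
setClass("OmicsExperiment",
  contains = "SummarizedExperiment",
  representation(layer = "character", scale = "character")
)

setValidity("OmicsExperiment", function(object) {
  msg <- character()
  if (length(object@layer) != 1L || !object@layer %in% .OMICS_LAYERS)
    msg <- c(msg, sprintf("layer must be one of: %s",
                          paste(.OMICS_LAYERS, collapse = ", ")))
  if (length(object@scale) != 1L || !object@scale %in% .OMICS_SCALES)
    msg <- c(msg, "scale must be 'raw' or 'log2'")
  if (!all(c("intensity", "missing") %in% assayNames(object)))
    msg <- c(msg, "assays 'intensity' and 'missing' are required")
  else {
    v <- assay(object, "intensity")
    m <- assay(object, "missing")
    if (!is.logical(m)) msg <- c(msg, "'missing' assay must be logical")
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, "duplicate variable id")
    if (anyDuplicated(colnames(object)))
      msg <- c(msg, "duplicate sample id")
    if (is.null(rownames(object)) || is.null(colnames(object)))
      msg <- c(msg, "variable and sample ids are required")
    if (identical(object@layer, "transcriptome")) {
      if (any(m)) msg <- c(msg, "transcriptome layer must have no missing values")
      if (anyNA(v)) msg <- c(msg, "NA in transcriptome layer")
    } else {
      if (any(is.na(v) & !m))
        msg <- c(msg, "NA intensity at cells not flagged missing")
    }
    if (identical(object@scale, "raw") && any(v[!m] <= 0, na.rm = TRUE))
      msg <- c(msg, "raw-scale intensities must be strictly positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsExperiment
#'
#' @param values numeric variables-by-samples matrix with row and column
#'   names. `NA` cells are taken as missing (metabolome layers only).
#' @param layer measurement layer label.
#' @param scale `"raw"` (default) or `"log2"`.
#' @param missing optional logical matrix of the same shape; defaults to
#'   `is.na(values)`.
#' @param colData optional per-sample annotation (e.g. a design table).
#' @return an `OmicsExperiment`.
#' @examples
#' m <- matrix(2^rnorm(6, 10), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' oe <- OmicsExperiment(m, layer = "transcriptome")
#' @export
OmicsExperiment <- function(values, layer, scale = "raw", missing = NULL,
                            colData = NULL) {
  values <- as.matrix(values)
  if (is.null(missing)) missing <- is.na(values)
  storage.mode(missing) <- "logical"
  dimnames(missing) <- dimnames(values)
  if (is.null(colData))
    colData <- DataFrame(row.names = colnames(values))
  se <- SummarizedExperiment(
    assays = list(intensity = values, missing = missing),
    colData = colData)
  new("OmicsExperiment", se, layer = layer, scale = scale)
}

#' @describeIn OmicsExperiment measurement layer of the object.
#' @param object,x an `OmicsExperiment`.
#' @export
setGeneric("omicsLayer", function(object) standardGeneric("omicsLayer"))

#' @rdname OmicsExperiment
#' @export
setMethod("omicsLayer", "OmicsExperiment", function(object) object@layer)

#' @describeIn OmicsExperiment `"raw"` or `"log2"`.
#' @export
setGeneric("valueScale", function(object) standardGeneric("valueScale"))

#' @rdname OmicsExperiment
#' @export
setMethod("valueScale", "OmicsExperiment", function(object) object@scale)

#' @describeIn OmicsExperiment the intensity matrix.
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname OmicsExperiment
#' @export
setMethod("intensities", "OmicsExperiment",
          function(object) assay(object, "intensity"))

#' @describeIn OmicsExperiment logical not-detected mask.
#' @export
setGeneric("missingMask", function(object) standardGeneric("missingMask"))

#' @rdname OmicsExperiment
#' @export
setMethod("missingMask", "OmicsExperiment",
          function(object) assay(object, "missing"))

setMethod("show", "OmicsExperiment", function(object) {
  cat(sprintf("OmicsExperiment (%s, %s scale): %d variables x %d samples\n",
              object@layer, object@scale, nrow(object), ncol(object)))
  nmiss <- sum(assay(object, "missing"))
  if (nmiss > 0)
    cat(sprintf("  %d missing cells (%.1f%%)\n", nmiss,
                100 * nmiss / length(assay(object, "missing"))))
  callNextMethod()
})

#' Fitted regularized CCA model
#'
#' Holds canonical correlations, per-layer projection weights and sample
#' scores of a ridge-regularized canonical correlation analysis, together
#' with the regularization intensities used.
#'
#' @slot cor numeric vector of canonical correlations, non-increasing.
#' @slot xWeights,yWeights variables-by-components weight matrices.
#' @slot xScores,yScores samples-by-components canonical variate scores.
#' @slot lambdaX,lambdaY ridge shrinkage intensities in \[0, 1\].
#' @slot xVariables,yVariables ids of the variables entering the fit.
#' @export
setClass("CCAModel", representation(
  cor = "numeric",
  xWeights = "matrix", yWeights = "matrix",
  xScores = "matrix", yScores = "matrix",
  lambdaX = "numeric", lambdaY = "numeric",
  xVariables = "character", yVariables = "character"))

setValidity("CCAModel", function(object) {
  msg <- character()
  if (any(diff(object@cor) > 1e-8))
    msg <- c(msg, "canonical correlations must be non-increasing")
  if (any(object@cor < -1e-8 | object@cor > 1 + 1e-8))
    msg <- c(msg, "canonical correlations must lie in [0, 1]")
  if (object@lambdaX < 0 || object@lambdaX > 1 ||
      object@lambdaY < 0 || object@lambdaY > 1)
    msg <- c(msg, "lambda must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn CCAModel canonical correlations.
#' @param object a `CCAModel`.
#' @export
setGeneric("canonicalCorrelations",
           function(object) standardGeneric("canonicalCorrelations"))

#' @rdname CCAModel
#' @export
setMethod("canonicalCorrelations", "CCAModel", function(object) object@cor)

#' @describeIn CCAModel samples-by-components score matrices as a list with
#'   elements `x` and `y`.
#' @export
setGeneric("sampleScores", function(object) standardGeneric("sampleScores"))

#' @rdname CCAModel
#' @export
setMethod("sampleScores", "CCAModel",
          function(object) list(x = object@xScores, y = object@yScores))

setMethod("show", "CCAModel", function(object) {
  cat(sprintf("CCAModel: %d components, lambda = (%.3g, %.3g)\n",
              length(object@cor), object@lambdaX, object@lambdaY))
  cat("  canonical correlations:",
      paste(sprintf("%.3f", object@cor), collapse = ", "), "\n")
})
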