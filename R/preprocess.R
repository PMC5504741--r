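.designFor <- function(m, design = NULL) {
  if (is.null(design)) design <- as.data.frame(SummarizedExperiment::colData(m))
  if (!nrow(design) || is.null(design$condition))
    stop("a design with a 'condition' column is required")
  if (!all(colnames(m) %in% rownames(design)))
    stop("samples of the matrix are missing from the design")
  design[colnames(m), , drop = FALSE]
}

#' Quantile-normalize a complete intensity matrix
#'
#' Forces every sample (column) to share the same empirical distribution:
#' each column's sorted values are replaced by the across-column mean of
#' sorted values; ties within a column receive the mean of the reference
#' values over their rank span. Only valid for the complete transcriptome
#' layer; metabolome matrices with missing values are normalized by total
#' ion current instead ([ticNormalize()]).
#'
#' @param m an [OmicsExperiment] without missing values.
#' @return the normalized [OmicsExperiment].
#' @export
quantileNormalize <- function(m) {
  if (any(missingMask(m)))
    stop("quantile normalization requires a complete matrix; ",
         "use ticNormalize() for metabolome layers")
  v <- limma::normalizeQuantiles(intensities(m), ties = TRUE)
  dimnames(v) <- dimnames(intensities(m))
  SummarizedExperiment::assay(m, "intensity") <- v
  m
}

#' Normalize metabolite intensities by total ion current
#'
#' Divides each observed value by its sample's sum of observed intensities
#' (the total ion current), then rescales by the mean column sum so
#' magnitudes remain comparable to the raw scale.
#'
#' @param m a raw-scale metabolome [OmicsExperiment].
#' @return the normalized [OmicsExperiment].
#' @export
ticNormalize <- function(m) {
  if (!identical(valueScale(m), "raw"))
    stop("TIC normalization applies to raw-scale data")
  v <- intensities(m)
  obs <- !missingMask(m) & !is.na(v)
  tic <- colSums(v * obs, na.rm = TRUE)
  if (any(tic == 0)) stop("sample with no observed values: ",
                          paste(colnames(v)[tic == 0], collapse = ", "))
  v <- sweep(v, 2L, tic, "/") * mean(tic)
  SummarizedExperiment::assay(m, "intensity") <- v
  m
}

#' Filter metabolite masses by per-condition detection
#'
#' Retains a variable if it is observed in at least `detect_fraction` of the
#' samples of at least one condition; computed on the pre-imputation missing
#' mask, so a floor-imputed value never counts as detected.
#'
#' @param m a metabolome [OmicsExperiment].
#' @param design optional design table (defaults to `colData(m)`).
#' @param detect_fraction minimum within-condition detection fraction
#'   (default 2/3).
#' @return the filtered [OmicsExperiment].
#' @export
filterByDetection <- function(m, design = NULL, detect_fraction = 2 / 3) {
  design <- .designFor(m, design)
  cond <- droplevels(factor(design$condition))
  if (any(table(cond) == 0)) stop("condition with zero samples")
  obs <- !missingMask(m)
  keep <- rep(FALSE, nrow(m))
  for (cc in levels(cond)) {
    idx <- which(cond == cc)
    frac <- rowMeans(obs[, idx, drop = FALSE])
    keep <- keep | (frac >= detect_fraction - 1e-12)
  }
  m[keep, ]
}

#' Impute censored values at the detection floor and log2-transform
#'
#' Sets every not-detected cell to the instrument's lower detection limit and
#' takes log2 of the whole matrix. The missing mask is retained for
#' provenance; the scale becomes `log2`.
#'
#' @param m a raw-scale [OmicsExperiment].
#' @param floor detection limit (default 5e5).
#' @return the imputed, log2-scale [OmicsExperiment].
#' @export
imputeFloorAndLog <- function(m, floor = 5e5) {
  if (!identical(valueScale(m), "raw"))
    stop("matrix is already log2-transformed")
  stopifnot(floor > 0)
  v <- intensities(m)
  mask <- missingMask(m)
  if (any(v[!mask] <= 0, na.rm = TRUE))
    stop("non-positive observed intensity")
  v[mask] <- floor
  v <- log2(v)
  SummarizedExperiment::assay(m, "intensity") <- v
  m@scale <- "log2"
  validObject(m)
  m
}

#' Remove batch (and measurement-order) effects
#'
#' Fits an additive linear model with the condition factor preserved and the
#' batch factor (sum-to-zero coded) plus an optional numeric
#' measurement-order covariate removed, per variable. On balanced designs
#' this leaves condition-mean differences exactly invariant.
#'
#' @param m a log2-scale [OmicsExperiment].
#' @param design optional design table with `condition` and `batch` columns.
#' @param order_covariate optional name of a numeric design column (e.g.
#'   replicate measurement order) removed as a linear covariate.
#' @return the corrected [OmicsExperiment].
#' @export
correctBatch <- function(m, design = NULL, order_covariate = NULL) {
  if (!identical(valueScale(m), "log2"))
    stop("batch correction expects log2-scale data")
  design <- .designFor(m, design)
  batch <- droplevels(factor(design$batch))
  if (nlevels(batch) < 2L) return(m)
  cond <- droplevels(factor(design$condition))
  mm <- stats::model.matrix(~cond + batch)
  if (qr(mm)$rank < ncol(mm))
    stop("batch and condition are confounded (rank-deficient design)")
  cov <- NULL
  if (!is.null(order_covariate)) {
    cov <- as.numeric(design[[order_covariate]])
    if (anyNA(cov)) stop("order covariate has missing values")
  }
  v <- limma::removeBatchEffect(intensities(m), batch = batch,
                                covariates = cov,
                                design = stats::model.matrix(~cond))
  dimnames(v) <- dimnames(intensities(m))
  SummarizedExperiment::assay(m, "intensity") <- v
  m
}

#' Average probe-level rows into gene-level rows
#'
#' @param m a probe-level [OmicsExperiment].
#' @param probe_to_gene named character vector mapping probe ids (names) to
#'   gene ids; unmapped probes are dropped with a message.
#' @return gene-level [OmicsExperiment].
#' @export
collapseProbes <- function(m, probe_to_gene) {
  probes <- rownames(m)
  mapped <- probes[probes %in% names(probe_to_gene)]
  dropped <- length(probes) - length(mapped)
  if (dropped > 0)
    message(dropped, " unmapped probe(s) dropped")
  if (!length(mapped)) stop("no probes could be mapped")
  v <- intensities(m)[mapped, , drop = FALSE]
  gene <- probe_to_gene[mapped]
  out <- rowsum(v, gene) / as.vector(table(gene)[sort(unique(gene))])
  out <- out[order(rownames(out)), , drop = FALSE]
  OmicsExperiment(out, layer = omicsLayer(m), scale = valueScale(m),
                  missing = matrix(FALSE, nrow(out), ncol(out),
                                   dimnames = dimnames(out)),
                  colData = SummarizedExperiment::colData(m))
}
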