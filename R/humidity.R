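#' Per-condition contrasts versus control
#'
#' Fits, per variable, a one-way linear model on the six-level condition
#' factor (all samples, genotypes pooled) and reports each stress condition's
#' estimate as its mean minus the control mean, with standard errors from the
#' pooled residual variance. Variances are optionally moderated as in
#' [fitFactorialModel()]; p-values are FDR-adjusted per condition across
#' variables.
#'
#' @param m a log2-scale [OmicsExperiment].
#' @param design optional design table.
#' @param moderation moderate variances (default `TRUE`).
#' @return a `data.frame` contrast table with columns `variable_id`,
#'   `condition`, `estimate`, `std_error`, `statistic`, `df`, `p_value`,
#'   `p_adjusted`.
#' @export
fitConditionContrasts <- function(m, design = NULL, moderation = TRUE) {
  design <- .designFor(m, design)
  cond <- factor(design$condition, levels = .CONDITIONS)
  cond <- droplevels(cond)
  if (!"control" %in% levels(cond)) stop("control samples are required")
  y <- intensities(m)[, rownames(design), drop = FALSE]
  X <- stats::model.matrix(~cond)
  colnames(X) <- sub("^cond", "", colnames(X))
  fit <- stats::lm.fit(X, t(y))
  cf <- fit$coefficients                    # lm.fit drops dims for 1 variable
  if (is.null(dim(cf)))
    cf <- matrix(cf, ncol = 1L, dimnames = list(names(cf), rownames(y)))
  coefs <- t(cf)
  res <- fit$residuals
  if (is.null(dim(res)))
    res <- matrix(res, ncol = 1L, dimnames = list(NULL, rownames(y)))
  df <- nrow(X) - ncol(X)
  s2 <- colSums(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  unscaled <- sqrt(diag(XtXinv))
  names(unscaled) <- colnames(X)
  if (moderation) {
    sq <- .squeezeVariances(s2, df)
    s2use <- sq$s2_post
    dfTotal <- df + sq$df_prior
  } else {
    s2use <- s2
    dfTotal <- df
  }
  conds <- setdiff(colnames(X), "(Intercept)")
  out <- do.call(rbind, lapply(conds, function(cc) {
    est <- coefs[, cc]
    se <- sqrt(s2use) * unscaled[cc]
    tt <- est / se
    p <- 2 * stats::pt(-abs(tt), df = dfTotal)
    data.frame(variable_id = rownames(coefs), condition = cc,
               estimate = est, std_error = se, statistic = tt,
               df = dfTotal, p_value = p, p_adjusted = adjustFDR(p),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

.conditionCalls <- function(contrasts, condition, th) {
  sub <- contrasts[contrasts$condition == condition, ]
  if (!nrow(sub)) stop("unknown condition label: ", condition)
  stats::setNames(
    .callOne(sub$estimate, sub$p_adjusted, th$lfc, th$alpha),
    sub$variable_id)
}

#' Venn decomposition of two conditions' regulated sets
#'
#' Applies the differential-call rule to both conditions' contrasts versus
#' control and partitions, per direction, the regulated variables into
#' A-only, B-only and overlap — e.g. low- versus high-air-humidity heat
#' responses, where the A-only set is the "dry air" component. A variable up
#' in A and down in B lands in A_only(up) and B_only(down).
#'
#' @param contrasts table from [fitConditionContrasts()].
#' @param pairA,pairB condition labels (e.g. `"H_LrH"`, `"H_HrH"`).
#' @param th a [thresholds()] list.
#' @return nested list: `$up` and `$down`, each with `A_only`, `B_only`,
#'   `overlap` character vectors of variable ids.
#' @export
vennDecompose <- function(contrasts, pairA, pairB, th = thresholds()) {
  callsA <- .conditionCalls(contrasts, pairA, th)
  callsB <- .conditionCalls(contrasts, pairB, th)
  ids <- union(names(callsA), names(callsB))
  out <- lapply(c(up = "up", down = "down"), function(dir) {
    A <- names(callsA)[callsA == dir]
    B <- names(callsB)[callsB == dir]
    list(A_only = setdiff(A, B), B_only = setdiff(B, A),
         overlap = intersect(A, B))
  })
  attr(out, "pair") <- c(A = pairA, B = pairB)
  out
}

#' Count regulated variables per condition
#'
#' @param contrasts table from [fitConditionContrasts()].
#' @param th a [thresholds()] list.
#' @return a `data.frame` with columns `condition`, `up`, `down`.
#' @export
countRegulated <- function(contrasts, th = thresholds()) {
  conds <- unique(contrasts$condition)
  out <- do.call(rbind, lapply(conds, function(cc) {
    calls <- .conditionCalls(contrasts, cc, th)
    data.frame(condition = cc, up = sum(calls == "up"),
               down = sum(calls == "down"), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
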