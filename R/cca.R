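#' Restrict two layers to their shared samples
#'
#' @param x,y [OmicsExperiment]s.
#' @return list with `x` and `y` restricted to the sample intersection, in
#'   `x`'s order.
#' @export
pairSamples <- function(x, y) {
  shared <- intersect(colnames(x), colnames(y))
  if (!length(shared)) stop("no shared samples between the two layers")
  list(x = x[, shared], y = y[, shared])
}

#' Keep the k highest-variance variables
#'
#' Ties are broken by variable id (lexicographic) for determinism.
#'
#' @param m an [OmicsExperiment].
#' @param k number of variables to keep.
#' @return the reduced [OmicsExperiment].
#' @export
selectTopVariance <- function(m, k) {
  if (k <= 0) stop("k must be positive")
  if (k > nrow(m)) stop("k exceeds the number of variables")
  v <- intensities(m)
  vars <- apply(v, 1L, stats::var)
  ord <- order(-vars, rownames(m))
  m[sort(ord[seq_len(k)]), ]
}

#' Analytic shrinkage intensity toward the identity correlation target
#'
#' Estimates the ridge weight `lambda* = sum var_hat(r_ij) / sum r_ij^2`
#' over the off-diagonal entries of the empirical correlation matrix, where
#' `var_hat(r_ij)` is the unbiased estimate of the sampling variance of each
#' correlation, clipped to \[0, 1\]. High-dimensional noisy data yield
#' lambda near 1; strongly correlated low-dimensional data yield lambda near
#' 0.
#'
#' @param m samples-by-variables numeric matrix (or an [OmicsExperiment],
#'   transposed internally).
#' @return shrinkage intensity in \[0, 1\].
#' @export
estimateShrinkageLambda <- function(m) {
  if (is(m, "OmicsExperiment")) m <- t(intensities(m))
  m <- as.matrix(m)
  n <- nrow(m); p <- ncol(m)
  if (n < 3L) stop("at least 3 samples required")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) stop("zero-variance variable; remove before estimation")
  xs <- scale(m)                       # standardized: w_kij = xs_ki * xs_kj
  S1 <- matrix(0, p, p); S2 <- matrix(0, p, p)
  for (k in seq_len(n)) {
    w <- tcrossprod(xs[k, ])
    S1 <- S1 + w
    S2 <- S2 + w * w
  }
  r <- S1 / (n - 1)
  wvar <- (S2 - S1^2 / n) * n / ((n - 1)^3)   # var_hat(r_ij)
  off <- upper.tri(r)
  denom <- sum(r[off]^2)
  if (denom == 0) return(1)
  min(1, max(0, sum(wvar[off]) / denom))
}

#' Fit ridge-regularized canonical correlation analysis
#'
#' Finds per-layer projection weights maximizing the correlation of the
#' projected samples, with the within-layer correlation matrices
#' regularized as `C + lambda I`. Weights are the leading eigenvectors of
#' `(Cxx+lx I)^-1 Cxy (Cyy+ly I)^-1 Cyx`; canonical correlations are the
#' square roots of its eigenvalues, returned non-increasing. Variables are
#' standardized internally (so covariance and correlation formulations
#' coincide); eigenvector signs are fixed so each component's
#' largest-magnitude x-weight is positive.
#'
#' @param x,y samples-by-variables matrices (or [OmicsExperiment]s) with
#'   identical sample order.
#' @param lambda_x,lambda_y ridge intensities in \[0, 1\]; `NULL` (default)
#'   estimates them by [estimateShrinkageLambda()].
#' @param n_components number of components (default 2).
#' @param standardize scale variables to unit variance (default `TRUE`).
#' @return a [CCAModel].
#' @export
fitRCCA <- function(x, y, lambda_x = NULL, lambda_y = NULL,
                    n_components = 2L, standardize = TRUE) {
  if (is(x, "OmicsExperiment")) x <- t(intensities(x))
  if (is(y, "OmicsExperiment")) y <- t(intensities(y))
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must share samples")
  n <- nrow(x)
  if (is.null(lambda_x)) lambda_x <- estimateShrinkageLambda(x)
  if (is.null(lambda_y)) lambda_y <- estimateShrinkageLambda(y)
  stopifnot(lambda_x >= 0, lambda_x <= 1, lambda_y >= 0, lambda_y <= 1)
  xc <- scale(x, scale = standardize)
  yc <- scale(y, scale = standardize)
  Cxx <- crossprod(xc) / (n - 1)
  Cyy <- crossprod(yc) / (n - 1)
  Cxy <- crossprod(xc, yc) / (n - 1)
  p <- ncol(x); q <- ncol(y)
  maxComp <- min(p, q, n - 1)
  if (n_components > maxComp)
    stop("n_components exceeds the rank of the problem")
  Mx <- Cxx + diag(lambda_x, p)
  My <- Cyy + diag(lambda_y, q)
  ex <- eigen(Mx, symmetric = TRUE)
  keep <- ex$values > max(ex$values) * 1e-12
  MxInvSqrt <- ex$vectors[, keep, drop = FALSE] %*%
    (t(ex$vectors[, keep, drop = FALSE]) / sqrt(ex$values[keep]))
  B <- MxInvSqrt %*% Cxy %*% solve(My, t(Cxy)) %*% MxInvSqrt
  eb <- eigen((B + t(B)) / 2, symmetric = TRUE)
  k <- seq_len(n_components)
  rho <- sqrt(pmin(pmax(eb$values[k], 0), 1))
  a <- MxInvSqrt %*% eb$vectors[, k, drop = FALSE]
  b <- solve(My, t(Cxy)) %*% a
  # unit-variance-in-regularized-metric scaling for b, and sign pinning
  for (j in k) {
    nb <- sqrt(drop(crossprod(b[, j], My %*% b[, j])))
    if (nb > 0) b[, j] <- b[, j] / nb
    top <- which.max(abs(a[, j]))
    if (a[top, j] < 0) { a[, j] <- -a[, j]; b[, j] <- -b[, j] }
  }
  xs <- xc %*% a; ys <- yc %*% b
  # align y scores with x scores (sign of b is only fixed up to rho's sign)
  for (j in k) {
    cj <- suppressWarnings(stats::cor(xs[, j], ys[, j]))
    if (!is.na(cj) && cj < 0) { b[, j] <- -b[, j]; ys[, j] <- -ys[, j] }
  }
  dimnames(a) <- list(colnames(x), paste0("C", k))
  dimnames(b) <- list(colnames(y), paste0("C", k))
  dimnames(xs) <- list(rownames(x), paste0("C", k))
  dimnames(ys) <- list(rownames(y), paste0("C", k))
  new("CCAModel", cor = rho, xWeights = a, yWeights = b,
      xScores = xs, yScores = ys, lambdaX = lambda_x, lambdaY = lambda_y,
      xVariables = rownames(a) %||% character(),
      yVariables = rownames(b) %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correlations between canonical variates and original variables
#'
#' For each component, correlates every original variable of each layer with
#' that layer's canonical score; p-values use the t-transform
#' `t = r sqrt((n-2)/(1-r^2))` with `n-2` df and are FDR-adjusted within
#' component and layer. Constant variables are reported with `NA` and
#' flagged.
#'
#' @param model a [CCAModel].
#' @param x,y the samples-by-variables matrices (or [OmicsExperiment]s) the
#'   model was fit on; may contain more variables than entered the fit.
#' @return a `data.frame` with `variable_id`, `layer`, `component`, `r`,
#'   `p_value`, `p_adjusted`, `constant`.
#' @export
variateVariableCorrelations <- function(model, x, y) {
  if (is(x, "OmicsExperiment")) x <- t(intensities(x))
  if (is(y, "OmicsExperiment")) y <- t(intensities(y))
  scores <- sampleScores(model)
  doLayer <- function(mat, sc, layer) {
    n <- nrow(mat)
    sds <- apply(mat, 2L, stats::sd)
    do.call(rbind, lapply(seq_len(ncol(sc)), function(j) {
      r <- suppressWarnings(as.vector(stats::cor(mat, sc[, j])))
      r[sds == 0] <- NA
      tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
      padj <- rep(NA_real_, length(p))
      ok <- !is.na(p)
      padj[ok] <- adjustFDR(p[ok])
      data.frame(variable_id = colnames(mat), layer = layer,
                 component = j, r = r, p_value = p, p_adjusted = padj,
                 constant = sds == 0, stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(doLayer(x, scores$x, "x"), doLayer(y, scores$y, "y"))
  rownames(out) <- NULL
  out
}
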