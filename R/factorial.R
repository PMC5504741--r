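#' Benjamini-Hochberg step-up adjustment
#'
#' Computes FDR-adjusted p-values by the step-up rule: after sorting
#' ascending, `p_adj(i) = min_{j >= i} m * p(j) / j`, clipped at 1. One call
#' corresponds to one adjustment family (e.g. one model coefficient across
#' all variables of one layer).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
adjustFDR <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric())
  o <- order(p)
  padj <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  out <- numeric(m)
  out[o] <- padj
  out
}

# Newton solve of trigamma(x) = y, vectorized; used by the moment estimator
# of the variance prior.
.trigammaInverse <- function(y) {
  out <- y
  hi <- y > 1e7; out[hi] <- 1 / sqrt(y[hi])
  lo <- y < 1e-6; out[lo] <- 1 / y[lo]
  mid <- !hi & !lo
  x <- 0.5 + 1 / y[mid]
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y[mid]) / psigamma(x, 2L)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  out[mid] <- x
  out
}

# Empirical-Bayes shrinkage of per-variable residual variances toward a
# common prior. The prior (s02, d0) is estimated by method of moments on the
# log variances: with z = log(s2), E[z] and Var[z] under the scaled-F model
# involve digamma/trigamma of d/2 and d0/2, so matching the sample moments
# reduces to one trigamma inversion.
.squeezeVariances <- function(s2, df) {
  ok <- s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(mean(e))
    s2post <- rep(s02, length(s2))
  } else {
    d0 <- 2 * .trigammaInverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    s2post <- (d0 * s02 + df * s2) / (d0 + df)
  }
  list(s2_prior = s02, df_prior = d0, s2_post = s2post)
}

#' Fit the two-factor drought-by-heat model per variable
#'
#' Restricts to the low-humidity factorial cells (`control`, `D`, `H_LrH`,
#' `DH_LrH`; the air-humidity settings are analyzed separately) and fits, per
#' variable, ordinary least squares on the model
#' `y = b0 + bD*D + bH*H + bDH*D*H` with the samples of all genotypes
#' pooled. With `moderation = TRUE` (default) residual variances are shrunk
#' toward an empirical-Bayes prior estimated by moment matching on the log
#' variances, and t-statistics use the moderated variance with augmented
#' degrees of freedom.
#'
#' @param m a log2-scale [OmicsExperiment].
#' @param design optional design table (defaults to `colData(m)`).
#' @param moderation logical; moderate variances (default `TRUE`).
#' @return an object of class `"FactorialFit"`: coefficients, standard
#'   errors, (moderated) t, p, residual and posterior variances, prior
#'   parameters.
#' @export
fitFactorialModel <- function(m, design = NULL, moderation = TRUE) {
  design <- .designFor(m, design)
  keep <- design$condition %in% c("control", "D", "H_LrH", "DH_LrH")
  design <- design[keep, , drop = FALSE]
  y <- intensities(m)[, rownames(design), drop = FALSE]
  if (!all(is.finite(y))) stop("non-finite values in matrix")
  D <- design$drought; H <- design$heat
  cellN <- table(paste(D, H))
  if (length(cellN) < 4L || any(cellN < 2L))
    stop("each of the four factorial cells needs at least 2 replicates")
  X <- cbind(intercept = 1, D = D, H = H, DH = D * H)
  n <- nrow(X); p <- ncol(X)
  fit <- stats::lm.fit(X, t(y))
  cf <- fit$coefficients                    # lm.fit drops dims for 1 variable
  if (is.null(dim(cf)))
    cf <- matrix(cf, ncol = 1L, dimnames = list(names(cf), rownames(y)))
  coefs <- t(cf)                            # variables x 4
  res <- fit$residuals                      # samples x variables
  if (is.null(dim(res)))
    res <- matrix(res, ncol = 1L, dimnames = list(NULL, rownames(y)))
  df <- n - p
  s2 <- colSums(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  unscaled <- sqrt(diag(XtXinv))            # per-coefficient sd factor
  if (moderation) {
    sq <- .squeezeVariances(s2, df)
    s2use <- sq$s2_post
    dfTotal <- df + sq$df_prior
  } else {
    sq <- list(s2_prior = NA_real_, df_prior = 0)
    s2use <- s2
    dfTotal <- df
  }
  se <- outer(sqrt(s2use), unscaled)
  dimnames(se) <- dimnames(coefs)
  tstat <- coefs / se
  pval <- 2 * stats::pt(-abs(tstat), df = dfTotal)
  structure(list(coefficients = coefs, stderr = se, t = tstat, p = pval,
                 s2 = s2, df = df, s2_post = s2use,
                 s2_prior = sq$s2_prior, df_prior = sq$df_prior,
                 df_total = dfTotal, moderation = moderation,
                 n_samples = n),
            class = "FactorialFit")
}

#' @export
print.FactorialFit <- function(x, ...) {
  cat(sprintf("FactorialFit: %d variables, %d samples, residual df %d\n",
              nrow(x$coefficients), x$n_samples, x$df))
  if (x$moderation)
    cat(sprintf("  moderated variances: prior df %.2f, prior var %.4g\n",
                x$df_prior, x$s2_prior))
  invisible(x)
}

#' Long-format contrast table from a factorial fit
#'
#' One row per variable and model term (`D`, `H`, `DH`), with
#' Benjamini-Hochberg adjustment applied per term across variables.
#'
#' @param fit a `"FactorialFit"`.
#' @return a `data.frame` with columns `variable_id`, `term`, `estimate`,
#'   `std_error`, `statistic`, `df`, `p_value`, `p_adjusted`.
#' @export
factorialContrasts <- function(fit) {
  terms <- c("D", "H", "DH")
  out <- do.call(rbind, lapply(terms, function(tm) {
    data.frame(variable_id = rownames(fit$coefficients), term = tm,
               estimate = fit$coefficients[, tm],
               std_error = fit$stderr[, tm],
               statistic = fit$t[, tm], df = fit$df_total,
               p_value = fit$p[, tm],
               p_adjusted = adjustFDR(fit$p[, tm]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

.callOne <- function(estimate, p_adjusted, lfc, alpha, use_lfc = TRUE) {
  sig <- p_adjusted < alpha & (!use_lfc | abs(estimate) > lfc)
  ifelse(sig & estimate > 0, "up", ifelse(sig & estimate < 0, "down", "ns"))
}

#' Per-variable significance calls for the three factorial terms
#'
#' A term is called `up` if its estimate exceeds the log2 fold-change
#' threshold and its adjusted p falls below `alpha`; `down` for the negated
#' rule; `ns` otherwise. By default the fold-change rule also applies to the
#' interaction term (`interaction_lfc = FALSE` drops it there).
#'
#' @param fit a `"FactorialFit"`.
#' @param th a [thresholds()] list.
#' @param interaction_lfc apply the fold-change rule to the interaction term
#'   (default `TRUE`).
#' @return a `data.frame` with columns `variable_id`, `D`, `H`, `DH`
#'   (each `up`/`down`/`ns`).
#' @export
callSignificance <- function(fit, th = thresholds(), interaction_lfc = TRUE) {
  co <- fit$coefficients
  padj <- apply(fit$p[, c("D", "H", "DH"), drop = FALSE], 2L, adjustFDR)
  data.frame(
    variable_id = rownames(co),
    D = .callOne(co[, "D"], padj[, "D"], th$lfc, th$alpha),
    H = .callOne(co[, "H"], padj[, "H"], th$lfc, th$alpha),
    DH = .callOne(co[, "DH"], padj[, "DH"], th$lfc, th$alpha,
                  use_lfc = interaction_lfc),
    stringsAsFactors = FALSE)
}

#' Classify variables into combined-stress response groups
#'
#' Total function over the 27 combinations of the three calls. Columns encode
#' single-stress specificity (.1 drought-only, .2 shared same-sign, .3
#' heat-only), rows the interaction category (1 reduced: interaction
#' counteracts the single-stress sign; 2 additive: no interaction; 3
#' enhanced: interaction matches it); group 4 has no single-stress call but a
#' significant interaction; variables with opposite single-stress signs fall
#' into `opp_additive` / `opp_interaction`; all-`ns` is `null`.
#'
#' @param calls output of [callSignificance()].
#' @return a `data.frame` with `variable_id`, `group`, `direction` plus the
#'   three calls.
#' @export
classifyResponseGroups <- function(calls) {
  classifyOne <- function(D, H, DH) {
    if (D == "ns" && H == "ns") {
      if (DH == "ns") return(c("null", "none"))
      return(c("4", DH))
    }
    if (D != "ns" && H != "ns" && D != H) {       # opposite single stresses
      if (DH == "ns") return(c("opp_additive", "mixed"))
      return(c("opp_interaction", "mixed"))
    }
    col <- if (D != "ns" && H != "ns") "2" else if (D != "ns") "1" else "3"
    dir <- if (D != "ns") D else H
    row <- if (DH == "ns") "2" else if (DH == dir) "3" else "1"
    c(paste0(row, ".", col), dir)
  }
  lab <- t(mapply(classifyOne, calls$D, calls$H, calls$DH))
  data.frame(variable_id = calls$variable_id,
             group = unname(lab[, 1L]), direction = unname(lab[, 2L]),
             D = calls$D, H = calls$H, DH = calls$DH,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tabulate response groups
#'
#' Counts variables per group and direction and derives the shares of
#' additive, enhanced and specific response among the combined-stress
#' players (groups 2.x, 3.x and 4).
#'
#' @param table a response-group table from [classifyResponseGroups()].
#' @return a list with `counts` (group x direction), and `combined_shares`.
#' @export
summarizeGroups <- function(table) {
  groups <- c(rownames(.GROUP_PATTERNS), "null")
  counts <- table(factor(table$group, levels = groups),
                  factor(table$direction,
                         levels = c("up", "down", "mixed", "none")))
  additive <- sum(counts[c("2.1", "2.2", "2.3"), ])
  enhanced <- sum(counts[c("3.1", "3.2", "3.3"), ])
  specific <- sum(counts["4", ])
  tot <- additive + enhanced + specific
  shares <- if (tot > 0)
    c(additive = additive / tot, enhanced = enhanced / tot,
      specific = specific / tot)
  else c(additive = NA_real_, enhanced = NA_real_, specific = NA_real_)
  list(counts = counts, n = nrow(table), combined_shares = shares)
}
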