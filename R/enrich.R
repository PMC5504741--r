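#' Term-set over-representation test
#'
#' One-sided hypergeometric (Fisher) test per term: with universe size `N`,
#' term size `K`, selection size `n` and overlap `a`, the over-representation
#' p-value is the upper tail `P(X >= a)` for `X ~ Hypergeom(N, K, n)`. Odds
#' ratios are the conditional maximum-likelihood estimates of the 2x2 table;
#' p-values are Benjamini-Hochberg adjusted across terms. Term sets are
#' intersected with the universe first.
#'
#' @param selection character vector of selected variable ids; must be a
#'   subset of `universe`.
#' @param universe character vector of all eligible variable ids (typically
#'   every variable surviving preprocessing on the layer).
#' @param sets named list of member-id vectors (see [readGMT()]).
#' @param alternative `"greater"` (over-representation, default) or
#'   `"less"` (depletion).
#' @return a `data.frame` sorted by adjusted p with columns `term`,
#'   `overlap`, `selection_size`, `term_size`, `universe_size`,
#'   `odds_ratio`, `p_value`, `p_adjusted`.
#' @export
fisherEnrichment <- function(selection, universe, sets,
                             alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  universe <- unique(universe)
  selection <- unique(selection)
  if (!length(universe)) stop("empty universe")
  if (!all(selection %in% universe))
    stop("selection must be a subset of the universe")
  N <- length(universe)
  n <- length(selection)
  rows <- lapply(names(sets), function(tm) {
    members <- intersect(sets[[tm]], universe)
    K <- length(members)
    a <- length(intersect(selection, members))
    p <- if (alternative == "greater")
      stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
    else
      stats::phyper(a, K, N - K, n)
    tab <- matrix(c(a, n - a, K - a, N - K - n + a), 2L)
    or <- unname(stats::fisher.test(tab, alternative = alternative)$estimate)
    data.frame(term = tm, overlap = a, selection_size = n, term_size = K,
               universe_size = N, odds_ratio = or, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjustFDR(out$p_value)
  out <- out[order(out$p_adjusted, out$p_value, out$term), ]
  rownames(out) <- NULL
  out
}
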