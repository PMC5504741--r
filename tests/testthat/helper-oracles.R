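# Shared fixtures and independent oracles used across the suite.

# balanced 2x2 factorial design (low-humidity cells only)
makeFactorialDesign <- function(reps = 5L) {
  cond <- rep(c("control", "D", "H_LrH", "DH_LrH"), each = reps)
  d <- data.frame(
    sample_id = sprintf("s%02d", seq_along(cond)),
    drought = as.integer(cond %in% c("D", "DH_LrH")),
    heat = as.integer(cond %in% c("H_LrH", "DH_LrH")),
    humidity = ifelse(cond %in% c("H_LrH", "DH_LrH"), "low", "ambient"),
    genotype = "WT", batch = "b1", stringsAsFactors = FALSE)
  d$condition <- deriveCondition(d$drought, d$heat, d$humidity)
  rownames(d) <- d$sample_id
  d
}

makeExpr <- function(values, design, layer = "transcriptome") {
  dimnames(values) <- list(
    sprintf("g%04d", seq_len(nrow(values))), design$sample_id)
  OmicsExperiment(values, layer = layer, scale = "log2")
}

# Mann-Whitney AUC of a score separating a binary group
aucScore <- function(score, group) {
  r <- rank(score)
  n1 <- sum(group == 1); n0 <- sum(group == 0)
  a <- (sum(r[group == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  max(a, 1 - a)
}

# brute-force maximal clique enumeration by subset scan (n <= 15)
bruteMaximalCliques <- function(adjacency, min_size = 2L) {
  n <- nrow(adjacency)
  subsets <- lapply(seq_len(2^n - 1), function(mask)
    which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0))
  isClique <- vapply(subsets, function(s) {
    if (length(s) < 2) return(TRUE)
    all(adjacency[t(utils::combn(s, 2))] == 1)
  }, TRUE)
  cl <- subsets[isClique]
  maximal <- vapply(seq_along(cl), function(i) {
    !any(vapply(cl, function(other)
      length(other) > length(cl[[i]]) && all(cl[[i]] %in% other), TRUE))
  }, TRUE)
  out <- cl[maximal]
  out[lengths(out) >= min_size]
}

# independent response-group oracle: literal lookup over the caption rules,
# written as a flat table rather than the package's control flow
oracleGroupLabel <- function(D, H, DH) {
  key <- paste(D, H, DH)
  specificity <- if (D != "ns" && H == "ns") "drought"
    else if (D == "ns" && H != "ns") "heat"
    else if (D != "ns" && H != "ns" && D == H) "shared"
    else if (D != "ns" && H != "ns") "opposite"
    else "none"
  single <- if (D != "ns") D else H
  if (specificity == "none")
    return(if (DH == "ns") "null" else "4")
  if (specificity == "opposite")
    return(if (DH == "ns") "opp_additive" else "opp_interaction")
  row <- if (DH == "ns") "2" else if (DH == single) "3" else "1"
  col <- c(drought = "1", shared = "2", heat = "3")[[specificity]]
  paste0(row, ".", col)
}

# hypergeometric upper-tail by explicit term-by-term summation
tailSumHyper <- function(a, K, N, n) {
  i <- a:min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Erdos-Renyi graph as a CorrelationGraph-like igraph with positive edges
randomPositiveGraph <- function(n, p_edge, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- stats::rbinom(n * (n - 1) / 2, 1L, p_edge)
  adj <- adj + t(adj)
  dimnames(adj) <- list(sprintf("v%02d", 1:n), sprintf("v%02d", 1:n))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::E(g)$sign <- "positive"
  list(graph = g, adjacency = adj)
}

# graph of two planted blocks with given within/between edge probabilities
plantedTwoBlockGraph <- function(n_per_block, p_in, p_out, seed) {
  set.seed(seed)
  n <- 2L * n_per_block
  block <- rep(1:2, each = n_per_block)
  adj <- matrix(0L, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pr <- if (block[i] == block[j]) p_in else p_out
    adj[i, j] <- adj[j, i] <- stats::rbinom(1L, 1L, pr)
  }
  dimnames(adj) <- list(sprintf("v%02d", 1:n), sprintf("v%02d", 1:n))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::E(g)$sign <- "positive"
  list(graph = g, block = stats::setNames(block, rownames(adj)))
}
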