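makePairedMatrices <- function(n = 20, p = 6, q = 4, seed = 51) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(paste0("s", 1:n),
                                                  sprintf("g%02d", 1:p)))
  y <- matrix(rnorm(n * q), n, q, dimnames = list(paste0("s", 1:n),
                                                  sprintf("m%02d", 1:q)))
  list(x = x, y = y)
}

test_that("pairwise correlations match cor.test and are symmetric", {
  pm <- makePairedMatrices()
  pm$y[, 1] <- pm$x[, 1]                       # identical pair
  cand <- pairwiseCorrelations(pm$x, pm$y)
  r11 <- cand$r[cand$from == "g01" & cand$to == "m01" &
                  cand$class == "gene-mass"]
  expect_equal(r11, 1, tolerance = 1e-12)
  # p-values equal cor.test's for every gene-mass pair
  gm <- cand[cand$class == "gene-mass", ]
  for (i in seq_len(nrow(gm))) {
    ct <- stats::cor.test(pm$x[, gm$from[i]], pm$y[, gm$to[i]])
    expect_equal(gm$p_value[i], ct$p.value, tolerance = 1e-10)
  }
  # symmetry: swapping the inputs transposes but preserves r
  cand2 <- pairwiseCorrelations(pm$y, pm$x, classes = "gene-mass")
  m <- merge(gm, cand2, by.x = c("from", "to"), by.y = c("to", "from"))
  expect_equal(m$r.x, m$r.y, tolerance = 1e-12)
  # r = 0 gives p = 1
  x0 <- cbind(a = c(1, 2, 1, 2, 1, 2), b = c(0, 0, 1, 1, -1, -1))
  c0 <- pairwiseCorrelations(x0, x0, classes = "gene-mass")
  expect_equal(c0$p_value[c0$from == "a" & c0$to == "b"], 1)
  expect_error(pairwiseCorrelations(pm$x[1:3, ], pm$y[1:3, ]), "4 paired")
})

test_that("correlation p-values agree with a permutation null", {
  set.seed(52)
  n <- 20
  x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "g"))
  y <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "m"))
  cand <- pairwiseCorrelations(x, y, classes = "gene-mass")
  robs <- abs(cand$r[1])
  perm <- replicate(10000, abs(stats::cor(x[sample(n), 1], y[, 1])))
  expect_lt(abs(cand$p_value[1] - mean(perm >= robs)), 0.02)
})

test_that("network admission is defined by gene-mass edges", {
  mk <- function(from, to, ftype, ttype, class, r, padj)
    data.frame(from = from, to = to, from_type = ftype, to_type = ttype,
               class = class, r = r, p_value = padj, p_adjusted = padj)
  cand <- rbind(
    mk("g1", "m1", "gene", "mass", "gene-mass", 0.9, 1e-9),
    mk("g2", "g3", "gene", "gene", "gene-gene", 0.9, 1e-9),  # no mass edge
    mk("g1", "g4", "gene", "gene", "gene-gene", 0.95, 1e-9), # g4 unadmitted
    mk("g1", "m1", "gene", "mass", "mass-mass", 0, 1))
  g <- buildNetwork(cand[1, , drop = FALSE])
  expect_equal(igraph::vcount(g), 2L)
  expect_equal(igraph::ecount(g), 1L)
  g2 <- buildNetwork(cand)
  expect_setequal(igraph::V(g2)$name, c("g1", "m1"))
  expect_equal(igraph::ecount(g2), 1L)     # gene-gene edges to outsiders drop
  expect_warning(g0 <- buildNetwork(cand[cand$r > 2, , drop = FALSE]),
                 "empty")
  expect_equal(igraph::vcount(g0), 0L)
  # raising edge_r shrinks the edge and node sets
  set.seed(53)
  pm <- makePairedMatrices(n = 15, p = 15, q = 8)
  pm$y[, 1:4] <- pm$x[, 1:4] + matrix(rnorm(60, 0, 0.4), 15, 4)
  cand2 <- pairwiseCorrelations(pm$x, pm$y)
  gA <- buildNetwork(cand2, thresholds(edge_r = 0.5, edge_alpha = 0.2))
  gB <- buildNetwork(cand2, thresholds(edge_r = 0.7, edge_alpha = 0.2))
  expect_true(all(igraph::V(gB)$name %in% igraph::V(gA)$name))
  expect_lte(igraph::ecount(gB), igraph::ecount(gA))
})

test_that("a planted cross-omics module forms one connected component", {
  sim <- generatePairedDataset(simulationConfig(
    n_genes = 120, n_masses = 40, replicates_per_cell = 3,
    latent = list(list(driver = "drought", n_genes = 10, n_masses = 3,
                       loading = 2)),
    group_proportions = c("2.1" = 0), noise_sd = 0.3, seed = 54))
  met <- imputeFloorAndLog(ticNormalize(sim$metabolome))
  pp <- pairSamples(sim$transcriptome, met)
  cand <- pairwiseCorrelations(pp$x, pp$y)
  g <- buildNetwork(cand, thresholds(edge_r = 0.85, edge_alpha = 1e-5))
  tv <- sim$truth$variables
  members <- tv$variable_id[!is.na(tv$latent_factor)]
  present <- intersect(members, igraph::V(g)$name)
  expect_gte(length(present), 10)
  comp <- igraph::components(g)$membership[present]
  expect_equal(length(unique(comp)), 1L)
})

test_that("submodule views split positive and negative edges", {
  # two anti-correlated blocks with known covariance
  set.seed(55)
  z <- rnorm(30)
  x <- cbind(a1 = z, a2 = z + rnorm(30, 0, 0.2),
             b1 = -z + rnorm(30, 0, 0.2), b2 = -z + rnorm(30, 0, 0.2))
  cand <- pairwiseCorrelations(x, x[, 0, drop = FALSE],
                               classes = "gene-gene")
  g <- submoduleView(cand, c("a1", "a2", "b1", "b2"), 0.75, 0.75)
  ed <- igraph::as_data_frame(g)
  within <- (substr(ed$from, 1, 1) == substr(ed$to, 1, 1))
  expect_true(all(ed$sign[within] == "positive"))
  expect_true(all(ed$sign[!within] == "negative"))
  g1 <- submoduleView(cand, c("a1", "a2"), pos_r = 1, neg_r = 0.75)
  expect_equal(igraph::ecount(g1), 0L)
  g2 <- submoduleView(cand, "a1", 0.75, 0.75)
  expect_equal(igraph::ecount(g2), 0L)
  expect_equal(igraph::vcount(g2), 1L)
  expect_error(submoduleView(cand, "nope", 0.75, 0.75), "unknown")
})

test_that("label propagation finds components and satisfies the fixed point", {
  # two disjoint triangles
  g <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d)
  igraph::E(g)$sign <- "positive"
  lp <- labelPropagation(g, 1)
  expect_equal(length(unique(lp$membership)), 2L)
  expect_true(isLabelFixedPoint(g, lp$membership))
  expect_identical(lp$membership, labelPropagation(g, 1)$membership)
  # edgeless graph: everyone their own community
  g0 <- igraph::make_empty_graph(5, directed = FALSE)
  igraph::V(g0)$name <- paste0("v", 1:5)
  lp0 <- labelPropagation(g0, 1)
  expect_equal(length(unique(lp0$membership)), 5L)
  # fixed-point property on random graphs
  for (s in 1:10) {
    rg <- randomPositiveGraph(15, 0.25, 500 + s)
    lps <- labelPropagation(rg$graph, s)
    expect_true(isLabelFixedPoint(rg$graph, lps$membership))
  }
})

test_that("two cliques joined by one edge usually split into two communities", {
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(5))
  g <- igraph::add_edges(g, c(1, 6))
  igraph::V(g)$name <- paste0("v", 1:10)
  igraph::E(g)$sign <- "positive"
  hits <- mean(vapply(1:50, function(s) {
    m <- labelPropagation(g, s)$membership
    length(unique(m)) == 2L &&
      length(unique(m[1:5])) == 1L && length(unique(m[6:10])) == 1L
  }, TRUE))
  expect_gte(hits, 0.9)
})

test_that("planted two-block graphs are recovered with high ARI", {
  okARI <- vapply(1:50, function(s) {
    pb <- plantedTwoBlockGraph(15, 0.9, 0.05, 600 + s)
    m <- labelPropagation(pb$graph, s)$membership
    evaluateRecovery(m, pb$block)$ari >= 0.9
  }, TRUE)
  expect_gte(mean(okARI), 0.9)
  # independent implementation agrees on a clear-cut instance
  pb <- plantedTwoBlockGraph(15, 0.95, 0.02, 777)
  mine <- labelPropagation(pb$graph, 4)$membership
  igr <- igraph::membership(igraph::cluster_label_prop(pb$graph))
  expect_equal(evaluateRecovery(mine, stats::setNames(as.vector(igr),
                                                      names(igr)))$ari, 1)
})

test_that("maximal cliques match exhaustive enumeration", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  igraph::E(tri)$sign <- "positive"
  expect_equal(maximalCliques(tri), list(c("a", "b", "c")),
               ignore_attr = TRUE)
  path <- igraph::make_graph(~ a - b, b - c)
  igraph::E(path)$sign <- "positive"
  expect_equal(maximalCliques(path, 2), list(c("a", "b"), c("b", "c")),
               ignore_attr = TRUE)
  for (s in 1:30) {
    n <- sample(5:12, 1)
    rg <- randomPositiveGraph(n, stats::runif(1, 0.2, 0.7), 700 + s)
    got <- maximalCliques(rg$graph, 2)
    want <- bruteMaximalCliques(rg$adjacency, 2)
    want <- lapply(want, function(ix) sort(rownames(rg$adjacency)[ix]))
    ord <- order(-lengths(want),
                 vapply(want, function(x) paste(x, collapse = "\r"), ""))
    expect_equal(got, want[ord], ignore_attr = TRUE)
    expect_false(attr(got, "truncated"))
    # cross-check against igraph's enumeration
    ig <- lapply(igraph::max_cliques(rg$graph, min = 2),
                 function(v) sort(names(v)))
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(ig, paste, "", collapse = ","))
  }
})

test_that("clique enumeration honors the max_count cap", {
  # near-complete graph: complete on 12 nodes minus a perfect matching has
  # many maximal cliques; the cap truncates with a warning
  g <- igraph::make_full_graph(12)
  g <- igraph::delete_edges(g, igraph::get_edge_ids(g, 1:12))
  igraph::V(g)$name <- sprintf("v%02d", 1:12)
  igraph::E(g)$sign <- "positive"
  full <- maximalCliques(g)
  expect_false(attr(full, "truncated"))
  expect_equal(length(full), 64L)   # 2^6 ways to pick one node per pair
  expect_warning(capped <- maximalCliques(g, max_count = 10), "truncated")
  expect_true(attr(capped, "truncated"))
  expect_lte(length(capped), 10L)
  # capped output still consists of genuine maximal cliques
  fullKeys <- vapply(full, paste, "", collapse = ",")
  expect_true(all(vapply(capped, paste, "", collapse = ",") %in% fullKeys))
})

test_that("top-genes-per-mass reduction keeps the best correlated genes", {
  mk <- function(from, to, r)
    data.frame(from = from, to = to, from_type = "gene", to_type = "mass",
               class = "gene-mass", r = r, p_value = 0, p_adjusted = 0)
  cand <- rbind(mk(paste0("g", 1:5), "m1", c(0.9, 0.8, 0.95, 0.7, 0.85)),
                mk(c("g3", "g9"), "m2", c(0.99, 0.5)))
  kept <- topGenesPerMass(cand, 3)
  expect_setequal(kept, c("g1", "g3", "g5", "g9"))   # union counts g3 once
  expect_setequal(topGenesPerMass(mk("g1", "m1", 0.9), 3), "g1")
  expect_error(topGenesPerMass(cand, 0), "positive")
})

test_that("cross-targeted edges require shared samples and connections", {
  set.seed(56)
  n <- 30
  genes <- matrix(rnorm(n * 3), n, 3,
                  dimnames = list(paste0("s", 1:n), paste0("g", 1:3)))
  targ <- cbind(suc = genes[, "g1"], other = rnorm(n))
  rownames(targ) <- rownames(genes)
  ed <- crossTargetedEdges(genes, targ, r_thresh = 0.85)
  expect_equal(ed$r[ed$from == "g1" & ed$to == "suc"], 1, tolerance = 1e-12)
  expect_true(all(ed$class == "cross-targeted"))
  # minimum-connection filter drops weakly connected metabolites
  ed2 <- crossTargetedEdges(genes, targ, r_thresh = 0.85,
                            min_connections = 10)
  expect_equal(nrow(ed2), 0L)
  # independent noise at n = 56 yields no edges at 0.85 over several seeds
  noEdge <- vapply(1:20, function(s) {
    set.seed(900 + s)
    gg <- matrix(rnorm(56 * 5), 56, 5,
                 dimnames = list(paste0("s", 1:56), paste0("g", 1:5)))
    tt <- matrix(rnorm(56 * 5), 56, 5,
                 dimnames = list(paste0("s", 1:56), paste0("t", 1:5)))
    nrow(crossTargetedEdges(gg, tt, 0.85)) == 0L
  }, TRUE)
  expect_true(all(noEdge))
  rownames(targ) <- paste0("z", 1:n)
  expect_error(crossTargetedEdges(genes, targ), "shared")
})

test_that("GraphML export round-trips structure and attributes", {
  pm <- makePairedMatrices(n = 15, p = 6, q = 4, seed = 57)
  pm$y[, 1] <- pm$x[, 1] + rnorm(15, 0, 0.1)
  cand <- pairwiseCorrelations(pm$x, pm$y)
  g <- buildNetwork(cand, thresholds(edge_r = 0.5, edge_alpha = 0.5))
  f <- withr::local_tempfile(fileext = ".graphml")
  writeNetworkGraphML(g, f)
  back <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(g))
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  expect_setequal(igraph::V(back)$type, igraph::V(g)$type)
})
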