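#' @importFrom igraph graph_from_data_frame make_empty_graph vertex_attr
#'   edge_attr V E ecount vcount as_data_frame subgraph_from_edges write_graph
#'   neighbors degree
NULL

.corLong <- function(A, B, typeA, typeB, class, symmetric) {
  n <- nrow(A)
  sdsA <- apply(A, 2L, stats::sd)
  sdsB <- apply(B, 2L, stats::sd)
  dropped <- sum(sdsA == 0) + if (symmetric) 0L else sum(sdsB == 0)
  if (dropped > 0)
    message(class, ": ", dropped, " constant variable(s) excluded")
  A <- A[, sdsA > 0, drop = FALSE]
  B <- B[, sdsB > 0, drop = FALSE]
  R <- stats::cor(A, B)
  if (symmetric) {
    idx <- which(upper.tri(R), arr.ind = TRUE)
  } else {
    idx <- as.matrix(expand.grid(row = seq_len(nrow(R)),
                                 col = seq_len(ncol(R))))
  }
  r <- R[idx]
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  data.frame(from = colnames(A)[idx[, 1L]], to = colnames(B)[idx[, 2L]],
             from_type = typeA, to_type = typeB, class = class,
             r = r, p_value = p, p_adjusted = adjustFDR(p),
             stringsAsFactors = FALSE)
}

#' Pairwise Pearson correlations between and within layers
#'
#' Computes Pearson correlations across paired samples with two-sided
#' p-values from the t-transform (`n-2` df), Benjamini-Hochberg adjusted
#' within each edge class (`gene-mass`, `gene-gene`, `mass-mass`). Constant
#' variables are excluded with a message.
#'
#' @param x genes layer: [OmicsExperiment] or samples-by-variables matrix.
#' @param y masses layer, paired with `x`.
#' @param classes which edge classes to compute.
#' @return edge-candidate `data.frame` with columns `from`, `to`,
#'   `from_type`, `to_type`, `class`, `r`, `p_value`, `p_adjusted`.
#' @export
pairwiseCorrelations <- function(x, y,
                                 classes = c("gene-mass", "gene-gene",
                                             "mass-mass")) {
  if (is(x, "OmicsExperiment")) x <- t(intensities(x))
  if (is(y, "OmicsExperiment")) y <- t(intensities(y))
  if (nrow(x) != nrow(y)) stop("x and y must share samples")
  if (nrow(x) < 4L) stop("at least 4 paired samples required")
  out <- list()
  if ("gene-mass" %in% classes)
    out$gm <- .corLong(x, y, "gene", "mass", "gene-mass", FALSE)
  if ("gene-gene" %in% classes)
    out$gg <- .corLong(x, x, "gene", "gene", "gene-gene", TRUE)
  if ("mass-mass" %in% classes)
    out$mm <- .corLong(y, y, "mass", "mass", "mass-mass", TRUE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build the thresholded gene-mass correlation network
#'
#' Node membership is defined by the gene-mass relation: all genes and
#' masses joined by a gene-mass correlation above `th$edge_r` (and, by
#' default, adjusted p below `th$edge_alpha`) enter the graph. Gene-gene and
#' mass-mass edges are then added among admitted nodes when they pass
#' `r > th$edge_r` and `p_adjusted < th$edge_alpha`.
#'
#' @param candidates table from [pairwiseCorrelations()].
#' @param th a [thresholds()] list.
#' @param admission_alpha apply the adjusted-p rule also to the admitting
#'   gene-mass edges (default `TRUE`).
#' @return an [igraph::igraph] with vertex attribute `type` and edge
#'   attributes `r`, `sign`, `p_value`, `p_adjusted`, `class`.
#' @export
buildNetwork <- function(candidates, th = thresholds(),
                         admission_alpha = TRUE) {
  gm <- candidates[candidates$class == "gene-mass" &
                     candidates$r > th$edge_r, , drop = FALSE]
  if (admission_alpha)
    gm <- gm[gm$p_adjusted < th$edge_alpha, , drop = FALSE]
  if (!nrow(gm)) {
    warning("no gene-mass edge passes the thresholds; empty network")
    return(make_empty_graph(directed = FALSE))
  }
  nodes <- unique(rbind(
    data.frame(name = gm$from, type = gm$from_type),
    data.frame(name = gm$to, type = gm$to_type)))
  within <- candidates[candidates$class %in% c("gene-gene", "mass-mass") &
                         candidates$r > th$edge_r &
                         candidates$p_adjusted < th$edge_alpha &
                         candidates$from %in% nodes$name &
                         candidates$to %in% nodes$name, , drop = FALSE]
  edges <- rbind(gm, within)
  edges$sign <- ifelse(edges$r >= 0, "positive", "negative")
  graph_from_data_frame(
    edges[, c("from", "to", "r", "sign", "p_value", "p_adjusted", "class")],
    directed = FALSE, vertices = nodes)
}

#' Submodule view over an explicit variable set
#'
#' Graph over exactly the requested variables with positive edges at
#' `r > pos_r` (solid) and negative edges at `r < -neg_r` (dashed),
#' regardless of edge class.
#'
#' @param candidates table from [pairwiseCorrelations()].
#' @param variables variable ids to include.
#' @param pos_r,neg_r positive / negative correlation cutoffs (default
#'   0.75 each).
#' @return an [igraph::igraph] with a `sign` edge attribute.
#' @export
submoduleView <- function(candidates, variables, pos_r = 0.75,
                          neg_r = 0.75) {
  known <- unique(c(candidates$from, candidates$to))
  unknown <- setdiff(variables, known)
  if (length(unknown))
    stop("unknown variable id(s): ", paste(unknown, collapse = ", "))
  sub <- candidates[candidates$from %in% variables &
                      candidates$to %in% variables, , drop = FALSE]
  sub <- sub[sub$r > pos_r | sub$r < -neg_r, , drop = FALSE]
  sub$sign <- ifelse(sub$r >= 0, "positive", "negative")
  types <- unique(rbind(
    data.frame(name = candidates$from, type = candidates$from_type),
    data.frame(name = candidates$to, type = candidates$to_type)))
  nodes <- types[match(variables, types$name), ]
  graph_from_data_frame(
    sub[, c("from", "to", "r", "sign", "p_value", "p_adjusted", "class")],
    directed = FALSE, vertices = nodes)
}

.positiveSubgraph <- function(graph) {
  sg <- edge_attr(graph, "sign")
  if (is.null(sg) || ecount(graph) == 0L) return(graph)
  subgraph_from_edges(graph, E(graph)[sg == "positive"],
                      delete.vertices = FALSE)
}

#' Asynchronous label-propagation community detection
#'
#' Runs on the positive-edge subgraph. Every node starts with its own label;
#' in seeded-random order each node adopts the majority label among its
#' neighbors, ties broken uniformly at random (seeded); sweeps repeat until
#' every node's label is a weak neighborhood majority. Deterministic given
#' the seed; isolated nodes keep their own label.
#'
#' @param graph an [igraph::igraph] as built by [buildNetwork()].
#' @param seed integer seed.
#' @param max_sweeps safety cap on full sweeps (default 100).
#' @return a list with `membership` (named integer vector), `seed`,
#'   `sweeps`.
#' @export
labelPropagation <- function(graph, seed, max_sweeps = 100L) {
  g <- .positiveSubgraph(graph)
  n <- vcount(g)
  labels <- seq_len(n)
  names(labels) <- V(g)$name
  if (n == 0L)
    return(list(membership = labels, seed = seed, sweeps = 0L))
  adj <- lapply(seq_len(n), function(i) as.integer(neighbors(g, i)))
  rng <- .seededRNG(seed)
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    changed <- FALSE
    for (i in rng$sample(seq_len(n))) {
      nb <- adj[[i]]
      if (!length(nb)) next
      tab <- table(labels[nb])
      best <- as.integer(names(tab)[tab == max(tab)])
      if (!labels[i] %in% best) {
        labels[i] <- if (length(best) == 1L) best else rng$sample(best, 1L)
        changed <- TRUE
      }
    }
    if (!changed || sweeps >= max_sweeps) break
  }
  # relabel communities to consecutive ids in order of first appearance
  membership <- match(labels, unique(labels))
  names(membership) <- names(labels)
  list(membership = membership, seed = seed, sweeps = sweeps)
}

# local RNG so community detection does not disturb the global seed state
.seededRNG <- function(seed) {
  env <- new.env()
  env$state <- local({ set.seed(seed); .Random.seed })
  list(sample = function(x, size = length(x)) {
    old <- .GlobalEnv$.Random.seed
    assign(".Random.seed", env$state, envir = .GlobalEnv)
    out <- if (length(x) == 1L && size == 1L) x else sample(x, size)
    env$state <- .GlobalEnv$.Random.seed
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    out
  })
}

#' Verify the label-propagation fixed point
#'
#' Checks that every node's label is a weak majority among its positive-edge
#' neighbors.
#'
#' @param graph the graph the partition was computed on.
#' @param membership named membership vector.
#' @return logical.
#' @export
isLabelFixedPoint <- function(graph, membership) {
  g <- .positiveSubgraph(graph)
  for (i in seq_len(vcount(g))) {
    nb <- as.integer(neighbors(g, i))
    if (!length(nb)) next
    tab <- table(membership[nb])
    cnt <- tab[as.character(membership[i])]
    if (is.na(cnt) || cnt < max(tab)) return(FALSE)
  }
  TRUE
}

#' Enumerate maximal cliques (Bron-Kerbosch with pivoting)
#'
#' Runs on the positive-edge subgraph and returns all maximal cliques of at
#' least `min_size` nodes, ordered by decreasing size then lexicographically
#' for reproducibility.
#'
#' @param graph an [igraph::igraph].
#' @param min_size minimum clique size (default 2).
#' @param max_count stop enumerating (with a warning) once this many maximal
#'   cliques have been found (default `Inf`, exhaustive). Dense
#'   quasi-complete graphs can hold combinatorially many maximal cliques;
#'   the cap bounds runtime at the cost of completeness. Truncation is
#'   flagged in the `truncated` attribute of the result.
#' @return list of character vectors of node names; attribute `truncated`
#'   says whether the cap was hit.
#' @export
maximalCliques <- function(graph, min_size = 2L, max_count = Inf) {
  g <- .positiveSubgraph(graph)
  n <- vcount(g)
  if (n == 0L) return(structure(list(), truncated = FALSE))
  adj <- lapply(seq_len(n), function(i) sort(as.integer(neighbors(g, i))))
  cliques <- list()
  bk <- function(R, P, X) {
    if (length(cliques) >= max_count) return(invisible())
    if (!length(P) && !length(X)) {
      cliques[[length(cliques) + 1L]] <<- R
      return(invisible())
    }
    cand <- c(P, X)
    pivot <- cand[which.max(vapply(cand,
      function(u) length(intersect(P, adj[[u]])), 0L))]
    for (v in setdiff(P, adj[[pivot]])) {
      bk(c(R, v), intersect(P, adj[[v]]), intersect(X, adj[[v]]))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(), seq_len(n), integer())
  truncated <- length(cliques) >= max_count
  if (truncated)
    warning("clique enumeration truncated at ", max_count, " maximal cliques")
  nm <- V(g)$name
  out <- lapply(cliques, function(cl) sort(nm[cl]))
  out <- out[lengths(out) >= min_size]
  ord <- order(-lengths(out),
               vapply(out, function(x) paste(x, collapse = "\r"), ""))
  structure(out[ord], truncated = truncated)
}

#' Reduce gene-mass candidates to the top correlated genes per mass
#'
#' Keeps, per mass, the `k` genes with largest correlation (ties broken by
#' gene id) and returns the union of kept genes.
#'
#' @param candidates gene-mass rows of [pairwiseCorrelations()] output.
#' @param k genes per mass (default 3).
#' @return character vector of gene ids.
#' @export
topGenesPerMass <- function(candidates, k = 3L) {
  if (k <= 0) stop("k must be positive")
  gm <- candidates[candidates$class == "gene-mass", , drop = FALSE]
  kept <- lapply(split(gm, gm$to), function(d) {
    d <- d[order(-d$r, d$from), , drop = FALSE]
    utils::head(d$from, k)
  })
  sort(unique(unlist(kept)))
}

#' Correlation edges from network genes to targeted metabolites
#'
#' Correlates the given genes against every variable of a targeted
#' metabolomics layer over their shared samples and keeps edges with
#' `r > r_thresh`; optionally filters to metabolites with at least
#' `min_connections` gene edges.
#'
#' @param genes an [OmicsExperiment] (transcriptome) restricted to the genes
#'   of interest, or a samples-by-genes matrix.
#' @param targeted a targeted-metabolome [OmicsExperiment] or
#'   samples-by-metabolites matrix.
#' @param r_thresh correlation cutoff (default 0.85).
#' @param min_connections drop metabolites with fewer gene edges (default 0,
#'   no filter).
#' @return edge `data.frame` with class `cross-targeted`.
#' @export
crossTargetedEdges <- function(genes, targeted, r_thresh = 0.85,
                               min_connections = 0L) {
  gm <- if (is(genes, "OmicsExperiment")) t(intensities(genes)) else as.matrix(genes)
  tm <- if (is(targeted, "OmicsExperiment")) t(intensities(targeted)) else as.matrix(targeted)
  shared <- intersect(rownames(gm), rownames(tm))
  if (!length(shared)) stop("no shared samples with the targeted dataset")
  edges <- .corLong(gm[shared, , drop = FALSE], tm[shared, , drop = FALSE],
                    "gene", "targeted_metabolite", "cross-targeted", FALSE)
  edges <- edges[edges$r > r_thresh, , drop = FALSE]
  if (min_connections > 0L) {
    conn <- table(edges$to)
    keep <- names(conn)[conn >= min_connections]
    edges <- edges[edges$to %in% keep, , drop = FALSE]
  }
  rownames(edges) <- NULL
  edges
}

#' Write a network as GraphML
#'
#' @param graph an [igraph::igraph].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNetworkGraphML <- function(graph, path) {
  write_graph(graph, path, format = "graphml")
  invisible(path)
}
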