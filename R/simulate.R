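#' Response-group sign patterns
#'
#' Signs of (beta_D, beta_H, beta_DH) planted for the "up" subgroup of each
#' response group; the "down" subgroup uses the negated pattern. Rows 1-3 of
#' the group code give the interaction category (reduced / additive /
#' enhanced), the decimal the single-stress specificity (.1 drought-only,
#' .2 shared, .3 heat-only); group 4 is the combined-stress specific class
#' and the `opp_*` classes hold the rare variables regulated oppositely by
#' the two single stresses.
#' @keywords internal
.GROUP_PATTERNS <- rbind(
  "2.1" = c(1, 0, 0),  "2.2" = c(1, 1, 0),  "2.3" = c(0, 1, 0),
  "3.1" = c(1, 0, 1),  "3.2" = c(1, 1, 1),  "3.3" = c(0, 1, 1),
  "1.1" = c(1, 0, -1), "1.2" = c(1, 1, -1), "1.3" = c(0, 1, -1),
  "4"   = c(0, 0, 1),
  "opp_additive" = c(1, -1, 0), "opp_interaction" = c(1, -1, -1))
colnames(.GROUP_PATTERNS) <- c("D", "H", "DH")

.GROUP_LABELS <- c(rownames(.GROUP_PATTERNS), "null")

#' Configuration of the paired-omics simulator
#'
#' Defines the study design emulated by [generatePairedDataset()]: six
#' environmental conditions (control, drought, heat at low/high relative air
#' humidity, and the drought-heat combinations), three genotypes with no
#' genotype effect, replicate plants per condition-genotype cell spread over
#' experimental batches, planted factorial response groups, humidity-specific
#' responders, latent factors inducing transcriptome-metabolome correlation,
#' and below-floor censoring of metabolite intensities.
#'
#' @param n_genes,n_masses number of transcript / metabolite-mass variables.
#' @param replicates_per_cell plants per condition-by-genotype cell.
#' @param genotypes genotype labels; effects are structurally zero.
#' @param batch_offsets additive per-batch shifts (log2 units); their length
#'   sets the number of batches.
#' @param group_proportions named fractions of variables planted per response
#'   group (names from `rownames(stressfactor:::.GROUP_PATTERNS)`); the
#'   remainder is null. Applied to each layer separately.
#' @param effect_size magnitude of the non-zero planted coefficients
#'   (log2 units).
#' @param noise_sd residual standard deviation (log2 units).
#' @param hum_fraction fraction of variables responding to the air-humidity
#'   difference between the two heat settings.
#' @param humidity_effect log2 shift added to humidity-responsive variables
#'   in high-relative-humidity heat cells.
#' @param latent list of latent-factor specs, each a list with `driver`
#'   (`"drought"`, `"heat"` or `"random"`), `n_genes`, `n_masses`,
#'   `loading`; members are drawn from null variables.
#' @param latent_score_sd sample-to-sample noise of latent factor scores.
#' @param gene_baseline_mean,gene_baseline_sd,mass_baseline_mean,mass_baseline_sd
#'   log2 baseline distributions per layer.
#' @param detection_floor raw-intensity limit below which metabolite values
#'   are censored (unobserved).
#' @param seed integer RNG seed; identical configurations give identical
#'   datasets.
#' @return a classed list.
#' @export
simulationConfig <- function(n_genes = 2000L, n_masses = 300L,
                             replicates_per_cell = 5L,
                             genotypes = c("WT", "DM", "TM"),
                             batch_offsets = c(0.6, -0.6, 0),
                             group_proportions = c(
                               "2.1" = 0.02, "2.2" = 0.02, "2.3" = 0.02,
                               "3.1" = 0.02, "3.2" = 0.02, "3.3" = 0.02,
                               "1.1" = 0.02, "1.2" = 0.02, "1.3" = 0.02,
                               "4" = 0.02,
                               "opp_additive" = 0.002,
                               "opp_interaction" = 0.002),
                             effect_size = 2.5, noise_sd = 0.3,
                             hum_fraction = 0.05, humidity_effect = 2,
                             latent = list(
                               list(driver = "drought", n_genes = 20L,
                                    n_masses = 5L, loading = 1.0),
                               list(driver = "heat", n_genes = 20L,
                                    n_masses = 5L, loading = 1.0)),
                             latent_score_sd = 0.3,
                             gene_baseline_mean = 8, gene_baseline_sd = 1.5,
                             mass_baseline_mean = 21, mass_baseline_sd = 1.5,
                             detection_floor = 5e5, seed = 1L) {
  if (length(group_proportions)) {
    if (is.null(names(group_proportions)) ||
        !all(names(group_proportions) %in% rownames(.GROUP_PATTERNS)))
      stop("group_proportions names must be response-group labels")
    if (any(group_proportions < 0)) stop("negative group proportion")
    if (sum(group_proportions) > 1) stop("group proportions exceed 1")
  }
  stopifnot(noise_sd > 0, detection_floor > 0, n_genes >= 1, n_masses >= 1,
            replicates_per_cell >= 1, hum_fraction >= 0, hum_fraction <= 1)
  structure(as.list(environment()), class = "SimulationConfig")
}

.simDesign <- function(config) {
  n_batch <- length(config$batch_offsets)
  cells <- expand.grid(rep = seq_len(config$replicates_per_cell),
                       genotype = config$genotypes,
                       condition = .CONDITIONS,
                       stringsAsFactors = FALSE)
  cond <- cells$condition
  d <- data.frame(
    sample_id = sprintf("s%03d", seq_len(nrow(cells))),
    drought = as.integer(cond %in% c("D", "DH_LrH", "DH_HrH")),
    heat = as.integer(grepl("H_", cond, fixed = TRUE)),
    humidity = ifelse(grepl("LrH", cond), "low",
               ifelse(grepl("HrH", cond), "high", "ambient")),
    genotype = cells$genotype,
    batch = paste0("b", ((cells$rep - 1L) %% n_batch) + 1L),
    stringsAsFactors = FALSE)
  d$condition <- deriveCondition(d$drought, d$heat, d$humidity)
  d$genotype <- factor(d$genotype, levels = config$genotypes)
  d$batch <- factor(d$batch, levels = paste0("b", seq_len(n_batch)))
  rownames(d) <- d$sample_id
  d
}

.assignGroups <- function(n, prop) {
  counts <- if (length(prop)) round(prop * n) else integer()
  labs <- c(rep(names(counts), counts),
            rep("null", n - sum(counts)))
  labs[seq_len(n)]
}

#' Generate a paired transcriptome/metabolome dataset with ground truth
#'
#' Simulates log2 intensities per variable and sample as
#' `baseline + bD*D + bH*H + bDH*D*H + humidity shift + batch offset +
#' latent loadings x factor scores + N(0, noise_sd)`. The metabolome layer is
#' exponentiated to the raw scale and values below the detection floor are
#' censored (masked as not detected); the transcriptome layer is returned
#' complete on the log2 scale. Latent factor scores follow the configured
#' driver (e.g. +1 for drought samples, -1 otherwise, plus noise), inducing
#' cross-omics correlation among member variables.
#'
#' @param config a [simulationConfig()].
#' @return a list with elements `transcriptome` and `metabolome`
#'   ([OmicsExperiment]s), `design` (data.frame) and `truth` (list with
#'   per-variable truth table, batch offsets, latent scores).
#' @examples
#' sim <- generatePairedDataset(simulationConfig(n_genes = 50, n_masses = 20,
#'                                               replicates_per_cell = 2))
#' table(sim$truth$variables$group)
#' @export
generatePairedDataset <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  design <- .simDesign(config)
  n <- nrow(design)
  D <- design$drought; H <- design$heat
  hiHum <- as.integer(H == 1L & design$humidity == "high")
  batch_off <- config$batch_offsets[as.integer(design$batch)]

  n_var <- c(transcriptome = config$n_genes, metabolome = config$n_masses)
  ids <- list(transcriptome = sprintf("g%05d", seq_len(config$n_genes)),
              metabolome = sprintf("m%04d", seq_len(config$n_masses)))

  truth <- do.call(rbind, lapply(names(n_var), function(layer) {
    nv <- n_var[[layer]]
    grp <- .assignGroups(nv, config$group_proportions)
    dir <- ifelse(grp == "null", "none",
                  sample(c("up", "down"), nv, replace = TRUE))
    sgn <- ifelse(dir == "down", -1, 1)
    pat <- matrix(0, nv, 3, dimnames = list(NULL, c("D", "H", "DH")))
    planted <- grp != "null"
    pat[planted, ] <- .GROUP_PATTERNS[grp[planted], , drop = FALSE]
    pat <- pat * sgn * config$effect_size
    data.frame(variable_id = ids[[layer]], layer = layer, group = grp,
               direction = ifelse(grp %in% c("opp_additive", "opp_interaction"),
                                  "mixed", dir),
               beta_D = pat[, "D"], beta_H = pat[, "H"], beta_DH = pat[, "DH"],
               stringsAsFactors = FALSE)
  }))

  # humidity responders and latent-factor members drawn from null variables
  # so planted factorial groups stay correctly specified
  truth$humidity_responsive <- FALSE
  truth$latent_factor <- NA_integer_
  nullIdx <- which(truth$group == "null")
  nHum <- round(config$hum_fraction * nrow(truth))
  humIdx <- sample(nullIdx, min(nHum, length(nullIdx)))
  truth$humidity_responsive[humIdx] <- TRUE
  avail <- setdiff(nullIdx, humIdx)
  scores <- NULL
  if (length(config$latent)) {
    scores <- matrix(0, n, length(config$latent),
                     dimnames = list(design$sample_id,
                                     paste0("F", seq_along(config$latent))))
    for (f in seq_along(config$latent)) {
      spec <- config$latent[[f]]
      driver <- switch(spec$driver,
                       drought = 2 * D - 1,
                       heat = 2 * H - 1,
                       random = stats::rnorm(n))
      scores[, f] <- driver + stats::rnorm(n, 0, config$latent_score_sd)
      for (layer in names(n_var)) {
        k <- if (layer == "transcriptome") spec$n_genes else spec$n_masses
        pool <- avail[truth$layer[avail] == layer]
        if (length(pool) < k)
          stop("not enough null variables for latent factor members")
        memb <- pool[seq_len(k)]
        truth$latent_factor[memb] <- f
        avail <- setdiff(avail, memb)
      }
    }
  }

  makeLayer <- function(layer) {
    tt <- truth[truth$layer == layer, ]
    nv <- nrow(tt)
    base <- stats::rnorm(nv,
      if (layer == "transcriptome") config$gene_baseline_mean else config$mass_baseline_mean,
      if (layer == "transcriptome") config$gene_baseline_sd else config$mass_baseline_sd)
    mu <- outer(base, rep(1, n)) +
      outer(tt$beta_D, D) + outer(tt$beta_H, H) + outer(tt$beta_DH, D * H) +
      outer(ifelse(tt$humidity_responsive, config$humidity_effect, 0), hiHum) +
      outer(rep(1, nv), batch_off)
    if (!is.null(scores)) {
      L <- matrix(0, nv, ncol(scores))
      memb <- !is.na(tt$latent_factor)
      for (f in which(memb))
        L[f, tt$latent_factor[f]] <-
          config$latent[[tt$latent_factor[f]]]$loading
      mu <- mu + L %*% t(scores)
    }
    vals <- mu + matrix(stats::rnorm(nv * n, 0, config$noise_sd), nv, n)
    dimnames(vals) <- list(tt$variable_id, design$sample_id)
    vals
  }

  expr <- makeLayer("transcriptome")
  met_log <- makeLayer("metabolome")
  met_raw <- 2^met_log
  cens <- met_raw < config$detection_floor
  met_raw[cens] <- NA

  cd <- S4Vectors::DataFrame(design)
  list(
    transcriptome = OmicsExperiment(expr, layer = "transcriptome",
                                    scale = "log2", colData = cd),
    metabolome = OmicsExperiment(met_raw, layer = "metabolome",
                                 scale = "raw", missing = cens, colData = cd),
    design = design,
    truth = list(variables = truth, batch_offsets = config$batch_offsets,
                 latent_scores = scores, config = config))
}

#' Generate annotation term sets with one planted enriched term
#'
#' Builds `n_terms` random term sets over one layer's variables plus a single
#' planted term whose overlap with a chosen response group exceeds chance by
#' the requested fold.
#'
#' @param truth ground truth from [generatePairedDataset()].
#' @param group response-group label targeted by the planted term.
#' @param term_size size of the planted term.
#' @param fold enrichment fold of the planted term over the chance overlap
#'   (`fold = 1` plants no enrichment).
#' @param n_terms number of additional uniformly random terms.
#' @param layer which layer's variables form the universe.
#' @param seed RNG seed.
#' @return named list of member-id vectors; planted term is `"planted"`.
#' @export
generateAnnotationSets <- function(truth, group = "2.1", term_size = 50L,
                                   fold = 4, n_terms = 50L,
                                   layer = "transcriptome", seed = 1L) {
  set.seed(seed)
  tv <- truth$variables[truth$variables$layer == layer, ]
  universe <- tv$variable_id
  N <- length(universe)
  if (term_size <= 0L) stop("term size must be positive")
  if (term_size > N) stop("term size exceeds number of variables")
  members <- tv$variable_id[tv$group == group]
  K <- length(members)
  expected <- term_size * K / N
  k_in <- min(round(fold * expected), term_size, K)
  planted <- c(sample(members, k_in),
               sample(setdiff(universe, members), term_size - k_in))
  sets <- lapply(seq_len(n_terms), function(i)
    sample(universe, sample(10:100, 1L)))
  names(sets) <- sprintf("T%03d", seq_len(n_terms))
  c(list(planted = planted), sets)
}

#' Compare recovered classifications or partitions with the planted truth
#'
#' For a response-group table, reports per-group sensitivity (fraction of
#' planted members receiving their true label) and the false-discovery
#' proportion among variables declared regulated (truth null but called
#' non-null). For a community partition (named membership vector), reports
#' the adjusted Rand index against the planted labels.
#'
#' @param result a `data.frame` with columns `variable_id`, `group` (a
#'   response-group table) or a named vector (partition memberships).
#' @param truth either the `truth` list from [generatePairedDataset()] or a
#'   named vector of true labels for partitions.
#' @return a list of metrics.
#' @export
evaluateRecovery <- function(result, truth) {
  if (is.data.frame(result)) {
    tv <- truth$variables
    if (!all(result$variable_id %in% tv$variable_id))
      stop("variable ids of result and truth do not match")
    tv <- tv[match(result$variable_id, tv$variable_id), ]
    planted <- tv$group != "null"
    sens <- tapply(result$group[planted] == tv$group[planted],
                   tv$group[planted], mean)
    declared <- result$group != "null"
    # latent-factor members carry real stress-driven signal through their
    # factor scores, so a regulated call on them is not a false discovery
    noLatent <- if (is.null(tv$latent_factor)) TRUE else is.na(tv$latent_factor)
    trulyNull <- tv$group == "null" & noLatent
    fdp <- if (any(declared)) mean(trulyNull[declared]) else 0
    list(sensitivity = sens, fdp = fdp,
         overall_sensitivity = mean(result$group[planted] == tv$group[planted]))
  } else {
    if (is.null(names(result)) || is.null(names(truth)) ||
        !all(names(result) %in% names(truth)))
      stop("partition and truth must share names")
    t2 <- truth[names(result)]
    list(ari = mclust::adjustedRandIndex(as.vector(result), as.vector(t2)))
  }
}
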