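#' Analysis thresholds
#'
#' Bundles the cutoffs used across the pipeline: the absolute log2
#' fold-change and adjusted-p thresholds of the differential analysis, the
#' correlation and significance thresholds of network construction, the
#' metabolite detection rule, and the variable-selection sizes of the CCA
#' and network reduction steps.
#'
#' @param lfc absolute log2 fold-change cutoff (default 1).
#' @param alpha adjusted-p cutoff for differential calls (default 0.05).
#' @param edge_r Pearson correlation cutoff for network edges (default 0.85).
#' @param sub_r relaxed correlation cutoff for submodule views (default 0.75).
#' @param edge_alpha adjusted-p cutoff for network edges (default 1e-5).
#' @param detect_fraction minimum fraction of samples within at least one
#'   condition in which a metabolite mass must be observed (default 2/3).
#' @param detection_floor raw-intensity lower detection limit used for
#'   imputation (default 5e5).
#' @param top_variance_k number of highest-variance variables per layer
#'   entering CCA (default 100).
#' @param top_genes_per_mass genes kept per mass in network reduction
#'   (default 3).
#' @return a named list of class `"Thresholds"`.
#' @export
thresholds <- function(lfc = 1, alpha = 0.05, edge_r = 0.85, sub_r = 0.75,
                       edge_alpha = 1e-5, detect_fraction = 2 / 3,
                       detection_floor = 5e5, top_variance_k = 100L,
                       top_genes_per_mass = 3L) {
  stopifnot(lfc > 0, alpha > 0, alpha < 1, edge_r > 0, edge_r <= 1,
            edge_alpha > 0, detect_fraction > 0, detect_fraction <= 1,
            detection_floor > 0, top_variance_k >= 1,
            top_genes_per_mass >= 1)
  structure(list(lfc = lfc, alpha = alpha, edge_r = edge_r, sub_r = sub_r,
                 edge_alpha = edge_alpha, detect_fraction = detect_fraction,
                 detection_floor = detection_floor,
                 top_variance_k = as.integer(top_variance_k),
                 top_genes_per_mass = as.integer(top_genes_per_mass)),
            class = "Thresholds")
}

#' Derive the condition label from design factors
#'
#' Maps the two binary stress factors plus the air-humidity level of heated
#' samples onto the six condition labels: `control`, `D` (drought), `H_LrH`
#' and `H_HrH` (heat at low / high relative air humidity), and their
#' combinations `DH_LrH`, `DH_HrH`.
#'
#' @param drought,heat binary (0/1) vectors.
#' @param humidity `"ambient"`, `"low"` or `"high"`; `low`/`high` are only
#'   valid for heated samples, `ambient` only for non-heated samples.
#' @return character vector of condition labels.
#' @export
deriveCondition <- function(drought, heat, humidity) {
  drought <- as.integer(drought); heat <- as.integer(heat)
  if (!all(drought %in% 0:1) || !all(heat %in% 0:1))
    stop("drought and heat must be binary (0/1)")
  if (!all(humidity %in% c("ambient", "low", "high")))
    stop("unknown humidity token: ",
         paste(setdiff(humidity, c("ambient", "low", "high")), collapse = ", "))
  bad <- (heat == 1L & humidity == "ambient") |
         (heat == 0L & humidity != "ambient")
  if (any(bad))
    stop("humidity must be 'low' or 'high' exactly when heat = 1 ",
         "(offending rows: ", paste(which(bad), collapse = ", "), ")")
  hum <- ifelse(humidity == "low", "LrH", "HrH")
  cond <- ifelse(heat == 0L & drought == 0L, "control",
          ifelse(heat == 0L, "D",
          ifelse(drought == 0L, paste0("H_", hum), paste0("DH_", hum))))
  factor(cond, levels = .CONDITIONS)[drop = TRUE]
}

#' Read a variables-by-samples intensity table
#'
#' Reads a TSV whose header row holds sample ids and whose first column holds
#' variable ids. Empty cells and `NA` are interpreted as not-detected and are
#' only permitted for metabolome layers; raw zeros are likewise treated as
#' not-detected for metabolome layers and rejected for the transcriptome.
#'
#' @param path TSV file path.
#' @param layer measurement layer label (see [OmicsExperiment()]).
#' @param scale `"raw"` (default) or `"log2"`.
#' @return an [OmicsExperiment].
#' @export
readOmicsMatrix <- function(path, layer, scale = "raw") {
  nf <- utils::count.fields(path, sep = "\t", quote = "", blank.lines.skip = FALSE)
  if (length(unique(nf)) != 1L)
    stop("ragged rows in ", path)
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           na.strings = c("", "NA"), quote = "")
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) stop("duplicate variable id in ", path)
  sids <- colnames(tab)[-1L]
  if (anyDuplicated(sids)) stop("duplicate sample id in ", path)
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  dimnames(vals) <- list(ids, sids)
  if (identical(layer, "transcriptome")) {
    if (anyNA(vals)) stop("missing values not allowed in transcriptome layer")
    if (identical(scale, "raw") && any(vals <= 0))
      stop("non-positive raw intensity in transcriptome layer")
    miss <- matrix(FALSE, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  } else {
    if (identical(scale, "raw")) vals[!is.na(vals) & vals <= 0] <- NA
    miss <- is.na(vals)
  }
  OmicsExperiment(vals, layer = layer, scale = scale, missing = miss)
}

#' Write an OmicsExperiment as TSV
#'
#' Missing cells are written as empty strings; round-trips through
#' [readOmicsMatrix()] preserve values, ids and the missing mask.
#'
#' @param x an [OmicsExperiment].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeOmicsMatrix <- function(x, path) {
  v <- intensities(x)
  m <- missingMask(x)
  ch <- matrix(sprintf("%.15g", v), nrow(v), ncol(v))
  ch[is.na(v)] <- ""     # imputed cells keep their value; undetected-and-
                         # unimputed cells round-trip as missing
  out <- cbind(variable_id = rownames(v), ch)
  colnames(out) <- c("variable_id", colnames(v))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' Expects TSV columns `sample_id`, `drought`, `heat`, `humidity`,
#' `genotype`, `batch`; derives the condition label and validates the
#' humidity rules (see [deriveCondition()]).
#'
#' @param path TSV file path.
#' @return a `data.frame` with one row per sample and a derived `condition`
#'   factor.
#' @export
readDesign <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         colClasses = "character", quote = "")
  need <- c("sample_id", "drought", "heat", "humidity", "genotype", "batch")
  if (!all(need %in% colnames(d)))
    stop("design table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(d$sample_id)) stop("duplicate sample id in design")
  d$drought <- as.integer(d$drought)
  d$heat <- as.integer(d$heat)
  d$condition <- deriveCondition(d$drought, d$heat, d$humidity)
  d$genotype <- factor(d$genotype)
  d$batch <- factor(d$batch)
  rownames(d) <- d$sample_id
  d
}

#' Write a design table
#' @param design data.frame as returned by [readDesign()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeDesign <- function(design, path) {
  cols <- c("sample_id", "drought", "heat", "humidity", "genotype", "batch")
  utils::write.table(design[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read annotation term sets in GMT format
#'
#' Standard GMT: one term per line, fields `term_id`, `description`, then the
#' member ids, tab-separated. Duplicate members within a line are collapsed.
#'
#' @param path GMT file path.
#' @return a named list of character vectors (members per term) with the
#'   descriptions in `attr(, "description")`.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 0L) < 3L
  if (any(short))
    stop("GMT line with fewer than 3 fields: line ",
         paste(which(short), collapse = ", "))
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate term: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  if (any(lengths(sets) == 0L)) stop("empty member set in GMT")
  attr(sets, "description") <- stats::setNames(vapply(fields, `[[`, "", 2L), ids)
  sets
}

#' Write annotation sets in GMT format
#' @param sets named list of member-id vectors.
#' @param path output path.
#' @param description optional named descriptions; defaults to term ids.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- attr(sets, "description")
  if (is.null(description)) description <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id)
    paste(c(id, description[[id]], sets[[id]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
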