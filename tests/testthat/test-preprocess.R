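test_that("quantile normalization equalizes column distributions", {
  v <- matrix(c(1, 3, 2, 6), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  oe <- OmicsExperiment(v, layer = "transcriptome")
  out <- intensities(quantileNormalize(oe))
  expect_equal(unname(out), matrix(c(1.5, 4.5, 1.5, 4.5), 2, 2))

  set.seed(8)
  big <- OmicsExperiment(
    matrix(2^rnorm(200, 8), 20, 10,
           dimnames = list(paste0("g", 1:20), paste0("s", 1:10))),
    layer = "transcriptome")
  once <- quantileNormalize(big)
  twice <- quantileNormalize(once)
  expect_equal(intensities(twice), intensities(once), tolerance = 1e-10)
  sorted <- apply(intensities(once), 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-10))

  ident <- OmicsExperiment(
    matrix(rep(c(4, 2, 7), 3), 3, 3,
           dimnames = list(paste0("g", 1:3), paste0("s", 1:3))),
    layer = "transcriptome")
  expect_equal(intensities(quantileNormalize(ident)), intensities(ident))
  single <- ident[, 1]
  expect_equal(intensities(quantileNormalize(single)), intensities(single))

  withNA <- OmicsExperiment(
    matrix(c(1, NA, 3, 4), 2, 2,
           dimnames = list(c("m1", "m2"), c("s1", "s2"))),
    layer = "metabolome")
  expect_error(quantileNormalize(withNA), "complete")
})

test_that("TIC normalization rescales by observed column sums", {
  v <- matrix(c(10, 30, 20, 60), 2, 2,
              dimnames = list(c("m1", "m2"), c("s1", "s2")))
  oe <- OmicsExperiment(v, layer = "metabolome")
  out <- intensities(ticNormalize(oe))
  # column sums S and 2S: second column halved relative to first
  expect_equal(unname(out[, 1]), unname(out[, 2]))
  # equal column sums: fixed point
  v2 <- matrix(c(10, 30, 15, 25), 2, 2,
               dimnames = list(c("m1", "m2"), c("s1", "s2")))
  oe2 <- OmicsExperiment(v2, layer = "metabolome")
  expect_equal(intensities(ticNormalize(oe2)), v2)
  # masked cells stay masked and excluded from sums
  v3 <- matrix(c(10, NA, 40, 40), 2, 2,
               dimnames = list(c("m1", "m2"), c("s1", "s2")))
  oe3 <- OmicsExperiment(v3, layer = "metabolome")
  out3 <- ticNormalize(oe3)
  expect_true(missingMask(out3)["m2", "s1"])
  expect_equal(intensities(out3)["m1", "s1"],
               10 / 10 * mean(c(10, 80)))
  v4 <- matrix(c(NA, NA, 1, 2), 2, 2,
               dimnames = list(c("m1", "m2"), c("s1", "s2")))
  expect_error(ticNormalize(OmicsExperiment(v4, layer = "metabolome")),
               "no observed")
})

test_that("detection filter applies the per-condition fraction rule", {
  design <- do.call(rbind, lapply(c("control", "D"), function(cc) {
    data.frame(sample_id = paste0(cc, 1:5),
               drought = as.integer(cc == "D"), heat = 0L,
               humidity = "ambient", genotype = "WT", batch = "b1")
  }))
  design$condition <- deriveCondition(design$drought, design$heat,
                                      design$humidity)
  rownames(design) <- design$sample_id
  v <- matrix(2, 3, 10,
              dimnames = list(c("m1", "m2", "m3"), design$sample_id))
  # m1: 4/5 in D, 0/5 in control -> retained at 2/3
  v["m1", 1:5] <- NA; v["m1", 6] <- NA
  # m2: 3/5 in each condition -> 0.6 < 2/3 everywhere -> dropped
  v["m2", c(1, 2, 6, 7)] <- NA
  oe <- OmicsExperiment(v, layer = "metabolome")
  kept <- rownames(filterByDetection(oe, design, 2 / 3))
  expect_setequal(kept, c("m1", "m3"))
  # boundary: exactly 2/3 counts as detected (n=3 per condition, 2 observed)
  d3 <- design[c(1:3, 6:8), ]
  v3 <- matrix(2, 1, 6, dimnames = list("m1", d3$sample_id))
  v3[1, c(1, 4)] <- NA
  expect_equal(nrow(filterByDetection(
    OmicsExperiment(v3, layer = "metabolome"), d3, 2 / 3)), 1L)
  # monotone in the fraction
  set.seed(2)
  vr <- matrix(2, 50, 10, dimnames = list(paste0("m", 1:50), design$sample_id))
  vr[sample(length(vr), 250)] <- NA
  oer <- OmicsExperiment(vr, layer = "metabolome")
  fr <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  keeps <- lapply(fr, function(f)
    rownames(filterByDetection(oer, design, f)))
  for (i in seq_along(fr)[-1])
    expect_true(all(keeps[[i]] %in% keeps[[i - 1]]))
})

test_that("floor imputation writes log2(floor) at masked cells", {
  v <- matrix(c(1e6, NA, 2e6, 8e5), 2, 2,
              dimnames = list(c("m1", "m2"), c("s1", "s2")))
  oe <- OmicsExperiment(v, layer = "metabolome")
  out <- imputeFloorAndLog(oe, 5e5)
  expect_equal(valueScale(out), "log2")
  expect_equal(intensities(out)["m2", "s1"], log2(5e5))
  expect_equal(intensities(out)["m1", "s1"], log2(1e6))
  expect_true(missingMask(out)["m2", "s1"])   # provenance retained
  expect_error(imputeFloorAndLog(out), "log2")
  # non-positive raw intensities are rejected at construction already
  v2 <- v; v2["m2", "s1"] <- -1
  expect_error(OmicsExperiment(v2, layer = "metabolome",
                               missing = matrix(FALSE, 2, 2)),
               "strictly positive")
})

test_that("batch correction removes planted offsets and keeps condition means", {
  design <- makeFactorialDesign(reps = 6)
  design$batch <- rep(c("b1", "b2", "b3"), 8)
  set.seed(4)
  # deterministic condition means per variable; batch is the only nuisance
  condMeans <- matrix(rnorm(20 * 4, 8), 20, 4,
                      dimnames = list(NULL, levels(design$condition)))
  base <- condMeans[, as.character(design$condition)]
  offsets <- c(b1 = 0.8, b2 = -0.8, b3 = 0)
  y <- base + matrix(offsets[design$batch], 20, 24, byrow = TRUE)
  oe <- makeExpr(y, design)
  v <- intensities(correctBatch(oe, design))
  # exact removal under balance: per-batch residual means vanish
  resid <- v - base
  for (b in c("b1", "b2", "b3"))
    expect_lt(max(abs(rowMeans(resid[, design$batch == b]))), 1e-8)
  # condition-mean differences invariant on a balanced noisy matrix
  yn <- y + matrix(rnorm(20 * 24, 0, 0.3), 20, 24)
  oen <- makeExpr(yn, design)
  vn <- intensities(correctBatch(oen, design))
  for (cc in c("D", "H_LrH", "DH_LrH")) {
    diffB <- rowMeans(yn[, design$condition == cc]) -
      rowMeans(yn[, design$condition == "control"])
    diffA <- rowMeans(vn[, design$condition == cc]) -
      rowMeans(vn[, design$condition == "control"])
    expect_lt(max(abs(diffB - diffA)), 1e-8)
  }
  # single batch: unchanged
  design1 <- makeFactorialDesign(reps = 2)
  oe1 <- makeExpr(matrix(rnorm(10 * 8, 8), 10, 8), design1)
  expect_equal(intensities(correctBatch(oe1, design1)), intensities(oe1))
  # batch nested in condition: error
  designN <- makeFactorialDesign(reps = 2)
  designN$batch <- as.character(designN$condition)
  oeN <- makeExpr(matrix(rnorm(10 * 8, 8), 10, 8), designN)
  expect_error(correctBatch(oeN, designN), "confounded")
})

test_that("probe collapsing averages probes of the same gene", {
  v <- matrix(c(4, 8, 1, 6, 10, 2), 3, 2,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  oe <- OmicsExperiment(v, layer = "transcriptome", scale = "log2")
  out <- collapseProbes(oe, c(p1 = "geneA", p2 = "geneA", p3 = "geneB"))
  expect_equal(intensities(out)["geneA", ], c(s1 = 6, s2 = 8))
  expect_equal(intensities(out)["geneB", ], c(s1 = 1, s2 = 2))
  # one probe per gene: identity up to naming
  out2 <- collapseProbes(oe, c(p1 = "a", p2 = "b", p3 = "c"))
  expect_equal(unname(intensities(out2)[order(c("a", "b", "c")), ]),
               unname(v))
  # unmapped probe dropped with a message
  expect_message(out3 <- collapseProbes(oe, c(p1 = "a", p2 = "b")),
                 "1 unmapped")
  expect_equal(nrow(out3), 2L)
})
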