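test_that("blank masking applies the ratio-of-means rule", {
    m <- matrix(c(1000, 0,    1500, 900,  1600, 1100,   # F1: dropped
                  0,    0,    500,  0,    700,  600,    # F2: blank-free
                  100,  100,  290,  310,  305,  295),   # F3: ratio ~3
                3, 6, byrow = TRUE,
                dimnames = list(c("F1", "F2", "F3"),
                                c("b1", "b2", "s1", "s2", "s3", "s4")))
    # F1 blank mean 500, study mean ~1275 < 3*500: dropped
    # F2 blank mean 0: retained regardless
    # F3 blank mean 100, study mean 300 >= 300: retained (inclusive)
    ft <- FeatureTable(m, mz = c(200, 300, 400), rtime = c(10, 20, 30))
    out <- blankMask(ft, c("b1", "b2"), c("s1", "s2", "s3", "s4"))
    expect_setequal(featureIds(out), c("F2", "F3"))
    expect_setequal(colnames(out), c("s1", "s2", "s3", "s4"))
    expect_error(blankMask(ft, character(), c("s1", "s2")), "skip")
})

test_that("blank masking is monotone in its threshold", {
    set.seed(42)
    ft <- randomTable(80, 8, seed = 42)
    blanks <- colnames(ft)[1:3]
    study <- colnames(ft)[4:8]
    kept <- lapply(c(1, 3, 5), function(th)
        featureIds(blankMask(ft, blanks, study,
                             curationParams(blankRatioThreshold = th))))
    expect_true(all(kept[[2]] %in% kept[[1]]))
    expect_true(all(kept[[3]] %in% kept[[2]]))
})

test_that("feature-count Z-scores reproduce the worked examples", {
    z <- sampleZscores(makeCountTable(c(100, 100, 100, 100, 40)),
                       "feature_count")
    expect_equal(unname(z), c(0.5, 0.5, 0.5, 0.5, -2.0))
    z2 <- sampleZscores(makeCountTable(c(rep(100, 9), 10)),
                        "feature_count")
    expect_equal(unname(z2[10]), -3.0)
    zc <- sampleZscores(makeCountTable(rep(50, 4)), "feature_count")
    expect_equal(unname(zc), rep(0, 4))
    expect_error(sampleZscores(makeCountTable(c(10, 20))), "3 samples")
})

test_that("missing-count and correlation metrics behave", {
    ft <- makeCountTable(c(100, 100, 100, 100, 40))
    zm <- sampleZscores(ft, "missing_count")
    expect_equal(unname(zm), c(-0.5, -0.5, -0.5, -0.5, 2.0))
    ft2 <- randomTable(60, 6, seed = 10)
    zc <- sampleZscores(ft2, "median_correlation")
    expect_equal(sum(zc), 0, tolerance = 1e-9)
})

test_that("outlier samples drop at |Z| > 2.5 on the input table", {
    out <- dropOutlierSamples(makeCountTable(c(rep(100, 9), 10)))
    expect_equal(ncol(out), 9L)                 # Z = -3.0 dropped
    out2 <- dropOutlierSamples(makeCountTable(c(100, 100, 100, 100, 40)))
    expect_equal(ncol(out2), 5L)                # |Z| = 2.0 kept
    out3 <- dropOutlierSamples(randomTable(50, 8, seed = 2),
                               curationParams(zscoreCutoff = 0.1))
    expect_lt(ncol(out3), 8L)
})

test_that("TIC normalization reproduces the worked examples exactly", {
    m <- matrix(c(1000, 2000, 4000, 4000), 1, 4,
                dimnames = list("F1", paste0("s", 1:4)))
    ft <- FeatureTable(m, mz = 100, rtime = 10)
    two <- normalizeTIC(ft, "two_pass",
                        batches = c("b1", "b1", "b2", "b2"))
    expect_equal(unname(colSums(intensityMatrix(two))), rep(2750, 4))

    m2 <- matrix(c(10, 20, 40), 1, 3,
                 dimnames = list("F1", paste0("s", 1:3)))
    one <- normalizeTIC(FeatureTable(m2, mz = 100, rtime = 10),
                        "one_pass")
    expect_equal(unname(colSums(intensityMatrix(one))), rep(20, 3))

    m3 <- matrix(c(50, 30, 50, 30, 50, 30), 2, 3,
                 dimnames = list(c("F1", "F2"), paste0("s", 1:3)))
    ident <- normalizeTIC(FeatureTable(m3, mz = c(1, 2) * 100,
                                       rtime = c(1, 2)), "one_pass")
    expect_identical(intensityMatrix(ident), m3)
})

test_that("conserved-feature TICs equalize within relative 1e-9", {
    ft <- randomTable(120, 10, seed = 5, missingRate = 0.05)
    p <- curationParams()
    for (mode in c("one_pass", "two_pass")) {
        out <- normalizeTIC(ft, mode,
                            batches = rep(c("b1", "b2"), each = 5),
                            params = p)
        m <- intensityMatrix(out)
        conserved <- rowMeans(intensityMatrix(ft) > 0) >=
            p$conservedFraction
        tics <- colSums(m[conserved, ])
        expect_lt(diff(range(tics)) / stats::median(tics), 1e-9)
    }
})

test_that("two-pass normalization removes a pure batch-scale effect", {
    a <- makeSyntheticExperiment(nCompounds = 15, nSamples = 8,
                                 nBatches = 2,
                                 batchScaleFactors = c(1, 1),
                                 missingRate = 0, seed = 8)
    b <- makeSyntheticExperiment(nCompounds = 15, nSamples = 8,
                                 nBatches = 2,
                                 batchScaleFactors = c(1, 2.5),
                                 missingRate = 0, seed = 8)
    batches <- stats::setNames(a$metadata$batch, a$metadata$name)
    na <- normalizeTIC(a$table, "two_pass", batches = batches)
    nb <- normalizeTIC(b$table, "two_pass", batches = batches)
    # the between-batch effect vanishes exactly: the two normalized
    # tables agree up to one global factor across every cell
    ratio <- intensityMatrix(nb) / intensityMatrix(na)
    expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
})

test_that("zero-TIC samples are a named error", {
    m <- matrix(c(10, 0, 20), 1, 3,
                dimnames = list("F1", c("s1", "failed", "s3")))
    ft <- FeatureTable(m, mz = 100, rtime = 10)
    expect_error(normalizeTIC(ft, "one_pass",
                              params = curationParams(
                                  conservedFraction = 0)),
                 "failed")
})

test_that("infrequent features drop at the inclusive presence bound", {
    counts <- c(2, 5, 10)     # features present in 2, 5 and 10 of 10
    m <- matrix(0, 3, 10, dimnames = list(c("F1", "F2", "F3"),
                                          sprintf("s%02d", 1:10)))
    for (i in 1:3) m[i, seq_len(counts[i])] <- 100
    ft <- FeatureTable(m, mz = c(100, 200, 300), rtime = 1:3)
    out <- dropInfrequentFeatures(ft)
    expect_setequal(featureIds(out), c("F2", "F3"))  # 5/10 kept: >= 0.5
    all3 <- dropInfrequentFeatures(ft, curationParams(
        minFeatureFraction = 0))
    expect_equal(nrow(all3), 3L)
})

test_that("scalar-minimum imputation touches only zeros", {
    m <- matrix(c(0, 100, 200), 1, 3,
                dimnames = list("F1", paste0("s", 1:3)))
    ft <- FeatureTable(m, mz = 100, rtime = 10)
    out <- imputeMissing(ft)
    expect_equal(unname(intensityMatrix(out)[1, ]), c(50, 100, 200))

    m2 <- matrix(c(0, 7, 9), 1, 3, dimnames = dimnames(m))
    out2 <- imputeMissing(FeatureTable(m2, mz = 100, rtime = 10),
                          curationParams(imputationScalar = 1))
    expect_equal(unname(intensityMatrix(out2)[1, ]), c(7, 7, 9))

    full <- randomTable(40, 5, seed = 12, missingRate = 0)
    expect_identical(intensityMatrix(imputeMissing(full)),
                     intensityMatrix(full))
    # idempotent: a second pass changes nothing
    once <- imputeMissing(randomTable(40, 5, seed = 13))
    expect_identical(intensityMatrix(imputeMissing(once)),
                     intensityMatrix(once))

    allZero <- matrix(c(0, 0, 0, 1, 2, 3), 2, 3, byrow = TRUE,
                      dimnames = list(c("F1", "F2"), paste0("s", 1:3)))
    expect_error(imputeMissing(FeatureTable(allZero, mz = c(1, 2) * 100,
                                            rtime = 1:2)), "F1")
})

test_that("ComBat wrapper reduces a planted batch shift", {
    syn <- makeSyntheticExperiment(nCompounds = 20, nSamples = 12,
                                   nBatches = 2,
                                   batchScaleFactors = c(1, 2),
                                   missingRate = 0, seed = 14)
    batches <- stats::setNames(syn$metadata$batch, syn$metadata$name)
    shift <- function(tab) {
        lg <- log2(intensityMatrix(tab))
        mean(abs(rowMeans(lg[, batches == "B1"]) -
                 rowMeans(lg[, batches == "B2"])))
    }
    before <- shift(syn$table)
    out <- batchCorrect(syn$table, batches)
    expect_identical(dim(out), dim(syn$table))
    expect_identical(featureIds(out), featureIds(syn$table))
    expect_lt(shift(out), 0.1 * before)

    expect_error(batchCorrect(syn$table, rep("B1", 12)), "2 batches")
    expect_error(batchCorrect(syn$table,
                              c(rep("B1", 11), "B2")), "at least 2")
    zero <- randomTable(5, 4, seed = 1)
    expect_error(batchCorrect(zero, rep(c("a", "b"), 2)), "impute")
})

test_that("the default curation order chains end-to-end", {
    syn <- makeSyntheticExperiment(nCompounds = 20, nSamples = 10,
                                   nBatches = 2,
                                   batchScaleFactors = c(1, 1.5),
                                   nBlanks = 2,
                                   contaminationFraction = 0.2,
                                   nFailed = 1, seed = 15)
    meta <- syn$metadata
    tab <- blankMask(syn$table,
                     meta$name[meta$sample_type == "blank"],
                     meta$name[meta$sample_type == "study"])
    tab <- dropOutlierSamples(tab)
    expect_false(syn$truth$failedSamples %in% colnames(tab))
    batches <- stats::setNames(meta$batch, meta$name)[colnames(tab)]
    tab <- normalizeTIC(tab, "two_pass", batches = batches)
    tab <- dropInfrequentFeatures(tab)
    tab <- imputeMissing(tab)
    expect_true(all(intensityMatrix(tab) > 0))
    expect_s4_class(tab, "FeatureTable")
    # contamination features were masked out
    expect_false(any(syn$truth$contaminationFeatures %in%
                         featureIds(tab)))
})
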