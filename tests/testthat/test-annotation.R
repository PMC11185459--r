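glucoseEmpcpd <- function(id = "E00001", mass = 180.063389) {
    memb <- data.frame(feature_id = paste0(id, "_F1"),
                       mz = mass + 1.007276, rtime = 100,
                       isotope = "M0", adduct = "M+H+", charge = 1L,
                       mass_offset = 1.007276, stringsAsFactors = FALSE)
    EmpiricalCompound(id, memb, neutralMass = mass)
}

test_that("level-4 annotation matches neutral masses in ppm", {
    db <- data.frame(name = c("glucose", "fructose", "other"),
                     formula = NA_character_,
                     neutral_mass = c(180.06339, 180.06339, 500.01),
                     id = c("C1", "C2", "C3"),
                     stringsAsFactors = FALSE)
    e <- glucoseEmpcpd()
    out <- annotateLevel4(list(e), db, mzTolPpm = 5)
    ann <- annotations(out[[1]])
    expect_length(ann, 2L)  # the two isomers, not the distant decoy
    expect_setequal(vapply(ann, `[[`, "", "candidate_name"),
                    c("glucose", "fructose"))
    expect_true(all(vapply(ann, function(a)
        abs(a$evidence$ppm_error) <= 5, logical(1))))

    far <- glucoseEmpcpd("E00002", mass = 500.0)  # 20 ppm from 500.01
    out2 <- annotateLevel4(list(far), db, mzTolPpm = 5)
    expect_length(annotations(out2[[1]]), 0L)

    # a singleton without neutral mass is untouched
    memb <- members(e)
    memb$isotope <- NA; memb$adduct <- NA; memb$mass_offset <- NA
    single <- EmpiricalCompound("E00003", memb)
    out3 <- annotateLevel4(list(single), db)
    expect_length(annotations(out3[[1]]), 0L)

    expect_warning(annotateLevel4(list(e), db[0, ]), "empty")
})

test_that("level-4 queries scale with compounds, not features", {
    syn <- makeSyntheticExperiment(nCompounds = 10, nSamples = 5,
                                   seed = 31)
    e <- buildEmpiricalCompounds(syn$table)
    out <- annotateLevel4(e, syn$compoundDb)
    withMass <- sum(!vapply(e, function(x) is.na(neutralMass(x)),
                            logical(1)))
    expect_equal(attr(out, "nQueries"), withMass)
    expect_lt(attr(out, "nQueries"), nrow(syn$table))
})

test_that("level-1b requires both the m/z and retention-time gates", {
    std <- data.frame(name = "glucose", mz = 181.070665, rtime = 102,
                      mode = "pos", stringsAsFactors = FALSE)
    e <- glucoseEmpcpd()
    hit <- annotateLevel1b(list(e), std, mzTolPpm = 5, rtTolS = 5)
    expect_length(annotations(hit[[1]]), 1L)
    expect_equal(annotations(hit[[1]])[[1]]$level, "1b")

    stdFarRt <- std; stdFarRt$rtime <- 120
    expect_length(annotations(annotateLevel1b(
        list(e), stdFarRt, 5, 5)[[1]]), 0L)

    stdFarMz <- std; stdFarMz$mz <- std$mz * (1 + 10e-6)
    expect_length(annotations(annotateLevel1b(
        list(e), stdFarMz, 5, 5)[[1]]), 0L)
})

test_that("the precursor index answers stabbing queries exactly", {
    empcpds <- lapply(c(100, 200, 300), function(mz) {
        memb <- data.frame(feature_id = sprintf("F%d", mz), mz = mz,
                           rtime = 50, isotope = "M0", adduct = "M+H+",
                           charge = 1L, mass_offset = 1.007276,
                           stringsAsFactors = FALSE)
        EmpiricalCompound(sprintf("E%d", mz), memb)
    })
    idx <- buildPrecursorIndex(empcpds, mzTolPpm = 5)
    hit <- queryPrecursorIndex(idx, 200.0005)  # window 200 +/- 0.001
    expect_equal(hit$feature_id, "F200")
    expect_equal(nrow(queryPrecursorIndex(idx, 150)), 0L)
})

test_that("index queries equal a linear scan on random instances", {
    set.seed(33)
    n <- 400
    empcpds <- lapply(seq_len(n), function(i) {
        mz <- runif(1, 80, 1000)
        memb <- data.frame(feature_id = sprintf("F%04d", i), mz = mz,
                           rtime = runif(1, 0, 1200), isotope = "M0",
                           adduct = "M+H+", charge = 1L,
                           mass_offset = 1.007276,
                           stringsAsFactors = FALSE)
        EmpiricalCompound(sprintf("E%04d", i), memb)
    })
    idx <- buildPrecursorIndex(empcpds, mzTolPpm = 5)
    e <- idx@entries
    queries <- c(runif(300, 80, 1000),
                 e$mz[1:50] * (1 + runif(50, -6e-6, 6e-6)))
    got <- queryPrecursorIndex(idx, queries)
    for (qi in seq_along(queries)) {
        brute <- which(e$lo <= queries[qi] & queries[qi] <= e$hi)
        expect_identical(sort(got$feature_id[got$query == qi]),
                         sort(e$feature_id[brute]))
    }
})

test_that("MS2 spectra map onto empirical compounds by both gates", {
    e <- glucoseEmpcpd()
    s <- MS2Spectrum(precursorMz = 181.0707, precursorRtime = 101,
                     peaks = cbind(c(59, 85), c(1, 2)))
    res <- mapMS2ToEmpCpds(list(s), list(e), mzTolPpm = 5, rtTolS = 30)
    expect_length(ms2Spectra(res$empcpds[[1]]), 1L)
    expect_length(res$unassigned, 0L)

    res2 <- mapMS2ToEmpCpds(list(s), list(e), mzTolPpm = 5,
                            rtTolS = 0.5)
    expect_length(ms2Spectra(res2$empcpds[[1]]), 0L)
    expect_length(res2$unassigned, 1L)

    res3 <- mapMS2ToEmpCpds(list(), list(e))
    expect_equal(res3$empcpds[[1]], e)
})

test_that("cosine score reproduces the worked examples", {
    q <- MS2Spectrum(200, cbind(c(100, 150), c(1, 0.5)))
    r <- MS2Spectrum(200, cbind(c(100, 150), c(0.5, 1)))
    m <- cosineScore(q, r, fragTolDa = 0.01, minMatched = 2)
    expect_equal(m@score, 0.8)
    expect_equal(m@nMatched, 2L)
    expect_false(m@belowThreshold)

    ident <- cosineScore(q, q, 0.01, 2)
    expect_equal(ident@score, 1)
    expect_equal(ident@nMatched, nrow(peaks(q)))

    far <- MS2Spectrum(200, cbind(c(300, 400), c(1, 1)))
    expect_equal(cosineScore(q, far, 0.01, 2)@score, 0)

    expect_error(cosineScore(
        q, MS2Spectrum(200, matrix(numeric(), 0, 2))), "empty")
})

test_that("cosine score is symmetric, bounded and scale-invariant", {
    set.seed(34)
    for (i in 1:20) {
        a <- MS2Spectrum(300, cbind(sort(runif(8, 50, 280)),
                                    runif(8, 0.01, 1)))
        b <- MS2Spectrum(300, cbind(sort(runif(8, 50, 280)),
                                    runif(8, 0.01, 1)))
        s1 <- cosineScore(a, b)@score
        s2 <- cosineScore(b, a)@score
        expect_lt(abs(s1 - s2), 1e-12)
        expect_gte(s1, 0); expect_lte(s1, 1)
        scaled <- MS2Spectrum(300, cbind(peaks(a)[, 1],
                                         peaks(a)[, 2] * 37))
        expect_equal(cosineScore(a, scaled)@score, 1)
    }
})

test_that("MS2 annotation levels follow library provenance", {
    set.seed(35)
    pkMz <- sort(runif(8, 50, 170))
    pkInt <- runif(8, 0.1, 1)
    lib <- MS2Spectrum(181.070665, cbind(pkMz, pkInt),
                       provenance = "reference_public",
                       compound = "glucose", source = "lib")
    noisy <- MS2Spectrum(181.0707, cbind(pkMz,
                                         pkInt * (1 + rnorm(8, 0, 0.05))),
                         precursorRtime = 101, source = "dda")
    e <- glucoseEmpcpd()
    e@ms2Spectra <- list(noisy)
    out <- annotateMS2(list(e), list(lib), scoreCutoff = 0.7)
    ann <- annotations(out[[1]])
    expect_length(ann, 1L)
    expect_equal(ann[[1]]$level, "2")
    expect_gt(ann[[1]]$score, 0.95)

    auth <- lib; auth@provenance <- "reference_authentic"
    out2 <- annotateMS2(list(e), list(auth), scoreCutoff = 0.7)
    expect_equal(annotations(out2[[1]])[[1]]$level, "1a")

    out3 <- annotateMS2(list(e), list(lib), scoreCutoff = 1.01)
    expect_length(annotations(out3[[1]]), 0L)

    expVec <- lib; expVec@provenance <- "experimental"
    expect_error(annotateMS2(list(e), list(expVec)), "provenance")
})

test_that("annotations map back to features with product counts", {
    memb <- data.frame(feature_id = c("f1", "f2", "f3"),
                       mz = c(100, 101, 122), rtime = 50,
                       isotope = "M0", adduct = "M+H+", charge = 1L,
                       mass_offset = 1.007276, stringsAsFactors = FALSE)
    e <- EmpiricalCompound("E1", memb, annotations = list(
        annotationRecord("4", "a", "db"),
        annotationRecord("4", "b", "db")))
    tab3 <- FeatureTable(matrix(1, 3, 2, dimnames = list(
        c("f1", "f2", "f3"), c("s1", "s2"))),
        mz = memb$mz, rtime = memb$rtime)
    expect_equal(nrow(mapAnnotationsToFeatures(list(e), tab3)), 6L)

    tab1 <- FeatureTable(matrix(1, 1, 2, dimnames = list(
        "f1", c("s1", "s2"))), mz = 100, rtime = 50)
    rows <- mapAnnotationsToFeatures(list(e), tab1)
    expect_equal(nrow(rows), 2L)
    expect_true(all(rows$feature_id == "f1"))

    eNone <- EmpiricalCompound("E2", memb)
    expect_equal(nrow(mapAnnotationsToFeatures(list(eNone), tab3)), 0L)
})

test_that("annotation ranking orders by level precedence then score", {
    recs <- list(annotationRecord("4", "d", "db"),
                 annotationRecord("2", "c", "lib", score = 0.8),
                 annotationRecord("2", "c2", "lib", score = 0.95),
                 annotationRecord("1a", "a", "auth", score = 0.9),
                 annotationRecord("1b", "b", "std"))
    ranked <- rankAnnotations(recs)
    expect_equal(vapply(ranked, `[[`, "", "level"),
                 c("1a", "1b", "2", "2", "4"))
    expect_equal(ranked[[3]]$candidate_name, "c2")
})
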