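test_that("metadata loads into an experiment with defaults and tags", {
    csv <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("name,path,sample_type,operator",
                 "s1,/data/s1.mzML,study,ab",
                 "s2,/data/s2.mzML,blank,ab",
                 "s3,/data/s3.mzML,,cd"), csv)
    expt <- loadMetadata(csv)
    acq <- acquisitions(expt)
    expect_equal(nrow(acq), 3L)
    expect_equal(acq$sample_type, c("study", "blank", "unknown"))
    expect_equal(acq$operator, c("ab", "ab", "cd"))
    expect_equal(nrow(commandLog(expt)), 1L)

    csv2 <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("name,path", "s1,/a", "s1,/b"), csv2)
    expect_error(loadMetadata(csv2), "s1")

    csv3 <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("foo,bar", "x,y"), csv3)
    expect_error(loadMetadata(csv3), "name")
})

test_that("feature tables read, write and round-trip exactly", {
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("id_number\tmz\trtime\tsnr\tsA\tsB\tsC",
                 "F1\t181.070665\t100.5\t12\t1000\t0\t500.25",
                 "F2\t203.052609\t99.8\t30\t0\t2000\t1500"), tsv)
    ft <- readFeatureTable(tsv)
    expect_s4_class(ft, "FeatureTable")
    expect_equal(dim(ft), c(2L, 3L))
    expect_equal(unname(featureMz(ft)), c(181.070665, 203.052609))
    expect_equal(intensityMatrix(ft)["F1", "sC"], 500.25)
    # snr kept as opaque metadata, not a sample
    expect_true("snr" %in%
        colnames(SummarizedExperiment::rowData(ft)))

    out <- withr::local_tempfile(fileext = ".tsv")
    writeFeatureTable(ft, out)
    back <- readFeatureTable(out)
    expect_identical(intensityMatrix(ft), intensityMatrix(back))
    expect_identical(featureMz(ft), featureMz(back))
    expect_identical(featureRtime(ft), featureRtime(back))
    # zero intensity written as literal 0, not blank
    expect_match(grep("^F1", readLines(out), value = TRUE), "\t0\t")

    bad <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("id_number\tmz\trtime\tsA", "F1\tabc\t10\t5"), bad)
    expect_error(readFeatureTable(bad), "F1")
    bad2 <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("id_number\tmz\tsA", "F1\t100\t5"), bad2)
    expect_error(readFeatureTable(bad2), "rtime")
})

test_that("minutes dialect converts retention times to seconds", {
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("id\tmass\trt\tsA", "F1\t100\t2.5\t10"), tsv)
    ft <- readFeatureTable(tsv, tableDialect(id = "id", mz = "mass",
                                             rtime = "rt",
                                             rtimeUnit = "minutes"))
    expect_equal(unname(featureRtime(ft)), 150)
})

test_that("high-precision values survive TSV round trips", {
    set.seed(11)
    for (i in 1:5) {
        ft <- randomTable(30, 4, seed = i)
        out <- withr::local_tempfile(fileext = ".tsv")
        writeFeatureTable(ft, out)
        back <- readFeatureTable(out)
        expect_identical(intensityMatrix(ft), intensityMatrix(back))
        expect_identical(featureMz(ft), featureMz(back))
    }
})

test_that("empirical-compound JSON round-trips and chains annotations", {
    memb <- data.frame(feature_id = c("F1", "F2", "F3"),
                       mz = c(181.070665, 182.07402, 203.052609),
                       rtime = c(100, 100.3, 99.8),
                       isotope = c("M0", "13C/3C1", "M0"),
                       adduct = c("M+H+", "M+H+", "M+Na+"),
                       charge = 1L,
                       mass_offset = c(1.007276, 2.010631, 22.989218),
                       stringsAsFactors = FALSE)
    e <- EmpiricalCompound("E00001", memb, neutralMass = 180.063389,
                           annotations = list(annotationRecord(
                               "4", "glucose", "hmdb_subset",
                               evidence = list(ppm_error = 0.1))))
    # chaining a second source appends, never replaces
    e <- addAnnotation(e, annotationRecord("1b", "glucose", "standards",
                                           evidence = list(rt_error = 2)))
    expect_length(annotations(e), 2L)

    json <- empcpdsToJSON(list(e))
    back <- empcpdsFromJSON(json)
    expect_length(back, 1L)
    expect_equal(back[[1]], e, tolerance = 0)
    expect_length(annotations(back[[1]]), 2L)
    expect_equal(nrow(members(back[[1]])), 3L)

    expect_error(empcpdsToJSON(list(e, e)), "duplicate")
})

test_that("command log is append-only with ordered timestamps", {
    csv <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("name,path", "s1,/a"), csv)
    dir <- withr::local_tempdir()
    expt <- loadMetadata(csv, directory = dir)
    for (cmd in c("blank_masking", "normalize", "impute"))
        expt <- logStep(expt, cmd, list(x = 1))
    cl <- commandLog(expt)
    expect_equal(cl$command, c("assemble", "blank_masking", "normalize",
                               "impute"))
    expect_true(!is.unsorted(cl$timestamp))
    # persistence round trip keeps the log intact
    saveExperiment(expt)
    back <- loadExperiment(file.path(dir, "experiment.json"))
    expect_equal(commandLog(back), cl)
    expect_equal(acquisitions(back), acquisitions(expt))
})

test_that("registries store and retrieve tables and empcpd sets", {
    csv <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("name,path", "s01,/a", "s02,/b", "s03,/c", "s04,/d"),
               csv)
    dir <- withr::local_tempdir()
    expt <- loadMetadata(csv, directory = dir)
    ft <- randomTable(20, 4, seed = 3)
    expt <- registerFeatureTable(expt, "full", ft)
    expect_identical(intensityMatrix(retrieveFeatureTable(expt, "full")),
                     intensityMatrix(ft))
    empcpds <- randomEmpCpds(5, n = 3)
    expt <- registerEmpCpds(expt, "raw", empcpds)
    expect_equal(retrieveEmpCpds(expt, "raw"), empcpds, tolerance = 0)
    expect_error(retrieveFeatureTable(expt, "nope"), "nope")
})

test_that("three-table output is emitted with cross-reference integrity", {
    ft <- randomTable(5, 4, seed = 9)
    memb <- data.frame(feature_id = "F0001", mz = featureMz(ft)[[1]],
                       rtime = featureRtime(ft)[[1]], isotope = "M0",
                       adduct = "M+H+", charge = 1L,
                       mass_offset = 1.007276, stringsAsFactors = FALSE)
    e <- EmpiricalCompound("E00001", memb, neutralMass = 100,
                           annotations = list(
        annotationRecord("4", "cpdA", "db"),
        annotationRecord("4", "cpdB", "db")))
    csv <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("name,path,sample_type,batch",
                 paste0("s", sprintf("%02d", 1:4), ",/x,study,B1")), csv)
    expt <- loadMetadata(csv)
    out <- withr::local_tempdir()
    files <- emitThreeTables(expt, ft, list(e), out)
    expect_true(all(file.exists(files)))
    ann <- read.delim(files[["annotation_table"]])
    expect_equal(nrow(ann), 2L)  # one row per (feature, annotation)
    feat <- read.delim(files[["feature_table"]])
    expect_true(all(ann$feature_id %in% feat$id_number))
    meta <- read.delim(files[["sample_metadata"]])
    expect_true(all(c("sample_type", "batch") %in% colnames(meta)))

    # no annotations: header-only annotation table, others still emitted
    e0 <- EmpiricalCompound("E00002", memb)
    out2 <- withr::local_tempdir()
    files2 <- emitThreeTables(expt, ft, list(e0), out2)
    expect_equal(nrow(read.delim(files2[["annotation_table"]])), 0L)
    expect_true(file.exists(files2[["feature_table"]]))

    # dangling member feature id is a hard error naming the feature
    membBad <- memb; membBad$feature_id <- "F999"
    eBad <- EmpiricalCompound("E00003", membBad)
    expect_error(emitThreeTables(expt, ft, list(eBad),
                                 withr::local_tempdir()), "F999")
})

test_that("MS2 spectra extract from synthetic centroided mzML", {
    set.seed(21)
    spectra <- lapply(1:5, function(i)
        MS2Spectrum(precursorMz = 100 + 50 * i,
                    precursorRtime = 60 * i,
                    peaks = cbind(sort(runif(4 + i, 50, 400)),
                                  runif(4 + i, 10, 1000)),
                    source = sprintf("syn#%d", i)))
    path <- withr::local_tempfile(fileext = ".mzML")
    writeSyntheticMzML(spectra, path)
    got <- extractMS2(path)
    expect_length(got, 5L)
    expect_equal(vapply(got, precursorMz, numeric(1)),
                 vapply(spectra, precursorMz, numeric(1)),
                 tolerance = 1e-6)
    expect_equal(vapply(got, precursorRtime, numeric(1)),
                 vapply(spectra, precursorRtime, numeric(1)),
                 tolerance = 1e-6)

    # min-peak filter: drop the 2-peak scan, keep the rest
    small <- c(spectra[1:4], list(MS2Spectrum(
        precursorMz = 500, precursorRtime = 400,
        peaks = cbind(c(100, 200), c(10, 20)), source = "syn#small")))
    path2 <- withr::local_tempfile(fileext = ".mzML")
    writeSyntheticMzML(small, path2)
    expect_length(extractMS2(path2, minPeaks = 3L), 4L)

    # MS1-only file: empty list, no error
    path3 <- withr::local_tempfile(fileext = ".mzML")
    writeSyntheticMzML(list(), path3)
    expect_length(extractMS2(path3), 0L)
})

test_that("MSP and MGF libraries round-trip through the readers", {
    s <- MS2Spectrum(precursorMz = 181.070665, precursorRtime = 100,
                     peaks = cbind(c(59.013, 85.029, 127.039),
                                   c(0.4, 1, 0.2)),
                     provenance = "reference_authentic",
                     compound = "glucose")
    msp <- withr::local_tempfile(fileext = ".msp")
    writeMSP(list(s), msp)
    back <- readMSP(msp)
    expect_length(back, 1L)
    expect_equal(precursorMz(back[[1]]), 181.070665)
    expect_equal(provenance(back[[1]]), "reference_authentic")
    expect_equal(peaks(back[[1]]), peaks(s))

    mgf <- withr::local_tempfile(fileext = ".mgf")
    writeLines(c("BEGIN IONS", "TITLE=glucose", "PEPMASS=181.070665",
                 "RTINSECONDS=100", "59.013 0.4", "85.029 1.0",
                 "END IONS"), mgf)
    g <- readMGF(mgf)
    expect_length(g, 1L)
    expect_equal(precursorMz(g[[1]]), 181.070665)
    expect_equal(nrow(peaks(g[[1]])), 2L)
})
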