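#' Generate a synthetic LC-MS experiment with planted ground truth
#'
#' Builds a fully synthetic feature table (plus metadata, compound
#' database, authentic-standards table, MS2 library and query spectra)
#' in which every feature derives from a planted compound: feature m/z =
#' neutral mass + ion offsets with multiplicative Gaussian ppm noise,
#' intensities log-normal around a per-compound abundance with the
#' stated coefficient of variation, multiplied by per-batch scale
#' factors. Optional blank acquisitions carry contamination compounds at
#' levels at least as high as in study samples; failed injections retain
#' under 10% of their features. The same `(parameters, seed)` pair
#' reproduces the output exactly.
#'
#' @param nCompounds number of planted compounds.
#' @param nSamples number of study samples.
#' @param nBatches number of batches (samples split evenly).
#' @param batchScaleFactors multiplicative intensity factor per batch
#'   (default all 1).
#' @param adducts,isotopes ion species planted per compound (labels from
#'   [defaultIonTable()]).
#' @param mzNoisePpm standard deviation of the m/z noise in ppm.
#' @param intensityCv coefficient of variation of the log-normal
#'   intensity noise.
#' @param missingRate probability that an intensity cell is missing (0).
#' @param nBlanks number of blank acquisitions.
#' @param contaminationFraction contamination compounds as a fraction of
#'   `nCompounds`; their features dominate in blanks.
#' @param nFailed number of planted failed injections.
#' @param ms2Fraction,standardsFraction fraction of compounds with a
#'   planted public-library MS2 spectrum / authentic standard. A
#'   compound's planted annotation level is `2` if it has an MS2
#'   spectrum, else `1b` if it has a standard, else `4`.
#' @param nDecoys extra database compounds at least 20 ppm away from any
#'   planted mass.
#' @param mode ionization mode.
#' @param seed RNG seed; all randomness derives from it.
#' @return list with `table` ([FeatureTable-class]), `metadata`
#'   (data.frame: name, path, sample_type, batch), `compoundDb`,
#'   `standards`, `library` and `querySpectra` (MS2), and `truth` (a
#'   `GroundTruth` list: `features` mapping each feature to its
#'   compound/ion/true m/z, `compounds` with planted masses, retention
#'   times, abundances and planted levels, `failedSamples`,
#'   `contaminationFeatures`, `batchFactors`).
#' @export
makeSyntheticExperiment <- function(nCompounds = 50, nSamples = 20,
                                    nBatches = 1,
                                    batchScaleFactors = rep(1, nBatches),
                                    adducts = c("M+H+", "M+Na+"),
                                    isotopes = c("M0", "13C/3C1"),
                                    mzNoisePpm = 2, intensityCv = 0.2,
                                    missingRate = 0.05, nBlanks = 0,
                                    contaminationFraction = 0,
                                    nFailed = 0, ms2Fraction = 0.3,
                                    standardsFraction = 0.3, nDecoys = 25,
                                    mode = "pos", seed = 1) {
    stopifnot(nCompounds > 0, nSamples > 0, nBatches > 0,
              length(batchScaleFactors) == nBatches,
              missingRate >= 0, missingRate <= 1,
              nFailed < nSamples)
    set.seed(seed)
    ion <- defaultIonTable(mode)
    isoTab <- ion@isotopes[match(isotopes, ion@isotopes$label), ]
    addTab <- ion@adducts[match(adducts, ion@adducts$label), ]
    if (any(is.na(isoTab$offset)) || any(is.na(addTab$offset)))
        stop("unknown isotope/adduct label for mode ", mode)

    cpd <- data.frame(
        name = sprintf("CPD_%03d", seq_len(nCompounds)),
        neutral_mass = round(stats::runif(nCompounds, 120, 800), 6),
        rtime = round(stats::runif(nCompounds, 60, 1140), 2),
        abundance = stats::rlnorm(nCompounds, log(1e6), 0.8),
        stringsAsFactors = FALSE)

    sampleNames <- sprintf("S%02d", seq_len(nSamples))
    batch <- sprintf("B%d", sort(rep(seq_len(nBatches),
                                     length.out = nSamples)))
    batchFactor <- stats::setNames(batchScaleFactors,
                                   sprintf("B%d", seq_len(nBatches)))
    blankNames <- if (nBlanks > 0) sprintf("BLANK%02d", seq_len(nBlanks))
                  else character()
    nContam <- round(contaminationFraction * nCompounds)
    contam <- if (nContam > 0) data.frame(
        name = sprintf("CONTAM_%03d", seq_len(nContam)),
        neutral_mass = round(stats::runif(nContam, 120, 800), 6),
        rtime = round(stats::runif(nContam, 60, 1140), 2),
        abundance = stats::rlnorm(nContam, log(5e5), 0.5),
        stringsAsFactors = FALSE)
    else cpd[0, ]

    # adduct response factors: protonated strongest, then the rest
    addFactor <- stats::setNames(
        c(1, 0.3, 0.2)[seq_len(nrow(addTab))], addTab$label)
    isoFactor <- stats::setNames(
        c(1, 0.25, 0.05)[seq_len(nrow(isoTab))], isoTab$label)

    buildRows <- function(tab, contamFlag) {
        rows <- expand.grid(ci = seq_len(nrow(tab)),
                            ai = seq_len(nrow(addTab)),
                            ii = seq_len(nrow(isoTab)))
        trueMz <- tab$neutral_mass[rows$ci] + isoTab$offset[rows$ii] +
            addTab$offset[rows$ai]
        data.frame(compound = tab$name[rows$ci],
                   isotope = isoTab$label[rows$ii],
                   adduct = addTab$label[rows$ai],
                   true_mz = trueMz,
                   rtime = tab$rtime[rows$ci],
                   base = tab$abundance[rows$ci] *
                       addFactor[rows$ai] * isoFactor[rows$ii],
                   contaminant = contamFlag,
                   stringsAsFactors = FALSE)
    }
    feat <- rbind(buildRows(cpd, FALSE),
                  if (nrow(contam)) buildRows(contam, TRUE))
    nf <- nrow(feat)
    feat$feature_id <- sprintf("F%04d", seq_len(nf))
    feat$mz <- feat$true_mz *
        (1 + stats::rnorm(nf, 0, mzNoisePpm) * 1e-6)
    feat$rt_obs <- feat$rtime + stats::rnorm(nf, 0, 0.3)

    sdlog <- sqrt(log(1 + intensityCv^2))
    studyMat <- matrix(0, nf, nSamples,
                       dimnames = list(feat$feature_id, sampleNames))
    for (s in seq_len(nSamples)) {
        v <- feat$base * batchFactor[batch[s]] *
            stats::rlnorm(nf, -sdlog^2 / 2, sdlog)
        v[stats::runif(nf) < missingRate] <- 0
        studyMat[, s] <- v
    }
    # contamination features appear in study samples below blank level
    if (any(feat$contaminant))
        studyMat[feat$contaminant, ] <- studyMat[feat$contaminant, ] * 0.2

    failed <- character()
    if (nFailed > 0) {
        failed <- sample(sampleNames, nFailed)
        for (s in failed) {
            keep <- stats::runif(nf) < 0.05
            studyMat[!keep, s] <- 0
        }
    }

    blankMat <- NULL
    if (nBlanks > 0) {
        blankMat <- matrix(0, nf, nBlanks,
                           dimnames = list(feat$feature_id, blankNames))
        if (any(feat$contaminant)) {
            ci <- which(feat$contaminant)
            for (b in seq_len(nBlanks))
                blankMat[ci, b] <- feat$base[ci] *
                    stats::rlnorm(length(ci), -sdlog^2 / 2, sdlog)
        }
    }

    mat <- cbind(studyMat, blankMat)
    table <- FeatureTable(mat, mz = feat$mz,
                          rtime = pmax(feat$rt_obs, 0),
                          featureIds = feat$feature_id)

    metadata <- data.frame(
        name = colnames(mat),
        path = sprintf("%s.mzML", colnames(mat)),
        sample_type = c(rep("study", nSamples), rep("blank", nBlanks)),
        batch = c(batch, rep(NA_character_, nBlanks)),
        stringsAsFactors = FALSE)

    # planted annotation sources
    nMs2 <- round(ms2Fraction * nCompounds)
    nStd <- round(standardsFraction * nCompounds)
    ms2Cpds <- if (nMs2 > 0) sample(cpd$name, nMs2) else character()
    stdPool <- setdiff(cpd$name, ms2Cpds)
    stdCpds <- if (nStd > 0) sample(stdPool, min(nStd, length(stdPool)))
               else character()
    cpd$planted_level <- ifelse(cpd$name %in% ms2Cpds, "2",
                                ifelse(cpd$name %in% stdCpds, "1b", "4"))

    decoys <- data.frame(
        name = sprintf("DECOY_%03d", seq_len(nDecoys)),
        neutral_mass = round(stats::runif(nDecoys, 120, 800), 6) *
            (1 + sample(c(-1, 1), nDecoys, TRUE) *
                 stats::runif(nDecoys, 50, 200) * 1e-6),
        stringsAsFactors = FALSE)
    # push decoys at least ~25 ppm away from any planted mass
    for (i in seq_len(nrow(decoys))) {
        rel <- abs(decoys$neutral_mass[i] - cpd$neutral_mass) /
            cpd$neutral_mass * 1e6
        if (any(rel < 25))
            decoys$neutral_mass[i] <- decoys$neutral_mass[i] * (1 + 1e-4)
    }
    compoundDb <- rbind(
        data.frame(name = cpd$name, formula = NA_character_,
                   neutral_mass = cpd$neutral_mass,
                   id = cpd$name, stringsAsFactors = FALSE),
        data.frame(name = decoys$name, formula = NA_character_,
                   neutral_mass = decoys$neutral_mass, id = decoys$name,
                   stringsAsFactors = FALSE))

    protonated <- addTab$offset[1L]
    standards <- data.frame(
        name = stdCpds,
        mz = cpd$neutral_mass[match(stdCpds, cpd$name)] + protonated,
        rtime = cpd$rtime[match(stdCpds, cpd$name)],
        mode = mode, stringsAsFactors = FALSE)

    libSpectra <- list(); querySpectra <- list()
    for (nm in ms2Cpds) {
        i <- match(nm, cpd$name)
        nPk <- sample(6:12, 1)
        fragMz <- sort(stats::runif(nPk, 50,
                                    cpd$neutral_mass[i] + protonated - 1))
        fragInt <- stats::runif(nPk, 0.05, 1)
        ref <- MS2Spectrum(precursorMz = cpd$neutral_mass[i] + protonated,
                           peaks = cbind(fragMz, fragInt),
                           source = "planted_library",
                           provenance = "reference_public",
                           compound = nm)
        libSpectra[[length(libSpectra) + 1L]] <- ref
        noisy <- fragInt * (1 + stats::rnorm(nPk, 0, 0.05))
        noisy[noisy <= 0] <- 0.01
        querySpectra[[length(querySpectra) + 1L]] <- MS2Spectrum(
            precursorMz = (cpd$neutral_mass[i] + protonated) *
                (1 + stats::rnorm(1, 0, mzNoisePpm) * 1e-6),
            precursorRtime = cpd$rtime[i] + stats::rnorm(1, 0, 2),
            peaks = cbind(fragMz, noisy),
            source = sprintf("dda_%s", nm), provenance = "experimental")
    }

    truth <- list(
        features = feat[, c("feature_id", "compound", "isotope", "adduct",
                            "true_mz", "contaminant")],
        compounds = cpd,
        failedSamples = failed,
        contaminationFeatures = feat$feature_id[feat$contaminant],
        batchFactors = batchFactor,
        seed = seed)
    list(table = table, metadata = metadata, compoundDb = compoundDb,
         standards = standards, library = libSpectra,
         querySpectra = querySpectra, truth = truth)
}

#' Score grouping recovery against planted truth
#'
#' For each planted compound the representative empirical compound is
#' the one that is pure (all members derive from that compound) and
#' holds a strict majority of the compound's planted features present
#' in the grouped table. A feature counts as correctly assigned when it
#' belongs to its compound's representative empirical compound; thus a
#' planted singleton recovered as a singleton is correct, features of a
#' group split down the middle (no majority) are all incorrect, and
#' members of an empirical compound mixing two compounds are all
#' incorrect. `groupRecovery` is stricter: the fraction of planted
#' groups recovered exactly. Neutral-mass ppm errors are reported for
#' the representative empirical compounds with an inferred mass.
#'
#' @param empcpds list of [EmpiricalCompound-class] built from a
#'   synthetic table.
#' @param truth the `truth` element of [makeSyntheticExperiment()].
#' @return list: `featureRecovery`, `groupRecovery`, `massErrorsPpm`
#'   (named by compound), `nFeatures`, `nGroups`.
#' @export
scoreRecovery <- function(empcpds, truth) {
    groupedIds <- unlist(lapply(empcpds, function(e)
        e@members$feature_id))
    tf <- truth$features[truth$features$feature_id %in% groupedIds, ]
    planted <- split(tf$feature_id, tf$compound)
    cpdOf <- stats::setNames(tf$compound, tf$feature_id)
    cpdMass <- stats::setNames(truth$compounds$neutral_mass,
                               truth$compounds$name)

    representative <- list()  # compound -> member ids of its empcpd
    errs <- c()
    for (e in empcpds) {
        ids <- e@members$feature_id
        cpds <- unique(cpdOf[ids])
        if (length(cpds) != 1L || anyNA(cpds)) next       # impure
        cp <- cpds[[1L]]
        if (length(ids) <= length(planted[[cp]]) / 2) next # no majority
        representative[[cp]] <- ids
        if (!is.na(e@neutralMass) && cp %in% names(cpdMass))
            errs[cp] <- ppmError(e@neutralMass, cpdMass[[cp]])
    }
    correct <- vapply(seq_len(nrow(tf)), function(i) {
        rep_ <- representative[[tf$compound[i]]]
        !is.null(rep_) && tf$feature_id[i] %in% rep_
    }, logical(1))
    groupOk <- vapply(names(planted), function(cp)
        !is.null(representative[[cp]]) &&
            setequal(representative[[cp]], planted[[cp]]), logical(1))
    list(featureRecovery = mean(correct),
         groupRecovery = mean(groupOk),
         massErrorsPpm = errs,
         nFeatures = nrow(tf), nGroups = length(planted))
}

#' Write a minimal centroided mzML file of synthetic spectra
#'
#' Serializes MS1/MS2 spectra through `mzR::writeMSData` so that
#' [extractMS2()] can be exercised without instrument data.
#'
#' @param spectra list of [MS2Spectrum-class] (written as MS2 scans,
#'   preceded by one trivial MS1 scan).
#' @param path output mzML path.
#' @return `path`, invisibly.
#' @export
writeSyntheticMzML <- function(spectra, path) {
    if (!requireNamespace("mzR", quietly = TRUE))
        stop("package 'mzR' is required to write mzML files")
    n <- length(spectra) + 1L
    pk <- c(list(matrix(c(100, 1000), 1, 2)),
            lapply(spectra, function(s) unname(s@peaks)))
    rt <- c(0, vapply(spectra, function(s)
        if (is.na(s@precursorRtime)) 0 else s@precursorRtime, numeric(1)))
    hdr <- data.frame(
        seqNum = seq_len(n), acquisitionNum = seq_len(n),
        msLevel = c(1L, rep(2L, n - 1L)), polarity = 1L,
        peaksCount = vapply(pk, nrow, integer(1)),
        totIonCurrent = vapply(pk, function(p) sum(p[, 2L]), numeric(1)),
        retentionTime = rt,
        basePeakMZ = vapply(pk, function(p) p[which.max(p[, 2L]), 1L],
                            numeric(1)),
        basePeakIntensity = vapply(pk, function(p) max(p[, 2L]),
                                   numeric(1)),
        collisionEnergy = c(0, rep(30, n - 1L)),
        ionisationEnergy = 0,
        lowMZ = vapply(pk, function(p) min(p[, 1L]), numeric(1)),
        highMZ = vapply(pk, function(p) max(p[, 1L]), numeric(1)),
        precursorScanNum = c(0L, rep(1L, n - 1L)),
        precursorMZ = c(0, vapply(spectra, function(s) s@precursorMz,
                                  numeric(1))),
        precursorCharge = c(0L, rep(1L, n - 1L)),
        precursorIntensity = c(0, rep(1000, n - 1L)),
        mergedScan = 0L, mergedResultScanNum = 0L,
        mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
        injectionTime = 0, filterString = NA_character_,
        spectrumId = sprintf("scan=%d", seq_len(n)),
        centroided = TRUE, ionMobilityDriftTime = NA_real_,
        isolationWindowTargetMZ = c(NA_real_,
                                    vapply(spectra, function(s)
                                        s@precursorMz, numeric(1))),
        isolationWindowLowerOffset = c(NA_real_, rep(0.5, n - 1L)),
        isolationWindowUpperOffset = c(NA_real_, rep(0.5, n - 1L)),
        scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
        stringsAsFactors = FALSE)
    mzR::writeMSData(pk, file = path, header = hdr)
    invisible(path)
}
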