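#' Curation parameters with defaults
#'
#' Bundles the tunable thresholds of the table-correction stages. The
#' outlier Z-score cutoff of 2.5 matches the pipeline default for
#' dropping samples on |feature-count Z|; the remaining values are
#' package defaults chosen for typical untargeted LC-MS experiments and
#' are documented in the methods vignette.
#'
#' @param blankRatioThreshold a feature is kept by blank masking when its
#'   mean study intensity is at least this multiple of its mean blank
#'   intensity (default 3).
#' @param zscoreCutoff |Z| cutoff for outlier-sample removal (default
#'   2.5).
#' @param conservedFraction fraction of samples a feature must be
#'   observed in to count as conserved for TIC normalization (default
#'   0.9).
#' @param minFeatureFraction minimum presence fraction for
#'   infrequent-feature removal (default 0.5).
#' @param imputationScalar multiple of the per-feature minimum observed
#'   intensity used to fill missing values (default 0.5).
#' @return a named list of validated parameters.
#' @export
curationParams <- function(blankRatioThreshold = 3, zscoreCutoff = 2.5,
                           conservedFraction = 0.9,
                           minFeatureFraction = 0.5,
                           imputationScalar = 0.5) {
    stopifnot(blankRatioThreshold > 0, zscoreCutoff > 0,
              conservedFraction >= 0, conservedFraction <= 1,
              minFeatureFraction >= 0, minFeatureFraction <= 1,
              imputationScalar > 0)
    list(blankRatioThreshold = blankRatioThreshold,
         zscoreCutoff = zscoreCutoff,
         conservedFraction = conservedFraction,
         minFeatureFraction = minFeatureFraction,
         imputationScalar = imputationScalar)
}

.subsetFeatures <- function(table, keep) {
    out <- table[keep, , drop = FALSE]
    new("FeatureTable", out)
}

.subsetSamples <- function(table, keep) {
    out <- table[, keep, drop = FALSE]
    new("FeatureTable", out)
}

#' Mask blank-borne features
#'
#' A feature is retained when its mean study intensity (over nonmissing
#' study samples) is at least `blankRatioThreshold` times its mean blank
#' intensity (over all blanks, missing counted as 0). Features absent
#' from every blank are always retained. Blank columns are dropped from
#' the output. The retained set shrinks (or stays equal) as the
#' threshold grows.
#'
#' @param table a [FeatureTable-class].
#' @param blankNames,studyNames disjoint sets of sample column names.
#' @param params a [curationParams()].
#' @return the masked [FeatureTable-class] without blank columns.
#' @export
blankMask <- function(table, blankNames, studyNames,
                      params = curationParams()) {
    if (!length(blankNames))
        stop("no blank acquisitions given; skip the blank-masking stage ",
             "instead of calling it without blanks")
    if (length(intersect(blankNames, studyNames)))
        stop("blankNames and studyNames must be disjoint")
    m <- intensityMatrix(table)
    missing <- setdiff(c(blankNames, studyNames), colnames(m))
    if (length(missing))
        stop("samples absent from table: ", paste(missing, collapse = ", "))
    blank <- m[, blankNames, drop = FALSE]
    study <- m[, studyNames, drop = FALSE]
    blankMean <- rowMeans(blank)
    studyMean <- apply(study, 1L, function(x)
        if (any(x > 0)) mean(x[x > 0]) else 0)
    keep <- blankMean == 0 |
        studyMean >= params$blankRatioThreshold * blankMean
    .subsetSamples(.subsetFeatures(table, keep),
                   setdiff(colnames(m), blankNames))
}

.popSd <- function(x) sqrt(mean((x - mean(x))^2))

.zscore <- function(x) {
    s <- .popSd(x)
    if (s == 0) return(stats::setNames(rep(0, length(x)), names(x)))
    (x - mean(x)) / s
}

#' Per-sample quality Z-scores
#'
#' Computes one quality metric per sample and standardizes it as
#' `Z = (x - mean(x)) / sd_pop(x)` with the population (n-divisor)
#' standard deviation, so small worked examples are exact. Metrics:
#' `feature_count` (features observed, intensity > 0), `missing_count`
#' (features at 0), `median_correlation` (median over the other samples
#' of the Pearson correlation of log10(intensity + 1) over features
#' observed in both samples). A constant metric yields all-zero Z.
#'
#' @param table a [FeatureTable-class] with at least 3 samples.
#' @param metric which metric to standardize.
#' @return named numeric vector of Z-scores (one per sample).
#' @export
sampleZscores <- function(table,
                          metric = c("feature_count", "missing_count",
                                     "median_correlation")) {
    metric <- match.arg(metric)
    m <- intensityMatrix(table)
    if (ncol(m) < 3L) stop("at least 3 samples are required")
    x <- switch(metric,
        feature_count = colSums(m > 0),
        missing_count = colSums(m == 0),
        median_correlation = .medianCorrelations(m))
    .zscore(stats::setNames(as.numeric(x), colnames(m)))
}

.medianCorrelations <- function(m) {
    lm10 <- log10(m + 1)
    n <- ncol(m)
    cors <- matrix(NA_real_, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        shared <- m[, i] > 0 & m[, j] > 0
        r <- if (sum(shared) >= 3L)
            suppressWarnings(stats::cor(lm10[shared, i], lm10[shared, j]))
        else NA_real_
        cors[i, j] <- cors[j, i] <- if (is.na(r)) 0 else r
    }
    vapply(seq_len(n), function(i)
        stats::median(cors[i, -i]), numeric(1))
}

#' Drop outlier samples by feature-count Z-score
#'
#' Samples whose |feature-count Z| exceeds the cutoff (default 2.5) are
#' removed. Z-scores are computed once on the input table, not
#' iteratively.
#'
#' @inheritParams blankMask
#' @return the [FeatureTable-class] without outlier samples.
#' @export
dropOutlierSamples <- function(table, params = curationParams()) {
    z <- sampleZscores(table, "feature_count")
    keep <- names(z)[abs(z) <= params$zscoreCutoff]
    if (!length(keep)) stop("all samples flagged as outliers")
    .subsetSamples(table, keep)
}

#' TIC normalization (one- or two-pass)
#'
#' The per-sample TIC is the summed intensity of the conserved features
#' (those observed in at least `conservedFraction` of samples; if none
#' qualify, all features are used). In `one_pass` mode every sample is
#' scaled by `median(TIC) / TIC_s`. In `two_pass` mode samples are first
#' scaled to their batch-median TIC, then each batch is scaled to the
#' global median of the pass-1 TICs, so batches measured at different
#' overall response are brought onto one scale. After either mode all
#' conserved-feature TICs are equal (to the applicable median) within
#' relative 1e-9; non-conserved features are scaled by the same
#' per-sample factor.
#'
#' @param table a [FeatureTable-class].
#' @param mode `"one_pass"` or `"two_pass"`.
#' @param batches named character/factor of batch labels (required for
#'   two-pass; names = sample names, or in table column order).
#' @param params a [curationParams()].
#' @return the normalized [FeatureTable-class].
#' @export
normalizeTIC <- function(table, mode = c("one_pass", "two_pass"),
                         batches = NULL, params = curationParams()) {
    mode <- match.arg(mode)
    m <- intensityMatrix(table)
    conserved <- rowMeans(m > 0) >= params$conservedFraction
    if (!any(conserved)) {
        warning("no conserved features at fraction ",
                params$conservedFraction, "; using all features for TIC")
        conserved <- rep(TRUE, nrow(m))
    }
    tic <- colSums(m[conserved, , drop = FALSE])
    if (any(tic == 0))
        stop("zero TIC for sample(s): ",
             paste(colnames(m)[tic == 0], collapse = ", "),
             " (likely failed injections; drop them first)")
    if (mode == "one_pass") {
        factor <- stats::median(tic) / tic
    } else {
        if (is.null(batches))
            stop("two-pass normalization requires batch labels")
        b <- as.character(batches)
        if (!is.null(names(batches))) b <- b[match(colnames(m),
                                                   names(batches))]
        if (length(b) != ncol(m) || any(is.na(b)))
            stop("batch labels required for every sample")
        batchMed <- tapply(tic, b, stats::median)
        pass1 <- batchMed[b]                      # pass-1 TIC per sample
        globalMed <- stats::median(pass1)
        factor <- as.numeric(batchMed[b] / tic * globalMed / batchMed[b])
    }
    out <- sweep(m, 2L, factor, "*")
    res <- table
    SummarizedExperiment::assay(res, "intensity") <- out
    new("FeatureTable", res)
}

#' Remove infrequent features
#'
#' Keeps features observed (intensity > 0) in at least
#' `minFeatureFraction` of the samples (inclusive bound).
#'
#' @inheritParams blankMask
#' @return the filtered [FeatureTable-class].
#' @export
dropInfrequentFeatures <- function(table, params = curationParams()) {
    m <- intensityMatrix(table)
    keep <- rowMeans(m > 0) >= params$minFeatureFraction
    .subsetFeatures(table, keep)
}

#' Impute missing values by scalar minimum
#'
#' Every missing (zero) cell of a feature becomes `imputationScalar`
#' times the smallest nonzero intensity observed for that feature.
#' Nonmissing cells are untouched, so the operation is idempotent. A
#' feature with no observed value at all is an error — it should have
#' been removed by [dropInfrequentFeatures()].
#'
#' @inheritParams blankMask
#' @return the imputed [FeatureTable-class] (no zeros remain).
#' @export
imputeMissing <- function(table, params = curationParams()) {
    m <- intensityMatrix(table)
    allZero <- rowSums(m > 0) == 0
    if (any(allZero))
        stop("feature(s) with no observed value: ",
             paste(utils::head(rownames(m)[allZero], 5L), collapse = ", "),
             " (remove them with dropInfrequentFeatures first)")
    mins <- apply(m, 1L, function(x) min(x[x > 0]))
    fill <- params$imputationScalar * mins
    idx <- which(m == 0, arr.ind = TRUE)
    if (nrow(idx)) m[idx] <- fill[idx[, 1L]]
    res <- table
    SummarizedExperiment::assay(res, "intensity") <- m
    new("FeatureTable", res)
}

#' Batch correction (ComBat wrapper)
#'
#' Delegates to `sva::ComBat` on log2-transformed intensities and
#' back-transforms; feature and sample identities are preserved. Run
#' after imputation — batch correction is sensitive to missing values.
#'
#' @param table a [FeatureTable-class] without missing (zero) values.
#' @param batches batch label per sample (>= 2 batches, each with >= 2
#'   samples; named by sample or in column order).
#' @return the corrected [FeatureTable-class].
#' @export
batchCorrect <- function(table, batches) {
    if (!requireNamespace("sva", quietly = TRUE))
        stop("package 'sva' is required for batch correction")
    m <- intensityMatrix(table)
    if (any(m == 0))
        stop("missing (zero) values present; impute before batch correction")
    b <- as.character(batches)
    if (!is.null(names(batches))) b <- b[match(colnames(m), names(batches))]
    if (length(b) != ncol(m) || any(is.na(b)))
        stop("batch labels required for every sample")
    tab <- table(b)
    if (length(tab) < 2L)
        stop("batch correction requires at least 2 batches")
    if (any(tab < 2L))
        stop("every batch needs at least 2 samples (offending: ",
             paste(names(tab)[tab < 2L], collapse = ", "), ")")
    lg <- log2(m)
    corrected <- suppressMessages(sva::ComBat(dat = lg, batch = b))
    out <- 2^corrected
    dimnames(out) <- dimnames(m)
    res <- table
    SummarizedExperiment::assay(res, "intensity") <- out
    new("FeatureTable", res)
}
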