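#' Construct a FeatureTable
#'
#' @param intensities numeric matrix, features x samples, nonnegative.
#'   A value of 0 encodes a missing measurement.
#' @param mz numeric vector of feature m/z values in Daltons.
#' @param rtime numeric vector of retention times in seconds.
#' @param featureIds character vector of unique feature ids; defaults to
#'   the rownames of `intensities`.
#' @param extra optional data.frame of additional per-feature metadata
#'   (kept opaque, e.g. preprocessor quality scores).
#' @return a [FeatureTable-class].
#' @examples
#' ft <- FeatureTable(matrix(c(0, 100, 200, 300), 2, 2,
#'                           dimnames = list(c("F1", "F2"), c("s1", "s2"))),
#'                    mz = c(181.0707, 182.0740), rtime = c(100, 100.3))
#' featureMz(ft)
#' @export
FeatureTable <- function(intensities, mz, rtime, featureIds = NULL,
                         extra = NULL) {
    intensities <- as.matrix(intensities)
    if (is.null(featureIds)) featureIds <- rownames(intensities)
    if (is.null(featureIds))
        stop("featureIds required (or rownames on the intensity matrix)")
    rownames(intensities) <- featureIds
    rd <- S4Vectors::DataFrame(mz = as.numeric(mz), rtime = as.numeric(rtime),
                               row.names = featureIds)
    if (!is.null(extra) && ncol(extra))
        rd <- cbind(rd, S4Vectors::DataFrame(extra))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = intensities), rowData = rd)
    new("FeatureTable", se)
}

#' @rdname metaboPost-accessors
#' @export
setMethod("featureMz", "FeatureTable", function(object)
    stats::setNames(SummarizedExperiment::rowData(object)$mz,
                    rownames(object)))

#' @rdname metaboPost-accessors
#' @export
setMethod("featureRtime", "FeatureTable", function(object)
    stats::setNames(SummarizedExperiment::rowData(object)$rtime,
                    rownames(object)))

#' @rdname metaboPost-accessors
#' @export
setMethod("intensityMatrix", "FeatureTable", function(object)
    SummarizedExperiment::assay(object, "intensity"))

#' @rdname metaboPost-accessors
#' @export
setMethod("featureIds", "FeatureTable", function(object) rownames(object))

setMethod("show", "FeatureTable", function(object) {
    cat(sprintf("FeatureTable: %d features x %d samples\n",
                nrow(object), ncol(object)))
    cat(sprintf("  m/z range: %.4f-%.4f  rtime range: %.1f-%.1f s\n",
                min(featureMz(object)), max(featureMz(object)),
                min(featureRtime(object)), max(featureRtime(object))))
    a <- intensityMatrix(object)
    cat(sprintf("  missing (zero) cells: %.1f%%\n", 100 * mean(a == 0)))
})

#' Column dialect of a feature-table TSV
#'
#' Names the id, m/z and retention-time columns of a feature-table file
#' and any known non-sample metadata columns. The default follows the
#' Asari preprocessor output (`id_number`, `mz`, `rtime`, retention time
#' in seconds). Columns listed in `extra` are carried as opaque feature
#' metadata; all remaining columns are treated as sample intensities.
#'
#' @param id,mz,rtime column names in the file.
#' @param extra character vector of non-sample metadata column names.
#' @param rtimeUnit `"seconds"` or `"minutes"`; minutes are converted to
#'   seconds when reading (seconds are canonical throughout).
#' @return a named list understood by [readFeatureTable()].
#' @export
tableDialect <- function(id = "id_number", mz = "mz", rtime = "rtime",
                         extra = c("parent_masstrack_id", "peak_area",
                                   "cSelectivity", "goodness_fitting", "snr",
                                   "detection_counts", "left_base",
                                   "right_base"),
                         rtimeUnit = c("seconds", "minutes")) {
    list(id = id, mz = mz, rtime = rtime, extra = extra,
         rtimeUnit = match.arg(rtimeUnit))
}

.parseNumericColumn <- function(x, what, ids) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(x)))
    if (length(bad) == 0L) bad <- which(is.na(out))
    if (length(bad))
        stop(sprintf("non-numeric %s in row(s): %s", what,
                     paste(utils::head(ids[bad], 5L), collapse = ", ")))
    out
}

#' Read a feature table from TSV
#'
#' Reads a preprocessor feature table (one row per feature: id, m/z,
#' retention time, per-sample intensities). Unparseable numeric cells are
#' a hard error naming the offending row. Retention times declared in
#' minutes by the dialect are converted to seconds.
#'
#' @param path TSV file path.
#' @param dialect a [tableDialect()].
#' @param sampleColumns optionally, the exact sample column names; by
#'   default every column not named by the dialect is a sample.
#' @return a [FeatureTable-class].
#' @export
readFeatureTable <- function(path, dialect = tableDialect(),
                             sampleColumns = NULL) {
    d <- utils::read.delim(path, check.names = FALSE, sep = "\t",
                           colClasses = "character")
    for (nm in c("id", "mz", "rtime"))
        if (!dialect[[nm]] %in% colnames(d))
            stop(sprintf("missing required column '%s' (expected columns: %s, %s, %s)",
                         dialect[[nm]], dialect$id, dialect$mz, dialect$rtime))
    ids <- d[[dialect$id]]
    if (anyDuplicated(ids))
        stop(sprintf("duplicate feature ids: %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    mz <- .parseNumericColumn(d[[dialect$mz]], "m/z", ids)
    rtime <- .parseNumericColumn(d[[dialect$rtime]], "retention time", ids)
    if (identical(dialect$rtimeUnit, "minutes")) rtime <- rtime * 60
    known <- c(dialect$id, dialect$mz, dialect$rtime)
    extraCols <- intersect(dialect$extra, colnames(d))
    if (is.null(sampleColumns))
        sampleColumns <- setdiff(colnames(d), c(known, extraCols))
    if (!length(sampleColumns)) stop("no sample columns found")
    mat <- vapply(sampleColumns, function(cn)
        .parseNumericColumn(d[[cn]], sprintf("intensity in '%s'", cn), ids),
        numeric(nrow(d)))
    mat <- matrix(mat, nrow = nrow(d),
                  dimnames = list(ids, sampleColumns))
    extra <- if (length(extraCols)) d[, extraCols, drop = FALSE] else NULL
    FeatureTable(mat, mz = mz, rtime = rtime, featureIds = ids, extra = extra)
}

.fmt <- function(x) {
    # %.17g round-trips doubles exactly; integers print without exponent
    ifelse(x == round(x) & abs(x) < 1e15,
           sprintf("%.0f", x), sprintf("%.17g", x))
}

#' Write a feature table as TSV
#'
#' Numeric values are written with full double precision so that
#' `readFeatureTable(writeFeatureTable(x))` reproduces `x` exactly.
#' Missing intensities are written as `0`, never as blank.
#'
#' @param table a [FeatureTable-class].
#' @param path output TSV path.
#' @param dialect a [tableDialect()] naming the output columns.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(table, path, dialect = tableDialect()) {
    stopifnot(is(table, "FeatureTable"))
    rd <- SummarizedExperiment::rowData(table)
    out <- data.frame(id = featureIds(table),
                      mz = .fmt(featureMz(table)),
                      rtime = .fmt(featureRtime(table)),
                      check.names = FALSE, stringsAsFactors = FALSE)
    names(out) <- c(dialect$id, dialect$mz, dialect$rtime)
    for (cn in setdiff(colnames(rd), c("mz", "rtime")))
        out[[cn]] <- as.character(rd[[cn]])
    m <- intensityMatrix(table)
    for (cn in colnames(m)) out[[cn]] <- .fmt(m[, cn])
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
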