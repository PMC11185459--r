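#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.SAMPLE_TYPES <- c("study", "blank", "pool_qc", "standard", "unknown")
.ANNOTATION_LEVELS <- c("1a", "1b", "2", "4")
.PROVENANCES <- c("experimental", "reference_public", "reference_authentic")

#' FeatureTable: aligned LC-MS features with per-sample intensities
#'
#' A `FeatureTable` is a [SummarizedExperiment::SummarizedExperiment]
#' carrying one `intensity` assay (features x acquisitions), with `mz`
#' (Daltons) and `rtime` (seconds) in its `rowData`. An intensity of 0
#' encodes a missing value throughout the package; no other sentinel is
#' used. Any extra per-feature columns read from the input table are kept
#' as opaque metadata in `rowData`.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @aliases FeatureTable-class
#' @exportClass FeatureTable
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
    msg <- character()
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'intensity' is required")
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("mz", "rtime") %in% colnames(rd)))
        msg <- c(msg, "rowData must contain 'mz' and 'rtime'")
    else {
        if (!is.numeric(rd$mz) || any(!is.finite(rd$mz)) || any(rd$mz <= 0))
            msg <- c(msg, "mz must be finite and > 0")
        if (!is.numeric(rd$rtime) || any(!is.finite(rd$rtime)) ||
            any(rd$rtime < 0))
            msg <- c(msg, "rtime must be finite and >= 0")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "feature ids (rownames) must be present and unique")
    if (ncol(object) < 1L)
        msg <- c(msg, "at least one sample column is required")
    if ("intensity" %in% SummarizedExperiment::assayNames(object)) {
        a <- SummarizedExperiment::assay(object, "intensity")
        if (any(!is.finite(a)) || any(a < 0))
            msg <- c(msg, "intensities must be finite and nonnegative")
    }
    if (length(msg)) msg else TRUE
})

#' MS2Spectrum: a centroided fragment spectrum
#'
#' Fragment peak list with precursor m/z and (optionally) precursor
#' retention time. `provenance` distinguishes experimental spectra from
#' public-library and authentic-standard reference spectra, which decides
#' the confidence level of MS2 annotations (2 vs 1a).
#'
#' @slot precursorMz precursor m/z in Daltons (> 0).
#' @slot precursorRtime precursor retention time in seconds, or `NA` for
#'   library spectra without retention information.
#' @slot peaks two-column numeric matrix (`mz`, `intensity`), rows sorted
#'   ascending by m/z, intensities strictly positive.
#' @slot source free-text origin (file + scan index, or library name).
#' @slot provenance one of `"experimental"`, `"reference_public"`,
#'   `"reference_authentic"`.
#' @slot compound compound name for reference spectra (`NA` otherwise).
#' @aliases MS2Spectrum-class
#' @exportClass MS2Spectrum
setClass("MS2Spectrum", representation(
    precursorMz = "numeric",
    precursorRtime = "numeric",
    peaks = "matrix",
    source = "character",
    provenance = "character",
    compound = "character"
))

setValidity("MS2Spectrum", function(object) {
    msg <- character()
    if (length(object@precursorMz) != 1L || !is.finite(object@precursorMz) ||
        object@precursorMz <= 0)
        msg <- c(msg, "precursorMz must be a single positive number")
    if (length(object@precursorRtime) != 1L)
        msg <- c(msg, "precursorRtime must be length 1 (NA allowed)")
    p <- object@peaks
    if (!is.numeric(p) || ncol(p) != 2L)
        msg <- c(msg, "peaks must be a numeric matrix with columns mz, intensity")
    else {
        if (nrow(p) > 0L) {
            if (is.unsorted(p[, 1L]))
                msg <- c(msg, "peaks must be sorted ascending by m/z")
            if (any(p[, 2L] <= 0))
                msg <- c(msg, "peak intensities must be > 0")
        }
    }
    if (!object@provenance %in% .PROVENANCES)
        msg <- c(msg, sprintf("provenance must be one of: %s",
                              paste(.PROVENANCES, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' IonTable: isotope steps and adduct offsets for one ionization mode
#'
#' Mass offsets used to recognize isotopologue and adduct relations
#' between features. Isotope steps are offsets from the monoisotopic
#' species (M0 = 0); adduct offsets are Daltons added to the neutral mass
#' for a singly charged ion.
#'
#' @slot mode `"pos"` or `"neg"`.
#' @slot isotopes data.frame with columns `label`, `offset` (Daltons).
#' @slot adducts data.frame with columns `label`, `offset` (Daltons).
#' @aliases IonTable-class
#' @exportClass IonTable
setClass("IonTable", representation(
    mode = "character",
    isotopes = "data.frame",
    adducts = "data.frame"
))

setValidity("IonTable", function(object) {
    msg <- character()
    if (!object@mode %in% c("pos", "neg"))
        msg <- c(msg, "mode must be 'pos' or 'neg'")
    for (nm in c("isotopes", "adducts")) {
        d <- slot(object, nm)
        if (!all(c("label", "offset") %in% colnames(d)))
            msg <- c(msg, sprintf("%s needs columns label, offset", nm))
        else {
            if (anyDuplicated(d$label))
                msg <- c(msg, sprintf("%s labels must be unique", nm))
            if (any(!is.finite(d$offset)))
                msg <- c(msg, sprintf("%s offsets must be finite", nm))
        }
    }
    if (length(msg)) msg else TRUE
})

#' EmpiricalCompound: a group of degenerate features
#'
#' The unit of annotation: co-eluting isotopologue/adduct features
#' attributed to one tentative compound, with an inferred neutral mass
#' and a chainable list of annotation records. Annotations from several
#' sources accumulate; none are suppressed.
#'
#' @slot empcpdId unique identifier within one set.
#' @slot neutralMass inferred neutral monoisotopic mass in Daltons, `NA`
#'   when the ion species is unknown (e.g. ungrouped singletons).
#' @slot mode ionization mode, `"pos"` or `"neg"`.
#' @slot members data.frame with one row per member feature: `feature_id`,
#'   `mz`, `rtime`, `isotope`, `adduct` (labels, `NA` when unknown),
#'   `charge`, `mass_offset` (total ion offset in Daltons, `NA` unknown).
#' @slot ms2Spectra list of [MS2Spectrum-class] attached to this compound.
#' @slot annotations list of annotation records (see [annotationRecord()]).
#' @aliases EmpiricalCompound-class
#' @exportClass EmpiricalCompound
setClass("EmpiricalCompound", representation(
    empcpdId = "character",
    neutralMass = "numeric",
    mode = "character",
    members = "data.frame",
    ms2Spectra = "list",
    annotations = "list"
))

setValidity("EmpiricalCompound", function(object) {
    msg <- character()
    m <- object@members
    need <- c("feature_id", "mz", "rtime", "isotope", "adduct", "charge",
              "mass_offset")
    if (!all(need %in% colnames(m)))
        msg <- c(msg, sprintf("members needs columns: %s",
                              paste(need, collapse = ", ")))
    else {
        if (nrow(m) < 1L) msg <- c(msg, "members must be nonempty")
        if (anyDuplicated(m$feature_id))
            msg <- c(msg, "member feature_ids must be distinct")
    }
    if (!object@mode %in% c("pos", "neg"))
        msg <- c(msg, "mode must be 'pos' or 'neg'")
    bad <- vapply(object@annotations, function(a)
        !is.list(a) || is.null(a$level) || !a$level %in% .ANNOTATION_LEVELS,
        logical(1))
    if (any(bad))
        msg <- c(msg, "annotations must be records with level in 1a/1b/2/4")
    if (length(msg)) msg else TRUE
})

#' MetaboExperiment: acquisitions, on-disk registries and command log
#'
#' Book-keeping object for one experiment: the acquisition list from the
#' sample metadata CSV, registries mapping monikers to feature tables and
#' empirical-compound documents stored under `directory`, and an
#' append-only log of the commands applied, which the PDF report renders
#' as the analysis timeline.
#'
#' @slot directory path used for on-disk intermediates.
#' @slot acquisitions data.frame with columns `name`, `source_path`,
#'   `sample_type`, `batch` plus any extra tag columns from the metadata.
#' @slot tableRegistry named character: moniker -> feature-table file.
#' @slot empcpdRegistry named character: moniker -> empcpd JSON file.
#' @slot commandLog data.frame `timestamp`, `command`, `params` (JSON).
#' @aliases MetaboExperiment-class
#' @exportClass MetaboExperiment
setClass("MetaboExperiment", representation(
    directory = "character",
    acquisitions = "data.frame",
    tableRegistry = "character",
    empcpdRegistry = "character",
    commandLog = "data.frame"
))

setValidity("MetaboExperiment", function(object) {
    msg <- character()
    a <- object@acquisitions
    if (!all(c("name", "source_path", "sample_type", "batch") %in% colnames(a)))
        msg <- c(msg, "acquisitions needs name, source_path, sample_type, batch")
    else {
        if (anyDuplicated(a$name))
            msg <- c(msg, sprintf("duplicate acquisition names: %s",
                paste(unique(a$name[duplicated(a$name)]), collapse = ", ")))
        if (nrow(a) && !all(a$sample_type %in% .SAMPLE_TYPES))
            msg <- c(msg, sprintf("sample_type must be one of: %s",
                                  paste(.SAMPLE_TYPES, collapse = ", ")))
    }
    if (anyDuplicated(names(object@tableRegistry)))
        msg <- c(msg, "table registry monikers must be unique")
    if (anyDuplicated(names(object@empcpdRegistry)))
        msg <- c(msg, "empcpd registry monikers must be unique")
    if (!all(c("timestamp", "command", "params") %in%
             colnames(object@commandLog)))
        msg <- c(msg, "commandLog needs timestamp, command, params")
    if (length(msg)) msg else TRUE
})

#' PrecursorIndex: interval index over member feature m/z windows
#'
#' One ppm tolerance window per empirical-compound member feature, held
#' both as exact numeric bounds and as an integer interval forest
#' (micro-Dalton resolution) used as an overlap prefilter. A stabbing
#' query returns exactly the members whose window contains the query m/z,
#' provably identical to a linear scan.
#'
#' @slot entries data.frame: `empcpd_id`, `feature_id`, `mz`, `rtime`,
#'   `lo`, `hi` (window bounds in Daltons).
#' @slot ranges an [IRanges::IRanges] prefilter over scaled bounds.
#' @slot tolPpm the ppm half-width used to build the windows.
#' @aliases PrecursorIndex-class
#' @exportClass PrecursorIndex
setClass("PrecursorIndex", representation(
    entries = "data.frame",
    ranges = "ANY",
    tolPpm = "numeric"
))

#' QCSummary: per-sample and pairwise quality-control metrics
#'
#' @slot perSample data.frame keyed by acquisition name with TIC, feature
#'   and missing-feature counts, median/mean nonmissing intensity, median
#'   inter-sample correlation, and the three Z-score columns.
#' @slot pearson,spearman symmetric correlation matrices across samples.
#' @slot pca list with `coords` (samples x 2) and `explainedVariance`.
#' @slot tsne optional list with `coords`; empty when not computed.
#' @aliases QCSummary-class
#' @exportClass QCSummary
setClass("QCSummary", representation(
    perSample = "data.frame",
    pearson = "matrix",
    spearman = "matrix",
    pca = "list",
    tsne = "list"
))

#' SpectralMatch: result of comparing two MS2 spectra
#'
#' @slot score cosine similarity in `[0, 1]`.
#' @slot nMatched number of greedily paired peaks.
#' @slot pairs integer matrix of paired peak indices (query, reference).
#' @slot belowThreshold `TRUE` when `nMatched` fell short of the
#'   requested minimum; the score is still reported.
#' @aliases SpectralMatch-class
#' @exportClass SpectralMatch
setClass("SpectralMatch", representation(
    score = "numeric",
    nMatched = "integer",
    pairs = "matrix",
    belowThreshold = "logical"
))

setValidity("SpectralMatch", function(object) {
    if (object@score < -1e-12 || object@score > 1 + 1e-12)
        "score must lie in [0, 1]" else TRUE
})
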