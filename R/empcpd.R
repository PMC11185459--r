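.EMPCPD_SCHEMA <- "metaboPost-empcpd-1.0"

#' Construct an EmpiricalCompound
#'
#' @param empcpdId unique identifier.
#' @param members data.frame with columns `feature_id`, `mz`, `rtime`,
#'   `isotope`, `adduct`, `charge`, `mass_offset` (labels/offset may be
#'   `NA` for features of unknown ion species).
#' @param mode ionization mode, `"pos"` or `"neg"`.
#' @param neutralMass inferred neutral mass in Daltons, or `NA`.
#' @param ms2Spectra list of [MS2Spectrum-class].
#' @param annotations list of [annotationRecord()] entries.
#' @return an [EmpiricalCompound-class].
#' @export
EmpiricalCompound <- function(empcpdId, members, mode = "pos",
                              neutralMass = NA_real_, ms2Spectra = list(),
                              annotations = list()) {
    members <- as.data.frame(members, stringsAsFactors = FALSE)
    members$feature_id <- as.character(members$feature_id)
    for (cn in c("isotope", "adduct"))
        members[[cn]] <- as.character(members[[cn]])
    for (cn in c("mz", "rtime", "mass_offset"))
        members[[cn]] <- as.numeric(members[[cn]])
    members$charge <- as.integer(members$charge)
    rownames(members) <- NULL
    new("EmpiricalCompound", empcpdId = empcpdId,
        neutralMass = as.numeric(neutralMass), mode = mode,
        members = members, ms2Spectra = ms2Spectra,
        annotations = annotations)
}

#' @rdname metaboPost-accessors
#' @export
setMethod("empcpdId", "EmpiricalCompound", function(object) object@empcpdId)
#' @rdname metaboPost-accessors
#' @export
setMethod("neutralMass", "EmpiricalCompound", function(object)
    object@neutralMass)
#' @rdname metaboPost-accessors
#' @export
setMethod("members", "EmpiricalCompound", function(object) object@members)
#' @rdname metaboPost-accessors
#' @export
setMethod("annotations", "EmpiricalCompound", function(object)
    object@annotations)
#' @rdname metaboPost-accessors
#' @export
setMethod("ms2Spectra", "EmpiricalCompound", function(object)
    object@ms2Spectra)

setMethod("show", "EmpiricalCompound", function(object) {
    cat(sprintf("EmpiricalCompound %s (%s): %d member(s), M = %s\n",
                object@empcpdId, object@mode, nrow(object@members),
                if (is.na(object@neutralMass)) "unknown"
                else sprintf("%.6f", object@neutralMass)))
    if (nrow(object@members))
        cat(sprintf("  %s\n", paste(sprintf("%s[%s,%s]",
            object@members$feature_id,
            ifelse(is.na(object@members$isotope), "?",
                   object@members$isotope),
            ifelse(is.na(object@members$adduct), "?",
                   object@members$adduct)), collapse = " ")))
    cat(sprintf("  MS2 spectra: %d  annotations: %d\n",
                length(object@ms2Spectra), length(object@annotations)))
})

#' Create one annotation record
#'
#' A candidate identity at a given confidence level. Levels follow the
#' Schymanski-style scheme used throughout: `1a` (MS2 match to authentic
#' standard), `1b` (m/z + retention-time match to authentic standard),
#' `2` (MS2 match to a public library), `4` (neutral-mass match only).
#' Records are appended to an empirical compound's annotation list and
#' never overwrite earlier ones, so annotation tools can be chained.
#'
#' @param level one of `"1a"`, `"1b"`, `"2"`, `"4"`.
#' @param candidateName compound name of the candidate.
#' @param source database / library / standards-set name.
#' @param candidateId optional database identifier.
#' @param score similarity score; required for MS2-based levels (1a, 2).
#' @param evidence named list of supporting detail (ppm error, RT error,
#'   matched peak count, ...).
#' @return a named list with class-checked fields.
#' @export
annotationRecord <- function(level, candidateName, source,
                             candidateId = NA_character_, score = NA_real_,
                             evidence = list()) {
    level <- as.character(level)
    if (!level %in% .ANNOTATION_LEVELS)
        stop("level must be one of: ", paste(.ANNOTATION_LEVELS,
                                             collapse = ", "))
    if (level %in% c("1a", "2") && is.na(score))
        stop("MS2-based levels (1a, 2) require a score")
    list(level = level, candidate_name = candidateName,
         candidate_id = candidateId, score = as.numeric(score),
         source = source, evidence = evidence)
}

#' Append an annotation to an empirical compound
#' @param empcpd an [EmpiricalCompound-class].
#' @param record an [annotationRecord()].
#' @return the compound with the record appended.
#' @export
addAnnotation <- function(empcpd, record) {
    empcpd@annotations <- c(empcpd@annotations, list(record))
    validObject(empcpd)
    empcpd
}

#' Rank annotation records by confidence then score
#'
#' Level precedence is 1a > 1b > 2 > 4; ties are broken by descending
#' score. All records are kept — ranking orders, it never suppresses.
#'
#' @param records list of annotation records.
#' @return the records, reordered.
#' @export
rankAnnotations <- function(records) {
    if (!length(records)) return(records)
    prec <- c("1a" = 1, "1b" = 2, "2" = 3, "4" = 4)
    lev <- prec[vapply(records, function(r) r$level, character(1))]
    sc <- vapply(records, function(r)
        if (is.null(r$score) || is.na(r$score)) -Inf else r$score, numeric(1))
    records[order(lev, -sc)]
}

.spectrumToList <- function(s) {
    list(precursor_mz = s@precursorMz,
         precursor_rtime = s@precursorRtime,
         source = s@source,
         provenance = s@provenance,
         compound = s@compound,
         peaks = lapply(seq_len(nrow(s@peaks)), function(i)
             list(s@peaks[i, 1L], s@peaks[i, 2L])))
}

.spectrumFromList <- function(x) {
    pk <- if (length(x$peaks))
        do.call(rbind, lapply(x$peaks, function(p)
            c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    else matrix(numeric(), 0, 2)
    colnames(pk) <- c("mz", "intensity")
    MS2Spectrum(precursorMz = as.numeric(x$precursor_mz),
                precursorRtime = if (is.null(x$precursor_rtime))
                    NA_real_ else as.numeric(x$precursor_rtime),
                peaks = pk, source = as.character(x$source),
                provenance = as.character(x$provenance),
                compound = if (is.null(x$compound)) NA_character_
                           else as.character(x$compound))
}

.annotationToList <- function(a) {
    a$score <- if (is.null(a$score)) NA_real_ else as.numeric(a$score)
    a
}

.empcpdToList <- function(e) {
    m <- e@members
    list(empcpd_id = e@empcpdId,
         neutral_mass = e@neutralMass,
         mode = e@mode,
         members = lapply(seq_len(nrow(m)), function(i)
             list(feature_id = m$feature_id[i], mz = m$mz[i],
                  rtime = m$rtime[i], isotope = m$isotope[i],
                  adduct = m$adduct[i], charge = m$charge[i],
                  mass_offset = m$mass_offset[i])),
         mass_discordant = attr(e@members, "massDiscordant"),
         ms2_spectra = lapply(e@ms2Spectra, .spectrumToList),
         annotations = lapply(e@annotations, .annotationToList))
}

.empcpdFromList <- function(x) {
    mem <- do.call(rbind, lapply(x$members, function(m) data.frame(
        feature_id = as.character(m$feature_id),
        mz = as.numeric(m$mz), rtime = as.numeric(m$rtime),
        isotope = if (is.null(m$isotope)) NA_character_
                  else as.character(m$isotope),
        adduct = if (is.null(m$adduct)) NA_character_
                 else as.character(m$adduct),
        charge = if (is.null(m$charge)) NA_integer_
                 else as.integer(m$charge),
        mass_offset = if (is.null(m$mass_offset)) NA_real_
                      else as.numeric(m$mass_offset),
        stringsAsFactors = FALSE)))
    ann <- lapply(x$annotations, function(a) {
        a$score <- if (is.null(a$score)) NA_real_ else as.numeric(a$score)
        a$candidate_id <- if (is.null(a$candidate_id)) NA_character_
                          else as.character(a$candidate_id)
        if (is.null(a$evidence)) a$evidence <- list()
        a[c("level", "candidate_name", "candidate_id", "score", "source",
            "evidence")]
    })
    out <- EmpiricalCompound(empcpdId = as.character(x$empcpd_id),
                             members = mem, mode = as.character(x$mode),
                             neutralMass = if (is.null(x$neutral_mass))
                                 NA_real_ else as.numeric(x$neutral_mass),
                             ms2Spectra = lapply(x$ms2_spectra,
                                                 .spectrumFromList),
                             annotations = ann)
    if (!is.null(x$mass_discordant))
        attr(out@members, "massDiscordant") <- as.logical(x$mass_discordant)
    out
}

#' Serialize empirical compounds to chainable JSON
#'
#' The document is a map keyed by `empcpd_id`; each entry lists the MS1
#' members with their ion relations, attached MS2 spectra, and the full
#' annotation list with level and source. Deserialization inverts the
#' serialization exactly (numbers are written with round-trip-safe
#' precision). The schema identifier is embedded under `_schema`; the
#' schema itself ships in `inst/extdata/empcpd-schema-1.0.json`.
#'
#' @param empcpds list of [EmpiricalCompound-class].
#' @param path optional output file; when `NULL` the JSON text is
#'   returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
empcpdsToJSON <- function(empcpds, path = NULL) {
    ids <- vapply(empcpds, function(e) e@empcpdId, character(1))
    if (anyDuplicated(ids))
        stop(sprintf("duplicate empcpd_id: %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    doc <- stats::setNames(lapply(empcpds, .empcpdToList), ids)
    doc <- c(list(`_schema` = .EMPCPD_SCHEMA), doc)
    txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                            na = "null", null = "null", pretty = FALSE)
    if (is.null(path)) return(as.character(txt))
    writeLines(as.character(txt), path)
    invisible(path)
}

#' @rdname empcpdsToJSON
#' @param json a file path or JSON string produced by [empcpdsToJSON()].
#' @export
empcpdsFromJSON <- function(json) {
    doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
    doc[["_schema"]] <- NULL
    unname(lapply(doc, .empcpdFromList))
}

#' Emit the three-table output
#'
#' Writes the standardized final output: (1) a feature table (id, m/z,
#' retention time, per-sample intensities); (2) an annotation table with
#' one row per (feature, annotation) pair — a feature carrying several
#' annotations yields several rows; (3) a metadata table with
#' acquisition- and experiment-level information (sample type, batch).
#' Every feature id referenced by the annotation table is guaranteed to
#' occur in the feature table; a member feature id missing from `table`
#' is a hard error.
#'
#' @param experiment a [MetaboExperiment-class].
#' @param table the final [FeatureTable-class].
#' @param empcpds list of [EmpiricalCompound-class] built on `table`.
#' @param outDir output directory (created if needed).
#' @return named character vector of the three file paths.
#' @export
emitThreeTables <- function(experiment, table, empcpds, outDir) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    allMembers <- unlist(lapply(empcpds, function(e) e@members$feature_id))
    dangling <- setdiff(allMembers, featureIds(table))
    if (length(dangling))
        stop(sprintf("empirical-compound member feature(s) absent from table: %s",
                     paste(dangling, collapse = ", ")))
    ftPath <- file.path(outDir, "feature_table.tsv")
    writeFeatureTable(table, ftPath)

    rows <- mapAnnotationsToFeatures(empcpds, table)
    annPath <- file.path(outDir, "annotation_table.tsv")
    utils::write.table(rows, annPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    acq <- experiment@acquisitions
    meta <- acq[acq$name %in% colnames(table), , drop = FALSE]
    if (!nrow(meta)) meta <- acq
    meta$experiment_directory <- experiment@directory
    meta$n_features <- nrow(table)
    meta$n_empirical_compounds <- length(empcpds)
    metaPath <- file.path(outDir, "sample_metadata.tsv")
    utils::write.table(meta, metaPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    c(feature_table = ftPath, annotation_table = annPath,
      sample_metadata = metaPath)
}
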