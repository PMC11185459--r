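#' Assemble an experiment from a sample metadata CSV
#'
#' The metadata minimally maps acquisition names to file paths; optional
#' `sample_type` and `batch` columns are carried through, any further
#' columns are kept as extra tags. `sample_type` defaults to `"unknown"`.
#'
#' @param csvPath metadata CSV with at least columns `name` and `path`
#'   (aliases `sample`/`sample_name` and `filepath`/`file_path`/
#'   `source_path` are accepted).
#' @param directory directory for on-disk intermediates; defaults to the
#'   directory containing the CSV.
#' @return a [MetaboExperiment-class] with empty registries and an
#'   initialized command log.
#' @export
loadMetadata <- function(csvPath, directory = dirname(csvPath)) {
    d <- utils::read.csv(csvPath, check.names = FALSE,
                         stringsAsFactors = FALSE)
    nameCol <- intersect(c("name", "sample", "sample_name"), colnames(d))[1]
    pathCol <- intersect(c("path", "filepath", "file_path", "source_path"),
                         colnames(d))[1]
    if (is.na(nameCol) || is.na(pathCol))
        stop("metadata must contain sample-name and file-path columns ",
             "(expected headers: 'name' and 'path')")
    if (anyDuplicated(d[[nameCol]]))
        stop(sprintf("duplicate sample names: %s",
            paste(unique(d[[nameCol]][duplicated(d[[nameCol]])]),
                  collapse = ", ")))
    st <- if ("sample_type" %in% colnames(d)) d$sample_type
          else rep("unknown", nrow(d))
    st[is.na(st) | !nzchar(st)] <- "unknown"
    if (!all(st %in% .SAMPLE_TYPES))
        stop(sprintf("sample_type must be one of: %s",
                     paste(.SAMPLE_TYPES, collapse = ", ")))
    batch <- if ("batch" %in% colnames(d)) as.character(d$batch)
             else rep(NA_character_, nrow(d))
    acq <- data.frame(name = as.character(d[[nameCol]]),
                      source_path = as.character(d[[pathCol]]),
                      sample_type = st, batch = batch,
                      stringsAsFactors = FALSE)
    extra <- setdiff(colnames(d), c(nameCol, pathCol, "sample_type", "batch"))
    for (cn in extra) acq[[cn]] <- as.character(d[[cn]])
    expt <- new("MetaboExperiment", directory = directory, acquisitions = acq,
                tableRegistry = stats::setNames(character(), character()),
                empcpdRegistry = stats::setNames(character(), character()),
                commandLog = data.frame(timestamp = character(),
                                        command = character(),
                                        params = character(),
                                        stringsAsFactors = FALSE))
    logStep(expt, "assemble", list(metadata = csvPath))
}

#' @rdname metaboPost-accessors
#' @export
setMethod("acquisitions", "MetaboExperiment", function(object)
    object@acquisitions)

#' @rdname metaboPost-accessors
#' @export
setMethod("commandLog", "MetaboExperiment", function(object)
    object@commandLog)

#' @rdname metaboPost-accessors
#' @export
setMethod("tableRegistry", "MetaboExperiment", function(object)
    object@tableRegistry)

#' @rdname metaboPost-accessors
#' @export
setMethod("empcpdRegistry", "MetaboExperiment", function(object)
    object@empcpdRegistry)

setMethod("show", "MetaboExperiment", function(object) {
    cat(sprintf("MetaboExperiment: %d acquisitions (%s)\n",
                nrow(object@acquisitions),
                paste(sprintf("%d %s", table(object@acquisitions$sample_type),
                              names(table(object@acquisitions$sample_type))),
                      collapse = ", ")))
    cat(sprintf("  directory: %s\n", object@directory))
    cat(sprintf("  feature tables: %s\n",
                if (length(object@tableRegistry))
                    paste(names(object@tableRegistry), collapse = ", ")
                else "<none>"))
    cat(sprintf("  empcpd sets: %s\n",
                if (length(object@empcpdRegistry))
                    paste(names(object@empcpdRegistry), collapse = ", ")
                else "<none>"))
    cat(sprintf("  commands logged: %d\n", nrow(object@commandLog)))
})

#' Append a command to the experiment log
#'
#' The log is append-only: each call adds exactly one timestamped entry
#' and never modifies earlier entries, giving a full timeline of the
#' analysis for the report.
#'
#' @param experiment a [MetaboExperiment-class].
#' @param command command text.
#' @param params named list of parameters (stored as JSON).
#' @return the experiment with one more log entry.
#' @export
logStep <- function(experiment, command, params = list()) {
    entry <- data.frame(
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS6%z"),
        command = command,
        params = as.character(jsonlite::toJSON(params, auto_unbox = TRUE,
                                               digits = I(17))),
        stringsAsFactors = FALSE)
    experiment@commandLog <- rbind(experiment@commandLog, entry)
    validObject(experiment)
    experiment
}

.registryPath <- function(expt, kind, moniker) {
    sub <- file.path(expt@directory,
                     if (kind == "table") "feature_tables" else "empcpds")
    if (!dir.exists(sub)) dir.create(sub, recursive = TRUE)
    file.path(sub, paste0(moniker, if (kind == "table") ".tsv" else ".json"))
}

#' Register a feature table under a moniker
#'
#' Writes the table to disk under the experiment directory and records
#' its location, so chained commands can retrieve it by name.
#'
#' @param experiment a [MetaboExperiment-class].
#' @param moniker registry name for the table.
#' @param table a [FeatureTable-class].
#' @return the updated experiment.
#' @export
registerFeatureTable <- function(experiment, moniker, table) {
    path <- .registryPath(experiment, "table", moniker)
    writeFeatureTable(table, path)
    experiment@tableRegistry[moniker] <- path
    validObject(experiment)
    experiment
}

#' Retrieve a registered feature table
#' @param experiment a [MetaboExperiment-class].
#' @param moniker registry name.
#' @return a [FeatureTable-class].
#' @export
retrieveFeatureTable <- function(experiment, moniker) {
    if (!moniker %in% names(experiment@tableRegistry))
        stop(sprintf("no feature table registered as '%s' (have: %s)",
                     moniker, paste(names(experiment@tableRegistry),
                                    collapse = ", ")))
    path <- experiment@tableRegistry[[moniker]]
    if (!file.exists(path))
        stop(sprintf("registered table file is missing: %s", path))
    readFeatureTable(path)
}

#' Register an empirical-compound set under a moniker
#' @inheritParams registerFeatureTable
#' @param empcpds list of [EmpiricalCompound-class].
#' @return the updated experiment.
#' @export
registerEmpCpds <- function(experiment, moniker, empcpds) {
    path <- .registryPath(experiment, "empcpd", moniker)
    empcpdsToJSON(empcpds, path)
    experiment@empcpdRegistry[moniker] <- path
    validObject(experiment)
    experiment
}

#' Retrieve a registered empirical-compound set
#' @inheritParams retrieveFeatureTable
#' @return list of [EmpiricalCompound-class].
#' @export
retrieveEmpCpds <- function(experiment, moniker) {
    if (!moniker %in% names(experiment@empcpdRegistry))
        stop(sprintf("no empcpd set registered as '%s' (have: %s)", moniker,
                     paste(names(experiment@empcpdRegistry), collapse = ", ")))
    path <- experiment@empcpdRegistry[[moniker]]
    if (!file.exists(path))
        stop(sprintf("registered empcpd file is missing: %s", path))
    empcpdsFromJSON(path)
}

#' Persist / restore an experiment as JSON
#'
#' @param experiment a [MetaboExperiment-class].
#' @param path JSON path; defaults to `experiment.json` in the
#'   experiment directory.
#' @return `saveExperiment` returns the path invisibly;
#'   `loadExperiment` returns the restored [MetaboExperiment-class].
#' @export
saveExperiment <- function(experiment,
                           path = file.path(experiment@directory,
                                            "experiment.json")) {
    doc <- list(directory = experiment@directory,
                acquisitions = experiment@acquisitions,
                table_registry = as.list(experiment@tableRegistry),
                empcpd_registry = as.list(experiment@empcpdRegistry),
                command_log = experiment@commandLog)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                         na = "null", null = "null")
    invisible(path)
}

#' @rdname saveExperiment
#' @export
loadExperiment <- function(path) {
    doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    acq <- as.data.frame(doc$acquisitions, stringsAsFactors = FALSE)
    if (is.null(acq$batch)) acq$batch <- rep(NA_character_, nrow(acq))
    for (cn in colnames(acq)) acq[[cn]] <- as.character(acq[[cn]])
    cl <- as.data.frame(doc$command_log, stringsAsFactors = FALSE)
    if (!nrow(cl)) cl <- data.frame(timestamp = character(),
                                    command = character(),
                                    params = character(),
                                    stringsAsFactors = FALSE)
    asReg <- function(x) {
        r <- unlist(x)
        if (is.null(r)) stats::setNames(character(), character()) else r
    }
    new("MetaboExperiment", directory = doc$directory, acquisitions = acq,
        tableRegistry = asReg(doc$table_registry),
        empcpdRegistry = asReg(doc$empcpd_registry),
        commandLog = cl)
}
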