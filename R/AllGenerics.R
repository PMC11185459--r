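#' @name metaboPost-accessors
#' @title Accessors for metaboPost classes
#' @description Slot accessors for the core S4 classes. Use these rather
#'   than `@` access.
#' @param object a metaboPost S4 object.
#' @param value replacement value.
#' @return the corresponding slot content.
NULL

#' @rdname metaboPost-accessors
#' @export
setGeneric("featureMz", function(object) standardGeneric("featureMz"))
#' @rdname metaboPost-accessors
#' @export
setGeneric("featureRtime", function(object) standardGeneric("featureRtime"))
#' @rdname metaboPost-accessors
#' @export
setGeneric("intensityMatrix", function(object)
    standardGeneric("intensityMatrix"))
#' @rdname metaboPost-accessors
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))
#' @rdname metaboPost-accessors
#' @export
setGeneric("acquisitions", function(object) standardGeneric("acquisitions"))
#' @rdname metaboPost-accessors
#' @export
setGeneric("commandLog", function(object) standardGeneric("commandLog"))
#' @rdname metaboPost-accessors
#' @export
setGeneric("tableRegistry", function(object) standardGeneric("tableRegistry"))
#' @rdname metaboPost-accessors
#' @export
setGeneric("empcpdRegistry", function(object)
    standardGeneric("empcpdRegistry"))
#' @rdname metaboPost-accessors
#' @export
setGeneric("empcpdId", function(object) standardGeneric("empcpdId"))
#' @rdname metaboPost-accessors
#' @export
setGeneric("neutralMass", function(object) standardGeneric("neutralMass"))
#' @rdname metaboPost-accessors
#' @export
setGeneric("members", function(object) standardGeneric("members"))
#' @rdname metaboPost-accessors
#' @export
setGeneric("annotations", function(object) standardGeneric("annotations"))
#' @rdname metaboPost-accessors
#' @export
setGeneric("ms2Spectra", function(object) standardGeneric("ms2Spectra"))
#' @rdname metaboPost-accessors
#' @export
setGeneric("peaks", function(object) standardGeneric("peaks"))
#' @rdname metaboPost-accessors
#' @export
setGeneric("precursorMz", function(object) standardGeneric("precursorMz"))
#' @rdname metaboPost-accessors
#' @export
setGeneric("precursorRtime", function(object)
    standardGeneric("precursorRtime"))
#' @rdname metaboPost-accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
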