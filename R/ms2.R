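#' Construct an MS2Spectrum
#'
#' @param precursorMz precursor m/z in Daltons.
#' @param peaks two-column numeric matrix or data.frame (`mz`,
#'   `intensity`); rows are sorted by m/z on construction.
#' @param precursorRtime precursor retention time in seconds (`NA` for
#'   library spectra without retention information).
#' @param source free-text origin (file + scan index, library name).
#' @param provenance `"experimental"`, `"reference_public"` or
#'   `"reference_authentic"`.
#' @param compound compound name (reference spectra only).
#' @return an [MS2Spectrum-class].
#' @export
MS2Spectrum <- function(precursorMz, peaks, precursorRtime = NA_real_,
                        source = "", provenance = "experimental",
                        compound = NA_character_) {
    peaks <- as.matrix(peaks)
    if (ncol(peaks) != 2L) stop("peaks must have two columns (mz, intensity)")
    storage.mode(peaks) <- "double"
    peaks <- peaks[order(peaks[, 1L]), , drop = FALSE]
    colnames(peaks) <- c("mz", "intensity")
    new("MS2Spectrum", precursorMz = as.numeric(precursorMz),
        precursorRtime = as.numeric(precursorRtime), peaks = peaks,
        source = source, provenance = provenance, compound = compound)
}

#' @rdname metaboPost-accessors
#' @export
setMethod("peaks", "MS2Spectrum", function(object) object@peaks)
#' @rdname metaboPost-accessors
#' @export
setMethod("precursorMz", "MS2Spectrum", function(object) object@precursorMz)
#' @rdname metaboPost-accessors
#' @export
setMethod("precursorRtime", "MS2Spectrum", function(object)
    object@precursorRtime)
#' @rdname metaboPost-accessors
#' @export
setMethod("provenance", "MS2Spectrum", function(object) object@provenance)

setMethod("show", "MS2Spectrum", function(object) {
    cat(sprintf("MS2Spectrum: precursor %.4f @ %s s, %d peaks [%s]%s\n",
                object@precursorMz,
                if (is.na(object@precursorRtime)) "?"
                else sprintf("%.1f", object@precursorRtime),
                nrow(object@peaks), object@provenance,
                if (is.na(object@compound)) ""
                else sprintf(" <%s>", object@compound)))
})

#' Extract MS2 spectra from a centroided mzML file
#'
#' Reads every MS2 scan of a centroided mzML file into
#' [MS2Spectrum-class] objects (precursor m/z, scan retention time in
#' seconds, fragment peaks sorted by m/z). Spectra with fewer than
#' `minPeaks` fragment peaks are dropped. Profile-mode MS2 scans are
#' refused: centroid the data during conversion (e.g. with msconvert or
#' ThermoRawFileParser) first.
#'
#' @param mzmlPath path to a centroided mzML file.
#' @param minPeaks minimum fragment-peak count to keep a spectrum.
#' @return list of [MS2Spectrum-class] (empty for MS1-only files).
#' @export
extractMS2 <- function(mzmlPath, minPeaks = 2L) {
    if (!requireNamespace("mzR", quietly = TRUE))
        stop("package 'mzR' is required to read mzML files")
    if (!file.exists(mzmlPath)) stop("file not found: ", mzmlPath)
    handle <- mzR::openMSfile(mzmlPath)
    on.exit(mzR::close(handle), add = TRUE)
    hdr <- mzR::header(handle)
    ms2 <- which(hdr$msLevel == 2L)
    if (!length(ms2)) return(list())
    if (any(hdr$centroided[ms2] %in% FALSE))
        stop("profile-mode MS2 scans found; please centroid the mzML ",
             "(peak picking during raw-file conversion) before extraction")
    out <- lapply(ms2, function(i) {
        p <- mzR::peaks(handle, i)
        p <- p[p[, 2L] > 0, , drop = FALSE]
        if (nrow(p) < minPeaks) return(NULL)
        MS2Spectrum(precursorMz = hdr$precursorMZ[i],
                    precursorRtime = hdr$retentionTime[i],
                    peaks = p,
                    source = sprintf("%s#%d", basename(mzmlPath),
                                     hdr$acquisitionNum[i]),
                    provenance = "experimental")
    })
    out[!vapply(out, is.null, logical(1))]
}

.mspField <- function(block, keys) {
    for (k in keys) {
        hit <- grep(sprintf("^%s\\s*:", k), block, ignore.case = TRUE,
                    value = TRUE)
        if (length(hit))
            return(trimws(sub("^[^:]*:", "", hit[1L])))
    }
    NA_character_
}

#' Read an MSP spectral library
#'
#' Minimal reader for NIST-style MSP: `NAME:`, `PRECURSORMZ:` (or
#' `PRECURSOR_MZ:`/`PEPMASS:`), optional `RETENTIONTIME:` (seconds) and
#' `PROVENANCE:` fields, `Num Peaks:` followed by whitespace-separated
#' `mz intensity` lines.
#'
#' @param path MSP file.
#' @param provenance default provenance for spectra without an explicit
#'   `PROVENANCE:` field; reference libraries must be tagged
#'   `reference_public` or `reference_authentic`.
#' @return list of [MS2Spectrum-class].
#' @export
readMSP <- function(path, provenance = "reference_public") {
    lines <- readLines(path)
    starts <- grep("^NAME\\s*:", lines, ignore.case = TRUE)
    if (!length(starts)) return(list())
    ends <- c(starts[-1L] - 1L, length(lines))
    lapply(seq_along(starts), function(b) {
        block <- lines[starts[b]:ends[b]]
        pk <- grep("^[[:space:]]*[0-9][0-9.eE+-]*[[:space:];]+[0-9]",
                   block, value = TRUE)
        pk <- pk[!grepl(":", pk)]
        mat <- if (length(pk)) {
            do.call(rbind, lapply(strsplit(trimws(pk), "[[:space:];]+"),
                                  function(x) as.numeric(x[1:2])))
        } else matrix(numeric(), 0, 2)
        prov <- .mspField(block, "PROVENANCE")
        if (is.na(prov)) prov <- provenance
        rt <- suppressWarnings(as.numeric(.mspField(block, "RETENTIONTIME")))
        MS2Spectrum(
            precursorMz = as.numeric(.mspField(
                block, c("PRECURSORMZ", "PRECURSOR_MZ", "PEPMASS"))),
            precursorRtime = if (length(rt)) rt else NA_real_,
            peaks = mat, source = basename(path), provenance = prov,
            compound = .mspField(block, "NAME"))
    })
}

#' Write spectra as MSP
#' @param spectra list of [MS2Spectrum-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMSP <- function(spectra, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (s in spectra) {
        writeLines(c(
            sprintf("NAME: %s", if (is.na(s@compound)) s@source
                                else s@compound),
            sprintf("PRECURSORMZ: %.17g", s@precursorMz),
            if (!is.na(s@precursorRtime))
                sprintf("RETENTIONTIME: %.17g", s@precursorRtime),
            sprintf("PROVENANCE: %s", s@provenance),
            sprintf("Num Peaks: %d", nrow(s@peaks)),
            sprintf("%.17g %.17g", s@peaks[, 1L], s@peaks[, 2L]),
            ""), con)
    }
    invisible(path)
}

#' Read an MGF spectral library
#'
#' Minimal MGF reader: `BEGIN IONS`/`END IONS` blocks with `TITLE=`,
#' `PEPMASS=`, optional `RTINSECONDS=` and `PROVENANCE=` headers and
#' `mz intensity` peak lines.
#'
#' @inheritParams readMSP
#' @return list of [MS2Spectrum-class].
#' @export
readMGF <- function(path, provenance = "reference_public") {
    lines <- readLines(path)
    starts <- grep("^BEGIN IONS", lines)
    ends <- grep("^END IONS", lines)
    if (length(starts) != length(ends))
        stop("malformed MGF: unbalanced BEGIN IONS/END IONS")
    lapply(seq_along(starts), function(b) {
        block <- lines[(starts[b] + 1L):(ends[b] - 1L)]
        kv <- grep("=", block, value = TRUE)
        getv <- function(key) {
            hit <- grep(sprintf("^%s=", key), kv, ignore.case = TRUE,
                        value = TRUE)
            if (length(hit)) trimws(sub("^[^=]*=", "", hit[1L]))
            else NA_character_
        }
        pk <- block[!grepl("=", block) & nzchar(trimws(block))]
        mat <- if (length(pk))
            do.call(rbind, lapply(strsplit(trimws(pk), "\\s+"),
                                  function(x) as.numeric(x[1:2])))
        else matrix(numeric(), 0, 2)
        prov <- getv("PROVENANCE")
        if (is.na(prov)) prov <- provenance
        rt <- suppressWarnings(as.numeric(getv("RTINSECONDS")))
        MS2Spectrum(
            precursorMz = as.numeric(strsplit(getv("PEPMASS"),
                                              "\\s+")[[1L]][1L]),
            precursorRtime = if (length(rt)) rt else NA_real_,
            peaks = mat, source = basename(path), provenance = prov,
            compound = getv("TITLE"))
    })
}
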