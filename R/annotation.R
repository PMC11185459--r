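#' @importFrom IRanges IRanges findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Build a precursor interval index over empirical-compound members
#'
#' One ppm window per member feature: `[mz*(1 - tol), mz*(1 + tol)]`
#' with `tol = mzTolPpm / 1e6`. Windows are held exactly and also as an
#' integer interval forest at micro-Dalton resolution used as an overlap
#' prefilter; stabbing queries filter the prefiltered candidates against
#' the exact bounds, so results are identical to a linear scan over all
#' (empcpd, member) pairs.
#'
#' @param empcpds list of [EmpiricalCompound-class].
#' @param mzTolPpm window half-width in ppm.
#' @return a [PrecursorIndex-class].
#' @export
buildPrecursorIndex <- function(empcpds, mzTolPpm = 5) {
    entries <- do.call(rbind, lapply(empcpds, function(e)
        data.frame(empcpd_id = e@empcpdId,
                   feature_id = e@members$feature_id,
                   mz = e@members$mz, rtime = e@members$rtime,
                   stringsAsFactors = FALSE)))
    if (is.null(entries))
        entries <- data.frame(empcpd_id = character(),
                              feature_id = character(), mz = numeric(),
                              rtime = numeric(), stringsAsFactors = FALSE)
    tol <- mzTolPpm * 1e-6
    entries$lo <- entries$mz * (1 - tol)
    entries$hi <- entries$mz * (1 + tol)
    ranges <- IRanges::IRanges(start = as.integer(floor(entries$lo * 1e5)),
                               end = as.integer(ceiling(entries$hi * 1e5)))
    new("PrecursorIndex", entries = entries, ranges = ranges,
        tolPpm = mzTolPpm)
}

#' Stabbing query against a precursor index
#'
#' @param index a [PrecursorIndex-class].
#' @param mzQuery numeric vector of query m/z values.
#' @return data.frame of hits: `query` (index into `mzQuery`),
#'   `empcpd_id`, `feature_id`, `mz`, `rtime`.
#' @export
queryPrecursorIndex <- function(index, mzQuery) {
    e <- index@entries
    empty <- data.frame(query = integer(), empcpd_id = character(),
                        feature_id = character(), mz = numeric(),
                        rtime = numeric(), stringsAsFactors = FALSE)
    if (!nrow(e) || !length(mzQuery)) return(empty)
    q <- IRanges::IRanges(start = as.integer(floor(mzQuery * 1e5)),
                          width = 1L)
    ov <- IRanges::findOverlaps(q, index@ranges)
    if (!length(ov)) return(empty)
    qi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    exact <- e$lo[si] <= mzQuery[qi] & mzQuery[qi] <= e$hi[si]
    qi <- qi[exact]; si <- si[exact]
    data.frame(query = qi, empcpd_id = e$empcpd_id[si],
               feature_id = e$feature_id[si], mz = e$mz[si],
               rtime = e$rtime[si], stringsAsFactors = FALSE)
}

#' Read a compound database (TSV or JSON)
#'
#' Minimal schema: `name`, `neutral_mass` (monoisotopic Daltons, > 0),
#' optional `formula` and `id`.
#'
#' @param path `.tsv`/`.txt` or `.json` file.
#' @return data.frame with columns `name`, `formula`, `neutral_mass`,
#'   `id`.
#' @export
readCompoundTable <- function(path) {
    d <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    else utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("name", "neutral_mass") %in% colnames(d)))
        stop("compound database needs columns 'name' and 'neutral_mass'")
    d$neutral_mass <- as.numeric(d$neutral_mass)
    if (any(is.na(d$neutral_mass) | d$neutral_mass <= 0))
        stop("neutral_mass must be positive for every compound")
    if (is.null(d$formula)) d$formula <- NA_character_
    if (is.null(d$id)) d$id <- NA_character_
    d[, c("name", "formula", "neutral_mass", "id")]
}

#' Read an authentic-standards table (CSV)
#'
#' Columns: `name`, `mz`, `rtime` (seconds), optional `mode`.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
readStandards <- function(path) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("name", "mz", "rtime") %in% colnames(d)))
        stop("standards table needs columns 'name', 'mz', 'rtime'")
    if (is.null(d$mode)) d$mode <- NA_character_
    d
}

#' Level-4 annotation by neutral mass
#'
#' For every empirical compound with an inferred neutral mass, every
#' database compound whose monoisotopic mass lies within `mzTolPpm`
#' (relative to the database mass) is appended as a level-4 annotation
#' with the signed ppm error in the evidence. Multiple hits yield
#' multiple records; compounds without a neutral mass are untouched.
#' Exactly one database query is made per empirical compound (not per
#' feature): the returned list carries the query count in attribute
#' `nQueries`.
#'
#' @param empcpds list of [EmpiricalCompound-class].
#' @param compoundDb data.frame from [readCompoundTable()].
#' @param mzTolPpm mass tolerance in ppm.
#' @param source label recorded on the annotation records.
#' @return the annotated list.
#' @export
annotateLevel4 <- function(empcpds, compoundDb, mzTolPpm = 5,
                           source = "compound_db") {
    if (!nrow(compoundDb)) {
        warning("empty compound database; no level-4 annotation performed")
        return(empcpds)
    }
    nQueries <- 0L
    out <- lapply(empcpds, function(e) {
        if (is.na(e@neutralMass)) return(e)
        nQueries <<- nQueries + 1L
        err <- ppmError(e@neutralMass, compoundDb$neutral_mass)
        hits <- which(abs(err) <= mzTolPpm)
        for (h in hits)
            e <- addAnnotation(e, annotationRecord(
                level = "4", candidateName = compoundDb$name[h],
                candidateId = compoundDb$id[h], source = source,
                evidence = list(ppm_error = err[h])))
        e
    })
    attr(out, "nQueries") <- nQueries
    out
}

#' Level-1b annotation against authentic standards
#'
#' A member feature matches a standard when both gates pass: ppm error
#' within `mzTolPpm` and absolute retention-time difference within
#' `rtTolS`. Matches are recorded as level-1b annotations on the owning
#' empirical compound with both errors in the evidence.
#'
#' @param empcpds list of [EmpiricalCompound-class].
#' @param standards data.frame from [readStandards()].
#' @param mzTolPpm m/z tolerance in ppm.
#' @param rtTolS retention-time tolerance in seconds.
#' @param source label recorded on the annotation records.
#' @return the annotated list.
#' @export
annotateLevel1b <- function(empcpds, standards, mzTolPpm = 5, rtTolS = 5,
                            source = "authentic_standards") {
    lapply(empcpds, function(e) {
        for (i in seq_len(nrow(e@members))) {
            err <- ppmError(e@members$mz[i], standards$mz)
            dRt <- abs(e@members$rtime[i] - standards$rtime)
            hits <- which(abs(err) <= mzTolPpm & dRt <= rtTolS)
            for (h in hits)
                e <- addAnnotation(e, annotationRecord(
                    level = "1b", candidateName = standards$name[h],
                    source = source,
                    evidence = list(
                        feature_id = e@members$feature_id[i],
                        ppm_error = err[h], rt_error =
                            e@members$rtime[i] - standards$rtime[h])))
        }
        e
    })
}

#' Map experimental MS2 spectra to empirical compounds
#'
#' A spectrum attaches to every empirical compound owning a member whose
#' precursor ppm window contains the spectrum's precursor m/z and whose
#' retention time is within `rtTolS` of the spectrum's precursor
#' retention time. Spectra matching nothing are returned in the
#' `unassigned` pool.
#'
#' @param spectra list of experimental [MS2Spectrum-class].
#' @param empcpds list of [EmpiricalCompound-class].
#' @param mzTolPpm precursor m/z tolerance in ppm.
#' @param rtTolS retention-time tolerance in seconds.
#' @return list with elements `empcpds` (spectra attached) and
#'   `unassigned`.
#' @export
mapMS2ToEmpCpds <- function(spectra, empcpds, mzTolPpm = 5, rtTolS = 30) {
    if (!length(spectra)) return(list(empcpds = empcpds,
                                      unassigned = list()))
    index <- buildPrecursorIndex(empcpds, mzTolPpm)
    prec <- vapply(spectra, function(s) s@precursorMz, numeric(1))
    hits <- queryPrecursorIndex(index, prec)
    byId <- stats::setNames(seq_along(empcpds),
                            vapply(empcpds, function(e) e@empcpdId,
                                   character(1)))
    assigned <- rep(FALSE, length(spectra))
    if (nrow(hits)) {
        rts <- vapply(spectra, function(s) s@precursorRtime, numeric(1))
        ok <- !is.na(rts[hits$query]) &
            abs(rts[hits$query] - hits$rtime) <= rtTolS
        hits <- hits[ok, , drop = FALSE]
        # attach each spectrum at most once per empcpd
        hits <- hits[!duplicated(hits[, c("query", "empcpd_id")]), ,
                     drop = FALSE]
        for (r in seq_len(nrow(hits))) {
            i <- byId[[hits$empcpd_id[r]]]
            empcpds[[i]]@ms2Spectra <-
                c(empcpds[[i]]@ms2Spectra, list(spectra[[hits$query[r]]]))
            assigned[hits$query[r]] <- TRUE
        }
    }
    list(empcpds = empcpds, unassigned = spectra[!assigned])
}

#' Greedy cosine similarity between two MS2 spectra
#'
#' Candidate peak pairs within `fragTolDa` are taken greedily in order
#' of descending intensity product, each peak used at most once; the
#' score is the cosine of the paired raw intensities:
#' `sum(Iq * Ir) / (||Iq|| * ||Ir||)`. Identical spectra score exactly
#' 1; spectra with no peaks within tolerance score 0. If fewer than
#' `minMatched` peaks pair, the match is still reported but flagged
#' below threshold.
#'
#' @param query,reference [MS2Spectrum-class] objects with nonempty peak
#'   lists.
#' @param fragTolDa fragment m/z tolerance in Daltons.
#' @param minMatched minimum paired-peak count.
#' @return a [SpectralMatch-class].
#' @export
cosineScore <- function(query, reference, fragTolDa = 0.01,
                        minMatched = 3L) {
    pq <- query@peaks
    pr <- reference@peaks
    if (!nrow(pq) || !nrow(pr)) stop("empty peak list")
    cand <- which(abs(outer(pq[, 1L], pr[, 1L], "-")) <= fragTolDa,
                  arr.ind = TRUE)
    nMatched <- 0L
    dot <- 0
    pairs <- matrix(integer(), 0, 2,
                    dimnames = list(NULL, c("query", "reference")))
    if (nrow(cand)) {
        prod <- pq[cand[, 1L], 2L] * pr[cand[, 2L], 2L]
        ord <- order(-prod, cand[, 1L], cand[, 2L])
        usedQ <- logical(nrow(pq)); usedR <- logical(nrow(pr))
        for (k in ord) {
            i <- cand[k, 1L]; j <- cand[k, 2L]
            if (usedQ[i] || usedR[j]) next
            usedQ[i] <- TRUE; usedR[j] <- TRUE
            dot <- dot + prod[k]
            pairs <- rbind(pairs, c(i, j))
            nMatched <- nMatched + 1L
        }
    }
    score <- dot / (sqrt(sum(pq[, 2L]^2)) * sqrt(sum(pr[, 2L]^2)))
    score <- min(max(score, 0), 1)
    new("SpectralMatch", score = score, nMatched = nMatched,
        pairs = pairs, belowThreshold = nMatched < minMatched)
}

#' MS2 annotation (levels 2 and 1a)
#'
#' Every (attached experimental spectrum, library spectrum) pair scoring
#' at least `scoreCutoff` with at least `minMatched` paired peaks is
#' appended as an annotation: level 1a when the library spectrum's
#' provenance is `reference_authentic`, level 2 when
#' `reference_public`. All qualifying hits are retained.
#'
#' @param empcpds list of [EmpiricalCompound-class] with spectra already
#'   mapped (see [mapMS2ToEmpCpds()]).
#' @param library list of reference [MS2Spectrum-class]; every spectrum
#'   must carry a reference provenance.
#' @param fragTolDa fragment tolerance in Daltons.
#' @param scoreCutoff minimum cosine score.
#' @param minMatched minimum paired-peak count.
#' @param source label recorded on the annotation records.
#' @return the annotated list.
#' @export
annotateMS2 <- function(empcpds, library, fragTolDa = 0.01,
                        scoreCutoff = 0.7, minMatched = 3L,
                        source = "ms2_library") {
    prov <- vapply(library, function(s) s@provenance, character(1))
    bad <- !prov %in% c("reference_public", "reference_authentic")
    if (any(bad))
        stop("library spectra must carry provenance 'reference_public' ",
             "or 'reference_authentic'")
    lapply(empcpds, function(e) {
        for (s in e@ms2Spectra) {
            if (!nrow(s@peaks)) next
            for (li in seq_along(library)) {
                ref <- library[[li]]
                if (!nrow(ref@peaks)) next
                match <- cosineScore(s, ref, fragTolDa, minMatched)
                if (match@score >= scoreCutoff && !match@belowThreshold) {
                    lv <- if (prov[li] == "reference_authentic") "1a"
                          else "2"
                    e <- addAnnotation(e, annotationRecord(
                        level = lv, candidateName = ref@compound,
                        score = match@score, source = source,
                        evidence = list(n_matched = match@nMatched,
                                        query_source = s@source,
                                        library_source = ref@source)))
                }
            }
        }
        e
    })
}

#' Map empirical-compound annotations back to features
#'
#' Every annotation of an empirical compound is emitted once per member
#' feature present in `table` (ranked by level precedence then score);
#' member features absent from the table are skipped silently. The
#' result feeds [emitThreeTables()].
#'
#' @param empcpds list of [EmpiricalCompound-class].
#' @param table a [FeatureTable-class].
#' @return data.frame with one row per (feature, annotation) pair.
#' @export
mapAnnotationsToFeatures <- function(empcpds, table) {
    ids <- featureIds(table)
    rows <- lapply(empcpds, function(e) {
        present <- intersect(e@members$feature_id, ids)
        anns <- rankAnnotations(e@annotations)
        if (!length(present) || !length(anns)) return(NULL)
        do.call(rbind, lapply(anns, function(a)
            data.frame(feature_id = present, empcpd_id = e@empcpdId,
                       level = a$level, candidate_name = a$candidate_name,
                       candidate_id = a$candidate_id,
                       score = if (is.na(a$score)) NA_real_ else a$score,
                       source = a$source,
                       stringsAsFactors = FALSE)))
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(feature_id = character(), empcpd_id = character(),
                          level = character(), candidate_name = character(),
                          candidate_id = character(), score = numeric(),
                          source = character(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}
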