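#' Default isotope/adduct ion table
#'
#' Offsets are derived from standard atomic masses: +1.003355 Da per
#' 13C substitution; proton 1.007276, Na+ 22.989218 (Na - e), NH4+
#' 18.033823, Cl- 34.969402, formate 44.998201.
#'
#' @param mode `"pos"` or `"neg"`.
#' @return an [IonTable-class].
#' @export
defaultIonTable <- function(mode = c("pos", "neg")) {
    mode <- match.arg(mode)
    isotopes <- data.frame(
        label = c("M0", "13C/3C1", "13C/3C2"),
        offset = c(0, 1.003355, 2.006710),
        stringsAsFactors = FALSE)
    adducts <- if (mode == "pos")
        data.frame(label = c("M+H+", "M+NH4+", "M+Na+"),
                   offset = c(1.007276, 18.033823, 22.989218),
                   stringsAsFactors = FALSE)
    else
        data.frame(label = c("M-H-", "M+Cl-", "M+formate-"),
                   offset = c(-1.007276, 34.969402, 44.998201),
                   stringsAsFactors = FALSE)
    new("IonTable", mode = mode, isotopes = isotopes, adducts = adducts)
}

#' Load an ion table from a JSON config
#'
#' Expected shape: `{"mode": "pos", "isotopes": [{"label": ..,
#' "offset": ..}, ...], "adducts": [...]}`.
#'
#' @param path JSON file.
#' @return an [IonTable-class].
#' @export
readIonTable <- function(path) {
    doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    new("IonTable", mode = doc$mode,
        isotopes = as.data.frame(doc$isotopes, stringsAsFactors = FALSE),
        adducts = as.data.frame(doc$adducts, stringsAsFactors = FALSE))
}

#' Signed ppm mass error
#'
#' @param mzObs observed m/z.
#' @param mzRef reference m/z (> 0).
#' @return `(mzObs - mzRef) / mzRef * 1e6`, vectorized.
#' @examples
#' ppmError(100.0005, 100) # +5
#' @export
ppmError <- function(mzObs, mzRef) {
    if (any(mzRef <= 0)) stop("mzRef must be positive")
    (mzObs - mzRef) / mzRef * 1e6
}

# Candidate m/z deltas that link two features: isotope steps (and their
# pairwise differences) and pairwise differences between adduct offsets.
# For charge z > 1 the isotope spacings shrink to 1.003355/z.
.candidateDeltas <- function(ionTable, maxCharge = 1L) {
    iso <- ionTable@isotopes$offset
    add <- ionTable@adducts$offset
    isoD <- unique(round(abs(as.vector(outer(iso, iso, "-"))), 9))
    isoD <- isoD[isoD > 0]
    addD <- unique(round(abs(as.vector(outer(add, add, "-"))), 9))
    addD <- addD[addD > 0]
    out <- rbind(
        if (length(isoD)) data.frame(delta = isoD, type = "isotope",
                                     charge = 1L),
        if (length(addD)) data.frame(delta = addD, type = "adduct",
                                     charge = 1L))
    if (maxCharge >= 2L)
        for (z in 2L:maxCharge)
            out <- rbind(out, data.frame(delta = isoD / z, type = "isotope",
                                         charge = as.integer(z)))
    out
}

# Pairwise feature links. A pair links when retention times agree within
# rtTolS and the m/z difference matches a candidate delta within
# mzTolPpm evaluated on the heavier member's m/z. Isotope-only links must
# additionally pass the abundance plausibility gate: the sample-wise
# median intensity ratio heavier/lighter (over samples where both are
# observed) must not exceed isotopeRatioMax.
.linkFeaturePairs <- function(mz, rtime, intensities, deltas, mzTolPpm,
                              rtTolS, isotopeRatioMax) {
    n <- length(mz)
    links <- matrix(integer(), 0, 2)
    if (n < 2L) return(links)
    ord <- order(mz)
    maxDelta <- max(deltas$delta)
    for (a in seq_len(n - 1L)) {
        i <- ord[a]
        for (b in (a + 1L):n) {
            j <- ord[b]
            dm <- mz[j] - mz[i]
            if (dm > maxDelta + mz[j] * mzTolPpm * 1e-6) break
            if (abs(rtime[i] - rtime[j]) > rtTolS) next
            ok <- abs(dm - deltas$delta) <= mz[j] * mzTolPpm * 1e-6
            if (!any(ok)) next
            types <- unique(deltas$type[ok])
            accept <- "adduct" %in% types
            if (!accept && "isotope" %in% types) {
                both <- intensities[i, ] > 0 & intensities[j, ] > 0
                ratio <- if (any(both))
                    stats::median(intensities[j, both] / intensities[i, both])
                else Inf
                accept <- is.finite(ratio) && ratio <= isotopeRatioMax
            }
            if (accept) links <- rbind(links, c(i, j))
        }
    }
    links
}

# Lay one connected component onto the isotope x adduct grid.
# Every (feature, cell) pair implies a neutral mass; the consensus mass
# is the implied mass supported by the most features (ties: smallest
# total |ppm error|, then smallest mass). Features get their best-fitting
# cell; cell conflicts keep the feature with the smaller |ppm error| and
# eject the loser; features fitting no cell are ejected too.
# Returns list(assigned = data.frame(idx, isotope, adduct, charge,
# mass_offset), ejected = integer()).
.assignGrid <- function(mz, idx, ionTable, mzTolPpm, charge = 1L) {
    iso <- ionTable@isotopes
    add <- ionTable@adducts
    cells <- expand.grid(iso_i = seq_len(nrow(iso)),
                         add_i = seq_len(nrow(add)))
    # for charge z, mz = (M + iso_off)/z + add_off, i.e.
    # M = z*mz - iso_off - z*add_off
    cellOffset <- iso$offset[cells$iso_i] +
        charge * add$offset[cells$add_i]
    n <- length(idx)
    # implied[f, c] = neutral mass if feature f occupies cell c
    implied <- outer(mz * charge, cellOffset, "-")
    cand <- as.vector(implied)
    best <- NULL
    for (m in cand) {
        if (m <= 0) next
        err <- abs(implied - m) / m * 1e6
        fits <- err <= mzTolPpm
        nf <- sum(apply(fits, 1L, any))
        tot <- sum(apply(err, 1L, function(e) min(e[is.finite(e)])))
        # ties in support break to the smallest total ppm error (a grid
        # translated to higher-offset cells scores a larger relative
        # error, so the lowest-offset anchoring wins); exact ties break
        # to the larger mass, i.e. the lowest-offset interpretation
        if (is.null(best) || nf > best$nf ||
            (nf == best$nf && tot < best$tot - 1e-12) ||
            (nf == best$nf && abs(tot - best$tot) <= 1e-12 && m > best$m))
            best <- list(m = m, nf = nf, tot = tot)
    }
    if (is.null(best))
        return(list(assigned = data.frame(idx = integer(),
                                          isotope = character(),
                                          adduct = character(),
                                          charge = integer(),
                                          mass_offset = numeric()),
                    ejected = sort(idx)))
    m <- best$m
    err <- abs(implied - m) / m * 1e6
    assign <- data.frame(idx = integer(), iso_i = integer(),
                         add_i = integer(), err = numeric())
    for (f in seq_len(n)) {
        ok <- which(err[f, ] <= mzTolPpm)
        if (!length(ok)) next
        c0 <- ok[which.min(err[f, ok])]
        assign <- rbind(assign, data.frame(idx = idx[f],
                                           iso_i = cells$iso_i[c0],
                                           add_i = cells$add_i[c0],
                                           err = err[f, c0]))
    }
    ejected <- setdiff(idx, assign$idx)
    # resolve cell conflicts: smaller |ppm error| wins
    if (nrow(assign)) {
        key <- paste(assign$iso_i, assign$add_i)
        keep <- unlist(lapply(split(seq_len(nrow(assign)), key),
                              function(rows)
                                  rows[which.min(assign$err[rows])]))
        ejected <- c(ejected, assign$idx[-keep])
        if (length(keep) < nrow(assign))
            assign <- assign[sort(keep), , drop = FALSE]
    }
    if (nrow(assign) < 2L) {
        ejected <- sort(unique(c(ejected, assign$idx)))
        assign <- assign[0, , drop = FALSE]
    }
    list(assigned = if (nrow(assign)) data.frame(
             idx = assign$idx,
             isotope = iso$label[assign$iso_i],
             adduct = add$label[assign$add_i],
             charge = as.integer(charge),
             mass_offset = iso$offset[assign$iso_i] +
                 add$offset[assign$add_i],
             stringsAsFactors = FALSE)
         else data.frame(idx = integer(), isotope = character(),
                         adduct = character(), charge = integer(),
                         mass_offset = numeric()),
         ejected = sort(unique(ejected)))
}

#' Group degenerate features into empirical compounds
#'
#' Khipu-style pre-annotation: feature pairs are linked when they
#' co-elute within `rtTolS` and their m/z difference matches an isotope
#' step or an adduct-pair difference within `mzTolPpm` (tolerance on the
#' heavier member); isotope links must also pass an abundance
#' plausibility gate (sample-wise median M+1/M0 ratio at most
#' `isotopeRatioMax`). Connected components are laid onto an isotope x
#' adduct grid around a consensus neutral mass; cell conflicts keep the
#' mass-accurate feature and eject the other. Every feature belonging to
#' no grid becomes a singleton empirical compound of unknown ion species,
#' so the returned compounds partition the feature set exactly.
#'
#' @param table a [FeatureTable-class].
#' @param ionTable an [IonTable-class]; default positive-mode table.
#' @param mzTolPpm m/z tolerance in ppm (> 0, default 5).
#' @param rtTolS co-elution tolerance in seconds (> 0, default 2).
#' @param isotopeRatioMax isotope abundance gate (default 1.5).
#' @param maxCharge highest charge state considered (default 1; 2 adds
#'   half-spaced isotope links).
#' @return list of [EmpiricalCompound-class], ordered by the smallest
#'   member m/z, with neutral masses inferred (see [inferNeutralMass()]).
#' @export
buildEmpiricalCompounds <- function(table, ionTable = defaultIonTable("pos"),
                                    mzTolPpm = 5, rtTolS = 2,
                                    isotopeRatioMax = 1.5, maxCharge = 1L) {
    if (mzTolPpm <= 0 || rtTolS <= 0)
        stop("tolerances must be positive")
    n <- nrow(table)
    if (n == 0L) return(list())
    mz <- unname(featureMz(table))
    rt <- unname(featureRtime(table))
    ids <- featureIds(table)
    ints <- intensityMatrix(table)
    deltas <- .candidateDeltas(ionTable, maxCharge)
    links <- .linkFeaturePairs(mz, rt, ints, deltas, mzTolPpm, rtTolS,
                               isotopeRatioMax)
    membership <- seq_len(n)
    if (nrow(links)) {
        g <- igraph::graph_from_data_frame(
            data.frame(from = as.character(links[, 1L]),
                       to = as.character(links[, 2L])),
            directed = FALSE,
            vertices = data.frame(name = as.character(seq_len(n))))
        membership <- igraph::components(g)$membership[
            as.character(seq_len(n))]
    }
    groups <- split(seq_len(n), membership)

    empcpds <- list()
    singles <- integer()
    for (grp in groups) {
        if (length(grp) < 2L) { singles <- c(singles, grp); next }
        res <- NULL
        for (z in seq_len(max(1L, maxCharge))) {
            r <- .assignGrid(mz[grp], grp, ionTable, mzTolPpm, charge = z)
            if (is.null(res) || nrow(r$assigned) > nrow(res$assigned))
                res <- r
        }
        singles <- c(singles, res$ejected)
        a <- res$assigned
        if (!nrow(a)) next
        memb <- data.frame(feature_id = ids[a$idx], mz = mz[a$idx],
                           rtime = rt[a$idx], isotope = a$isotope,
                           adduct = a$adduct, charge = a$charge,
                           mass_offset = a$mass_offset,
                           stringsAsFactors = FALSE)
        empcpds[[length(empcpds) + 1L]] <-
            EmpiricalCompound("tmp", memb, mode = ionTable@mode)
    }
    for (s in singles) {
        memb <- data.frame(feature_id = ids[s], mz = mz[s], rtime = rt[s],
                           isotope = NA_character_, adduct = NA_character_,
                           charge = NA_integer_, mass_offset = NA_real_,
                           stringsAsFactors = FALSE)
        empcpds[[length(empcpds) + 1L]] <-
            EmpiricalCompound("tmp", memb, mode = ionTable@mode)
    }
    ord <- order(vapply(empcpds, function(e) min(e@members$mz), numeric(1)),
                 vapply(empcpds, function(e) e@members$feature_id[1L],
                        character(1)))
    empcpds <- empcpds[ord]
    for (i in seq_along(empcpds)) {
        empcpds[[i]]@empcpdId <- sprintf("E%05d", i)
        empcpds[[i]] <- inferNeutralMass(empcpds[[i]], mzTolPpm = mzTolPpm)
    }
    empcpds
}

#' Infer the neutral mass of an empirical compound
#'
#' Each member with an assigned ion relation implies a neutral mass
#' `observed m/z * |charge| - mass_offset`; the compound's neutral mass
#' is the mean of the implied masses. Members of unknown ion species
#' contribute nothing; a compound with no interpretable member (e.g. an
#' ungrouped singleton) gets `NA`. When the implied masses disagree by
#' more than `mzTolPpm` the mean is kept but the spread is flagged in
#' the object metadata (`massDiscordant` attribute on the members).
#'
#' @param empcpd an [EmpiricalCompound-class].
#' @param mzTolPpm discordance threshold in ppm.
#' @return the compound with `neutralMass` filled in.
#' @export
inferNeutralMass <- function(empcpd, mzTolPpm = 5) {
    m <- empcpd@members
    ok <- !is.na(m$mass_offset) & !is.na(m$charge)
    if (!any(ok)) { empcpd@neutralMass <- NA_real_; return(empcpd) }
    implied <- m$mz[ok] * abs(m$charge[ok]) - m$mass_offset[ok]
    mass <- mean(implied)
    empcpd@neutralMass <- mass
    spreadPpm <- if (length(implied) > 1L)
        (max(implied) - min(implied)) / mass * 1e6 else 0
    attr(empcpd@members, "massDiscordant") <- spreadPpm > mzTolPpm
    empcpd
}
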