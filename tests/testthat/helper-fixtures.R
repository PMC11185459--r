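# Shared fixture builders and independent oracles.

# a FeatureTable whose per-sample feature counts are exactly `counts`
makeCountTable <- function(counts, nFeatures = max(counts)) {
    n <- length(counts)
    m <- matrix(0, nFeatures, n,
                dimnames = list(sprintf("F%04d", seq_len(nFeatures)),
                                sprintf("s%02d", seq_len(n))))
    for (i in seq_len(n)) if (counts[i] > 0) m[seq_len(counts[i]), i] <- 100
    FeatureTable(m, mz = seq(100, 500, length.out = nFeatures),
                 rtime = seq(10, 1000, length.out = nFeatures))
}

randomTable <- function(nFeatures, nSamples, seed, missingRate = 0.1) {
    set.seed(seed)
    m <- matrix(rlnorm(nFeatures * nSamples, log(1e5), 1),
                nFeatures, nSamples,
                dimnames = list(sprintf("F%04d", seq_len(nFeatures)),
                                sprintf("s%02d", seq_len(nSamples))))
    m[runif(length(m)) < missingRate] <- 0
    # guarantee at least one observation per feature
    empty <- rowSums(m > 0) == 0
    m[empty, 1L] <- 1e5
    FeatureTable(m, mz = runif(nFeatures, 100, 900),
                 rtime = runif(nFeatures, 10, 1100))
}

# ---- independent grouping oracle -------------------------------------
# Candidate deltas recomputed from first principles (standard atomic
# masses), not taken from the package.
ORACLE_ISO_STEPS <- c(1.003355, 2.006710)
ORACLE_POS_ADDUCTS <- c(H = 1.007276, NH4 = 18.033823, Na = 22.989218)

oracleDeltas <- function() {
    addD <- abs(as.vector(outer(ORACLE_POS_ADDUCTS, ORACLE_POS_ADDUCTS,
                                "-")))
    isoD <- unique(c(ORACLE_ISO_STEPS,
                     abs(outer(ORACLE_ISO_STEPS, ORACLE_ISO_STEPS, "-"))))
    list(iso = isoD[isoD > 0], add = unique(addD[addD > 0]))
}

# naive O(n^2) pair enumeration straight from the linking definition
oracleLinks <- function(mz, rt, ints, mzTolPpm = 5, rtTolS = 2,
                        ratioMax = 1.5) {
    d <- oracleDeltas()
    out <- list()
    n <- length(mz)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        lo <- if (mz[i] <= mz[j]) i else j
        hi <- i + j - lo
        if (abs(rt[i] - rt[j]) > rtTolS) next
        dm <- mz[hi] - mz[lo]
        tol <- mz[hi] * mzTolPpm * 1e-6
        isAdd <- any(abs(dm - d$add) <= tol)
        isIso <- any(abs(dm - d$iso) <= tol)
        gateOk <- FALSE
        if (isIso) {
            both <- ints[lo, ] > 0 & ints[hi, ] > 0
            gateOk <- any(both) &&
                median(ints[hi, both] / ints[lo, both]) <= ratioMax
        }
        if (isAdd || (isIso && gateOk))
            out[[length(out) + 1L]] <- c(i, j)
    }
    out
}

# connected components by repeated closure (no graph library)
oracleComponents <- function(nNodes, links) {
    comp <- seq_len(nNodes)
    repeat {
        changed <- FALSE
        for (l in links) {
            m <- min(comp[l]); M <- max(comp[l])
            if (m != M) {
                comp[comp == M] <- m
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    unname(split(seq_len(nNodes), comp))
}

# random small instance exercising matches, rt gates and isotope gates
randomGroupingInstance <- function(seed, nMax = 12) {
    set.seed(seed)
    n <- sample(4:nMax, 1)
    d <- oracleDeltas()
    mz <- numeric(n); rt <- numeric(n)
    mz[1] <- runif(1, 150, 600); rt[1] <- runif(1, 0, 8)
    for (k in 2:n) {
        if (runif(1) < 0.55) {
            base <- sample(seq_len(k - 1L), 1)
            step <- sample(c(d$iso, d$add), 1)
            mz[k] <- (mz[base] + step) * (1 + rnorm(1, 0, 3e-6))
            rt[k] <- rt[base] + rnorm(1, 0, 1.5)
        } else {
            mz[k] <- runif(1, 150, 600)
            rt[k] <- runif(1, 0, 8)
        }
    }
    rt <- pmax(rt, 0)
    ints <- matrix(rlnorm(n * 4, log(1e5), 0.3) *
                       runif(n, 0.1, 3), n, 4,
                   dimnames = list(sprintf("F%02d", seq_len(n)),
                                   paste0("s", 1:4)))
    ints[runif(length(ints)) < 0.1] <- 0
    FeatureTable(ints, mz = mz, rtime = rt)
}

# partition induced by the implementation's linking stage
implementationComponents <- function(table, mzTolPpm = 5, rtTolS = 2,
                                     ratioMax = 1.5) {
    ion <- defaultIonTable("pos")
    deltas <- metaboPost:::.candidateDeltas(ion, 1L)
    links <- metaboPost:::.linkFeaturePairs(
        unname(featureMz(table)), unname(featureRtime(table)),
        intensityMatrix(table), deltas, mzTolPpm, rtTolS, ratioMax)
    oracleComponents(nrow(table),
                     lapply(seq_len(nrow(links)), function(r) links[r, ]))
}

canonicalPartition <- function(groups) {
    groups <- lapply(groups, sort)
    groups[order(vapply(groups, `[`, numeric(1), 1L))]
}

# random empirical compounds for serialization round trips
randomEmpCpds <- function(seed, n = 5) {
    set.seed(seed)
    lapply(seq_len(n), function(i) {
        k <- sample(1:4, 1)
        mass <- runif(1, 100, 800)
        memb <- data.frame(
            feature_id = sprintf("F%d_%d", i, seq_len(k)),
            mz = mass + 1.007276 + runif(k, 0, 25) + rnorm(k, 0, 1e-4),
            rtime = runif(1, 0, 1200) + rnorm(k, 0, 0.5),
            isotope = sample(c("M0", "13C/3C1", NA), k, TRUE),
            adduct = sample(c("M+H+", "M+Na+", NA), k, TRUE),
            charge = sample(c(1L, NA), k, TRUE),
            mass_offset = c(1.007276, runif(k - 1, 0, 25)),
            stringsAsFactors = FALSE)
        spectra <- lapply(seq_len(sample(0:2, 1)), function(s)
            MS2Spectrum(precursorMz = mass + 1.007276,
                        precursorRtime = runif(1, 0, 1200),
                        peaks = cbind(sort(runif(5, 50, mass)),
                                      runif(5, 0.01, 1)),
                        source = sprintf("scan_%d_%d", i, s),
                        provenance = sample(c("experimental",
                                              "reference_public"), 1)))
        anns <- lapply(seq_len(sample(0:3, 1)), function(a)
            annotationRecord(level = sample(c("1a", "1b", "2", "4"), 1),
                             candidateName = sprintf("cpd_%d_%d", i, a),
                             source = "test_db", score = runif(1),
                             evidence = list(ppm_error = rnorm(1))))
        EmpiricalCompound(sprintf("E%05d", i), memb,
                          neutralMass = if (runif(1) < 0.8) mass
                                        else NA_real_,
                          ms2Spectra = spectra, annotations = anns)
    })
}
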