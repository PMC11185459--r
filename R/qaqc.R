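#' @importFrom grDevices pdf dev.off
#' @importFrom graphics plot.new text par title
NULL

# run expr with a private RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else on.exit(suppressWarnings(
        rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    expr
}

#' Compute per-sample and pairwise QC metrics
#'
#' Per-sample: TIC, feature count (intensity > 0), missing-feature
#' count, median and mean nonmissing intensity, the three Z-scores
#' (feature count, missing count, median correlation). Pairwise: Pearson
#' and Spearman correlation across all features on log10(intensity + 1).
#' Projection: PCA of the samples on log10(intensity + 1), centered per
#' feature (deterministic solver), with explained-variance fractions.
#'
#' @param table a [FeatureTable-class] with at least 3 samples.
#' @param tsne if `TRUE`, no t-SNE is run (not bundled); the slot is
#'   kept for downstream tools to fill.
#' @return a [QCSummary-class].
#' @export
computeQCSummary <- function(table, tsne = FALSE) {
    m <- intensityMatrix(table)
    if (ncol(m) < 3L) stop("at least 3 samples are required")
    lm10 <- log10(m + 1)
    perSample <- data.frame(
        sample = colnames(m),
        tic = colSums(m),
        feature_count = colSums(m > 0),
        missing_count = colSums(m == 0),
        median_intensity = apply(m, 2L, function(x)
            if (any(x > 0)) stats::median(x[x > 0]) else 0),
        mean_intensity = apply(m, 2L, function(x)
            if (any(x > 0)) mean(x[x > 0]) else 0),
        median_correlation = .medianCorrelations(m),
        row.names = colnames(m), stringsAsFactors = FALSE)
    perSample$z_feature_count <- .zscore(perSample$feature_count)
    perSample$z_missing_count <- .zscore(perSample$missing_count)
    perSample$z_median_correlation <- .zscore(perSample$median_correlation)
    pearson <- stats::cor(lm10, method = "pearson")
    spearman <- stats::cor(lm10, method = "spearman")
    pc <- stats::prcomp(t(lm10), center = TRUE, scale. = FALSE)
    k <- min(2L, ncol(pc$x))
    ev <- pc$sdev^2 / sum(pc$sdev^2)
    new("QCSummary", perSample = perSample, pearson = pearson,
        spearman = spearman,
        pca = list(coords = pc$x[, seq_len(k), drop = FALSE],
                   explainedVariance = ev),
        tsne = list())
}

setMethod("show", "QCSummary", function(object) {
    cat(sprintf("QCSummary: %d samples\n", nrow(object@perSample)))
    cat(sprintf("  feature counts: %d-%d; TIC: %.3g-%.3g\n",
                min(object@perSample$feature_count),
                max(object@perSample$feature_count),
                min(object@perSample$tic), max(object@perSample$tic)))
    cat(sprintf("  PC1/PC2 explained variance: %.1f%% / %.1f%%\n",
                100 * object@pca$explainedVariance[1L],
                100 * object@pca$explainedVariance[min(
                    2L, length(object@pca$explainedVariance))]))
})

#' Detect failed injections
#'
#' A failed injection loses most of its features, so detection is
#' one-sided: samples with feature-count Z below `-cutoff` are flagged.
#' (Outlier *removal* in the curation stage stays two-sided at
#' |Z| > 2.5.)
#'
#' @param table a [FeatureTable-class] with at least 3 samples.
#' @param cutoff positive Z threshold (default 2.5).
#' @return character vector of flagged acquisition names.
#' @export
detectFailedInjections <- function(table, cutoff = 2.5) {
    z <- sampleZscores(table, "feature_count")
    names(z)[z < -cutoff]
}

.REPORT_SECTIONS <- c("pca", "log_tics", "correlation_clustermap",
                      "missing_feature_zscores", "annotation_accounting",
                      "timestamp", "command_timeline")

#' The default report template
#'
#' The seven default sections: PCA, log TICs, Pearson correlation
#' clustermap and missing-feature Z-score plots for each registered
#' feature table; an accounting of annotations and features explained
#' for each empirical-compound set; the report timestamp; and the
#' timeline of all commands used in the analysis.
#'
#' @return character vector of section names.
#' @export
defaultReportTemplate <- function() .REPORT_SECTIONS

.textPage <- function(title, lines) {
    plot.new()
    text(0.5, 0.97, title, cex = 1.4, font = 2)
    if (length(lines)) {
        n <- length(lines)
        text(0.02, 0.9 - (seq_len(n) - 1L) * min(0.03, 0.85 / n),
             lines, adj = 0, cex = 0.7, family = "mono")
    }
}

#' Annotation accounting for one empirical-compound set
#'
#' Counts, per annotation level, the empirical compounds and features
#' carrying at least one annotation at that level, plus totals.
#'
#' @param empcpds list of [EmpiricalCompound-class].
#' @return data.frame with columns `level`, `n_empcpds`, `n_features`.
#' @export
annotationAccounting <- function(empcpds) {
    rows <- lapply(.ANNOTATION_LEVELS, function(lv) {
        has <- vapply(empcpds, function(e)
            any(vapply(e@annotations, function(a) a$level == lv,
                       logical(1))), logical(1))
        data.frame(level = lv, n_empcpds = sum(has),
                   n_features = sum(vapply(empcpds[has], function(e)
                       nrow(e@members), integer(1))),
                   stringsAsFactors = FALSE)
    })
    tot <- data.frame(level = "any",
                      n_empcpds = sum(vapply(empcpds, function(e)
                          length(e@annotations) > 0, logical(1))),
                      n_features = sum(vapply(empcpds, function(e)
                          if (length(e@annotations)) nrow(e@members)
                          else 0L, integer(1))),
                      stringsAsFactors = FALSE)
    do.call(rbind, c(rows, list(tot)))
}

#' Assemble the PDF report
#'
#' Renders the requested sections (default: [defaultReportTemplate()])
#' for every feature table and empirical-compound set registered in the
#' experiment. The template can also be given as a JSON file holding a
#' list of section names. Unknown section names are an error listing the
#' valid ones. TIC bar plots show at most `maxTicSamples` samples,
#' drawn with a fixed seed.
#'
#' @param experiment a [MetaboExperiment-class] with at least one
#'   registered feature table.
#' @param path output PDF path.
#' @param template character vector of section names, or a JSON file.
#' @param maxTicSamples sample cap for TIC bar plots (default 50).
#' @return invisibly, a list with the `path` and a data.frame `sections`
#'   of the rendered (section, subject) pairs.
#' @export
assembleReport <- function(experiment,
                           path = file.path(experiment@directory,
                                            "report.pdf"),
                           template = defaultReportTemplate(),
                           maxTicSamples = 50L) {
    if (length(template) == 1L && file.exists(template) &&
        grepl("\\.json$", template))
        template <- unlist(jsonlite::fromJSON(template))
    unknown <- setdiff(template, .REPORT_SECTIONS)
    if (length(unknown))
        stop(sprintf("unknown report section(s): %s (valid: %s)",
                     paste(unknown, collapse = ", "),
                     paste(.REPORT_SECTIONS, collapse = ", ")))
    if (!length(experiment@tableRegistry))
        stop("experiment has no registered feature table")
    tables <- lapply(names(experiment@tableRegistry), function(mk)
        retrieveFeatureTable(experiment, mk))
    names(tables) <- names(experiment@tableRegistry)
    qcs <- lapply(tables, computeQCSummary)

    rendered <- data.frame(section = character(), subject = character(),
                           stringsAsFactors = FALSE)
    note <- function(section, subject)
        rendered <<- rbind(rendered, data.frame(section = section,
                                                subject = subject,
                                                stringsAsFactors = FALSE))
    pdf(path, width = 8, height = 6)
    on.exit(dev.off(), add = TRUE)
    .textPage("Experiment report", c(
        sprintf("Acquisitions: %d", nrow(experiment@acquisitions)),
        sprintf("Feature tables: %s",
                paste(names(experiment@tableRegistry), collapse = ", ")),
        sprintf("Empirical-compound sets: %s",
                if (length(experiment@empcpdRegistry))
                    paste(names(experiment@empcpdRegistry), collapse = ", ")
                else "<none>")))
    for (section in template) {
        if (section == "timestamp") {
            .textPage("Report generated",
                      format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))
            note(section, "report")
        } else if (section == "command_timeline") {
            cl <- experiment@commandLog
            .textPage("Command timeline", if (nrow(cl))
                sprintf("%s  %s  %s", cl$timestamp, cl$command, cl$params)
                else "(no commands logged)")
            note(section, "experiment")
        } else if (section == "annotation_accounting") {
            for (mk in names(experiment@empcpdRegistry)) {
                empcpds <- retrieveEmpCpds(experiment, mk)
                acc <- annotationAccounting(empcpds)
                .textPage(sprintf("Annotation accounting: %s", mk), c(
                    sprintf("%d empirical compounds over %d features",
                            length(empcpds),
                            sum(vapply(empcpds, function(e)
                                nrow(e@members), integer(1)))),
                    "",
                    sprintf("%-6s %10s %10s", "level", "empcpds",
                            "features"),
                    sprintf("%-6s %10d %10d", acc$level, acc$n_empcpds,
                            acc$n_features)))
                note(section, mk)
            }
        } else {
            for (mk in names(tables)) {
                .renderTableSection(section, tables[[mk]], qcs[[mk]], mk,
                                    maxTicSamples)
                note(section, mk)
            }
        }
    }
    invisible(list(path = path, sections = rendered))
}

.renderTableSection <- function(section, table, qc, moniker,
                                maxTicSamples) {
    ps <- qc@perSample
    if (section == "pca") {
        d <- data.frame(PC1 = qc@pca$coords[, 1L],
                        PC2 = if (ncol(qc@pca$coords) > 1L)
                            qc@pca$coords[, 2L] else 0,
                        sample = rownames(qc@pca$coords))
        ev <- qc@pca$explainedVariance
        p <- ggplot2::ggplot(d, ggplot2::aes(PC1, PC2)) +
            ggplot2::geom_point() +
            ggplot2::labs(
                title = sprintf("PCA: %s", moniker),
                x = sprintf("PC1 (%.1f%%)", 100 * ev[1L]),
                y = sprintf("PC2 (%.1f%%)",
                            100 * ev[min(2L, length(ev))])) +
            ggplot2::theme_bw()
        print(p)
    } else if (section == "log_tics") {
        pick <- if (nrow(ps) > maxTicSamples)
            sort(.withSeed(1L, sample.int(nrow(ps), maxTicSamples)))
        else seq_len(nrow(ps))
        d <- data.frame(sample = ps$sample[pick],
                        logTIC = log10(ps$tic[pick] + 1))
        p <- ggplot2::ggplot(d, ggplot2::aes(sample, logTIC)) +
            ggplot2::geom_col() +
            ggplot2::labs(title = sprintf("log10 TIC: %s", moniker),
                          y = "log10(TIC + 1)") +
            ggplot2::theme_bw() +
            ggplot2::theme(axis.text.x = ggplot2::element_text(
                angle = 90, vjust = 0.5, size = 6))
        print(p)
    } else if (section == "correlation_clustermap") {
        ph <- pheatmap::pheatmap(qc@pearson, silent = TRUE,
                                 main = sprintf(
                                     "Pearson correlation: %s", moniker),
                                 fontsize = 6)
        grid::grid.newpage()
        grid::grid.draw(ph$gtable)
    } else if (section == "missing_feature_zscores") {
        d <- data.frame(sample = ps$sample, z = ps$z_missing_count)
        p <- ggplot2::ggplot(d, ggplot2::aes(sample, z)) +
            ggplot2::geom_col() +
            ggplot2::geom_hline(yintercept = c(-2.5, 2.5),
                                linetype = "dashed") +
            ggplot2::labs(title = sprintf(
                "Missing-feature Z-scores: %s", moniker),
                y = "Z (missing-feature count)") +
            ggplot2::theme_bw() +
            ggplot2::theme(axis.text.x = ggplot2::element_text(
                angle = 90, vjust = 0.5, size = 6))
        print(p)
    }
}
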