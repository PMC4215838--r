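.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full screening pipeline
#'
#' Orchestrates input loading (or simulation), rarefaction, the
#' within-level correlation screen, sign-consistency classification, clade
#' enrichment, EC50 defence assessment and the univariate treatment
#' statistics, writing every result table plus a machine-readable manifest
#' to `out_dir`.
#'
#' @param config either a YAML file path or a list with fields:
#'   \describe{
#'     \item{input}{list with `otu_table`, `metadata`, optional `taxonomy`
#'       paths and `orientation`; mutually exclusive with `simulate`.}
#'     \item{simulate}{list of arguments for [simulationConfig()]; mutually
#'       exclusive with `input`.}
#'     \item{depth}{rarefaction depth: a number, `"min"` (smallest sample
#'       total), or `NULL` to skip (e.g. for pre-rarefied inputs).}
#'     \item{compounds}{compounds to screen (default: all concentration
#'       columns in the metadata).}
#'     \item{min_levels}{passed to [classifyConsistency()] (default 1).}
#'     \item{strata}{passed to [enrichmentTable()] (default `"per_level"`).}
#'     \item{ec50_table}{path to an EC50 TSV; default the bundled panel.}
#'     \item{condition_means}{`"metadata"` (default; per-level means of the
#'       sample concentrations), `"bundled"` (the measured condition means),
#'       or a TSV path with columns experiment, level_label, compound,
#'       mean, sd.}
#'     \item{alpha}{significance level (default 0.05).}
#'   }
#' @param out_dir output directory.
#' @param seed integer seed controlling simulation and rarefaction.
#' @return the run manifest (list), invisibly; all tables are written as
#'   TSV under `out_dir`.
#' @export
runPipeline <- function(config, out_dir, seed = 1L) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(config$input) && !is.null(config$simulate))
        stop("config must have exactly one of 'input' or 'simulate'")

    truth <- NULL
    oe <- .stage("community_io", {
        if (!is.null(config$simulate)) {
            sc <- do.call(simulationConfig, config$simulate)
            bundle <- simulateStudy(sc, seed = seed)
            truth <- bundle$truth
            bundle$otu
        } else if (!is.null(config$input)) {
            inp <- config$input
            x <- readOtuTable(inp$otu_table,
                              orientation = inp$orientation %||% "otus")
            md <- readSampleMetadata(inp$metadata)
            tax <- if (!is.null(inp$taxonomy)) readTaxonomy(inp$taxonomy)
            OtuExperiment(otuCounts(x), sampleData = md, taxonomy = tax)
        } else stop("config must have exactly one of 'input' or 'simulate'")
    })
    depth <- config$depth
    if (!is.null(depth)) {
        if (identical(depth, "min")) depth <- min(colSums(otuCounts(oe)))
        oe <- .stage("community_io", rarefy(oe, depth, seed = seed + 2L))
    }

    compounds <- config$compounds %||%
        sub("_ng_cm2$", "",
            grep("_ng_cm2$", colnames(sampleData(oe)), value = TRUE))

    screen <- .stage("response_screen", {
        recs <- do.call(rbind, lapply(compounds, levelCorrelations, x = oe))
        cls <- classifyConsistency(recs, min_levels = config$min_levels %||% 1L)
        fr <- do.call(rbind, lapply(split(cls, list(cls$compound, cls$experiment),
                                          drop = TRUE), function(d)
            data.frame(compound = d$compound[1L], experiment = d$experiment[1L],
                       t(subgroupFractions(d)))))
        rownames(fr) <- NULL
        list(records = recs, classes = cls, fractions = fr)
    })

    enrich <- .stage("clade_enrichment", {
        lin <- otuLineages(oe)
        if (is.null(lin)) NULL else {
            clades <- assignClades(lin)
            enrichmentTable(oe, screen$classes, clades,
                            strata = config$strata %||% "per_level")
        }
    })

    defence <- .stage("defence_assessment", {
        means <- config$condition_means %||% "metadata"
        meansTab <- if (identical(means, "bundled")) conditionMeans()
        else if (identical(means, "metadata")) {
            md <- as.data.frame(sampleData(oe))
            do.call(rbind, lapply(compounds, function(comp) {
                v <- md[[paste0(comp, "_ng_cm2")]]
                key <- interaction(md$experiment, md$level_label, drop = TRUE)
                data.frame(experiment = tapply(md$experiment, key, `[`, 1L),
                           level_label = tapply(md$level_label, key, `[`, 1L),
                           compound = comp,
                           mean = as.numeric(tapply(v, key, mean)),
                           sd = as.numeric(tapply(v, key, stats::sd)),
                           row.names = NULL)
            }))
        } else utils::read.delim(means, sep = "\t", stringsAsFactors = FALSE)
        ec50 <- if (is.null(config$ec50_table)) defaultEc50Table()
                else readEc50Table(config$ec50_table)
        mat <- strainMatrix(meansTab, ec50)
        list(matrix = mat, summary = sufficiencySummary(mat))
    })

    tstats <- .stage("treatment_stats",
        treatmentStats(as.data.frame(sampleData(oe)), compounds,
                       alpha = config$alpha %||% 0.05))

    files <- c(
        correlations = .writeTsv(screen$records, file.path(out_dir, "correlations.tsv")),
        classes = .writeTsv(screen$classes, file.path(out_dir, "classes.tsv")),
        fractions = .writeTsv(screen$fractions, file.path(out_dir, "fractions.tsv")),
        inhibition = .writeTsv(defence$matrix, file.path(out_dir, "inhibition.tsv")),
        sufficiency = .writeTsv(defence$summary, file.path(out_dir, "sufficiency.tsv")),
        treatment_stats = .writeTsv(tstats, file.path(out_dir, "treatment_stats.tsv")))
    if (!is.null(enrich))
        files["enrichment"] <- .writeTsv(enrich, file.path(out_dir, "enrichment.tsv"))
    if (!is.null(truth))
        files["ground_truth"] <- .writeTsv(truth, file.path(out_dir, "ground_truth.tsv"))

    manifest <- list(
        package = "EpibiontScreen",
        version = as.character(utils::packageVersion("EpibiontScreen")),
        seed = seed,
        stages = c("community_io", "response_screen", "clade_enrichment",
                   "defence_assessment", "treatment_stats"),
        parameters = list(depth = depth,
                          compounds = compounds,
                          min_levels = config$min_levels %||% 1L,
                          strata = config$strata %||% "per_level",
                          alpha = config$alpha %||% 0.05),
        files = as.list(vapply(files, function(f)
            unname(tools::md5sum(f)), "")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    writeLines(c(
        sprintf("EpibiontScreen run (seed %d)", seed),
        sprintf("samples: %d, OTUs: %d", ncol(oe), nrow(oe)),
        sprintf("compounds screened: %s", paste(compounds, collapse = ", ")),
        sprintf("conditions with any defence: %d of %d",
                sum(defence$summary$any_defence), nrow(defence$summary))),
        file.path(out_dir, "summary.txt"))
    invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Forest-style clade enrichment plot
#'
#' Geometric-mean odds of presence with 95% confidence intervals per clade,
#' one panel per compound, compound-negative subgroups in red and
#' compound-positive in green, with significance stars from the chi-squared
#' tests; the dashed unity line marks no over/under-representation.
#'
#' @param enrichment an enrichment `data.frame` from [enrichmentTable()] or
#'   the path of a written `enrichment.tsv`.
#' @param file optional output path ([ggplot2::ggsave()]-compatible).
#' @return the ggplot object, invisibly; `NULL` with a warning when the
#'   table is empty.
#' @export
plotEnrichment <- function(enrichment, file = NULL) {
    if (is.character(enrichment))
        enrichment <- utils::read.delim(enrichment, sep = "\t",
                                        stringsAsFactors = FALSE)
    if (!NROW(enrichment)) {
        warning("empty enrichment table; nothing to plot")
        return(invisible(NULL))
    }
    enrichment$star <- ifelse(is.na(enrichment$significance) |
                              enrichment$significance == "ns", "",
                              enrichment$significance)
    p <- ggplot2::ggplot(enrichment,
            ggplot2::aes(x = .data$geometric_mean, y = .data$clade,
                         colour = .data$subgroup)) +
        ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                            colour = "grey50") +
        ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                             xmax = .data$ci_high),
                                height = 0.25,
                                position = ggplot2::position_dodge(0.6)) +
        ggplot2::geom_point(position = ggplot2::position_dodge(0.6)) +
        ggplot2::geom_text(ggplot2::aes(label = .data$star),
                           position = ggplot2::position_dodge(0.6),
                           hjust = -0.6, size = 3, show.legend = FALSE) +
        ggplot2::scale_x_log10() +
        ggplot2::scale_colour_manual(values = c(negative = "#c0392b",
                                                positive = "#27ae60")) +
        ggplot2::facet_wrap(~compound) +
        ggplot2::labs(x = "odds of presence (geometric mean, 95% CI)",
                      y = NULL, colour = "subgroup") +
        ggplot2::theme_minimal()
    if (!is.null(file)) ggplot2::ggsave(file, p, width = 8, height = 6)
    invisible(p)
}
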