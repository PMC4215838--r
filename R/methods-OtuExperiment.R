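#' Accessors for OtuExperiment
#'
#' `otuCounts` returns the integer count matrix (OTUs x samples),
#' `sampleData` the per-sample metadata `DataFrame`, and `otuLineages` the
#' named vector of Greengenes-style lineage strings (or `NULL` when no
#' taxonomy was attached).
#'
#' @param x an [OtuExperiment-class] object.
#' @return `otuCounts`: integer matrix; `sampleData`: `DataFrame`;
#'   `otuLineages`: named character vector or `NULL`.
#' @name OtuExperiment-accessors
NULL

#' @rdname OtuExperiment-accessors
#' @export
setMethod("otuCounts", "OtuExperiment", function(x)
    SummarizedExperiment::assay(x, "counts"))

#' @rdname OtuExperiment-accessors
#' @export
setMethod("sampleData", "OtuExperiment", function(x)
    SummarizedExperiment::colData(x))

#' @rdname OtuExperiment-accessors
#' @export
setMethod("otuLineages", "OtuExperiment", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if (!"lineage" %in% colnames(rd)) return(NULL)
    stats::setNames(rd$lineage, rownames(x))
})

#' @importMethodsFrom methods show
setMethod("show", "OtuExperiment", function(object) {
    m <- otuCounts(object)
    cat(sprintf("OtuExperiment: %d OTUs x %d samples\n", nrow(m), ncol(m)))
    tot <- colSums(m)
    if (ncol(m))
        cat(sprintf("  sample depths: %s%s\n",
                    paste(utils::head(tot, 5), collapse = ", "),
                    if (ncol(m) > 5) ", ..." else ""))
    cd <- SummarizedExperiment::colData(object)
    if ("experiment" %in% colnames(cd)) {
        for (e in unique(cd$experiment))
            cat(sprintf("  %s: %d levels, %d samples\n", e,
                        length(unique(cd$level_label[cd$experiment == e])),
                        sum(cd$experiment == e)))
    }
    conc <- grep("_ng_cm2$", colnames(cd), value = TRUE)
    if (length(conc))
        cat("  compounds:", paste(sub("_ng_cm2$", "", conc), collapse = ", "), "\n")
    if (!is.null(otuLineages(object)))
        cat("  taxonomy: attached\n")
    invisible(NULL)
})
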