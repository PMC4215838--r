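#' OtuExperiment: rarefied amplicon counts with treatment metadata
#'
#' `OtuExperiment` extends [SummarizedExperiment::SummarizedExperiment] to
#' hold an OTU count matrix (OTUs as rows, samples as columns) together with
#' the sample-level treatment design and per-sample surface concentrations of
#' the defence metabolites, and (optionally) a Greengenes-style lineage per
#' OTU in `rowData`.
#'
#' The `colData` is expected to carry the columns `experiment` (one of
#' `"temperature"`, `"light"`), `level_label` (e.g. `"20°C"`, `"44%"`),
#' `replicate` (integer), and one `<compound>_ng_cm2` column per measured
#' compound (concentrations in ng cm^-2).
#'
#' @section Validity:
#' \itemize{
#'   \item the `"counts"` assay exists, is numeric, non-negative and integral;
#'   \item row (OTU) and column (sample) names are present and unique;
#'   \item every sample has a positive total count;
#'   \item `(experiment, level_label, replicate)` triples are unique when the
#'         design columns are present.
#' }
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass OtuExperiment
setClass("OtuExperiment", contains = "SummarizedExperiment")

.validOtuExperiment <- function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is missing")
    m <- SummarizedExperiment::assay(object, "counts")
    if (!is.numeric(m))
        msg <- c(msg, "'counts' must be numeric")
    else {
        if (any(m < 0)) msg <- c(msg, "'counts' contains negative values")
        if (any(m != round(m))) msg <- c(msg, "'counts' contains non-integer values")
        if (ncol(m) > 0L && any(colSums(m) <= 0))
            msg <- c(msg, "every sample must have total count > 0")
    }
    rn <- rownames(object); cn <- colnames(object)
    if (is.null(rn) || anyDuplicated(rn))
        msg <- c(msg, "OTU (row) names must be present and unique")
    if (is.null(cn) || anyDuplicated(cn))
        msg <- c(msg, "sample (column) names must be present and unique")
    cd <- SummarizedExperiment::colData(object)
    if (all(c("experiment", "level_label", "replicate") %in% colnames(cd))) {
        key <- paste(cd$experiment, cd$level_label, cd$replicate, sep = "\r")
        if (anyDuplicated(key))
            msg <- c(msg, "(experiment, level_label, replicate) must be unique")
    }
    conc <- grep("_ng_cm2$", colnames(cd), value = TRUE)
    for (cc in conc)
        if (any(cd[[cc]] < 0, na.rm = TRUE))
            msg <- c(msg, sprintf("negative concentration in '%s'", cc))
    if (length(msg)) msg else TRUE
}

setValidity("OtuExperiment", .validOtuExperiment)

#' Construct an OtuExperiment
#'
#' @param counts integer matrix of OTU counts, OTUs as rows and samples as
#'   columns, with dimnames.
#' @param sampleData `data.frame` or `DataFrame` of per-sample metadata
#'   (design columns plus `<compound>_ng_cm2` concentrations); row names or a
#'   `sample_id` column must match `colnames(counts)`.
#' @param taxonomy optional named character vector or `data.frame` with an
#'   `otu_id` and `lineage` column giving a Greengenes-style lineage string
#'   (`"k__Bacteria; p__...; ..."`) per OTU.
#'
#' @return a validated [OtuExperiment-class] object.
#' @examples
#' m <- matrix(c(5L, 2L, 0L, 8L, 5L, 0L), nrow = 3,
#'             dimnames = list(paste0("otu", 1:3), c("s1", "s2")))
#' oe <- OtuExperiment(m)
#' otuCounts(oe)
#' @export
OtuExperiment <- function(counts, sampleData = NULL, taxonomy = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("'counts' must have OTU row names and sample column names")
    if (is.null(sampleData)) {
        cd <- S4Vectors::DataFrame(row.names = colnames(counts))
    } else {
        sampleData <- as.data.frame(sampleData)
        if ("sample_id" %in% colnames(sampleData)) {
            rownames(sampleData) <- sampleData$sample_id
            sampleData$sample_id <- NULL
        }
        missing <- setdiff(colnames(counts), rownames(sampleData))
        if (length(missing))
            stop("sampleData lacks entries for: ", paste(missing, collapse = ", "))
        cd <- S4Vectors::DataFrame(sampleData[colnames(counts), , drop = FALSE])
    }
    rd <- S4Vectors::DataFrame(row.names = rownames(counts))
    if (!is.null(taxonomy)) {
        if (is.data.frame(taxonomy)) {
            lin <- stats::setNames(as.character(taxonomy$lineage), taxonomy$otu_id)
        } else lin <- taxonomy
        rd$lineage <- unname(lin[rownames(counts)])
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd, rowData = rd)
    methods::new("OtuExperiment", se)
}
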