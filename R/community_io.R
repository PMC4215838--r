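#' Read an OTU count table from TSV
#'
#' Reads a tab-separated OTU table. By default OTUs are in rows (the common
#' amplicon convention: first column the OTU id, remaining columns one per
#' sample); `orientation = "samples"` reads the transposed layout.
#'
#' @param path path to a tab-separated file with a header row of ids.
#' @param orientation `"otus"` (default; OTUs in rows) or `"samples"`.
#' @return an [OtuExperiment-class] with the counts (no metadata attached).
#' @seealso [writeOtuTable()], [readSampleMetadata()], [readTaxonomy()]
#' @export
readOtuTable <- function(path, orientation = c("otus", "samples")) {
    orientation <- match.arg(orientation)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate ids in first column of ", path)
    if (anyDuplicated(colnames(df)[-1L]))
        stop("duplicate ids in header of ", path)
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m) || any(is.na(m)))
        stop("non-numeric counts in ", path)
    if (any(m < 0) || any(m != round(m)))
        stop("counts must be non-negative integers in ", path)
    rownames(m) <- ids
    if (orientation == "samples") m <- t(m)
    OtuExperiment(m)
}

#' Write an OTU count table to TSV
#'
#' Inverse of [readOtuTable()]; `readOtuTable(writeOtuTable(x, f))` restores
#' the counts exactly.
#'
#' @param x an [OtuExperiment-class].
#' @param path output file path.
#' @param orientation `"otus"` (default) or `"samples"`, as in [readOtuTable()].
#' @return `path`, invisibly.
#' @export
writeOtuTable <- function(x, path, orientation = c("otus", "samples")) {
    orientation <- match.arg(orientation)
    m <- otuCounts(x)
    if (orientation == "samples") m <- t(m)
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1L] <- if (orientation == "otus") "otu_id" else "sample_id"
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read an OTU table from a BIOM 2.1 file
#'
#' Optional reader for the BIOM interchange format; requires the
#' `biomformat` package.
#'
#' @param path path to a BIOM file.
#' @return an [OtuExperiment-class].
#' @export
readBiomTable <- function(path) {
    if (!requireNamespace("biomformat", quietly = TRUE))
        stop("the 'biomformat' package is required to read BIOM files")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")   # observations x samples
    OtuExperiment(m)
}

#' Read sample metadata
#'
#' Reads the sample metadata TSV with columns `sample_id`, `experiment`,
#' `level_label`, `replicate` and one `<compound>_ng_cm2` concentration
#' column per compound.
#'
#' @param path path to the metadata TSV.
#' @return a `data.frame` with one row per sample.
#' @export
readSampleMetadata <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("sample_id", "experiment", "level_label", "replicate")
    missing <- setdiff(need, colnames(df))
    if (length(missing))
        stop("metadata lacks columns: ", paste(missing, collapse = ", "))
    if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in ", path)
    df
}

#' Read a Greengenes-style taxonomy table
#'
#' Two tab-separated columns: OTU id and lineage string
#' (`"k__Bacteria; p__Proteobacteria; c__...; o__...; f__...; g__; s__"`).
#'
#' @param path path to the taxonomy TSV (header optional, detected from the
#'   first line).
#' @return `data.frame` with columns `otu_id`, `lineage`.
#' @export
readTaxonomy <- function(path) {
    first <- readLines(path, n = 1L)
    header <- grepl("^otu_id\t", first)
    df <- utils::read.delim(path, header = header, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df)[1:2] <- c("otu_id", "lineage")
    if (anyDuplicated(df$otu_id)) stop("duplicate otu_id in ", path)
    df[, c("otu_id", "lineage")]
}

#' Rarefy samples to a fixed depth
#'
#' Draws, independently for each sample, a random subsample of `depth` reads
#' without replacement (a multivariate hypergeometric draw, delegated to
#' [vegan::rrarefy()]). Samples whose total count is below `depth` are
#' dropped with a warning rather than padded.
#'
#' @param x an [OtuExperiment-class].
#' @param depth positive integer target depth (the study design used 1024
#'   reads per sample for the light experiment and 1352 for the temperature
#'   experiment).
#' @param seed optional integer seed; the same seed reproduces the same draw.
#' @return an [OtuExperiment-class] whose retained samples all sum to `depth`.
#'   OTU rows are preserved (some may drop to all-zero counts).
#' @examples
#' m <- matrix(c(900L, 100L), ncol = 1,
#'             dimnames = list(c("a", "b"), "s1"))
#' oe <- rarefy(OtuExperiment(m), depth = 100, seed = 1)
#' colSums(otuCounts(oe))
#' @rdname rarefy
#' @export
setMethod("rarefy", "OtuExperiment", function(x, depth, seed = NULL) {
    if (length(depth) != 1L || !is.finite(depth) || depth <= 0 ||
        depth != round(depth))
        stop("'depth' must be a positive integer")
    m <- otuCounts(x)
    tot <- colSums(m)
    keep <- tot >= depth
    if (!all(keep)) {
        warning(sprintf("dropping %d sample(s) below depth %d: %s",
                        sum(!keep), depth,
                        paste(colnames(m)[!keep], collapse = ", ")))
        if (!any(keep)) stop("no sample reaches depth ", depth)
    }
    m <- m[, keep, drop = FALSE]
    draw <- function() {
        # vegan::rrarefy works on samples-in-rows matrices; muffle its
        # smallest-count heuristic, which misfires on valid count data
        r <- withCallingHandlers(
            t(vegan::rrarefy(t(m), sample = depth)),
            warning = function(w) {
                if (grepl("smallest count", conditionMessage(w)))
                    invokeRestart("muffleWarning")
            })
        storage.mode(r) <- "integer"
        dimnames(r) <- dimnames(m)
        r
    }
    r <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    out <- x[, keep]
    SummarizedExperiment::assay(out, "counts") <- r
    methods::validObject(out)
    out
})

#' Relative abundances per sample
#'
#' Divides each sample's counts by its total, so each sample (column) sums
#' to 1.
#'
#' @param x an [OtuExperiment-class] with positive sample totals.
#' @return numeric matrix (OTUs x samples) of relative abundances in `[0, 1]`.
#' @rdname relativeAbundance
#' @export
setMethod("relativeAbundance", "OtuExperiment", function(x) {
    m <- otuCounts(x)
    tot <- colSums(m)
    if (any(tot <= 0)) stop("sample(s) with zero total count")
    sweep(m, 2L, tot, "/")
})

#' OTUs detected in a set of samples
#'
#' An OTU is detected if it has a nonzero count in at least one of the given
#' samples.
#'
#' @param x an [OtuExperiment-class].
#' @param samples character vector of sample ids (subset of `colnames(x)`).
#' @return character vector of detected OTU ids (possibly empty).
#' @export
detectedOtus <- function(x, samples) {
    unknown <- setdiff(samples, colnames(x))
    if (length(unknown))
        stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
    if (!length(samples)) return(character())
    m <- otuCounts(x)[, samples, drop = FALSE]
    rownames(m)[rowSums(m > 0) > 0]
}
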