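#' Spearman rank correlation with sign
#'
#' Spearman's rho computed as the Pearson correlation of average (midrank)
#' ranks, together with its sign. The screen uses only the sign of rho, so
#' no tie-corrected variance or p-value is computed. If either vector is
#' constant the correlation is undefined.
#'
#' @param x,y numeric vectors of equal length (>= 3); ties allowed.
#' @return list with elements `rho` (numeric, `NA` when undefined) and
#'   `sign` (one of `"positive"`, `"negative"`, `"zero"`, `"undefined"`).
#' @examples
#' spearmanRho(1:5, c(2, 4, 6, 8, 10))  # rho = 1
#' @export
spearmanRho <- function(x, y) {
    if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
    if (length(x) < 3L) stop("need at least 3 observations")
    rx <- rank(x); ry <- rank(y)
    rxc <- rx - mean(rx); ryc <- ry - mean(ry)
    sx <- sum(rxc^2); sy <- sum(ryc^2)
    if (sx == 0 || sy == 0)
        return(list(rho = NA_real_, sign = "undefined"))
    rho <- sum(rxc * ryc) / sqrt(sx * sy)
    rho <- max(-1, min(1, rho))
    list(rho = rho, sign = .rhoSign(rho))
}

# exact-zero rho (possible with ranks) breaks sign consistency; a small
# tolerance absorbs floating-point noise around 0
.rhoSign <- function(rho, tol = 1e-12) {
    ifelse(is.na(rho), "undefined",
           ifelse(rho > tol, "positive",
                  ifelse(rho < -tol, "negative", "zero")))
}

#' Per-treatment-level correlations between OTU abundance and a compound
#'
#' For every treatment level of every experiment, correlates (Spearman) the
#' relative abundance of each OTU detected at that level with the surface
#' concentration of `compound` across that level's replicates. Because
#' treatment effects on the community are confounded with direct effects on
#' the metabolites, correlations are computed strictly within levels, never
#' across them.
#'
#' An OTU is *detected* at a level if it has a nonzero count in at least one
#' of the level's replicate samples; undetected OTUs produce no record for
#' that level. OTUs whose abundance is constant across the replicates (or a
#' constant concentration vector) give `sign = "undefined"`.
#'
#' @param x an [OtuExperiment-class] whose `colData` has `experiment`,
#'   `level_label`, `replicate` and `<compound>_ng_cm2` columns.
#' @param compound compound name, e.g. `"proline"`; concentrations are read
#'   from the `<compound>_ng_cm2` metadata column.
#' @return `data.frame` with columns `otu_id`, `compound`, `experiment`,
#'   `level_label`, `rho`, `n`, `sign` — one row per (detected OTU, level).
#' @seealso [classifyConsistency()], [subgroupFractions()]
#' @export
levelCorrelations <- function(x, compound) {
    cd <- as.data.frame(sampleData(x))
    col <- paste0(compound, "_ng_cm2")
    if (!col %in% colnames(cd))
        stop("compound '", compound, "' missing from metadata (no column '",
             col, "')")
    counts <- otuCounts(x)
    ab <- relativeAbundance(x)
    out <- list()
    for (exper in unique(cd$experiment)) {
        for (lvl in unique(cd$level_label[cd$experiment == exper])) {
            sids <- rownames(cd)[cd$experiment == exper & cd$level_label == lvl]
            n <- length(sids)
            if (n < 3L)
                stop(sprintf("level '%s' of experiment '%s' has %d replicate(s); >= 3 required",
                             lvl, exper, n))
            y <- cd[sids, col]
            det <- rowSums(counts[, sids, drop = FALSE] > 0) > 0
            if (!any(det)) next
            a <- ab[det, sids, drop = FALSE]
            rx <- t(apply(a, 1L, rank))
            ry <- rank(y)
            rxc <- rx - rowMeans(rx)
            ryc <- ry - mean(ry)
            sx <- rowSums(rxc^2)
            sy <- sum(ryc^2)
            rho <- if (sy == 0) rep(NA_real_, nrow(a)) else {
                r <- as.vector(rxc %*% ryc) / sqrt(sx * sy)
                r[sx == 0] <- NA_real_
                pmax(-1, pmin(1, r))
            }
            out[[length(out) + 1L]] <- data.frame(
                otu_id = rownames(a), compound = compound,
                experiment = exper, level_label = lvl,
                rho = rho, n = n, sign = .rhoSign(rho),
                stringsAsFactors = FALSE, row.names = NULL)
        }
    }
    if (!length(out))
        return(data.frame(otu_id = character(), compound = character(),
                          experiment = character(), level_label = character(),
                          rho = numeric(), n = integer(), sign = character(),
                          stringsAsFactors = FALSE))
    do.call(rbind, out)
}

#' Classify OTUs by sign consistency across treatment levels
#'
#' Groups correlation records per (OTU, compound, experiment) and labels
#' each group:
#' \itemize{
#'   \item `positive` — every evaluable level has a positive sign;
#'   \item `negative` — every evaluable level has a negative sign;
#'   \item `neutral` — mixed positive/negative signs, or any exactly-zero
#'     rho among evaluable levels;
#'   \item `unevaluable` — no level yields a defined sign (all constant).
#' }
#' `levels_evaluated` counts levels with a defined, nonzero sign. With the
#' default `min_levels = 1` an OTU evaluable at a single level can be
#' classified from that level alone; raising `min_levels` demotes
#' consistent-but-thin calls (fewer evaluated levels than required) to
#' `unevaluable`.
#'
#' @param records output of [levelCorrelations()] (possibly concatenated over
#'   compounds).
#' @param min_levels minimum number of evaluated levels required to call an
#'   OTU positive or negative (default 1).
#' @return `data.frame` with columns `otu_id`, `compound`, `experiment`,
#'   `label`, `levels_evaluated`.
#' @export
classifyConsistency <- function(records, min_levels = 1L) {
    stopifnot(is.data.frame(records))
    if (!nrow(records))
        return(data.frame(otu_id = character(), compound = character(),
                          experiment = character(), label = character(),
                          levels_evaluated = integer(),
                          stringsAsFactors = FALSE))
    key <- paste(records$otu_id, records$compound, records$experiment,
                 sep = "\r")
    sgn <- records$sign
    pos <- rowsum((sgn == "positive") + 0, key)
    neg <- rowsum((sgn == "negative") + 0, key)
    zer <- rowsum((sgn == "zero") + 0, key)
    ks <- rownames(pos)
    npos <- pos[, 1L]; nneg <- neg[, 1L]; nzer <- zer[, 1L]
    evaluated <- npos + nneg
    label <- rep("unevaluable", length(ks))
    label[nzer > 0 | (npos > 0 & nneg > 0)] <- "neutral"
    ok <- nzer == 0
    label[ok & npos > 0 & nneg == 0 & npos >= min_levels] <- "positive"
    label[ok & nneg > 0 & npos == 0 & nneg >= min_levels] <- "negative"
    parts <- do.call(rbind, strsplit(ks, "\r", fixed = TRUE))
    data.frame(otu_id = parts[, 1L], compound = parts[, 2L],
               experiment = parts[, 3L], label = label,
               levels_evaluated = as.integer(evaluated),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Fractions of OTUs per response class
#'
#' @param classes output of [classifyConsistency()] for one
#'   (compound, experiment) stratum or any set whose rows are to be pooled.
#' @return named numeric vector over `positive`, `negative`, `neutral`,
#'   `unevaluable`, summing to 1.
#' @export
subgroupFractions <- function(classes) {
    if (!is.data.frame(classes) || !nrow(classes))
        stop("'classes' must be a non-empty data.frame")
    lv <- c("positive", "negative", "neutral", "unevaluable")
    tab <- table(factor(classes$label, levels = lv))
    stats::setNames(as.numeric(tab) / nrow(classes), lv)
}
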