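#' Odds of presence of a clade within an OTU subgroup
#'
#' Compares a clade's odds inside a subgroup of OTUs against its odds in the
#' total community:
#' \deqn{odds = \frac{a/(m-a)}{A/(M-A)}}
#' where `a` of the `m` subgroup OTUs and `A` of the `M` community OTUs
#' belong to the clade. Odds > 1 mean the clade is better represented inside
#' the subgroup than in the community at large; < 1 the inverse. When any of
#' `a`, `m - a`, `A`, `M - A` is zero, 0.5 is added to all four terms
#' (Haldane–Anscombe continuity correction) and the cell is flagged. An
#' exactly proportional cell (`a/m == A/M`, e.g. a clade saturating both
#' subgroup and community) is the null case and returns odds 1 uncorrected.
#'
#' @param a clade OTUs inside the subgroup.
#' @param m subgroup size.
#' @param A clade OTUs in the total community.
#' @param M total community size.
#' @return list with `odds` (positive numeric, `NA` if `m` or `M` is 0) and
#'   `corrected` (logical: continuity correction applied).
#' @examples
#' oddsOfPresence(5, 10, 10, 100)$odds  # (5/5)/(10/90) = 9
#' @export
oddsOfPresence <- function(a, m, A, M) {
    if (any(c(a, m, A, M) < 0)) stop("counts must be non-negative")
    if (a > m || A > M || m > M || a > A)
        stop("require a <= min(m, A), m <= M, A <= M")
    if (m == 0 || M == 0) {
        warning("odds undefined for m = 0 or M = 0; cell skipped")
        return(list(odds = NA_real_, corrected = FALSE))
    }
    if (a * M == A * m) return(list(odds = 1, corrected = FALSE))
    cells <- c(a, m - a, A, M - A)
    corrected <- any(cells == 0)
    if (corrected) cells <- cells + 0.5
    list(odds = (cells[1L] / cells[2L]) / (cells[3L] / cells[4L]),
         corrected = corrected)
}

#' Pool odds across strata by geometric mean with a 95% confidence interval
#'
#' The geometric mean is `exp(mean(log(odds)))`; the interval is the t-based
#' 95% CI on the log scale, back-transformed. Intervals excluding 1 indicate
#' odds significantly different between subgroup and total community. With a
#' single stratum the interval degenerates to the point estimate and is
#' flagged.
#'
#' @param odds vector of strictly positive odds, one per stratum (continuity
#'   correction must already have been applied upstream).
#' @param conf confidence level (default 0.95).
#' @return list with `geometric_mean`, `ci_low`, `ci_high`, `k` (number of
#'   strata) and `degenerate` (TRUE when `k == 1`).
#' @export
pooledOdds <- function(odds, conf = 0.95) {
    if (!length(odds)) stop("need at least one odds value")
    if (any(!is.finite(odds) | odds <= 0))
        stop("all odds must be positive and finite")
    k <- length(odds)
    lo <- log(odds)
    gm <- exp(mean(lo))
    if (k == 1L)
        return(list(geometric_mean = gm, ci_low = gm, ci_high = gm,
                    k = 1L, degenerate = TRUE))
    half <- stats::qt(1 - (1 - conf) / 2, df = k - 1L) *
        stats::sd(lo) / sqrt(k)
    list(geometric_mean = gm, ci_low = exp(mean(lo) - half),
         ci_high = exp(mean(lo) + half), k = k, degenerate = FALSE)
}

#' Chi-squared test of clade representation within a subgroup
#'
#' One-degree-of-freedom goodness-of-fit test of the observed clade count
#' `a` inside a subgroup of size `m` against its expectation under the total
#' community's composition, `E = m A / M`:
#' \deqn{\chi^2 = (a - E)^2 (1/E + 1/(m - E))}
#'
#' @inheritParams oddsOfPresence
#' @return list with `chi2`, `p_value`, `significance`
#'   (`***` p < 0.001, `**` p < 0.025, `*` p < 0.05, else `ns`); all `NA`
#'   with a warning when `E` is 0 or `m`.
#' @examples
#' chiSquareGof(20, 50, 100, 500)$chi2  # E = 10 -> 100 * (1/10 + 1/40) = 12.5
#' @export
chiSquareGof <- function(a, m, A, M) {
    if (m < 1) stop("subgroup size m must be >= 1")
    E <- m * A / M
    if (E <= 0 || E >= m) {
        warning("expected count degenerate (E = ", format(E), "); test skipped")
        return(list(chi2 = NA_real_, p_value = NA_real_,
                    significance = NA_character_))
    }
    chi2 <- (a - E)^2 * (1 / E + 1 / (m - E))
    p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
    list(chi2 = chi2, p_value = p, significance = significanceStars(p))
}

#' Significance stars
#'
#' @param p p-value(s).
#' @return `"***"` for p < 0.001, `"**"` for p < 0.025, `"*"` for p < 0.05,
#'   `"ns"` otherwise.
#' @export
significanceStars <- function(p) {
    ifelse(p < 0.001, "***", ifelse(p < 0.025, "**",
        ifelse(p < 0.05, "*", "ns")))
}

#' Clade enrichment within compound-positive and compound-negative subgroups
#'
#' For every (clade, compound, subgroup in positive/negative) combination,
#' computes one odds-of-presence value per stratum, pools them as geometric
#' mean with 95% CI, and tests divergence of observed from expected clade
#' counts with a single pooled chi-squared test.
#'
#' With `strata = "per_level"` (default) each treatment level of each
#' experiment contributes one stratum whose universe is the set of OTUs
#' detected at that level (subgroup membership taken from the experiment-wide
#' classification); with `"per_experiment"` each experiment contributes one
#' stratum over all its classified OTUs. The chi-squared test always uses
#' counts pooled across experiments (universe = classified OTUs per
#' experiment), 1 df, no Yates correction, and no multiple-testing
#' correction (set `p_adjust = "BH"` to add Benjamini–Hochberg).
#'
#' @param x the [OtuExperiment-class] the classification came from (used for
#'   per-level detection universes).
#' @param classes output of [classifyConsistency()].
#' @param clades named character vector OTU id -> clade, from
#'   [assignClades()].
#' @param strata `"per_level"` or `"per_experiment"`.
#' @param p_adjust `"none"` (default) or a [stats::p.adjust()] method applied
#'   within each compound x subgroup family.
#' @return `data.frame` with columns `clade`, `compound`, `subgroup`, `k`,
#'   `geometric_mean`, `ci_low`, `ci_high`, `chi2`, `p_value`,
#'   `significance`, `n_continuity_cells`. Clades absent from every stratum
#'   are omitted with a message.
#' @export
enrichmentTable <- function(x, classes, clades,
                            strata = c("per_level", "per_experiment"),
                            p_adjust = "none") {
    strata <- match.arg(strata)
    stopifnot(is.data.frame(classes), nrow(classes) > 0)
    if (!all(classes$otu_id %in% names(clades)))
        stop("'clades' must cover every classified OTU")
    cd <- as.data.frame(sampleData(x))
    allClades <- unique(unname(clades))
    rows <- list()
    for (comp in unique(classes$compound)) {
        cls <- classes[classes$compound == comp, ]
        for (sub in c("positive", "negative")) {
            # per-stratum presence counts
            strat <- list()
            for (exper in unique(cls$experiment)) {
                clsE <- cls[cls$experiment == exper, ]
                members <- clsE$otu_id[clsE$label == sub]
                if (strata == "per_level") {
                    lvls <- unique(cd$level_label[cd$experiment == exper])
                    for (lvl in lvls) {
                        sids <- rownames(cd)[cd$experiment == exper &
                                             cd$level_label == lvl]
                        U <- intersect(detectedOtus(x, sids), clsE$otu_id)
                        strat[[length(strat) + 1L]] <-
                            list(universe = U, members = intersect(members, U))
                    }
                } else {
                    strat[[length(strat) + 1L]] <-
                        list(universe = clsE$otu_id, members = members)
                }
            }
            # chi2 counts pooled across experiments (experiment-wide universes)
            pooledCounts <- function(clade) {
                a <- m <- A <- M <- 0
                for (exper in unique(cls$experiment)) {
                    clsE <- cls[cls$experiment == exper, ]
                    U <- clsE$otu_id
                    S <- clsE$otu_id[clsE$label == sub]
                    inClade <- clades[U] == clade
                    a <- a + sum(inClade[match(S, U)])
                    m <- m + length(S)
                    A <- A + sum(inClade)
                    M <- M + length(U)
                }
                c(a = a, m = m, A = A, M = M)
            }
            for (clade in allClades) {
                odds <- numeric(); ncorr <- 0L
                for (st in strat) {
                    M <- length(st$universe); m <- length(st$members)
                    if (M == 0 || m == 0) next
                    A <- sum(clades[st$universe] == clade)
                    a <- sum(clades[st$members] == clade)
                    o <- oddsOfPresence(a, m, A, M)
                    odds <- c(odds, o$odds)
                    ncorr <- ncorr + o$corrected
                }
                if (!length(odds)) {
                    message("clade '", clade, "' absent from every stratum for ",
                            comp, "/", sub, "; row omitted")
                    next
                }
                po <- pooledOdds(odds)
                pc <- pooledCounts(clade)
                ct <- if (pc["m"] == 0 || pc["A"] == 0 || pc["A"] == pc["M"])
                    list(chi2 = NA_real_, p_value = NA_real_,
                         significance = NA_character_)
                else chiSquareGof(pc["a"], pc["m"], pc["A"], pc["M"])
                rows[[length(rows) + 1L]] <- data.frame(
                    clade = clade, compound = comp, subgroup = sub,
                    k = po$k, geometric_mean = po$geometric_mean,
                    ci_low = po$ci_low, ci_high = po$ci_high,
                    chi2 = unname(ct$chi2), p_value = unname(ct$p_value),
                    significance = unname(ct$significance),
                    n_continuity_cells = ncorr,
                    stringsAsFactors = FALSE)
            }
        }
    }
    out <- do.call(rbind, rows)
    if (p_adjust != "none") {
        for (comp in unique(out$compound)) for (sub in unique(out$subgroup)) {
            sel <- out$compound == comp & out$subgroup == sub
            out$p_value[sel] <- stats::p.adjust(out$p_value[sel],
                                                method = p_adjust)
            out$significance[sel] <- significanceStars(out$p_value[sel])
        }
    }
    rownames(out) <- NULL
    out
}
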