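.asGrouped <- function(data) {
    stopifnot(is.list(data), !is.null(names(data)))
    if (length(data) < 2L) stop("need at least 2 groups")
    if (any(vapply(data, length, 1L) < 2L))
        stop("every group needs at least 2 observations")
    data.frame(y = unlist(data, use.names = FALSE),
               g = factor(rep(names(data), vapply(data, length, 1L)),
                          levels = names(data)))
}

#' One-way analysis of variance
#'
#' Classical between/within sums-of-squares decomposition over the groups of
#' a named list (one numeric vector per treatment level), via [stats::aov()].
#'
#' @param data named list of numeric vectors, one per group; >= 2 groups,
#'   each with >= 2 observations.
#' @return list with `F`, `df_between`, `df_within`, `p_value`, and
#'   `degenerate` (TRUE when the within-group variance is zero, in which
#'   case `F` and `p_value` are `NA`).
#' @seealso [checkAssumptions()], [tukeyHsd()]
#' @export
oneWayAnova <- function(data) {
    df <- .asGrouped(data)
    fit <- stats::aov(y ~ g, data = df)
    tab <- summary(fit)[[1L]]
    if (tab["Residuals", "Sum Sq"] <= .Machine$double.eps * sum(df$y^2)) {
        return(list(F = NA_real_, df_between = tab[1L, "Df"],
                    df_within = tab["Residuals", "Df"], p_value = NA_real_,
                    degenerate = TRUE))
    }
    list(F = tab[1L, "F value"], df_between = tab[1L, "Df"],
         df_within = tab["Residuals", "Df"],
         p_value = tab[1L, "Pr(>F)"], degenerate = FALSE)
}

#' ANOVA assumption checks
#'
#' Shapiro–Wilk on the pooled within-group residuals (normality) and
#' Levene's test, centred on group means (homoscedasticity), both at
#' `alpha`. With constant data, or fewer than 3 residuals, the
#' corresponding test is skipped and its flag is `NA`.
#'
#' @param data named list of numeric vectors, one per group.
#' @param alpha significance level for the flags (default 0.05).
#' @return list with `shapiro_p`, `normal` (flag), `levene_p`,
#'   `homoscedastic` (flag).
#' @export
checkAssumptions <- function(data, alpha = 0.05) {
    df <- .asGrouped(data)
    res <- df$y - stats::ave(df$y, df$g)
    shapiro_p <- NA_real_
    if (length(res) >= 3L && stats::sd(res) > 0)
        shapiro_p <- stats::shapiro.test(res)$p.value
    levene_p <- NA_real_
    if (stats::sd(df$y) > 0) {
        lt <- car::leveneTest(y ~ g, data = df, center = "mean")
        levene_p <- lt[1L, "Pr(>F)"]
    }
    list(shapiro_p = shapiro_p,
         normal = if (is.na(shapiro_p)) NA else shapiro_p >= alpha,
         levene_p = levene_p,
         homoscedastic = if (is.na(levene_p)) NA else levene_p >= alpha)
}

#' Box-Cox power transformation
#'
#' Chooses the power lambda maximizing the profile log-likelihood (via
#' [MASS::boxcox()]) on a grid from -3 to 3 in steps of 0.01, and applies
#' `y^(lambda) = (y^lambda - 1)/lambda` (natural log at lambda = 0). Used on
#' responses that fail the homoscedasticity check before ANOVA.
#'
#' @param y positive numeric vector. If zeros are present and `shift` is
#'   `TRUE`, a documented shift of half the smallest positive value is added
#'   first (reported in the result).
#' @param shift allow an additive shift for zero values (default `FALSE`).
#' @return list with `lambda`, `transformed`, `shift` (the shift applied,
#'   0 when none).
#' @seealso [boxCoxInverse()]
#' @export
boxCox <- function(y, shift = FALSE) {
    delta <- 0
    if (any(y < 0)) stop("Box-Cox requires non-negative data")
    if (any(y == 0)) {
        if (!shift) stop("zeros present; set shift = TRUE to apply a shift")
        delta <- min(y[y > 0]) / 2
        y <- y + delta
    }
    grid <- seq(-3, 3, by = 0.01)
    bc <- MASS::boxcox(y ~ 1, data = data.frame(y = y), lambda = grid,
                       plotit = FALSE)
    lambda <- bc$x[which.max(bc$y)]
    z <- if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
    list(lambda = lambda, transformed = z, shift = delta)
}

#' Invert a Box-Cox transformation
#'
#' @param z transformed values.
#' @param lambda the power used.
#' @param shift the shift reported by [boxCox()] (default 0).
#' @return the original-scale values.
#' @export
boxCoxInverse <- function(z, lambda, shift = 0) {
    y <- if (abs(lambda) < 1e-12) exp(z) else (lambda * z + 1)^(1 / lambda)
    y - shift
}

#' Tukey HSD with compact letter display
#'
#' Pairwise comparisons of group means via the studentized range
#' ([stats::TukeyHSD()]) followed by a compact letter display: groups
#' sharing a letter are not significantly different at `alpha`. Letters are
#' built by the greedy insert–absorb algorithm (start from one set holding
#' all groups; split every set containing a significantly different pair;
#' drop sets contained in others), so the display is a deterministic
#' function of the pairwise decision matrix. Letter sets are not unique in
#' general; this construction is the documented convention.
#'
#' @param data named list of numeric vectors, one per group.
#' @param alpha family-wise significance level (default 0.05).
#' @return list with `pairs` (`data.frame`: `group1`, `group2`, `diff`,
#'   `p_adj`, `significant`) and `letters` (named character vector,
#'   group -> letter string).
#' @export
tukeyHsd <- function(data, alpha = 0.05) {
    df <- .asGrouped(data)
    fit <- stats::aov(y ~ g, data = df)
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairs <- data.frame(group1 = vapply(nm, `[`, "", 1L),
                        group2 = vapply(nm, `[`, "", 2L),
                        diff = tk[, "diff"], p_adj = tk[, "p adj"],
                        significant = tk[, "p adj"] < alpha,
                        row.names = NULL, stringsAsFactors = FALSE)
    groups <- levels(df$g)
    sig <- pairs[pairs$significant, , drop = FALSE]
    sets <- list(groups)
    if (nrow(sig)) {
        for (i in seq_len(nrow(sig))) {
            g1 <- sig$group1[i]; g2 <- sig$group2[i]
            newSets <- list()
            for (s in sets) {
                if (g1 %in% s && g2 %in% s) {
                    newSets <- c(newSets, list(setdiff(s, g1)),
                                 list(setdiff(s, g2)))
                } else newSets <- c(newSets, list(s))
            }
            # absorb: drop sets contained in another set
            keep <- rep(TRUE, length(newSets))
            for (a in seq_along(newSets)) for (b in seq_along(newSets)) {
                if (a != b && keep[a] && keep[b] &&
                    all(newSets[[a]] %in% newSets[[b]]) &&
                    !(all(newSets[[b]] %in% newSets[[a]]) && a < b))
                    keep[a] <- FALSE
            }
            sets <- newSets[keep]
        }
    }
    # order sets by the mean of their best group for stable lettering
    gmeans <- vapply(data, mean, 0)[groups]
    ord <- order(vapply(sets, function(s) min(match(s, groups[order(-gmeans)])), 1L))
    sets <- sets[ord]
    letters_ <- stats::setNames(rep("", length(groups)), groups)
    for (i in seq_along(sets))
        letters_[sets[[i]]] <- paste0(letters_[sets[[i]]], letters[i])
    list(pairs = pairs, letters = letters_)
}

#' Ordinary least-squares line with r-squared
#'
#' @param x,y numeric vectors of equal length >= 3; `x` must not be
#'   constant.
#' @return list with `slope`, `intercept`, `r_squared`
#'   (`1 - SSres/SStot`, equal to the squared Pearson correlation) and
#'   `p_value` of the slope.
#' @export
linearFit <- function(x, y) {
    if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
    if (length(x) < 3L) stop("need at least 3 observations")
    if (stats::sd(x) == 0) stop("'x' is constant")
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = sm$r.squared,
         p_value = sm$coefficients[2L, 4L])
}

#' Per-compound treatment statistics
#'
#' Runs, for each compound and experiment, the concentration-versus-level
#' analysis: assumption checks, a Box-Cox transform of the response when
#' homoscedasticity fails, one-way ANOVA, and Tukey HSD letters.
#'
#' @param metadata sample metadata `data.frame` (columns `experiment`,
#'   `level_label`, `<compound>_ng_cm2`).
#' @param compounds compounds to analyse (default: all `*_ng_cm2` columns).
#' @param alpha significance level (default 0.05).
#' @return `data.frame` with one row per (experiment, compound): `F`,
#'   `df_between`, `df_within`, `p_value`, `shapiro_p`, `levene_p`,
#'   `boxcox_lambda` (`NA` when not applied), and `letters` (compact letter
#'   display collapsed to `"level=letter"` pairs).
#' @export
treatmentStats <- function(metadata,
                           compounds = sub("_ng_cm2$", "",
                               grep("_ng_cm2$", colnames(metadata), value = TRUE)),
                           alpha = 0.05) {
    out <- list()
    for (exper in unique(metadata$experiment)) {
        md <- metadata[metadata$experiment == exper, ]
        for (comp in compounds) {
            vals <- split(md[[paste0(comp, "_ng_cm2")]], md$level_label)
            chk <- checkAssumptions(vals, alpha)
            lambda <- NA_real_
            if (isFALSE(chk$homoscedastic)) {
                y <- unlist(vals, use.names = FALSE)
                bc <- boxCox(y, shift = any(y == 0))
                lambda <- bc$lambda
                vals <- split(bc$transformed,
                              rep(names(vals), lengths(vals)))
            }
            an <- oneWayAnova(vals)
            tk <- tukeyHsd(vals, alpha)
            out[[length(out) + 1L]] <- data.frame(
                experiment = exper, compound = comp, F = an$F,
                df_between = an$df_between, df_within = an$df_within,
                p_value = an$p_value, shapiro_p = chk$shapiro_p,
                levene_p = chk$levene_p, boxcox_lambda = lambda,
                letters = paste(names(tk$letters), tk$letters,
                                sep = "=", collapse = ";"),
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, out)
}
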