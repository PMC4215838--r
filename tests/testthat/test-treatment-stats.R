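test_that("two-group ANOVA F equals the squared pooled t statistic", {
    withr::with_seed(2, {
        a <- rnorm(8); b <- rnorm(8, 0.5)
        an <- oneWayAnova(list(a = a, b = b))
        tt <- t.test(a, b, var.equal = TRUE)
        expect_equal(an$F, unname(tt$statistic)^2)
        expect_equal(an$p_value, tt$p.value)
    })
})

test_that("ANOVA matches an independent sums-of-squares computation", {
    withr::with_seed(4, {
        groups <- lapply(1:5, function(i) rnorm(5, mean = i / 4))
        names(groups) <- paste0("g", 1:5)
        an <- oneWayAnova(groups)
        # hand computation from first principles
        all_ <- unlist(groups); gm <- mean(all_)
        ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
        ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
        Fref <- (ssb / 4) / (ssw / 20)
        expect_equal(an$F, Fref)
        expect_equal(an$df_between, 4)
        expect_equal(an$df_within, 20)
        expect_equal(an$p_value, pf(Fref, 4, 20, lower.tail = FALSE))
        # invariant to shift and scale
        sh <- oneWayAnova(lapply(groups, function(g) 3 * g + 10))
        expect_equal(sh$F, an$F)
    })
})

test_that("degenerate constant groups are flagged", {
    an <- oneWayAnova(list(a = c(1, 1), b = c(1, 1)))
    expect_true(an$degenerate)
    expect_true(is.na(an$F))
    expect_error(oneWayAnova(list(a = 1, b = c(1, 2))), "at least 2")
    expect_error(oneWayAnova(list(a = c(1, 2))), "2 groups")
})

test_that("assumption checks flag heteroscedasticity and skip constants", {
    withr::with_seed(16, {
        eq <- list(a = rnorm(25), b = rnorm(25))
        chk <- checkAssumptions(eq)
        expect_true(chk$normal)
        expect_true(chk$homoscedastic)
        une <- list(a = rnorm(25), b = rnorm(25, sd = 10))
        expect_false(checkAssumptions(une)$homoscedastic)
    })
    const <- checkAssumptions(list(a = c(2, 2, 2), b = c(2, 2, 2)))
    expect_true(is.na(const$shapiro_p))
    expect_true(is.na(const$normal))
})

test_that("Levene holds its nominal size under equal variances", {
    rej <- withr::with_seed(8, vapply(1:400, function(i) {
        d <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10))
        checkAssumptions(d)$levene_p < 0.05
    }, NA))
    expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 400) + 0.02)
})

test_that("Box-Cox recovers the log and identity limits", {
    withr::with_seed(10, {
        ln <- exp(rnorm(400))
        expect_lt(abs(boxCox(ln)$lambda), 0.15)
        nm <- rnorm(400, mean = 20, sd = 1)
        expect_lt(abs(boxCox(nm)$lambda - 1), 0.5)
    })
    # invertibility
    y <- c(0.5, 1, 2, 7)
    for (lam in c(-1, 0, 0.33, 2)) {
        z <- if (lam == 0) log(y) else (y^lam - 1) / lam
        expect_equal(boxCoxInverse(z, lam), y, tolerance = 1e-9)
    }
    expect_error(boxCox(c(0, 1, 2)), "shift")
    bc <- boxCox(c(0, 1, 2), shift = TRUE)
    expect_gt(bc$shift, 0)
})

test_that("Tukey letters join indistinguishable groups and split outliers", {
    withr::with_seed(12, {
        same <- lapply(1:4, function(i) rnorm(6))
        names(same) <- paste0("g", 1:4)
        tk <- tukeyHsd(same)
        expect_true(all(tk$letters == tk$letters[1]))
        far <- list(lo1 = rnorm(6), lo2 = rnorm(6), hi = rnorm(6, 50))
        tk2 <- tukeyHsd(far)
        expect_false(tk2$letters["hi"] %in% tk2$letters[c("lo1", "lo2")])
        expect_identical(tk2$letters[["lo1"]], tk2$letters[["lo2"]])
        # letters are a pure function of the inputs
        expect_identical(tukeyHsd(far)$letters, tk2$letters)
        # groups sharing a letter are exactly the non-significant pairs
        for (i in seq_len(nrow(tk2$pairs))) {
            shared <- any(strsplit(tk2$letters[[tk2$pairs$group1[i]]], "")[[1]] %in%
                          strsplit(tk2$letters[[tk2$pairs$group2[i]]], "")[[1]])
            expect_identical(shared, !tk2$pairs$significant[i])
        }
    })
})

test_that("linearFit matches the normal equations", {
    x <- c(1, 2, 3, 4, 5)
    # summary.lm warns about the numerically perfect fit; that is the point
    exact <- suppressWarnings(linearFit(x, 2 * x + 1))
    expect_equal(exact$slope, 2)
    expect_equal(exact$intercept, 1)
    expect_equal(exact$r_squared, 1)
    withr::with_seed(14, {
        x <- rnorm(30); y <- 1.5 * x + rnorm(30)
        fit <- linearFit(x, y)
        # normal equations by hand
        bref <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
        expect_equal(fit$slope, bref)
        expect_equal(fit$intercept, mean(y) - bref * mean(x))
        expect_equal(fit$r_squared, cor(x, y)^2)
        # orthogonal response: slope and r2 collapse to 0
        yo <- resid(lm(rnorm(30) ~ x))
        fo <- linearFit(x, yo)
        expect_lt(abs(fo$slope), 1e-10)
        expect_lt(fo$r_squared, 1e-10)
    })
    expect_error(linearFit(rep(1, 5), 1:5), "constant")
})

test_that("treatmentStats runs the per-compound univariate battery", {
    md <- generateConcentrations(simulationConfig(), seed = 3)
    ts <- treatmentStats(md, compounds = c("dmsp", "proline"))
    expect_equal(nrow(ts), 4L)  # 2 experiments x 2 compounds
    expect_true(all(ts$df_between %in% c(4L, 5L)))
    expect_true(all(is.na(ts$p_value) | (ts$p_value >= 0 & ts$p_value <= 1)))
    expect_true(all(grepl("=", ts$letters)))
})
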