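test_that("oddsOfPresence follows the subgroup-vs-community formula", {
    # proportional composition gives odds exactly 1
    expect_equal(oddsOfPresence(2, 10, 20, 100)$odds, 1)
    # hand-computed: (5/5)/(10/90) = 9
    o <- oddsOfPresence(5, 10, 10, 100)
    expect_equal(o$odds, 9)
    expect_false(o$corrected)
    # zero cell: all four terms get +0.5 -> (0.5/10.5)/(10.5/90.5)
    oc <- oddsOfPresence(0, 10, 10, 100)
    expect_equal(oc$odds, (0.5 / 10.5) / (10.5 / 90.5))
    expect_true(oc$corrected)
    expect_warning(oddsOfPresence(0, 0, 10, 100), "skipped")
    expect_error(oddsOfPresence(5, 4, 10, 100), "a <= min")
})

test_that("complement duality holds for two-clade schemes", {
    withr::with_seed(21, {
        for (i in 1:50) {
            M <- sample(50:200, 1); A <- sample(10:(M - 10), 1)
            m <- sample(5:(M - 5), 1)
            a <- max(max(0, m - (M - A)) + 1,
                     min(min(m, A) - 1, rpois(1, m * A / M)))
            if (a <= 0 || a >= min(m, A)) next  # keep cells nonzero
            x <- oddsOfPresence(a, m, A, M)$odds
            y <- oddsOfPresence(m - a, m, M - A, M)$odds
            expect_equal(x, 1 / y, tolerance = 1e-12)
        }
    })
})

test_that("pooledOdds returns geometric means with t-based intervals", {
    z <- pooledOdds(c(2, 2, 2, 2))
    expect_equal(z$geometric_mean, 2)
    expect_equal(z$ci_low, 2)
    expect_equal(z$ci_high, 2)
    expect_equal(pooledOdds(c(0.5, 2))$geometric_mean, 1)
    # independent arithmetic oracle on ln odds
    odds <- c(1, 2, 4, 8)
    lo <- log(odds)
    se <- sd(lo) / sqrt(4)
    got <- pooledOdds(odds)
    expect_equal(got$geometric_mean, exp(mean(lo)))
    expect_equal(got$ci_low, exp(mean(lo) - qt(0.975, 3) * se))
    expect_equal(got$ci_high, exp(mean(lo) + qt(0.975, 3) * se))
    expect_true(got$ci_low <= got$geometric_mean &&
                got$geometric_mean <= got$ci_high)
    # single stratum degenerates to the point estimate
    single <- pooledOdds(3)
    expect_true(single$degenerate)
    expect_equal(single$ci_low, 3)
    expect_error(pooledOdds(c(1, 0)), "positive")
    expect_error(pooledOdds(numeric()), "at least one")
})

test_that("chiSquareGof matches hand arithmetic and maps stars", {
    # observed equals expected
    z <- chiSquareGof(10, 50, 100, 500)
    expect_equal(z$chi2, 0)
    expect_equal(z$p_value, 1)
    expect_identical(z$significance, "ns")
    # E = 10 -> 100 * (1/10 + 1/40) = 12.5
    z2 <- chiSquareGof(20, 50, 100, 500)
    expect_equal(z2$chi2, 12.5)
    expect_equal(z2$p_value, pchisq(12.5, 1, lower.tail = FALSE))
    expect_identical(z2$significance, "***")
    # swapping clade with its complement leaves chi2 unchanged
    expect_equal(chiSquareGof(30, 50, 400, 500)$chi2,
                 chiSquareGof(20, 50, 100, 500)$chi2)
    expect_warning(chiSquareGof(0, 5, 0, 100), "skipped")
    expect_identical(significanceStars(c(0.03, 0.02, 5e-4, 0.2)),
                     c("*", "**", "***", "ns"))
})

test_that("pooled odds CIs cover the true geometric mean at ~95%", {
    cover <- withr::with_seed(31, vapply(1:2000, function(i) {
        odds <- rlnorm(11, meanlog = 0.3, sdlog = 0.8)
        ci <- pooledOdds(odds)
        ci$ci_low <= exp(0.3) && exp(0.3) <= ci$ci_high
    }, NA))
    expect_lt(abs(mean(cover) - 0.95), 3 * sqrt(0.95 * 0.05 / 2000))
})

test_that("a single all-covering clade always has odds 1", {
    b <- simulateStudy(oneExperimentConfig(n_otus = 120), seed = 8)
    recs <- levelCorrelations(b$otu, "dmsp")
    cls <- classifyConsistency(recs)
    clades <- setNames(rep("everything", length(b$clades)), names(b$clades))
    et <- suppressMessages(enrichmentTable(b$otu, cls, clades))
    expect_true(all(abs(et$geometric_mean - 1) < 1e-9))
    expect_true(all(et$ci_low <= et$geometric_mean &
                    et$geometric_mean <= et$ci_high))
})

test_that("a planted deterred clade is flagged in the negative subgroup", {
    cfg <- oneExperimentConfig(
        n_otus = 500, firmicutes_weight = 0.04,
        planted = list(list(clade = "Firmicutes", compound = "dmsp",
                            beta = -3, occupancy = 1)))
    b <- simulateStudy(cfg, seed = 17)
    recs <- levelCorrelations(b$otu, "dmsp")
    cls <- classifyConsistency(recs)
    et <- suppressMessages(enrichmentTable(b$otu, cls, b$clades))
    row <- et[et$clade == "Firmicutes" & et$subgroup == "negative", ]
    expect_equal(nrow(row), 1L)
    expect_gt(row$geometric_mean, 1)
    expect_lt(row$p_value, 0.05)
    expect_equal(row$k, 5L)
    # output contract
    expect_named(et, c("clade", "compound", "subgroup", "k", "geometric_mean",
                       "ci_low", "ci_high", "chi2", "p_value", "significance",
                       "n_continuity_cells"))
})

test_that("shuffling clade labels destroys planted enrichment signal", {
    cfg <- oneExperimentConfig(
        n_otus = 500, firmicutes_weight = 0.04,
        planted = list(list(clade = "Firmicutes", compound = "dmsp",
                            beta = -3, occupancy = 1)))
    b <- simulateStudy(cfg, seed = 23)
    recs <- levelCorrelations(b$otu, "dmsp")
    cls <- classifyConsistency(recs)
    ps <- withr::with_seed(29, vapply(1:20, function(i) {
        shuf <- setNames(sample(unname(b$clades)), names(b$clades))
        et <- suppressMessages(enrichmentTable(b$otu, cls, shuf))
        et$p_value[et$clade == "Firmicutes" & et$subgroup == "negative"]
    }, 0))
    # under shuffled labels the planted signal should rarely reach p < 0.05
    expect_lte(sum(ps < 0.05), 4)
})

test_that("Benjamini-Hochberg adjustment never lowers a p-value", {
    b <- simulateStudy(oneExperimentConfig(n_otus = 200), seed = 41)
    recs <- levelCorrelations(b$otu, "dmsp")
    cls <- classifyConsistency(recs)
    raw <- suppressMessages(enrichmentTable(b$otu, cls, b$clades))
    adj <- suppressMessages(enrichmentTable(b$otu, cls, b$clades,
                                            p_adjust = "BH"))
    key <- paste(raw$clade, raw$subgroup)
    akey <- paste(adj$clade, adj$subgroup)
    ok <- !is.na(raw$p_value)
    expect_true(all(adj$p_value[match(key[ok], akey)] >= raw$p_value[ok]))
})
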