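test_that("spearmanRho recovers monotone relationships and their signs", {
    up <- spearmanRho(1:5, c(2, 4, 6, 8, 10))
    expect_equal(up$rho, 1)
    expect_identical(up$sign, "positive")
    down <- spearmanRho(1:5, c(5, 4, 3, 2, 1))
    expect_equal(down$rho, -1)
    expect_identical(down$sign, "negative")
    const <- spearmanRho(1:5, rep(2, 5))
    expect_true(is.na(const$rho))
    expect_identical(const$sign, "undefined")
    expect_error(spearmanRho(1:4, 1:5), "equal length")
})

test_that("spearmanRho agrees with a naive average-rank oracle under ties", {
    expect_equal(spearmanRho(c(1, 1, 2, 3, 3), 1:5)$rho,
                 naiveSpearman(c(1, 1, 2, 3, 3), 1:5))
    withr::with_seed(77, {
        for (i in 1:300) {
            x <- sample(1:3, 5, replace = TRUE)
            y <- sample(1:4, 5, replace = TRUE)
            ref <- naiveSpearman(x, y)
            got <- spearmanRho(x, y)
            if (is.na(ref)) expect_identical(got$sign, "undefined")
            else expect_equal(got$rho, ref)
        }
    })
})

test_that("spearmanRho is antisymmetric and monotone-invariant", {
    withr::with_seed(3, {
        for (i in 1:25) {
            x <- rnorm(6); y <- rnorm(6)
            expect_equal(spearmanRho(x, -y)$rho, -spearmanRho(x, y)$rho)
            expect_equal(spearmanRho(exp(x), y)$rho, spearmanRho(x, y)$rho)
            expect_equal(spearmanRho(x, y^3 + 2)$rho,
                         spearmanRho(x, sign(y) * abs(y))$rho)
        }
    })
})

test_that("levelCorrelations screens only detected OTUs, within levels", {
    md <- levelMeta(levels = c("A", "B"), replicates = 5,
                    conc = c(1, 2, 3, 4, 5, 5, 4, 3, 2, 1))
    # sample totals are constant within each level, so otuB's relative
    # abundance really is constant and otuA is entirely absent at level B
    counts <- rbind(
        otuA = c(10L, 20L, 30L, 40L, 50L, 0L, 0L, 0L, 0L, 0L),
        otuB = rep(3L, 10),
        otuC = c(50L, 40L, 30L, 20L, 10L, 1L, 2L, 3L, 4L, 5L),
        otuD = c(0L, 0L, 0L, 0L, 0L, 5L, 4L, 3L, 2L, 1L))
    colnames(counts) <- md$sample_id
    oe <- OtuExperiment(counts, sampleData = md)
    recs <- levelCorrelations(oe, "dmsp")
    expect_identical(sort(unique(recs$otu_id[recs$level_label == "B"])),
                     c("otuB", "otuC", "otuD"))
    expect_false("otuA" %in% recs$otu_id[recs$level_label == "B"])
    expect_true(all(recs$sign[recs$otu_id == "otuB"] == "undefined"))
    # otuC falls with concentration at both levels, otuD rises at level B
    expect_true(all(recs$sign[recs$otu_id == "otuC"] == "negative"))
    expect_identical(recs$sign[recs$otu_id == "otuD"], "positive")
    expect_error(levelCorrelations(oe, "proline"), "missing from metadata")
    expect_true(all(recs$n == 5))
})

test_that("levelCorrelations requires 3 replicates per level", {
    md <- levelMeta(levels = "A", replicates = 2, conc = c(1, 2))
    counts <- matrix(c(1L, 2L), 1, dimnames = list("o1", md$sample_id))
    oe <- OtuExperiment(counts, sampleData = md)
    expect_error(levelCorrelations(oe, "dmsp"), ">= 3 required")
})

test_that("classifyConsistency applies the sign-consistency rule", {
    rec <- function(signs, otu = "o1")
        data.frame(otu_id = otu, compound = "dmsp", experiment = "temperature",
                   level_label = paste0("L", seq_along(signs)),
                   rho = ifelse(signs == "positive", 0.5,
                                ifelse(signs == "negative", -0.5,
                                       ifelse(signs == "zero", 0, NA))),
                   n = 5, sign = signs)
    expect_identical(classifyConsistency(rec(rep("positive", 3)))$label, "positive")
    expect_identical(classifyConsistency(rec(rep("negative", 4)))$label, "negative")
    # mixed signs across levels make the OTU neutral
    expect_identical(classifyConsistency(rec(c("positive", "negative")))$label,
                     "neutral")
    # an exactly-zero rho breaks consistency
    expect_identical(classifyConsistency(rec(c("positive", "zero")))$label,
                     "neutral")
    expect_identical(classifyConsistency(rec(c("undefined", "undefined")))$label,
                     "unevaluable")
    # a single evaluable level suffices by default but not with min_levels = 2
    one <- rec(c("positive", "undefined"))
    expect_identical(classifyConsistency(one)$label, "positive")
    expect_identical(classifyConsistency(one, min_levels = 2)$label,
                     "unevaluable")
    expect_identical(classifyConsistency(one)$levels_evaluated, 1L)
})

test_that("classification is invariant to level order", {
    withr::with_seed(5, {
        signs <- sample(c("positive", "negative", "zero", "undefined"),
                        6, replace = TRUE)
        rec <- data.frame(otu_id = "o", compound = "c", experiment = "e",
                          level_label = paste0("L", 1:6), rho = 0.1,
                          n = 5, sign = signs)
        a <- classifyConsistency(rec)
        b <- classifyConsistency(rec[sample(6), ])
        expect_identical(a$label, b$label)
    })
})

test_that("subgroupFractions partitions the classified OTUs", {
    cls <- data.frame(otu_id = paste0("o", 1:10), compound = "dmsp",
                      experiment = "temperature",
                      label = rep(c("negative", "positive", "neutral"),
                                  c(3, 3, 4)),
                      levels_evaluated = 5L)
    f <- subgroupFractions(cls)
    expect_equal(unname(f), c(0.3, 0.3, 0.4, 0))
    expect_equal(sum(f), 1, tolerance = 1e-9)
    expect_equal(unname(subgroupFractions(cls[cls$label == "neutral", ])["neutral"]), 1)
    expect_error(subgroupFractions(cls[0, ]), "non-empty")
})

test_that("a strongly deterred planted OTU shows negative signs at most levels", {
    cfg <- oneExperimentConfig(
        n_otus = 300,
        planted = list(list(otus = "otu0001", compound = "dmsp",
                            beta = -2, occupancy = 1)))
    hits <- withr::with_seed(101, vapply(1:60, function(i) {
        b <- simulateStudy(cfg, seed = sample.int(1e6, 1))
        r <- levelCorrelations(b$otu, "dmsp")
        sum(r$sign[r$otu_id == "otu0001"] == "negative") >= 4L
    }, NA))
    # simulation-calibrated rate: >= 4 of 5 negative levels in ~93% of runs;
    # assert 3 Monte-Carlo SEs below that
    expect_gte(mean(hits), 0.83)
})
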