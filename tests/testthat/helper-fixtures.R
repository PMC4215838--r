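# tiny builders used across test files

toyOtu <- function(counts = matrix(c(5L, 2L, 0L, 8L, 5L, 0L), nrow = 3,
                                   dimnames = list(paste0("otu", 1:3),
                                                   c("s1", "s2"))),
                   sampleData = NULL, taxonomy = NULL) {
    OtuExperiment(counts, sampleData = sampleData, taxonomy = taxonomy)
}

# metadata for one experiment with one compound column
levelMeta <- function(experiment = "temperature",
                      levels = c("L1", "L2", "L3"),
                      replicates = 5, compound = "dmsp",
                      conc = NULL) {
    n <- length(levels) * replicates
    md <- data.frame(
        sample_id = sprintf("%s_%s_r%d", experiment,
                            rep(levels, each = replicates),
                            rep(seq_len(replicates), length(levels))),
        experiment = experiment,
        level_label = rep(levels, each = replicates),
        replicate = rep(seq_len(replicates), length(levels)))
    md[[paste0(compound, "_ng_cm2")]] <-
        if (is.null(conc)) stats::runif(n) else conc
    md
}

# independent naive Spearman oracle: integer midranks by counting, Pearson
# through explicit sums (shares no code with spearmanRho)
naiveSpearman <- function(x, y) {
    midrank <- function(v) {
        r <- numeric(length(v))
        for (i in seq_along(v))
            r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
        r
    }
    rx <- midrank(x); ry <- midrank(y)
    n <- length(x)
    num <- sum(rx * ry) - n * mean(rx) * mean(ry)
    den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
    if (den == 0) return(NA_real_)
    num / den
}

# small single-experiment simulation config used by recovery-style tests
oneExperimentConfig <- function(n_otus = 500, planted = list(),
                                firmicutes_weight = NULL) {
    cw <- NULL
    if (!is.null(firmicutes_weight)) {
        cw <- simulationConfig()$clade_weights
        others <- setdiff(names(cw), "Firmicutes")
        cw[others] <- cw[others] * (1 - firmicutes_weight) / sum(cw[others])
        cw["Firmicutes"] <- firmicutes_weight
    }
    simulationConfig(
        n_otus = n_otus,
        experiments = list(temperature = list(
            levels = c("5°C", "10°C", "15°C", "20°C", "25°C"),
            replicates = 5, depth = 1352)),
        clade_weights = cw,
        planted_effects = planted)
}
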