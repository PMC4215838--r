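.CLADE_LINEAGES <- c(
    "Rhodobacteraceae" = "k__Bacteria; p__Proteobacteria; c__Alphaproteobacteria; o__Rhodobacterales; f__Rhodobacteraceae",
    "Sphingomonadaceae" = "k__Bacteria; p__Proteobacteria; c__Alphaproteobacteria; o__Sphingomonadales; f__Sphingomonadaceae",
    "Hyphomonadaceae" = "k__Bacteria; p__Proteobacteria; c__Alphaproteobacteria; o__Rhodobacterales; f__Hyphomonadaceae",
    "unclassified Alphaproteobacteria" = "k__Bacteria; p__Proteobacteria; c__Alphaproteobacteria",
    "other Alphaproteobacteria" = "k__Bacteria; p__Proteobacteria; c__Alphaproteobacteria; o__Rickettsiales; f__Rickettsiaceae",
    "Alteromonadaceae" = "k__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__Alteromonadales; f__Alteromonadaceae",
    "Pseudoalteromonadaceae" = "k__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__Alteromonadales; f__Pseudoalteromonadaceae",
    "Colwelliaceae" = "k__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__Alteromonadales; f__Colwelliaceae",
    "Thiotrichales" = "k__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__Thiotrichales; f__Thiotrichaceae",
    "Oceanospirillales" = "k__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__Oceanospirillales; f__Oceanospirillaceae",
    "other Gammaproteobacteria" = "k__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__Vibrionales; f__Vibrionaceae",
    "Betaproteobacteria" = "k__Bacteria; p__Proteobacteria; c__Betaproteobacteria; o__Burkholderiales",
    "Deltaproteobacteria" = "k__Bacteria; p__Proteobacteria; c__Deltaproteobacteria; o__Myxococcales",
    "unclassified Proteobacteria" = "k__Bacteria; p__Proteobacteria",
    "other Proteobacteria" = "k__Bacteria; p__Proteobacteria; c__Epsilonproteobacteria",
    "Flavobacteriaceae" = "k__Bacteria; p__Bacteroidetes; c__Flavobacteriia; o__Flavobacteriales; f__Flavobacteriaceae",
    "other Flavobacteriia" = "k__Bacteria; p__Bacteroidetes; c__Flavobacteriia; o__Flavobacteriales; f__Cryomorphaceae",
    "Saprospiraceae" = "k__Bacteria; p__Bacteroidetes; c__Saprospirae; o__Saprospirales; f__Saprospiraceae",
    "other Bacteroidetes" = "k__Bacteria; p__Bacteroidetes; c__Cytophagia; o__Cytophagales; f__Flammeovirgaceae",
    "Firmicutes" = "k__Bacteria; p__Firmicutes; c__Bacilli; o__Bacillales; f__Bacillaceae",
    "Actinobacteria" = "k__Bacteria; p__Actinobacteria; c__Actinobacteria",
    "Cyanobacteria" = "k__Bacteria; p__Cyanobacteria; c__Synechococcophycideae",
    "Planctomycetes" = "k__Bacteria; p__Planctomycetes; c__Planctomycetia",
    "Verrucomicrobia" = "k__Bacteria; p__Verrucomicrobia; c__Verrucomicrobiae",
    "other phyla" = "k__Bacteria; p__Chloroflexi; c__Anaerolineae",
    "unclassified" = "k__Bacteria"
)

#' Default simulation configuration
#'
#' Describes a full synthetic study mirroring the design the analysis
#' expects: a temperature experiment (5 levels x 5 replicates, 1352 reads
#' per sample) and a light experiment (6 levels x 5 replicates, 1024 reads
#' per sample); per-level metabolite concentrations drawn lognormal around
#' the measured condition means and SDs ([conditionMeans()]); a community
#' of `n_otus` OTUs with lognormal (long-tailed) base intensities, per-OTU
#' occupancy thinning so most OTUs are absent from most samples, clades
#' allocated over the default 26-clade scheme with Rhodobacteraceae and
#' Flavobacteriaceae dominating, and a configurable list of planted
#' abundance-concentration couplings.
#'
#' @param n_otus number of OTUs (default 2000).
#' @param experiments named list; each element has `levels` (character),
#'   `replicates` and `depth`.
#' @param concentration_table data.frame as [conditionMeans()] giving the
#'   per-level mean and SD used by the lognormal concentration model.
#' @param conc_cv optional coefficient of variation overriding the table's
#'   SDs (0 makes every replicate equal to its level mean).
#' @param base_sigma sdlog of the lognormal OTU intensity distribution
#'   (default 2, giving a long-tailed rank-abundance curve).
#' @param occupancy_shape1,occupancy_shape2 Beta parameters of the per-OTU
#'   detection probability (defaults 0.5 and 1, mean 1/3).
#' @param clade_weights named numeric of expected clade shares (normalized
#'   internally); names must be clades of [defaultCladeScheme()].
#' @param planted_effects list of effects, each a list with `compound`,
#'   `beta` (effect size on the log-intensity scale; negative = deterred,
#'   positive = attracted), and either `clade` or `otus`, plus optional
#'   `occupancy` (set to 1 for fully occupant responders).
#' @param dirichlet_scale optional positive number adding Dirichlet
#'   overdispersion to the multinomial counts (larger = less noise; `NULL`,
#'   the default, is plain multinomial sampling).
#' @return configuration list accepted by [simulateStudy()].
#' @export
simulationConfig <- function(n_otus = 2000,
                             experiments = list(
                                 temperature = list(
                                     levels = c("5°C", "10°C", "15°C", "20°C", "25°C"),
                                     replicates = 5, depth = 1352),
                                 light = list(
                                     levels = c("0%", "5%", "13%", "23%", "44%", "100%"),
                                     replicates = 5, depth = 1024)),
                             concentration_table = conditionMeans(),
                             conc_cv = NULL,
                             base_sigma = 2,
                             occupancy_shape1 = 0.5, occupancy_shape2 = 1,
                             clade_weights = NULL,
                             planted_effects = list(),
                             dirichlet_scale = NULL) {
    if (!is.null(conc_cv) && conc_cv < 0) stop("conc_cv must be >= 0")
    if (n_otus < 1) stop("n_otus must be >= 1")
    for (e in experiments)
        if (e$depth < 1) stop("depth must be >= 1")
    if (is.null(clade_weights)) {
        clade_weights <- c(
            "Rhodobacteraceae" = 0.22, "Flavobacteriaceae" = 0.18,
            "Saprospiraceae" = 0.08, "other Alphaproteobacteria" = 0.06,
            "unclassified Alphaproteobacteria" = 0.03,
            "other Gammaproteobacteria" = 0.06, "Alteromonadaceae" = 0.03,
            "Pseudoalteromonadaceae" = 0.02, "Colwelliaceae" = 0.01,
            "Thiotrichales" = 0.02, "Oceanospirillales" = 0.02,
            "Betaproteobacteria" = 0.02, "Deltaproteobacteria" = 0.01,
            "unclassified Proteobacteria" = 0.04,
            "other Proteobacteria" = 0.01, "Sphingomonadaceae" = 0.02,
            "Hyphomonadaceae" = 0.01, "other Flavobacteriia" = 0.03,
            "other Bacteroidetes" = 0.03, "Firmicutes" = 0.02,
            "Actinobacteria" = 0.02, "Cyanobacteria" = 0.02,
            "Planctomycetes" = 0.02, "Verrucomicrobia" = 0.02,
            "other phyla" = 0.02, "unclassified" = 0.02)
    }
    bad <- setdiff(names(clade_weights), names(.CLADE_LINEAGES))
    if (length(bad)) stop("unknown clade(s): ", paste(bad, collapse = ", "))
    list(n_otus = n_otus, experiments = experiments,
         concentration_table = concentration_table, conc_cv = conc_cv,
         base_sigma = base_sigma, occupancy_shape1 = occupancy_shape1,
         occupancy_shape2 = occupancy_shape2,
         clade_weights = clade_weights / sum(clade_weights),
         planted_effects = planted_effects,
         dirichlet_scale = dirichlet_scale)
}

#' Draw per-sample surface concentrations
#'
#' For every replicate of every treatment level, draws each compound's
#' concentration from a lognormal distribution moment-matched to the
#' level's mean and SD (from the configuration's concentration table, or
#' with SD = `conc_cv` x mean when a CV override is set). `conc_cv = 0`
#' makes every replicate equal to its level mean.
#'
#' @param config a [simulationConfig()] list.
#' @param seed integer seed; identical seeds give identical draws.
#' @return sample metadata `data.frame` with columns `sample_id`,
#'   `experiment`, `level_label`, `replicate` and one `<compound>_ng_cm2`
#'   column per compound in the concentration table.
#' @export
generateConcentrations <- function(config, seed = 1L) {
    tab <- config$concentration_table
    compounds <- unique(tab$compound)
    rows <- list()
    withr::with_seed(seed, {
        for (exper in names(config$experiments)) {
            ex <- config$experiments[[exper]]
            for (lvl in ex$levels) {
                for (r in seq_len(ex$replicates)) {
                    rec <- list(sample_id = sprintf("%s_%s_r%d", exper, lvl, r),
                                experiment = exper, level_label = lvl,
                                replicate = r)
                    for (comp in compounds) {
                        sel <- tab$experiment == exper &
                            tab$level_label == lvl & tab$compound == comp
                        if (!any(sel))
                            stop("no concentration entry for ", exper, "/",
                                 lvl, "/", comp)
                        mu <- tab$mean[sel][1L]
                        sdv <- if (is.null(config$conc_cv)) tab$sd[sel][1L]
                               else config$conc_cv * mu
                        val <- if (sdv == 0 || mu == 0) mu else {
                            sdlog2 <- log(1 + (sdv / mu)^2)
                            stats::rlnorm(1, meanlog = log(mu) - sdlog2 / 2,
                                          sdlog = sqrt(sdlog2))
                        }
                        rec[[paste0(comp, "_ng_cm2")]] <- val
                    }
                    rows[[length(rows) + 1L]] <- as.data.frame(rec)
                }
            }
        }
    })
    do.call(rbind, rows)
}

# deterministic largest-remainder allocation of n_otus over clade weights
.allocateClades <- function(n_otus, weights) {
    raw <- weights * n_otus
    base <- floor(raw)
    rem <- n_otus - sum(base)
    if (rem > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
    }
    rep(names(weights), base)
}

#' Generate a synthetic OTU community coupled to the concentrations
#'
#' Per sample, each OTU's expected intensity is its lognormal base
#' intensity, thinned by a Bernoulli occupancy draw; planted responder
#' OTUs' intensity is multiplied by `exp(beta * z)` where `z` is the
#' within-level z-score of the sample's concentration of the targeted
#' compound (so planted effects act on the within-level screen, not on
#' across-level trends). Counts are a multinomial draw of the experiment's
#' depth over the normalized intensities, so every sample sums exactly to
#' its depth.
#'
#' @param config a [simulationConfig()] list.
#' @param metadata output of [generateConcentrations()].
#' @param seed integer seed.
#' @return list with `otu` (an [OtuExperiment-class] carrying counts,
#'   metadata and taxonomy), `taxonomy` (`data.frame` `otu_id`, `lineage`),
#'   `clades` (named vector otu_id -> clade) and `truth` (`data.frame`
#'   `otu_id`, `compound`, `direction` for every planted responder).
#' @export
generateCommunity <- function(config, metadata, seed = 1L) {
    n <- config$n_otus
    otu_ids <- sprintf("otu%04d", seq_len(n))
    clades <- stats::setNames(.allocateClades(n, config$clade_weights), otu_ids)
    taxonomy <- data.frame(otu_id = otu_ids,
                           lineage = unname(.CLADE_LINEAGES[clades]),
                           stringsAsFactors = FALSE)
    # planted effect bookkeeping: beta matrix OTU x compound
    compounds <- sub("_ng_cm2$", "",
                     grep("_ng_cm2$", colnames(metadata), value = TRUE))
    beta <- matrix(0, n, length(compounds),
                   dimnames = list(otu_ids, compounds))
    occOverride <- rep(NA_real_, n)
    truth <- list()
    for (eff in config$planted_effects) {
        target <- if (!is.null(eff$otus)) eff$otus
                  else otu_ids[clades == eff$clade]
        if (!length(target)) stop("planted effect matches no OTU")
        if (!all(target %in% otu_ids))
            stop("planted effect references unknown OTU(s)")
        if (!eff$compound %in% compounds)
            stop("planted compound '", eff$compound, "' not in metadata")
        beta[target, eff$compound] <- beta[target, eff$compound] + eff$beta
        if (!is.null(eff$occupancy)) occOverride[match(target, otu_ids)] <- eff$occupancy
        truth[[length(truth) + 1L]] <- data.frame(
            otu_id = target, compound = eff$compound,
            direction = if (eff$beta < 0) "deterred" else "attracted",
            beta = eff$beta, stringsAsFactors = FALSE)
    }
    truth <- if (length(truth)) do.call(rbind, truth)
             else data.frame(otu_id = character(), compound = character(),
                             direction = character(), beta = numeric())
    # within-level z-scores of each compound
    z <- matrix(0, nrow(metadata), length(compounds),
                dimnames = list(metadata$sample_id, compounds))
    for (comp in compounds) {
        v <- metadata[[paste0(comp, "_ng_cm2")]]
        key <- paste(metadata$experiment, metadata$level_label)
        mu <- stats::ave(v, key)
        sdv <- stats::ave(v, key, FUN = stats::sd)
        z[, comp] <- ifelse(sdv > 0, (v - mu) / sdv, 0)
    }
    counts <- matrix(0L, n, nrow(metadata),
                     dimnames = list(otu_ids, metadata$sample_id))
    withr::with_seed(seed, {
        lambda <- stats::rlnorm(n, 0, config$base_sigma)
        occ <- stats::rbeta(n, config$occupancy_shape1, config$occupancy_shape2)
        occ[!is.na(occOverride)] <- occOverride[!is.na(occOverride)]
        depth <- vapply(metadata$experiment,
                        function(e) config$experiments[[e]]$depth, 0)
        for (s in seq_len(nrow(metadata))) {
            present <- stats::rbinom(n, 1L, occ)
            mult <- exp(as.vector(beta %*% z[s, ]))
            w <- lambda * present * mult
            if (sum(w) == 0) w <- lambda * mult
            if (!is.null(config$dirichlet_scale))
                w <- stats::rgamma(n, shape = w * config$dirichlet_scale)
            counts[, s] <- stats::rmultinom(1L, size = depth[s], prob = w)[, 1L]
        }
    })
    oe <- OtuExperiment(counts, sampleData = metadata, taxonomy = taxonomy)
    list(otu = oe, taxonomy = taxonomy, clades = clades, truth = truth)
}

#' Simulate a complete study
#'
#' Convenience wrapper: draws concentrations and the coupled community in
#' one call.
#'
#' @param config a [simulationConfig()] list.
#' @param seed integer seed; concentrations and community use seeds derived
#'   from it.
#' @return list as [generateCommunity()] plus `metadata` and `config`.
#' @export
simulateStudy <- function(config = simulationConfig(), seed = 1L) {
    metadata <- generateConcentrations(config, seed = seed)
    bundle <- generateCommunity(config, metadata, seed = seed + 1L)
    c(bundle, list(metadata = metadata, config = config, seed = seed))
}

#' Write a simulated study to disk as the pipeline's input files
#'
#' Emits `otu_table.tsv`, `metadata.tsv`, `taxonomy.tsv` and
#' `ground_truth.tsv` in the exact formats the readers consume; re-reading
#' reproduces the bundle.
#'
#' @param bundle output of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeFixture <- function(bundle, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(otu_table = file.path(dir, "otu_table.tsv"),
               metadata = file.path(dir, "metadata.tsv"),
               taxonomy = file.path(dir, "taxonomy.tsv"),
               ground_truth = file.path(dir, "ground_truth.tsv"))
    writeOtuTable(bundle$otu, paths["otu_table"])
    utils::write.table(bundle$metadata, paths["metadata"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(bundle$taxonomy, paths["taxonomy"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(bundle$truth, paths["ground_truth"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(paths)
}
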