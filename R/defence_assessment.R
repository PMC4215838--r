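#' Mean surface concentrations per treatment condition
#'
#' The measured mean (and SD) surface concentrations of DMSP, proline and
#' fucoxanthin on apical tips under each temperature (5–25 °C) and light
#' (0–100% of sunlight) condition, in ng cm^-2.
#'
#' @return `data.frame` with columns `experiment`, `level_label`,
#'   `compound`, `mean`, `sd`.
#' @export
conditionMeans <- function() {
    tl <- c("5°C", "10°C", "15°C", "20°C", "25°C")
    ll <- c("0%", "5%", "13%", "23%", "44%", "100%")
    rbind(
        data.frame(experiment = "temperature", level_label = tl,
                   compound = "dmsp",
                   mean = c(0.46, 0.17, 0.59, 0.96, 0.16),
                   sd = c(0.30, 0.07, 0.75, 0.76, 0.13)),
        data.frame(experiment = "temperature", level_label = tl,
                   compound = "proline",
                   mean = c(0.009, 0.006, 0.01, 0.004, 0.004),
                   sd = c(0.002, 0.003, 0.006, 0.001, 0.001)),
        data.frame(experiment = "temperature", level_label = tl,
                   compound = "fucoxanthin",
                   mean = c(18, 29, 74, 84, 400),
                   sd = c(11.08, 6.81, 37.84, 22.53, 187.04)),
        data.frame(experiment = "light", level_label = ll,
                   compound = "dmsp",
                   mean = c(0.45, 0.1, 0.17, 0.1, 0.03, 0.3),
                   sd = c(0.43, 0.04, 0.10, 0.09, 0.16, 0.57)),
        data.frame(experiment = "light", level_label = ll,
                   compound = "proline",
                   mean = c(0.01, 0.025, 0.02, 0.03, 0.02, 0.03),
                   sd = c(0.006, 0.01, 0.04, 0.12, 0.17, 0.39)),
        data.frame(experiment = "light", level_label = ll,
                   compound = "fucoxanthin",
                   mean = c(159, 206, 150, 353, 146, 192),
                   sd = c(84.36, 63, 187, 94, 101, 85.21))
    )
}

#' Bundled EC50 table for the bacterial strain panel
#'
#' Previously determined concentrations causing half-maximal settlement
#' inhibition of five marine bacterial isolates from rockweed-dominated
#' Baltic habitats. DMSP inhibits four of the strains at 0.05 ng cm^-2 while
#' *Cytophaga* sp. requires 0.38 ng cm^-2; proline EC50s span 0.01–0.13
#' ng cm^-2 across the four less resistant strains (*Cytophaga* sp. is more
#' resistant still and has no published value, so it carries no proline
#' row); fucoxanthin EC50s span 1.4–6 µg cm^-2, with isolate ISA 7311 at
#' 6 µg cm^-2. Where only a panel range is published, `ec50_min`/`ec50_max`
#' bracket it per strain. All values are stored in ng cm^-2.
#'
#' @return `data.frame` with columns `strain`, `compound`, `ec50_min`,
#'   `ec50_max` (ng cm^-2).
#' @export
defaultEc50Table <- function() {
    s4 <- c("Bacillus aquimaris", "Ulvibacter littoralis",
            "Alteromonadaceae E1", "ISA 7311")
    rbind(
        data.frame(strain = s4, compound = "dmsp",
                   ec50_min = 0.05, ec50_max = 0.05),
        data.frame(strain = "Cytophaga sp.", compound = "dmsp",
                   ec50_min = 0.38, ec50_max = 0.38),
        data.frame(strain = s4, compound = "proline",
                   ec50_min = 0.01, ec50_max = 0.13),
        data.frame(strain = c("Ulvibacter littoralis", "Alteromonadaceae E1",
                              "Cytophaga sp.", "Bacillus aquimaris"),
                   compound = "fucoxanthin",
                   ec50_min = 1400, ec50_max = 6000),
        data.frame(strain = "ISA 7311", compound = "fucoxanthin",
                   ec50_min = 6000, ec50_max = 6000)
    )
}

#' Read an EC50 table from TSV
#'
#' Columns: `strain`, `compound`, `ec50_value` (or `ec50_min`/`ec50_max`),
#' `ec50_unit` (`ng_cm2` or `ug_cm2`). Values are normalized to ng cm^-2 on
#' ingest.
#'
#' @param path TSV file path.
#' @return `data.frame` with columns `strain`, `compound`, `ec50_min`,
#'   `ec50_max` in ng cm^-2.
#' @export
readEc50Table <- function(path) {
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    if ("ec50_value" %in% colnames(df)) {
        df$ec50_min <- df$ec50_value
        df$ec50_max <- df$ec50_value
    }
    need <- c("strain", "compound", "ec50_min", "ec50_max", "ec50_unit")
    if (!all(need %in% colnames(df)))
        stop("EC50 table needs columns: ", paste(need, collapse = ", "))
    fac <- ifelse(df$ec50_unit == "ug_cm2", 1000,
                  ifelse(df$ec50_unit == "ng_cm2", 1, NA))
    if (anyNA(fac)) stop("ec50_unit must be 'ng_cm2' or 'ug_cm2'")
    df$ec50_min <- df$ec50_min * fac
    df$ec50_max <- df$ec50_max * fac
    if (any(df$ec50_min <= 0)) stop("EC50 values must be positive")
    df[, c("strain", "compound", "ec50_min", "ec50_max")]
}

#' Threshold inhibition call
#'
#' A condition is called inhibitory for a strain when the mean surface
#' concentration reaches the strain's EC50, boundary inclusive.
#'
#' @param mean_conc mean surface concentration(s), ng cm^-2.
#' @param ec50 EC50 value(s), ng cm^-2.
#' @return logical: `mean_conc >= ec50`.
#' @export
inhibitionCall <- function(mean_conc, ec50) {
    if (any(mean_conc < 0) || any(ec50 <= 0))
        stop("concentrations must be >= 0 and EC50 > 0")
    mean_conc >= ec50
}

#' Strain x compound x condition inhibition matrix
#'
#' Crosses every (strain, compound) EC50 with every treatment condition's
#' mean concentration of that compound and records threshold calls. For
#' EC50s published as a range, `inhibited` uses the range minimum (the most
#' sensitive reading) and `inhibited_at_max` the range maximum.
#'
#' @param means condition means as from [conditionMeans()] (columns
#'   `experiment`, `level_label`, `compound`, `mean`).
#' @param ec50s EC50 table as from [defaultEc50Table()] (ng cm^-2).
#' @return `data.frame` with columns `strain`, `compound`, `experiment`,
#'   `level_label`, `mean`, `ec50_min`, `ec50_max`, `inhibited`,
#'   `inhibited_at_max`. Strain/compound pairs absent from `ec50s` are
#'   simply not represented.
#' @export
strainMatrix <- function(means = conditionMeans(), ec50s = defaultEc50Table()) {
    if (!nrow(ec50s))
        return(data.frame(strain = character(), compound = character(),
                          experiment = character(), level_label = character(),
                          mean = numeric(), ec50_min = numeric(),
                          ec50_max = numeric(), inhibited = logical(),
                          inhibited_at_max = logical()))
    out <- merge(ec50s, means, by = "compound")
    missing <- setdiff(ec50s$compound, means$compound)
    if (length(missing))
        message("no condition means for compound(s): ",
                paste(missing, collapse = ", "), "; entries omitted")
    out$inhibited <- inhibitionCall(out$mean, out$ec50_min)
    out$inhibited_at_max <- inhibitionCall(out$mean, out$ec50_max)
    out[, c("strain", "compound", "experiment", "level_label", "mean",
            "ec50_min", "ec50_max", "inhibited", "inhibited_at_max")]
}

#' Defence sufficiency per treatment condition
#'
#' Summarizes an inhibition matrix per condition: how many (strain,
#' compound) pairs are called inhibited, and whether at least one compound
#' inhibits at least one strain (`any_defence`) — i.e. whether the alga's
#' chemical defence remains effective against some part of the fouler panel
#' under that condition.
#'
#' @param matrix output of [strainMatrix()].
#' @param use_max use the EC50 range-maximum calls instead of the default
#'   range-minimum calls.
#' @return `data.frame` with columns `experiment`, `level_label`,
#'   `n_inhibited`, `n_pairs`, `any_defence`.
#' @export
sufficiencySummary <- function(matrix, use_max = FALSE) {
    if (!nrow(matrix)) stop("empty inhibition matrix")
    call <- if (use_max) matrix$inhibited_at_max else matrix$inhibited
    key <- interaction(matrix$experiment, matrix$level_label, drop = TRUE)
    agg <- data.frame(
        experiment = tapply(matrix$experiment, key, `[`, 1L),
        level_label = tapply(matrix$level_label, key, `[`, 1L),
        n_inhibited = as.integer(tapply(call, key, sum)),
        n_pairs = as.integer(tapply(call, key, length)))
    agg$any_defence <- agg$n_inhibited >= 1L
    rownames(agg) <- NULL
    agg
}
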